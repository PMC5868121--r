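test_that("one-way ANOVA matches hand computation and the aov oracle", {
  r <- anova_f(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(r$f, 8)         # SSB = 4 (df 1), SSW = 1 (df 2)
  expect_equal(r$df_between, 1)
  expect_equal(r$df_within, 2)

  expect_equal(anova_f(c(1, 2, 1, 2), c("a", "a", "b", "b"))$f, 0)

  # zero within-class variance, distinct means
  z <- anova_f(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  expect_equal(z$f, Inf)
  expect_equal(z$p, 0)

  set.seed(21)
  for (k in 1:100) {
    n_per <- sample(3:8, 1)
    g <- rep(letters[1:sample(2:6, 1)], each = n_per)
    x <- rnorm(length(g), mean = as.integer(factor(g)) * runif(1))
    mine <- anova_f(x, g)
    oracle <- summary(aov(x ~ g))[[1]]
    expect_equal(mine$f, oracle$`F value`[1], tolerance = 1e-10)
    expect_equal(mine$p, oracle$`Pr(>F)`[1], tolerance = 1e-10)
  }

  # matrix form agrees with the scalar form
  xm <- matrix(rnorm(60), 12, 5)
  g <- rep(c("a", "b", "c"), each = 4)
  vf <- anova_f(xm, g)
  for (j in 1:5) expect_equal(vf$f[j], anova_f(xm[, j], g)$f)
})

test_that("the one-vs-one ensemble has C(k,2) members and separates blobs", {
  set.seed(22)
  classes <- c("anger", "disgust", "fear", "joy", "sadness", "surprise")
  y <- rep(classes, each = 10)
  centers <- 10 * diag(6)
  x <- centers[as.integer(factor(y)), ] + matrix(rnorm(60 * 6, sd = 0.3),
                                                 60, 6)
  mod <- train_pairwise_ensemble(x, y, decoding_spec())
  expect_length(mod$models, 15)
  expect_equal(predict_vote(mod, x), y) # separable: perfect training fit

  v <- predict_vote(mod, x, type = "votes")
  expect_true(all(rowSums(v$votes) == 15))

  two <- train_pairwise_ensemble(x[y %in% classes[1:2], ],
                                 y[y %in% classes[1:2]], decoding_spec())
  expect_length(two$models, 1)

  expect_error(train_pairwise_ensemble(x[y != "joy", ],
                                       factor(y[y != "joy"],
                                              levels = classes),
                                       decoding_spec()),
               "missing class")
})

test_that("vote ties are broken by summed signed margins", {
  # three tight clusters at the corners of a triangle produce cyclic
  # pairwise decisions (1-1-1 vote ties) for points near the centroid
  set.seed(23)
  ang <- c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3)
  centers <- cbind(cos(ang), sin(ang))
  y <- rep(c("a", "b", "c"), each = 15)
  x <- centers[as.integer(factor(y)), ] +
    matrix(rnorm(90, sd = 0.05), 45, 2)
  mod <- train_pairwise_ensemble(x, y, decoding_spec())
  grid <- as.matrix(expand.grid(x = seq(-0.2, 0.2, length.out = 41),
                                y = seq(-0.2, 0.2, length.out = 41)))
  v <- predict_vote(mod, grid, type = "votes")
  tied <- which(apply(v$votes, 1, max) == 1)
  expect_gt(length(tied), 0)
  pred <- predict_vote(mod, grid)
  for (s in tied) {
    expect_equal(pred[s], mod$levels[which.max(v$margins[s, ])])
  }
  # lowest-index rule picks the first tied class instead
  mod2 <- mod
  mod2$tie_break <- "lowest_index"
  pred2 <- predict_vote(mod2, grid)
  for (s in tied) {
    expect_equal(pred2[s],
                 mod$levels[which(v$votes[s, ] == max(v$votes[s, ]))[1]])
  }
})

test_that("leave-one-subject-out decoding has the right fold structure", {
  samp <- make_z_samples(18, 120, effect = 0.5,
                         signal_edges = list(anger = 1:5, disgust = 6:10,
                                             fear = 11:15, joy = 16:20,
                                             sadness = 21:25,
                                             surprise = 26:30),
                         seed = 24)
  res <- loocv_decode(samp, decoding_spec())
  expect_length(res$selected_features, 18)
  expect_equal(nrow(res$predictions), 108)
  expect_equal(sum(res$confusion), 108)
  # pooled accuracy equals the confusion-trace accuracy exactly
  expect_equal(res$accuracy, sum(diag(res$confusion)) / sum(res$confusion))
  # and equals the mean of per-fold accuracies (folds are equal-sized)
  fold_acc <- tidy(res) |>
    dplyr::group_by(left_out_subject) |>
    dplyr::summarise(acc = mean(correct))
  expect_equal(res$accuracy, mean(fold_acc$acc))
  # every test sample belongs to the left-out subject
  expect_true(all(res$predictions$left_out_subject ==
                    rep(unique(samp$subject_id), each = 6)))
  # planted signal: well above chance
  expect_gt(res$accuracy, 0.5)
})

test_that("fold-internal selection never sees the held-out subject", {
  # every fold's selected set must equal an independent re-selection
  # computed on the training subjects alone
  samp <- make_z_samples(8, 80, effect = 0.4,
                         signal_edges = list(anger = 1:3, joy = 4:6),
                         noise_sd = 0.2, seed = 25)
  spec <- decoding_spec()
  res <- loocv_decode(samp, spec)
  for (s in unique(samp$subject_id)) {
    tr <- samp$subject_id != s
    an <- anova_f(samp$x[tr, , drop = FALSE], samp$expression[tr])
    oracle <- which(an$p < spec$anova_alpha)
    expect_identical(res$selected_features[[s]], oracle)
  }
  # a feature that varies only in the held-out subject is invisible to
  # that fold's selection (training column is constant, F = 0)
  k <- 70
  samp$x[, k] <- 0
  rows <- samp$subject_id == "sub-03"
  samp$x[rows, k] <- as.integer(factor(samp$expression[rows])) * 10
  res2 <- loocv_decode(samp, spec)
  expect_false(k %in% res2$selected_features[["sub-03"]])
})

test_that("selection bias inflates accuracy when the guard is removed", {
  # deliberately leaky variant (test-only): feature selection on ALL
  # subjects including the held-out one, then LOOCV without re-selection
  leaky_decode <- function(samples, spec) {
    an <- anova_f(samples$x, samples$expression)
    mask <- an$p < 0.05
    sp <- spec
    sp$anova_alpha <- 1
    loocv_decode(samples, sp, mask)
  }
  accs <- vapply(1:3, function(s) {
    samp <- make_z_samples(18, 1000, effect = 0, seed = 300 + s)
    c(honest = loocv_decode(samp, decoding_spec())$accuracy,
      leaky = leaky_decode(samp, decoding_spec())$accuracy)
  }, numeric(2))
  chance_upper <- qbinom(0.975, 108, 1 / 6) / 108
  expect_lte(mean(accs["honest", ]), chance_upper)
  expect_true(all(accs["leaky", ] > chance_upper))
  expect_gt(min(accs["leaky", ]) - max(accs["honest", ]), 0.1)
})

test_that("zero selected features falls back to the full feature space", {
  samp <- make_z_samples(6, 30, effect = 0, seed = 26)
  spec <- decoding_spec(anova_alpha = 1e-12)
  res <- loocv_decode(samp, spec)
  expect_equal(sort(res$fallback_folds), sort(unique(samp$subject_id)))
  expect_true(all(vapply(res$selected_features, length, integer(1)) == 30))
})

test_that("permutation test is deterministic and counts exactly", {
  samp <- make_z_samples(8, 60, effect = 0.6,
                         signal_edges = list(anger = 1:4, disgust = 5:8,
                                             fear = 9:12, joy = 13:16,
                                             sadness = 17:20,
                                             surprise = 21:24),
                         seed = 27)
  spec <- decoding_spec(n_permutations = 30, seed = 99)
  r1 <- permutation_test(samp, spec)
  r2 <- permutation_test(samp, spec)
  expect_identical(r1$permutation_null, r2$permutation_null)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$predictions, r2$predictions)

  # p is exactly the count fraction (0 allowed when no null reaches it)
  expect_equal(r1$p_value,
               sum(r1$permutation_null >= r1$accuracy) / 30)

  spec_s <- decoding_spec(n_permutations = 30, seed = 99, smoothed_p = TRUE)
  r3 <- permutation_test(samp, spec_s)
  expect_equal(r3$p_value,
               (sum(r3$permutation_null >= r3$accuracy) + 1) / 31)

  other <- permutation_test(samp, decoding_spec(n_permutations = 30,
                                                seed = 100))
  expect_false(identical(r1$permutation_null, other$permutation_null))
})

test_that("consensus networks are exact per-fold intersections", {
  fake <- structure(list(
    selected_features = list(s1 = c(1L, 2L, 5L, 9L),
                             s2 = c(2L, 5L, 7L, 9L),
                             s3 = c(2L, 3L, 5L, 9L, 10L)),
    n_rois = 6, condition = "static"
  ), class = "decoding_result")
  net <- consensus_network(fake)
  brute <- Reduce(intersect, fake$selected_features)
  expect_setequal(net$edges$edge, brute)
  expect_true(all(net$edges$n_folds_selected == 3))
  expect_equal(sum(net$node_degrees$degree), 2 * nrow(net$edges))

  # identical selections: consensus is that set
  same <- fake
  same$selected_features <- list(a = c(1L, 4L), b = c(1L, 4L))
  expect_setequal(consensus_network(same)$edges$edge, c(1L, 4L))

  # disjoint selections: valid empty network
  none <- fake
  none$selected_features <- list(a = 1L, b = 2L)
  net0 <- consensus_network(none)
  expect_equal(nrow(net0$edges), 0)
  expect_true(all(net0$node_degrees$degree == 0))

  # atlas labels attach to nodes
  net_lab <- consensus_network(fake, atlas_table(6))
  expect_true(all(grepl("^ROI_", net_lab$edges$label_i)))
})

test_that("tidiers and plots summarize decoding results faithfully", {
  samp <- make_z_samples(6, 40, effect = 0.8,
                         signal_edges = list(anger = 1:3, disgust = 4:6,
                                             fear = 7:9, joy = 10:12,
                                             sadness = 13:15,
                                             surprise = 16:18),
                         seed = 28)
  res <- permutation_test(samp, decoding_spec(n_permutations = 10,
                                              seed = 1))
  td <- tidy(res)
  expect_equal(nrow(td), 36)
  expect_equal(mean(td$correct), res$accuracy)
  gl <- glance(res)
  expect_equal(gl$accuracy, res$accuracy)
  expect_equal(gl$p_value, res$p_value)
  expect_s3_class(autoplot(res), "ggplot")
  net <- consensus_network(res)
  expect_s3_class(glance(net), "tbl_df")
  if (nrow(net$edges) > 0) {
    expect_s3_class(autoplot(net), "ggplot")
  }
  expect_s3_class(plot_confusion(res), "ggplot")
})

test_that("the ensemble agrees with an independent LIBSVM reference", {
  set.seed(29)
  # binary decision values match e1071::svm exactly (same solver, two
  # independent call paths)
  for (k in 1:20) {
    n <- sample(10:40, 1)
    p <- sample(2:30, 1)
    y <- factor(sample(c("a", "b"), n, replace = TRUE))
    while (nlevels(droplevels(y)) < 2) {
      y <- factor(sample(c("a", "b"), n, replace = TRUE))
    }
    x <- matrix(rnorm(n * p), n, p) + as.integer(y)
    mine <- fcdecoder:::fit_linear_binary_svm(x, y, cost = 1)
    ref <- e1071::svm(x, y, kernel = "linear", cost = 1, scale = FALSE)
    pr <- predict(ref, x, decision.values = TRUE)
    dv_ref <- attr(pr, "decision.values")
    dv_mine <- drop(x %*% mine$w) - mine$rho
    lab <- strsplit(colnames(dv_ref)[1], "/", fixed = TRUE)[[1]]
    if (lab[1] != mine$positive) dv_mine <- -dv_mine
    expect_equal(unname(dv_ref[, 1]), unname(dv_mine), tolerance = 1e-8)
  }

  # multiclass predictions match e1071's own one-vs-one voting away from
  # vote ties (tie rules differ by design)
  y6 <- rep(c("anger", "disgust", "fear", "joy", "sadness", "surprise"),
            each = 8)
  x6 <- 3 * diag(6)[as.integer(factor(y6)), ] +
    matrix(rnorm(48 * 6, sd = 0.5), 48, 6)
  mod <- train_pairwise_ensemble(x6, y6, decoding_spec())
  ref6 <- e1071::svm(scale(x6), factor(y6), kernel = "linear", cost = 1,
                     scale = FALSE)
  v <- predict_vote(mod, x6, type = "votes")
  clear <- apply(v$votes, 1, function(r) sum(r == max(r)) == 1)
  mine6 <- predict_vote(mod, x6)
  expect_equal(mine6[clear],
               as.character(predict(ref6, scale(x6)))[clear])
  expect_gt(mean(clear), 0.8)
})

test_that("nested positivity rebuilds the feature space per training fold", {
  samp <- make_z_samples(8, 60, effect = 0.5,
                         signal_edges = list(anger = 1:5, joy = 6:10),
                         noise_sd = 0.2, seed = 33)
  # shift half the edges negative so positivity actually filters
  samp$x[, 31:60] <- samp$x[, 31:60] - 1
  spec <- decoding_spec(nested_positivity = TRUE, positive_q = 0.05)
  res <- loocv_decode(samp, spec)
  for (s in unique(samp$subject_id)) {
    tr <- samp$subject_id != s
    xtr <- samp$x[tr, , drop = FALSE]
    ytr <- samp$expression[tr]
    pos <- Reduce(`|`, lapply(unique(ytr), function(cl) {
      st <- one_sample_t(xtr[ytr == cl, , drop = FALSE])
      st$t > 0 & bh_fdr(st$p) <= 0.05
    }))
    # every selected feature lies inside that fold's own positive set
    expect_true(all(res$selected_features[[s]] %in% which(pos)))
    expect_false(any(res$selected_features[[s]] %in% 31:60))
  }
  # and the fixed-space default can pick negative-mean edges if told to
  res_fixed <- loocv_decode(samp, decoding_spec())
  expect_s3_class(res_fixed$predictions, "tbl_df")
})
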