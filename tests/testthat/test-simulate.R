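test_that("ground-truth covariances are valid and carry the planted effect", {
  spec <- cohort_spec(n_subjects = 2, n_rois = 20,
                      n_signal_edges_per_class = 8,
                      class_effect_size = 0.3)
  truth <- make_class_covariances(spec)

  for (m in c(list(truth$base), truth$class_cov)) {
    expect_equal(diag(m), rep(1, 20))
    expect_true(all(eigen(m, symmetric = TRUE, only.values = TRUE)$values > 0))
    expect_equal(m, t(m))
  }

  # disjoint signal-edge sets
  by_class <- split(truth$signal_edges$edge, truth$signal_edges$class)
  expect_equal(length(by_class), 6)
  expect_equal(length(unique(unlist(by_class))), 6 * 8)

  # mean planted Fisher-z increment survives the PD projection
  lin <- truth$signal_edges
  incr <- vapply(seq_len(nrow(lin)), function(r) {
    a <- lin$i[r] + 1
    b <- lin$j[r] + 1
    atanh(truth$class_cov[[lin$class[r]]][a, b]) - atanh(truth$base[a, b])
  }, numeric(1))
  expect_lt(abs(mean(incr) - 0.3), 0.05)
})

test_that("null mode plants nothing", {
  spec <- cohort_spec(n_subjects = 2, n_rois = 15, null_mode = TRUE)
  truth <- make_class_covariances(spec)
  for (m in truth$class_cov) expect_identical(m, truth$base)
})

test_that("subject datasets have the right shapes and are deterministic", {
  spec <- cohort_spec(n_subjects = 1, n_rois = 8,
                      n_signal_edges_per_class = 3)
  truth <- make_class_covariances(spec)
  sub <- simulate_subject(spec, truth, "sub-01", seed = 5)
  expect_length(sub$runs, 4)
  for (run in sub$runs) {
    # 684 s / 2 s TR minus 5 discarded volumes
    expect_equal(nrow(run$roi_timeseries), 337)
    expect_equal(ncol(run$roi_timeseries), 8)
    expect_equal(dim(run$motion), c(337, 6))
    expect_equal(ncol(run$nuisance_signals), 10)
    expect_false(anyNA(run$roi_timeseries))
  }
  again <- simulate_subject(spec, truth, "sub-01", seed = 5)
  expect_identical(sub$runs[[1]]$roi_timeseries,
                   again$runs[[1]]$roi_timeseries)
  expect_identical(sub$behavior, again$behavior)
  other <- simulate_subject(spec, truth, "sub-01", seed = 6)
  expect_false(identical(sub$runs[[1]]$roi_timeseries,
                         other$runs[[1]]$roi_timeseries))
})

test_that("noise-free class correlation estimates sharpen with more data", {
  # with noise off and a large planted effect, the within-class sample
  # correlation approaches the true class correlation as blocks accumulate
  base <- cohort_spec(n_rois = 10, n_signal_edges_per_class = 5,
                      class_effect_size = 1.0, subject_noise_sd = 0,
                      white_noise_sd = 0, n_nuisance_signals = 0,
                      motion_amplitude = 0)
  truth <- make_class_covariances(base)
  frob <- function(n_runs, seed) {
    spec <- base
    spec$paradigm <- paradigm_spec(n_runs = n_runs)
    sub <- simulate_subject(spec, truth, "s", seed = seed)
    fc <- condition_fc(lapply(sub$runs, `[[`, "roi_timeseries"),
                       lapply(sub$runs, `[[`, "schedule"),
                       "anger", "static")
    est <- tanh(unclass(fc))
    diag(est) <- 1
    norm(est - truth$class_cov[["anger"]], "F")
  }
  d1 <- mean(vapply(1:4, function(s) frob(1, s), numeric(1)))
  d4 <- mean(vapply(1:4, function(s) frob(4, s), numeric(1)))
  expect_lt(d4, d1)
})

test_that("behavioral generator respects its contract", {
  spec <- cohort_spec(n_subjects = 1, n_rois = 5,
                      n_signal_edges_per_class = 1)
  perfect <- simulate_behavior(spec, "s1", seed = 1,
                               p_correct_static = 1, p_correct_dynamic = 1)
  expect_true(all(perfect$correct))
  expect_true(all(perfect$response == perfect$expression))

  b <- simulate_behavior(spec, "s1", seed = 2, p_correct_static = 0.5,
                         p_correct_dynamic = 0.5)
  expect_true(all(b$intensity %in% 1:9))
  expect_true(all(b$rt_ms >= 0))
  expect_equal(nrow(b), 2 * 6 * 12) # condition x expression x exemplar
  # errors never echo the true label
  expect_true(all(b$response[!b$correct] != b$expression[!b$correct]))
})

test_that("the planted accuracy advantage is detectable at high power", {
  spec <- cohort_spec(n_subjects = 1, n_rois = 5,
                      n_signal_edges_per_class = 1)
  reject <- replicate(200, {
    seed <- sample.int(1e6, 1)
    acc <- vapply(1:18, function(s) {
      b <- simulate_behavior(spec, sprintf("s%d", s),
                             seed = seed + s,
                             p_correct_static = 0.7,
                             p_correct_dynamic = 0.9)
      c(mean(b$correct[b$condition == "static"]),
        mean(b$correct[b$condition == "dynamic"]))
    }, numeric(2))
    tt <- paired_t_one_tailed(acc[1, ], acc[2, ], "greater")
    tt$p < 0.05
  })
  expect_gte(mean(reject), 0.9)
})

test_that("cohorts round-trip through the on-disk TSV layout", {
  co <- simulate_cohort(cohort_spec(n_subjects = 2, n_rois = 6,
                                    n_signal_edges_per_class = 2),
                        seed = 77)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(names(back$subjects), names(co$subjects))
  orig <- co$subjects[[1]]$runs[[1]]$roi_timeseries
  got <- back$subjects[[1]]$runs[[1]]$roi_timeseries
  expect_equal(unname(got), unname(orig), tolerance = 1e-6)
  expect_equal(back$subjects[[2]]$behavior$response,
               co$subjects[[2]]$behavior$response)
  expect_equal(schedule_duration(back$subjects[[1]]$runs[[1]]$schedule), 684)
})
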