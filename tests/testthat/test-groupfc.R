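test_that("one-sample t matches closed forms and flags zero variance", {
  r <- one_sample_t(c(1, 2, 3))
  expect_equal(r$t, 3.4641, tolerance = 1e-4)
  expect_equal(r$df, 2)
  expect_equal(one_sample_t(c(-1, 1))$t, 0)
  expect_error(one_sample_t(c(1, 1, 1)), "variance")

  # matrix form agrees with t.test on 100 random columns
  set.seed(10)
  x <- matrix(rnorm(18 * 100, mean = 0.1), 18, 100)
  vt <- one_sample_t(x)
  for (k in sample(100, 10)) {
    tt <- t.test(x[, k])
    expect_equal(vt$t[k], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(vt$p[k], tt$p.value, tolerance = 1e-10)
  }
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(numeric(0)), numeric(0))

  # the classic staircase: all survive at q = 0.05 because p(5) <= 5/5 * q
  p <- c(0.01, 0.02, 0.03, 0.04, 0.05)
  expect_true(all(bh_fdr(p) <= 0.05))

  set.seed(11)
  for (k in 1:100) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    adj <- bh_fdr(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-10)
    expect_true(all(adj >= p - 1e-12))
    # monotone in the raw p after sorting
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
  }
})

make_stats_tbl <- function(z_matrix, expression = "anger",
                           condition = "static") {
  n_rois <- as.integer(round((1 + sqrt(1 + 8 * ncol(z_matrix))) / 2))
  ei <- edge_index(n_rois)
  st <- one_sample_t(z_matrix)
  tibble::tibble(expression = expression, condition = condition,
                 edge = ei$edge, i = ei$i, j = ei$j,
                 mean_z = st$mean, t_stat = st$t, df = st$df,
                 p_value = st$p, p_adjusted = bh_fdr(st$p),
                 n_subjects = nrow(z_matrix))
}

test_that("positive-edge masks honor both significance and sign", {
  set.seed(12)
  strong <- matrix(rnorm(18 * 45, mean = 1, sd = 0.2), 18, 45)
  stats <- make_stats_tbl(strong)
  mask <- positive_edge_mask(stats, q = 0.01)
  expect_true(all(mask))
  expect_equal(attr(mask, "n_selected"), 45)

  flipped <- make_stats_tbl(-strong)
  mask2 <- positive_edge_mask(flipped, q = 0.01)
  expect_false(any(mask2))
})

test_that("realized false-discovery proportion on null edges stays at q", {
  set.seed(13)
  q <- 0.05
  fdp <- replicate(100, {
    z <- matrix(rnorm(18 * 300, mean = 0, sd = 0.2), 18, 300)
    mask <- positive_edge_mask(make_stats_tbl(z), q = q)
    # every edge is null, so FDP = V / max(R, 1) is 1 whenever R > 0
    as.numeric(sum(mask) > 0)
  })
  # E[FDP] <= q under BH; allow Monte-Carlo error
  expect_lt(mean(fdp), q + 3 * sd(fdp) / sqrt(100) + 0.01)
})

test_that("mask pooling is an exact union", {
  set.seed(14)
  base <- make_stats_tbl(matrix(rnorm(10 * 45, 1, 0.2), 10, 45))
  m <- positive_edge_mask(base, 0.01)

  expect_equal(pool_masks(list(m, m, m)), m, ignore_attr = TRUE)

  mk <- function(idx, cond = "static") {
    v <- rep(FALSE, 45)
    v[idx] <- TRUE
    structure(v, condition = cond, n_selected = length(idx))
  }
  pooled <- pool_masks(list(mk(1:10), mk(21:40)))
  expect_equal(attr(pooled, "n_features"), 30)
  expect_error(pool_masks(list(mk(1:3), mk(4:6, "dynamic"))), "different")

  for (k in 1:20) {
    ms <- lapply(1:6, function(i) mk(sample(45, sample(0:20, 1))))
    pooled <- pool_masks(ms)
    brute <- rep(FALSE, 45)
    for (mm in ms) brute <- brute | mm
    expect_equal(as.logical(pooled), as.logical(brute))
    expect_true(all(vapply(ms, function(mm) all(pooled[mm]), logical(1))))
  }
})

test_that("second-level thresholding recovers planted edges and rejects null", {
  set.seed(15)
  # null: almost never any surviving edge at adjusted p < 0.001
  n_hits <- replicate(40, {
    z <- matrix(rnorm(18 * 190, 0, 0.2), 18, 190)
    nrow(second_level_network(make_stats_tbl(z), 0.001))
  })
  expect_gte(mean(n_hits == 0), 0.95)

  # planted strong positive edges recovered with high sensitivity
  planted <- sample(190, 30)
  z <- matrix(rnorm(18 * 190, 0, 0.2), 18, 190)
  z[, planted] <- z[, planted] + 0.8
  net <- second_level_network(make_stats_tbl(z), 0.001)
  expect_gt(mean(planted %in% net$edge), 0.9)
  expect_true(all(net$edge %in% seq_len(190)))
  expect_true(all(diff(abs(net$t_stat)) <= 1e-12)) # sorted by |t|
  expect_true(all(net$sign[net$edge %in% planted] == 1))
})
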