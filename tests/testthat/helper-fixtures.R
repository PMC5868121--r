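# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small planted-signal cohort exercising the full simulate -> decode chain
fixture_cohort_small <- function() {
  cached("cohort_small", function() {
    simulate_cohort(
      cohort_spec(n_subjects = 6, n_rois = 12,
                  n_signal_edges_per_class = 6,
                  class_effect_size = 0.8),
      seed = 101
    )
  })
}

fixture_fc_small <- function() {
  cached("fc_small", function() cohort_fc(fixture_cohort_small()))
}

# subject x class edge-vector samples drawn directly in z-space, bypassing
# the time-series simulation: fast input for decoder-level tests
make_z_samples <- function(n_subjects, n_edges_total, classes = c(
                             "anger", "disgust", "fear", "joy",
                             "sadness", "surprise"),
                           signal_edges = list(), effect = 0,
                           noise_sd = 0.2, seed = 1,
                           condition = "static") {
  set.seed(seed)
  subj <- rep(sprintf("sub-%02d", seq_len(n_subjects)),
              each = length(classes))
  y <- rep(classes, n_subjects)
  x <- matrix(stats::rnorm(length(y) * n_edges_total, sd = noise_sd),
              length(y), n_edges_total)
  if (effect > 0 && length(signal_edges)) {
    for (cl in names(signal_edges)) {
      x[y == cl, signal_edges[[cl]]] <-
        x[y == cl, signal_edges[[cl]]] + effect
    }
  }
  list(x = x, subject_id = subj, expression = y, condition = condition)
}

# independent Benjamini-Hochberg oracle: explicit step-up search over
# thresholds, no shortcuts shared with the implementation
bh_oracle <- function(p) {
  m <- length(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    # adjusted p_i = min over all thresholds t >= p_i of t * m / rank(t)
    cands <- vapply(seq_len(m), function(j) {
      if (p[j] >= p[i]) p[j] * m / sum(p <= p[j]) else Inf
    }, numeric(1))
    adj[i] <- min(1, min(cands))
  }
  adj
}
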