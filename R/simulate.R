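#' Synthetic cohort specification
#'
#' Parameters of the simulated block-design fMRI cohort. The generator
#' plants class information at the edge (covariance) level: each expression
#' gets a disjoint set of "signal" ROI pairs whose Fisher-z correlation is
#' raised by `class_effect_size` relative to a shared base connectome, so
#' the decoded quantity and the planted ground truth live in the same
#' space. Defaults emulate the cohort the pipeline is designed for:
#' 18 subjects, a 112-region parcellation, 4 runs of the default paradigm.
#'
#' @param n_subjects Number of subjects.
#' @param n_rois Number of regions.
#' @param paradigm A [paradigm_spec()].
#' @param base_covariance_seed Seed for the shared base connectome.
#' @param class_effect_size Mean Fisher-z increment planted on each class's
#'   signal edges.
#' @param n_signal_edges_per_class Signal edges per class (disjoint sets).
#' @param subject_noise_sd SD of subject-level edge jitter, z units.
#' @param white_noise_sd SD of volume-wise white noise added to each ROI
#'   channel (latent signal has unit SD).
#' @param n_nuisance_signals Number of slow nuisance signals (WM/CSF-like).
#' @param motion_amplitude Scale of the simulated head-motion random walks.
#' @param hrf_peak_s,hrf_undershoot_s,hrf_ratio Double-gamma hemodynamic
#'   response shape: time-to-peak, undershoot peak time, undershoot ratio.
#' @param null_mode If `TRUE`, no class effects are planted: all class
#'   covariances equal the base connectome (chance-level decoding).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 18,
                        n_rois = 112,
                        paradigm = paradigm_spec(),
                        base_covariance_seed = 2026,
                        class_effect_size = 0.3,
                        n_signal_edges_per_class = 60,
                        subject_noise_sd = 0.1,
                        white_noise_sd = 0.5,
                        n_nuisance_signals = 10,
                        motion_amplitude = 0.2,
                        hrf_peak_s = 6,
                        hrf_undershoot_s = 16,
                        hrf_ratio = 1 / 6,
                        null_mode = FALSE) {
  stopifnot(n_rois >= 2, n_subjects >= 1, class_effect_size >= 0,
            n_signal_edges_per_class >= 0, subject_noise_sd >= 0,
            white_noise_sd >= 0, n_nuisance_signals >= 0,
            inherits(paradigm, "paradigm_spec"))
  n_classes <- length(paradigm$expressions)
  if (null_mode) n_signal_edges_per_class <- 0
  if (n_classes * n_signal_edges_per_class > n_edges(n_rois)) {
    stop("not enough edges for disjoint signal sets: reduce ",
         "n_signal_edges_per_class or increase n_rois")
  }
  structure(list(
    n_subjects = n_subjects, n_rois = n_rois, paradigm = paradigm,
    base_covariance_seed = base_covariance_seed,
    class_effect_size = class_effect_size,
    n_signal_edges_per_class = n_signal_edges_per_class,
    subject_noise_sd = subject_noise_sd,
    white_noise_sd = white_noise_sd,
    n_nuisance_signals = n_nuisance_signals,
    motion_amplitude = motion_amplitude,
    hrf = list(peak_s = hrf_peak_s, undershoot_s = hrf_undershoot_s,
               ratio = hrf_ratio),
    null_mode = null_mode
  ), class = "cohort_spec")
}

#' Double-gamma hemodynamic response kernel
#'
#' Canonical two-gamma HRF sampled at the repetition time and normalized to
#' unit peak, used to convolve the latent neural series per ROI channel.
#'
#' @param tr_s Sampling interval, seconds.
#' @param peak_s,undershoot_s,ratio Shape parameters.
#' @param length_s Kernel support, seconds.
#' @return Numeric kernel vector.
#' @export
hrf_kernel <- function(tr_s = 2, peak_s = 6, undershoot_s = 16,
                       ratio = 1 / 6, length_s = 32) {
  t <- seq(0, length_s, by = tr_s)
  # gamma densities parameterized by mode = (shape-1)*scale, scale = 1
  h <- stats::dgamma(t, shape = peak_s + 1, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot_s + 1, rate = 1)
  h / max(h)
}

#' Build ground-truth class covariances with planted signal edges
#'
#' Constructs one base correlation matrix with predominantly positive
#' off-diagonal mass from a random low-rank factor model (mirroring the
#' positive-dominant connectomes the positive-edge selection step targets),
#' samples disjoint signal-edge sets per class, raises those edges by the
#' class effect size in Fisher-z space and projects each result back to the
#' nearest positive-definite correlation matrix.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `fc_ground_truth`: list with `base`
#'   (correlation matrix), `class_cov` (named list of matrices),
#'   `signal_edges` (tibble class / edge / i / j, 0-based ROI indices),
#'   `master_seed`.
#' @export
make_class_covariances <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  R <- spec$n_rois
  classes <- spec$paradigm$expressions
  seed <- spec$base_covariance_seed
  base <- with_seed(derive_seed(seed, "base_cov"), {
    # loading scale calibrated so that, at 18 subjects and FDR q = 0.01,
    # roughly a quarter to a third of edges test significantly positive
    # per expression (pooling to about half), the prevalence regime the
    # positive-edge selection step is designed for
    k <- max(3, round(R / 8))
    lam <- matrix(stats::rnorm(R * k, mean = 0.13, sd = 0.20), R, k)
    s <- tcrossprod(lam)
    diag(s) <- diag(s) + stats::runif(R, 0.4, 0.8)
    stats::cov2cor(s)
  })
  base <- as.matrix(Matrix::nearPD(base, corr = TRUE)$mat)
  dimnames(base) <- NULL

  ei <- edge_index(R)
  n_sig <- spec$n_signal_edges_per_class
  sig <- with_seed(derive_seed(seed, "signal_edges"), {
    pool <- sample.int(nrow(ei))
    lapply(seq_along(classes), function(ci) {
      if (n_sig == 0) return(integer())
      sort(pool[((ci - 1) * n_sig + 1):(ci * n_sig)])
    })
  })
  names(sig) <- classes

  class_cov <- lapply(classes, function(cl) {
    if (spec$null_mode || n_sig == 0 || spec$class_effect_size == 0) {
      return(base)
    }
    z <- atanh(pmin(pmax(base, -1 + 1e-7), 1 - 1e-7))
    diag(z) <- 0
    rows <- ei[sig[[cl]], , drop = FALSE]
    for (r in seq_len(nrow(rows))) {
      a <- rows$i[r] + 1L
      b <- rows$j[r] + 1L
      z[a, b] <- z[a, b] + spec$class_effect_size
      z[b, a] <- z[a, b]
    }
    m <- tanh(z)
    diag(m) <- 1
    pd <- try(Matrix::nearPD(m, corr = TRUE, maxit = 200), silent = TRUE)
    if (inherits(pd, "try-error")) {
      stop("positive-definite projection failed for class '", cl, "'")
    }
    out <- as.matrix(pd$mat)
    dimnames(out) <- NULL
    out
  })
  names(class_cov) <- classes

  signal_edges <- dplyr::bind_rows(lapply(classes, function(cl) {
    dplyr::mutate(ei[sig[[cl]], , drop = FALSE], class = cl, .before = 1)
  }))
  structure(list(base = base, class_cov = class_cov,
                 signal_edges = tibble::as_tibble(signal_edges),
                 master_seed = seed),
            class = "fc_ground_truth")
}

#' @keywords internal subject-specific jittered covariances + cholesky factors
#' @noRd
subject_covariances <- function(spec, truth, seed) {
  R <- spec$n_rois
  jit <- with_seed(seed, {
    j <- matrix(0, R, R)
    j[upper.tri(j)] <- stats::rnorm(R * (R - 1) / 2, sd = spec$subject_noise_sd)
    j + t(j)
  })
  perturb <- function(m) {
    if (spec$subject_noise_sd == 0) return(m)
    z <- atanh(pmin(pmax(m, -1 + 1e-7), 1 - 1e-7))
    diag(z) <- 0
    out <- tanh(z + jit)
    diag(out) <- 1
    make_pd_correlation(out)
  }
  covs <- c(list(.base = perturb(truth$base)),
            lapply(truth$class_cov, perturb))
  lapply(covs, chol)
}

#' Simulate one subject's dataset
#'
#' For each run, draws volume-wise latent neural vectors from a
#' multivariate normal whose covariance is the active block's class
#' covariance during stimulus blocks and the base covariance elsewhere,
#' convolves each ROI channel with the double-gamma HRF, adds subject-level
#' edge jitter (applied in z-space to the covariances), nuisance-signal
#' loadings, slow motion-correlated drifts and white noise, then discards
#' the leading equilibration volumes. Deterministic given `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param truth Ground truth from [make_class_covariances()].
#' @param subject_id Subject identifier (e.g. `"sub-01"`).
#' @param seed Integer seed for this subject.
#' @return A `subject_dataset`: list with `subject_id`, `runs` (each run a
#'   list of `schedule`, `roi_timeseries` T x R, `motion` T x 6,
#'   `nuisance_signals` T x K), and `behavior` (tibble).
#' @export
simulate_subject <- function(spec, truth, subject_id, seed) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(truth, "fc_ground_truth"))
  pd <- spec$paradigm
  R <- spec$n_rois
  chols <- subject_covariances(spec, truth, derive_seed(seed, "jitter"))
  hrf <- hrf_kernel(pd$tr_s, spec$hrf$peak_s, spec$hrf$undershoot_s,
                    spec$hrf$ratio)
  runs <- lapply(seq_len(pd$n_runs) - 1L, function(r) {
    sched <- build_run_schedule(pd, run_index = r,
                                seed = derive_seed(seed, "sched", r))
    n_vol <- as.integer(round(schedule_duration(sched) / pd$tr_s))
    with_seed(derive_seed(seed, "run", r), {
      # active class per volume (neural level: unshifted block membership)
      active <- rep(".base", n_vol)
      for (cl in pd$expressions) {
        for (co in pd$conditions) {
          m <- condition_boxcar(sched, cl, co, pd$tr_s, n_vol, 0)
          active[m == 1L] <- cl
        }
      }
      latent <- matrix(0, n_vol, R)
      for (cl in unique(active)) {
        rows <- which(active == cl)
        latent[rows, ] <- matrix(stats::rnorm(length(rows) * R),
                                 length(rows), R) %*% chols[[cl]]
      }
      bold <- apply(latent, 2, function(x) {
        stats::convolve(x, rev(hrf), type = "open")[seq_len(n_vol)]
      })
      K <- spec$n_nuisance_signals
      nuis <- if (K > 0) {
        n0 <- apply(matrix(stats::rnorm(n_vol * K), n_vol, K), 2, cumsum)
        scale(n0)
      } else {
        matrix(0, n_vol, 0)
      }
      motion <- spec$motion_amplitude *
        apply(matrix(stats::rnorm(n_vol * 6, sd = 0.1), n_vol, 6), 2, cumsum)
      y <- bold
      if (K > 0) {
        y <- y + nuis %*% matrix(stats::rnorm(K * R, sd = 0.5), K, R)
      }
      y <- y + motion %*% matrix(stats::rnorm(6 * R, sd = 0.3), 6, R)
      y <- y + matrix(stats::rnorm(n_vol * R, sd = spec$white_noise_sd),
                      n_vol, R)
      keep <- setdiff(seq_len(n_vol), seq_len(pd$discard_initial_volumes))
      list(schedule = sched,
           roi_timeseries = y[keep, , drop = FALSE],
           motion = motion[keep, , drop = FALSE],
           nuisance_signals = nuis[keep, , drop = FALSE])
    })
  })
  behavior <- simulate_behavior(spec, subject_id,
                                derive_seed(seed, "behavior"))
  structure(list(subject_id = subject_id, runs = runs, behavior = behavior),
            class = "subject_dataset")
}

#' Simulate a post-scan behavioral response table
#'
#' One classification + intensity-rating trial per stimulus (12 exemplars
#' per expression x condition, mirroring the 12 stimulus identities).
#' Responses are Bernoulli-correct with condition-specific accuracy (errors
#' uniform over the five wrong labels), intensities are integers on 1-9,
#' and reaction times log-normal. The dynamic condition is more accurate
#' than the static one by default, emulating the behavioral advantage for
#' moving faces.
#'
#' @param spec A [cohort_spec()].
#' @param subject_id Subject identifier.
#' @param seed Integer seed.
#' @param p_correct_static,p_correct_dynamic Per-condition probability of a
#'   correct category response.
#' @param n_stimuli_per_cell Stimuli per expression x condition cell.
#' @return A tibble with columns `subject_id`, `stimulus_id`, `condition`,
#'   `expression`, `response`, `correct`, `intensity`, `rt_ms`, `task`.
#' @export
simulate_behavior <- function(spec, subject_id, seed,
                              p_correct_static = 0.80,
                              p_correct_dynamic = 0.88,
                              n_stimuli_per_cell = 12) {
  stopifnot(p_correct_static >= 0, p_correct_static <= 1,
            p_correct_dynamic >= 0, p_correct_dynamic <= 1)
  exprs <- spec$paradigm$expressions
  conds <- intersect(c("static", "dynamic"), spec$paradigm$conditions)
  if (length(conds) == 0) conds <- spec$paradigm$conditions[1]
  p_map <- c(static = p_correct_static, dynamic = p_correct_dynamic)
  grid <- tidyr::expand_grid(condition = conds, expression = exprs,
                             exemplar = seq_len(n_stimuli_per_cell))
  with_seed(seed, {
    n <- nrow(grid)
    p <- unname(p_map[grid$condition])
    p[is.na(p)] <- p_correct_static
    correct <- stats::runif(n) < p
    response <- grid$expression
    wrong <- !correct
    if (any(wrong)) {
      response[wrong] <- vapply(grid$expression[wrong], function(e) {
        sample(setdiff(exprs, e), 1)
      }, character(1))
    }
    intensity <- pmin(9L, pmax(1L, as.integer(round(stats::rnorm(n, 6, 1.5)))))
    rt_ms <- stats::rlnorm(n, meanlog = log(1200), sdlog = 0.3)
    tibble::tibble(
      subject_id = subject_id,
      stimulus_id = sprintf("%s_%s_%02d", grid$condition, grid$expression,
                            grid$exemplar),
      condition = grid$condition,
      expression = grid$expression,
      response = response,
      correct = correct,
      intensity = intensity,
      rt_ms = rt_ms,
      task = "classification"
    )
  })
}

#' Simulate a full cohort
#'
#' @param spec A [cohort_spec()].
#' @param seed Master seed; every subject, run and behavioral table derives
#'   its own sub-stream from it.
#' @return A `cohort`: list with `spec`, `truth`, `subjects` (list of
#'   [simulate_subject()] results), `seed`.
#' @export
#' @examples
#' \donttest{
#' co <- simulate_cohort(cohort_spec(n_subjects = 2, n_rois = 10), seed = 1)
#' length(co$subjects)
#' }
simulate_cohort <- function(spec, seed) {
  truth <- make_class_covariances(spec)
  ids <- sprintf("sub-%02d", seq_len(spec$n_subjects))
  subjects <- lapply(seq_along(ids), function(i) {
    simulate_subject(spec, truth, ids[i], derive_seed(seed, "subject", i))
  })
  names(subjects) <- ids
  structure(list(spec = spec, truth = truth, subjects = subjects,
                 seed = seed),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects, %d ROIs, %d runs%s\n",
              x$spec$n_subjects, x$spec$n_rois, x$spec$paradigm$n_runs,
              if (x$spec$null_mode) " [null mode]" else ""))
  invisible(x)
}

#' Write a cohort to disk as plain-text tables
#'
#' One directory per subject holding per-run `events.tsv`,
#' `roi_timeseries.tsv` (T rows x R labelled columns), `motion.tsv`,
#' `nuisance.tsv`, plus `behavior.tsv`; and a cohort `manifest.json` with
#' the spec, seeds and ground-truth signal-edge lists.
#'
#' @param cohort A cohort from [simulate_cohort()].
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  roi_labels <- sprintf("ROI_%03d", seq_len(cohort$spec$n_rois))
  for (sub in cohort$subjects) {
    sdir <- file.path(dir, sub$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    for (k in seq_along(sub$runs)) {
      run <- sub$runs[[k]]
      tag <- sprintf("run-%d", k)
      write_events(run$schedule, file.path(sdir, paste0(tag, "_events.tsv")))
      write_matrix_tsv(run$roi_timeseries, roi_labels,
                       file.path(sdir, paste0(tag, "_roi_timeseries.tsv")))
      write_matrix_tsv(run$motion, paste0("mot_", 1:6),
                       file.path(sdir, paste0(tag, "_motion.tsv")))
      if (ncol(run$nuisance_signals) > 0) {
        write_matrix_tsv(run$nuisance_signals,
                         sprintf("nuis_%02d", seq_len(ncol(run$nuisance_signals))),
                         file.path(sdir, paste0(tag, "_nuisance.tsv")))
      }
    }
    readr::write_tsv(sub$behavior, file.path(sdir, "behavior.tsv"),
                     progress = FALSE)
  }
  manifest <- list(
    n_subjects = cohort$spec$n_subjects,
    n_rois = cohort$spec$n_rois,
    n_runs = cohort$spec$paradigm$n_runs,
    tr_s = cohort$spec$paradigm$tr_s,
    discard_initial_volumes = cohort$spec$paradigm$discard_initial_volumes,
    expressions = cohort$spec$paradigm$expressions,
    conditions = cohort$spec$paradigm$conditions,
    null_mode = cohort$spec$null_mode,
    seed = cohort$seed,
    subjects = names(cohort$subjects),
    signal_edges = cohort$truth$signal_edges
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @keywords internal
#' @noRd
write_matrix_tsv <- function(m, labels, path) {
  df <- as.data.frame(m)
  names(df) <- labels
  utils::write.table(format(df, digits = 8, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A `cohort` (without ground-truth covariance matrices; the
#'   manifest's signal-edge table is retained).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  subjects <- lapply(manifest$subjects, function(id) {
    sdir <- file.path(dir, id)
    runs <- lapply(seq_len(manifest$n_runs), function(k) {
      tag <- sprintf("run-%d", k)
      nuis_path <- file.path(sdir, paste0(tag, "_nuisance.tsv"))
      list(
        schedule = read_events(file.path(sdir, paste0(tag, "_events.tsv")),
                               tr_s = manifest$tr_s, run_index = k - 1L),
        roi_timeseries = read_matrix_tsv(
          file.path(sdir, paste0(tag, "_roi_timeseries.tsv"))),
        motion = read_matrix_tsv(file.path(sdir, paste0(tag, "_motion.tsv"))),
        nuisance_signals = if (file.exists(nuis_path)) {
          read_matrix_tsv(nuis_path)
        } else {
          matrix(0, 0, 0)
        }
      )
    })
    behavior <- readr::read_tsv(file.path(sdir, "behavior.tsv"),
                                show_col_types = FALSE, progress = FALSE)
    structure(list(subject_id = id, runs = runs, behavior = behavior),
              class = "subject_dataset")
  })
  names(subjects) <- manifest$subjects
  structure(list(spec = NULL, manifest = manifest, subjects = subjects,
                 seed = manifest$seed),
            class = "cohort")
}

#' @keywords internal
#' @noRd
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.delim(path, sep = "\t", check.names = FALSE))
}
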