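#' Number of unordered ROI pairs (edges)
#'
#' @param n_rois Number of regions (>= 2).
#' @return `n_rois * (n_rois - 1) / 2`; 6216 for a 112-region parcellation.
#' @export
#' @examples
#' n_edges(112) # 6216
n_edges <- function(n_rois) {
  if (!is.numeric(n_rois) || length(n_rois) != 1 || n_rois < 2) {
    stop("n_rois must be a single number >= 2")
  }
  as.integer(n_rois * (n_rois - 1) / 2)
}

#' Canonical edge index table
#'
#' The package-wide edge order: upper-triangle pairs `(i, j)` with `i < j`,
#' sorted lexicographically by `i` then `j`, ROI indices 0-based so they
#' match the atlas label file. Every edge vector, mask, feature id and
#' network output uses this order.
#'
#' @param n_rois Number of regions.
#' @return Tibble with columns `edge` (1-based position), `i`, `j`
#'   (0-based ROI indices).
#' @export
edge_index <- function(n_rois) {
  E <- n_edges(n_rois)
  i <- rep.int(seq_len(n_rois - 1) - 1L, times = (n_rois - 1):1)
  j <- unlist(lapply(seq_len(n_rois - 1), function(a) a:(n_rois - 1)),
              use.names = FALSE)
  tibble::tibble(edge = seq_len(E), i = as.integer(i), j = as.integer(j))
}

#' @keywords internal column-major linear indices of the canonical edges
#' @noRd
edge_linear_index <- function(n_rois) {
  ei <- edge_index(n_rois)
  ei$j * n_rois + ei$i + 1L
}

#' Vectorize / restore a symmetric connectivity matrix
#'
#' `fc_vectorize()` extracts the canonical upper-triangle edge vector;
#' `fc_unvectorize()` rebuilds the symmetric matrix (diagonal set to
#' `diag`). The two are exact inverses.
#'
#' @param m Symmetric R x R matrix.
#' @param v Edge vector of length `n_rois * (n_rois - 1) / 2`.
#' @param n_rois Number of regions (inferred from `length(v)` if omitted).
#' @param diag Value placed on the rebuilt diagonal.
#' @return A numeric vector (`fc_vectorize`) or symmetric matrix
#'   (`fc_unvectorize`).
#' @export
fc_vectorize <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  m[edge_linear_index(nrow(m))]
}

#' @rdname fc_vectorize
#' @export
fc_unvectorize <- function(v, n_rois = NULL, diag = 0) {
  if (is.null(n_rois)) {
    n_rois <- as.integer(round((1 + sqrt(1 + 8 * length(v))) / 2))
  }
  stopifnot(length(v) == n_edges(n_rois))
  m <- matrix(diag, n_rois, n_rois)
  lin <- edge_linear_index(n_rois)
  m[lin] <- v
  m <- t(m)
  m[lin] <- v
  m
}

#' Condition-specific Fisher-z connectivity matrix
#'
#' Concatenates, across runs, the volumes whose shifted boxcar flags the
#' given expression x condition, computes the Pearson correlation for every
#' ROI pair on the concatenation, and Fisher-z transforms it
#' (`z = atanh(r)`, `|r|` clipped at `1 - 1e-7`). Time-series rows are the
#' post-discard volumes, so the boxcar is trimmed by
#' `discard_initial_volumes` before masking.
#'
#' @param runs List of denoised T x R matrices, one per run.
#' @param schedules List of run schedules matching `runs`.
#' @param expression,condition Labels of the block type wanted.
#' @param tr_s Repetition time, seconds.
#' @param hemodynamic_shift_s Boxcar shift, seconds (default 4 = 2 TR).
#' @param discard_initial_volumes Leading volumes already dropped from the
#'   time series.
#' @param min_volumes Fail if fewer volumes than this are selected.
#' @return An `fc_matrix`: symmetric R x R z-matrix (diagonal 0) with
#'   attributes `expression`, `condition`, `n_volumes_used`.
#' @export
condition_fc <- function(runs, schedules, expression, condition,
                         tr_s = 2, hemodynamic_shift_s = 4,
                         discard_initial_volumes = 5, min_volumes = 10) {
  stopifnot(length(runs) == length(schedules), length(runs) >= 1)
  picked <- lapply(seq_along(runs), function(k) {
    y <- runs[[k]]
    n_full <- nrow(y) + discard_initial_volumes
    mask <- condition_boxcar(schedules[[k]], expression, condition,
                             tr_s, n_full, hemodynamic_shift_s)
    mask <- mask[-seq_len(discard_initial_volumes)]
    if (length(mask) != nrow(y)) {
      stop("schedule/timeseries length mismatch in run ", k)
    }
    y[mask == 1L, , drop = FALSE]
  })
  x <- do.call(rbind, picked)
  if (nrow(x) < max(2, min_volumes)) {
    stop(sprintf("only %d volumes selected for %s/%s (minimum %d)",
                 nrow(x), expression, condition, min_volumes))
  }
  r <- suppressWarnings(stats::cor(x))
  r[is.na(r)] <- 0
  r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  structure(z, expression = expression, condition = condition,
            n_volumes_used = nrow(x), class = c("fc_matrix", "matrix", "array"))
}

#' Per-subject connectivity matrices for all analyzed conditions
#'
#' One Fisher-z matrix per expression x analyzed condition. By default the
#' analyzed conditions are static and dynamic; the obscured-eyes condition,
#' though present in the schedules, is skipped.
#'
#' @param subject A `subject_dataset` whose runs hold *denoised* time
#'   series (see [denoise_subject()]).
#' @param expressions,conditions Labels to compute (defaults: all six
#'   expressions x static + dynamic).
#' @param tr_s,hemodynamic_shift_s,discard_initial_volumes,min_volumes
#'   Passed to [condition_fc()].
#' @return A tibble with one row per expression x condition: columns
#'   `subject_id`, `expression`, `condition`, `n_volumes_used`, and `fc`
#'   (list-column of z-matrices).
#' @export
subject_fc_set <- function(subject,
                           expressions = c("anger", "disgust", "fear",
                                           "joy", "sadness", "surprise"),
                           conditions = c("static", "dynamic"),
                           tr_s = 2, hemodynamic_shift_s = 4,
                           discard_initial_volumes = 5, min_volumes = 10) {
  runs <- lapply(subject$runs, `[[`, "roi_timeseries")
  schedules <- lapply(subject$runs, `[[`, "schedule")
  grid <- tidyr::expand_grid(expression = expressions, condition = conditions)
  fcs <- purrr::pmap(grid, function(expression, condition) {
    condition_fc(runs, schedules, expression, condition, tr_s,
                 hemodynamic_shift_s, discard_initial_volumes, min_volumes)
  })
  tibble::tibble(
    subject_id = subject$subject_id,
    expression = grid$expression,
    condition = grid$condition,
    n_volumes_used = vapply(fcs, attr, integer(1), "n_volumes_used"),
    fc = fcs
  )
}

#' Connectivity matrices for every subject of a cohort
#'
#' Denoises each subject (unless `denoise = FALSE`) and stacks the
#' per-subject [subject_fc_set()] tibbles.
#'
#' @param cohort A cohort from [simulate_cohort()] / [read_cohort()].
#' @param denoise_spec A [denoise_spec()]; `NULL` skips denoising.
#' @inheritParams subject_fc_set
#' @return Row-bound tibble of per-subject FC sets.
#' @export
cohort_fc <- function(cohort, denoise_spec = fcdecoder::denoise_spec(),
                      expressions = c("anger", "disgust", "fear",
                                      "joy", "sadness", "surprise"),
                      conditions = c("static", "dynamic"),
                      tr_s = 2, hemodynamic_shift_s = 4,
                      discard_initial_volumes = 5) {
  dplyr::bind_rows(lapply(cohort$subjects, function(sub) {
    if (!is.null(denoise_spec)) {
      sub <- denoise_subject(sub, denoise_spec, tr_s = tr_s)
    }
    subject_fc_set(sub, expressions, conditions, tr_s,
                   hemodynamic_shift_s, discard_initial_volumes)
  }))
}

#' Edge-sample matrix for one condition
#'
#' Flattens a connectivity tibble into the samples x edges matrix the
#' decoder consumes: one row per subject x expression, columns in the
#' canonical edge order.
#'
#' @param fc_tbl Tibble from [cohort_fc()] / [subject_fc_set()].
#' @param condition Condition to keep.
#' @return List with `x` (samples x edges matrix), `subject_id`,
#'   `expression` (vectors aligned with rows), `condition`.
#' @export
edge_samples <- function(fc_tbl, condition) {
  keep <- fc_tbl[fc_tbl$condition == condition, , drop = FALSE]
  if (nrow(keep) == 0) stop("no rows for condition '", condition, "'")
  x <- do.call(rbind, lapply(keep$fc, fc_vectorize))
  list(x = x, subject_id = keep$subject_id, expression = keep$expression,
       condition = condition)
}

#' Write a connectivity matrix with its JSON sidecar
#'
#' Square TSV with ROI-label header plus a sidecar recording subject,
#' expression, condition and volumes used.
#'
#' @param fc An `fc_matrix` from [condition_fc()].
#' @param path Output TSV path (sidecar gets extension `.json`).
#' @param roi_labels Column labels (default `ROI_001`...).
#' @param subject_id Recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_fc_matrix <- function(fc, path, roi_labels = NULL, subject_id = NA) {
  R <- nrow(fc)
  roi_labels <- roi_labels %||% sprintf("ROI_%03d", seq_len(R))
  write_matrix_tsv(unclass(fc), roi_labels, path)
  sidecar <- list(subject_id = subject_id,
                  expression = attr(fc, "expression"),
                  condition = attr(fc, "condition"),
                  n_volumes_used = attr(fc, "n_volumes_used"))
  jsonlite::write_json(sidecar, sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
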