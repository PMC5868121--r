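#' Denoising specification
#'
#' CompCor-style nuisance removal followed by band-pass filtering of the
#' ROI time series. Nuisance principal components (from WM/CSF-like
#' signals), the six motion parameters and an optional linear trend are
#' regressed out, then each channel is band-pass filtered with a
#' zero-phase frequency-domain mask.
#'
#' @param n_compcor_components Number of nuisance principal components.
#' @param include_motion Regress out the six motion parameters.
#' @param detrend `"linear"` or `"none"`.
#' @param band_hz Length-2 pass band (low, high) in Hz; must sit below the
#'   Nyquist frequency of the repetition time.
#' @return An object of class `denoise_spec`.
#' @export
denoise_spec <- function(n_compcor_components = 5,
                         include_motion = TRUE,
                         detrend = c("linear", "none"),
                         band_hz = c(0.01, 0.10)) {
  detrend <- match.arg(detrend)
  stopifnot(n_compcor_components >= 0, length(band_hz) == 2,
            band_hz[1] >= 0, band_hz[1] < band_hz[2])
  structure(list(n_compcor_components = n_compcor_components,
                 include_motion = include_motion,
                 detrend = detrend,
                 band_hz = band_hz),
            class = "denoise_spec")
}

#' CompCor components of a nuisance-signal matrix
#'
#' Top left singular vectors of the column-demeaned, column-standardized
#' nuisance matrix, ordered by singular value. Zero-variance columns are
#' dropped. If the matrix rank is below `n_components`, the available
#' components are returned with a warning.
#'
#' @param nuisance_signals T x K numeric matrix.
#' @param n_components Number of components requested (>= 1, <= K).
#' @return T x n orthonormal matrix with attribute `explained_variance`
#'   (fraction of total variance per component).
#' @export
compcor_components <- function(nuisance_signals, n_components) {
  x <- as.matrix(nuisance_signals)
  stopifnot(n_components >= 1, ncol(x) >= n_components,
            nrow(x) > ncol(x))
  sds <- col_sds(x)
  keep <- which(sds > 0)
  if (length(keep) == 0) stop("all nuisance columns are constant")
  x <- scale(x[, keep, drop = FALSE])
  sv <- svd(x)
  pos <- sv$d > max(sv$d) * 1e-10
  avail <- sum(pos)
  n_out <- min(n_components, avail)
  if (n_out < n_components) {
    warning(sprintf("nuisance matrix rank %d < %d requested components",
                    avail, n_components))
  }
  u <- sv$u[, seq_len(n_out), drop = FALSE]
  attr(u, "explained_variance") <- (sv$d[seq_len(n_out)]^2) / sum(sv$d^2)
  u
}

#' Regress confounds out of a time-series matrix
#'
#' Per-column least-squares residuals after projecting out the confound
#' columns (an intercept is always added internally, so the output is also
#' demeaned). A rank-deficient design falls back to the minimum-norm
#' solution with a warning.
#'
#' @param timeseries T x R matrix.
#' @param confounds T x C matrix (may have zero columns).
#' @return T x R residual matrix, orthogonal to every confound column.
#' @export
regress_out <- function(timeseries, confounds = NULL) {
  y <- as.matrix(timeseries)
  x <- matrix(1, nrow(y), 1)
  if (!is.null(confounds) && ncol(as.matrix(confounds)) > 0) {
    conf <- as.matrix(confounds)
    if (nrow(conf) != nrow(y)) stop("confounds and timeseries disagree on T")
    x <- cbind(x, conf)
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    warning("singular confound design; using minimum-norm projection")
  }
  y - qr.fitted(qx, y)
}

#' Zero-phase band-pass filter
#'
#' Frequency-domain masking with cosine-tapered band edges: unit gain
#' inside `band_hz`, cosine roll-off of width `taper_hz` outside it, DC
#' removed exactly, no phase distortion. Applied per column.
#'
#' @param timeseries T x R matrix.
#' @param tr_s Sampling interval, seconds.
#' @param band_hz Length-2 pass band (low, high), Hz; `high` must be below
#'   Nyquist.
#' @param taper_hz Transition-band width, Hz. The default is at or below
#'   the frequency resolution of typical run lengths, so band edges are
#'   effectively sharp and repeated filtering is near-idempotent.
#' @return Filtered T x R matrix.
#' @export
bandpass <- function(timeseries, tr_s, band_hz = c(0.01, 0.10),
                     taper_hz = 0.001) {
  y <- as.matrix(timeseries)
  n <- nrow(y)
  nyq <- 1 / (2 * tr_s)
  if (band_hz[2] >= nyq) stop("band high edge must be below Nyquist (",
                              nyq, " Hz)")
  freqs <- (seq_len(n) - 1) / (n * tr_s)
  freqs <- pmin(freqs, 1 / tr_s - freqs) # fold to [0, Nyquist]
  if (floor(band_hz[2] * n * tr_s) - ceiling(band_hz[1] * n * tr_s) < 1) {
    stop("time series too short to resolve the pass band")
  }
  ramp <- function(f, edge, width) {
    # 0 below edge-width, 1 above edge, cosine in between
    g <- (f - (edge - width)) / width
    ifelse(f >= edge, 1, ifelse(f <= edge - width, 0,
                                0.5 * (1 - cos(pi * g))))
  }
  gain <- ramp(freqs, band_hz[1], taper_hz) *
    (1 - ramp(freqs, band_hz[2] + taper_hz, taper_hz))
  gain[1] <- 0 # DC
  ctr <- colMeans(y)
  yc <- sweep(y, 2, ctr)
  out <- Re(stats::mvfft(stats::mvfft(yc) * gain, inverse = TRUE)) / n
  dimnames(out) <- dimnames(y)
  out
}

#' Denoise one run
#'
#' Order of operations: build the confound matrix (CompCor components of
#' the nuisance signals, motion parameters, linear trend), regress it out,
#' then band-pass filter. Regression precedes filtering, per run, after
#' the initial-volume discard.
#'
#' @param roi_timeseries T x R matrix (post-discard).
#' @param motion T x 6 matrix or `NULL`.
#' @param nuisance_signals T x K matrix or `NULL`.
#' @param spec A [denoise_spec()].
#' @param tr_s Repetition time, seconds.
#' @return Denoised T x R matrix.
#' @export
denoise_run <- function(roi_timeseries, motion = NULL,
                        nuisance_signals = NULL,
                        spec = denoise_spec(), tr_s = 2) {
  y <- as.matrix(roi_timeseries)
  conf <- NULL
  if (!is.null(nuisance_signals) && ncol(as.matrix(nuisance_signals)) > 0 &&
      spec$n_compcor_components > 0) {
    n_use <- min(spec$n_compcor_components,
                 ncol(as.matrix(nuisance_signals)))
    conf <- cbind(conf, compcor_components(nuisance_signals, n_use))
  }
  if (spec$include_motion && !is.null(motion) &&
      ncol(as.matrix(motion)) > 0) {
    conf <- cbind(conf, as.matrix(motion))
  }
  if (spec$detrend == "linear") {
    conf <- cbind(conf, seq_len(nrow(y)))
  }
  resid <- regress_out(y, conf)
  bandpass(resid, tr_s, spec$band_hz)
}

#' Denoise every run of a subject dataset
#'
#' @param subject A `subject_dataset`.
#' @param spec A [denoise_spec()].
#' @param tr_s Repetition time, seconds.
#' @return The subject with `roi_timeseries` replaced by its denoised
#'   version in every run.
#' @export
denoise_subject <- function(subject, spec = denoise_spec(), tr_s = 2) {
  subject$runs <- lapply(subject$runs, function(run) {
    run$roi_timeseries <- denoise_run(
      run$roi_timeseries,
      motion = run$motion,
      nuisance_signals = run$nuisance_signals,
      spec = spec, tr_s = tr_s
    )
    run
  })
  subject
}
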