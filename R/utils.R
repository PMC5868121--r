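#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one master seed. Stages and
#' subjects get named sub-streams so any stage can be re-run in isolation
#' and still reproduce the full-pipeline result.
#'
#' @param seed Master integer seed.
#' @param ... Character or integer tags naming the sub-stream
#'   (e.g. `"subject"`, `3`, `"run"`, `1`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "subject", 3)
derive_seed <- function(seed, ...) {
  tags <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(tags)
  # 32-bit FNV-1a style fold, kept in double precision (exact below 2^53)
  h <- 2166136261
  for (b in bytes) {
    h <- (h + b) %% 2147483647
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h)
}

#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# column standard deviations without apply() overhead
#' @keywords internal
#' @noRd
col_sds <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  sqrt((colSums(x^2) - n * mu^2) / (n - 1))
}

#' Repair a symmetric matrix to the nearest valid correlation matrix (fast)
#'
#' Eigenvalue clipping followed by rescaling to unit diagonal. Used for the
#' per-subject jittered covariances where a full alternating-projection run
#' per matrix would dominate simulation time; ground-truth class matrices use
#' [Matrix::nearPD()].
#'
#' @param m Symmetric numeric matrix.
#' @param eps Smallest admitted eigenvalue.
#' @return A symmetric positive-definite correlation matrix.
#' @keywords internal
make_pd_correlation <- function(m, eps = 1e-6) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  out <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  (out + t(out)) / 2
}
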