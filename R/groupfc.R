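#' One-sample t-test (vectorized over edges)
#'
#' `t = mean / (sd / sqrt(n))` with `df = n - 1` and a two-sided p-value.
#' Accepts a vector (one edge) or an n x E matrix (subjects x edges).
#'
#' @param values Numeric vector, or matrix with one column per edge.
#' @return For a vector: list with `t`, `df`, `p`. For a matrix: tibble
#'   with columns `mean`, `t`, `df`, `p` (one row per column).
#' @export
#' @examples
#' one_sample_t(c(1, 2, 3)) # t = 3.4641, df = 2
one_sample_t <- function(values) {
  if (is.matrix(values)) {
    n <- nrow(values)
    if (n < 2) stop("need at least 2 observations")
    mu <- colMeans(values)
    s <- col_sds(values)
    if (any(s == 0)) stop("zero variance in ", sum(s == 0), " column(s)")
    t <- mu / (s / sqrt(n))
    df <- n - 1
    return(tibble::tibble(mean = mu, t = t, df = df,
                          p = 2 * stats::pt(-abs(t), df)))
  }
  n <- length(values)
  if (n < 2) stop("need at least 2 observations")
  s <- stats::sd(values)
  if (s == 0) stop("zero sample variance")
  t <- mean(values) / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone, capped at 1). Selection at level `q`
#' is `bh_fdr(p) <= q`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Group edge statistics for each expression x condition
#'
#' For every expression x condition cell, stacks the subjects' edge
#' vectors and computes the per-edge mean z, one-sample t across subjects,
#' two-sided p and BH-adjusted p (FDR family = all edges of that cell).
#'
#' @param fc_tbl Connectivity tibble from [cohort_fc()].
#' @return Tibble with one row per expression x condition x edge: columns
#'   `expression`, `condition`, `edge`, `i`, `j`, `mean_z`, `t_stat`,
#'   `df`, `p_value`, `p_adjusted`, `n_subjects`.
#' @export
group_edge_stats <- function(fc_tbl) {
  cells <- dplyr::distinct(fc_tbl, .data$expression, .data$condition)
  R <- nrow(fc_tbl$fc[[1]])
  ei <- edge_index(R)
  dplyr::bind_rows(purrr::pmap(cells, function(expression, condition) {
    rows <- fc_tbl[fc_tbl$expression == expression &
                     fc_tbl$condition == condition, , drop = FALSE]
    x <- do.call(rbind, lapply(rows$fc, fc_vectorize))
    st <- one_sample_t(x)
    tibble::tibble(
      expression = expression, condition = condition,
      edge = ei$edge, i = ei$i, j = ei$j,
      mean_z = st$mean, t_stat = st$t, df = st$df,
      p_value = st$p, p_adjusted = bh_fdr(st$p),
      n_subjects = nrow(x)
    )
  }))
}

#' Positive-edge mask for one expression x condition
#'
#' Edges whose connectivity is significantly greater than zero: positive t
#' combined with BH-adjusted two-sided p at level `q` (default 0.01), the
#' FDR family being all edges of the cell.
#'
#' @param stats One cell of [group_edge_stats()] output (single
#'   expression x condition).
#' @param q FDR level.
#' @return Logical vector over canonical edges with attributes
#'   `expression`, `condition`, `q_level`, `n_selected`.
#' @export
positive_edge_mask <- function(stats, q = 0.01) {
  stopifnot(dplyr::n_distinct(stats$expression) == 1,
            dplyr::n_distinct(stats$condition) == 1)
  stats <- dplyr::arrange(stats, .data$edge)
  mask <- stats$t_stat > 0 & stats$p_adjusted <= q
  structure(mask,
            expression = stats$expression[1],
            condition = stats$condition[1],
            q_level = q, n_selected = sum(mask))
}

#' Pool positive-edge masks into one feature set
#'
#' Elementwise union of the per-expression masks of one condition: the
#' edges significantly positive for at least one expression, which form
#' the decoder's feature space.
#'
#' @param masks List of masks from [positive_edge_mask()], all of the same
#'   condition and edge space.
#' @return Logical vector with attributes `condition`, `n_features`.
#' @export
pool_masks <- function(masks) {
  stopifnot(length(masks) >= 1)
  conds <- vapply(masks, attr, character(1), "condition")
  if (length(unique(conds)) != 1) {
    stop("cannot pool masks from different conditions: ",
         paste(unique(conds), collapse = ", "))
  }
  lens <- vapply(masks, length, integer(1))
  stopifnot(length(unique(lens)) == 1)
  pooled <- Reduce(`|`, masks)
  structure(as.logical(pooled), condition = conds[1],
            n_features = sum(pooled))
}

#' Pooled positive-edge feature sets per condition
#'
#' Convenience wrapper: runs [positive_edge_mask()] per expression and
#' [pool_masks()] per condition.
#'
#' @param stats Full [group_edge_stats()] tibble.
#' @param q FDR level for the per-expression masks.
#' @return Named list (by condition) of pooled logical masks.
#' @export
pooled_feature_sets <- function(stats, q = 0.01) {
  conds <- unique(stats$condition)
  out <- lapply(conds, function(co) {
    exprs <- unique(stats$expression[stats$condition == co])
    masks <- lapply(exprs, function(ex) {
      positive_edge_mask(stats[stats$expression == ex &
                                 stats$condition == co, ], q)
    })
    pool_masks(masks)
  })
  names(out) <- conds
  out
}

#' Second-level thresholded group network
#'
#' Edges whose FDR-adjusted two-sided one-sample p falls below the
#' threshold, sign retained, sorted by decreasing `|t|`.
#'
#' @param stats One cell of [group_edge_stats()] output.
#' @param p_threshold Threshold on the adjusted p (default 0.001).
#' @return Tibble of surviving edges: `edge`, `i`, `j`, `mean_z`,
#'   `t_stat`, `p_adjusted`, `sign`.
#' @export
second_level_network <- function(stats, p_threshold = 0.001) {
  stopifnot(dplyr::n_distinct(stats$expression) == 1,
            dplyr::n_distinct(stats$condition) == 1)
  keep <- stats[stats$p_adjusted < p_threshold, , drop = FALSE]
  keep$sign <- sign(keep$t_stat)
  keep <- keep[order(-abs(keep$t_stat)), , drop = FALSE]
  tibble::as_tibble(keep[, c("expression", "condition", "edge", "i", "j",
                             "mean_z", "t_stat", "p_adjusted", "sign")])
}
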