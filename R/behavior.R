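#' Summarize a behavioral response table
#'
#' Per subject x condition x expression means of classification accuracy,
#' intensity rating and reaction time, with trial counts.
#'
#' @param table Behavioral tibble with columns `subject_id`, `condition`,
#'   `expression`, `correct`, `intensity`, `rt_ms` (see
#'   [simulate_behavior()]).
#' @param expressions,conditions Admissible labels; unknown labels fail.
#' @return Tibble with one row per observed subject x condition x
#'   expression cell: `n_trials`, `accuracy`, `mean_intensity`,
#'   `mean_rt_ms`.
#' @export
summarize_behavior <- function(table,
                               expressions = c("anger", "disgust", "fear",
                                               "joy", "sadness", "surprise"),
                               conditions = c("static", "dynamic")) {
  if (nrow(table) == 0) stop("empty behavioral table")
  bad_e <- setdiff(unique(table$expression), expressions)
  bad_c <- setdiff(unique(table$condition), conditions)
  if (length(bad_e) || length(bad_c)) {
    stop("unknown labels: ", paste(c(bad_e, bad_c), collapse = ", "))
  }
  if (any(table$intensity < 1 | table$intensity > 9)) {
    stop("intensity ratings must lie in 1..9")
  }
  table |>
    dplyr::group_by(.data$subject_id, .data$condition, .data$expression) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      accuracy = mean(.data$correct),
      mean_intensity = mean(.data$intensity),
      mean_rt_ms = mean(.data$rt_ms),
      .groups = "drop"
    )
}

#' One-tailed paired t-test
#'
#' t on the paired differences `d = b - a`:
#' `t = mean(d) / (sd(d) / sqrt(n))`, `df = n - 1`, one-tailed p in the
#' stated direction. With 18 paired subjects, `df = 17`.
#'
#' @param a,b Paired per-subject values (same order and length).
#' @param alternative `"greater"` tests `b > a`; `"less"` tests `b < a`.
#' @return List with `t`, `df`, `p`, `mean_diff`.
#' @export
#' @examples
#' paired_t_one_tailed(c(0.1, 0.2), c(0.2, 0.5)) # t = 2, df = 1
paired_t_one_tailed <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- b - a
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, df = n - 1, p = 0.5, mean_diff = 0))
    }
    stop("zero variance in paired differences")
  }
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  p <- if (alternative == "greater") {
    stats::pt(t, n - 1, lower.tail = FALSE)
  } else {
    stats::pt(t, n - 1)
  }
  list(t = t, df = n - 1, p = p, mean_diff = mean(d))
}

#' Static-vs-dynamic behavioral comparison
#'
#' Averages accuracy over expressions to one value per subject per
#' condition and runs the one-tailed paired t-test for a dynamic-over-
#' static accuracy advantage; intensity and reaction time are compared the
#' same way (two summaries often reported alongside).
#'
#' @param table Behavioral tibble.
#' @return Tibble with one row per measure (`accuracy`, `intensity`,
#'   `rt_ms`): `t`, `df`, `p_one_tailed`, `mean_static`, `mean_dynamic`.
#' @export
compare_conditions_behavior <- function(table) {
  summ <- summarize_behavior(table) |>
    dplyr::group_by(.data$subject_id, .data$condition) |>
    dplyr::summarise(accuracy = mean(.data$accuracy),
                     intensity = mean(.data$mean_intensity),
                     rt_ms = mean(.data$mean_rt_ms), .groups = "drop")
  wide <- tidyr::pivot_wider(summ, names_from = "condition",
                             values_from = c("accuracy", "intensity",
                                             "rt_ms"))
  one <- function(measure) {
    a <- wide[[paste0(measure, "_static")]]
    b <- wide[[paste0(measure, "_dynamic")]]
    tt <- paired_t_one_tailed(a, b, "greater")
    tibble::tibble(measure = measure, t = tt$t, df = tt$df,
                   p_one_tailed = tt$p,
                   mean_static = mean(a), mean_dynamic = mean(b))
  }
  dplyr::bind_rows(lapply(c("accuracy", "intensity", "rt_ms"), one))
}
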