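#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a decoding result
#'
#' One row per test prediction: the held-out subject, the true and the
#' predicted expression, and whether they agree.
#'
#' @param x A `decoding_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy decoding_result
#' @export
tidy.decoding_result <- function(x, ...) {
  dplyr::mutate(x$predictions, correct = .data$true == .data$predicted)
}

#' Summarize a decoding result in one row
#'
#' @param x A `decoding_result`.
#' @param ... Unused.
#' @return One-row tibble: `condition`, `accuracy`, `n_predictions`,
#'   `n_folds`, `p_value` (NA without a permutation run),
#'   `n_permutations`.
#' @method glance decoding_result
#' @export
glance.decoding_result <- function(x, ...) {
  tibble::tibble(
    condition = x$condition %||% NA_character_,
    accuracy = x$accuracy,
    n_predictions = nrow(x$predictions),
    n_folds = length(x$selected_features),
    p_value = x$p_value %||% NA_real_,
    n_permutations = length(x$permutation_null %||% numeric(0))
  )
}

#' @rdname tidy.decoding_result
#' @method tidy discriminative_network
#' @export
tidy.discriminative_network <- function(x, ...) {
  x$edges
}

#' @rdname glance.decoding_result
#' @method glance discriminative_network
#' @export
glance.discriminative_network <- function(x, ...) {
  tibble::tibble(condition = x$condition %||% NA_character_,
                 n_consensus_edges = nrow(x$edges),
                 n_folds = x$n_folds,
                 n_involved_nodes = sum(x$node_degrees$degree > 0))
}

#' Plot a decoding result
#'
#' Permutation-null histogram with the observed accuracy (solid line) and
#' the six-way chance level (dashed line). Without a permutation null,
#' plots the per-class accuracy from the confusion counts.
#'
#' @param object A `decoding_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot decoding_result
#' @export
autoplot.decoding_result <- function(object, ...) {
  chance <- 1 / length(object$classes)
  if (!is.null(object$permutation_null)) {
    df <- tibble::tibble(accuracy = object$permutation_null)
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$accuracy)) +
        ggplot2::geom_histogram(bins = 30, fill = "grey70",
                                color = "grey40") +
        ggplot2::geom_vline(xintercept = object$accuracy,
                            linewidth = 0.8) +
        ggplot2::geom_vline(xintercept = chance, linetype = "dashed") +
        ggplot2::labs(
          x = "accuracy", y = "permutations",
          title = sprintf("%s decoding: accuracy %.3f, p = %.3g",
                          object$condition %||% "", object$accuracy,
                          object$p_value),
          subtitle = "solid: observed; dashed: chance") +
        ggplot2::theme_minimal()
    )
  }
  per_class <- tibble::tibble(
    class = rownames(object$confusion),
    accuracy = diag(object$confusion) / rowSums(object$confusion)
  )
  ggplot2::ggplot(per_class,
                  ggplot2::aes(x = .data$class, y = .data$accuracy)) +
    ggplot2::geom_col(fill = "grey60") +
    ggplot2::geom_hline(yintercept = chance, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "accuracy") +
    ggplot2::theme_minimal()
}

#' Plot a discriminative network's node degrees
#'
#' Horizontal bar chart of the nodes incident to at least one consensus
#' edge, ordered by degree.
#'
#' @param object A `discriminative_network`.
#' @param top_n Show at most this many nodes.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot discriminative_network
#' @export
autoplot.discriminative_network <- function(object, top_n = 30, ...) {
  df <- object$node_degrees |>
    dplyr::filter(.data$degree > 0) |>
    dplyr::arrange(dplyr::desc(.data$degree)) |>
    utils::head(top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree,
                                   y = stats::reorder(.data$label,
                                                      .data$degree))) +
    ggplot2::geom_col(fill = "grey50") +
    ggplot2::labs(x = "consensus-edge degree", y = NULL,
                  title = sprintf("%s discriminative network",
                                  object$condition %||% "")) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap for a decoding result
#'
#' @param result A `decoding_result`.
#' @return A ggplot object.
#' @export
plot_confusion <- function(result) {
  df <- tibble::as_tibble(as.data.frame(result$confusion))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "true", fill = "count") +
    ggplot2::theme_minimal()
}
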