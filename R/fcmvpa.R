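#' Decoding specification
#'
#' Parameters of the leave-one-subject-out decoding engine: fold-internal
#' one-way ANOVA feature selection at `anova_alpha`, a one-vs-one linear
#' support-vector ensemble with majority voting, and a permutation null of
#' `n_permutations` label shuffles re-running the full cross-validation.
#'
#' @param anova_alpha Selection threshold on the per-feature ANOVA p.
#' @param n_permutations Label shuffles for the permutation null.
#' @param svm_c Soft-margin cost of the binary linear SVMs.
#' @param tie_break Vote-tie rule: `"summed_margins"` (largest summed
#'   signed decision values among tied classes) or `"lowest_index"`.
#' @param permute_within_subject Shuffle labels within each subject
#'   (preserves subject exchangeability); `FALSE` shuffles globally.
#' @param nested_positivity Recompute the pooled positive-edge feature
#'   space inside each training fold (no test subject enters the
#'   positivity masks) instead of using a fixed, cohort-level feature
#'   space. The fixed space reproduces the classical analysis; the
#'   nested variant removes its mild circularity.
#' @param positive_q FDR level of the per-class positivity masks used
#'   when `nested_positivity = TRUE`.
#' @param smoothed_p Use `(b + 1) / (n + 1)` for the permutation p instead
#'   of the plain `b / n` count fraction.
#' @param seed Integer seed driving the permutation stream.
#' @return An object of class `decoding_spec`.
#' @export
decoding_spec <- function(anova_alpha = 0.05,
                          n_permutations = 1000,
                          svm_c = 1.0,
                          tie_break = c("summed_margins", "lowest_index"),
                          permute_within_subject = TRUE,
                          nested_positivity = FALSE,
                          positive_q = 0.01,
                          smoothed_p = FALSE,
                          seed = 1) {
  tie_break <- match.arg(tie_break)
  stopifnot(anova_alpha > 0, anova_alpha < 1, n_permutations >= 1,
            svm_c > 0, positive_q > 0, positive_q < 1)
  structure(list(anova_alpha = anova_alpha,
                 n_permutations = as.integer(n_permutations),
                 svm_c = svm_c, tie_break = tie_break,
                 permute_within_subject = permute_within_subject,
                 nested_positivity = nested_positivity,
                 positive_q = positive_q,
                 smoothed_p = smoothed_p, seed = seed),
            class = "decoding_spec")
}

#' One-way ANOVA F statistic
#'
#' `F = (SSB / (k - 1)) / (SSW / (n - k))` with the p-value from the F
#' distribution. Accepts a single feature vector or a samples x features
#' matrix (vectorized). Zero within-group variance with distinct group
#' means yields `F = Inf`, `p = 0`.
#'
#' @param feature_values Numeric vector, or n x p matrix.
#' @param labels Class labels, length n, at least two classes present.
#' @return For a vector: list with `f`, `df_between`, `df_within`, `p`.
#'   For a matrix: tibble with one row per feature.
#' @export
#' @examples
#' anova_f(c(1, 2, 3, 4), c("a", "a", "b", "b")) # F = 8
anova_f <- function(feature_values, labels) {
  g <- factor(labels)
  if (nlevels(g) < 2) stop("need at least 2 classes")
  if (is.matrix(feature_values)) {
    res <- col_anova(feature_values, g)
    return(tibble::tibble(f = res$f, df_between = res$df1,
                          df_within = res$df2, p = res$p))
  }
  res <- col_anova(matrix(feature_values, ncol = 1), g)
  list(f = res$f[1], df_between = res$df1, df_within = res$df2,
       p = res$p[1])
}

#' @keywords internal vectorized one-way ANOVA over matrix columns
#' @noRd
col_anova <- function(x, g, css = NULL) {
  n <- nrow(x)
  ng <- tabulate(g)
  k <- length(ng)
  if (any(ng == 0)) stop("empty class in ANOVA")
  if (n - k < 1) stop("no within-group degrees of freedom")
  gs <- rowsum(x, g)                      # k x p group sums
  gm <- gs / ng
  grand <- colSums(gs) / n
  ssb <- colSums(ng * (gm - rep(grand, each = k))^2)
  if (is.null(css)) css <- colSums(x^2)
  sst <- css - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[ssw == 0 & ssb > 0] <- Inf
  f[ssw == 0 & ssb == 0] <- 0
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  p[is.infinite(f)] <- 0
  list(f = f, df1 = k - 1, df2 = n - k, p = p)
}

#' @keywords internal fit one binary C-classification linear SVM via the
#'   LIBSVM solver that e1071 registers, returning the primal weights.
#'   A thin matrix-only path around the same C routine `e1071::svm` calls;
#'   equivalence with `e1071::svm` is asserted in the test suite.
#' @noRd
fit_linear_binary_svm <- function(x, y, cost) {
  nr <- nrow(x)
  err <- paste(rep(" ", 255), collapse = "")
  sym <- tryCatch(get("R_svmtrain", envir = asNamespace("e1071")),
                  error = function(e) {
                    getNativeSymbolInfo("svmtrain", PACKAGE = "e1071")
                  })
  cret <- .C(sym,
    as.double(t(x)), as.integer(nr), as.integer(ncol(x)),
    as.double(as.integer(y)),
    as.integer(0), as.integer(0),
    as.integer(0),             # type: C-classification
    as.integer(0),             # kernel: linear
    as.integer(3), as.double(1 / ncol(x)), as.double(0),
    as.double(cost), as.double(0.5),
    as.integer(integer(0)), as.double(numeric(0)), as.integer(0),
    as.double(40), as.double(0.001), as.double(0.1),
    as.integer(1), as.integer(0), as.integer(0), as.integer(0),
    nclasses = integer(1), nr = integer(1), index = integer(nr),
    labels = integer(2), nSV = integer(2), rho = double(1),
    coefs = double(nr), sigma = double(1), probA = double(1),
    probB = double(1), cresults = double(0), ctotal1 = double(1),
    ctotal2 = double(1), error = err)
  if (!identical(cret$error, err)) {
    stop("LIBSVM training failed: ", trimws(cret$error))
  }
  idx <- cret$index[seq_len(cret$nr)]
  w <- drop(crossprod(x[idx, , drop = FALSE], cret$coefs[seq_len(cret$nr)]))
  # decision value x.w - rho is positive for the class LIBSVM saw first
  list(w = w, rho = cret$rho[1],
       positive = levels(y)[cret$labels[1]],
       negative = levels(y)[cret$labels[2]])
}

#' Train a one-vs-one linear SVM ensemble
#'
#' One binary linear max-margin classifier per unordered class pair
#' (15 for six classes), each trained on the standardized training
#' features; standardization parameters are estimated on the training
#' data only and stored with the model.
#'
#' @param train_x Samples x features numeric matrix.
#' @param train_y Class labels (all classes must be present).
#' @param spec A [decoding_spec()].
#' @return An object of class `pairwise_ensemble`.
#' @export
train_pairwise_ensemble <- function(train_x, train_y,
                                    spec = decoding_spec()) {
  y <- as.factor(train_y) # declared factor levels are kept
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (any(tabulate(y, nbins = nlevels(y)) == 0)) {
    stop("missing class in training data")
  }
  x <- as.matrix(train_x)
  ctr <- colMeans(x)
  scl <- col_sds(x)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  pairs <- utils::combn(levels(y), 2, simplify = FALSE)
  models <- lapply(pairs, function(pr) {
    rows <- y %in% pr
    fit_linear_binary_svm(xs[rows, , drop = FALSE],
                          factor(y[rows], levels = pr), spec$svm_c)
  })
  structure(list(models = models, pairs = pairs, levels = levels(y),
                 center = ctr, scale = scl, tie_break = spec$tie_break),
            class = "pairwise_ensemble")
}

#' Predict by one-vs-one majority vote
#'
#' Every pairwise classifier casts one vote per sample; the class with the
#' most votes wins. Vote ties are broken by the largest summed signed
#' margin (default) or the lowest class index.
#'
#' @param model A [train_pairwise_ensemble()] fit.
#' @param x Test samples x features matrix (training feature space).
#' @param type `"class"` for labels, `"votes"` for the vote and margin
#'   matrices.
#' @return Character labels, or a list with `votes` and `margins`
#'   matrices.
#' @export
predict_vote <- function(model, x, type = c("class", "votes")) {
  type <- match.arg(type)
  x <- as.matrix(x)
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  n <- nrow(xs)
  k <- length(model$levels)
  votes <- matrix(0L, n, k, dimnames = list(NULL, model$levels))
  margins <- matrix(0, n, k, dimnames = list(NULL, model$levels))
  for (m in model$models) {
    dv <- drop(xs %*% m$w) - m$rho # positive favors m$positive
    a <- m$positive
    b <- m$negative
    up <- dv > 0
    votes[, a] <- votes[, a] + as.integer(up)
    votes[, b] <- votes[, b] + as.integer(!up)
    margins[, a] <- margins[, a] + dv
    margins[, b] <- margins[, b] - dv
  }
  if (type == "votes") return(list(votes = votes, margins = margins))
  vapply(seq_len(n), function(s) {
    best <- which(votes[s, ] == max(votes[s, ]))
    if (length(best) > 1 && model$tie_break == "summed_margins") {
      best <- best[which.max(margins[s, best])]
    }
    model$levels[best[1]]
  }, character(1))
}

#' @export
print.pairwise_ensemble <- function(x, ...) {
  cat(sprintf("<pairwise_ensemble> %d classes, %d binary linear SVMs\n",
              length(x$levels), length(x$models)))
  invisible(x)
}

#' @keywords internal lean LOOCV accuracy used by the permutation engine
#' @noRd
loocv_accuracy_fast <- function(fold_x_tr, fold_x_te, fold_css, fold_y_tr,
                                y_te, spec) {
  correct <- 0L
  total <- 0L
  for (f in seq_along(fold_x_tr)) {
    g <- factor(fold_y_tr[[f]])
    an <- col_anova(fold_x_tr[[f]], g, css = fold_css[[f]])
    sel <- which(an$p < spec$anova_alpha)
    if (length(sel) == 0) sel <- seq_len(ncol(fold_x_tr[[f]]))
    mod <- train_pairwise_ensemble(fold_x_tr[[f]][, sel, drop = FALSE],
                                   fold_y_tr[[f]], spec)
    pred <- predict_vote(mod, fold_x_te[[f]][, sel, drop = FALSE])
    correct <- correct + sum(pred == y_te[[f]])
    total <- total + length(pred)
  }
  correct / total
}

#' @keywords internal pooled positive-edge mask computed from a sample
#'   block (rows = subject x class samples): per-class one-sample t
#'   across that class's rows, BH within class, t > 0, union over classes
#' @noRd
nested_positive_mask <- function(x, y, q) {
  classes <- unique(y)
  masks <- lapply(classes, function(cl) {
    st <- one_sample_t(x[y == cl, , drop = FALSE])
    st$t > 0 & bh_fdr(st$p) <= q
  })
  Reduce(`|`, masks)
}

#' Leave-one-subject-out decoding
#'
#' Per fold: hold out one subject, select features on the training
#' subjects only (one-way ANOVA at `anova_alpha` over the feature space),
#' train the one-vs-one linear SVM ensemble, and predict the held-out
#' subject's samples. Accuracy is pooled over all test predictions. A fold
#' selecting zero features falls back to the full feature space (logged in
#' the result).
#'
#' @param samples List from [edge_samples()]: `x` (samples x canonical
#'   edges), `subject_id`, `expression`, `condition`.
#' @param spec A [decoding_spec()].
#' @param feature_space Logical mask over canonical edges (e.g. a pooled
#'   positive-edge set); `NULL` uses every edge.
#' @return A `decoding_result`: `accuracy`, `predictions` (tibble with
#'   `left_out_subject`, `true`, `predicted`), `confusion` (table),
#'   `selected_features` (per-fold list of canonical edge ids),
#'   `fallback_folds`, `condition`, `n_rois`, `classes`, `spec`.
#' @export
loocv_decode <- function(samples, spec = decoding_spec(),
                         feature_space = NULL) {
  x <- samples$x
  y <- as.character(samples$expression)
  subj <- as.character(samples$subject_id)
  E <- ncol(x)
  n_rois <- as.integer(round((1 + sqrt(1 + 8 * E)) / 2))
  cols <- if (is.null(feature_space)) seq_len(E) else which(feature_space)
  if (length(cols) == 0) stop("empty feature space")
  xs <- x[, cols, drop = FALSE]
  subjects <- unique(subj)
  per_subj <- table(factor(subj, levels = subjects))
  cls <- sort(unique(y))
  preds <- vector("list", length(subjects))
  selected <- vector("list", length(subjects))
  fallback <- character(0)
  for (f in seq_along(subjects)) {
    te <- subj == subjects[f]
    tr <- !te
    fold_cols <- seq_len(ncol(xs))
    if (isTRUE(spec$nested_positivity)) {
      pos <- nested_positive_mask(xs[tr, , drop = FALSE], y[tr],
                                  spec$positive_q)
      if (any(pos)) fold_cols <- which(pos)
    }
    an <- col_anova(xs[tr, fold_cols, drop = FALSE], factor(y[tr]))
    sel <- fold_cols[an$p < spec$anova_alpha]
    if (length(sel) == 0) {
      sel <- fold_cols
      fallback <- c(fallback, subjects[f])
    }
    mod <- train_pairwise_ensemble(xs[tr, sel, drop = FALSE], y[tr], spec)
    pr <- predict_vote(mod, xs[te, sel, drop = FALSE])
    preds[[f]] <- tibble::tibble(left_out_subject = subjects[f],
                                 true = y[te], predicted = pr)
    selected[[f]] <- cols[sel]
  }
  names(selected) <- subjects
  predictions <- dplyr::bind_rows(preds)
  conf <- table(true = factor(predictions$true, levels = cls),
                predicted = factor(predictions$predicted, levels = cls))
  structure(list(
    accuracy = mean(predictions$true == predictions$predicted),
    predictions = predictions,
    confusion = conf,
    selected_features = selected,
    fallback_folds = fallback,
    condition = samples$condition,
    n_rois = n_rois,
    classes = cls,
    spec = spec
  ), class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> condition %s: accuracy %.3f over %d predictions (%d folds)\n",
              x$condition %||% "?", x$accuracy, nrow(x$predictions),
              length(x$selected_features)))
  if (!is.null(x$p_value)) {
    cat(sprintf("  permutation p = %.4g (%d shuffles)\n",
                x$p_value, length(x$permutation_null)))
  }
  invisible(x)
}

#' Permutation test of decoding accuracy
#'
#' Repeats the full leave-one-subject-out procedure — including the
#' fold-internal feature selection — for `n_permutations` random shuffles
#' of the class labels (within subject by default), and reports
#' `p = #(null accuracies >= observed) / n_permutations`.
#'
#' @inheritParams loocv_decode
#' @return The observed [loocv_decode()] result augmented with
#'   `permutation_null` (vector of null accuracies) and `p_value`.
#' @export
permutation_test <- function(samples, spec = decoding_spec(),
                             feature_space = NULL) {
  observed <- loocv_decode(samples, spec, feature_space)
  x <- samples$x
  y <- as.character(samples$expression)
  subj <- as.character(samples$subject_id)
  cols <- if (is.null(feature_space)) seq_len(ncol(x)) else which(feature_space)
  xs <- x[, cols, drop = FALSE]
  subjects <- unique(subj)
  te_idx <- lapply(subjects, function(s) which(subj == s))
  tr_idx <- lapply(te_idx, function(ix) setdiff(seq_along(subj), ix))
  fold_x_tr <- lapply(tr_idx, function(ix) xs[ix, , drop = FALSE])
  fold_x_te <- lapply(te_idx, function(ix) xs[ix, , drop = FALSE])
  fold_css <- lapply(fold_x_tr, function(m) colSums(m^2))
  null_acc <- with_seed(derive_seed(spec$seed, "permutation"), {
    vapply(seq_len(spec$n_permutations), function(b) {
      yb <- if (spec$permute_within_subject) {
        out <- y
        for (s in subjects) {
          ix <- which(subj == s)
          out[ix] <- y[ix][sample.int(length(ix))]
        }
        out
      } else {
        y[sample.int(length(y))]
      }
      loocv_accuracy_fast(fold_x_tr, fold_x_te, fold_css,
                          lapply(tr_idx, function(ix) yb[ix]),
                          lapply(te_idx, function(ix) yb[ix]),
                          spec)
    }, numeric(1))
  })
  observed$permutation_null <- null_acc
  observed$p_value <- if (spec$smoothed_p) {
    (sum(null_acc >= observed$accuracy) + 1) / (spec$n_permutations + 1)
  } else {
    sum(null_acc >= observed$accuracy) / spec$n_permutations
  }
  observed
}

#' Consensus-feature discriminative network
#'
#' Edges selected by the fold-internal ANOVA filter in *every*
#' leave-one-subject-out fold, mapped to ROI pairs; their per-node incident
#' counts form the node-degree table. Labels and MNI coordinates come from
#' an atlas table when provided.
#'
#' @param result A [loocv_decode()] / [permutation_test()] result.
#' @param atlas Optional atlas tibble ([atlas_table()]): columns
#'   `roi_index` (0-based), `label`, and optionally `mni_x/y/z`.
#' @return A `discriminative_network`: `edges` (tibble `edge`, `i`, `j`,
#'   labels, selection count per fold), `node_degrees` (tibble
#'   `roi_index`, `label`, `degree`), `condition`, `n_folds`.
#' @export
consensus_network <- function(result, atlas = NULL) {
  stopifnot(inherits(result, "decoding_result"))
  sel <- result$selected_features
  consensus <- Reduce(intersect, sel)
  counts <- table(unlist(sel))
  ei <- edge_index(result$n_rois)
  edges <- ei[ei$edge %in% consensus, , drop = FALSE]
  edges$n_folds_selected <- as.integer(counts[as.character(edges$edge)])
  if (!is.null(atlas)) {
    lab <- atlas$label[match(edges$i, atlas$roi_index)]
    edges$label_i <- lab
    edges$label_j <- atlas$label[match(edges$j, atlas$roi_index)]
  } else {
    edges$label_i <- sprintf("ROI_%03d", edges$i + 1L)
    edges$label_j <- sprintf("ROI_%03d", edges$j + 1L)
  }
  deg <- tabulate(c(edges$i, edges$j) + 1L, nbins = result$n_rois)
  node_degrees <- tibble::tibble(
    roi_index = seq_len(result$n_rois) - 1L,
    label = if (!is.null(atlas)) {
      atlas$label[match(seq_len(result$n_rois) - 1L, atlas$roi_index)]
    } else {
      sprintf("ROI_%03d", seq_len(result$n_rois))
    },
    degree = deg
  )
  structure(list(edges = tibble::as_tibble(edges),
                 node_degrees = node_degrees,
                 condition = result$condition,
                 n_folds = length(sel)),
            class = "discriminative_network")
}

#' @export
print.discriminative_network <- function(x, ...) {
  cat(sprintf("<discriminative_network> %s: %d consensus edges over %d folds, %d involved nodes\n",
              x$condition %||% "?", nrow(x$edges), x$n_folds,
              sum(x$node_degrees$degree > 0)))
  invisible(x)
}
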