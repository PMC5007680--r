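#' Configuration for the gene-subset fitness
#'
#' The gene-selection fitness to be maximized is
#' \deqn{F(x) = w_1 A(x) + w_2 \frac{M - R(x)}{M}}
#' where A(x) is the leave-one-out cross-validation accuracy of a classifier
#' restricted to the subset x, R(x) the number of selected genes and M the
#' total gene count.  w1 weights accuracy, w2 rewards small subsets.
#'
#' @param w1 Non-negative weight for the accuracy term (default 0.75).
#' @param w2 Non-negative weight for the subset-size reward (default 0.25).
#' @param M Total number of genes (>= 1).
#' @return Object of class `selection_config`.
#' @export
selection_config <- function(w1 = 0.75, w2 = 0.25, M) {
  if (!is.numeric(w1) || length(w1) != 1L || is.na(w1) || w1 < 0) {
    stop("w1 must be a non-negative scalar")
  }
  if (!is.numeric(w2) || length(w2) != 1L || is.na(w2) || w2 < 0) {
    stop("w2 must be a non-negative scalar")
  }
  M <- as.integer(M)
  if (length(M) != 1L || is.na(M) || M < 1L) stop("M must be >= 1")
  structure(list(w1 = w1, w2 = w2, M = M), class = "selection_config")
}

#' Weighted gene-subset fitness F(x)
#'
#' @param A Classification accuracy in \[0, 1\].
#' @param R Number of selected genes, 0 <= R <= M.
#' @param cfg A [selection_config()].
#' @return Scalar fitness `w1 * A + w2 * (M - R) / M` (maximization
#'   semantics).
#' @examples
#' subset_fitness(0.8, 25, selection_config(0.75, 0.25, M = 100))  # 0.7875
#' @export
subset_fitness <- function(A, R, cfg) {
  if (!inherits(cfg, "selection_config")) stop("cfg must be a selection_config")
  if (!is.numeric(A) || length(A) != 1L || is.na(A) || A < 0 || A > 1) {
    stop("accuracy A must lie in [0, 1]")
  }
  R <- as.integer(R)
  if (length(R) != 1L || is.na(R) || R < 0L || R > cfg$M) {
    stop("R must satisfy 0 <= R <= M (M = ", cfg$M, ")")
  }
  cfg$w1 * A + cfg$w2 * (cfg$M - R) / cfg$M
}

#' Nearest-centroid classifier
#'
#' The default pluggable classifier: training computes one centroid (mean
#' expression vector over the selected genes) per class; prediction assigns
#' the class of the Euclidean-nearest centroid.  Ties are broken in favour of
#' the class that comes first in sorted class-label order, so the classifier
#' is fully deterministic.
#'
#' A classifier spec is a list with fields `name`, `train(X, y)` returning a
#' model, and `predict(model, X)` returning one label per row of `X`.
#'
#' @return A classifier spec usable by [loocv_accuracy()].
#' @export
nearest_centroid_classifier <- function() {
  list(
    name = "nearest-centroid",
    train = function(X, y) {
      y <- as.character(y)
      classes <- sort(unique(y))
      centroids <- do.call(rbind, lapply(classes, function(cl) {
        colMeans(X[y == cl, , drop = FALSE])
      }))
      list(classes = classes, centroids = centroids)
    },
    predict = function(model, X) {
      X <- matrix(X, ncol = ncol(model$centroids))
      apply(X, 1L, function(x) {
        d2 <- rowSums(sweep(model$centroids, 2L, x)^2)
        model$classes[which.min(d2)]  # which.min: first (sorted) class wins
      })
    })
}

resolve_classifier <- function(classifier) {
  if (is.character(classifier)) {
    return(switch(classifier,
      "nearest-centroid" = nearest_centroid_classifier(),
      stop("unknown classifier: ", classifier)))
  }
  if (is.list(classifier) && is.function(classifier$train) &&
      is.function(classifier$predict)) {
    return(classifier)
  }
  stop("classifier must be a name or a list with train() and predict()")
}

#' Leave-one-out cross-validation accuracy of a gene subset
#'
#' For each of the N samples the classifier is trained on the other N - 1
#' samples restricted to the selected genes and then predicts the held-out
#' sample.  The result is deterministic for any deterministic classifier.
#'
#' @param d A [labeled_dataset()] with N >= 2 samples and >= 2 classes.
#' @param x A [gene_subset()] with mask length M and at least one selected
#'   gene (a plain logical vector is accepted).
#' @param classifier A classifier spec or name; default
#'   [nearest_centroid_classifier()].
#' @return Object of class `accuracy_result`: list with `A` (fraction
#'   correct) and `per_fold` (logical correctness per sample).
#' @export
loocv_accuracy <- function(d, x, classifier = nearest_centroid_classifier()) {
  if (!inherits(d, "labeled_dataset")) stop("d must be a labeled_dataset")
  if (is.logical(x)) x <- gene_subset(x)
  if (!inherits(x, "gene_subset")) stop("x must be a gene_subset")
  if (length(x$mask) != ncol(d$matrix)) {
    stop("mask length (", length(x$mask), ") != number of genes (",
         ncol(d$matrix), ")")
  }
  if (x$R < 1L) stop("no genes selected")
  if (nlevels(droplevels(d$labels)) < 2L) {
    stop("classification needs at least 2 classes")
  }
  N <- nrow(d$matrix)
  if (N < 2L) stop("LOOCV needs at least 2 samples")
  clf <- resolve_classifier(classifier)
  X <- as_plain_matrix(d$matrix)[, x$mask, drop = FALSE]
  y <- as.character(d$labels)
  per_fold <- logical(N)
  for (i in seq_len(N)) {
    model <- clf$train(X[-i, , drop = FALSE], y[-i])
    per_fold[i] <- identical(clf$predict(model, X[i, , drop = FALSE])[[1L]],
                             y[i])
  }
  structure(list(A = mean(per_fold), per_fold = per_fold),
            class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("LOOCV accuracy: %.4f (%d/%d folds correct)\n",
              x$A, sum(x$per_fold), length(x$per_fold)))
  invisible(x)
}

#' Dataset-backed gene-subset fitness
#'
#' Computes `subset_fitness(loocv_accuracy(d, x, classifier)$A, x$R, cfg)`.
#'
#' @inheritParams loocv_accuracy
#' @param cfg A [selection_config()]; its `M` must equal the dataset's gene
#'   count.
#' @return Scalar fitness F(x).
#' @export
evaluate_subset <- function(d, x, cfg,
                            classifier = nearest_centroid_classifier()) {
  if (is.logical(x)) x <- gene_subset(x)
  if (cfg$M != ncol(d$matrix)) {
    stop("cfg$M (", cfg$M, ") != number of genes (", ncol(d$matrix), ")")
  }
  acc <- loocv_accuracy(d, x, classifier)
  subset_fitness(acc$A, x$R, cfg)
}
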