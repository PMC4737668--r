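# Feature-matrix construction and the cross-validated classification
# harness: binary subgraph indicators stacked row-wise, optionally
# concatenated with (normalized) side-view measures per subject, fed to a
# linear-kernel SVM under stratified k-fold cross-validation.

#' Binary feature matrix of patterns over a dataset
#'
#' Row i is the indicator vector of pattern i; column j is the binary
#' subgraph representation of graph j.
#'
#' @param patterns list of \code{subgraph_pattern} objects (e.g. from
#'   \code{\link{mine_top_k}}).
#' @param dataset the \code{\link{graph_dataset}} the indicators refer to.
#' @return object of class \code{feature_matrix}: \code{X} (m x n binary),
#'   \code{patterns}, \code{ids}.
#' @export
feature_matrix <- function(patterns, dataset) {
  stopifnot(inherits(dataset, "graph_dataset"))
  n <- dataset$n
  if (length(patterns) == 0L) {
    X <- matrix(0L, 0L, n)
  } else {
    for (p in patterns)
      if (length(p$indicator) != n)
        stop("pattern indicator length does not match the dataset")
    X <- do.call(rbind, lapply(patterns, `[[`, "indicator"))
  }
  colnames(X) <- dataset$ids
  structure(list(X = X, patterns = patterns, ids = dataset$ids),
            class = "feature_matrix")
}

#' Concatenate subgraph features with side-view measures
#'
#' Returns the per-subject design matrix: one row per graph, binary subgraph
#' features first, then the (already normalized) side-view columns. With no
#' patterns this is the views-only baseline; with no views, pure subgraph
#' features.
#'
#' @param X a \code{feature_matrix} (or m x n binary matrix).
#' @param views list of \code{\link{side_view}} objects.
#' @return numeric n x (m + sum d_p) matrix.
#' @export
augment_with_views <- function(X, views = list()) {
  if (inherits(X, "feature_matrix")) X <- X$X
  design <- t(X)
  if (inherits(views, "side_view")) views <- list(views)
  for (v in views) {
    if (nrow(v$features) != nrow(design))
      stop("side view rows do not align with the subgraph features")
    design <- cbind(design, v$features)
  }
  design
}

stratified_folds <- function(labels, folds, seed = NULL) {
  assign_folds <- function() {
    fold <- integer(length(labels))
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      if (length(idx) < folds)
        stop("class ", cls, " has fewer subjects than folds")
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    fold
  }
  if (is.null(seed)) assign_folds() else with_seed(seed, assign_folds())
}

binary_metrics <- function(truth, pred) {
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == -1)
  fn <- sum(pred == -1 & truth == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(accuracy = mean(pred == truth), precision = precision,
    recall = recall, f1 = f1)
}

fit_predict_svm <- function(train_x, train_y, test_x) {
  keep <- apply(train_x, 2L, function(col) stats::var(col) > 0)
  if (!any(keep)) {
    # no informative feature: predict the majority training class
    maj <- if (sum(train_y == 1) >= sum(train_y == -1)) 1 else -1
    return(rep(maj, nrow(test_x)))
  }
  fit <- e1071::svm(train_x[, keep, drop = FALSE], factor(train_y),
                    kernel = "linear", scale = FALSE)
  as.numeric(as.character(stats::predict(fit, test_x[, keep, drop = FALSE])))
}

#' Cross-validated classification with fixed features
#'
#' Stratified k-fold cross-validation of a linear-kernel SVM on a per-subject
#' design matrix (subgraph features and/or side views). Reports mean
#' accuracy, precision, recall and F1 over folds; precision is the fraction
#' of positive predictions that are positive subjects, recall the fraction
#' of positive subjects predicted positive, F1 their harmonic mean.
#'
#' @param features n x p numeric design matrix (see
#'   \code{\link{augment_with_views}}).
#' @param labels vector in \code{{-1, +1}}, no missing values.
#' @param folds number of folds (default 3).
#' @param seed seed for the fold assignment.
#' @return list with \code{metrics} (mean over folds), \code{per_fold},
#'   \code{folds}, \code{seed}.
#' @export
cross_validate <- function(features, labels, folds = 3, seed = NULL) {
  features <- as.matrix(features)
  labels <- as.numeric(labels)
  if (anyNA(labels)) stop("cross-validation needs fully labeled data")
  if (nrow(features) != length(labels))
    stop("features and labels are misaligned")
  fold <- stratified_folds(labels, folds, seed)
  per_fold <- matrix(NA_real_, folds, 4L,
                     dimnames = list(NULL, c("accuracy", "precision",
                                             "recall", "f1")))
  for (f in seq_len(folds)) {
    test <- fold == f
    pred <- fit_predict_svm(features[!test, , drop = FALSE], labels[!test],
                            features[test, , drop = FALSE])
    per_fold[f, ] <- binary_metrics(labels[test], pred)
  }
  list(metrics = colMeans(per_fold), per_fold = per_fold,
       folds = folds, seed = seed)
}

#' End-to-end cross-validation with per-fold mining
#'
#' The honest protocol: within each fold, patterns are mined and the
#' guidance Laplacian is built from the training subjects only, so test-fold
#' subjects never influence pattern selection (no test leakage). Mined
#' patterns are then evaluated on the test fold by recomputing their support
#' there.
#'
#' @param dataset a fully labeled \code{\link{graph_dataset}}.
#' @param views list of \code{\link{side_view}} objects.
#' @param k,min_sup,max_edges,include_singletons forwarded to
#'   \code{\link{mine_top_k}}.
#' @param folds,seed cross-validation controls.
#' @param use_views append side-view columns to the subgraph features
#'   (default TRUE; FALSE gives the graphs-only model).
#' @return as \code{\link{cross_validate}}, plus \code{k} and
#'   \code{min_sup}.
#' @export
cross_validate_end_to_end <- function(dataset, views = list(), k = 10,
                                      min_sup = 0.3, folds = 3, seed = NULL,
                                      max_edges = Inf,
                                      include_singletons = TRUE,
                                      use_views = TRUE) {
  stopifnot(inherits(dataset, "graph_dataset"))
  labels <- dataset$labels
  if (anyNA(labels)) stop("end-to-end cross-validation needs full labels")
  fold <- stratified_folds(labels, folds, seed)
  per_fold <- matrix(NA_real_, folds, 4L,
                     dimnames = list(NULL, c("accuracy", "precision",
                                             "recall", "f1")))
  for (f in seq_len(folds)) {
    test <- fold == f
    tr_idx <- which(!test)
    tr_ds <- graph_dataset(dataset$graphs[tr_idx], labels[tr_idx],
                           dataset$ids[tr_idx])
    tr_views <- lapply(views, function(v) {
      side_view(v$features[tr_idx, , drop = FALSE], weight = v$weight,
                kernel_kind = v$kernel_kind, normalize = FALSE,
                name = v$name)
    })
    mined <- mine_top_k(tr_ds, tr_views, k = k, min_sup = min_sup,
                        max_edges = max_edges,
                        include_singletons = include_singletons)
    tr_x <- t(feature_matrix(mined$patterns, tr_ds)$X)
    te_idx <- which(test)
    te_x <- vapply(mined$patterns, function(p) {
      vapply(te_idx, function(j)
        as.numeric(is_subgraph_isomorphic(p$graph, dataset$graphs[[j]])),
        numeric(1))
    }, numeric(length(te_idx)))
    te_x <- matrix(te_x, nrow = length(te_idx))
    if (use_views) {
      for (v in views) {
        tr_x <- cbind(tr_x, v$features[tr_idx, , drop = FALSE])
        te_x <- cbind(te_x, v$features[te_idx, , drop = FALSE])
      }
    }
    pred <- fit_predict_svm(tr_x, labels[tr_idx], te_x)
    per_fold[f, ] <- binary_metrics(labels[te_idx], pred)
  }
  list(metrics = colMeans(per_fold), per_fold = per_fold, folds = folds,
       seed = seed, k = k, min_sup = min_sup)
}

#' Balance a dataset by undersampling the majority class
#'
#' @param labels vector in \code{{-1, +1}}.
#' @param seed seed for the subsample.
#' @return sorted integer indices of the retained subjects.
#' @export
balance_indices <- function(labels, seed = NULL) {
  labels <- as.numeric(labels)
  pos <- which(labels == 1); neg <- which(labels == -1)
  m <- min(length(pos), length(neg))
  pick <- function() {
    sort(c(if (length(pos) > m) sample(pos, m) else pos,
           if (length(neg) > m) sample(neg, m) else neg))
  }
  if (is.null(seed)) pick() else with_seed(seed, pick())
}
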