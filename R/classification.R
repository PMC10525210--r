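#' Z-score standardization fitted on training data
#'
#' Computes per-feature mean and population standard deviation on the
#' training matrix; `apply_standardize()` applies them to any matrix with the
#' same columns. Constant training columns (sd 0) map to 0 everywhere, so
#' degenerate features never produce NaN.
#'
#' @param train Numeric training matrix.
#' @return List with `mean`, `sd` (population), usable with [apply_standardize()].
#' @export
standardize <- function(train) {
  train <- as.matrix(train)
  if (nrow(train) == 0L) stop("empty training matrix")
  mu <- colMeans(train)
  s <- sqrt(colMeans(sweep(train, 2, mu)^2))
  list(mean = mu, sd = s)
}

#' @rdname standardize
#' @param params A [standardize()] result.
#' @param x Matrix to transform.
#' @export
apply_standardize <- function(params, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(params$mean)) stop("dimension mismatch in standardization")
  s <- params$sd
  out <- sweep(x, 2, params$mean)
  out <- sweep(out, 2, ifelse(s == 0, 1, s), "/")
  out[, s == 0] <- 0
  out
}

#' 1-nearest-neighbour prediction
#'
#' Assigns each query row the label of its Euclidean-nearest training row;
#' exact distance ties go to the lowest training-row index.
#'
#' @param train_x,train_y Training matrix and integer class codes.
#' @param query_x Query matrix with matching column count.
#' @return Integer vector of predicted class codes.
#' @export
knn1_predict <- function(train_x, train_y, query_x) {
  train_x <- as.matrix(train_x); query_x <- as.matrix(query_x)
  if (nrow(train_x) == 0L) stop("empty training set")
  if (ncol(train_x) != ncol(query_x))
    stop("dimension mismatch: train has ", ncol(train_x), " features, query ",
         ncol(query_x))
  as.integer(.knn1_cpp(train_x, as.integer(train_y), query_x))
}

#' Cross-validation configuration
#'
#' @param n_folds Number of folds (default 10).
#' @param seed Fold-assignment seed.
#' @param stratified Preserve per-fold class proportions (default TRUE).
#' @param grouped Keep samples sharing a `group_id` in one fold.
#' @param mode `"per-fold"` standardizes inside each training fold (the
#'   leakage-free default); `"global"` standardizes once on the whole dataset
#'   before splitting, for strict replication of toolbox-style protocols.
#' @return List of class `asnet_cv_config`.
#' @export
cv_control <- function(n_folds = 10L, seed = 1L, stratified = TRUE,
                       grouped = FALSE, mode = c("per-fold", "global")) {
  structure(list(n_folds = as.integer(n_folds), seed = as.integer(seed),
                 stratified = isTRUE(stratified), grouped = isTRUE(grouped),
                 mode = match.arg(mode)),
            class = "asnet_cv_config")
}

#' Stratified (optionally grouped) fold assignment
#'
#' Shuffles samples within each class with the configured seed, then deals
#' them round-robin over folds, so per-fold class counts differ from exact
#' proportionality by at most one sample. With `grouped = TRUE`, whole
#' groups (e.g. patients) are dealt instead of samples, so no group spans
#' two folds.
#'
#' @param y Integer class codes.
#' @param cfg A [cv_control()].
#' @param group_id Optional group labels (required when `cfg$grouped`).
#' @return Integer fold ids in `1..n_folds`, one per sample.
#' @export
make_folds <- function(y, cfg = cv_control(), group_id = NULL) {
  n <- length(y)
  k <- cfg$n_folds
  if (k < 2L) stop("n_folds must be >= 2")
  if (k > n) stop("n_folds (", k, ") exceeds sample count (", n, ")")
  folds <- integer(n)
  if (cfg$grouped) {
    if (is.null(group_id)) stop("grouped CV requires group_id")
    groups <- unique(group_id)
    # majority class per group for stratified dealing of whole groups
    gclass <- vapply(groups, function(g) {
      tab <- table(y[group_id == g])
      as.integer(names(tab)[which.max(tab)])
    }, integer(1))
    gfold <- integer(length(groups))
    with_seed(cfg$seed, {
      offset <- 0L
      for (cl in sort(unique(gclass))) {
        idx <- which(gclass == cl)
        idx <- idx[sample.int(length(idx))]
        gfold[idx] <- (seq_along(idx) + offset - 1L) %% k + 1L
        offset <- offset + length(idx)
      }
    })
    folds <- gfold[match(group_id, groups)]
  } else if (cfg$stratified) {
    with_seed(cfg$seed, {
      offset <- 0L  # continue the round-robin across classes so no fold is empty
      for (cl in sort(unique(y))) {
        idx <- which(y == cl)
        idx <- idx[sample.int(length(idx))]
        folds[idx] <- (seq_along(idx) + offset - 1L) %% k + 1L
        offset <- offset + length(idx)
      }
    })
  } else {
    with_seed(cfg$seed, {
      idx <- sample.int(n)
      folds[idx] <- rep_len(seq_len(k), n)
    })
  }
  if (any(tabulate(folds, k) == 0L))
    stop("empty fold produced; reduce n_folds")
  folds
}

#' Out-of-fold 1-NN predictions under cross-validation
#'
#' For each fold, fits standardization on the training folds only, applies it
#' to the held-out fold, and predicts with the standardized 1-NN classifier.
#' The returned labels are in the original sample order, each sample
#' predicted exactly once while held out.
#'
#' @param x Feature matrix (typically one selected 272-column set).
#' @param y Integer class codes (truth).
#' @param cfg A [cv_control()].
#' @param group_id Optional group labels for grouped CV.
#' @param provenance Optional identifier stored with the result.
#' @return List of class `asnet_prediction`: `labels` (out-of-fold predicted
#'   codes), `accuracy`, `folds`, `provenance`.
#' @export
cross_val_predict <- function(x, y, cfg = cv_control(), group_id = NULL,
                              provenance = NULL) {
  x <- as.matrix(x)
  y <- as.integer(y)
  folds <- make_folds(y, cfg, group_id)
  pred <- integer(length(y))
  if (cfg$mode == "global") {
    x <- apply_standardize(standardize(x), x)
  }
  for (f in seq_len(cfg$n_folds)) {
    test <- folds == f
    train_x <- x[!test, , drop = FALSE]
    test_x <- x[test, , drop = FALSE]
    if (cfg$mode == "per-fold") {
      p <- standardize(train_x)
      train_x <- apply_standardize(p, train_x)
      test_x <- apply_standardize(p, test_x)
    }
    pred[test] <- knn1_predict(train_x, y[!test], test_x)
  }
  new_prediction(pred, y, provenance, folds = folds)
}

new_prediction <- function(labels, truth, provenance = NULL, folds = NULL) {
  structure(list(labels = as.integer(labels),
                 accuracy = mean(labels == truth),
                 provenance = provenance, folds = folds),
            class = "asnet_prediction")
}

#' @export
print.asnet_prediction <- function(x, ...) {
  cat("Prediction vector (", if (is.null(x$provenance)) "unnamed" else x$provenance,
      "): n = ", length(x$labels), ", accuracy = ",
      sprintf("%.2f%%", 100 * x$accuracy), "\n", sep = "")
  invisible(x)
}
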