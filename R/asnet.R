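#' Fit the self-organized deep feature engineering classifier
#'
#' Runs the full pipeline: per feature matrix and per selector, keep the
#' `k` most informative features, classify with a standardized 1-NN under
#' stratified cross-validation to get one out-of-fold prediction vector per
#' (matrix, selector) pair, fuse the vectors by iterative majority voting,
#' and select the highest-accuracy outcome among all classifier-wise and
#' voted candidates. At the default configuration (6 matrices, 3 selectors,
#' voting loop 3..18) this yields 18 prediction vectors, 16 voted outcomes,
#' and a best-of-34 selection.
#'
#' @param x One of: an `asnet_manifest` (images are read and passed through
#'   the feature extractor), a list of feature matrices with aligned rows, or
#'   a single feature matrix.
#' @param y Integer class codes (1..C), required unless `x` is a manifest.
#' @param selectors Selector names in report order; default
#'   `c("nca", "chi2", "relieff")`.
#' @param k Features kept per selector (default 272, clamped to the matrix width).
#' @param cv A [cv_control()]; its seed defaults to `seed + 101`.
#' @param r_min,r_max Voting loop range (defaults 3 and 18; `r_max` clamps to
#'   the number of prediction vectors).
#' @param pool `"all34"` (default) scans classifier-wise and voted candidates;
#'   `"voted16"` restricts the final selection to voted outcomes.
#' @param selection_mode `"full"` (default) scores features once on the full
#'   dataset before cross-validation, mirroring the pipeline's published
#'   protocol; `"nested"` re-scores inside every training fold (leakage-free,
#'   slower).
#' @param extractor `"toy"` or `"pretrained"`, used only when `x` is a manifest.
#' @param class_labels Optional class names when `x` is not a manifest.
#' @param selector_control Named list of selector hyperparameters
#'   (see [rank_features()]).
#' @param seed Master seed; fans out to the extraction and fold seeds.
#' @return Object of class `asnet`; see [print.asnet()], [summary.asnet()],
#'   [predict.asnet()], [plot.asnet()].
#' @export
#' @examples
#' bank <- gen_feature_bank(fixture_spec(n_per_class = 15, d = 40, seed = 7),
#'                          n_matrices = 2)
#' fit <- asnet(bank$x, bank$labels, k = 20, cv = cv_control(n_folds = 5),
#'              class_labels = bank$class_names)
#' fit
asnet <- function(x, y = NULL, selectors = c("nca", "chi2", "relieff"),
                  k = 272L, cv = NULL, r_min = 3L, r_max = 18L,
                  pool = c("all34", "voted16"),
                  selection_mode = c("full", "nested"),
                  extractor = c("toy", "pretrained"),
                  class_labels = NULL, selector_control = list(),
                  seed = 1L) {
  pool <- match.arg(pool)
  selection_mode <- match.arg(selection_mode)
  extractor <- match.arg(extractor)
  if (!all(selectors %in% c("nca", "chi2", "relieff")))
    stop("unknown selector: ", setdiff(selectors, c("nca", "chi2", "relieff"))[1L])
  group_id <- NULL
  if (inherits(x, "asnet_manifest")) {
    manifest <- x
    y <- manifest$label
    class_labels <- class_names(manifest)
    group_id <- manifest$group_id
    mats <- extract_all(manifest, mode = extractor, seed = seed)
  } else if (is.matrix(x) || is.data.frame(x)) {
    mats <- list(as.matrix(x))
  } else if (is.list(x)) {
    mats <- lapply(x, as.matrix)
  } else stop("x must be a manifest, a feature matrix, or a list of matrices")
  if (is.null(y)) stop("y is required when x is not a manifest")
  y <- as.integer(y)
  n <- length(y)
  if (any(vapply(mats, nrow, integer(1)) != n))
    stop("all feature matrices must have one row per sample (", n, ")")
  if (is.null(class_labels)) class_labels <- as.character(sort(unique(y)))
  if (is.null(cv)) cv <- cv_control(seed = seed + 101L)
  mat_ids <- vapply(seq_along(mats), function(i) {
    bb <- attr(mats[[i]], "backbone"); ly <- attr(mats[[i]], "layer")
    if (!is.null(bb)) paste0(bb, "/", ly) else paste0("F", i)
  }, character(1))

  feature_sets <- list()
  predictions <- list()
  idx <- 0L
  for (m in seq_along(mats)) {
    for (sel in selectors) {
      idx <- idx + 1L
      id <- paste0(mat_ids[m], "+", sel)
      if (selection_mode == "full") {
        ranking <- rank_features(sel, mats[[m]], y, control = selector_control)
        fs <- select_top_k(ranking, mats[[m]], k = k)
        pred <- cross_val_predict(fs$x, y, cfg = cv, group_id = group_id,
                                  provenance = id)
      } else {
        fs <- NULL
        pred <- nested_cv_predict(mats[[m]], y, sel, k, cv, group_id,
                                  selector_control, provenance = id)
      }
      feature_sets[[id]] <- list(matrix = m, selector = sel,
                                 indices = fs$indices, k = fs$k %||% min(k, ncol(mats[[m]])))
      predictions[[id]] <- pred
    }
  }

  voted <- imv(predictions, truth = y, r_min = r_min, r_max = r_max)
  sel_best <- select_best(predictions, voted, pool = pool)
  cm <- confusion(y, sel_best$best$labels, class_labels)
  fit <- structure(list(
    predictions = predictions,
    voted = voted,
    candidates = sel_best$candidates,
    best = sel_best$best,
    best_id = sel_best$best_id,
    accuracy = sel_best$best$accuracy,
    confusion = cm,
    metrics = panel(cm),
    truth = y,
    class_names = class_labels,
    feature_sets = feature_sets,
    matrices = mats,
    matrix_ids = mat_ids,
    sorted_ids = vapply(sort_by_accuracy(predictions),
                        function(p) p$provenance, character(1)),
    config = list(selectors = selectors, k = k, cv = cv, r_min = r_min,
                  r_max = min(r_max, length(predictions)), pool = pool,
                  selection_mode = selection_mode, extractor = extractor,
                  selector_control = selector_control, seed = seed)
  ), class = "asnet")
  counts <- pipeline_counts(fit)
  stopifnot(counts$candidates == counts$classifier_wise + counts$voted)
  fit
}

nested_cv_predict <- function(x, y, sel, k, cv, group_id, control, provenance) {
  folds <- make_folds(y, cv, group_id)
  pred <- integer(length(y))
  for (f in seq_len(cv$n_folds)) {
    test <- folds == f
    ranking <- rank_features(sel, x[!test, , drop = FALSE], y[!test],
                             control = control)
    fs <- select_top_k(ranking, x[!test, , drop = FALSE], k = k)
    train_x <- fs$x
    test_x <- x[test, fs$indices, drop = FALSE]
    if (cv$mode == "per-fold") {
      p <- standardize(train_x)
      train_x <- apply_standardize(p, train_x)
      test_x <- apply_standardize(p, test_x)
    }
    pred[test] <- knn1_predict(train_x, y[!test], test_x)
  }
  new_prediction(pred, y, provenance, folds = folds)
}

#' Structural counts of a fitted pipeline
#'
#' @param fit An `asnet` object.
#' @return List: `matrices`, `selected_sets`, `classifier_wise`, `voted`,
#'   `candidates`.
#' @export
pipeline_counts <- function(fit) {
  list(matrices = length(fit$matrices),
       selected_sets = length(fit$feature_sets),
       classifier_wise = length(fit$predictions),
       voted = length(fit$voted),
       candidates = length(fit$candidates))
}

#' @export
print.asnet <- function(x, ...) {
  ct <- pipeline_counts(x)
  cat("Self-organized deep feature engineering fit\n")
  cat(sprintf("  %d feature matrices x %d selectors -> %d prediction vectors; %d voted outcomes; %d candidates\n",
              ct$matrices, length(x$config$selectors), ct$classifier_wise,
              ct$voted, ct$candidates))
  cat(sprintf("  best outcome: %s, accuracy %s%%\n", x$best_id,
              format(round_half_up(100 * x$accuracy, 2))))
  invisible(x)
}

#' @export
summary.asnet <- function(object, ...) {
  structure(list(fit = object, table = candidate_table(object)),
            class = "summary.asnet")
}

#' @export
print.summary.asnet <- function(x, ...) {
  print(x$fit)
  cat("\nCandidate outcomes (descending accuracy, top 10):\n")
  tab <- x$table[order(-x$table$accuracy), ]
  print(head(tab, 10), row.names = FALSE)
  cat("\n")
  print(x$fit$metrics)
  invisible(x)
}

#' Accuracy table over all candidate outcomes
#'
#' @param fit An `asnet` object.
#' @return Data frame: `id`, `type` (`"classifier-wise"`/`"voted"`),
#'   `accuracy` (percent, 2 decimals).
#' @export
candidate_table <- function(fit) {
  ids <- vapply(fit$candidates, function(p) p$provenance, character(1))
  acc <- vapply(fit$candidates, function(p) p$accuracy, numeric(1))
  data.frame(id = ids,
             type = ifelse(grepl("^voted_r", ids), "voted", "classifier-wise"),
             accuracy = round_half_up(100 * acc, 2),
             stringsAsFactors = FALSE)
}

#' @export
fitted.asnet <- function(object, ...) {
  factor(object$class_names[object$best$labels], levels = object$class_names)
}

#' Classify new samples with a fitted pipeline
#'
#' Each classifier-wise candidate is refit on the full training data (its
#' selected feature columns, standardized) and applied to the new samples;
#' if the selected best outcome is a voted one, the constituent candidates'
#' predictions are fused by per-sample mode exactly as during fitting.
#'
#' @param object An `asnet` fit (with `selection_mode = "full"`).
#' @param newdata A manifest (toy extractor mode), a list of feature matrices
#'   aligned with the training matrices, or a single matrix if the fit used one.
#' @param ... Unused.
#' @return Factor of predicted class names.
#' @export
predict.asnet <- function(object, newdata, ...) {
  if (object$config$selection_mode != "full")
    stop("predict() requires a fit with selection_mode = \"full\"")
  if (inherits(newdata, "asnet_manifest")) {
    newmats <- extract_all(newdata, mode = object$config$extractor,
                           seed = object$config$seed)
  } else if (is.matrix(newdata) || is.data.frame(newdata)) {
    newmats <- list(as.matrix(newdata))
  } else newmats <- lapply(newdata, as.matrix)
  if (length(newmats) != length(object$matrices))
    stop("newdata must provide ", length(object$matrices), " feature matrices")
  predict_one <- function(id) {
    fs <- object$feature_sets[[id]]
    train <- object$matrices[[fs$matrix]][, fs$indices, drop = FALSE]
    query <- newmats[[fs$matrix]][, fs$indices, drop = FALSE]
    p <- standardize(train)
    knn1_predict(apply_standardize(p, train), object$truth,
                 apply_standardize(p, query))
  }
  best <- object$best
  labels <- if (!is.null(best$r)) {
    constituents <- object$sorted_ids[seq_len(best$r)]
    majority_vote(lapply(constituents, predict_one))
  } else predict_one(best$provenance)
  factor(object$class_names[labels], levels = object$class_names)
}

#' Plot candidate accuracies
#'
#' Bar plot of all candidate outcomes' accuracies in candidate order (voted
#' outcomes first, ascending `r`, then classifier-wise), with the selected
#' best highlighted.
#'
#' @param x An `asnet` object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.asnet <- function(x, ...) {
  tab <- candidate_table(x)
  cols <- ifelse(tab$id == x$best_id, "firebrick",
                 ifelse(tab$type == "voted", "steelblue", "grey70"))
  graphics::barplot(tab$accuracy, names.arg = tab$id, col = cols, las = 2,
                    cex.names = 0.55, ylab = "Accuracy (%)",
                    main = "Candidate outcomes", ...)
  invisible(x)
}
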