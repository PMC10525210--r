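#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes, both in `class_names`
#' order (the same order that defines the integer codes).
#'
#' @param truth,predicted Integer class codes of equal length.
#' @param class_names Ordered class names; codes index into it.
#' @return `C x C` integer matrix with dimnames, class `asnet_confusion`.
#' @export
confusion <- function(truth, predicted, class_names) {
  if (length(truth) != length(predicted))
    stop("truth and predicted differ in length")
  C <- length(class_names)
  bad <- setdiff(unique(c(truth, predicted)), seq_len(C))
  if (length(bad)) stop("unknown class code: ", bad[1L])
  cm <- matrix(0L, C, C, dimnames = list(truth = class_names,
                                         predicted = class_names))
  for (i in seq_along(truth))
    cm[truth[i], predicted[i]] <- cm[truth[i], predicted[i]] + 1L
  structure(cm, class = c("asnet_confusion", "matrix", "array"))
}

#' @export
print.asnet_confusion <- function(x, ...) {
  cat("Confusion matrix (rows = truth, cols = predicted):\n")
  print(unclass(x))
  invisible(x)
}

#' Accuracy / recall / precision / F1 panel from a confusion matrix
#'
#' Overall accuracy is the trace over the total. Per class `c`:
#' recall `TP/(TP+FN)`, precision `TP/(TP+FP)`, F1 the harmonic mean of the
#' two; a zero denominator yields 0. `percent = TRUE` reports values times
#' 100, rounded half-up to 2 decimals (the printed-table convention).
#'
#' @param cm An [confusion()] matrix.
#' @param percent Report percentages rounded to 2 decimals (default TRUE).
#' @return List of class `asnet_metrics`: `accuracy` and data frame
#'   `per_class` with columns `class`, `recall`, `precision`, `f1`.
#' @export
panel <- function(cm, percent = TRUE) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  acc <- sum(diag(cm)) / total
  per <- lapply(seq_len(nrow(cm)), function(c) {
    tp <- cm[c, c]
    fn <- sum(cm[c, ]) - tp
    fp <- sum(cm[, c]) - tp
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (r + p > 0) 2 * r * p / (r + p) else 0
    c(recall = r, precision = p, f1 = f1)
  })
  per <- do.call(rbind, per)
  fmt <- if (percent) function(v) round_half_up(100 * v, 2) else identity
  structure(list(
    accuracy = fmt(acc),
    per_class = data.frame(class = rownames(cm),
                           recall = fmt(per[, "recall"]),
                           precision = fmt(per[, "precision"]),
                           f1 = fmt(per[, "f1"]),
                           stringsAsFactors = FALSE),
    percent = percent
  ), class = "asnet_metrics")
}

#' F1 score from a (recall, precision) pair
#'
#' Harmonic mean on whatever scale the inputs share (fractions or percents);
#' 0 when both inputs are 0.
#'
#' @param recall,precision Recall and precision on a common scale.
#' @param digits Round half-up to this many decimals (NULL = no rounding).
#' @return F1 on the same scale.
#' @export
f1_score <- function(recall, precision, digits = 2) {
  f1 <- ifelse(recall + precision > 0,
               2 * recall * precision / (recall + precision), 0)
  if (is.null(digits)) f1 else round_half_up(f1, digits)
}

#' @export
print.asnet_metrics <- function(x, ...) {
  unit <- if (x$percent) "%" else ""
  cat(sprintf("Accuracy: %s%s\n", format(x$accuracy), unit))
  df <- x$per_class
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-20s recall %6s%s  precision %6s%s  F1 %6s%s\n",
                df$class[i], format(df$recall[i]), unit,
                format(df$precision[i]), unit, format(df$f1[i]), unit))
  invisible(x)
}
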