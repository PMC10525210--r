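#' Sort prediction vectors by accuracy
#'
#' Stable descending sort: equal accuracies keep their original order
#' (feature-matrix-by-selector order for classifier-wise predictions).
#'
#' @param preds List of `asnet_prediction` objects of equal length.
#' @return The list reordered, with attribute `order` (the permutation).
#' @export
sort_by_accuracy <- function(preds) {
  if (length(preds) == 0L) stop("no prediction vectors to sort")
  lens <- vapply(preds, function(p) length(p$labels), integer(1))
  if (length(unique(lens)) != 1L) stop("prediction vectors differ in length")
  acc <- vapply(preds, function(p) p$accuracy, numeric(1))
  ord <- order(-acc, seq_along(acc))
  structure(preds[ord], order = ord)
}

#' Per-sample majority vote (mode)
#'
#' Fuses equal-length prediction vectors by taking, per sample, the most
#' frequent class code; ties go to the smallest class code.
#'
#' @param preds List of `asnet_prediction` objects (or integer vectors).
#' @return Integer vector of fused class codes.
#' @export
majority_vote <- function(preds) {
  if (length(preds) == 0L) stop("no prediction vectors to vote over")
  labs <- lapply(preds, function(p)
    if (inherits(p, "asnet_prediction")) p$labels else as.integer(p))
  if (length(unique(lengths(labs))) != 1L)
    stop("prediction vectors differ in length")
  mat <- do.call(cbind, labs)
  apply(mat, 1, function(v) {
    counts <- tabulate(v)
    which.max(counts)  # first maximum = smallest class code
  })
}

#' Iterative majority voting
#'
#' Sorts the classifier-wise prediction vectors by descending accuracy, then
#' for each prefix size `r` in `r_min..r_max` fuses the top `r` vectors by
#' per-sample mode. With the default 18 inputs and loop range 3..18 this
#' produces the 16 voted outcomes.
#'
#' @param preds List of `asnet_prediction` objects (classifier-wise outputs).
#' @param truth Integer truth codes used for voted accuracies.
#' @param r_min,r_max Loop range (defaults 3 and 18; `r_max` is clamped to
#'   the number of available vectors).
#' @return List of `asnet_prediction` objects, one per `r`, ascending `r`;
#'   each carries `r` and provenance `"voted_r<r>"`.
#' @export
imv <- function(preds, truth, r_min = 3L, r_max = 18L) {
  r_max <- min(r_max, length(preds))
  if (r_min < 2L) stop("r_min must be >= 2")
  if (length(preds) < r_min)
    stop("need at least r_min = ", r_min, " prediction vectors, got ", length(preds))
  if (r_min > r_max) stop("r_min exceeds r_max")
  sorted <- sort_by_accuracy(preds)
  lapply(seq(r_min, r_max), function(r) {
    fused <- majority_vote(sorted[seq_len(r)])
    out <- new_prediction(fused, truth, provenance = paste0("voted_r", r))
    out$r <- r
    out
  })
}

#' Select the best candidate outcome
#'
#' Scans all candidate outcomes — the classifier-wise prediction vectors and
#' the voted outcomes (34 at default configuration) — and returns the one
#' with maximum accuracy. Ties prefer voted over classifier-wise outcomes,
#' then smaller `r`, then the earlier classifier-wise index.
#'
#' @param classifier_wise List of classifier-wise `asnet_prediction`s.
#' @param voted List of voted `asnet_prediction`s from [imv()].
#' @param pool `"all34"` scans both lists; `"voted16"` restricts the scan to
#'   the voted outcomes.
#' @return List: `best` (the winning prediction), `best_id`, `candidates`
#'   (all scanned, voted first), `n_candidates`.
#' @export
select_best <- function(classifier_wise, voted, pool = c("all34", "voted16")) {
  pool <- match.arg(pool)
  candidates <- c(voted, if (pool == "all34") classifier_wise)
  if (length(candidates) == 0L) stop("no candidate outcomes")
  acc <- vapply(candidates, function(p) p$accuracy, numeric(1))
  best_i <- which.max(acc)  # first maximum respects the tie preference order
  list(best = candidates[[best_i]],
       best_id = candidates[[best_i]]$provenance,
       candidates = candidates,
       n_candidates = length(candidates))
}
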