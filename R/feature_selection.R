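#' Chi-square feature scores
#'
#' Scores each feature column by the Pearson chi-square statistic of the
#' dependence between a binned version of the feature and the class label.
#' Each feature is discretized into `n_bins` equal-width bins over its
#' observed range (a constant feature occupies a single bin and scores 0);
#' bins with zero total count are dropped before computing
#' \eqn{\sum (O - E)^2 / E} on the bins-by-classes contingency table.
#' Deterministic and invariant to affine rescaling of any single feature.
#'
#' @param x Numeric matrix, samples in rows.
#' @param y Integer class codes (>= 2 distinct values).
#' @param n_bins Number of equal-width bins (default 10).
#' @return List of class `asnet_ranking`: `selector`, `scores` (length `ncol(x)`,
#'   higher = more informative), `params`.
#' @export
chi2_scores <- function(x, y, n_bins = 10L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (nrow(x) < 2L) stop("need at least 2 samples")
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("chi2 undefined for a single class")
  if (n_bins < 2L) stop("n_bins must be >= 2")
  yf <- match(y, classes)
  n_class <- length(classes)
  class_tot <- tabulate(yf, n_class)
  n <- nrow(x)
  scores <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    rng <- range(v)
    if (rng[1] == rng[2]) return(0)
    bin <- pmin(floor((v - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L, n_bins)
    obs <- matrix(0, n_bins, n_class)
    for (i in seq_len(n)) obs[bin[i], yf[i]] <- obs[bin[i], yf[i]] + 1
    obs <- obs[rowSums(obs) > 0, , drop = FALSE]
    expd <- outer(rowSums(obs), class_tot) / n
    sum((obs - expd)^2 / expd)
  }, numeric(1))
  structure(list(selector = "chi2", scores = scores,
                 params = list(n_bins = n_bins)),
            class = "asnet_ranking")
}

#' ReliefF feature weights
#'
#' Deterministic multiclass ReliefF: a single pass over all instances (no
#' random subsampling). For each instance, the `k_hits` nearest same-class
#' neighbours and `k_hits` nearest neighbours of every other class are found
#' under Manhattan distance on min-max scaled features; each feature's weight
#' is decreased by the mean same-class feature difference and increased by
#' the class-prior-weighted mean other-class difference, and finally divided
#' by the number of instances, so weights lie in `[-1, 1]`. A feature that is
#' identical across all samples has weight exactly 0.
#'
#' @inheritParams chi2_scores
#' @param k_hits Number of nearest hits/misses per class (default 10); every
#'   class must have more than `k_hits` members.
#' @return An `asnet_ranking` (see [chi2_scores()]).
#' @export
relieff_scores <- function(x, y, k_hits = 10L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (k_hits < 1L) stop("k_hits must be >= 1")
  classes <- sort(unique(y))
  counts <- tabulate(match(y, classes), length(classes))
  small <- counts <= k_hits
  if (any(small))
    stop("class ", classes[which(small)[1L]], " has ", counts[which(small)[1L]],
         " members; ReliefF with k_hits = ", k_hits, " needs more than k_hits")
  xs <- minmax_scale(x)
  priors <- counts / nrow(x)
  w <- .relieff_cpp(xs, match(y, classes), as.integer(k_hits), priors)
  structure(list(selector = "relieff", scores = as.numeric(w),
                 params = list(k_hits = k_hits)),
            class = "asnet_ranking")
}

minmax_scale <- function(x) {
  rng <- apply(x, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1  # constant feature -> all zeros after centering
  sweep(sweep(x, 2, rng[1, ]), 2, span, "/")
}

#' Neighborhood component analysis feature weights
#'
#' Diagonal feature-weighting NCA. Features are z-scored internally, then
#' per-feature weights `w` (initialized at 1) are fitted by full-batch
#' gradient ascent with backtracking on the regularized leave-one-out
#' expected correct-assignment objective
#' \deqn{\sum_i p_i - \lambda \sum_r w_r^2,}
#' where \eqn{p_{ij} \propto \exp(-\sum_r w_r^2 |x_{ir} - x_{jr}|)} over
#' \eqn{j \ne i} and \eqn{p_i} sums \eqn{p_{ij}} over same-class `j`.
#' Scores are the fitted \eqn{w_r^2}. The optimization is deterministic (no
#' sampling; `seed` is accepted for interface symmetry only).
#'
#' @inheritParams chi2_scores
#' @param lambda Ridge penalty on the weights; default `1/n`.
#' @param learn_rate Initial gradient-ascent step (adapted by backtracking).
#' @param max_iter Full-batch iteration budget (default 100).
#' @param tol Relative objective-improvement stopping tolerance.
#' @param seed Unused (the fit is deterministic); kept for interface symmetry.
#' @return An `asnet_ranking` with extra fields `w`, `objective`, `iterations`.
#' @export
nca_weights <- function(x, y, lambda = NULL, learn_rate = 0.1, max_iter = 100L,
                        tol = 1e-7, seed = 0L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  n <- nrow(x)
  if (n < 3L) stop("NCA needs at least 3 samples")
  if (is.null(lambda)) lambda <- 1 / n
  if (lambda < 0) stop("lambda must be >= 0")
  # a zero-variance column enters the objective only through the ridge
  # penalty, so its optimal weight is exactly 0: solve it analytically and
  # optimize over the informative columns only
  varying <- apply(x, 2, function(v) any(v != v[1]))
  xs <- zscore(x[, varying, drop = FALSE])
  fit <- .nca_cpp(xs, match(y, sort(unique(y))), lambda, learn_rate,
                  as.integer(max_iter), tol)
  if (!all(is.finite(fit$scores)) || !is.finite(fit$objective))
    stop("NCA objective became non-finite; check feature standardization")
  scores <- w <- numeric(ncol(x))
  scores[varying] <- as.numeric(fit$scores)
  w[varying] <- as.numeric(fit$w)
  structure(list(selector = "nca", scores = scores,
                 w = w, objective = fit$objective,
                 objective0 = fit$objective0, iterations = fit$iterations,
                 params = list(lambda = lambda, learn_rate = learn_rate,
                               max_iter = max_iter)),
            class = "asnet_ranking")
}

zscore <- function(x) {
  mu <- colMeans(x)
  s <- sqrt(colMeans(sweep(x, 2, mu)^2))  # population sd
  s[s == 0] <- 1
  sweep(sweep(x, 2, mu), 2, s, "/")
}

#' @export
print.asnet_ranking <- function(x, ...) {
  cat("Feature ranking (", x$selector, "): ", length(x$scores), " features, top score ",
      format(max(x$scores), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Run one selector by name
#'
#' @param selector `"nca"`, `"relieff"`, or `"chi2"`.
#' @param x,y Feature matrix and class codes.
#' @param control Named list overriding selector defaults
#'   (`chi2.n_bins`, `relieff.k_hits`, `nca.lambda` / `nca.learn_rate` /
#'   `nca.max_iter`).
#' @return An `asnet_ranking`.
#' @export
rank_features <- function(selector = c("nca", "relieff", "chi2"), x, y,
                          control = list()) {
  selector <- match.arg(selector)
  switch(selector,
    chi2 = chi2_scores(x, y, n_bins = control$chi2.n_bins %||% 10L),
    relieff = relieff_scores(x, y, k_hits = control$relieff.k_hits %||% 10L),
    nca = nca_weights(x, y, lambda = control$nca.lambda,
                      learn_rate = control$nca.learn_rate %||% 0.1,
                      max_iter = control$nca.max_iter %||% 100L)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Keep the top-k features of a ranking
#'
#' Retains the `min(k, d)` columns with the highest scores, ordered by
#' descending score with ties broken by ascending original column index.
#'
#' @param ranking An `asnet_ranking`.
#' @param x The matrix the ranking was computed on.
#' @param k Number of features to keep (default 272).
#' @return List with `indices` (retained original column indices, selection
#'   order), `x` (reduced matrix, columns in selection order), `selector`, `k`.
#' @export
select_top_k <- function(ranking, x, k = 272L) {
  x <- as.matrix(x)
  if (k <= 0L) stop("k must be positive")
  d <- ncol(x)
  if (length(ranking$scores) != d)
    stop("ranking length (", length(ranking$scores), ") != feature count (", d, ")")
  if (d < k)
    warning("only ", d, " features available; keeping all (k = ", k, ")")
  keep <- order(-ranking$scores, seq_len(d))[seq_len(min(k, d))]
  list(indices = keep, x = x[, keep, drop = FALSE],
       selector = ranking$selector, k = length(keep))
}
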