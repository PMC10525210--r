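# Independent brute-force oracles, deliberately written as direct
# transliterations of the definitions (no shared code with the package
# internals they check).

# 1-NN by exhaustive all-pairs scan; which.min takes the first (lowest-index)
# minimum, matching the tie contract.
brute_knn1 <- function(train_x, train_y, query_x) {
  apply(query_x, 1, function(q) {
    d2 <- rowSums(sweep(train_x, 2, q)^2)
    train_y[which.min(d2)]
  })
}

# Deterministic all-instances ReliefF by exhaustive enumeration.
brute_relieff <- function(x, y, k_hits) {
  n <- nrow(x); d <- ncol(x)
  rng <- apply(x, 2, range)
  span <- rng[2, ] - rng[1, ]; span[span == 0] <- 1
  xs <- sweep(sweep(x, 2, rng[1, ]), 2, span, "/")
  classes <- sort(unique(y))
  priors <- as.numeric(table(factor(y, levels = classes))) / n
  w <- numeric(d)
  for (i in seq_len(n)) {
    dist <- vapply(seq_len(n), function(j) sum(abs(xs[i, ] - xs[j, ])), numeric(1))
    for (ci in seq_along(classes)) {
      cand <- setdiff(which(y == classes[ci]), i)
      sel <- utils::head(cand[order(dist[cand], cand)], k_hits)
      if (length(sel) == 0L) next
      diffs <- colMeans(abs(xs[sel, , drop = FALSE] -
                              matrix(xs[i, ], length(sel), d, byrow = TRUE)))
      yi <- match(y[i], classes)
      if (ci == yi) w <- w - diffs
      else w <- w + priors[ci] / (1 - priors[yi]) * diffs
    }
  }
  w / n
}

# Direct evaluation of the diagonal-weight NCA objective from its formula.
direct_nca_objective <- function(xs, y, w, lambda) {
  n <- nrow(xs)
  total <- 0
  for (i in seq_len(n)) {
    k <- vapply(seq_len(n), function(j)
      exp(-sum(w^2 * abs(xs[i, ] - xs[j, ]))), numeric(1))
    k[i] <- 0
    p <- if (sum(k) > 0) k / sum(k) else k * 0
    total <- total + sum(p[y == y[i]]) - p[i]
  }
  total - lambda * sum(w^2)
}

# Per-sample mode with smallest-code tie break, by explicit counting.
brute_mode_vote <- function(label_matrix) {
  apply(label_matrix, 1, function(v) {
    counts <- table(v)
    as.integer(names(counts)[counts == max(counts)][1])  # names sorted ascending
  })
}

# Small helper: a quick two-class Gaussian instance.
gaussian_instance <- function(n_per_class, d, delta, seed) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_class * d), 2 * n_per_class, d)
  y <- rep(1:2, each = n_per_class)
  x[y == 2, 1] <- x[y == 2, 1] + delta
  list(x = x, y = y)
}
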