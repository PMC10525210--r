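test_that("chi2 scores constants at 0 and a perfectly aligned binary feature at n", {
  y <- rep(1:2, each = 5)
  x <- cbind(const = rep(3.7, 10), aligned = as.numeric(y == 2))
  r <- chi2_scores(x, y)
  expect_equal(r$scores[1], 0)
  expect_equal(r$scores[2], 10)  # 2x2 table with perfect dependence: statistic = n
  expect_error(chi2_scores(x, rep(1, 10)), "single class")
})

test_that("chi2 is invariant to sample permutation and per-feature affine rescaling", {
  set.seed(10)
  x <- matrix(rnorm(40 * 5), 40, 5)
  y <- rep(1:2, 20)
  r <- chi2_scores(x, y)
  perm <- sample(40)
  expect_equal(chi2_scores(x[perm, ], y[perm])$scores, r$scores, tolerance = 1e-12)
  x2 <- x; x2[, 3] <- -5 * x2[, 3] + 100
  expect_equal(chi2_scores(x2, y)$scores, r$scores, tolerance = 1e-10)
})

test_that("relieff matches the brute-force enumeration oracle on random instances", {
  set.seed(11)
  for (case in 1:30) {
    n <- sample(8:12, 1); d <- sample(2:4, 1)
    x <- matrix(rnorm(n * d), n, d)
    y <- c(rep(1, ceiling(n / 2)), rep(2, floor(n / 2)))
    k <- sample(1:3, 1)
    expect_equal(relieff_scores(x, y, k_hits = k)$scores,
                 brute_relieff(x, y, k), tolerance = 1e-12)
  }
  # three classes too
  x <- matrix(rnorm(15 * 3), 15, 3)
  y <- rep(1:3, each = 5)
  expect_equal(relieff_scores(x, y, k_hits = 2)$scores,
               brute_relieff(x, y, 2), tolerance = 1e-12)
})

test_that("relieff separates informative from noise features and zeroes constants", {
  x <- cbind(inf = c(0, 0, 1, 1), noise = c(0.3, 0.9, 0.1, 0.5), const = rep(2, 4))
  y <- c(1, 1, 2, 2)
  w <- relieff_scores(x, y, k_hits = 1)$scores
  expect_equal(w, unname(brute_relieff(x, y, 1)), tolerance = 1e-12)
  expect_gt(w[1], w[2])
  expect_equal(w[3], 0)
  expect_true(all(abs(w) <= 1))
})

test_that("relieff on duplicated samples still matches the oracle", {
  set.seed(12)
  x <- matrix(rnorm(10 * 3), 10, 3)
  y <- rep(1:2, each = 5)
  dup_idx <- rep(seq_len(10), each = 2)
  expect_equal(relieff_scores(x[dup_idx, ], y[dup_idx], k_hits = 2)$scores,
               brute_relieff(x[dup_idx, ], y[dup_idx], 2), tolerance = 1e-12)
})

test_that("relieff rejects classes smaller than k_hits + 1", {
  x <- matrix(rnorm(12), 6, 2)
  y <- c(1, 1, 1, 1, 2, 2)
  expect_error(relieff_scores(x, y, k_hits = 2), "class 2")
})

test_that("nca objective at initialization matches direct formula evaluation", {
  x <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1, 2, -1, 0.5, 0), 4, 3)
  y <- c(1, 1, 2, 2)
  xs <- asnet:::zscore(x)
  fit <- nca_weights(x, y, lambda = 0.25, max_iter = 5)
  expect_equal(fit$objective0, direct_nca_objective(xs, y, rep(1, 3), 0.25),
               tolerance = 1e-10)
  # fitting never decreases the objective
  expect_gte(fit$objective, fit$objective0)
})

test_that("nca downweights a pure-noise feature on a separable instance", {
  set.seed(13)
  n <- 30
  y <- rep(1:2, each = n / 2)
  x <- cbind(rnorm(n, mean = 3 * (y == 2)), rnorm(n, mean = -3 * (y == 2)), rnorm(n))
  fit <- nca_weights(x, y, lambda = 1 / n, max_iter = 200)
  expect_lt(fit$scores[3], 0.1 * max(fit$scores[1:2]))
})

test_that("nca weights shrink monotonically to zero as lambda grows", {
  set.seed(14)
  x <- matrix(rnorm(20 * 3), 20, 3)
  y <- rep(1:2, 10)
  norms <- vapply(c(0.01, 1, 100, 1e4),
                  function(l) sum(nca_weights(x, y, lambda = l, max_iter = 50)$scores),
                  numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[4], 1e-4)
})

test_that("nca is invariant to per-feature affine rescaling (internal z-scoring)", {
  set.seed(15)
  x <- matrix(rnorm(24 * 4), 24, 4)
  y <- rep(1:2, 12)
  f1 <- nca_weights(x, y, max_iter = 40)
  x2 <- x
  x2[, 2] <- 10 * x2[, 2] - 3
  f2 <- nca_weights(x2, y, max_iter = 40)
  expect_equal(f1$scores, f2$scores, tolerance = 1e-8)
})

test_that("select_top_k keeps min(k, d) columns with deterministic tie-breaks", {
  set.seed(16)
  x <- matrix(rnorm(10 * 1000), 10, 1000)
  r <- structure(list(selector = "chi2", scores = runif(1000)),
                 class = "asnet_ranking")
  sel <- select_top_k(r, x, k = 272)
  expect_length(sel$indices, 272)
  expect_equal(sel$indices, order(-r$scores)[1:272])
  expect_equal(sel$x, x[, sel$indices], ignore_attr = TRUE)

  small <- matrix(rnorm(10 * 100), 10, 100)
  rs <- structure(list(selector = "chi2", scores = runif(100)), class = "asnet_ranking")
  expect_warning(sel2 <- select_top_k(rs, small, k = 272), "keeping all")
  expect_length(sel2$indices, 100)

  ties <- structure(list(selector = "chi2", scores = rep(1, 100)), class = "asnet_ranking")
  expect_equal(suppressWarnings(select_top_k(ties, small, k = 272))$indices[1:10], 1:10)
  expect_error(select_top_k(rs, small, k = 0), "positive")
})

test_that("exactly 3 selectors x matrices selected sets are produced in a fit", {
  bank <- gen_feature_bank(fixture_spec(n_per_class = 12, d = 30, seed = 8),
                           n_matrices = 2)
  fit <- asnet(bank$x, bank$labels, k = 10, cv = cv_control(n_folds = 4),
               class_labels = bank$class_names)
  expect_length(fit$feature_sets, 6)
  expect_true(all(vapply(fit$feature_sets, function(f) length(f$indices), integer(1)) == 10))
})
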