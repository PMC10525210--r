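small_fit <- function(n_matrices = 2, seed = 70, ...) {
  bank <- gen_feature_bank(fixture_spec(n_per_class = 15, d = 40, delta = 4,
                                        informative_fraction = 0.25, seed = seed),
                           n_matrices = n_matrices)
  asnet(bank$x, bank$labels, k = 15, cv = cv_control(n_folds = 5, seed = seed),
        class_labels = bank$class_names, ...)
}

test_that("generalized counting: m matrices x 3 selectors, clamped voting range", {
  fit <- small_fit(n_matrices = 2)
  ct <- pipeline_counts(fit)
  expect_equal(ct$matrices, 2)
  expect_equal(ct$classifier_wise, 6)   # 2 x 3 selectors
  expect_equal(ct$voted, 4)             # r = 3..6
  expect_equal(ct$candidates, 10)
  expect_equal(fit$config$r_max, 6)
})

test_that("refitting with the same configuration is bitwise reproducible", {
  f1 <- small_fit(); f2 <- small_fit()
  expect_identical(lapply(f1$predictions, `[[`, "labels"),
                   lapply(f2$predictions, `[[`, "labels"))
  expect_identical(f1$best_id, f2$best_id)
  d1 <- withr::local_tempfile(fileext = ".json")
  d2 <- withr::local_tempfile(fileext = ".json")
  write_report_json(f1, d1); write_report_json(f2, d2)
  expect_identical(readLines(d1), readLines(d2))
})

test_that("best accuracy dominates every classifier-wise accuracy", {
  fit <- small_fit(seed = 71)
  cw_acc <- vapply(fit$predictions, function(p) p$accuracy, numeric(1))
  expect_gte(fit$accuracy, max(cw_acc))
  expect_equal(fit$accuracy,
               max(vapply(fit$candidates, function(p) p$accuracy, numeric(1))))
})

test_that("report tables mirror the fit and flag the best row", {
  fit <- small_fit(seed = 72)
  t2 <- classifier_table(fit)
  expect_equal(nrow(t2), 6)
  expect_equal(t2$selector, rep(c("nca", "chi2", "relieff"), 2))
  expect_equal(sum(t2$best), as.integer(grepl("voted", fit$best_id) == 0))
  t3 <- class_metrics_table(fit)
  expect_equal(t3$class, fit$class_names)
  expect_equal(t3$accuracy, rep(fit$metrics$accuracy, 2))
  f <- withr::local_tempfile(fileext = ".csv")
  classifier_table(fit, f)
  expect_equal(nrow(read.csv(f)), 6)
})

test_that("run_pipeline writes the full report set from an image directory", {
  dir <- withr::local_tempdir()
  out <- withr::local_tempdir()
  gen_image_dataset(fixture_spec(n_per_class = 8, image_size = c(24, 24),
                                 delta = 6, seed = 73), dir)
  fit <- run_pipeline(dir, out, k = 50, cv = cv_control(n_folds = 4, seed = 5),
                      selector_control = list(relieff.k_hits = 5), seed = 5)
  expect_true(all(file.exists(file.path(out, c("report.json", "classifier_wise.csv",
                                               "metrics.csv")))))
  rep <- jsonlite::read_json(file.path(out, "report.json"))
  expect_equal(rep$counts$matrices, 6)
  expect_equal(rep$counts$classifier_wise, 18)
  expect_equal(rep$counts$voted, 16)  # r = 3..18 over the 18 vectors
  expect_equal(length(rep$candidates), 34)
})

test_that("predict reproduces the voting structure on held-out phantoms", {
  dir <- withr::local_tempdir()
  spec <- fixture_spec(n_per_class = 10, image_size = c(24, 24), delta = 6, seed = 74)
  m <- gen_image_dataset(spec, dir)
  fit <- asnet(m, k = 60, cv = cv_control(n_folds = 5, seed = 6),
               selector_control = list(relieff.k_hits = 5), seed = 6)
  dir2 <- withr::local_tempdir()
  spec2 <- spec; spec2$seed <- 75
  m2 <- gen_image_dataset(spec2, dir2)
  pred <- predict(fit, m2)
  expect_s3_class(pred, "factor")
  expect_equal(levels(pred), c("case", "control"))
  expect_gt(mean(as.integer(pred) == m2$label), 0.9)
})

test_that("nested selection mode calibrates to chance under the null", {
  accs <- vapply(1:4, function(s) {
    bank <- gen_feature_bank(fixture_spec(n_per_class = 25, d = 60, delta = 0,
                                          seed = 300 + s), n_matrices = 3)
    fit <- asnet(bank$x, bank$labels, k = 25, cv = cv_control(n_folds = 5, seed = s),
                 selection_mode = "nested", class_labels = bank$class_names,
                 selector_control = list(nca.max_iter = 30, relieff.k_hits = 5))
    fit$accuracy
  }, numeric(1))
  # best-of-13 selection inflates slightly above 0.5; allow 3 SEs plus
  # a one-SE selection allowance on n = 50
  expect_lt(mean(accs), 0.5 + 4 * sqrt(0.25 / 50))
  expect_gt(mean(accs), 0.5 - 3 * sqrt(0.25 / 50))
})

test_that("full-data selection mode shows the documented optimistic null bias", {
  bank <- gen_feature_bank(fixture_spec(n_per_class = 25, d = 60, delta = 0,
                                        seed = 310), n_matrices = 3)
  fit_full <- asnet(bank$x, bank$labels, k = 25, cv = cv_control(n_folds = 5, seed = 1),
                    class_labels = bank$class_names)
  expect_gt(fit_full$accuracy, 0.6)  # leakage inflates well above chance
})

test_that("input validation catches misaligned and missing pieces", {
  bank <- gen_feature_bank(fixture_spec(n_per_class = 6, d = 10, seed = 76),
                           n_matrices = 2)
  expect_error(asnet(bank$x), "y is required")
  bad <- bank$x; bad[[2]] <- bad[[2]][-1, ]
  expect_error(asnet(bad, bank$labels, cv = cv_control(n_folds = 3)),
               "one row per sample")
  expect_error(asnet(bank$x, bank$labels, selectors = c("nca", "pca")),
               "unknown selector")
})
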