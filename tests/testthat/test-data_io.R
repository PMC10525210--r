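make_image_dir <- function(n_as = 3, n_ctrl = 2) {
  d <- withr::local_tempdir(.local_envir = parent.frame())
  dir.create(file.path(d, "AS")); dir.create(file.path(d, "control"))
  set.seed(1)
  for (i in seq_len(n_as))
    png::writePNG(matrix(runif(64), 8, 8), file.path(d, "AS", sprintf("a%d.png", i)))
  for (i in seq_len(n_ctrl))
    png::writePNG(matrix(runif(64), 8, 8), file.path(d, "control", sprintf("c%d.png", i)))
  d
}

test_that("class-subdirs manifest discovers samples with fixed class order", {
  d <- make_image_dir()
  m <- load_manifest(d)
  expect_equal(nrow(m), 5)
  expect_equal(class_names(m), c("AS", "control"))
  expect_equal(sum(m$label == 1), 3)
  expect_equal(sum(m$label == 2), 2)
  # repeated loads are identical, order included
  expect_identical(m, load_manifest(d))
})

test_that("degenerate directories are rejected", {
  d <- withr::local_tempdir()
  expect_error(load_manifest(d), "no samples")
  dir.create(file.path(d, "AS")); dir.create(file.path(d, "control"))
  png::writePNG(matrix(0.5, 4, 4), file.path(d, "AS", "a.png"))
  expect_error(load_manifest(d), "degenerate class")
})

test_that("manifest files validate paths, ids, and declared class order", {
  d <- make_image_dir()
  files <- list.files(d, recursive = TRUE, full.names = TRUE)
  mf <- file.path(d, "manifest.csv")
  write.csv(data.frame(sample_id = paste0("s", seq_along(files)), path = files,
                       label = c("ctl", "AS")[1 + grepl("AS", files)]),
            mf, row.names = FALSE)
  m <- load_manifest(mf, layout = "manifest-file")
  expect_equal(nrow(m), length(files))
  expect_equal(class_names(m), c("AS", "ctl"))  # first-appearance order

  bad <- data.frame(sample_id = c("a", "a"), path = files[1:2], label = c("x", "y"))
  write.csv(bad, mf, row.names = FALSE)
  expect_error(load_manifest(mf, layout = "manifest-file"), "duplicate sample_id")

  bad <- data.frame(sample_id = c("a", "b"), path = c(files[1], "/nope/missing.png"),
                    label = c("x", "y"))
  write.csv(bad, mf, row.names = FALSE)
  expect_error(load_manifest(mf, layout = "manifest-file"), "missing.png")
})

test_that("PNG images are read with expected shape and channels", {
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(runif(64 * 64), 64, 64), f)
  img <- read_image(f)
  expect_equal(dim(img), c(64, 64))

  frgb <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(16 * 16 * 3), c(16, 16, 3)), frgb)
  rgb <- read_image(frgb)
  expect_equal(dim(rgb), c(16, 16, 3))
})

test_that("DICOM rescale slope/intercept is applied to stored values", {
  f <- withr::local_tempfile(fileext = ".dcm")
  px <- matrix(10L, 4, 6)
  asnet:::write_minimal_dicom(f, px, slope = 2, intercept = -1)
  img <- read_image(f)
  expect_equal(dim(img), c(4, 6))
  expect_true(all(img == 19))  # 10 * 2 - 1
  expect_identical(attr(img, "value_range"), "raw")
})

test_that("DICOM pixel order and corruption errors are correct", {
  f <- withr::local_tempfile(fileext = ".dcm")
  px <- matrix(seq_len(12), 3, 4)
  asnet:::write_minimal_dicom(f, px)
  expect_equal(read_image(f), px, ignore_attr = TRUE)
  writeBin(as.raw(c(1, 2, 3)), f)
  expect_error(read_image(f), basename(f))
})

test_that("8-bit grayscale BMP files are decoded", {
  f <- withr::local_tempfile(fileext = ".bmp")
  w <- 5L; h <- 3L
  stride <- ((w + 3) %/% 4) * 4
  con <- file(f, "wb")
  writeBin(charToRaw("BM"), con)
  writeBin(as.integer(14 + 40 + 1024 + stride * h), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(as.integer(14 + 40 + 1024), con, size = 4, endian = "little")
  writeBin(40L, con, size = 4, endian = "little")
  writeBin(w, con, size = 4, endian = "little")
  writeBin(h, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(8L, con, size = 2, endian = "little")
  writeBin(rep(0L, 6), con, size = 4, endian = "little")  # compression..colors
  for (i in 0:255) writeBin(as.integer(c(i, i, i, 0)), con, size = 1)
  pix <- matrix(as.integer(seq(0, 250, length.out = h * w)), h, w, byrow = TRUE)
  for (row in h:1) writeBin(c(pix[row, ], rep(0L, stride - w)), con, size = 1)
  close(con)
  img <- read_image(f)
  expect_equal(dim(img), c(h, w))
  expect_equal(img, pix / 255, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("feature tables round-trip losslessly with labels and order", {
  f <- withr::local_tempfile(fileext = ".csv")
  set.seed(42)
  x <- matrix(rnorm(35), 5, 7) * 1e6
  labels <- c(1L, 2L, 1L, 2L, 2L)
  write_feature_table(x, labels, f, meta = list(backbone = "toy"))
  back <- read_feature_table(f)
  expect_equal(back$x, x, tolerance = 1e-13, ignore_attr = TRUE)
  expect_identical(back$labels, labels)
  expect_equal(back$meta$backbone, "toy")
})

test_that("malformed feature tables give located errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,label,f0001,f0002", "s1,1,0.5,oops", "s2,2,1.0,2.0"), f)
  expect_error(read_feature_table(f), "row 1, column f0002")
  writeLines("sample_id,label,f0001", f)
  expect_error(read_feature_table(f), "no samples")
})
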