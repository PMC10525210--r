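#' Synthetic fixture specification
#'
#' Describes the seeded two-class fixtures used in place of clinical data:
#' either Gaussian feature matrices with a class-dependent mean shift on a
#' fraction of columns, or grayscale phantom images where the disease-like
#' class carries hyperintense blobs adjacent to a joint line.
#'
#' @param n_per_class Samples per class (default 100).
#' @param d Feature count (feature fixtures, default 600).
#' @param image_size `(H, W)` for image fixtures (default `c(64, 64)`).
#' @param delta Class separation: informative-column mean shift in units of
#'   `noise_sd` (features), or blob contrast in the same units (images).
#'   Default 6 (a clearly separable task); 0 gives a null task.
#' @param noise_sd Noise standard deviation (default 1 for features, 0.05
#'   for image pixel noise on the unit intensity scale).
#' @param informative_fraction Share of feature columns carrying the shift
#'   (default 0.1).
#' @param seed RNG seed; every generated byte is a function of it.
#' @return List of class `asnet_fixture_spec`.
#' @export
fixture_spec <- function(n_per_class = 100L, d = 600L, image_size = c(64L, 64L),
                         delta = 6, noise_sd = NULL, informative_fraction = 0.1,
                         seed = 1L) {
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  if (delta < 0) stop("delta must be >= 0")
  if (informative_fraction < 0 || informative_fraction > 1)
    stop("informative_fraction must be in [0, 1]")
  structure(list(n_per_class = as.integer(n_per_class), d = as.integer(d),
                 image_size = as.integer(image_size), delta = delta,
                 noise_sd = noise_sd, informative_fraction = informative_fraction,
                 seed = as.integer(seed)),
            class = "asnet_fixture_spec")
}

#' Generate a two-class Gaussian feature fixture
#'
#' Rows alternate classes are not used: the first `n_per_class` rows are
#' class 1 ("control"), the rest class 2 ("case"). Informative columns (the
#' first `ceiling(d * informative_fraction)`) have class means 0 and
#' `delta * noise_sd`; the remaining columns are pure noise in both classes.
#'
#' @param spec A [fixture_spec()].
#' @return List: `x` (n x d matrix), `labels` (integer codes 1/2),
#'   `class_names` (`c("control", "case")`), `informative` (column indices).
#' @export
gen_feature_dataset <- function(spec = fixture_spec()) {
  noise_sd <- spec$noise_sd %||% 1
  n_inf <- ceiling(spec$d * spec$informative_fraction)
  if (n_inf < 1L && spec$delta > 0)
    warning("informative_fraction too small: no column carries the class signal")
  n <- 2L * spec$n_per_class
  labels <- rep(1:2, each = spec$n_per_class)
  x <- with_seed(spec$seed, {
    m <- matrix(stats::rnorm(n * spec$d, sd = noise_sd), n, spec$d)
    if (n_inf >= 1L)
      m[labels == 2L, seq_len(n_inf)] <-
        m[labels == 2L, seq_len(n_inf)] + spec$delta * noise_sd
    m
  })
  list(x = x, labels = labels, class_names = c("control", "case"),
       informative = seq_len(max(n_inf, 0L)))
}

#' Generate a bank of feature matrices sharing one label vector
#'
#' Emulates the six layer-wise feature matrices of a full extraction run:
#' each matrix is an independent [gen_feature_dataset()] draw (seed offset by
#' matrix index) over the same samples and labels.
#'
#' @param spec A [fixture_spec()].
#' @param n_matrices Number of matrices (default 6).
#' @return List: `x` (list of matrices), `labels`, `class_names`.
#' @export
gen_feature_bank <- function(spec = fixture_spec(), n_matrices = 6L) {
  mats <- lapply(seq_len(n_matrices), function(i) {
    s <- spec; s$seed <- spec$seed + 7919L * i
    gen_feature_dataset(s)$x
  })
  labels <- rep(1:2, each = spec$n_per_class)
  list(x = mats, labels = labels, class_names = c("control", "case"))
}

#' Generate a two-class phantom image dataset
#'
#' Writes grayscale PNG phantoms to `dir`: both classes share a symmetric
#' dark joint line on a smoothly varying background plus Gaussian pixel
#' noise; the "case" class adds 2-4 seeded hyperintense Gaussian blobs
#' adjacent to the joint line with peak contrast `delta * noise_sd`. This
#' mimics localized hyperintensity (bone-marrow-edema-like signal) as a
#' statistical task only, not MRI physics.
#'
#' @param spec A [fixture_spec()] (`image_size`, `delta`,
#'   `noise_sd` default 0.05 on the unit intensity scale).
#' @param dir Output directory (created if needed).
#' @return An `asnet_manifest` for the written files; ground truth is the
#'   manifest's `label` column (1 = control, 2 = case).
#' @export
gen_image_dataset <- function(spec = fixture_spec(), dir = tempfile("phantom")) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create fixture directory: ", dir)
  for (cl in c("case", "control"))
    if (!dir.exists(file.path(dir, cl)) && !dir.create(file.path(dir, cl)))
      stop("cannot create fixture directory: ", file.path(dir, cl))
  noise_sd <- spec$noise_sd %||% 0.05
  h <- spec$image_size[1]; w <- spec$image_size[2]
  with_seed(spec$seed, {
    for (cl in 1:2) {
      cl_name <- c("control", "case")[cl]
      for (i in seq_len(spec$n_per_class)) {
        img <- phantom_image(h, w, noise_sd,
                             blobs = cl == 2L, contrast = spec$delta * noise_sd)
        png::writePNG(img, file.path(dir, cl_name, sprintf("%s_%03d.png", cl_name, i)))
      }
    }
  })
  load_manifest(dir, layout = "class-subdirs")
}

phantom_image <- function(h, w, noise_sd, blobs = FALSE, contrast = 0) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  cx <- (w + 1) / 2
  # smooth background with a symmetric dark joint line down the center
  img <- 0.45 + 0.1 * sin(2 * pi * yy / h) - 0.25 * exp(-((xx - cx) / (0.03 * w + 1))^2)
  if (blobs && contrast > 0) {
    for (b in seq_len(sample(2:4, 1))) {
      side <- sample(c(-1, 1), 1)
      bx <- cx + side * stats::runif(1, 0.06, 0.2) * w
      by <- stats::runif(1, 0.2, 0.8) * h
      sigma <- stats::runif(1, 0.03, 0.07) * (h + w) / 2
      img <- img + contrast * exp(-((xx - bx)^2 + (yy - by)^2) / (2 * sigma^2))
    }
  }
  img <- img + matrix(stats::rnorm(h * w, sd = noise_sd), h, w)
  pmin(pmax(img, 0), 1)
}
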