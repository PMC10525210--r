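#' Registered backbone/layer taps
#'
#' The pipeline draws six deep feature vectors per image, two per pretrained
#' backbone: DenseNet201 (final affine layer `fc1000`, global-average-pool
#' `avg_pool`), ResNet50 (`fc1000`, `avg_pool`), and ShuffleNet (`node_200`,
#' `node_202`). `node_200`/`node_202` are export-graph node names rather than
#' canonical layer names; they are registered here as the last
#' global-average-pool output and the final fully-connected output and can be
#' remapped by editing the returned data frame before passing it to [asnet()].
#' `fc1000` taps are taken after the final affine layer, before softmax.
#'
#' The `d` column records each tap's output width in the stock ImageNet-1k
#' architectures (e.g. 1920 for the DenseNet201 pooled features); the toy
#' extractor emits features of the same widths so dimension contracts hold
#' without the pretrained weights.
#'
#' @return Data frame with columns `backbone`, `layer`, `d`, in the fixed
#'   pipeline order F1..F6.
#' @export
backbone_registry <- function() {
  data.frame(
    backbone = c("densenet201", "densenet201", "resnet50", "resnet50",
                 "shufflenet", "shufflenet"),
    layer = c("fc1000", "avg_pool", "fc1000", "avg_pool",
              "node_200", "node_202"),
    d = c(1000L, 1920L, 1000L, 2048L, 544L, 1000L),
    stringsAsFactors = FALSE
  )
}

# ImageNet normalization constants shared by all three backbones.
imagenet_norm <- list(mean = c(0.485, 0.456, 0.406), sd = c(0.229, 0.224, 0.225))

#' Resize and normalize an image for a backbone
#'
#' Bilinearly resizes to `input_size`, replicates grayscale across three
#' channels, and normalizes each channel with the backbones' published
#' ImageNet training-set constants. Deterministic; no augmentation.
#'
#' @param img `H x W` or `H x W x 3` numeric array with unit-scaled
#'   intensities (raw-valued DICOM images are min-max scaled first).
#' @param input_size Target `(H, W)`, default `c(224, 224)`.
#' @return `H x W x 3` normalized array.
#' @export
preprocess_for_backbone <- function(img, input_size = c(224L, 224L)) {
  if (length(dim(img)) == 2L) {
    if (any(dim(img) < 1L) || length(img) == 0L) stop("zero-area image")
    img <- array(rep(img, 3L), c(dim(img), 3L))
  }
  if (any(dim(img)[1:2] < 1L)) stop("zero-area image")
  if (identical(attr(img, "value_range"), "raw")) {
    rng <- range(img)
    img <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  }
  out <- array(0, c(input_size, 3L))
  for (ch in 1:3)
    out[, , ch] <- (bilinear_resize(img[, , ch], input_size) -
                      imagenet_norm$mean[ch]) / imagenet_norm$sd[ch]
  out
}

bilinear_resize <- function(m, size) {
  h <- nrow(m); w <- ncol(m)
  if (h == size[1] && w == size[2]) return(m)
  yi <- seq(1, h, length.out = size[1])
  xi <- seq(1, w, length.out = size[2])
  y0 <- pmax(pmin(floor(yi), h - 1), 1)
  x0 <- pmax(pmin(floor(xi), w - 1), 1)
  fy <- yi - y0; fx <- xi - x0
  y1 <- pmin(y0 + 1, h); x1 <- pmin(x0 + 1, w)
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
  c_ <- m[y1, x0, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
  top <- a * (1 - rep(fx, each = size[1])) + b * rep(fx, each = size[1])
  bot <- c_ * (1 - rep(fx, each = size[1])) + d * rep(fx, each = size[1])
  top * (1 - fy) + bot * fy
}

#' Toy deterministic feature extractor
#'
#' A dependency-free stand-in for a frozen CNN tap: computes a fixed
#' image-statistics vector (global moments, a 16-bin intensity histogram, and
#' per-block means and gradient energies on a 4x4 grid) and projects it to
#' dimension `d` with a seeded Gaussian random projection. Identical images
#' give identical rows; class-dependent intensity/texture differences survive
#' the projection.
#'
#' @param img Grayscale or RGB numeric array (RGB is averaged to luminance).
#' @param d Output dimension (>= 1).
#' @param seed Seed fixing the projection matrix.
#' @return Numeric feature row of length `d`.
#' @export
toy_extract <- function(img, d, seed = 0L) {
  if (d < 1L) stop("toy extractor dimension d must be >= 1")
  if (length(dim(img)) == 3L) img <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  rng <- range(img)
  u <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  mu <- mean(u); s <- sd(as.vector(u))
  z <- if (s > 0) (u - mu) / s else u * 0
  moments <- c(mu, s, mean(z^3), mean(z^4))
  hist16 <- tabulate(pmin(floor(u * 16) + 1L, 16L), 16L) / length(u)
  blocks <- block_stats(u, 4L)
  stats <- c(moments, hist16, blocks)  # length 4 + 16 + 32 = 52
  proj <- with_seed(seed, matrix(stats::rnorm(length(stats) * d),
                                 nrow = length(stats), ncol = d))
  as.numeric(stats %*% proj) / sqrt(length(stats))
}

block_stats <- function(u, g) {
  h <- nrow(u); w <- ncol(u)
  ry <- pmin(ceiling(seq_len(h) / (h / g)), g)
  rx <- pmin(ceiling(seq_len(w) / (w / g)), g)
  dy <- abs(u[-1, , drop = FALSE] - u[-h, , drop = FALSE])
  dx <- abs(u[, -1, drop = FALSE] - u[, -w, drop = FALSE])
  means <- numeric(g * g); grad <- numeric(g * g)
  k <- 0L
  for (i in seq_len(g)) for (j in seq_len(g)) {
    k <- k + 1L
    sel_y <- ry == i; sel_x <- rx == j
    means[k] <- mean(u[sel_y, sel_x])
    gy <- if (h > 1L) mean(dy[sel_y[-h], sel_x]) else 0
    gx <- if (w > 1L) mean(dx[sel_y, sel_x[-w]]) else 0
    grad[k] <- gy + gx
  }
  c(means, grad)
}

#' Extract a feature matrix for one backbone tap
#'
#' Reads each manifest image and produces the flattened activation row of the
#' requested tap. With `mode = "toy"` the seeded toy extractor emulates the
#' tap at its registered output width; `mode = "pretrained"` requires a deep
#' learning runtime with the frozen ImageNet weights, which this package does
#' not bundle — it raises an actionable error pointing at the toy extractor
#' and at [read_feature_table()] for features exported from the real networks.
#'
#' @param manifest An [load_manifest()] result.
#' @param backbone,layer One of the registered pairs (see [backbone_registry()]).
#' @param mode `"toy"` or `"pretrained"`.
#' @param seed Toy-mode projection seed.
#' @param batch_size Number of images decoded per batch; output independent of it.
#' @return `n x d` matrix with attributes `backbone`, `layer`.
#' @export
extract_features <- function(manifest, backbone, layer, mode = c("toy", "pretrained"),
                             seed = 0L, batch_size = 8L) {
  mode <- match.arg(mode)
  reg <- backbone_registry()
  row <- reg[reg$backbone == backbone & reg$layer == layer, ]
  if (nrow(row) != 1L)
    stop("unknown (backbone, layer) tap: ", backbone, "/", layer,
         "; valid taps: ", paste(paste(reg$backbone, reg$layer, sep = "/"), collapse = ", "))
  if (nrow(manifest) == 0L) stop("no samples in manifest")
  if (mode == "pretrained")
    stop("pretrained weights for ", backbone, " are not bundled; either use ",
         "mode = \"toy\" or import features exported from the pretrained ",
         "network with read_feature_table()")
  d <- row$d
  tap_seed <- seed + 1000L * match(paste(backbone, layer), paste(reg$backbone, reg$layer))
  x <- matrix(NA_real_, nrow(manifest), d)
  for (start in seq(1L, nrow(manifest), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, nrow(manifest))
    for (i in idx) {
      img <- preprocess_for_backbone(read_image(manifest$path[i]))
      x[i, ] <- toy_extract(img, d, seed = tap_seed)
    }
  }
  rownames(x) <- manifest$sample_id
  structure(x, backbone = backbone, layer = layer)
}

#' Extract all six registered feature matrices
#'
#' @inheritParams extract_features
#' @return List of 6 feature matrices in the fixed registry order
#'   (DenseNet201 fc1000, DenseNet201 avg_pool, ResNet50 fc1000,
#'   ResNet50 avg_pool, ShuffleNet node_200, ShuffleNet node_202).
#' @export
extract_all <- function(manifest, mode = c("toy", "pretrained"), seed = 0L,
                        batch_size = 8L) {
  mode <- match.arg(mode)
  reg <- backbone_registry()
  lapply(seq_len(nrow(reg)), function(i) {
    tryCatch(
      extract_features(manifest, reg$backbone[i], reg$layer[i], mode = mode,
                       seed = seed, batch_size = batch_size),
      error = function(e) stop("feature extraction failed for ", reg$backbone[i],
                               "/", reg$layer[i], ": ", conditionMessage(e),
                               call. = FALSE)
    )
  })
}
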