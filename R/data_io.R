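#' Build a dataset manifest from an image directory
#'
#' Discovers two-class (or multi-class) image datasets and returns the manifest
#' that every later pipeline stage is aligned to. Two layouts are supported:
#' `"class-subdirs"`, where each immediate subdirectory of `root` is a class and
#' contains that class's images, and `"manifest-file"`, where `root` is (or
#' contains) a CSV with columns `sample_id,path,label` and optionally
#' `group_id` (e.g. a patient identifier for grouped cross-validation).
#'
#' Classes are encoded as integers `1..C` in `class_names` order (sorted
#' lexicographically for the subdirectory layout, or first-appearance order as
#' declared by a manifest file). Samples are sorted by path so repeated loads
#' of the same directory give byte-identical manifests and stable
#' cross-validation folds.
#'
#' @param root Directory with class subdirectories, or a manifest CSV path.
#' @param layout `"class-subdirs"` or `"manifest-file"`.
#' @return An object of class `asnet_manifest`: a data frame with columns
#'   `sample_id`, `path`, `label` (integer code), and optionally `group_id`,
#'   plus attributes `class_names` (ordered character vector).
#' @export
#' @examples
#' d <- tempfile(); dir.create(file.path(d, "AS"), recursive = TRUE)
#' dir.create(file.path(d, "control"))
#' img <- matrix(runif(64), 8, 8)
#' png::writePNG(img, file.path(d, "AS", "a1.png"))
#' png::writePNG(img, file.path(d, "control", "c1.png"))
#' m <- load_manifest(d)
#' class_names(m)
load_manifest <- function(root, layout = c("class-subdirs", "manifest-file")) {
  layout <- match.arg(layout)
  if (layout == "class-subdirs") {
    if (!dir.exists(root)) stop("directory does not exist: ", root)
    classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
    if (length(classes) == 0L) stop("no samples: ", root, " has no class subdirectories")
    exts <- "\\.(png|jpg|jpeg|bmp|dcm|dicom)$"
    rows <- lapply(classes, function(cl) {
      files <- sort(list.files(file.path(root, cl), pattern = exts,
                               ignore.case = TRUE, full.names = TRUE))
      if (length(files) == 0L) stop("degenerate class: '", cl, "' contains no images")
      data.frame(sample_id = paste0(cl, "/", basename(files)),
                 path = files, label_name = cl, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df <- df[order(df$path), , drop = FALSE]
    class_names <- classes
    group_id <- NULL
  } else {
    mf <- if (dir.exists(root)) {
      cand <- list.files(root, pattern = "manifest.*\\.csv$", full.names = TRUE)
      if (length(cand) == 0L) stop("no manifest CSV found in ", root)
      cand[1L]
    } else root
    if (!file.exists(mf)) stop("manifest file does not exist: ", mf)
    df <- read.csv(mf, stringsAsFactors = FALSE)
    need <- c("sample_id", "path", "label")
    if (!all(need %in% names(df)))
      stop("manifest file must have columns: ", paste(need, collapse = ", "))
    if (nrow(df) == 0L) stop("no samples in manifest file")
    if (anyDuplicated(df$sample_id))
      stop("duplicate sample_id in manifest file: ",
           df$sample_id[duplicated(df$sample_id)][1L])
    rel <- !file.exists(df$path) & file.exists(file.path(dirname(mf), df$path))
    df$path[rel] <- file.path(dirname(mf), df$path[rel])
    missing <- !file.exists(df$path)
    if (any(missing)) stop("missing file: ", df$path[which(missing)[1L]])
    df$label_name <- as.character(df$label)
    class_names <- unique(df$label_name)  # declared order
    group_id <- if ("group_id" %in% names(df)) df$group_id else NULL
    df <- df[order(df$path), , drop = FALSE]
    if (!is.null(group_id)) group_id <- group_id[order(df$path)]
  }
  if (length(class_names) < 2L)
    stop("need at least 2 classes, found ", length(class_names))
  out <- data.frame(sample_id = df$sample_id, path = df$path,
                    label = match(df$label_name, class_names),
                    stringsAsFactors = FALSE)
  if (!is.null(group_id)) out$group_id <- group_id
  rownames(out) <- NULL
  attr(out, "class_names") <- class_names
  class(out) <- c("asnet_manifest", "data.frame")
  out
}

#' Class names of a manifest or fit
#' @param x An `asnet_manifest` or `asnet` object.
#' @return Ordered character vector of class names; position gives the integer code.
#' @export
class_names <- function(x) attr(x, "class_names")

#' @export
print.asnet_manifest <- function(x, ...) {
  cn <- attr(x, "class_names")
  cat("Dataset manifest:", nrow(x), "samples,", length(cn), "classes\n")
  tab <- table(factor(x$label, levels = seq_along(cn), labels = cn))
  for (i in seq_along(cn))
    cat(sprintf("  %d = %s: %d samples\n", i, cn[i], tab[i]))
  invisible(x)
}

#' Read an image file into an intensity array
#'
#' Reads PNG, JPEG, BMP or single-frame DICOM files. Grayscale files yield a
#' single-channel array; RGB files keep three channels in the decoder's R,G,B
#' order. PNG/JPEG/BMP intensities are unit-scaled to `[0, 1]`; DICOM pixel
#' data are returned as raw stored values after applying RescaleSlope and
#' RescaleIntercept when present (no display windowing is applied).
#'
#' @param path Image file path. Format is detected by extension, then content.
#' @return Numeric array `H x W` (grayscale) or `H x W x 3` (RGB) with
#'   attribute `value_range` (`"unit"` or `"raw"`).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image, no such file: ", path)
  magic <- readBin(path, "raw", n = 132L)
  fmt <- detect_image_format(path, magic)
  img <- switch(fmt,
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3L && dim(a)[3] >= 3L) a <- a[, , 1:3, drop = FALSE]
      if (length(dim(a)) == 3L && dim(a)[3] == 1L) a <- a[, , 1L]
      structure(a, value_range = "unit")
    },
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop("reading JPEG requires the EBImage package: ", path)
      a <- EBImage::imageData(EBImage::readImage(path))
      # EBImage stores x,y(,c); transpose to row = image row
      a <- if (length(dim(a)) == 3L) aperm(a[, , 1:3, drop = FALSE], c(2, 1, 3)) else t(a)
      structure(a, value_range = "unit")
    },
    bmp = structure(read_bmp(path), value_range = "unit"),
    dicom = structure(read_dicom_image(path), value_range = "raw"),
    stop("unreadable or unsupported image file: ", path)
  )
  if (any(!is.finite(img))) stop("non-finite pixel values in: ", path)
  img
}

detect_image_format <- function(path, magic) {
  if (length(magic) >= 8L &&
      identical(magic[1:8], as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))))
    return("png")
  if (length(magic) >= 2L && identical(magic[1:2], as.raw(c(0xff, 0xd8))))
    return("jpeg")
  if (length(magic) >= 2L && identical(magic[1:2], charToRaw("BM")))
    return("bmp")
  if (length(magic) >= 132L && identical(magic[129:132], charToRaw("DICM")))
    return("dicom")
  # fall back to extension (e.g. headerless implicit-VR DICOM)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("dcm", "dicom")) return("dicom")
  stop("unreadable or unsupported image file: ", path)
}

#' Write / read a feature table
#'
#' Feature matrices are persisted as comma-delimited text with a header row
#' `sample_id,label,f0001,...`. Values are written with 17 significant digits
#' so a round-trip preserves them to better than 1e-12, along with sample
#' order and labels. A sidecar JSON (`<path>.json`) records provenance
#' (backbone, layer, dimensions) when supplied.
#'
#' @param x Numeric matrix, samples in rows.
#' @param labels Integer class codes, one per row.
#' @param path Output CSV path.
#' @param sample_ids Optional sample identifiers (default `s0001...`).
#' @param meta Optional named list of provenance written to `<path>.json`.
#' @return `write_feature_table`: the path, invisibly. `read_feature_table`:
#'   a list with `x` (matrix), `labels`, `sample_ids`, and `meta` (or NULL).
#' @export
write_feature_table <- function(x, labels, path, sample_ids = NULL, meta = NULL) {
  x <- as.matrix(x)
  if (nrow(x) != length(labels)) stop("labels length must match row count")
  if (is.null(sample_ids)) sample_ids <- sprintf("s%04d", seq_len(nrow(x)))
  df <- data.frame(sample_id = sample_ids, label = labels, stringsAsFactors = FALSE)
  feat <- as.data.frame(x)
  names(feat) <- sprintf("f%04d", seq_len(ncol(x)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample_id", "label", names(feat)), collapse = ","), con)
  for (i in seq_len(nrow(x)))
    writeLines(paste(c(sample_ids[i], labels[i],
                       sprintf("%.17g", x[i, ])), collapse = ","), con)
  if (!is.null(meta))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("no such feature table: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0L) stop("no samples in feature table: ", path)
  if (ncol(df) < 3L || !identical(names(df)[1:2], c("sample_id", "label")))
    stop("feature table must start with columns sample_id,label: ", path)
  feat_cols <- names(df)[-(1:2)]
  x <- matrix(NA_real_, nrow(df), length(feat_cols))
  for (j in seq_along(feat_cols)) {
    v <- suppressWarnings(as.numeric(df[[feat_cols[j]]]))
    bad <- which(is.na(v) & !is.na(df[[feat_cols[j]]]))
    if (length(bad))
      stop(sprintf("non-numeric feature cell at row %d, column %s", bad[1L], feat_cols[j]))
    x[, j] <- v
  }
  colnames(x) <- feat_cols
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else NULL
  list(x = x, labels = as.integer(df$label), sample_ids = df$sample_id, meta = meta)
}
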