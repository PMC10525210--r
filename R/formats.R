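# Minimal readers for single-frame DICOM and uncompressed BMP.
# Scope: explicit/implicit VR little-endian DICOM without pixel-data
# compression; 8-bit palette and 24-bit uncompressed BMP. Anything else
# errors with the path so callers can convert upstream.

u16 <- function(r, off) as.integer(r[off + 1L]) + 256L * as.integer(r[off + 2L])
u32 <- function(r, off) {
  b <- as.numeric(r[off + 1:4])
  b[1] + 256 * b[2] + 65536 * b[3] + 16777216 * b[4]
}

read_dicom_image <- function(path) {
  r <- readBin(path, "raw", n = file.size(path))
  off <- 0L
  if (length(r) >= 132L && identical(r[129:132], charToRaw("DICM"))) off <- 132L
  tags <- list()
  n <- length(r)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  known_vrs <- c("AE", "AS", "AT", "CS", "DA", "DS", "DT", "FL", "FD", "IS",
                 "LO", "LT", "PN", "SH", "SL", "SS", "ST", "TM", "UI", "UL",
                 "US", long_vrs)
  while (off + 8L <= n) {
    group <- u16(r, off); elem <- u16(r, off + 2L)
    vr_bytes <- r[off + 5:6]
    vr <- if (all(vr_bytes >= 0x41 & vr_bytes <= 0x5A)) rawToChar(vr_bytes) else ""
    if (group != 0xFFFEL && vr %in% known_vrs) {       # explicit VR
      if (vr %in% long_vrs) { len <- u32(r, off + 8L); hdr <- 12L }
      else { len <- u16(r, off + 6L); hdr <- 8L }
    } else {                                           # implicit VR
      vr <- "UN"; len <- u32(r, off + 4L); hdr <- 8L
    }
    if (len == 4294967295) {  # undefined length (sequence): skip to delimiter
      off <- off + hdr
      while (off + 8L <= n) {
        g <- u16(r, off); el <- u16(r, off + 2L); l <- u32(r, off + 4L)
        off <- off + 8L
        if (g == 0xFFFEL && el == 0xE0DDL) break
        if (g != 0xFFFEL && l != 4294967295) off <- off + l
      }
      next
    }
    body_off <- off + hdr
    if (body_off + len > n) stop("corrupt DICOM file (truncated element): ", path)
    key <- sprintf("%04x,%04x", group, elem)
    if (group %in% c(2L, 0x0028L) || (group == 0x7FE0L && elem == 0x0010L))
      tags[[key]] <- list(vr = vr, off = body_off, len = len)
    off <- body_off + len
  }
  ts_tag <- tags[["0002,0010"]]
  if (!is.null(ts_tag)) {
    ts <- sub("\\0+$", "", rawToChar(r[ts_tag$off + seq_len(ts_tag$len)]))
    if (!ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
      stop("unsupported (compressed or big-endian) DICOM transfer syntax in: ", path)
  }
  str_tag <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    trimws(sub("\\0+$", "", rawToChar(r[t$off + seq_len(t$len)])))
  }
  int_tag <- function(key, default = NULL) {
    t <- tags[[key]]
    if (is.null(t)) return(default)
    if (t$vr %in% c("US", "UN") && t$len == 2L) return(u16(r, t$off))
    if (t$len == 4L && t$vr %in% c("UL", "UN")) return(u32(r, t$off))
    as.numeric(str_tag(key))
  }
  num_tag <- function(key, default) {
    v <- str_tag(key)
    if (is.null(v) || v == "") default else as.numeric(v)
  }
  nframes <- num_tag("0028,0008", 1)
  if (!is.na(nframes) && nframes > 1) stop("multi-frame DICOM not supported: ", path)
  rows <- int_tag("0028,0010"); cols <- int_tag("0028,0011")
  if (is.null(rows) || is.null(cols)) stop("corrupt DICOM file (no Rows/Columns): ", path)
  bits <- int_tag("0028,0100", 16L)
  pixrep <- int_tag("0028,0103", 0L)
  spp <- int_tag("0028,0002", 1L)
  if (spp != 1L) stop("only single-sample (grayscale) DICOM supported: ", path)
  pd <- tags[["7fe0,0010"]]
  if (is.null(pd)) stop("corrupt DICOM file (no PixelData): ", path)
  npix <- rows * cols
  bytes <- bits / 8L
  if (pd$len < npix * bytes) stop("corrupt DICOM file (short PixelData): ", path)
  raw_px <- r[pd$off + seq_len(npix * bytes)]
  vals <- if (bytes == 2L) {
    readBin(raw_px, "integer", n = npix, size = 2L, signed = pixrep == 1L,
            endian = "little")
  } else {
    as.integer(raw_px)
  }
  slope <- num_tag("0028,1053", 1)
  intercept <- num_tag("0028,1052", 0)
  matrix(vals * slope + intercept, nrow = rows, ncol = cols, byrow = TRUE)
}

# Writes a minimal explicit-VR little-endian part-10 DICOM file; used to
# build tiny in-code fixtures. 16-bit unsigned pixels.
write_minimal_dicom <- function(path, pixels, slope = 1, intercept = 0) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  le16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  elem_short <- function(group, elem, vr, body) {
    le16(group); le16(elem); writeBin(charToRaw(vr), con)
    le16(length(body)); writeBin(body, con)
  }
  pad <- function(s) { r <- charToRaw(s); if (length(r) %% 2L) c(r, as.raw(0)) else r }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con); writeBin(charToRaw("DICM"), con)
  ts <- pad("1.2.840.10008.1.2.1")
  # group length of the single meta element that follows (8-byte header + body)
  elem_short(0x0002L, 0x0000L, "UL", writeBin(8L + length(ts), raw(), size = 4L, endian = "little"))
  elem_short(0x0002L, 0x0010L, "UI", ts)
  us <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
  elem_short(0x0028L, 0x0002L, "US", us(1L))                 # SamplesPerPixel
  elem_short(0x0028L, 0x0010L, "US", us(nrow(pixels)))       # Rows
  elem_short(0x0028L, 0x0011L, "US", us(ncol(pixels)))       # Columns
  elem_short(0x0028L, 0x0100L, "US", us(16L))                # BitsAllocated
  elem_short(0x0028L, 0x0103L, "US", us(0L))                 # PixelRepresentation
  elem_short(0x0028L, 0x1052L, "DS", pad(format(intercept))) # RescaleIntercept
  elem_short(0x0028L, 0x1053L, "DS", pad(format(slope)))     # RescaleSlope
  body <- writeBin(as.integer(t(pixels)), raw(), size = 2L, endian = "little")
  le16(0x7FE0L); le16(0x0010L); writeBin(charToRaw("OW"), con)
  le16(0L)
  writeBin(length(body), con, size = 4L, endian = "little")
  writeBin(body, con)
  invisible(path)
}

read_bmp <- function(path) {
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 54L || !identical(r[1:2], charToRaw("BM")))
    stop("corrupt BMP file: ", path)
  data_off <- u32(r, 10L)
  width <- u32(r, 18L)
  height_raw <- u32(r, 22L)
  bottom_up <- height_raw < 2^31
  height <- if (bottom_up) height_raw else 2^32 - height_raw
  bitcount <- u16(r, 28L)
  compression <- u32(r, 30L)
  if (compression != 0) stop("compressed BMP not supported: ", path)
  if (!bitcount %in% c(8L, 24L)) stop("only 8-bit and 24-bit BMP supported: ", path)
  if (bitcount == 8L) {
    hdr_size <- u32(r, 14L)
    ncol_pal <- u32(r, 46L); if (ncol_pal == 0) ncol_pal <- 256
    pal_off <- 14L + hdr_size
    pal <- matrix(as.integer(r[pal_off + seq_len(4 * ncol_pal)]), ncol = 4, byrow = TRUE)
    gray <- (0.299 * pal[, 3] + 0.587 * pal[, 2] + 0.114 * pal[, 1]) / 255
    stride <- ((width + 3) %/% 4) * 4
    out <- matrix(0, height, width)
    for (row in seq_len(height)) {
      src <- data_off + (row - 1L) * stride
      idx <- as.integer(r[src + seq_len(width)]) + 1L
      dst <- if (bottom_up) height - row + 1L else row
      out[dst, ] <- gray[idx]
    }
    out
  } else {
    stride <- ((3 * width + 3) %/% 4) * 4
    out <- array(0, c(height, width, 3L))
    for (row in seq_len(height)) {
      src <- data_off + (row - 1L) * stride
      px <- matrix(as.integer(r[src + seq_len(3 * width)]), ncol = 3, byrow = TRUE)
      dst <- if (bottom_up) height - row + 1L else row
      out[dst, , 1] <- px[, 3] / 255  # stored BGR
      out[dst, , 2] <- px[, 2] / 255
      out[dst, , 3] <- px[, 1] / 255
    }
    out
  }
}
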