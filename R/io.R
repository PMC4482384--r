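#' Read a raster image as a B-scan
#'
#' Reads PNG, TIFF or uncompressed BMP (the common 8-bit export format of
#' OCT acquisition software; read bit-faithfully by the package's own
#' decoder, as are 24-bit BMPs). Color images are converted to grayscale by
#' Rec. 601 luminance (0.299 R + 0.587 G + 0.114 B).
#'
#' @param path image file; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`, `.bmp`).
#' @param y_um_per_px,x_um_per_px optional physical scales to attach.
#' @return a [bscan_image()].
#' @export
read_bscan <- function(path, y_um_per_px = NULL, x_um_per_px = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    bmp = read_bmp(path),
    stop("unsupported image format: .", ext, " (use PNG, TIFF or BMP)",
         call. = FALSE)
  )
  bscan_image(to_grayscale(arr), y_um_per_px = y_um_per_px,
              x_um_per_px = x_um_per_px, source = path)
}

to_grayscale <- function(arr) {
  if (is.matrix(arr)) return(arr)
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    if (nc >= 3L) {
      return(0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3])
    }
    return(arr[, , 1])
  }
  stop("unsupported image layout", call. = FALSE)
}

#' Write an intensity image to PNG or TIFF
#'
#' Intensities are clipped to `[0, 1]` on write. PNG output is 8-bit; TIFF
#' may be written with 8 or 16 bits per sample. For corrected images a
#' sidecar JSON with the full provenance (source, exact factor, calibration
#' summary, interpolation) is written next to the image.
#'
#' @param image a `bscan_image`, `corrected_image` or intensity matrix.
#' @param path output file (`.png`, `.tif`/`.tiff`).
#' @param bits 8 (default) or 16 (TIFF only).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = 8L) {
  px <- if (is.matrix(image)) image else image$pixels
  px <- pmin(pmax(px, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bits != 8L) stop("PNG output is 8-bit; use TIFF for 16-bit", call. = FALSE)
    png::writePNG(px, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px, path, bits.per.sample = as.integer(bits))
  } else {
    stop("unsupported output format: .", ext, call. = FALSE)
  }
  if (inherits(image, "corrected_image")) {
    jsonlite::write_json(image$provenance, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

# --- minimal BMP codec -------------------------------------------------
# Uncompressed BI_RGB Windows bitmaps only: 8-bit palette and 24-bit BGR,
# bottom-up or top-down row order, rows padded to 4-byte multiples.

read_u16 <- function(raw, off) as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
read_u32 <- function(raw, off) {
  sum(as.numeric(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
}
read_s32 <- function(raw, off) {
  v <- read_u32(raw, off)
  if (v >= 2^31) v - 2^32 else v
}

#' Read an uncompressed BMP file
#'
#' @param path a `.bmp` file (8-bit palette or 24-bit, BI_RGB).
#' @return a numeric matrix in `[0, 1]` (grayscale palettes collapse to
#'   their gray level; color data are returned as an RGB array).
#' @export
read_bmp <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 54 || rawToChar(raw[1:2]) != "BM") {
    stop("not a BMP file: ", path, call. = FALSE)
  }
  data_off <- read_u32(raw, 10)
  hdr_size <- read_u32(raw, 14)
  if (hdr_size < 40) stop("unsupported BMP header", call. = FALSE)
  width <- read_s32(raw, 18)
  height_raw <- read_s32(raw, 22)
  bottom_up <- height_raw > 0
  height <- abs(height_raw)
  bpp <- read_u16(raw, 28)
  compression <- read_u32(raw, 30)
  if (compression != 0) stop("compressed BMP files are not supported", call. = FALSE)
  if (!bpp %in% c(8L, 24L)) {
    stop("unsupported BMP bit depth: ", bpp, " (8 or 24 expected)", call. = FALSE)
  }

  if (bpp == 8L) {
    n_colors <- read_u32(raw, 46)
    if (n_colors == 0) n_colors <- 256
    pal_off <- 14 + hdr_size
    pal <- matrix(as.integer(raw[pal_off + seq_len(4 * n_colors)]),
                  ncol = 4, byrow = TRUE)  # B G R X
    row_bytes <- 4 * ceiling(width / 4)
    idx <- matrix(0L, height, width)
    for (r in seq_len(height)) {
      off <- data_off + (r - 1) * row_bytes
      idx[r, ] <- as.integer(raw[off + seq_len(width)])
    }
    if (bottom_up) idx <- idx[height:1, , drop = FALSE]
    lum <- (0.299 * pal[, 3] + 0.587 * pal[, 2] + 0.114 * pal[, 1]) / 255
    matrix(lum[idx + 1L], height, width)
  } else {
    row_bytes <- 4 * ceiling(3 * width / 4)
    out <- array(0, c(height, width, 3))
    cols <- seq_len(width)
    for (r in seq_len(height)) {
      off <- data_off + (r - 1) * row_bytes
      px <- as.integer(raw[off + seq_len(3 * width)])
      out[r, , 1] <- px[3 * cols - 0] / 255  # R
      out[r, , 2] <- px[3 * cols - 1] / 255  # G
      out[r, , 3] <- px[3 * cols - 2] / 255  # B
    }
    if (bottom_up) out <- out[height:1, , , drop = FALSE]
    out
  }
}

#' Write a grayscale image as an 8-bit palette BMP
#'
#' Intended for producing test fixtures and interoperating with tools that
#' expect the classic 8-bit bitmap export.
#'
#' @param image a `bscan_image` or intensity matrix in `[0, 1]`.
#' @param path output `.bmp` path.
#' @return `path`, invisibly.
#' @export
write_bmp <- function(image, path) {
  px <- if (is.matrix(image)) image else image$pixels
  v <- round(pmin(pmax(px, 0), 1) * 255)
  h <- nrow(v); w <- ncol(v)
  row_bytes <- 4 * ceiling(w / 4)
  data_size <- row_bytes * h
  data_off <- 14 + 40 + 4 * 256

  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  u32(data_off + data_size); u16(0); u16(0); u32(data_off)
  u32(40); u32(w); u32(h); u16(1); u16(8); u32(0); u32(data_size)
  u32(2835); u32(2835); u32(256); u32(0)
  pal <- as.raw(rep(0:255, each = 4) * c(1, 1, 1, 0))  # B G R 0 gray ramp
  writeBin(pal, con)
  pad <- as.raw(rep(0, row_bytes - w))
  for (r in h:1) {  # bottom-up
    writeBin(as.raw(v[r, ]), con)
    if (length(pad)) writeBin(pad, con)
  }
  invisible(path)
}
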