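# Minimal baseline TIFF support: little-endian, greyscale, uncompressed,
# 8- or 16-bit, multi-page. No TIFF package is available in the supported
# dependency set, so the small subset of the format the package needs is
# implemented here directly. Writing always emits 16-bit, one strip per page;
# reading accepts any uncompressed single-sample baseline file.

TIFF_SHORT <- 3L
TIFF_LONG <- 4L

u16le <- function(v) {
  v <- as.integer(v)
  as.raw(c(v %% 256L, v %/% 256L))
}

u32le <- function(v) {
  v <- as.numeric(v)
  as.raw(c(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256,
           (v %/% 16777216) %% 256))
}

tiff_entry <- function(tag, type, count, value) {
  val <- if (type == TIFF_SHORT && count == 1) c(u16le(value), as.raw(c(0, 0)))
         else u32le(value)
  c(u16le(tag), u16le(type), u32le(count), val)
}

#' Write a greyscale image stack as a multi-page TIFF
#'
#' Intensities in [0, 1] are quantized to 16-bit unsigned samples. One page
#' per slice, uncompressed, little-endian baseline TIFF.
#'
#' @param stack a 3D array ordered (page, y, x) with values in [0, 1], or a
#'   single matrix (y, x).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_tiff <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, c(1, dim(stack)))
  stopifnot(length(dim(stack)) == 3)
  if (any(!is.finite(stack)) || min(stack) < 0 || max(stack) > 1)
    stop("stack intensities must be finite and lie in [0, 1]")
  np <- dim(stack)[1]; h <- dim(stack)[2]; w <- dim(stack)[3]
  nbytes <- 2 * h * w
  ifd_size <- 2 + 9 * 12 + 4
  con <- file(path, "wb")
  on.exit(close(con))
  # layout: header | page1 data | page1 IFD | page2 data | page2 IFD | ...
  writeBin(c(charToRaw("II"), u16le(42), u32le(8 + nbytes)), con)
  pos <- 8
  for (p in seq_len(np)) {
    data_off <- pos
    ifd_off <- data_off + nbytes
    # pixel rows in y-major raster order; R array slice is (y, x)
    px <- round(pmin(pmax(t(stack[p, , , drop = TRUE]), 0), 1) * 65535)
    px <- as.vector(px)  # x fastest after transpose
    lo <- as.raw(px %% 256)
    hi <- as.raw(px %/% 256)
    buf <- as.raw(rbind(lo, hi))
    writeBin(buf, con)
    entries <- c(
      tiff_entry(256, TIFF_LONG, 1, w),        # ImageWidth
      tiff_entry(257, TIFF_LONG, 1, h),        # ImageLength
      tiff_entry(258, TIFF_SHORT, 1, 16),      # BitsPerSample
      tiff_entry(259, TIFF_SHORT, 1, 1),       # Compression = none
      tiff_entry(262, TIFF_SHORT, 1, 1),       # Photometric = BlackIsZero
      tiff_entry(273, TIFF_LONG, 1, data_off), # StripOffsets
      tiff_entry(277, TIFF_SHORT, 1, 1),       # SamplesPerPixel
      tiff_entry(278, TIFF_LONG, 1, h),        # RowsPerStrip
      tiff_entry(279, TIFF_LONG, 1, nbytes)    # StripByteCounts
    )
    next_ifd <- if (p < np) ifd_off + ifd_size + nbytes else 0
    writeBin(c(u16le(9), entries, u32le(next_ifd)), con)
    pos <- ifd_off + ifd_size
  }
  invisible(path)
}

read_u16 <- function(buf, off, n = 1) {
  idx <- off + seq_len(2 * n)
  b <- as.integer(buf[idx])
  b[seq(1, 2 * n, 2)] + 256 * b[seq(2, 2 * n, 2)]
}

read_u32 <- function(buf, off, n = 1) {
  idx <- off + seq_len(4 * n)
  b <- as.integer(buf[idx])
  i <- seq(1, 4 * n, 4)
  b[i] + 256 * b[i + 1] + 65536 * b[i + 2] + 16777216 * b[i + 3]
}

#' Read a multi-page greyscale TIFF
#'
#' Accepts uncompressed little-endian baseline TIFF with one sample per pixel
#' (8- or 16-bit). Intensities are rescaled to [0, 1].
#'
#' @param path TIFF file path.
#' @return a 3D array ordered (page, y, x) with values in [0, 1].
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop("no such TIFF file: ", path)
  buf <- readBin(path, "raw", n = file.info(path)$size)
  if (length(buf) < 8 || rawToChar(buf[1:2]) != "II" || read_u16(buf, 2) != 42)
    stop("not a little-endian TIFF file: ", path)
  ifd_off <- read_u32(buf, 4)
  pages <- list()
  while (ifd_off != 0) {
    n_entries <- read_u16(buf, ifd_off)
    tags <- list()
    for (e in seq_len(n_entries)) {
      base <- ifd_off + 2 + (e - 1) * 12
      tag <- read_u16(buf, base)
      type <- read_u16(buf, base + 2)
      count <- read_u32(buf, base + 4)
      esz <- c(1, 1, 2, 4)[type]  # BYTE, ASCII, SHORT, LONG
      if (is.na(esz)) next
      voff <- if (esz * count <= 4) base + 8 else read_u32(buf, base + 8)
      vals <- if (type == TIFF_SHORT) read_u16(buf, voff, count)
              else if (type == TIFF_LONG) read_u32(buf, voff, count)
              else as.integer(buf[voff + seq_len(count)])
      tags[[as.character(tag)]] <- vals
    }
    need <- function(tag) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) stop("malformed TIFF (missing tag ", tag, "): ", path)
      v
    }
    w <- need(256); h <- need(257)
    bits <- if (is.null(tags[["258"]])) 1L else tags[["258"]][1]
    comp <- if (is.null(tags[["259"]])) 1L else tags[["259"]][1]
    if (comp != 1) stop("unsupported TIFF compression (", comp, "): ", path)
    if (!bits %in% c(8, 16))
      stop("unsupported TIFF bit depth (", bits, "): ", path)
    offs <- need(273)
    cnts <- need(279)
    raw_px <- unlist(lapply(seq_along(offs), function(i)
      buf[offs[i] + seq_len(cnts[i])]), use.names = FALSE)
    if (bits == 16) {
      px <- read_u16(as.raw(raw_px), 0, h * w) / 65535
    } else {
      px <- as.integer(as.raw(raw_px))[seq_len(h * w)] / 255
    }
    pages[[length(pages) + 1]] <- t(matrix(px, nrow = w, ncol = h))
    ifd_off <- read_u32(buf, ifd_off + 2 + n_entries * 12)
  }
  if (length(pages) == 0) stop("TIFF file contains no pages: ", path)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  out <- array(0, c(length(pages), h, w))
  for (p in seq_along(pages)) out[p, , ] <- pages[[p]]
  out
}
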