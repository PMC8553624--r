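# Minimal baseline TIFF support. No TIFF package ships with this stack, so
# the package carries its own reader/writer for the subset microscopy
# exports here need: uncompressed, single-sample (grayscale) images,
# 8/16-bit unsigned or 32-bit float samples, one IFD per z-plane.

TIFF_TYPE_SHORT <- 3L
TIFF_TYPE_LONG <- 4L

#' Write a 2D/3D numeric array as an uncompressed grayscale TIFF
#'
#' One page per z-plane; 32-bit float samples by default so fluorescence
#' values round-trip exactly, or 16-bit unsigned for integer label maps.
#'
#' @param x Numeric/integer matrix `(y, x)` or array `(y, x, z)`.
#' @param path Output file path.
#' @param bits 32 (IEEE float) or 16 (unsigned integer).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(x, path, bits = 32L) {
  d <- dim(x) %||% stop("x must be a matrix or 3D array")
  if (length(d) == 2L) { x <- array(x, c(d, 1L)); d <- dim(x) }
  stopifnot(length(d) == 3L, bits %in% c(16L, 32L))
  h <- d[1L]; w <- d[2L]; np <- d[3L]
  bytes_pp <- bits %/% 8L
  strip_len <- h * w * bytes_pp
  ifd_size <- 2L + 10L * 12L + 4L
  data_off <- as.integer(8L + (seq_len(np) - 1L) * strip_len)
  ifd0 <- as.integer(8L + np * strip_len)
  ifd_off <- as.integer(ifd0 + (seq_len(np) - 1L) * ifd_size)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(ifd0, con, size = 4L, endian = "little")
  for (k in seq_len(np)) {
    v <- as.vector(t(x[, , k])) # row-major
    if (bits == 32L) {
      writeBin(as.numeric(v), con, size = 4L, endian = "little")
    } else {
      if (any(v < 0 | v > 65535)) stop("16-bit samples must be in 0..65535")
      writeBin(as.integer(round(v)), con, size = 2L, endian = "little")
    }
  }
  entry <- function(tag, type, value) {
    writeBin(as.integer(tag), con, size = 2L, endian = "little")
    writeBin(as.integer(type), con, size = 2L, endian = "little")
    writeBin(1L, con, size = 4L, endian = "little")
    if (type == TIFF_TYPE_SHORT) {
      writeBin(as.integer(value), con, size = 2L, endian = "little")
      writeBin(0L, con, size = 2L, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4L, endian = "little")
    }
  }
  for (k in seq_len(np)) {
    writeBin(10L, con, size = 2L, endian = "little")
    entry(256L, TIFF_TYPE_LONG, w)            # ImageWidth
    entry(257L, TIFF_TYPE_LONG, h)            # ImageLength
    entry(258L, TIFF_TYPE_SHORT, bits)        # BitsPerSample
    entry(259L, TIFF_TYPE_SHORT, 1L)          # Compression: none
    entry(262L, TIFF_TYPE_SHORT, 1L)          # Photometric: BlackIsZero
    entry(273L, TIFF_TYPE_LONG, data_off[k])  # StripOffsets
    entry(277L, TIFF_TYPE_SHORT, 1L)          # SamplesPerPixel
    entry(278L, TIFF_TYPE_LONG, h)            # RowsPerStrip
    entry(279L, TIFF_TYPE_LONG, as.integer(strip_len)) # StripByteCounts
    entry(339L, TIFF_TYPE_SHORT, if (bits == 32L) 3L else 1L) # SampleFormat
    writeBin(if (k < np) ifd_off[k + 1L] else 0L, con, size = 4L,
             endian = "little")
  }
  invisible(path)
}

#' Read an uncompressed grayscale TIFF into a numeric array
#'
#' Supports baseline single-sample TIFFs with 8/16-bit unsigned or 32-bit
#' float samples, multiple strips, both byte orders, and multiple pages
#' (returned as the z axis).
#'
#' @param path TIFF file path.
#' @return Numeric array `(y, x, z)`; `z = 1` for single-page files.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little"
  else if (order_tag == "MM") "big" else stop("not a TIFF file: ", path)
  rd <- function(off, n, size, what = "integer", signed = TRUE)
    readBin(raw[(off + 1L):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = signed || size > 2L)
  magic <- rd(2L, 1L, 2L, signed = FALSE)
  if (magic != 42L) stop("not a TIFF file: ", path)
  ifd <- rd(4L, 1L, 4L)
  pages <- list()
  while (ifd != 0L) {
    n_ent <- rd(ifd, 1L, 2L, signed = FALSE)
    tags <- list()
    for (e in seq_len(n_ent)) {
      off <- ifd + 2L + (e - 1L) * 12L
      tag <- rd(off, 1L, 2L, signed = FALSE)
      type <- rd(off + 2L, 1L, 2L, signed = FALSE)
      cnt <- rd(off + 4L, 1L, 4L)
      tsize <- c(1L, 1L, 2L, 4L)[type] # BYTE, ASCII, SHORT, LONG
      if (is.na(tsize)) next
      voff <- if (cnt * tsize <= 4L) off + 8L else rd(off + 8L, 1L, 4L)
      vals <- rd(voff, cnt, tsize, signed = FALSE)
      tags[[as.character(tag)]] <- vals
    }
    g <- function(tag, default = NULL) tags[[as.character(tag)]] %||% default
    w <- g(256L); h <- g(257L)
    if (is.null(w) || is.null(h)) stop("TIFF page lacks dimensions")
    bits <- g(258L, 1L)[1L]
    if (g(259L, 1L) != 1L) stop("compressed TIFFs are not supported")
    if (g(277L, 1L) != 1L) stop("only single-sample TIFFs are supported")
    fmt <- g(339L, 1L)[1L]
    offs <- g(273L); cnts <- g(279L)
    if (is.null(offs) || is.null(cnts)) stop("TIFF page lacks strip layout")
    buf <- raw(0L)
    for (s in seq_along(offs))
      buf <- c(buf, raw[(offs[s] + 1L):(offs[s] + cnts[s])])
    v <- if (bits == 32L && fmt == 3L) {
      readBin(buf, "numeric", n = w * h, size = 4L, endian = endian)
    } else if (bits == 16L && fmt %in% c(1L, 4L)) {
      readBin(buf, "integer", n = w * h, size = 2L, endian = endian,
              signed = FALSE)
    } else if (bits == 8L && fmt %in% c(1L, 4L)) {
      as.integer(buf[seq_len(w * h)])
    } else {
      stop("unsupported TIFF sample layout (bits=", bits,
           ", format=", fmt, ")")
    }
    pages[[length(pages) + 1L]] <- matrix(as.numeric(v), nrow = h,
                                          ncol = w, byrow = TRUE)
    ifd <- rd(ifd + 2L + n_ent * 12L, 1L, 4L)
  }
  if (!length(pages)) stop("TIFF contains no pages: ", path)
  arr <- array(0, c(dim(pages[[1L]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  arr
}
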