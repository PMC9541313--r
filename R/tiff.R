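# ---- minimal baseline TIFF I/O --------------------------------------------
# No TIFF library is available in the target R stack, so the package carries
# its own reader/writer for the narrow profile it needs: single-image,
# uncompressed, little-endian, grayscale, 16-bit unsigned (stain images) or
# 32-bit signed integer (label maps), one strip. The reader also accepts
# multi-strip files and big-endian byte order for interoperability with
# standard writers.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, rows_per_strip = 278L,
               strip_byte_counts = 279L, sample_format = 339L)

#' Write a matrix as a grayscale TIFF
#'
#' @param m numeric or integer matrix (rows = image rows); values are rounded
#' @param path output file
#' @param bits 16 (unsigned, images) or 32 (signed integer, label maps)
#' @export
write_tiff <- function(m, path, bits = 16) {
  stopifnot(bits %in% c(16L, 32L))
  v <- as.integer(round(as.vector(t(m)))) # row-major
  if (bits == 16) {
    v[v < 0] <- 0L
    v[v > 65535L] <- 65535L
    v <- ifelse(v > 32767L, v - 65536L, v) # two's complement bytes
  }
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2,
                             endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4,
                             endian = "little")
  nbytes <- length(v) * (bits / 8)
  data_offset <- 8L
  ifd_offset <- data_offset + nbytes
  if (ifd_offset %% 2 == 1) ifd_offset <- ifd_offset + 1L
  writeBin(charToRaw("II"), con)
  w2(42L)
  w4(ifd_offset)
  writeBin(v, con, size = bits / 8, endian = "little")
  if ((data_offset + nbytes) %% 2 == 1) writeBin(raw(1), con)
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count); w4(value)
  }
  w2(9L) # entry count
  entry(TIFF_TAGS["width"], 3L, 1L, ncol(m))
  entry(TIFF_TAGS["length"], 3L, 1L, nrow(m))
  entry(TIFF_TAGS["bits"], 3L, 1L, bits)
  entry(TIFF_TAGS["compression"], 3L, 1L, 1L)
  entry(TIFF_TAGS["photometric"], 3L, 1L, 1L)
  entry(TIFF_TAGS["strip_offsets"], 4L, 1L, data_offset)
  entry(TIFF_TAGS["rows_per_strip"], 3L, 1L, nrow(m))
  entry(TIFF_TAGS["strip_byte_counts"], 4L, 1L, nbytes)
  entry(TIFF_TAGS["sample_format"], 3L, 1L, if (bits == 32) 2L else 1L)
  w4(0L) # no further IFD
  invisible(path)
}

#' Read a grayscale TIFF written by [write_tiff()] (or an equivalent
#' uncompressed single-sample file)
#'
#' @param path TIFF file
#' @return integer matrix
#' @export
read_tiff <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  if (length(raw_all) < 8) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(raw_all[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM")
    "big" else stop("not a TIFF file: ", path)
  int_at <- function(off, size, signed = TRUE)
    readBin(raw_all[(off + 1):(off + size)], "integer", 1, size = size,
            signed = signed, endian = endian)
  magic <- int_at(2, 2, signed = FALSE)
  if (magic != 42) stop("not a TIFF file: ", path)
  ifd <- int_at(4, 4)
  n_entries <- int_at(ifd, 2, signed = FALSE)
  tags <- list()
  for (i in seq_len(n_entries)) {
    off <- ifd + 2 + (i - 1) * 12
    tag <- int_at(off, 2, signed = FALSE)
    type <- int_at(off + 2, 2, signed = FALSE)
    count <- int_at(off + 4, 4)
    value <- if (type == 3 && count == 1) int_at(off + 8, 2, signed = FALSE)
      else int_at(off + 8, 4)
    tags[[as.character(tag)]] <- list(type = type, count = count,
                                      value = value, off = off)
  }
  get_tag <- function(id, default = NULL) {
    t <- tags[[as.character(id)]]
    if (is.null(t)) return(default)
    t$value
  }
  if (get_tag(TIFF_TAGS["compression"], 1L) != 1)
    stop("only uncompressed TIFF is supported")
  w <- get_tag(TIFF_TAGS["width"])
  h <- get_tag(TIFF_TAGS["length"])
  bits <- get_tag(TIFF_TAGS["bits"], 16L)
  fmt <- get_tag(TIFF_TAGS["sample_format"], 1L)
  if (!bits %in% c(8L, 16L, 32L)) stop("unsupported bit depth: ", bits)
  # strip offsets/counts (possibly arrays)
  read_array <- function(id) {
    t <- tags[[as.character(id)]]
    if (is.null(t)) stop("missing TIFF tag ", id)
    size <- if (t$type == 3) 2L else 4L
    if (t$count == 1) return(t$value)
    base <- t$value
    vapply(seq_len(t$count), function(k)
      int_at(base + (k - 1) * size, size, signed = FALSE), numeric(1))
  }
  offs <- read_array(TIFF_TAGS["strip_offsets"])
  cnts <- read_array(TIFF_TAGS["strip_byte_counts"])
  bytes <- unlist(lapply(seq_along(offs), function(k)
    raw_all[(offs[k] + 1):(offs[k] + cnts[k])]))
  n <- w * h
  v <- readBin(bytes, "integer", n, size = bits / 8,
               signed = (fmt == 2 || bits == 32), endian = endian)
  if (bits == 16 && fmt == 1) v[v < 0] <- v[v < 0] + 65536L
  matrix(as.integer(v), nrow = h, ncol = w, byrow = TRUE)
}

#' Write an RGB array as a binary PPM (P6) image
#'
#' Overlay rasters (area colour maps, divided/non-divided maps) are written
#' as PPM: a dependency-free, deterministic, widely viewable format.
#'
#' @param rgb H x W x 3 array with values in \[0, 1\]
#' @param path output file
#' @export
write_ppm <- function(rgb, path) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(sprintf("P6\n%d %d\n255\n", w, h)), con)
  v <- as.integer(round(pmin(pmax(rgb, 0), 1) * 255))
  arr <- array(v, dim(rgb))
  interleaved <- as.vector(aperm(arr, c(3, 2, 1))) # RGB per pixel, row-major
  writeBin(as.raw(interleaved), con)
  invisible(path)
}
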