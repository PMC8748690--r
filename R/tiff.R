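# Minimal baseline TIFF codec (little-endian, uncompressed, single-sample
# grayscale, one strip per page). The execution environment ships no TIFF
# reader for R, so the handful of tags the pipeline needs are read and
# written here directly. Supports 8/16-bit unsigned integer and 32-bit
# float pages. Not a general TIFF implementation.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, StripOffsets = 273L,
               SamplesPerPixel = 277L, RowsPerStrip = 278L,
               StripByteCounts = 279L, SampleFormat = 339L)

# pages: list of numeric matrices (nx x ny; x = fastest/withing-row index).
# dtype: "uint16" or "float32".
write_tiff_pages <- function(pages, path, dtype = c("uint16", "float32")) {
  dtype <- match.arg(dtype)
  stopifnot(length(pages) >= 1, all(vapply(pages, is.matrix, logical(1))))
  bps <- if (dtype == "uint16") 16L else 32L
  fmt <- if (dtype == "uint16") 1L else 3L
  bytespp <- bps / 8L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")

  n <- length(pages)
  data_offsets <- integer(n)
  pos <- 8L
  # IFD offset placeholder, patched after data is laid out
  writeBin(0L, con, size = 4, endian = "little")
  pos <- pos # header(8) includes the IFD pointer; data starts at 8
  # layout: [header 8 bytes][page data ...][IFD chain]
  offset <- 8L
  for (i in seq_len(n)) {
    data_offsets[i] <- offset
    offset <- offset + length(pages[[i]]) * bytespp
    if (offset %% 2L == 1L) offset <- offset + 1L  # word-align
  }
  first_ifd <- offset
  # patch header IFD pointer
  seek(con, 4, origin = "start", rw = "write")
  writeBin(as.integer(first_ifd), con, size = 4, endian = "little")
  seek(con, 8, origin = "start", rw = "write")

  for (i in seq_len(n)) {
    v <- as.vector(pages[[i]])
    if (dtype == "uint16") {
      v <- as.integer(round(v))
      if (any(v < 0L | v > 65535L)) stop("uint16 TIFF values must lie in [0, 65535]")
      writeBin(v, con, size = 2, endian = "little")
    } else {
      writeBin(as.double(v), con, size = 4, endian = "little")
    }
    here <- seek(con, NA, rw = "write")
    if (here %% 2 == 1) writeBin(as.raw(0), con)
  }

  write_entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) { # SHORT packed into 4-byte value field
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }

  for (i in seq_len(n)) {
    nx <- nrow(pages[[i]]); ny <- ncol(pages[[i]])
    entries <- list(
      list(TIFF_TAGS[["ImageWidth"]], 4L, 1L, nx),
      list(TIFF_TAGS[["ImageLength"]], 4L, 1L, ny),
      list(TIFF_TAGS[["BitsPerSample"]], 3L, 1L, bps),
      list(TIFF_TAGS[["Compression"]], 3L, 1L, 1L),
      list(TIFF_TAGS[["Photometric"]], 3L, 1L, 1L),
      list(TIFF_TAGS[["StripOffsets"]], 4L, 1L, data_offsets[i]),
      list(TIFF_TAGS[["SamplesPerPixel"]], 3L, 1L, 1L),
      list(TIFF_TAGS[["RowsPerStrip"]], 4L, 1L, ny),
      list(TIFF_TAGS[["StripByteCounts"]], 4L, 1L, nx * ny * bytespp),
      list(TIFF_TAGS[["SampleFormat"]], 3L, 1L, fmt)
    )
    writeBin(length(entries), con, size = 2, endian = "little")
    for (e in entries) do.call(write_entry, e)
    ifd_size <- 2L + 12L * length(entries) + 4L
    next_ifd <- if (i < n) first_ifd + i * ifd_size else 0L
    # IFDs are contiguous and equally sized, so the chain offset is arithmetic
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
    first_ifd <- first_ifd # unchanged; next offsets derived from it
  }
  invisible(path)
}

read_tiff_pages <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  u16 <- function(off) as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
  u32 <- function(off) {
    as.numeric(as.integer(raw[off + 1])) + 256 * as.integer(raw[off + 2]) +
      65536 * as.integer(raw[off + 3]) + 16777216 * as.integer(raw[off + 4])
  }
  if (rawToChar(raw[1:2]) != "II" || u16(2) != 42L)
    stop("unsupported TIFF header (only little-endian baseline TIFF is read)")

  pages <- list()
  ifd <- u32(4)
  while (ifd != 0) {
    n_entries <- u16(ifd)
    tags <- list()
    for (k in seq_len(n_entries)) {
      off <- ifd + 2 + (k - 1) * 12
      tag <- u16(off); type <- u16(off + 2)
      val <- if (type == 3L) u16(off + 8) else u32(off + 8)
      tags[[as.character(tag)]] <- val
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(TIFF_TAGS[[tag]])]]
      if (is.null(v)) default else v
    }
    if (g("Compression", 1L) != 1L) stop("compressed TIFF is not supported")
    if (g("SamplesPerPixel", 1L) != 1L) stop("only single-sample grayscale TIFF is supported")
    nx <- g("ImageWidth"); ny <- g("ImageLength")
    bps <- g("BitsPerSample", 8L); fmt <- g("SampleFormat", 1L)
    so <- g("StripOffsets"); sbc <- g("StripByteCounts", nx * ny * bps / 8)
    if (is.null(nx) || is.null(ny) || is.null(so)) stop("missing required TIFF tags")
    bytes <- raw[(so + 1):(so + sbc)]
    vals <- if (fmt == 3L && bps == 32L) {
      readBin(bytes, "double", n = nx * ny, size = 4, endian = "little")
    } else if (fmt == 1L && bps == 16L) {
      readBin(bytes, "integer", n = nx * ny, size = 2, signed = FALSE,
              endian = "little")
    } else if (fmt == 1L && bps == 8L) {
      as.integer(bytes)
    } else stop("unsupported TIFF sample format: ", fmt, "/", bps, " bits")
    pages[[length(pages) + 1]] <- matrix(vals, nrow = nx, ncol = ny)
    ifd <- u32(ifd + 2 + n_entries * 12)
  }
  pages
}
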