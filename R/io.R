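#' Read a multi-channel volumetric stack from TIFF
#'
#' Reads a channel-major multi-page TIFF (all z-slices of channel 1, then all
#' of channel 2, ...) into a [voxel_grid()]. Channel identity is by the
#' supplied name-to-index map, never by heuristics.
#'
#' @param path TIFF file written by [write_stack()] or any uncompressed
#'   little-endian grayscale multipage TIFF.
#' @param channel_map named integer vector or list mapping channel name to
#'   1-based channel index, e.g. `c(spheroid = 1, tcell = 2, dead = 3)`.
#' @param voxel_size physical voxel size `c(dx, dy, dz)` in micrometres.
#' @param timepoint_h acquisition time (hours), stored on the grid.
#' @return a [voxel_grid()] with one named channel per `channel_map` entry.
#' @export
read_stack <- function(path, channel_map, voxel_size = c(3, 3, 3),
                       timepoint_h = NA_real_) {
  pages <- read_tiff_pages(path)
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("non-uniform page shape in ", path)
  idx <- unlist(channel_map)
  if (is.null(names(idx)) || any(!nzchar(names(idx))))
    stop("channel_map must be named")
  n_channels <- max(idx)
  if (length(pages) %% n_channels != 0L)
    stop(sprintf("page count %d is not divisible by channel count %d",
                 length(pages), n_channels))
  nz <- length(pages) %/% n_channels
  nx <- nrow(pages[[1]]); ny <- ncol(pages[[1]])
  channels <- lapply(idx, function(ci) {
    arr <- array(0, dim = c(nx, ny, nz))
    for (z in seq_len(nz)) arr[, , z] <- pages[[(ci - 1) * nz + z]]
    arr
  })
  names(channels) <- names(idx)
  voxel_grid(channels, voxel_size, timepoint_h)
}

#' Write a voxel grid to a channel-major multipage TIFF
#'
#' @param grid a [voxel_grid()].
#' @param path output path.
#' @param dtype `"uint16"` (default; values are rounded and must lie in
#'   `[0, 65535]`) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(grid, path, dtype = c("uint16", "float32")) {
  dtype <- match.arg(dtype)
  stopifnot(inherits(grid, "voxel_grid"))
  pages <- list()
  for (ch in grid$channels) {
    nz <- dim(ch)[3]
    for (z in seq_len(nz)) pages[[length(pages) + 1]] <- ch[, , z, drop = TRUE]
  }
  write_tiff_pages(pages, path, dtype = dtype)
}

#' Read / write delimited tables with a declared schema
#'
#' Thin CSV wrappers that enforce column presence and type. `write_table()`
#' followed by `read_table()` is lossless for numeric columns at full double
#' precision (17 significant digits round-trip exactly).
#'
#' @param path CSV path with a header row.
#' @param schema named character vector mapping required column names to one
#'   of `"numeric"`, `"integer"`, `"character"`, `"logical"`. Columns not in
#'   the schema are kept as read.
#' @return a `data.frame`.
#' @export
read_table <- function(path, schema = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    missing <- setdiff(names(schema), names(df))
    if (length(missing))
      stop("missing required column(s): ", paste(missing, collapse = ", "))
    for (col in names(schema)) {
      v <- df[[col]]
      df[[col]] <- switch(schema[[col]],
        numeric = {
          out <- suppressWarnings(as.numeric(v))
          if (any(is.na(out) & !is.na(v) & nzchar(trimws(as.character(v)))))
            stop("non-numeric cell in numeric column '", col, "'")
          out
        },
        integer = {
          out <- suppressWarnings(as.integer(v))
          if (any(is.na(out) & !is.na(v) & nzchar(trimws(as.character(v)))))
            stop("non-numeric cell in integer column '", col, "'")
          out
        },
        logical = as.logical(v),
        character = as.character(v),
        stop("unknown schema type: ", schema[[col]])
      )
    }
  }
  df
}

#' @rdname read_table
#' @param records a `data.frame` to serialize.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  num <- vapply(records, is.numeric, logical(1))
  out <- records
  for (col in names(records)[num]) {
    if (is.integer(records[[col]])) next
    out[[col]] <- formatC(records[[col]], digits = 17, format = "g")
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
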