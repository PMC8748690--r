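#' Voxel grid container
#'
#' One timepoint of a multi-channel anisotropic z-stack. Channels are 3D
#' arrays indexed `[x, y, z]` with z index 1 = bottom slice; physical
#' position of a voxel centre is `(index - 1) * voxel_size` (voxel-centre
#' convention, 0-based physical origin).
#'
#' @param channels named list of 3D numeric arrays of identical dimension;
#'   canonical channel names are `"spheroid"`, `"tcell"` and `"dead"`.
#' @param voxel_size numeric `c(dx, dy, dz)` in micrometres.
#' @param timepoint_h acquisition time in hours (optional).
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(channels, voxel_size, timepoint_h = NA_real_) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), all(nzchar(names(channels))))
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("all channels must be 3D arrays")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("all channels must share the same dimensions")
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0))
  structure(list(channels = channels,
                 voxel_size = as.numeric(voxel_size),
                 timepoint_h = as.numeric(timepoint_h)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, %d channel(s): %s\n",
              d[1], d[2], d[3], length(x$channels),
              paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  voxel size %s um, t = %s h\n",
              paste(format(x$voxel_size), collapse = " x "),
              format(x$timepoint_h)))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$channels[[1]])

grid_voxel_volume <- function(grid) prod(grid$voxel_size)
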