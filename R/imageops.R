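# Low-level 3D morphology on logical voxel arrays. Arrays are [x, y, z];
# physical scaling enters through voxel_size = c(dx, dy, dz) in um.

#' Otsu threshold of an intensity volume
#'
#' Classic between-class variance maximisation on a 256-bin histogram of the
#' intensity range. Returns the intensity cutoff; voxels strictly above it
#' are foreground.
#'
#' @param x numeric array or vector of intensities.
#' @param n_bins histogram resolution.
#' @return scalar threshold on the intensity scale of `x`.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.vector(x)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(n_bins, 1L + floor((v - rng[1]) / diff(rng) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  # cutoff at the upper edge of the argmax bin
  rng[1] + k / n_bins * diff(rng)
}

#' Connected-component labeling of a 3D mask
#'
#' @param mask logical 3D array.
#' @param connectivity 26 (default) or 6.
#' @return integer array of labels (0 = background) with attribute
#'   `n_labels`.
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  lab <- .cpp_label(as.logical(mask), dim(mask), as.integer(connectivity))
  n <- attr(lab, "n_labels")
  lab <- array(lab, dim = dim(mask))
  attr(lab, "n_labels") <- n
  lab
}

#' Anisotropy-aware Euclidean distance transform
#'
#' Distance in physical units (um) from each foreground voxel to the nearest
#' background voxel; exact squared-distance transform along each axis.
#'
#' @param mask logical 3D array.
#' @param voxel_size `c(dx, dy, dz)` in um.
#' @return numeric array of distances.
#' @export
distance_transform <- function(mask, voxel_size) {
  stopifnot(is.array(mask), length(dim(mask)) == 3, length(voxel_size) == 3)
  array(.cpp_edt(as.logical(mask), dim(mask), as.numeric(voxel_size)),
        dim = dim(mask))
}

# Ball dilation/erosion via the distance transform; radius in physical um.
dilate_ball <- function(mask, radius, voxel_size) {
  if (radius <= 0) return(mask)
  d_bg <- distance_transform(!mask, voxel_size) # distance from background to mask
  mask | (d_bg <= radius & d_bg > 0)
}

erode_ball <- function(mask, radius, voxel_size) {
  if (radius <= 0) return(mask)
  d_fg <- distance_transform(mask, voxel_size) # distance to nearest background
  mask & (d_fg > radius)
}

close_ball <- function(mask, radius, voxel_size) {
  erode_ball(dilate_ball(mask, radius, voxel_size), radius, voxel_size)
}

#' Fill internal cavities of a 3D mask
#'
#' Background voxels not 6-connected to the array border become foreground.
#'
#' @inheritParams label_components
#' @return logical array.
#' @export
fill_holes <- function(mask) {
  bg <- !mask
  lab <- label_components(bg, connectivity = 6L)
  d <- dim(mask)
  border <- unique(c(
    lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]
  ))
  border <- setdiff(border, 0L)
  mask | (bg & !(lab %in% border))
}

#' Alpha-hull gap filling of a voxel mask
#'
#' Fills labeling gaps and internal fragmentation using the union-of-balls
#' characterisation of the alpha hull on the voxel grid: morphological
#' closing with a Euclidean ball of radius `alpha` (computed with two
#' anisotropy-aware distance transforms) followed by internal-cavity
#' filling. The result always contains the input mask.
#'
#' With `alpha = "auto"` the critical radius is searched on a doubling grid
#' starting at the largest voxel dimension: the smallest alpha at which the
#' number of 26-connected foreground components stops decreasing.
#'
#' @param mask logical 3D array.
#' @param alpha ball radius in um, or `"auto"`.
#' @param voxel_size `c(dx, dy, dz)` in um.
#' @param max_alpha upper bound for the auto search.
#' @return logical array, a superset of `mask`.
#' @export
alpha_fill <- function(mask, alpha = "auto", voxel_size, max_alpha = 64) {
  if (!any(mask)) return(mask)
  if (identical(alpha, "auto")) {
    a <- max(voxel_size)
    prev_n <- attr(label_components(mask), "n_labels")
    repeat {
      filled <- fill_holes(close_ball(mask, a, voxel_size))
      n <- attr(label_components(filled), "n_labels")
      if (n >= prev_n || a >= max_alpha) break
      prev_n <- n
      a <- a * 2
    }
    return(fill_holes(close_ball(mask, a, voxel_size)))
  }
  fill_holes(close_ball(mask, alpha, voxel_size))
}

#' Local maxima of a 3D scalar field with minimum separation
#'
#' A voxel is a seed if it attains the maximum of its 26-neighbourhood;
#' seeds closer than `min_separation` (physical units) to a stronger seed
#' are suppressed.
#'
#' @param field numeric 3D array (e.g. a distance map).
#' @param mask logical array restricting candidate voxels.
#' @param min_separation minimum seed spacing in um.
#' @param voxel_size `c(dx, dy, dz)` in um.
#' @return integer matrix of seed voxel indices (one row per seed, columns
#'   x, y, z), ordered by decreasing field value.
#' @export
local_maxima <- function(field, mask, min_separation, voxel_size) {
  d <- dim(field)
  is_max <- mask & field > 0
  # compare against shifted copies over the 26 neighbourhood
  shift3 <- function(a, s, fill = -Inf) {
    out <- array(fill, dim = d)
    src <- lapply(1:3, function(i) {
      seq(max(1, 1 - s[i]), min(d[i], d[i] - s[i]))
    })
    dst <- lapply(1:3, function(i) src[[i]] + s[i])
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (!any(is_max)) break
    is_max <- is_max & field >= shift3(field, c(dx, dy, dz))
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(idx)
  ord <- order(field[idx], decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  pos <- sweep(idx - 1, 2, voxel_size, `*`)
  keep <- rep(TRUE, nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (!keep[i]) next
    if (i < nrow(idx)) {
      later <- (i + 1):nrow(idx)
      dd <- sqrt(rowSums(sweep(pos[later, , drop = FALSE], 2, pos[i, ])^2))
      keep[later][dd < min_separation] <- FALSE
    }
  }
  idx[keep, , drop = FALSE]
}

#' Marker-based watershed on a priority field
#'
#' Priority-flood growth from seed markers in order of decreasing priority
#' (use a distance map to split touching convex objects), restricted to
#' `mask`. Distinct markers never merge.
#'
#' @param priority numeric 3D array; flooding proceeds from high to low.
#' @param mask logical array of the region to partition.
#' @param seeds integer matrix of seed voxels (rows = seeds, columns x, y, z)
#'   or an integer marker array (0 = none).
#' @return integer label array; every `mask` voxel reachable from a seed is
#'   assigned.
#' @export
watershed_split <- function(priority, mask, seeds) {
  d <- dim(priority)
  if (is.matrix(seeds)) {
    markers <- array(0L, dim = d)
    for (i in seq_len(nrow(seeds)))
      markers[seeds[i, 1], seeds[i, 2], seeds[i, 3]] <- i
  } else {
    markers <- seeds
  }
  lab <- .cpp_watershed(as.numeric(priority), as.logical(mask),
                        as.integer(markers), d)
  array(lab, dim = d)
}

#' Separable Gaussian blur of a 3D volume
#'
#' @param vol numeric 3D array.
#' @param sigma standard deviation per axis in voxels (scalar or length 3).
#' @return numeric array.
#' @export
gaussian_blur3d <- function(vol, sigma) {
  if (length(sigma) == 1) sigma <- rep(sigma, 3)
  if (all(sigma <= 0)) return(vol)
  array(.cpp_gauss3d(as.numeric(vol), dim(vol), as.numeric(sigma)),
        dim = dim(vol))
}
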