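#' Steepest decline of a red-object area series
#'
#' Ordinary-least-squares slope over every contiguous window of
#' `window_points` samples; returns the most negative slope and its window.
#' This is the microscope cytotoxicity statistic: the linear gradient of the
#' red-object area at its steepest part, optionally restricted to the
#' interval between killing onset and monolayer eradication.
#'
#' @param times_h numeric vector of sample times, strictly increasing
#'   (default grid: 0.25 h spacing).
#' @param area_um2 red-object area per well at each time, `>= 0`.
#' @param window_points window length in samples (default 8 = 2 h at 15-min
#'   spacing); must be `>= 3` and `<=` the series length.
#' @param bounds_h optional `c(onset_h, eradication_h)`; only windows fully
#'   inside the interval are searched.
#' @return list with `slope` (um^2/h), `window` (`c(start_h, end_h)`) and
#'   `window_index` (`c(first, last)` sample index).
#' @export
steepest_slope <- function(times_h, area_um2, window_points = 8,
                           bounds_h = NULL) {
  stopifnot(length(times_h) == length(area_um2),
            all(diff(times_h) > 0), all(area_um2 >= 0),
            window_points >= 3)
  n <- length(times_h)
  if (n < window_points) stop("series shorter than window")
  starts <- seq_len(n - window_points + 1)
  if (!is.null(bounds_h)) {
    stopifnot(length(bounds_h) == 2)
    ends <- starts + window_points - 1
    ok <- times_h[starts] >= bounds_h[1] & times_h[ends] <= bounds_h[2]
    if (!any(ok)) stop("no window lies inside the supplied bounds")
    starts <- starts[ok]
  }
  slopes <- vapply(starts, function(s) {
    i <- s:(s + window_points - 1)
    ols_slope(times_h[i], area_um2[i])
  }, numeric(1))
  k <- which.min(slopes)
  s <- starts[k]
  list(slope = slopes[k],
       window = c(times_h[s], times_h[s + window_points - 1]),
       window_index = c(s, s + window_points - 1))
}

ols_slope <- function(x, y) {
  xm <- x - mean(x)
  sum(xm * y) / sum(xm^2)
}

#' Detect the killing onset / eradication interval of a target series
#'
#' Heuristic bounds for [steepest_slope()]: onset is the first time of a
#' sustained decline (`k` consecutive decreasing samples after the series
#' peak region), eradication the first time the area falls below
#' `floor_frac` of the series maximum. Off by default in [killing_rate()].
#'
#' @inheritParams steepest_slope
#' @param k consecutive decreasing samples that define a sustained decline.
#' @param floor_frac fraction of the peak area treated as eradicated.
#' @return `c(onset_h, eradication_h)`; falls back to the full support where
#'   a bound is not found.
#' @export
detect_kill_bounds <- function(times_h, area_um2, k = 3, floor_frac = 0.05) {
  n <- length(area_um2)
  dec <- diff(area_um2) < 0
  onset <- NA_real_
  run <- 0
  for (i in seq_along(dec)) {
    run <- if (dec[i]) run + 1 else 0
    if (run >= k) { onset <- times_h[i - k + 1]; break }
  }
  erad <- times_h[which(area_um2 < floor_frac * max(area_um2))[1]]
  c(if (is.na(onset)) times_h[1] else onset,
    if (is.na(erad)) times_h[n] else erad)
}

#' T-cell killing rate normalised to control growth
#'
#' The raw killing slope is the steepest OLS decline of the antigen-pulsed
#' target-well area; the control slope is the OLS slope of the unpulsed
#' control well over the same time window. The normalised rate is
#' `control_slope - raw_slope` by default (positive when killing outpaces
#' growth, zero when target matches control); a ratio convention
#' (`raw/control`) is available via `normalization`.
#'
#' @param target data.frame with columns `times_h`, `area_um2` for the
#'   antigen-pulsed well.
#' @param control same for the unpulsed control well; must share the target
#'   time grid.
#' @param window_points OLS window length in samples.
#' @param bounds_h optional killing-onset/eradication bounds (hours) passed
#'   to [steepest_slope()]; see [detect_kill_bounds()].
#' @param normalization `"difference"` (default) or `"ratio"`.
#' @return object of class `killing_rate`: list with `raw_slope`,
#'   `control_slope`, `normalized_rate` (all um^2/h) and `window`.
#' @export
killing_rate <- function(target, control, window_points = 8,
                         bounds_h = NULL,
                         normalization = c("difference", "ratio")) {
  normalization <- match.arg(normalization)
  stopifnot(is.data.frame(target), is.data.frame(control),
            all(c("times_h", "area_um2") %in% names(target)),
            all(c("times_h", "area_um2") %in% names(control)))
  if (length(target$times_h) != length(control$times_h) ||
      max(abs(target$times_h - control$times_h)) > 1e-9)
    stop("target and control series are on incompatible time grids")
  st <- steepest_slope(target$times_h, target$area_um2,
                       window_points = window_points, bounds_h = bounds_h)
  i <- st$window_index[1]:st$window_index[2]
  control_slope <- ols_slope(control$times_h[i], control$area_um2[i])
  rate <- switch(normalization,
                 difference = control_slope - st$slope,
                 ratio = st$slope / control_slope)
  structure(list(raw_slope = st$slope, control_slope = control_slope,
                 normalized_rate = rate, window = st$window,
                 normalization = normalization),
            class = "killing_rate")
}

#' @export
print.killing_rate <- function(x, ...) {
  cat(sprintf(
    "<killing_rate> raw %.3g, control %.3g, normalized %.3g um^2/h (%s) on [%.2f, %.2f] h\n",
    x$raw_slope, x$control_slope, x$normalized_rate, x$normalization,
    x$window[1], x$window[2]))
  invisible(x)
}
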