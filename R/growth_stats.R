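#' Modified elliptical tumor volume
#'
#' Caliper volume `0.5 * length * width^2` (mm^3). Length is by convention
#' the larger caliper dimension; inputs are swapped if needed.
#'
#' @param length_mm,width_mm caliper dimensions in mm, `>= 0`.
#' @return volume in mm^3.
#' @export
elliptical_volume <- function(length_mm, width_mm) {
  stopifnot(all(length_mm >= 0), all(width_mm >= 0))
  l <- pmax(length_mm, width_mm)
  w <- pmin(length_mm, width_mm)
  0.5 * l * w^2
}

#' Tumor growth-rate R-value
#'
#' Per-time growth statistic over a fixed division period: with cell count
#' proportional to volume (`qg` cells per mm^3 of tumor), the cell-number
#' change rate per starting cell is
#' `R = (dc/dt) / c = (V_final - V_initial) / (V_initial * dt)`,
#' in units of 1/h. The cells-per-volume constant `qg` cancels
#' algebraically; it is retained as an argument for unit bookkeeping and the
#' explicit computation `dc / (c * dt)` is used verbatim so the cancellation
#' is an identity of the implementation, not an assumption.
#'
#' @param v_initial_mm3 starting volume (mm^3), `> 0`.
#' @param v_final_mm3 final volume (mm^3).
#' @param dt_h division period in hours (default 8, one division of a cell
#'   line dividing three times per 24 h).
#' @param qg cells per mm^3 of tumor (default 2.76e5).
#' @return R in 1/h.
#' @export
r_value <- function(v_initial_mm3, v_final_mm3, dt_h = 8, qg = 2.76e5) {
  stopifnot(all(v_initial_mm3 > 0), dt_h > 0, qg > 0)
  c_cells <- qg * v_initial_mm3
  dc <- qg * v_final_mm3 - qg * v_initial_mm3
  (dc / dt_h) / c_cells
}

#' Classify a tumor growth course
#'
#' Flags derived from a caliper course relative to the treatment-start
#' volume:
#' \itemize{
#'   \item responder: volume falls below the start volume on at least two
#'     consecutive measurements after treatment start;
#'   \item relapsed: a responder whose volume later reaches or exceeds the
#'     start volume;
#'   \item stable remission: both caliper dimensions stay below
#'     `remission_mm` over a span of at least `remission_days` days.
#' }
#'
#' @param course data.frame with columns `day`, `length_mm`, `width_mm`
#'   (days strictly increasing, at least 3 measurements).
#' @param start_day treatment start (default day 12); the start volume is
#'   the measurement at the first day `>= start_day`.
#' @param remission_mm caliper cutoff for remission (default 5 mm).
#' @param remission_days minimum remission span (default 8 days).
#' @param dt_h,qg passed to [r_value()].
#' @param r_window_days days defining the early growth window for the
#'   R-value (default `c(12, 16)`).
#' @return object of class `growth_stats`: list with `v_initial`, `v_final`,
#'   `ratio_final_initial`, `r_value`, `responder`, `relapsed`,
#'   `stable_remission`.
#' @export
classify_course <- function(course, start_day = 12, remission_mm = 5,
                            remission_days = 8, dt_h = 8, qg = 2.76e5,
                            r_window_days = c(12, 16)) {
  stopifnot(is.data.frame(course),
            all(c("day", "length_mm", "width_mm") %in% names(course)))
  if (nrow(course) < 3) stop("course needs at least 3 measurements")
  stopifnot(all(diff(course$day) > 0))
  vol <- elliptical_volume(course$length_mm, course$width_mm)
  i0 <- which(course$day >= start_day)[1]
  if (is.na(i0)) stop("no measurement at or after start_day")
  v0 <- vol[i0]
  if (i0 >= nrow(course)) stop("no measurements after start_day")
  after <- seq(i0 + 1, nrow(course))
  below <- vol[after] < v0
  responder <- length(below) >= 2 && any(below[-length(below)] & below[-1])
  relapsed <- FALSE
  if (responder) {
    first_below <- after[which(below[-length(below)] & below[-1])[1]]
    relapsed <- any(vol[seq(first_below, nrow(course))] >= v0)
  }
  # stable remission: longest consecutive-day span with both dims < cutoff
  small <- course$length_mm < remission_mm & course$width_mm < remission_mm
  stable <- FALSE
  run_start <- NA_integer_
  for (i in seq_len(nrow(course))) {
    if (small[i]) {
      if (is.na(run_start)) run_start <- i
      if (course$day[i] - course$day[run_start] >= remission_days) stable <- TRUE
    } else run_start <- NA_integer_
  }
  # R-value over the early growth window
  iw <- which(course$day >= r_window_days[1] & course$day <= r_window_days[2])
  rv <- if (length(iw) >= 2 && vol[iw[1]] > 0) {
    r_value(vol[iw[1]], vol[iw[length(iw)]], dt_h = dt_h, qg = qg)
  } else NA_real_
  structure(list(
    v_initial = v0, v_final = vol[nrow(course)],
    ratio_final_initial = vol[nrow(course)] / v0,
    r_value = rv,
    responder = responder, relapsed = relapsed, stable_remission = stable
  ), class = "growth_stats")
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact conditional test: with margins fixed, the two-sided p-value is the
#' sum of hypergeometric probabilities of all tables whose probability does
#' not exceed that of the observed table (within relative tolerance 1e-7).
#'
#' @param table 2x2 integer matrix `rbind(c(a, b), c(c, d))`, rows = groups,
#'   columns = event / no event.
#' @return two-sided p-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(table == round(table)))
  a <- table[1, 1]; b <- table[1, 2]; cc <- table[2, 1]; d <- table[2, 2]
  m <- a + b          # row 1 total
  n <- cc + d         # row 2 total
  k <- a + cc         # column 1 total
  if (m + n == 0) stop("empty table")
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# one-sided (greater: group 1 proportion larger) Fisher p, used as the
# Boschloo ordering statistic
fisher_one_sided <- function(a, m, n, k) {
  # P(X >= a) for X ~ Hypergeom(m, n, k)
  phyper(a - 1, m, n, k, lower.tail = FALSE)
}

#' Boschloo exact unconditional test for a 2x2 table
#'
#' Uses the one-sided Fisher p-value as ordering statistic and maximises,
#' over a grid of the common nuisance success probability, the probability
#' under independent binomials of observing a table at least as extreme. The
#' two-sided p-value is twice the one-sided maximum, capped at 1.
#'
#' @param table 2x2 matrix as in [fisher_exact()]; row totals are the two
#'   group sizes, column 1 the event counts.
#' @param grid_size number of nuisance-probability grid points (`>= 10`,
#'   default 200).
#' @param alternative `"two.sided"` (doubled one-sided, capped) or
#'   `"greater"`/`"less"` for group 1 proportion larger/smaller.
#' @return p-value.
#' @export
boschloo <- function(table, grid_size = 200,
                     alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(table == round(table)))
  if (grid_size < 10) stop("grid_size must be at least 10")
  n1 <- sum(table[1, ]); n2 <- sum(table[2, ])
  if (n1 == 0 || n2 == 0) stop("empty margin")
  x1 <- table[1, 1]; x2 <- table[2, 1]

  one_sided <- function(direction) {
    # ordering statistic for every possible (y1, y2)
    y1 <- 0:n1; y2 <- 0:n2
    stat <- outer(y1, y2, function(i, j) {
      if (direction == "greater") fisher_one_sided(i, n1, n2, i + j)
      else fisher_one_sided(j, n2, n1, i + j)
    })
    t_obs <- if (direction == "greater")
      fisher_one_sided(x1, n1, n2, x1 + x2)
    else fisher_one_sided(x2, n2, n1, x1 + x2)
    extreme <- stat <= t_obs * (1 + 1e-12)
    pis <- seq(1e-6, 1 - 1e-6, length.out = grid_size)
    max(vapply(pis, function(p) {
      sum(outer(dbinom(y1, n1, p), dbinom(y2, n2, p))[extreme])
    }, numeric(1)))
  }
  p <- switch(alternative,
              greater = one_sided("greater"),
              less = one_sided("less"),
              two.sided = {
                side <- if (x1 / n1 >= x2 / n2) "greater" else "less"
                min(1, 2 * one_sided(side))
              })
  p
}

#' Pooled two-proportion z-test
#'
#' @param x1,n1 events and size in group 1.
#' @param x2,n2 events and size in group 2.
#' @return list with `z` and two-sided `p`.
#' @export
prop_ztest <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Sample size from standardized difference
#'
#' Power-based group size `n = (2 / d^2) * cp_power`, rounded up, with a
#' floor of 1. The default constant 11.7 corresponds to p < 0.01 at 80%
#' power on Altman's nomogram.
#'
#' @param d standardized difference (measurable difference / SD), `> 0`.
#' @param cp_power nomogram constant (default 11.7).
#' @return integer sample size per group.
#' @export
sample_size <- function(d, cp_power = 11.7) {
  stopifnot(all(d > 0), cp_power > 0)
  pmax(1L, as.integer(ceiling(2 / d^2 * cp_power)))
}

#' Exclude fast-growing outlier courses
#'
#' Computes the R-value per course over the early growth window and drops
#' courses whose R exceeds `mean(R) + 1 SD(R)` (one-sided: only abnormally
#' fast growers are excluded). A cohort with zero R spread excludes nothing.
#'
#' @param courses list of course data.frames (see [classify_course()]).
#' @param ... passed to [classify_course()].
#' @return the filtered list, with attribute `excluded` holding the dropped
#'   indices.
#' @export
exclude_outliers <- function(courses, ...) {
  if (length(courses) == 0) return(courses)
  r <- vapply(courses, function(cs) classify_course(cs, ...)$r_value,
              numeric(1))
  if (all(is.na(r))) return(courses)
  cut <- mean(r, na.rm = TRUE) + sd(r, na.rm = TRUE)
  drop <- which(!is.na(r) & r > cut & sd(r, na.rm = TRUE) > 0)
  out <- if (length(drop)) courses[-drop] else courses
  attr(out, "excluded") <- drop
  out
}
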