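# Cell-couple morphodynamics. Tracks carry T-cell and target outlines as
# simple polygons (n x 2 matrices, um) sampled at a fixed frame interval.
# Outline analysis uses radial profiles about the cell centroid and is
# therefore exact for star-shaped outlines (which the synthetic generator
# produces); strongly folded shapes would be smoothed by the resampling.

#' Construct a cell-couple track
#'
#' @param tcell list of T-cell outline polygons (one n x 2 matrix per
#'   frame, um).
#' @param target list of target-cell outline polygons.
#' @param contact logical per frame: cells in contact.
#' @param interface_len_um per-frame immune-synapse interface length (`NA`
#'   before contact).
#' @param synapse_pos n x 2 matrix of synapse centre positions (`NA` rows
#'   before contact).
#' @param dt_s frame interval in seconds (default 10).
#' @param coupling_frame optional known coupling frame (else derive with
#'   [find_coupling_frame()]).
#' @param interface_diameter_um synapse diameter at coupling; default taken
#'   from `interface_len_um` at the coupling frame.
#' @return object of class `couple_track`.
#' @export
couple_track <- function(tcell, target, contact, interface_len_um,
                         synapse_pos, dt_s = 10, coupling_frame = NA_integer_,
                         interface_diameter_um = NA_real_) {
  n <- length(tcell)
  stopifnot(length(target) == n, length(contact) == n,
            length(interface_len_um) == n, nrow(synapse_pos) == n, dt_s > 0)
  contact_frame <- if (any(contact)) which(contact)[1] else NA_integer_
  structure(list(
    tcell = tcell, target = target, contact = contact,
    interface_len_um = interface_len_um, synapse_pos = synapse_pos,
    dt_s = dt_s, n_frames = n, contact_frame = contact_frame,
    coupling_frame = coupling_frame,
    interface_diameter_um = interface_diameter_um
  ), class = "couple_track")
}

#' @export
print.couple_track <- function(x, ...) {
  cat(sprintf("<couple_track> %d frames @ %g s, contact at %s, coupling at %s\n",
              x$n_frames, x$dt_s, format(x$contact_frame),
              format(x$coupling_frame)))
  invisible(x)
}

# ---- polygon helpers -------------------------------------------------------

poly_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

poly_centroid <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(p))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# radius of a star-shaped polygon about `center`, interpolated at `angles`
radial_profile <- function(p, center, angles) {
  dx <- p[, 1] - center[1]; dy <- p[, 2] - center[2]
  th <- atan2(dy, dx)
  r <- sqrt(dx^2 + dy^2)
  o <- order(th)
  th <- th[o]; r <- r[o]
  # wrap for periodic interpolation
  th2 <- c(th[length(th)] - 2 * pi, th, th[1] + 2 * pi)
  r2 <- c(r[length(r)], r, r[1])
  stats::approx(th2, r2, xout = angles, rule = 2)$y
}

# signed discrete curvature sign at each vertex (positive = locally convex
# for a counterclockwise outline)
vertex_turn <- function(p) {
  n <- nrow(p)
  prv <- p[c(n, 1:(n - 1)), , drop = FALSE]
  nxt <- p[c(2:n, 1), , drop = FALSE]
  e1 <- p - prv; e2 <- nxt - p
  e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
}

angle_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

# ---- classifiers -----------------------------------------------------------

#' Find the tight-coupling frame
#'
#' Tight cell-couple formation is the earlier of (a) the first frame at
#' which the immune synapse is maximally spread — operationalised as
#' interface length at least `spread_fraction` of the track maximum — and
#' (b) two frames after initial cell contact; clamped to the movie end.
#'
#' @param track a [couple_track()].
#' @param spread_fraction fraction of the maximum interface length that
#'   counts as maximally spread (default 0.95).
#' @return frame index (1-based).
#' @export
find_coupling_frame <- function(track, spread_fraction = 0.95) {
  stopifnot(inherits(track, "couple_track"))
  if (is.na(track$contact_frame)) stop("track has no cell contact")
  len <- track$interface_len_um
  mx <- max(len, na.rm = TRUE)
  a <- which(!is.na(len) & len >= spread_fraction * mx)[1]
  b <- track$contact_frame + 2L
  min(min(a, b, na.rm = TRUE), track$n_frames)
}

#' Detect uropods in the pre-coupling migration phase
#'
#' A uropod candidate in a frame is a boundary protrusion (contiguous run
#' of vertices whose centroid distance exceeds `prot_frac` above the median
#' radius) whose direction lies within 45 degrees of the anti-motion vector
#' and whose base shows inverse curvature relative to the whole cell.
#' Candidates sustained for at least `min_duration_s` are reported.
#'
#' @param track a [couple_track()] with a known or derivable coupling frame.
#' @param prot_frac radial excess defining a protrusion (default 0.2).
#' @param min_duration_s minimum duration (default 60 s = 1 min).
#' @return data.frame of intervals (`start_s`, `end_s`), possibly empty.
#' @export
detect_uropod <- function(track, prot_frac = 0.2, min_duration_s = 60) {
  stopifnot(inherits(track, "couple_track"))
  cf <- if (!is.na(track$coupling_frame)) track$coupling_frame
        else find_coupling_frame(track)
  min_frames <- ceiling(min_duration_s / track$dt_s)
  pre <- seq_len(max(cf - 1, 0))
  if (length(pre) < min_frames) {
    warning("fewer than ", min_frames, " pre-coupling frames")
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  cents <- t(vapply(track$tcell[pre], poly_centroid, numeric(2)))
  has_uropod <- logical(length(pre))
  for (i in seq_along(pre)) {
    mv <- if (i < length(pre)) cents[i + 1, ] - cents[i, ]
          else cents[i, ] - cents[i - 1, ]
    if (sqrt(sum(mv^2)) < 1e-9) next
    anti <- atan2(-mv[2], -mv[1])
    p <- track$tcell[[pre[i]]]
    ctr <- cents[i, ]
    dx <- p[, 1] - ctr[1]; dy <- p[, 2] - ctr[2]
    r <- sqrt(dx^2 + dy^2); th <- atan2(dy, dx)
    excess <- r > (1 + prot_frac) * median(r)
    if (!any(excess)) next
    turns <- vertex_turn(p)
    mean_sign <- sign(sum(turns))
    # contiguous runs over the closed boundary
    nv <- length(excess)
    runs <- rle(excess)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    segs <- which(runs$values)
    seg_list <- lapply(segs, function(k) starts[k]:ends[k])
    # merge wrap-around run
    if (length(seg_list) >= 2 && excess[1] && excess[nv]) {
      seg_list[[1]] <- c(seg_list[[length(seg_list)]], seg_list[[1]])
      seg_list[[length(seg_list)]] <- NULL
    }
    for (seg in seg_list) {
      dir_ang <- atan2(mean(sin(th[seg])), mean(cos(th[seg])))
      if (angle_diff(dir_ang, anti) > pi / 4) next
      base <- unique(c((min(seg) - 2):(min(seg)), (max(seg)):(max(seg) + 2)))
      base <- ((base - 1) %% nv) + 1
      if (any(sign(turns[base]) == -mean_sign)) {
        has_uropod[i] <- TRUE
        break
      }
    }
  }
  r <- rle(has_uropod)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths >= min_frames)
  data.frame(start_s = (starts[keep] - 1) * track$dt_s,
             end_s = (ends[keep] - 1) * track$dt_s)
}

#' Detect off-interface lamellae after coupling
#'
#' Per post-coupling frame, a protrusion is the newly added outline area
#' relative to the previous frame (radial difference about the cell
#' centroid). An off-interface lamella event requires the protrusion
#' direction to lie more than `sector_deg` away from the synapse direction,
#' the protrusion area to reach `area_frac` of the cell area, and a
#' subsequent net retraction of the protruded sector.
#'
#' @param track a [couple_track()].
#' @param sector_deg minimum angular separation from the synapse direction
#'   (default 90).
#' @param area_frac minimum protrusion area as a fraction of cell area
#'   (default 0.10).
#' @param n_angles radial resampling resolution.
#' @param retraction_frames frames after onset within which the protruded
#'   sector must retract (default 12 = 2 min; lamellae are transient).
#' @return numeric vector of event onset times in seconds since coupling.
#' @export
detect_lamellae <- function(track, sector_deg = 90, area_frac = 0.10,
                            n_angles = 180, retraction_frames = 12) {
  stopifnot(inherits(track, "couple_track"))
  cf <- if (!is.na(track$coupling_frame)) track$coupling_frame
        else find_coupling_frame(track)
  if (cf >= track$n_frames) return(numeric(0))
  angles <- seq(-pi, pi, length.out = n_angles + 1)[-1]
  dth <- 2 * pi / n_angles
  events <- numeric(0)
  i <- cf + 1
  while (i <= track$n_frames) {
    prev <- track$tcell[[i - 1]]; cur <- track$tcell[[i]]
    ctr <- poly_centroid(prev)
    r0 <- radial_profile(prev, ctr, angles)
    r1 <- radial_profile(cur, ctr, angles)
    add <- pmax(0, r1^2 - r0^2) / 2 * dth
    area_new <- sum(add)
    cell_area <- poly_area(prev)
    if (area_new >= area_frac * cell_area) {
      w <- add / area_new
      dir_ang <- atan2(sum(w * sin(angles)), sum(w * cos(angles)))
      syn <- track$synapse_pos[i, ]
      syn_ang <- atan2(syn[2] - ctr[2], syn[1] - ctr[1])
      if (angle_diff(dir_ang, syn_ang) > sector_deg / 180 * pi) {
        # retraction: the sector excess over the pre-onset outline (each
        # frame in its own centroid frame, so cell translation does not
        # masquerade as sustained protrusion) must decay below 25% of its
        # peak within the retraction window
        sector <- angle_diff(angles, dir_ang) <= pi / 4
        base_r <- r0[sector]
        excess <- function(j) {
          pj <- track$tcell[[j]]
          rj <- radial_profile(pj, poly_centroid(pj), angles)[sector]
          mean(pmax(0, rj - base_r))
        }
        later <- seq(i, min(track$n_frames, i + retraction_frames))
        exc <- vapply(later, excess, numeric(1))
        peak <- max(exc)
        after_peak <- exc[which.max(exc):length(exc)]
        retracted <- peak > 0 && any(after_peak <= 0.25 * peak)
        if (retracted) {
          events <- c(events, (i - cf) * track$dt_s)
          ret_at <- later[which(exc <= 0.25 * peak &
                                  seq_along(exc) >= which.max(exc))[1]]
          i <- max(i, ret_at)
        }
      }
    }
    i <- i + 1
  }
  events
}

#' Classify translocation of the T cell over the target surface
#'
#' TRUE iff the synapse position moves, at any post-coupling frame, strictly
#' more than one interface diameter (measured at coupling) away from its
#' position at coupling.
#'
#' @param track a [couple_track()].
#' @return logical.
#' @export
classify_translocation <- function(track) {
  stopifnot(inherits(track, "couple_track"))
  cf <- if (!is.na(track$coupling_frame)) track$coupling_frame
        else find_coupling_frame(track)
  dia <- track$interface_diameter_um
  if (is.na(dia)) dia <- track$interface_len_um[cf]
  stopifnot(is.finite(dia), dia > 0)
  p0 <- track$synapse_pos[cf, ]
  post <- seq(cf, track$n_frames)
  disp <- sqrt(rowSums(sweep(track$synapse_pos[post, , drop = FALSE], 2, p0)^2))
  max(disp, na.rm = TRUE) > dia
}

#' All morphodynamic events of one track
#'
#' @param track a [couple_track()].
#' @param spread_fraction,sector_deg,area_frac classifier thresholds.
#' @return list: `coupling_frame`, `uropod_intervals`, `lamella_times_s`
#'   (since coupling), `first_lamella_time_s`, `censored` (no lamella by
#'   movie end), `translocated`.
#' @export
morpho_events <- function(track, spread_fraction = 0.95, sector_deg = 90,
                          area_frac = 0.10) {
  cf <- find_coupling_frame(track, spread_fraction)
  track$coupling_frame <- cf
  lam <- detect_lamellae(track, sector_deg = sector_deg, area_frac = area_frac)
  list(
    coupling_frame = cf,
    uropod_intervals = suppressWarnings(detect_uropod(track)),
    lamella_times_s = lam,
    first_lamella_time_s = if (length(lam)) lam[1]
      else (track$n_frames - cf) * track$dt_s,
    censored = length(lam) == 0,
    translocated = classify_translocation(track)
  )
}

# ---- survival --------------------------------------------------------------

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit estimator per group and the standard (O - E)^2 / V
#' log-rank statistic with the discrete-time (tied events pooled per
#' distinct time) convention; p from chi-square with 1 df.
#'
#' @param times_a,times_b event or censoring times per group (`>= 0`).
#' @param censored_a,censored_b logical: TRUE = censored (no event by end
#'   of observation).
#' @return list with `km_a`, `km_b` (data.frames time / n_risk / n_event /
#'   surv), `chisq`, `p`, `observed`, `expected`.
#' @export
km_logrank <- function(times_a, censored_a, times_b, censored_b) {
  stopifnot(length(times_a) == length(censored_a),
            length(times_b) == length(censored_b),
            all(times_a >= 0), all(times_b >= 0))
  if (length(times_a) == 0 || length(times_b) == 0)
    stop("a group has zero observations")
  km_a <- km_curve(times_a, censored_a)
  km_b <- km_curve(times_b, censored_b)

  ev_times <- sort(unique(c(times_a[!censored_a], times_b[!censored_b])))
  O1 <- E1 <- V <- 0
  for (t in ev_times) {
    n1 <- sum(times_a >= t); n2 <- sum(times_b >= t)
    d1 <- sum(times_a == t & !censored_a)
    d2 <- sum(times_b == t & !censored_b)
    n <- n1 + n2; d <- d1 + d2
    if (n < 2 || d == 0) next
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chisq <- if (V > 0) (O1 - E1)^2 / V else 0
  list(km_a = km_a, km_b = km_b, chisq = chisq,
       p = pchisq(chisq, df = 1, lower.tail = FALSE),
       observed = O1, expected = E1)
}

#' @rdname km_logrank
#' @param times,censored one group's times and censoring flags.
#' @return `km_curve` returns the product-limit curve for one group.
#' @export
km_curve <- function(times, censored) {
  tt <- sort(unique(times[!censored]))
  s <- 1
  out <- data.frame(time = numeric(0), n_risk = integer(0),
                    n_event = integer(0), surv = numeric(0))
  for (t in tt) {
    n <- sum(times >= t)
    d <- sum(times == t & !censored)
    s <- s * (1 - d / n)
    out <- rbind(out, data.frame(time = t, n_risk = n, n_event = d, surv = s))
  }
  out
}

# ---- calcium ---------------------------------------------------------------

#' Fura-2 ratio series aligned to coupling
#'
#' Background-subtracted 340/380 nm excitation ratio,
#' `(F340 - bg340) / (F380 - bg380)`, with time re-zeroed at the tight
#' coupling frame. Frames with non-positive denominator are masked `NA`.
#'
#' @param trace list or data.frame with `f340`, `f380` vectors, scalar field
#'   backgrounds `bg340`, `bg380`, frame interval `dt_s` and
#'   `coupling_frame`.
#' @return data.frame with `time_s` (0 at coupling) and `ratio`.
#' @export
fura2_ratio <- function(trace) {
  stopifnot(all(c("f340", "f380", "bg340", "bg380", "dt_s",
                  "coupling_frame") %in% names(trace)))
  den <- trace$f380 - trace$bg380
  num <- trace$f340 - trace$bg340
  ratio <- ifelse(den > 0, num / den, NA_real_)
  n <- length(ratio)
  time_s <- (seq_len(n) - trace$coupling_frame) * trace$dt_s
  data.frame(time_s = time_s, ratio = ratio)
}
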