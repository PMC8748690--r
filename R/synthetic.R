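# Synthetic-data generators. Every generator takes an explicit seed, leaves
# the caller's RNG state untouched, and returns a ground-truth object from
# which all downstream quantities are recoverable without re-simulation.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# ---- spheroid scenes -------------------------------------------------------

#' Generate a synthetic spheroid imaging scene with ground truth
#'
#' Renders spheres into the spheroid channel of a half-acquired z-stack
#' series (bottom slice to widest plane, the acquisition geometry of
#' confocal spheroid imaging), point-like T-cell blobs into the T-cell
#' channel, and a concentric dead core into the dead channel whose volume
#' fraction grows linearly with saturation, `f(t) = min(1, f0 + k t)`.
#' Optional Gaussian blur, Gaussian read noise and Poisson shot noise are
#' applied per timepoint. All spheroids share the widest (mirror) plane.
#'
#' T cells are placed strictly below the widest plane with a clearance
#' margin, so in the mirrored pseudo-complete spheroid each appears exactly
#' twice; the truth records both the physical and the expected mirrored
#' count, and `tcell_density` is interpreted on the mirrored volume.
#'
#' @param n_spheroids number of spheroids.
#' @param radius_um spheroid radius (um), recycled to `n_spheroids`; must be
#'   at least 5 voxels.
#' @param tcell_density target SIL density, cells per mm^3 of mirrored
#'   spheroid volume.
#' @param kill_rate dead-volume fraction increase per hour (`>= 0`).
#' @param dead_fraction0 dead fraction at t = 0.
#' @param n_timepoints number of timepoints (default 7: 0-12 h every 2 h).
#' @param imaging_interval_h spacing of timepoints (hours).
#' @param voxel_size `c(dx, dy, dz)` um; default 3 um isotropic with the
#'   3 um acquisition z-step.
#' @param touching if TRUE (requires `n_spheroids = 2`), centres are placed
#'   `touch_factor * (r1 + r2)` apart so the pair merges at threshold — the
#'   watershed test fixture.
#' @param touch_factor centre distance as a fraction of the radius sum.
#' @param intensities named vector: background, spheroid, tcell, dead
#'   channel levels.
#' @param blur_sigma Gaussian PSF sigma in voxels (0 = none).
#' @param noise_sd additive Gaussian read-noise SD (0 = none).
#' @param poisson_noise apply Poisson shot noise to the intensities.
#' @param tcell_blob_um T-cell blob radius (um); the 5 um default (10 um
#'   diameter blast) keeps voxelized blobs safely above the default 8 um
#'   minimum-detection volume.
#' @param fov_um optional fixed `c(x, y)` field of view; an error if the
#'   spheroids do not fit.
#' @param seed RNG seed.
#' @return list with `series` (list of half-stack [voxel_grid()]s) and
#'   `truth` (class `spheroid_scene_truth`): spheroid table (centres,
#'   radii, analytic and mirrored-voxel volumes), T-cell positions and
#'   counts, per-timepoint dead fractions and dead volumes (analytic and
#'   mirrored-voxel), and the generator parameters.
#' @export
make_spheroid_scene <- function(n_spheroids = 1, radius_um = 60,
                                tcell_density = 4000, kill_rate = 0.05,
                                dead_fraction0 = 0, n_timepoints = 7,
                                imaging_interval_h = 2,
                                voxel_size = c(3, 3, 3),
                                touching = FALSE, touch_factor = 0.9,
                                intensities = c(background = 10, spheroid = 100,
                                                tcell = 150, dead = 120),
                                blur_sigma = 0.5, noise_sd = 2,
                                poisson_noise = FALSE,
                                tcell_blob_um = 5, fov_um = NULL, seed = 1) {
  stopifnot(n_spheroids >= 1, n_timepoints >= 1, kill_rate >= 0,
            tcell_density >= 0, dead_fraction0 >= 0, dead_fraction0 <= 1)
  r <- rep(radius_um, length.out = n_spheroids)
  vs <- as.numeric(voxel_size)
  if (any(r < 5 * min(vs))) stop("radii must be at least 5 voxels")
  if (touching && n_spheroids != 2) stop("touching scenes need exactly 2 spheroids")

  margin <- 2 * max(vs) + 6
  cx <- numeric(n_spheroids)
  cx[1] <- margin + r[1]
  if (n_spheroids > 1) {
    for (i in 2:n_spheroids) {
      gap <- if (touching) (touch_factor - 1) * (r[i - 1] + r[i]) else 12
      cx[i] <- cx[i - 1] + r[i - 1] + r[i] + gap
    }
  }
  cy <- rep(margin + max(r), n_spheroids)
  dz <- vs[3]
  zc_idx <- ceiling(max(r) / dz) + 2          # widest-plane slice (1-based)
  cz <- (zc_idx - 1) * dz                      # shared physical centre z
  nz <- zc_idx
  extent_x <- cx[n_spheroids] + r[n_spheroids] + margin
  extent_y <- cy[1] + max(r) + margin
  if (!is.null(fov_um)) {
    if (fov_um[1] < extent_x || fov_um[2] < extent_y)
      stop("spheroids do not fit in the requested field of view")
    extent_x <- fov_um[1]; extent_y <- fov_um[2]
  }
  nx <- ceiling(extent_x / vs[1]); ny <- ceiling(extent_y / vs[2])
  xs <- (seq_len(nx) - 1) * vs[1]
  ys <- (seq_len(ny) - 1) * vs[2]
  zs <- (seq_len(nz) - 1) * vs[3]

  sphere_mask <- function(c3, rad) {
    d2 <- outer(outer((xs - c3[1])^2, (ys - c3[2])^2, `+`), (zs - c3[3])^2, `+`)
    d2 <= rad^2
  }
  # mirrored voxel count of a half-stack mask whose top slice is the plane
  mirrored_count <- function(m) 2 * sum(m) - sum(m[, , nz])

  sph_masks <- lapply(seq_len(n_spheroids),
                      function(i) sphere_mask(c(cx[i], cy[i], cz), r[i]))
  all_mask <- Reduce(`|`, sph_masks)
  vol_analytic <- 4 / 3 * pi * r^3
  vol_voxel <- vapply(sph_masks, function(m) mirrored_count(m) * prod(vs),
                      numeric(1))

  truth_tp_h <- (seq_len(n_timepoints) - 1) * imaging_interval_h
  dead_frac <- pmin(1, dead_fraction0 + kill_rate * truth_tp_h)

  res <- with_seed(seed, {
    # --- T cells: uniform in the lower half-balls, well separated ---
    total_v_mm3 <- sum(vol_analytic) * 1e-9
    n_cells <- round(tcell_density * total_v_mm3 / 2)
    pos <- matrix(numeric(0), ncol = 4)
    if (n_cells > 0) {
      min_sep <- 2 * tcell_blob_um + 2 * max(vs) + 2
      z_margin <- tcell_blob_um + max(2, dz)
      placed <- 0; tries <- 0
      while (placed < n_cells && tries < 20000) {
        tries <- tries + 1
        si <- sample.int(n_spheroids, 1, prob = vol_analytic)
        u <- runif(3, -1, 1)
        if (sum(u^2) > 1) next
        p <- c(cx[si], cy[si], cz) + u * (r[si] - tcell_blob_um - 2)
        if (p[3] > cz - z_margin || p[3] < tcell_blob_um) next
        if (placed > 0) {
          dd <- sqrt(rowSums(sweep(pos[, 1:3, drop = FALSE], 2, p)^2))
          if (any(dd < min_sep)) next
        }
        pos <- rbind(pos, c(p, si))
        placed <- placed + 1
      }
      if (placed < n_cells)
        warning("placed only ", placed, " of ", n_cells, " T cells")
    }
    tcell_mask <- array(FALSE, c(nx, ny, nz))
    if (nrow(pos) > 0)
      for (i in seq_len(nrow(pos)))
        tcell_mask <- tcell_mask | sphere_mask(pos[i, 1:3], tcell_blob_um)

    # --- per-timepoint stacks ---
    series <- vector("list", n_timepoints)
    dead_voxel <- numeric(n_timepoints)
    bg <- intensities[["background"]]
    for (k in seq_len(n_timepoints)) {
      rd <- r * dead_frac[k]^(1 / 3)
      dead_mask <- array(FALSE, c(nx, ny, nz))
      for (i in seq_len(n_spheroids))
        if (rd[i] >= min(vs))
          dead_mask <- dead_mask | sphere_mask(c(cx[i], cy[i], cz), rd[i])
      dead_voxel[k] <- mirrored_count(dead_mask) * prod(vs)

      mk_channel <- function(mask, level) {
        ch <- array(bg, c(nx, ny, nz))
        ch[mask] <- level
        if (blur_sigma > 0) ch <- gaussian_blur3d(ch, blur_sigma)
        if (poisson_noise) ch <- array(rpois(length(ch), pmax(ch, 0)), dim(ch))
        if (noise_sd > 0) ch <- ch + rnorm(length(ch), 0, noise_sd)
        pmax(ch, 0)
      }
      series[[k]] <- voxel_grid(
        list(spheroid = mk_channel(all_mask, intensities[["spheroid"]]),
             tcell = mk_channel(tcell_mask, intensities[["tcell"]]),
             dead = mk_channel(dead_mask, intensities[["dead"]])),
        voxel_size = vs, timepoint_h = truth_tp_h[k])
    }
    list(series = series, pos = pos, dead_voxel = dead_voxel)
  })

  n_phys <- nrow(res$pos)
  truth <- structure(list(
    spheroids = data.frame(
      id = seq_len(n_spheroids), cx_um = cx, cy_um = cy, cz_um = cz,
      radius_um = r, volume_analytic_um3 = vol_analytic,
      volume_voxel_um3 = vol_voxel),
    touching = touching,
    tcells = if (n_phys > 0)
      data.frame(x_um = res$pos[, 1], y_um = res$pos[, 2], z_um = res$pos[, 3],
                 spheroid = as.integer(res$pos[, 4]))
      else data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                      spheroid = integer(0)),
    n_tcells_physical = n_phys,
    n_tcells_mirrored = 2L * n_phys,
    sil_density_true = 2 * n_phys / (sum(vol_analytic) * 1e-9),
    timepoints_h = truth_tp_h,
    dead_fraction = dead_frac,
    dead_volume_analytic_um3 = outer(vol_analytic, dead_frac),
    dead_volume_total_analytic_um3 = as.numeric(sum(vol_analytic) * dead_frac),
    dead_volume_voxel_um3 = res$dead_voxel,
    widest_plane_index = zc_idx,
    params = list(voxel_size = vs, kill_rate = kill_rate,
                  dead_fraction0 = dead_fraction0, blur_sigma = blur_sigma,
                  noise_sd = noise_sd, seed = seed)
  ), class = "spheroid_scene_truth")
  list(series = res$series, truth = truth)
}

# ---- cytotoxicity curves ---------------------------------------------------

#' Generate control / target red-area curves with known killing kinetics
#'
#' Control wells grow exponentially, `A_c(t) = A0 * exp(g t)`. Target wells
#' hold at `A0` through a lag, then decline to a floor — logistically
#' (smooth, analytic steepest slope `-(A0 - floor) * s / 4`) or piecewise
#' linearly (constant decline slope). The truth records the analytic
#' steepest slope and, because a finite OLS window measures a window
#' average, also the exhaustive-window OLS slope of the noiseless series
#' together with the matching control slope and normalised rate.
#'
#' @param a0_um2 initial red-object area per well (um^2).
#' @param g_control control growth rate (1/h).
#' @param lag_h killing lag after plating (h).
#' @param kill_duration_h duration of the decline (h).
#' @param floor_frac residual area floor as a fraction of `a0_um2`.
#' @param shape `"logistic"` or `"linear"` decline profile.
#' @param duration_h,step_min series length and sampling interval (default
#'   14 h every 15 min).
#' @param noise_sd_frac Gaussian noise SD as a fraction of `a0_um2`.
#' @param window_points window used for the stored discrete truth.
#' @param seed RNG seed.
#' @return list with `target`, `control` (data.frames `times_h`,
#'   `area_um2`, `condition`, `well`) and `truth`.
#' @export
make_cytotox_curves <- function(a0_um2 = 1e5, g_control = 0.02, lag_h = 2,
                                kill_duration_h = 6, floor_frac = 0.05,
                                shape = c("logistic", "linear"),
                                duration_h = 14, step_min = 15,
                                noise_sd_frac = 0.01, window_points = 8,
                                seed = 1) {
  shape <- match.arg(shape)
  stopifnot(a0_um2 > 0, kill_duration_h > 0, duration_h > 0, step_min > 0,
            floor_frac >= 0, floor_frac < 1, noise_sd_frac >= 0)
  if (g_control < 0) stop("negative control growth rate")
  times <- seq(0, duration_h, by = step_min / 60)
  floor_a <- floor_frac * a0_um2
  tmid <- lag_h + kill_duration_h / 2
  target_clean <- if (shape == "logistic") {
    s <- 8 / kill_duration_h
    floor_a + (a0_um2 - floor_a) / (1 + exp(s * (times - tmid)))
  } else {
    slope <- (a0_um2 - floor_a) / kill_duration_h
    pmin(a0_um2, pmax(floor_a, a0_um2 - slope * (times - lag_h)))
  }
  control_clean <- a0_um2 * exp(g_control * times)
  steepest_analytic <- if (shape == "logistic")
    -(a0_um2 - floor_a) * (8 / kill_duration_h) / 4
  else -(a0_um2 - floor_a) / kill_duration_h

  # discrete truth by exhaustive enumeration on the noiseless series
  n <- length(times)
  starts <- seq_len(n - window_points + 1)
  sl <- vapply(starts, function(sx) {
    i <- sx:(sx + window_points - 1)
    ols_slope(times[i], target_clean[i])
  }, numeric(1))
  kbest <- which.min(sl)
  iwin <- starts[kbest]:(starts[kbest] + window_points - 1)
  ctrl_slope <- ols_slope(times[iwin], control_clean[iwin])

  out <- with_seed(seed, {
    noise <- function(x) pmax(0, x + rnorm(length(x), 0, noise_sd_frac * a0_um2))
    list(target = noise(target_clean), control = noise(control_clean))
  })
  truth <- list(
    shape = shape, steepest_slope_analytic = steepest_analytic,
    decline_window_h = c(lag_h, lag_h + kill_duration_h),
    steepest_slope_discrete = sl[kbest],
    control_slope_discrete = ctrl_slope,
    normalized_rate_discrete = ctrl_slope - sl[kbest],
    window_h = c(times[iwin[1]], times[iwin[window_points]]),
    g_control = g_control, a0_um2 = a0_um2, floor_um2 = floor_a)
  list(
    target = data.frame(times_h = times, area_um2 = out$target,
                        condition = "target", well = "T1"),
    control = data.frame(times_h = times, area_um2 = out$control,
                         condition = "control", well = "C1"),
    truth = truth)
}

# ---- couple tracks ---------------------------------------------------------

# star-shaped outline: circle of radius r0 with optional Gaussian radial
# bumps; bump = list(angle, height, width)
star_polygon <- function(center, r0, bumps = list(), n_vertices = 48,
                         jitter_um = 0) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  r <- rep(r0, n_vertices)
  for (b in bumps) {
    d <- (th - b$angle + pi) %% (2 * pi) - pi
    r <- r + b$height * exp(-(d / b$width)^2)
  }
  if (jitter_um > 0) r <- r + runif(n_vertices, -jitter_um, jitter_um)
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

#' Generate cell-couple tracks with injected morphodynamic events
#'
#' Parametric outlines at the cell-couple frame rate (10 s default): a T
#' cell migrates toward a static target, contacts it, forms a tight couple
#' two frames later, then optionally translocates over the target surface
#' and/or throws off-interface lamellae. Injected events exceed the
#' classifier thresholds by `margin` (default 1.5): translocation
#' displacement is `margin` interface diameters; lamella protrusion area is
#' `margin` times the area threshold; uropods last 8 frames with an
#' inverse-curvature base.
#'
#' @param n_tracks number of tracks.
#' @param translocation_frac fraction of tracks with injected translocation.
#' @param lamella_times onset times (seconds after coupling) of the injected
#'   first lamella, recycled over tracks; `NA` entries give censored tracks
#'   (no lamella in the movie). `NULL` = all censored.
#' @param uropod_frac fraction of tracks with an injected pre-coupling
#'   uropod (8 frames).
#' @param margin event margin over the classifier thresholds.
#' @param duration_s,dt_s movie length and frame interval (default 15 min at
#'   10 s).
#' @param area_frac lamella area threshold the injection is scaled against.
#' @param jitter_um uniform radial outline jitter (0 = exact geometry).
#' @param seed RNG seed.
#' @return list with `tracks` (list of [couple_track()]) and `truth`
#'   (data.frame: per-track injected labels, onset times, censor flags).
#' @export
make_couple_tracks <- function(n_tracks, translocation_frac = 0,
                               lamella_times = NULL, uropod_frac = 0,
                               margin = 1.5, duration_s = 900, dt_s = 10,
                               area_frac = 0.10, jitter_um = 0, seed = 1) {
  stopifnot(n_tracks >= 1, translocation_frac >= 0, translocation_frac <= 1,
            uropod_frac >= 0, uropod_frac <= 1, margin > 0)
  n_frames <- floor(duration_s / dt_s)
  r_t <- 5; r_tar <- 8              # cell radii, um
  contact_frame <- 13L
  coupling_frame <- contact_frame + 2L
  dia <- 6                          # interface diameter at coupling, um
  lam <- if (is.null(lamella_times)) rep(NA_real_, n_tracks)
         else rep(lamella_times, length.out = n_tracks)

  with_seed(seed, {
    transloc <- runif(n_tracks) < translocation_frac
    uropod <- runif(n_tracks) < uropod_frac

    tracks <- vector("list", n_tracks)
    for (tk in seq_len(n_tracks)) {
      tar_ctr <- c(0, 0)
      contact_pt <- c(-r_tar, 0)
      couple_ctr0 <- c(-(r_tar + r_t) + 0.5, 0)  # slight overlap when coupled
      speed <- 1.2
      start_x <- couple_ctr0[1] - speed * (contact_frame - 1)

      tcell <- vector("list", n_frames)
      target <- vector("list", n_frames)
      synapse <- matrix(NA_real_, n_frames, 2)
      iface <- rep(NA_real_, n_frames)
      contact <- rep(FALSE, n_frames)

      # translocation: orbit the target centre so the synapse chord
      # displacement reaches margin * dia between frames 20 and 70
      d_target <- margin * dia
      dth_total <- 2 * asin(min(1, d_target / (2 * r_tar))) * 1.02
      orbit_frames <- seq(20L, min(70L, n_frames))
      theta_of <- function(fr) {
        if (!transloc[tk] || fr < orbit_frames[1]) return(pi)
        prog <- min(1, (fr - orbit_frames[1]) /
                      (orbit_frames[length(orbit_frames)] - orbit_frames[1]))
        pi + dth_total * prog
      }

      lam_frame <- if (is.na(lam[tk])) NA_integer_
                   else coupling_frame + as.integer(round(lam[tk] / dt_s))

      for (fr in seq_len(n_frames)) {
        target[[fr]] <- star_polygon(tar_ctr, r_tar, jitter_um = jitter_um)
        if (fr < contact_frame) {
          ctr <- c(start_x + speed * (fr - 1), 0)
          bumps <- list()
          if (uropod[tk] && fr >= 3 && fr <= 10) {  # 8 frames = 80 s
            bumps <- list(list(angle = pi, height = 3.0, width = 0.35))
          }
          tcell[[fr]] <- star_polygon(ctr, r_t, bumps, jitter_um = jitter_um)
        } else {
          th <- theta_of(fr)
          ctr <- tar_ctr + (r_tar + r_t - 0.5) * c(cos(th), sin(th))
          syn <- tar_ctr + r_tar * c(cos(th), sin(th))
          contact[fr] <- TRUE
          ramp <- c(2, 4.5, 6)
          iface[fr] <- if (fr - contact_frame < length(ramp))
            ramp[fr - contact_frame + 1] else dia
          synapse[fr, ] <- syn
          bumps <- list()
          if (!is.na(lam_frame) && fr >= lam_frame && fr <= lam_frame + 1) {
            # appears at full size in one frame, held 2 frames, retracted;
            # height set so the added area = margin * area_frac * cell area
            w <- 0.5
            h <- margin * area_frac * pi * r_t^2 / (r_t * w * sqrt(pi))
            away <- atan2(ctr[2] - syn[2], ctr[1] - syn[1])
            bumps <- list(list(angle = away, height = h, width = w))
          }
          tcell[[fr]] <- star_polygon(ctr, r_t, bumps, jitter_um = jitter_um)
        }
      }
      tracks[[tk]] <- couple_track(
        tcell = tcell, target = target, contact = contact,
        interface_len_um = iface, synapse_pos = synapse, dt_s = dt_s,
        coupling_frame = coupling_frame, interface_diameter_um = dia)
    }
    truth <- data.frame(
      track = seq_len(n_tracks),
      translocated = transloc,
      has_uropod = uropod,
      first_lamella_s = vapply(seq_len(n_tracks), function(tk) {
        if (is.na(lam[tk])) (n_frames - coupling_frame) * dt_s
        else round(lam[tk] / dt_s) * dt_s
      }, numeric(1)),
      censored = is.na(lam),
      coupling_frame = coupling_frame)
    list(tracks = tracks, truth = truth)
  })
}

#' Generate a Fura-2 trace with a calcium step at coupling
#'
#' @param n_frames,dt_s trace length and frame interval.
#' @param coupling_frame frame of tight coupling.
#' @param base_ratio,peak_ratio true background-corrected 340/380 ratio
#'   before and from the coupling frame.
#' @param f380_level background-corrected 380 nm intensity.
#' @param bg340,bg380 field background levels.
#' @param noise_sd additive Gaussian noise on both raw channels.
#' @param seed RNG seed.
#' @return list with `trace` (input for [fura2_ratio()]) and `truth` (the
#'   noiseless ratio series).
#' @export
make_calcium_trace <- function(n_frames = 90, dt_s = 10, coupling_frame = 15,
                               base_ratio = 0.8, peak_ratio = 1.6,
                               f380_level = 150, bg340 = 50, bg380 = 50,
                               noise_sd = 0, seed = 1) {
  ratio_true <- ifelse(seq_len(n_frames) >= coupling_frame, peak_ratio,
                       base_ratio)
  f380 <- rep(bg380 + f380_level, n_frames)
  f340 <- bg340 + ratio_true * f380_level
  if (noise_sd > 0) {
    ns <- with_seed(seed, list(a = rnorm(n_frames, 0, noise_sd),
                               b = rnorm(n_frames, 0, noise_sd)))
    f340 <- f340 + ns$a
    f380 <- f380 + ns$b
  }
  list(trace = list(f340 = f340, f380 = f380, bg340 = bg340, bg380 = bg380,
                    dt_s = dt_s, coupling_frame = coupling_frame),
       truth = ratio_true)
}

# ---- tumor growth cohorts --------------------------------------------------

#' Generate a caliper tumor-growth cohort with known outcomes
#'
#' Emulates the triphasic growth of treated tumors: an initial growth phase
#' (6 days from treatment start at day 12), a response phase (8 days) in
#' which responders regress below the starting volume, and an open-ended
#' relapse phase in which a known fraction of responders regrow past the
#' starting volume; non-relapsing responders remain in stable remission
#' (both dimensions < 5 mm). Non-responders grow monotonically.
#'
#' @param n_mice_per_group mice per group, recycled over `groups`.
#' @param groups character vector of group names.
#' @param relapse_probs per-group probability that a responder relapses,
#'   recycled.
#' @param responder_prob probability a mouse responds to treatment.
#' @param days measurement days (alternate days from day 12).
#' @param start_volume_mm3 median treatment-start volume (5 x 5 mm caliper).
#' @param growth_rate_day exponential growth rate in the growth phase (1/d).
#' @param noise_sd lognormal measurement noise SD on caliper dimensions
#'   (0 = noise-free templates).
#' @param seed RNG seed.
#' @return list with `courses` (list of data.frames: mouse, group, day,
#'   length_mm, width_mm) and `truth` (data.frame of generating flags).
#' @export
make_growth_cohort <- function(n_mice_per_group = 12,
                               groups = c("ATT", "ATT_A2AR", "ATT_A2AR_TIM3"),
                               relapse_probs = c(8 / 17, 8 / 10, 3 / 12),
                               responder_prob = 0.85,
                               days = seq(12, 46, by = 2),
                               start_volume_mm3 = 62.5,
                               growth_rate_day = 0.33,
                               noise_sd = 0.04, seed = 1) {
  stopifnot(length(groups) >= 1, all(relapse_probs >= 0), all(relapse_probs <= 1),
            all(diff(days) > 0))
  n_per <- rep(n_mice_per_group, length.out = length(groups))
  relapse_probs <- rep(relapse_probs, length.out = length(groups))

  with_seed(seed, {
    courses <- list(); truth <- list(); mid <- 0
    for (gi in seq_along(groups)) {
      for (mi in seq_len(n_per[gi])) {
        mid <- mid + 1
        responder <- runif(1) < responder_prob
        relapse <- responder && runif(1) < relapse_probs[gi]
        v0 <- start_volume_mm3 * rlnorm(1, 0, 0.15)
        peak_day <- 18; response_end <- 26
        nadir_frac <- runif(1, 0.1, 0.25)
        g1 <- growth_rate_day * rlnorm(1, 0, 0.1)
        vol <- numeric(length(days))
        for (k in seq_along(days)) {
          d <- days[k]
          vol[k] <- if (d <= peak_day) {
            v0 * exp(g1 * (d - days[1]))
          } else if (!responder) {
            v0 * exp(g1 * (peak_day - days[1])) * exp(0.15 * (d - peak_day))
          } else if (d <= response_end) {
            v_peak <- v0 * exp(g1 * (peak_day - days[1]))
            v_nadir <- nadir_frac * v0
            exp(log(v_peak) + (log(v_nadir) - log(v_peak)) *
                  (d - peak_day) / (response_end - peak_day))
          } else if (relapse) {
            min(v0 * 40, nadir_frac * v0 * exp(0.35 * (d - response_end)))
          } else {
            nadir_frac * v0
          }
        }
        # caliper dimensions from volume, fixed aspect ratio W = 0.8 L
        l <- (vol / (0.5 * 0.8^2))^(1 / 3)
        w <- 0.8 * l
        if (noise_sd > 0) {
          l <- l * rlnorm(length(l), 0, noise_sd)
          w <- w * rlnorm(length(w), 0, noise_sd)
        }
        courses[[mid]] <- data.frame(
          mouse = sprintf("m%03d", mid), group = groups[gi], day = days,
          length_mm = pmax(l, w), width_mm = pmin(l, w))
        truth[[mid]] <- data.frame(
          mouse = sprintf("m%03d", mid), group = groups[gi],
          responder = responder, relapsed = relapse,
          v0_true = v0, nadir_frac = nadir_frac)
      }
    }
    list(courses = courses, truth = do.call(rbind, truth))
  })
}

# ---- marker matrices -------------------------------------------------------

#' Generate per-cell marker positivity matrices with a latent group effect
#'
#' Each mouse carries a latent suppression score; per-cell marker
#' positivity is Bernoulli with probability `plogis(qlogis(base) +
#' slope * score)`. The treated group's score distribution is shifted by
#' `effect_axis`, so with a positive effect the marker-combination PCA
#' separates the groups along PC1. Paired tumor volumes are log-normal and
#' negatively coupled to the score.
#'
#' @param n_mice_per_group mice per group (two groups: control, treated).
#' @param n_cells cells per mouse.
#' @param markers marker names; default the six functional inhibitory
#'   receptor / ectoenzyme markers profiled on CD8 TIL.
#' @param effect_axis latent score shift of the treated group (0 = groups
#'   identical in law).
#' @param base_probs per-marker baseline positivity, recycled.
#' @param slopes per-marker loading on the latent score, recycled.
#' @param seed RNG seed.
#' @return list with `samples` (named list of logical cell x marker
#'   matrices), `volumes_mm3`, `group` (factor), `truth` (latent scores and
#'   parameters).
#' @export
make_marker_cells <- function(n_mice_per_group = 6, n_cells = 5000,
                              markers = c("CD39", "CD73", "TIM3", "TIGIT",
                                          "LAG3", "PD1"),
                              effect_axis = 1.5,
                              base_probs = c(0.45, 0.4, 0.3, 0.35, 0.25, 0.5),
                              slopes = c(0.8, 0.6, 1.2, 0.9, 0.7, 1.0),
                              seed = 1) {
  stopifnot(n_mice_per_group >= 1, n_cells >= 1, length(markers) >= 2)
  base_probs <- rep(base_probs, length.out = length(markers))
  slopes <- rep(slopes, length.out = length(markers))
  with_seed(seed, {
    n <- 2 * n_mice_per_group
    group <- factor(rep(c("control", "treated"), each = n_mice_per_group),
                    levels = c("control", "treated"))
    score <- rnorm(n, mean = ifelse(group == "treated", effect_axis, 0), sd = 1)
    samples <- vector("list", n)
    names(samples) <- sprintf("mouse%02d", seq_len(n))
    for (i in seq_len(n)) {
      pr <- stats::plogis(stats::qlogis(base_probs) + slopes * score[i])
      m <- matrix(rbinom(n_cells * length(markers), 1,
                         rep(pr, each = n_cells)) == 1,
                  nrow = n_cells, ncol = length(markers),
                  dimnames = list(NULL, markers))
      samples[[i]] <- m
    }
    volumes <- rlnorm(n, meanlog = log(600) - 0.4 * (score - mean(score)),
                      sdlog = 0.2)
    list(samples = samples, volumes_mm3 = volumes, group = group,
         truth = list(score = score, effect_axis = effect_axis,
                      base_probs = base_probs, slopes = slopes))
  })
}
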