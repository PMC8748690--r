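# Shared fixtures. Expensive scenes are built once per test run and
# memoised; everything is generated in code with fixed seeds.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# noiseless single sphere, r in um
clean_sphere_scene <- function(r, seed = 1) {
  fixture(paste0("sphere_", r), function() {
    make_spheroid_scene(1, radius_um = r, tcell_density = 0, kill_rate = 0,
                        n_timepoints = 1, blur_sigma = 0, noise_sd = 0,
                        seed = seed)
  })
}

clean_pair_scene <- function() {
  fixture("pair", function() {
    make_spheroid_scene(2, radius_um = 60, touching = TRUE, tcell_density = 0,
                        kill_rate = 0, n_timepoints = 1, blur_sigma = 0,
                        noise_sd = 0, seed = 3)
  })
}

# brute-force OLS slope oracle via lm(), independent of ols_slope()
oracle_steepest <- function(times, areas, w) {
  n <- length(times)
  best <- Inf; win <- NULL
  for (s in 1:(n - w + 1)) {
    i <- s:(s + w - 1)
    sl <- unname(coef(lm(areas[i] ~ times[i]))[2])
    if (sl < best) { best <- sl; win <- c(times[s], times[s + w - 1]) }
  }
  list(slope = best, window = win)
}

# hypergeometric enumeration oracle for the two-sided Fisher p, written
# from the choose() definition (independent of dhyper)
oracle_fisher <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- cc + d; k <- a + cc; N <- m + n
  supp <- max(0, k - n):min(k, m)
  pr <- vapply(supp, function(x)
    choose(m, x) * choose(n, k - x) / choose(N, k), numeric(1))
  p_obs <- pr[supp == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# a simple constructed couple track: circles, explicit interface ramp
constructed_track <- function(n_frames = 40, contact_frame = 5,
                              iface_ramp = c(2, 4, 6), dia = 6,
                              displacement_um = 0, dt_s = 10) {
  circle <- function(ctr, r) {
    th <- seq(0, 2 * pi, length.out = 37)[-37]
    cbind(ctr[1] + r * cos(th), ctr[2] + r * sin(th))
  }
  tc <- vector("list", n_frames); tg <- vector("list", n_frames)
  contact <- rep(FALSE, n_frames)
  iface <- rep(NA_real_, n_frames)
  syn <- matrix(NA_real_, n_frames, 2)
  for (fr in 1:n_frames) {
    tg[[fr]] <- circle(c(0, 0), 8)
    if (fr < contact_frame) {
      tc[[fr]] <- circle(c(-20 + fr, 0), 5)
    } else {
      contact[fr] <- TRUE
      k <- fr - contact_frame + 1
      iface[fr] <- if (k <= length(iface_ramp)) iface_ramp[k] else max(iface_ramp)
      # synapse drifts linearly after coupling up to displacement_um
      frac <- max(0, min(1, (fr - contact_frame - 2) / 20))
      syn[fr, ] <- c(-8, 0) + c(0, displacement_um * frac)
      tc[[fr]] <- circle(c(-12.5, displacement_um * frac), 5)
    }
  }
  couple_track(tc, tg, contact, iface, syn, dt_s = dt_s,
               interface_diameter_um = dia)
}
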