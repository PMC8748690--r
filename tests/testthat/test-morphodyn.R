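test_that("coupling frame takes the earlier of spread and contact+2", {
  # interface maximal already at contact + 1: rule (a) fires first
  tr_a <- constructed_track(iface_ramp = c(2, 6, 6))
  expect_equal(find_coupling_frame(tr_a), tr_a$contact_frame + 1)
  # interface grows slowly: rule (b) caps at contact + 2
  tr_b <- constructed_track(iface_ramp = c(1, 1.5, 2, 2.5, 3, 4, 5, 6))
  expect_equal(find_coupling_frame(tr_b), tr_b$contact_frame + 2)
  # contact at the last frame: clamped to the movie end
  tr_c <- constructed_track(n_frames = 10, contact_frame = 10,
                            iface_ramp = c(2))
  expect_equal(find_coupling_frame(tr_c), 10)
  # no contact is an error
  tr_d <- constructed_track()
  tr_d$contact_frame <- NA_integer_
  expect_error(find_coupling_frame(tr_d), "no cell contact")
})

test_that("uropod detection needs direction, inverse base curvature, 1 min", {
  # circular migrating cell: no protrusion, no uropod
  tr <- make_couple_tracks(1, uropod_frac = 0, seed = 1)$tracks[[1]]
  expect_equal(nrow(detect_uropod(tr)), 0)
  # injected 8-frame uropod: one interval of at least 6 frames
  tr8 <- make_couple_tracks(1, uropod_frac = 1, seed = 1)$tracks[[1]]
  iv <- detect_uropod(tr8)
  expect_equal(nrow(iv), 1)
  expect_gte(iv$end_s - iv$start_s, 50)  # >= 6 frames at 10 s
  # too few pre-coupling frames warns and returns nothing
  short <- constructed_track(n_frames = 12, contact_frame = 3)
  expect_warning(iv2 <- detect_uropod(short), "pre-coupling frames")
  expect_equal(nrow(iv2), 0)
})

test_that("a 4-frame uropod is below the 1-minute rule", {
  # rebuild the standard track but shorten the injected uropod to 4 frames
  base <- make_couple_tracks(1, uropod_frac = 1, seed = 1)$tracks[[1]]
  donor <- make_couple_tracks(1, uropod_frac = 0, seed = 1)$tracks[[1]]
  short <- base
  # frames 3..10 carry the bump in the generator; revert frames 7..10
  for (fr in 7:10) short$tcell[[fr]] <- donor$tcell[[fr]]
  expect_equal(nrow(detect_uropod(short)), 0)
})

test_that("lamella detection needs off-synapse direction and retraction", {
  # static post-coupling cell: no events
  tr <- make_couple_tracks(1, seed = 1)$tracks[[1]]
  expect_length(detect_lamellae(tr), 0)
  # injected event at 100 s opposite the synapse
  tr1 <- make_couple_tracks(1, lamella_times = 100, seed = 1)$tracks[[1]]
  ev <- detect_lamellae(tr1)
  expect_length(ev, 1)
  expect_equal(ev[1], 100)
  # the same protrusion pointed toward the synapse is not an event:
  # rebuild the bump frames with the bump aimed at the synapse (angle 0
  # from the cell centre at (-12.5, 0) toward the synapse at (-8, 0))
  tr2 <- tr1
  cf <- tr1$coupling_frame
  lam_fr <- cf + 10
  h <- 1.5 * 0.10 * pi * 5^2 / (5 * 0.5 * sqrt(pi))
  for (fr in lam_fr:(lam_fr + 1)) {
    tr2$tcell[[fr]] <- spherotil:::star_polygon(
      c(-12.5, 0), 5, bumps = list(list(angle = 0, height = h, width = 0.5)))
  }
  expect_length(detect_lamellae(tr2), 0)
})

test_that("translocation is strict and monotone in displacement", {
  dia <- 6
  mk <- function(d) constructed_track(displacement_um = d, dia = dia)
  expect_false(classify_translocation(mk(0)))
  expect_false(classify_translocation(mk(dia)))        # tie: strict inequality
  expect_true(classify_translocation(mk(1.5 * dia)))
  # monotone: once over threshold, larger displacements stay TRUE
  res <- vapply(c(0.5, 0.9, 1, 1.1, 1.5, 2) * dia,
                function(d) classify_translocation(mk(d)), logical(1))
  expect_equal(res, c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
})

test_that("classifiers are invariant under rigid scene motion", {
  g <- make_couple_tracks(2, translocation_frac = 1, lamella_times = 150,
                          uropod_frac = 1, seed = 8)
  tr <- g$tracks[[1]]
  rot <- pi / 5; R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
  shift <- c(37, -12)
  tr2 <- tr
  tr2$tcell <- lapply(tr$tcell, function(p) sweep(p %*% t(R), 2, -shift))
  tr2$target <- lapply(tr$target, function(p) sweep(p %*% t(R), 2, -shift))
  tr2$synapse_pos <- sweep(tr$synapse_pos %*% t(R), 2, -shift)
  expect_equal(classify_translocation(tr2), classify_translocation(tr))
  expect_equal(detect_lamellae(tr2), detect_lamellae(tr))
  expect_equal(nrow(detect_uropod(tr2)), nrow(detect_uropod(tr)))
})

test_that("Kaplan-Meier equals empirical survival without censoring", {
  tt <- c(10, 20, 20, 30, 50)
  km <- km_curve(tt, rep(FALSE, 5))
  emp <- vapply(sort(unique(tt)), function(u) mean(tt > u), numeric(1))
  expect_equal(km$surv, emp)
})

test_that("log-rank: identical groups give p ~ 1, matches survdiff", {
  skip_if_not_installed("survival")
  tt <- c(30, 60, 90, 120, 200, 340)
  r <- km_logrank(tt, rep(FALSE, 6), tt, rep(FALSE, 6))
  expect_lt(r$chisq, 1e-9)
  expect_equal(r$p, 1)

  set.seed(10)
  ta <- round(rexp(25, 1 / 200)); ca <- ta > 700; ta[ca] <- 700
  tb <- round(rexp(25, 1 / 350)); cb <- tb > 700; tb[cb] <- 700
  mine <- km_logrank(ta, ca, tb, cb)
  sd <- survival::survdiff(
    survival::Surv(c(ta, tb), c(!ca, !cb)) ~ rep(1:2, each = 25))
  expect_equal(mine$chisq, unname(sd$chisq), tolerance = 1e-9)
  expect_error(km_logrank(numeric(0), logical(0), tt, rep(FALSE, 6)),
               "zero observations")
})

test_that("log-rank p matches its permutation distribution", {
  set.seed(11)
  n <- 30
  ta <- round(rexp(n, 1 / 220)); tb <- round(rexp(n, 1 / 330))
  ca <- ta > 900; ta[ca] <- 900; cb <- tb > 900; tb[cb] <- 900
  obs <- km_logrank(ta, ca, tb, cb)
  times <- c(ta, tb); cens <- c(ca, cb)
  B <- 2000
  stat <- numeric(B)
  for (b in 1:B) {
    idx <- sample(2 * n, n)
    stat[b] <- km_logrank(times[idx], cens[idx],
                          times[-idx], cens[-idx])$chisq
  }
  p_perm <- mean(stat >= obs$chisq - 1e-12)
  mc_err <- 3 * sqrt(p_perm * (1 - p_perm) / B)
  expect_lt(abs(obs$p - p_perm), mc_err + 0.03)  # chi-square approximation slack
})

test_that("Fura-2 ratio arithmetic, masking and alignment", {
  tr <- list(f340 = rep(200, 5), f380 = rep(150, 5), bg340 = 50, bg380 = 50,
             dt_s = 10, coupling_frame = 3)
  out <- fura2_ratio(tr)
  expect_equal(out$ratio, rep(1.5, 5))
  expect_equal(out$time_s, c(-20, -10, 0, 10, 20))

  tr$f380[4] <- 40  # denominator <= 0 is masked
  expect_true(is.na(fura2_ratio(tr)$ratio[4]))

  eq <- list(f340 = c(120, 130), f380 = c(120, 130), bg340 = 20, bg380 = 20,
             dt_s = 10, coupling_frame = 1)
  expect_equal(fura2_ratio(eq)$ratio, c(1, 1))

  gen <- make_calcium_trace(n_frames = 40, coupling_frame = 12,
                            base_ratio = 0.8, peak_ratio = 1.6)
  out2 <- fura2_ratio(gen$trace)
  expect_equal(out2$ratio, gen$truth)
  expect_equal(out2$time_s[12], 0)            # aligned step at t = 0
  expect_equal(out2$ratio[out2$time_s < 0], rep(0.8, 11))
  expect_equal(out2$ratio[out2$time_s >= 0], rep(1.6, 29))
})
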