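test_that("generators are bit-identical under the same seed", {
  a <- make_spheroid_scene(1, radius_um = 36, n_timepoints = 2, seed = 7)
  b <- make_spheroid_scene(1, radius_um = 36, n_timepoints = 2, seed = 7)
  expect_identical(a, b)
  expect_identical(make_cytotox_curves(seed = 5), make_cytotox_curves(seed = 5))
  expect_identical(make_couple_tracks(3, seed = 5), make_couple_tracks(3, seed = 5))
  expect_identical(make_growth_cohort(4, seed = 5), make_growth_cohort(4, seed = 5))
  expect_identical(make_marker_cells(2, 100, seed = 5),
                   make_marker_cells(2, 100, seed = 5))
  # the caller's RNG stream is untouched
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(make_spheroid_scene(1, radius_um = 36,
                                              n_timepoints = 1, seed = 1))
  expect_identical(runif(1), x1)
})

test_that("spheroid scene renders the stated dead-core kinetics", {
  # kill_rate = 0: dead channel holds background only, at every timepoint
  sc0 <- make_spheroid_scene(1, radius_um = 45, tcell_density = 0,
                             kill_rate = 0, n_timepoints = 3, blur_sigma = 0,
                             noise_sd = 0, seed = 1)
  for (g in sc0$series)
    expect_true(all(g$channels$dead == g$channels$dead[1, 1, 1]))

  # f(t) = min(1, f0 + k t): analytic fraction vs voxel-counted core
  k <- 0.08; f0 <- 0.1
  sc <- make_spheroid_scene(1, radius_um = 54, tcell_density = 0,
                            kill_rate = k, dead_fraction0 = f0,
                            n_timepoints = 7, blur_sigma = 0, noise_sd = 0,
                            seed = 2)
  tt <- sc$truth$timepoints_h
  expect_equal(sc$truth$dead_fraction, pmin(1, f0 + k * tt))
  expect_true(all(diff(sc$truth$dead_fraction) >= 0))
  v_sph <- sc$truth$spheroids$volume_analytic_um3
  frac_voxel <- sc$truth$dead_volume_voxel_um3 / v_sph
  # voxelization error on the rendered core, looser at small core radii
  expect_true(all(abs(frac_voxel - sc$truth$dead_fraction) < 0.05))
})

test_that("touching pairs are marked and T cells stay in bounds", {
  pair <- clean_pair_scene()
  expect_true(pair$truth$touching)
  dist_centres <- abs(diff(pair$truth$spheroids$cx_um))
  expect_lt(dist_centres, sum(pair$truth$spheroids$radius_um))

  sc <- make_spheroid_scene(1, radius_um = 60, tcell_density = 15000,
                            kill_rate = 0, n_timepoints = 1, seed = 3)
  tc <- sc$truth$tcells
  s <- sc$truth$spheroids
  expect_gt(nrow(tc), 0)
  d <- sqrt((tc$x_um - s$cx_um)^2 + (tc$y_um - s$cy_um)^2 +
              (tc$z_um - s$cz_um)^2)
  expect_true(all(d <= s$radius_um))
  expect_true(all(tc$z_um < s$cz_um))    # strictly below the mirror plane
  expect_equal(sc$truth$n_tcells_mirrored, 2 * nrow(tc))
})

test_that("cytotox truth matches the stated analytic profiles", {
  # zero-noise linear decline: slope equals the analytic truth everywhere
  cc <- make_cytotox_curves(shape = "linear", noise_sd_frac = 0,
                            g_control = 0, seed = 1)
  expect_equal(cc$truth$steepest_slope_discrete,
               cc$truth$steepest_slope_analytic, tolerance = 1e-9)
  expect_true(all(cc$control$area_um2 == cc$control$area_um2[1]))  # g = 0

  # lag 2 h, decline 2-8 h: the steepest window lies inside the decline
  cc2 <- make_cytotox_curves(lag_h = 2, kill_duration_h = 6,
                             noise_sd_frac = 0, seed = 1)
  o <- oracle_steepest(cc2$target$times_h, cc2$target$area_um2, 8)
  expect_equal(cc2$truth$steepest_slope_discrete, o$slope, tolerance = 1e-9)
  expect_gte(o$window[1], 2)
  expect_lte(o$window[2], 8)
})

test_that("couple-track truth flags drive the injections", {
  g0 <- make_couple_tracks(6, translocation_frac = 0, seed = 1)
  expect_true(all(!g0$truth$translocated))
  expect_true(all(g0$truth$censored))

  g1 <- make_couple_tracks(4, lamella_times = c(100, NA), seed = 1)
  expect_equal(g1$truth$first_lamella_s[c(1, 3)], c(100, 100))
  expect_true(all(g1$truth$censored[c(2, 4)]))

  g2 <- make_couple_tracks(5, translocation_frac = 1, seed = 2)
  expect_true(all(g2$truth$translocated))
})

test_that("growth cohort honours relapse probabilities and templates", {
  # relapse_prob 0: no noiseless responder course re-crosses its start
  g0 <- make_growth_cohort(8, groups = "g", relapse_probs = 0,
                           noise_sd = 0, seed = 1)
  for (cs in g0$courses) {
    v <- elliptical_volume(cs$length_mm, cs$width_mm)
    resp <- g0$truth$responder[g0$truth$mouse == cs$mouse[1]]
    if (resp) {
      nadir <- which.min(v)
      expect_true(all(v[nadir:length(v)] < v[1]))
    }
  }
  # relapse_prob 1: every responder re-crosses
  g1 <- make_growth_cohort(8, groups = "g", relapse_probs = 1,
                           noise_sd = 0, seed = 2)
  for (cs in g1$courses) {
    tr <- g1$truth[g1$truth$mouse == cs$mouse[1], ]
    v <- elliptical_volume(cs$length_mm, cs$width_mm)
    if (tr$responder) expect_true(any(v[-1] >= v[1]))
  }
  # non-responder template is monotone non-decreasing
  g2 <- make_growth_cohort(10, groups = "g", relapse_probs = 0.5,
                           responder_prob = 0, noise_sd = 0, seed = 3)
  for (cs in g2$courses) {
    v <- elliptical_volume(cs$length_mm, cs$width_mm)
    expect_true(all(diff(v) >= -1e-9))
  }
})

test_that("marker generator reproduces stated probabilities", {
  # marker prob 1 gives 100% positivity everywhere
  mm <- make_marker_cells(2, 500, markers = c("A", "B"),
                          base_probs = c(1, 0.5), slopes = c(0, 0),
                          effect_axis = 0, seed = 1)
  for (s in mm$samples) expect_true(all(s[, "A"]))

  # two independent markers at 0.5: joint frequency ~ 0.25 within the
  # exact binomial CI at the generated cell count
  n_cells <- 10000
  mm2 <- make_marker_cells(1, n_cells, markers = c("A", "B"),
                           base_probs = c(0.5, 0.5), slopes = c(0, 0),
                           effect_axis = 0, seed = 2)
  joint <- vapply(mm2$samples, function(s) mean(s[, "A"] & s[, "B"]),
                  numeric(1))
  for (j in joint) {
    ci <- binom.test(round(j * n_cells), n_cells)$conf.int
    expect_true(ci[1] <= 0.25 && 0.25 <= ci[2])
  }

  # effect_axis = 0: the two groups share the same generating law
  mm3 <- make_marker_cells(40, 10, effect_axis = 0, seed = 3)
  sc <- mm3$truth$score
  expect_equal(mean(sc[mm3$group == "treated"]),
               mean(sc[mm3$group == "control"]),
               tolerance = 0.5)  # same N(0,1) law, finite-sample wobble
})
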