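test_that("mirror concatenation reflects about the widest plane", {
  g1 <- voxel_grid(list(spheroid = array(1:16, c(4, 4, 1))), c(3, 3, 3))
  expect_equal(dim(mirror_concatenate(g1))[3], 1)  # Z = 1 maps to itself

  nz <- 40
  g <- voxel_grid(list(spheroid = array(rnorm(5 * 5 * nz), c(5, 5, nz))),
                  c(3, 3, 3))
  m <- mirror_concatenate(g)
  expect_equal(dim(m)[3], 2 * nz - 1)
  for (k in c(1, 10, 39))  # slice k and slice 2Z - k are voxel-identical
    expect_identical(m$channels$spheroid[, , k],
                     m$channels$spheroid[, , 2 * nz - k])
  expect_identical(m$channels$spheroid[, , nz], g$channels$spheroid[, , nz])
})

test_that("mirrored half-sphere volume matches the voxel-count oracle", {
  sc <- clean_sphere_scene(45)
  half <- sc$series[[1]]
  half_mask <- half$channels$spheroid > 50
  m <- mirror_concatenate(half)
  full_mask <- m$channels$spheroid > 50
  nz <- dim(half)[3]
  # 2 x half-volume minus the widest plane counted once
  expect_equal(sum(full_mask),
               2 * sum(half_mask) - sum(half_mask[, , nz]))
})

test_that("segmentation recovers spheres and splits touching pairs", {
  for (r in c(30, 60)) {
    sc <- clean_sphere_scene(r)
    seg <- segment_spheroids(mirror_concatenate(sc$series[[1]]))
    expect_equal(nrow(seg$records), 1)
    va <- 4 / 3 * pi * r^3
    expect_lt(abs(seg$records$volume_um3 - va) / va, 0.05)
    # centroid at the rendered centre
    tr <- sc$truth$spheroids
    expect_lt(abs(seg$records$centroid_x_um - tr$cx_um), 3)
    expect_lt(abs(seg$records$centroid_y_um - tr$cy_um), 3)
  }
  pair <- clean_pair_scene()
  seg <- segment_spheroids(mirror_concatenate(pair$series[[1]]))
  expect_equal(nrow(seg$records), 2)
  va <- 4 / 3 * pi * 60^3
  expect_true(all(abs(seg$records$volume_um3 - va) / va < 0.05))
})

test_that("empty spheroid channel yields an empty record set with warning", {
  g <- voxel_grid(list(spheroid = array(10, c(10, 10, 5)),
                       tcell = array(10, c(10, 10, 5)),
                       dead = array(10, c(10, 10, 5))), c(3, 3, 3), 0)
  expect_warning(seg <- segment_spheroids(mirror_concatenate(g)),
                 "no spheroid foreground")
  expect_equal(nrow(seg$records), 0)
})

test_that("labels partition the filled foreground; alpha fill is monotone", {
  pair <- clean_pair_scene()
  m <- mirror_concatenate(pair$series[[1]])
  ch <- m$channels$spheroid
  mask <- ch > otsu_threshold(ch)
  filled <- alpha_fill(mask, "auto", m$voxel_size)
  expect_true(all(filled[mask]))                      # extensive
  seg <- segment_spheroids(m)
  expect_equal(sum(seg$labels > 0), sum(filled))      # partition
  counts <- tabulate(seg$labels[seg$labels > 0])
  expect_equal(sum(counts), sum(filled))
})

test_that("T-cell counting, assignment and densities follow the rules", {
  sc <- fixture("tcell_scene", function()
    make_spheroid_scene(1, radius_um = 60, tcell_density = 14000,
                        kill_rate = 0, n_timepoints = 1, seed = 4))
  m <- mirror_concatenate(sc$series[[1]])
  seg <- segment_spheroids(m)
  cells <- segment_cells(m, seg$labels, seg$records)
  expect_equal(cells$scene_count, sc$truth$n_tcells_mirrored)
  expect_equal(cells$records$tcell_count, sc$truth$n_tcells_mirrored)
  # density identity: count / volume in mm^3
  expect_equal(cells$records$sil_density,
               cells$records$tcell_count / (cells$records$volume_um3 * 1e-9))

  # zero T cells
  sc0 <- clean_sphere_scene(30)
  m0 <- mirror_concatenate(sc0$series[[1]])
  seg0 <- segment_spheroids(m0)
  cells0 <- segment_cells(m0, seg0$labels, seg0$records)
  expect_equal(cells0$scene_count, 0)
  expect_equal(cells0$records$tcell_count, 0L)
  expect_equal(cells0$records$sil_density, 0)
})

test_that("density is invariant under uniform intensity rescaling", {
  sc <- fixture("tcell_scene", function()
    make_spheroid_scene(1, radius_um = 60, tcell_density = 14000,
                        kill_rate = 0, n_timepoints = 1, seed = 4))
  g <- sc$series[[1]]
  g2 <- voxel_grid(lapply(g$channels, function(ch) ch * 3.7),
                   g$voxel_size, g$timepoint_h)
  run <- function(gr) {
    m <- mirror_concatenate(gr)
    seg <- segment_spheroids(m)
    segment_cells(m, seg$labels, seg$records)$scene_density
  }
  expect_equal(run(g), run(g2), tolerance = 1e-6)
})

test_that("dead volume uses the intersection rule", {
  sc <- fixture("dead_scene", function()
    make_spheroid_scene(1, radius_um = 60, tcell_density = 0,
                        kill_rate = 0, dead_fraction0 = 0.3,
                        n_timepoints = 1, seed = 5))
  m <- mirror_concatenate(sc$series[[1]])
  seg <- segment_spheroids(m)
  rec <- segment_dead(m, seg$labels, seg$records)
  want <- 0.3 * 4 / 3 * pi * 60^3
  expect_lt(abs(rec$dead_volume_um3 - want) / want, 0.10)

  # dead signal rendered entirely outside any spheroid counts zero
  d <- dim(m)
  fake <- m
  fake$channels$dead <- array(10, d)
  fake$channels$dead[1:4, 1:4, 1:4] <- 150   # far corner, outside labels
  expect_true(all(seg$labels[1:4, 1:4, 1:4] == 0))
  rec2 <- segment_dead(fake, seg$labels, seg$records)
  expect_equal(rec2$dead_volume_um3, 0)

  # empty dead channel
  sc0 <- clean_sphere_scene(30)
  m0 <- mirror_concatenate(sc0$series[[1]])
  seg0 <- segment_spheroids(m0)
  expect_equal(segment_dead(m0, seg0$labels, seg0$records)$dead_volume_um3, 0)
})

test_that("pipeline death metric behaves over a timepoint series", {
  sc <- fixture("kill_scene", function()
    make_spheroid_scene(1, radius_um = 48, tcell_density = 8000,
                        kill_rate = 0.06, n_timepoints = 5, seed = 6))
  res <- run_spheroid_pipeline(sc$series)
  expect_equal(res$summary$death_metric_um3[1], 0)   # defined against t0
  expect_true(all(diff(res$summary$death_metric_um3) >= -1e-9))
  expect_equal(nrow(res$summary), 5)

  # single timepoint: metric 0 by definition
  res1 <- run_spheroid_pipeline(sc$series[1])
  expect_equal(res1$summary$death_metric_um3, 0)
})
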