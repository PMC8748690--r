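test_that("modified elliptical volume", {
  expect_equal(elliptical_volume(10, 8), 320)
  expect_equal(elliptical_volume(5, 5), 62.5)
  expect_equal(elliptical_volume(7, 0), 0)
  # larger dimension is treated as length regardless of argument order
  expect_equal(elliptical_volume(8, 10), elliptical_volume(10, 8))
})

test_that("R-value and the qg cancellation identity", {
  expect_equal(r_value(100, 500, dt_h = 8), 0.5)
  expect_equal(r_value(250, 250), 0)
  expect_error(r_value(0, 100))
  set.seed(6)
  vi <- runif(50, 10, 800); vf <- runif(50, 10, 3000)
  # explicit dc / (c * dt) with qg equals the cancelled form exactly
  expect_equal(r_value(vi, vf, 8, qg = 2.76e5), (vf - vi) / (vi * 8),
               tolerance = 1e-15)
  expect_equal(r_value(vi, vf, 8, qg = 1), r_value(vi, vf, 8, qg = 2.76e5))
})

test_that("course classification flags follow the stated rules", {
  grow <- data.frame(day = seq(12, 30, 2),
                     length_mm = seq(5, 14, 1), width_mm = seq(4, 13, 1))
  g <- classify_course(grow)
  expect_false(g$responder); expect_false(g$relapsed)

  # dips below start on 2+ consecutive days then re-crosses: relapse
  l <- c(5, 6, 4, 3.5, 3.5, 4, 6, 7, 8, 9)
  relapse <- data.frame(day = seq(12, 30, 2), length_mm = l, width_mm = 0.9 * l)
  g2 <- classify_course(relapse)
  expect_true(g2$responder); expect_true(g2$relapsed)

  # deep regression that never re-crosses: stable remission
  l3 <- c(5, 6, 3, 2.5, 2, 2, 2, 2, 2, 2)
  stable <- data.frame(day = seq(12, 30, 2), length_mm = l3, width_mm = 0.9 * l3)
  g3 <- classify_course(stable)
  expect_true(g3$responder); expect_false(g3$relapsed)
  expect_true(g3$stable_remission)

  expect_error(classify_course(grow[1:2, ]), "at least 3")

  # flags invariant under uniform volume rescaling (dimension scaling)
  s <- 1.31
  g4 <- classify_course(within(relapse, {
    length_mm <- length_mm * s; width_mm <- width_mm * s
  }), remission_mm = 5 * s)
  expect_equal(g4$responder, g2$responder)
  expect_equal(g4$relapsed, g2$relapsed)
})

test_that("classification recovers generator truth on a cohort", {
  gc <- make_growth_cohort(12, groups = c("a", "b"),
                           relapse_probs = c(0.3, 0.8), seed = 9)
  flags <- t(vapply(gc$courses, function(cs) {
    g <- classify_course(cs)
    c(g$responder, g$relapsed)
  }, logical(2)))
  expect_equal(flags[, 1], gc$truth$responder)
  expect_equal(flags[, 2], gc$truth$relapsed)
})

test_that("fisher exact matches the enumeration oracle", {
  expect_equal(fisher_exact(rbind(c(8, 2), c(3, 9))), 0.0300, tolerance = 1e-3)
  expect_equal(fisher_exact(rbind(c(6, 0), c(5, 14))), 0.00261, tolerance = 1e-3)
  expect_equal(fisher_exact(rbind(c(5, 5), c(5, 5))), 1)
  set.seed(7)
  for (i in 1:150) {
    n <- sample(4:40, 1)
    cells <- as.vector(stats::rmultinom(1, n, runif(4, 0.05, 1)))
    tab <- matrix(cells, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab), oracle_fisher(tab), tolerance = 1e-9)
  }
})

test_that("boschloo is a valid, more powerful exact test", {
  tab <- rbind(c(8, 2), c(3, 9))
  one_sided_fisher <- phyper(7, 10, 12, 11, lower.tail = FALSE)
  pb <- boschloo(tab)
  expect_lte(pb, 2 * one_sided_fisher)   # at least as powerful as Fisher
  expect_lte(pb, 1)
  expect_gt(pb, 0)
  # maximisation over the nuisance grid is stable beyond ~200 points
  expect_lt(abs(boschloo(tab, grid_size = 200) -
                  boschloo(tab, grid_size = 500)), 1e-3)
  # identical proportions carry no evidence
  expect_equal(boschloo(rbind(c(5, 0), c(5, 0))), 1)
  expect_gt(boschloo(rbind(c(5, 5), c(5, 5))), 0.9)
  expect_error(boschloo(tab, grid_size = 5), "grid_size")
  expect_error(boschloo(rbind(c(0, 0), c(3, 4))), "empty margin")

  # direct enumeration oracle at small n: the unconditional p is the
  # supremum over pi of P(T(table) <= T(observed))
  small <- rbind(c(7, 1), c(2, 6))
  n1 <- 8; n2 <- 8
  t_stat <- outer(0:n1, 0:n2, function(i, j)
    phyper(i - 1, n1, n2, i + j, lower.tail = FALSE))
  t_obs <- t_stat[small[1, 1] + 1, small[2, 1] + 1]
  oracle <- max(vapply(seq(0.001, 0.999, length.out = 999), function(p) {
    sum(outer(dbinom(0:n1, n1, p), dbinom(0:n2, n2, p))[t_stat <= t_obs + 1e-12])
  }, numeric(1)))
  expect_equal(boschloo(small, grid_size = 999, alternative = "greater"),
               oracle, tolerance = 1e-6)
})

test_that("proportion z-test", {
  z0 <- prop_ztest(5, 10, 10, 20)
  expect_equal(z0$z, 0); expect_equal(z0$p, 1)
  z1 <- prop_ztest(71, 100, 23, 100)
  expect_lt(z1$p, 1e-4)
  # z^2 equals the uncorrected chi-square statistic
  chi <- suppressWarnings(stats::prop.test(c(71, 23), c(100, 100),
                                           correct = FALSE)$statistic)
  expect_equal(z1$z^2, unname(chi), tolerance = 1e-9)
  expect_error(prop_ztest(1, 10, 0, 0))
})

test_that("sample size from the power formula", {
  expect_equal(sample_size(1), 24L)          # ceiling(23.4)
  expect_equal(sample_size(2), 6L)           # ceiling(5.85)
  expect_equal(sample_size(1e6), 1L)         # floor rule at huge effects
  expect_error(sample_size(0))
})

test_that("outlier exclusion drops only abnormally fast growers", {
  mk_course <- function(g) {
    day <- seq(12, 20, 2)
    v <- 60 * exp(g * (day - 12))
    l <- (v / 0.32)^(1 / 3)
    data.frame(day = day, length_mm = l, width_mm = 0.8 * l)
  }
  same <- replicate(6, mk_course(0.3), simplify = FALSE)
  out <- exclude_outliers(same)
  expect_length(out, 6)                      # zero spread: exclude none
  mixed <- c(replicate(6, mk_course(0.3), simplify = FALSE),
             list(mk_course(1.2)))           # one extreme fast grower
  out2 <- exclude_outliers(mixed)
  expect_length(out2, 6)
  expect_equal(attr(out2, "excluded"), 7L)
  # slow growers are never excluded (one-sided rule)
  mixed_slow <- c(replicate(6, mk_course(0.3), simplify = FALSE),
                  list(mk_course(0.01)))
  expect_length(exclude_outliers(mixed_slow), 7)
  expect_length(exclude_outliers(list()), 0)
})
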