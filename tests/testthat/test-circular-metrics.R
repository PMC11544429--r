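test_that("mean absolute phase difference: closed cases and symmetry", {
  expect_equal(mean_abs_phase_diff(c(0.2, -1, 3), c(0.2, -1, 3)), 0)
  expect_equal(mean_abs_phase_diff(c(0, 1), c(pi, 1 + pi)), 180)
  set.seed(12)
  p1 <- runif(1e5, -pi, pi); p2 <- runif(1e5, -pi, pi)
  expect_equal(mean_abs_phase_diff(p1, p2), 90, tolerance = 0.3 / 90)
  # differences are taken on the circle, never by raw subtraction
  expect_equal(mean_abs_phase_diff(3, -3), (2 * pi - 6) * 180 / pi)
  # weighted version
  expect_equal(mean_abs_phase_diff(c(0, 0), c(pi / 2, pi), c(3, 1)),
               (3 * 90 + 180) / 4)
  expect_error(mean_abs_phase_diff(numeric(0), numeric(0)), "empty")
})

test_that("phase-difference shift invariance holds per reflection, not globally", {
  set.seed(13)
  p1 <- runif(500, -pi, pi); p2 <- wrap_angle(p1 + rnorm(500, sd = 0.3))
  base <- mean_abs_phase_diff(p1, p2)
  # simultaneous per-reflection shifts leave every difference unchanged
  shifts <- runif(500, -pi, pi)
  expect_equal(mean_abs_phase_diff(p1 + shifts, p2 + shifts), base,
               tolerance = 1e-12)
  # a constant added to only one set changes the statistic (no rotational
  # invariance of the kind the Fisher-Lee coefficient has)
  expect_gt(mean_abs_phase_diff(p1 + 2.5, p2), base + 30)
})

test_that("map correlation equals voxel-space Pearson on random toy maps", {
  cell <- tiny_cell()
  refl <- reflection_set(reflection_indices(cell), cell)
  set.seed(14)
  for (rep_i in 1:3) {
    c1 <- complex(real = rnorm(nrow(refl)), imaginary = rnorm(nrow(refl)))
    c2 <- complex(real = rnorm(nrow(refl)), imaginary = rnorm(nrow(refl)))
    m1 <- structure_factors_to_density(c1, refl, f000 = 3)
    m2 <- structure_factors_to_density(c2, refl, f000 = -1)
    cc <- map_correlation(Mod(c1), Mod(c2), dphi = Arg(c1) - Arg(c2))
    expect_equal(cc, stats::cor(as.vector(m1), as.vector(m2)),
                 tolerance = 1e-8)
  }
  # exact limits
  f <- runif(50, 0.5, 2); ph <- runif(50, -pi, pi)
  expect_equal(map_correlation(f, f, dphi = rep(0, 50)), 1)
  expect_equal(map_correlation(f, f, dphi = rep(pi, 50)), -1)
  expect_error(map_correlation(rep(0, 5), rep(0, 5), dphi = rep(0, 5)),
               "zero-variance")
})

test_that("Fisher-Lee estimator: limits, brute-force identity, rotation invariance", {
  set.seed(15)
  p1 <- runif(40, -pi, pi)
  expect_equal(fisher_lee_correlation(p1, p1), 1, tolerance = 1e-10)
  expect_equal(fisher_lee_correlation(p1, -p1), -1, tolerance = 1e-10)
  # O(n) expansion equals the O(n^2) pairwise definition
  for (n in c(11, 50)) {
    a <- runif(n, -pi, pi); b <- wrap_angle(a + rnorm(n))
    expect_equal(fisher_lee_correlation(a, b), fisher_lee_pairwise(a, b),
                 tolerance = 1e-10)
  }
  # invariance to independent constant rotations of either set
  a <- runif(200, -pi, pi); b <- wrap_angle(a + rnorm(200, sd = 0.7))
  r0 <- fisher_lee_correlation(a, b)
  expect_equal(fisher_lee_correlation(wrap_angle(a + 1.3),
                                      wrap_angle(b - 2.1)), r0,
               tolerance = 1e-10)
  # independence: near zero on average
  reps <- vapply(1:100, function(i) {
    fisher_lee_correlation(runif(200, -pi, pi), runif(200, -pi, pi))
  }, numeric(1))
  expect_lt(max(abs(reps)), 0.35)
  expect_lt(abs(mean(reps)), 0.02)
  expect_gt(mean(abs(reps) < 0.2), 0.95)
  # degenerate set
  expect_error(fisher_lee_correlation(rep(1, 10), runif(10)), "degenerate")
})

test_that("circular moments match hand-computed vector sums", {
  m <- circular_moments(rep(0.7, 5))
  expect_equal(m$mean_length, 1)
  expect_equal(m$mean_direction, 0.7)
  m2 <- circular_moments(c(0, pi))
  expect_equal(m2$mean_length, 0, tolerance = 1e-12)
  expect_false(m2$direction_defined)
  expect_true(is.na(m2$mean_direction))
  m3 <- circular_moments(c(0, pi / 2))
  expect_equal(m3$mean_length, sqrt(2) / 2)
  expect_equal(m3$mean_direction, pi / 4)
})

test_that("von Mises concentration MLE solves A(kappa) = Rbar and round-trips", {
  expect_equal(fit_von_mises_kappa(0), 0)
  k <- fit_von_mises_kappa(0.4)
  expect_equal(vm_mean_length_quad(k), 0.4, tolerance = 1e-8)
  expect_equal(k, 0.87408, tolerance = 1e-4)
  # monotone in Rbar
  rs <- seq(0.05, 0.95, by = 0.1)
  ks <- vapply(rs, fit_von_mises_kappa, numeric(1))
  expect_true(all(diff(ks) > 0))
  expect_warning(kcap <- fit_von_mises_kappa(1), "capped")
  expect_equal(kcap, 1e4)
  # sampling round trip: kappa = 2 recovered from 1e5 draws
  set.seed(16)
  s <- sample_von_mises(1e5, 0.3, 2)
  R <- sqrt(mean(cos(s))^2 + mean(sin(s))^2)
  expect_equal(fit_von_mises_kappa(R), 2, tolerance = 0.05 / 2)
})

test_that("joint structure-factor PDF: fits, degenerate flag, normalization", {
  # constant trajectory
  fit0 <- fit_joint_sf_pdf(rep(3, 10), rep(0.4, 10))
  expect_equal(fit0$amplitude$mu, 3)
  expect_equal(fit0$amplitude$sigma, 0)
  expect_true(fit0$degenerate)
  expect_equal(fit0$circular$mean_direction, 0.4)
  expect_equal(fit0$circular$mean_length, 1)

  # parameter recovery within sampling error
  set.seed(17)
  n <- 1000
  amp <- rnorm(n, 10, 1)
  ph <- sample_von_mises(n, 0.3, 5)
  fit <- fit_joint_sf_pdf(amp, ph)
  expect_equal(fit$amplitude$mu, 10, tolerance = 3 / sqrt(n) / 10)
  expect_equal(fit$amplitude$sigma, 1, tolerance = 0.1)
  expect_equal(fit$circular$mean_direction, 0.3, tolerance = 3 * sqrt(1 / (n * 5)) / 0.3)
  expect_equal(fit$circular$kappa, 5, tolerance = 0.15)

  # joint density integrates to 1 over F in R, phi in (-pi, pi]
  gridF <- seq(10 - 6, 10 + 6, length.out = 121)
  gridP <- seq(-pi, pi, length.out = 181)
  vals <- outer(gridF, gridP, fit$density)
  integral <- sum(vals) * diff(gridF[1:2]) * diff(gridP[1:2])
  expect_equal(integral, 1, tolerance = 1e-3)
})

test_that("agreement metrics respond monotonically to the error variance", {
  refl <- make_phase_experiment_set(4000, centric_fraction = 0.05, seed = 18)
  vs <- seq(0.1, 0.9, by = 0.2)
  madp <- numeric(length(vs)); mc <- numeric(length(vs))
  for (i in seq_along(vs)) {
    out <- corrupt_phases(refl, error_spec(vs[i], seed = 23))
    madp[i] <- mean_abs_phase_diff(refl$phase_ref, out$phase_ref)
    mc[i] <- map_correlation(refl$f_measured, refl$f_measured,
                             dphi = refl$phase_ref - out$phase_ref)
  }
  expect_true(all(diff(madp) > 0))
  expect_true(all(diff(mc) < 0))
  # near-linear relationship: map correlation tracks 1 - V
  expect_lt(max(abs(mc - (1 - vs))), 0.06)
})
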