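# Build a synthetic trajectory record directly (no run needed): known
# per-reflection phase jitter around fixed mean directions.
fake_record <- function(refl, window = 30, kappa = Inf, amp = NULL,
                        seed = 1) {
  set.seed(seed)
  n <- nrow(refl)
  if (is.null(amp)) amp <- refl$f_measured
  ph0 <- refl$phase_ref
  sfw <- matrix(complex(1), n, window)
  for (j in seq_len(window)) {
    ph <- if (is.infinite(kappa)) ph0 else
      wrap_angle(ph0 + sample_von_mises(n, 0, kappa))
    sfw[, j] <- amp * exp(1i * ph)
  }
  structure(list(correlation = rep(NA_real_, window), sf_window = sfw,
                 window_iterations = seq_len(window),
                 config = ipa_config("RRR", beta = 0.8,
                                     n_iterations = window),
                 refl = refl),
            class = "trajectory_record")
}

grid_refl <- function() {
  cell <- unit_cell_grid(16, shape = 16, d_min = 2.5)
  refl <- reflection_set(reflection_indices(cell), cell)
  set.seed(41)
  refl$f_measured <- abs(rnorm(nrow(refl))) + 0.2
  refl$phase_ref <- runif(nrow(refl), -pi, pi)
  refl$is_measured <- rep(TRUE, nrow(refl))
  refl
}

test_that("trajectory summaries recover window moments", {
  refl <- grid_refl()
  # constant trajectory: mean length 1 everywhere, direction = stored phase
  rec <- fake_record(refl, kappa = Inf)
  s <- trajectory_summaries(rec)
  expect_true(all(abs(s$mean_length - 1) < 1e-12))
  expect_equal(s$mean_direction, refl$phase_ref, tolerance = 1e-12)
  expect_equal(s$amp_sd, rep(0, nrow(refl)), tolerance = 1e-12)

  # uniform phases for one reflection -> its mean length near 0
  rec2 <- fake_record(refl, window = 200, kappa = 0)
  s2 <- trajectory_summaries(rec2)
  expect_lt(mean(s2$mean_length), 0.12)

  # von Mises jitter kappa = 5: mean of Rbar across reflections ~ A(5)
  rec3 <- fake_record(refl, window = 100, kappa = 5)
  s3 <- trajectory_summaries(rec3)
  expect_equal(mean(s3$mean_length), vm_mean_length_quad(5),
               tolerance = 0.02)
  expect_error(trajectory_summaries(rec, window = 1), "at least 2")
  expect_error(trajectory_summaries(rec, window = 100), "exceeds")
})

test_that("averaged-map synthesis obeys the weighting contract", {
  refl <- grid_refl()
  rec <- fake_record(refl, kappa = Inf)
  s <- trajectory_summaries(rec)
  mu <- synthesize_averaged_map(s, refl, "unweighted", f000 = 0)
  mw <- synthesize_averaged_map(s, refl, "weighted", f000 = 0)
  # all mean lengths 1: weighted and unweighted identical
  expect_equal(unclass(mu), unclass(mw), tolerance = 1e-12)

  # all mean lengths ~0 (undefined directions): weighted map is flat
  s0 <- s
  s0$mean_length <- 0
  s0$direction_defined <- FALSE
  m0 <- synthesize_averaged_map(s0, refl, "weighted", f000 = 7)
  expect_lt(max(abs(m0 - mean(m0))), 1e-9)
  expect_equal(mean(m0), 7 / prod(attr(refl, "cell")$shape))
})

test_that("PRTF: exact limits and equality with the mean length", {
  refl <- grid_refl()
  # single-point phase distribution, reconstructed amplitude = measured
  rec <- fake_record(refl, kappa = Inf)
  p <- prtf(rec)
  expect_equal(p$per_reflection$prtf, rep(1, nrow(refl)), tolerance = 1e-12)
  expect_true(all(abs(p$per_shell$prtf - 1) < 1e-12))
  expect_equal(p$n_excluded, 0)

  # uniform random phases: shell PRTF ~ 0
  rec0 <- fake_record(refl, window = 200, kappa = 0)
  p0 <- prtf(rec0, n_shells = 4)
  expect_lt(max(p0$per_shell$prtf), 0.15)

  # with amplitudes held at measured, per-reflection PRTF == mean length
  # exactly (the constraint-B configuration)
  rec5 <- fake_record(refl, window = 60, kappa = 5)
  p5 <- prtf(rec5)
  expect_equal(p5$per_reflection$prtf, p5$per_reflection$mean_length,
               tolerance = 1e-12)
  # and approximates A(kappa)
  expect_equal(mean(p5$per_reflection$prtf), vm_mean_length_quad(5),
               tolerance = 0.03)

  # zero measured amplitude: excluded and counted
  reflz <- refl; reflz$f_measured[3] <- 0
  recz <- fake_record(reflz, kappa = Inf)
  pz <- prtf(recz)
  expect_equal(pz$n_excluded, 1)
  expect_true(is.na(pz$per_reflection$prtf[3]))
})

test_that("stationarity report separates constant from drifting trajectories", {
  refl <- grid_refl()
  rec <- fake_record(refl, kappa = 50)
  expect_true(stationarity_report(rec)$stationary)

  # linear phase drift across the window
  drift <- fake_record(refl, kappa = Inf)
  n <- nrow(refl)
  for (j in seq_len(ncol(drift$sf_window)))
    drift$sf_window[, j] <- drift$sf_window[, j] * exp(1i * 0.08 * j)
  rep_d <- stationarity_report(drift)
  expect_false(rep_d$stationary)
  expect_gt(rep_d$mean_direction_shift, 0.5)
})

test_that("ER polish is deterministic and fixes fixed points", {
  xt <- desk_crystal()
  p1 <- er_polish(xt$truth, xt$refl, xt$prior, n_iter = 3,
                  window_radius = DESK_WR, envelope0 = xt$envelope,
                  envelope_update = FALSE)
  p2 <- er_polish(xt$truth, xt$refl, xt$prior, n_iter = 3,
                  window_radius = DESK_WR, envelope0 = xt$envelope,
                  envelope_update = FALSE)
  expect_identical(unclass(p1), unclass(p2))
  # polishing the exact solution (a joint fixed point) leaves it unchanged
  Fp <- density_to_structure_factors(p1, xt$refl)
  cc <- map_correlation(Mod(Fp), xt$refl$f_measured,
                        dphi = Arg(Fp) - xt$refl$phase_ref)
  expect_gt(cc, 1 - 1e-6)
})

test_that("converged runs are flagged stationary, early-stopped ones are not", {
  xt <- desk_crystal()
  cor1 <- corrupt_phases(xt$refl, error_spec(0.5, seed = 71))
  cfg <- ipa_config("RRR", beta = 0.8, n_iterations = 120,
                    monitored_estimate = "B", trailing_window = 30)
  rec <- ipa_run(xt$refl, xt$prior, cfg, start_phases = cor1$phase_ref,
                 window_radius = DESK_WR, envelope0 = xt$envelope)
  expect_gt(rec$correlation[120], 0.9)
  expect_true(stationarity_report(rec)$stationary)
  cfg_short <- ipa_config("RRR", beta = 0.8, n_iterations = 8,
                          monitored_estimate = "B", trailing_window = 8)
  rec_s <- ipa_run(xt$refl, xt$prior, cfg_short,
                   start_phases = cor1$phase_ref,
                   window_radius = DESK_WR, envelope0 = xt$envelope)
  expect_false(stationarity_report(rec_s)$stationary)
})
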