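# Update rules are exercised on abstract vectors with constant projections
# (hand-evaluated compositions), on affine toys with closed-form solutions,
# and on toy crystals for the algorithm-identity properties.

test_that("constant-projection toys match the hand-evaluated update rules", {
  a <- c(1, 2); b <- c(-3, 5); x <- c(0.5, -0.5)
  p_a <- const_proj(a); p_b <- const_proj(b)

  expect_equal(er_update(x, p_a, p_b)$x, a)

  beta <- 0.6
  # DM by hand: f_B = (1 + 1/b) b_vec - x/b ; f_A = (1 - 1/b) a_vec + x/b
  # but with constant projections P_A(f_B) = a, P_B(f_A) = b
  expect_equal(dm_update(x, p_a, p_b, beta)$x, x + beta * (a - b))
  est <- dm_estimates(x, p_a, p_b, beta)
  expect_equal(est$estimate_A, a)
  expect_equal(est$estimate_B, b)

  # RRR: x' - x = beta (P_B(2a - x) - a) = beta (b - a)
  expect_equal(rrr_update(x, p_a, p_b, beta)$x - x, beta * (b - a))
  # revRRR swaps the roles: x' - x = beta (a - b)
  expect_equal(revrrr_update(x, p_a, p_b, beta)$x - x, beta * (a - b))
  # RAAR: x' = beta (x + P_A(2b - x)) + (1 - 2 beta) b
  expect_equal(raar_update(x, p_a, p_b, beta)$x,
               beta * (x + a) + (1 - 2 * beta) * b)
})

test_that("all algorithms preserve a joint fixed point", {
  x <- c(1.5, -2, 3)
  id <- function(z) z
  for (up in list(function(x) er_update(x, id, id),
                  function(x) dm_update(x, id, id, 0.7),
                  function(x) dm_update(x, id, id, -0.4),
                  function(x) rrr_update(x, id, id, 0.9),
                  function(x) revrrr_update(x, id, id, 1.4),
                  function(x) raar_update(x, id, id, 0.8))) {
    st <- up(x)
    expect_equal(st$x, x)
    expect_equal(st$estimate_A, x)
    expect_equal(st$estimate_B, x)
  }
})

test_that("beta domains are enforced", {
  id <- function(z) z
  expect_error(dm_update(1, id, id, 0), "beta")
  expect_error(dm_update(1, id, id, 1), "beta")
  expect_error(rrr_update(1, id, id, 2), "beta")
  expect_error(revrrr_update(1, id, id, 0), "beta")
  expect_error(raar_update(1, id, id, 1.2), "beta")
  expect_error(ipa_config("ER", beta = 0.5), "no adjustable")
  expect_error(ipa_config("DM", beta = 0), "beta")
})

test_that("affine two-line toy: every algorithm reaches the intersection", {
  # lines in the plane: A = {y = 0}, B = {x + y = 2}; intersection (2, 0)
  p_a <- function(v) c(v[1], 0)
  nb <- c(1, 1) / sqrt(2)
  p_b <- function(v) v + (2 / sqrt(2) - sum(v * nb)) * nb
  star <- c(2, 0)
  algos <- list(
    ER = function(x) er_update(x, p_a, p_b),
    DM = function(x) dm_update(x, p_a, p_b, 0.7),
    RRR = function(x) rrr_update(x, p_a, p_b, 0.9),
    revRRR = function(x) revrrr_update(x, p_a, p_b, 0.9),
    RAAR = function(x) raar_update(x, p_a, p_b, 0.8))
  for (nm in names(algos)) {
    x <- c(-3, 4); est <- NULL
    for (i in 1:400) { st <- algos[[nm]](x); x <- st$x; est <- st$estimate_B }
    expect_lt(sqrt(sum((est - star)^2)), 1e-6, label = nm)
    expect_lt(sqrt(sum((p_a(p_b(x)) - star)^2)), 1e-5, label = nm)
  }
})

test_that("projection applications per iteration: ER 2, DM 4, RRR/revRRR/RAAR 2", {
  counter <- new.env(); counter$a <- 0L; counter$b <- 0L
  p_a <- counted(function(z) z, counter, "a")
  p_b <- counted(function(z) z, counter, "b")
  reset <- function() { counter$a <- 0L; counter$b <- 0L }
  x <- c(1, 2)

  er_update(x, p_a, p_b)
  expect_equal(counter$a + counter$b, 2L); reset()
  dm_update(x, p_a, p_b, 0.5)
  expect_equal(counter$a + counter$b, 4L); reset()
  rrr_update(x, p_a, p_b, 0.5)
  expect_equal(c(counter$a, counter$b), c(1L, 1L)); reset()
  revrrr_update(x, p_a, p_b, 0.5)
  expect_equal(c(counter$a, counter$b), c(1L, 1L)); reset()
  raar_update(x, p_a, p_b, 0.5)
  expect_equal(c(counter$a, counter$b), c(1L, 1L))
})

test_that("DM stationarity implies coincidence of the two solution estimates", {
  # near the fixed point of the affine toy the iterate change bounds the
  # estimate discrepancy via x' - x = beta (est_A - est_B)
  p_a <- function(v) c(v[1], 0)
  nb <- c(1, 1) / sqrt(2)
  p_b <- function(v) v + (2 / sqrt(2) - sum(v * nb)) * nb
  beta <- 0.7
  x <- c(-3, 4)
  for (i in 1:300) x <- dm_update(x, p_a, p_b, beta)$x
  st <- dm_update(x, p_a, p_b, beta)
  delta <- sqrt(sum((st$x - x)^2))
  expect_lt(delta, 1e-6)
  expect_lt(sqrt(sum((st$estimate_A - st$estimate_B)^2)), delta / abs(beta) + 1e-12)
})

test_that("changing the sign of beta swaps the DM constraint roles", {
  set.seed(21)
  p_a <- function(v) c(v[1], 0)
  nb <- c(1, 1) / sqrt(2)
  p_b <- function(v) v + (2 / sqrt(2) - sum(v * nb)) * nb
  x <- rnorm(2)
  beta <- 0.6
  fwd <- dm_update(x, p_a, p_b, beta)
  swp <- dm_update(x, p_b, p_a, -beta)
  expect_equal(fwd$x, swp$x, tolerance = 1e-12)
})

test_that("RAAR(beta=1) reproduces the revRRR(beta=1) iterate sequence on a toy crystal", {
  xt <- desk_crystal()
  refl <- xt$refl
  cor1 <- corrupt_phases(refl, error_spec(0.5, seed = 31))
  run_seq <- function(alg) {
    cfg <- ipa_config(alg, beta = 1, n_iterations = 25,
                      monitored_estimate = "B", trailing_window = 2)
    ipa_run(refl, xt$prior, cfg, start_phases = cor1$phase_ref,
            window_radius = DESK_WR, envelope0 = xt$envelope)
  }
  r1 <- run_seq("RAAR"); r2 <- run_seq("revRRR")
  expect_lt(max(abs(r1$final_iterate - r2$final_iterate)),
            1e-10 * max(abs(r2$final_iterate)))
  expect_equal(r1$correlation, r2$correlation, tolerance = 1e-10)
})

test_that("RRR(beta=1) is the Douglas-Rachford iteration", {
  set.seed(33)
  p_a <- function(v) c(v[1], 0, v[3])
  nb <- c(1, 1, 1) / sqrt(3)
  p_b <- function(v) v + (1 - sum(v * nb)) * nb
  dr <- function(x) {  # x' = x + P_B(R_A x) - P_A x with R_A = 2 P_A - I
    a <- p_a(x); x + p_b(2 * a - x) - a
  }
  x1 <- x2 <- rnorm(3)
  for (i in 1:50) {
    x1 <- rrr_update(x1, p_a, p_b, 1)$x
    x2 <- dr(x2)
  }
  expect_lt(max(abs(x1 - x2)), 1e-12)
})

test_that("ER from the exact solution holds the known solution", {
  xt <- desk_crystal()
  cfg <- ipa_config("ER", n_iterations = 8, envelope_update = FALSE,
                    trailing_window = 2)
  rec <- ipa_run(xt$refl, xt$prior, cfg, start_map = xt$truth,
                 envelope0 = xt$envelope, window_radius = DESK_WR)
  expect_true(all(abs(rec$correlation - 1) < 1e-6))
})

test_that("run records are deterministic and divergence is diagnosed", {
  xt <- desk_crystal()
  cor1 <- corrupt_phases(xt$refl, error_spec(0.6, seed = 55))
  cfg <- ipa_config("RRR", beta = 0.8, n_iterations = 10)
  r1 <- ipa_run(xt$refl, xt$prior, cfg, start_phases = cor1$phase_ref,
                window_radius = DESK_WR, envelope0 = xt$envelope)
  r2 <- ipa_run(xt$refl, xt$prior, cfg, start_phases = cor1$phase_ref,
                window_radius = DESK_WR, envelope0 = xt$envelope)
  expect_identical(r1$correlation, r2$correlation)
  expect_identical(r1$sf_window, r2$sf_window)
})
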