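# Shared fixtures, memoized for the session so expensive simulation runs are
# built once and reused across test files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Desk-scale toy crystal used by the simulation experiments: 27 A cubic cell,
# 32^3 grid, d_min 2.5 A, solvent fraction 0.74, atom-like blobs.
desk_spec <- function(seed = 101) {
  toy_crystal_spec(cell_length = 27, shape = 32, d_min = 2.5,
                   solvent_fraction = 0.74, n_blobs = 170, blob_width = 1,
                   seed = seed)
}

desk_crystal <- function() {
  memo("desk_crystal", function() {
    xt <- make_toy_crystal(desk_spec())
    xt$refl <- simulate_data(xt$truth, seed = 101)
    xt
  })
}

# envelope window radius used for all desk-toy runs (small relative to the
# ~8 A protein sphere; see the methods vignette)
DESK_WR <- 1.7

# A tiny cell/grid for exact Fourier oracles.
tiny_cell <- function(n = 8, len = 8, d_min = 2) {
  unit_cell_grid(rep(len, 3), shape = rep(n, 3), d_min = d_min)
}

# Brute-force O(N^2) DFT oracle: F(h) = sum_x rho(x) exp(+2 pi i h.x/N).
dft_oracle <- function(map, hkl) {
  shape <- dim(map)
  idx <- as.matrix(expand.grid(x = 0:(shape[1] - 1), y = 0:(shape[2] - 1),
                               z = 0:(shape[3] - 1)))
  rho <- as.vector(map[cbind(idx[, 1] + 1, idx[, 2] + 1, idx[, 3] + 1)])
  vapply(seq_len(nrow(hkl)), function(i) {
    ph <- 2 * pi * (idx %*% (hkl[i, ] / shape))
    sum(rho * exp(1i * ph))
  }, complex(1))
}

# O(n^2) pairwise Fisher-Lee estimator oracle.
fisher_lee_pairwise <- function(p1, p2) {
  n <- length(p1)
  num <- 0; d1 <- 0; d2 <- 0
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    num <- num + sum(sin(p1[i] - p1[j]) * sin(p2[i] - p2[j]))
    d1 <- d1 + sum(sin(p1[i] - p1[j])^2)
    d2 <- d2 + sum(sin(p2[i] - p2[j])^2)
  }
  num / sqrt(d1 * d2)
}

# Quadrature oracles for the von Mises distribution (independent of the
# Bessel-ratio implementation path).
vm_density <- function(theta, kappa) exp(kappa * cos(theta)) /
  (2 * pi * besselI(kappa, 0))
vm_mean_length_quad <- function(kappa) {
  stats::integrate(function(t) cos(t) * vm_density(t, kappa), -pi, pi,
                   rel.tol = 1e-10)$value
}
vm_mean_absdev_quad <- function(kappa) {
  stats::integrate(function(t) abs(t) * vm_density(t, kappa), -pi, pi,
                   rel.tol = 1e-10)$value
}

# Constant projections for hand-evaluated update-rule toys.
const_proj <- function(v) function(x) v

# Counting wrapper for projection-cost accounting.
counted <- function(f, counter, name) {
  function(x) {
    counter[[name]] <- counter[[name]] + 1L
    f(x)
  }
}
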