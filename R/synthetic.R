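#' Specification of a synthetic toy crystal
#'
#' Describes a periodic toy crystal emulating the high-solvent regime in
#' which the solvent-flatness constraint is strong: a contiguous protein
#' region (a sphere centered in the cell, sized for the requested solvent
#' fraction) filled with positive Gaussian blobs, embedded in flat solvent.
#' Defaults describe a 40 Angstrom cubic P1 cell on a 48^3 grid at 2.5
#' Angstrom resolution with solvent fraction 0.74.
#'
#' @param cell_length cubic cell edge in Angstrom.
#' @param shape grid divisions per axis.
#' @param d_min resolution limit in Angstrom.
#' @param solvent_fraction solvent volume fraction in (0, 1).
#' @param n_blobs number of Gaussian blobs (>= 1).  The default fills the
#'   protein volume at roughly one blob per 28 cubic Angstrom, giving the
#'   density atom-like texture at the 2.5 Angstrom resolution limit (real
#'   protein density is strongly textured at this scale, which is what makes
#'   local-variance envelope determination work).
#' @param blob_width Gaussian sigma in Angstrom (atom-like, ~1 Angstrom).
#' @param amplitude_noise fractional standard deviation of the simulated
#'   amplitude error.
#' @param completeness fraction of reflections flagged measured.
#' @param centric_fraction reserved for the geometry-free statistical sets
#'   ([make_phase_experiment_set()]); the spatial toy crystal is acentric.
#' @param seed integer seed.
#' @return list of class `toy_crystal_spec`.
#' @export
toy_crystal_spec <- function(cell_length = 40, shape = 48, d_min = 2.5,
                             solvent_fraction = 0.74, n_blobs = 600,
                             blob_width = 1, amplitude_noise = 0,
                             completeness = 1, centric_fraction = 0,
                             seed = 1L) {
  if (solvent_fraction <= 0 || solvent_fraction >= 1)
    stop("solvent fraction must be in (0, 1)")
  if (n_blobs < 1L) stop("need at least one blob")
  if (completeness <= 0 || completeness > 1)
    stop("completeness must be in (0, 1]")
  structure(list(cell_length = cell_length, shape = shape, d_min = d_min,
                 solvent_fraction = solvent_fraction,
                 n_blobs = as.integer(n_blobs), blob_width = blob_width,
                 amplitude_noise = amplitude_noise,
                 completeness = completeness,
                 centric_fraction = centric_fraction,
                 seed = as.integer(seed)),
            class = "toy_crystal_spec")
}

#' Generate a synthetic toy crystal
#'
#' Builds the ground-truth density: `n_blobs` positive Gaussian blobs with
#' centers drawn uniformly inside a protein sphere whose volume matches
#' `1 - solvent_fraction` of the cell, on an exactly flat (zero) solvent
#' background.  Returns the truth map, the true envelope (the protein
#' sphere) and the density prior taken from the truth's protein-region
#' histogram with solvent level 0, so the truth exactly satisfies the
#' real-space constraints by construction.
#'
#' @param spec a [toy_crystal_spec()].
#' @return list with `truth` ([density_map()]), `envelope` ([envelope()]),
#'   `prior` ([density_prior()]) and `cell` ([unit_cell_grid()]).
#' @export
make_toy_crystal <- function(spec) {
  stopifnot(inherits(spec, "toy_crystal_spec"))
  L <- spec$cell_length
  cell <- unit_cell_grid(rep(L, 3), shape = rep(spec$shape, 3),
                         d_min = spec$d_min)
  fp <- 1 - spec$solvent_fraction
  r_prot <- L * (3 * fp / (4 * pi))^(1 / 3)
  if (2 * r_prot >= L)
    stop("protein sphere does not fit the cell at this solvent fraction")
  if (r_prot <= spec$blob_width)
    stop("blobs cannot fit at the requested solvent fraction")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$seed)

  n <- spec$shape
  ax <- (seq_len(n) - 1) / n * L
  gx <- ax[slice.index(array(0, rep(n, 3)), 1)]
  gy <- ax[slice.index(array(0, rep(n, 3)), 2)]
  gz <- ax[slice.index(array(0, rep(n, 3)), 3)]
  ctr <- L / 2

  # blob centers uniform over the whole protein sphere so the density fills
  # the molecular volume out to its surface (as real protein density does);
  # tails crossing the surface are truncated by the solvent flattening below
  r_in <- r_prot
  centers <- matrix(NA_real_, spec$n_blobs, 3)
  got <- 0L
  while (got < spec$n_blobs) {
    cand <- matrix(stats::runif(3 * spec$n_blobs, -r_in, r_in), ncol = 3)
    keep <- rowSums(cand^2) <= r_in^2
    take <- min(sum(keep), spec$n_blobs - got)
    if (take > 0) {
      centers[got + seq_len(take), ] <- cand[which(keep)[seq_len(take)], ]
      got <- got + take
    }
  }
  heights <- stats::runif(spec$n_blobs, 0.5, 1.5)

  rho <- array(0, rep(n, 3))
  s2 <- 2 * spec$blob_width^2
  pmin_image <- function(d) d - L * round(d / L)
  for (b in seq_len(spec$n_blobs)) {
    dx <- pmin_image(gx - (ctr + centers[b, 1]))
    dy <- pmin_image(gy - (ctr + centers[b, 2]))
    dz <- pmin_image(gz - (ctr + centers[b, 3]))
    rho <- rho + heights[b] * exp(-(dx^2 + dy^2 + dz^2) / s2)
  }

  d2ctr <- pmin_image(gx - ctr)^2 + pmin_image(gy - ctr)^2 +
    pmin_image(gz - ctr)^2
  mask <- array(d2ctr <= r_prot^2, rep(n, 3))
  achieved <- 1 - mean(mask)
  if (abs(achieved - spec$solvent_fraction) > 0.02)
    stop(sprintf("achieved solvent fraction %.3f misses target %.3f",
                 achieved, spec$solvent_fraction))
  rho[!mask] <- 0  # exactly flat solvent

  truth <- density_map(rho, cell)
  env <- envelope(mask, spec$solvent_fraction)
  prior <- density_prior(rho[mask], solvent_level = 0,
                         solvent_fraction = achieved)
  list(truth = truth, envelope = env, prior = prior, cell = cell)
}

#' Simulate reflection data from a ground-truth density
#'
#' Fourier-transforms the truth, keeps the Friedel-unique reflections to the
#' cell's resolution limit, applies optional multiplicative Gaussian
#' amplitude noise, stores the true phases as reference phases for scoring,
#' flags a random `1 - completeness` subset as unmeasured, and records
#' F(000) separately.
#'
#' @param truth a [density_map()] (e.g. from [make_toy_crystal()]).
#' @param amplitude_noise fractional standard deviation of the amplitude
#'   error (0 = exact amplitudes).
#' @param completeness fraction of reflections flagged measured.
#' @param seed integer seed for noise and completeness draws.
#' @return a [reflection_set()].
#' @export
simulate_data <- function(truth, amplitude_noise = 0, completeness = 1,
                          seed = 1L) {
  cell <- map_cell(truth)
  if (completeness <= 0 || completeness > 1)
    stop("completeness must be in (0, 1]")
  hkl <- reflection_indices(cell)
  refl <- reflection_set(hkl, cell = cell, f000 = sum(truth))
  Fc <- density_to_structure_factors(truth, refl)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)

  amp <- Mod(Fc)
  if (amplitude_noise > 0)
    amp <- pmax(0, amp * (1 + amplitude_noise * stats::rnorm(length(amp))))
  measured <- rep(TRUE, nrow(refl))
  if (completeness < 1)
    measured <- stats::runif(nrow(refl)) < completeness
  refl$f_measured <- ifelse(measured, amp, NA_real_)
  refl$phase_ref <- wrap_angle(Arg(Fc))
  refl$is_measured <- measured
  refl
}

#' Geometry-free reflection set for statistical experiments
#'
#' Generates `n_reflections` synthetic reflections with amplitudes drawn
#' from the acentric Wilson (Rayleigh) law normalized to unit mean-square,
#' uniform random phases, and a stated fraction of centric reflections whose
#' phases are restricted to the two-point set {0, pi}.  Used to calibrate
#' the error model and the agreement metrics where no real-space grid is
#' needed.
#'
#' @param n_reflections number of reflections (>= 1).
#' @param centric_fraction fraction of centric terms in `[0, 1)`.
#' @param seed integer seed.
#' @return a geometry-free [reflection_set()] (placeholder Miller indices).
#' @export
make_phase_experiment_set <- function(n_reflections, centric_fraction = 0,
                                      seed = 1L) {
  n <- as.integer(n_reflections)
  if (n < 1L) stop("need at least one reflection")
  if (centric_fraction < 0 || centric_fraction >= 1)
    stop("centric fraction must be in [0, 1)")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)

  # unique canonical-hemisphere placeholder indices h >= 1
  kmax <- ceiling(n^(1 / 3)) + 1L
  grid <- expand.grid(l = seq_len(kmax) - 1L, k = seq_len(kmax) - 1L,
                      h = seq_len(kmax))
  hkl <- cbind(h = grid$h, k = grid$k, l = grid$l)[seq_len(n), , drop = FALSE]

  amp <- sqrt(stats::rexp(n))  # Rayleigh with <F^2> = 1
  centric <- stats::runif(n) < centric_fraction
  phase <- wrap_angle(stats::runif(n, -pi, pi))
  phase[centric] <- ifelse(stats::runif(sum(centric)) < 0.5, 0, pi)

  reflection_set(hkl, cell = NULL, f_measured = amp, phase_ref = phase,
                 centric = centric, epsilon = 1)
}
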