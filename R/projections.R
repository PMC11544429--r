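#' Binary protein/solvent envelope
#'
#' @param mask logical array (`TRUE` = protein) matching a grid shape.
#' @param solvent_fraction_target the solvent fraction the mask was built for.
#' @return object of class `envelope`.
#' @export
envelope <- function(mask, solvent_fraction_target) {
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stop("mask must be a logical 3D array")
  if (solvent_fraction_target <= 0 || solvent_fraction_target >= 1)
    stop("solvent fraction must be in (0, 1)")
  structure(list(mask = mask,
                 solvent_fraction_target = solvent_fraction_target),
            class = "envelope")
}

#' @export
print.envelope <- function(x, ...) {
  cat(sprintf("Envelope: %.1f%% solvent (target %.1f%%), grid %s\n",
              100 * mean(!x$mask), 100 * x$solvent_fraction_target,
              paste(dim(x$mask), collapse = " x ")))
  invisible(x)
}

#' Density prior for the real-space constraints
#'
#' The protein-region prior is a reference histogram represented by its
#' sorted sample values (an empirical quantile function with linear
#' interpolation between order statistics); the solvent prior is the
#' one-point distribution at `solvent_level`.
#'
#' @param reference numeric sample of protein-region density values.
#' @param solvent_level mean solvent density.
#' @param solvent_fraction solvent volume fraction, used to fix F(000).
#' @return object of class `density_prior`.
#' @export
density_prior <- function(reference, solvent_level = 0,
                          solvent_fraction = NULL) {
  reference <- sort(as.numeric(reference))
  if (length(reference) < 2L) stop("reference histogram needs >= 2 values")
  if (any(!is.finite(reference))) stop("non-finite reference values")
  structure(list(reference = reference, solvent_level = solvent_level,
                 solvent_fraction = solvent_fraction),
            class = "density_prior")
}

# Evaluate the reference quantile function at probabilities p in [0,1]
# (linear interpolation through ((k-1)/(m-1), ref[k])).
prior_quantile <- function(prior, p) {
  m <- length(prior$reference)
  stats::approx(x = seq(0, 1, length.out = m), y = prior$reference,
                xout = p, rule = 2)$y
}

#' F(000) implied by a prior
#'
#' The DC term is never projected; it is fixed from the prior's solvent level
#' and the mean of the protein reference histogram.
#'
#' @param prior a [density_prior()] with a known solvent fraction.
#' @param cell the [unit_cell_grid()] (fixes the number of grid points).
#' @return scalar F(000) on the unnormalized-DFT scale (sum of density).
#' @export
f000_from_prior <- function(prior, cell) {
  fs <- prior$solvent_fraction
  if (is.null(fs)) stop("prior carries no solvent fraction")
  prod(cell$shape) * (fs * prior$solvent_level +
                        (1 - fs) * mean(prior$reference))
}

# Periodic spherical smoothing kernel (unnormalized), returned with its FFT
# cached so repeated envelope estimation reuses it.
spherical_kernel_fft <- function(cell, radius) {
  shape <- cell$shape
  frac <- lapply(seq_len(3L), function(a) {
    i <- seq_len(shape[a]) - 1L
    (((i + shape[a] %/% 2L) %% shape[a]) - shape[a] %/% 2L) / shape[a]
  })
  # Cartesian distances via the cell metric; orthorhombic and general cells
  # handled alike.
  fx <- frac[[1]][slice.index(array(0, shape), 1)]
  fy <- frac[[2]][slice.index(array(0, shape), 2)]
  fz <- frac[[3]][slice.index(array(0, shape), 3)]
  G <- cell$metric
  d2 <- G[1, 1] * fx^2 + G[2, 2] * fy^2 + G[3, 3] * fz^2 +
    2 * (G[1, 2] * fx * fy + G[1, 3] * fx * fz + G[2, 3] * fy * fz)
  ker <- array(as.numeric(d2 <= radius^2), shape)
  if (sum(ker) < 19) stop("smoothing window too small for this grid")
  list(fft = stats::fft(ker), n = sum(ker))
}

periodic_smooth <- function(values, kfft) {
  Re(stats::fft(stats::fft(values) * kfft$fft, inverse = TRUE)) /
    (length(values) * kfft$n)
}

# Smooth two real fields with one complex transform pair: the kernel is
# centro-symmetric so its FFT is real and convolution acts separately on the
# real and imaginary parts of fft(a + i b).
periodic_smooth2 <- function(a, b, kfft) {
  z <- stats::fft(stats::fft(a + 1i * b) * Re(kfft$fft), inverse = TRUE) /
    (length(a) * kfft$n)
  list(Re(z), Im(z))
}

#' Estimate the molecular envelope by local-variance thresholding
#'
#' Computes the local variance of the map in a spherical window (periodic
#' boundaries) as smoothed-mean-of-squares minus squared smoothed mean, then
#' thresholds it so that the `solvent_fraction` of voxels with the lowest
#' local variance are flagged as solvent.  Ties in the local variance are
#' broken by voxel lexicographic index so the solvent count is deterministic
#' (exactly `ceiling(solvent_fraction * n_voxels)` voxels are solvent).
#'
#' @param map a [density_map()].
#' @param solvent_fraction target solvent fraction in (0, 1).
#' @param window_radius smoothing sphere radius in Angstrom (default 4).
#' @param kernel optional cached kernel from a previous call on the same
#'   grid/radius (performance).
#' @return an [envelope()].
#' @export
estimate_envelope <- function(map, solvent_fraction, window_radius = 4,
                              kernel = NULL) {
  cell <- map_cell(map)
  if (solvent_fraction <= 0 || solvent_fraction >= 1)
    stop("solvent fraction must be in (0, 1)")
  v <- unclass(map)
  if (stats::var(as.vector(v)) == 0) stop("featureless map")
  if (is.null(kernel)) kernel <- spherical_kernel_fft(cell, window_radius)
  sm <- periodic_smooth2(v, v * v, kernel)
  lv <- pmax(sm[[2]] - sm[[1]] * sm[[1]], 0)
  nvox <- length(lv)
  n_solvent <- ceiling(solvent_fraction * nvox)
  ord <- order(as.vector(lv), seq_len(nvox))  # stable lexicographic tie-break
  mask <- array(TRUE, cell$shape)
  mask[ord[seq_len(n_solvent)]] <- FALSE
  envelope(mask, solvent_fraction)
}

#' Real-space projection: solvent flattening and histogram equivalence
#'
#' Sets every solvent voxel to the mean of the input solvent-region values
#' and replaces the protein voxels by the reference quantile at their input
#' rank (an order-preserving transformation generating the desired
#' histogram).  This is the distance-minimizing projection onto the
#' real-space constraint set for a fixed envelope and prior, and it is
#' idempotent.
#'
#' @param map a [density_map()].
#' @param env an [envelope()] on the same grid.
#' @param prior a [density_prior()].
#' @return projected [density_map()].
#' @export
project_real <- function(map, env, prior) {
  cell <- map_cell(map)
  if (!all(dim(env$mask) == cell$shape)) stop("envelope/grid shape mismatch")
  v <- unclass(map)
  protein <- env$mask
  v[!protein] <- mean(v[!protein])
  pv <- v[protein]
  np <- length(pv)
  r <- rank(pv, ties.method = "first")
  v[protein] <- prior_quantile(prior, if (np > 1) (r - 1) / (np - 1) else 0.5)
  density_map(v, cell)
}

#' Per-shell Wilson amplitude expectations
#'
#' Mean measured amplitude in equal-count resolution shells, used to restrain
#' unmeasured terms during the Fourier-space projection.
#'
#' @param refl a [reflection_set()] with d-spacings.
#' @param n_shells number of shells (default 10, reduced if the set is small).
#' @return numeric vector: expected amplitude per reflection (NA where a
#'   shell contains no measured terms).
#' @export
wilson_expectations <- function(refl, n_shells = 10) {
  n_shells <- max(1L, min(as.integer(n_shells), nrow(refl) %/% 20L + 1L))
  sh <- resolution_shells(refl, n_shells)
  means <- tapply(refl$f_measured[refl$is_measured],
                  sh$shell[refl$is_measured], mean)
  out <- rep(NA_real_, nrow(refl))
  have <- as.integer(names(means))
  for (s in have) out[sh$shell == s] <- means[as.character(s)]
  out
}

#' Fourier-space projection: measured amplitudes with Wilson restraints
#'
#' Transforms the map to reciprocal space and, for every measured reflection,
#' replaces the amplitude with the measured value while keeping the phase
#' (a coefficient with zero amplitude is assigned phase 0 first).  Unmeasured
#' reflections are capped at `c_w` times the per-shell Wilson expectation of
#' the measured amplitudes, again keeping phase.  F(000) and coefficients
#' outside the stored reflection list are left unchanged (they are not
#' constrained), and the map is transformed back.  The operation is the
#' distance-minimizing projection onto the amplitude constraint set and is
#' idempotent.
#'
#' @param map a [density_map()].
#' @param refl a [reflection_set()] on the same cell.
#' @param wilson per-reflection expected amplitudes for the restraint;
#'   computed from the measured data via [wilson_expectations()] when `NULL`
#'   and any reflection is unmeasured.
#' @param c_w restraint multiplier (default 2.0).
#' @return projected [density_map()].
#' @export
project_fourier <- function(map, refl, wilson = NULL, c_w = 2) {
  project_fourier_coeffs(map, refl, wilson, c_w)$map
}

# As project_fourier, but also returns the projected coefficients aligned to
# the reflection rows (the run loop records them without a second transform).
project_fourier_coeffs <- function(map, refl, wilson = NULL, c_w = 2) {
  cell <- map_cell(map)
  check_same_cell(cell, attr(refl, "cell"))
  if (any(refl$f_measured < 0, na.rm = TRUE))
    stop("negative measured amplitude")
  unmeasured <- !refl$is_measured
  if (any(unmeasured) && is.null(wilson)) wilson <- wilson_expectations(refl)

  Farr <- stats::fft(unclass(map), inverse = TRUE)
  hkl <- as.matrix(refl[, c("h", "k", "l")])
  ip <- grid_linear_index(hkl, cell$shape)
  Fc <- Farr[ip]
  amp <- Mod(Fc)
  ph <- ifelse(amp == 0, 0, Arg(Fc))  # zero-amplitude coefficients: phase 0

  new_amp <- amp
  meas <- refl$is_measured
  new_amp[meas] <- refl$f_measured[meas]
  if (any(unmeasured)) {
    cap <- c_w * wilson[unmeasured]
    if (any(!is.finite(cap)))
      stop("Wilson expectation unavailable for a shell with unmeasured terms")
    if (any(cap < 0)) stop("Wilson expectations must be positive")
    new_amp[unmeasured] <- pmin(amp[unmeasured], cap)
  }
  Fnew <- new_amp * exp(1i * ph)
  Farr[ip] <- Fnew
  Farr[grid_linear_index(-hkl, cell$shape)] <- Conj(Fnew)
  rho <- Re(stats::fft(Farr) / prod(cell$shape))
  list(map = density_map(rho, cell), coeffs = Fnew)
}
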