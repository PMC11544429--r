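#' Wrap angles into (-pi, pi]
#'
#' @param x angles in radians.
#' @return wrapped angles.
#' @export
wrap_angle <- function(x) {
  w <- x - 2 * pi * round(x / (2 * pi))
  w[w <= -pi] <- pi
  w
}

check_weights <- function(w, n) {
  if (is.null(w)) return(rep(1, n))
  w <- rep_len(as.numeric(w), n)
  if (any(!is.finite(w)) || any(w < 0) || sum(w) <= 0)
    stop("weights must be non-negative with positive sum")
  w
}

#' Mean absolute phase difference
#'
#' The mean unsigned phase difference between two aligned phase sets, with
#' each difference placed on the circle in [0, pi] via its cosine (never by
#' raw subtraction), optionally weighted by statistical epsilon factors for
#' summations over an asymmetric unit.
#'
#' @param phases1,phases2 aligned phase vectors in radians.
#' @param weights optional non-negative weights (epsilon factors).
#' @param degrees return degrees (default) or radians.
#' @return scalar mean absolute phase difference.
#' @export
mean_abs_phase_diff <- function(phases1, phases2, weights = NULL,
                                degrees = TRUE) {
  n <- length(phases1)
  if (n == 0L) stop("empty phase sets")
  if (length(phases2) != n) stop("phase sets must be aligned and equal length")
  w <- check_weights(weights, n)
  dphi <- acos(pmin(1, pmax(-1, cos(phases1 - phases2))))
  out <- sum(w * dphi) / sum(w)
  if (degrees) out * 180 / pi else out
}

#' Real-space map correlation from amplitudes and phase differences
#'
#' The Pearson correlation coefficient between two density maps, computed in
#' reciprocal space from the Fourier amplitudes and phase differences:
#' sum(w F1 F2 cos dphi) / sqrt(sum(w F1^2) sum(w F2^2)), the sum running
#' over the Friedel-unique reflections with F(000) excluded.  Identical to the
#' voxel-space Pearson correlation of the two synthesized maps.
#'
#' @param f1,f2 amplitude vectors (aligned).
#' @param dphi phase differences in radians, or `NULL` to pass `phases1` and
#'   `phases2` instead.
#' @param phases1,phases2 phase sets used when `dphi` is `NULL`.
#' @param weights optional epsilon weights.
#' @return correlation in `[-1, 1]`.
#' @export
map_correlation <- function(f1, f2, dphi = NULL, phases1 = NULL,
                            phases2 = NULL, weights = NULL) {
  n <- length(f1)
  if (length(f2) != n) stop("amplitude sets must be aligned")
  if (is.null(dphi)) {
    if (is.null(phases1) || is.null(phases2))
      stop("supply dphi or both phase sets")
    dphi <- phases1 - phases2
  }
  if (length(dphi) != n) stop("phase differences must be aligned")
  w <- check_weights(weights, n)
  den <- sqrt(sum(w * f1^2) * sum(w * f2^2))
  if (den == 0) stop("zero-variance map")
  sum(w * f1 * f2 * cos(dphi)) / den
}

#' Fisher-Lee circular correlation coefficient
#'
#' The circular analogue of the Pearson correlation for two aligned phase
#' sets: +1 for positive (rotational) association, -1 for negative
#' (reflective) association, and 0 in expectation for independent sets.
#' Computed via the O(n) expansion of the pairwise sine estimator through the
#' auxiliary trigonometric sums; invariant to independent constant rotations
#' of either set.
#'
#' @param phases1,phases2 aligned phase vectors (n >= 3).
#' @param weights optional epsilon weights.
#' @return estimated circular correlation.
#' @export
fisher_lee_correlation <- function(phases1, phases2, weights = NULL) {
  n <- length(phases1)
  if (n < 3L) stop("need at least 3 paired observations")
  if (length(phases2) != n) stop("phase sets must be aligned")
  w <- check_weights(weights, n)
  sw <- sum(w)
  A <- sum(w * cos(phases1) * cos(phases2))
  B <- sum(w * sin(phases1) * sin(phases2))
  C <- sum(w * cos(phases1) * sin(phases2))
  D <- sum(w * sin(phases1) * cos(phases2))
  E <- sum(w * cos(2 * phases1)); Fs <- sum(w * sin(2 * phases1))
  G <- sum(w * cos(2 * phases2)); H <- sum(w * sin(2 * phases2))
  den2 <- (sw^2 - E^2 - Fs^2) * (sw^2 - G^2 - H^2)
  if (den2 <= .Machine$double.eps * sw^4)
    stop("degenerate phase set: circular correlation undefined when either set has no spread")
  4 * (A * B - C * D) / sqrt(den2)
}

#' First trigonometric moment of a circular sample
#'
#' Sample mean length and mean direction from the component sums
#' C = sum cos(phi), S = sum sin(phi): Rbar = sqrt(C^2 + S^2)/n and
#' phibar = arctan2(S, C).  When Rbar is numerically zero the mean direction
#' is undefined; the summary is flagged rather than silently zeroed.
#'
#' @param phases phase sample in radians (n >= 1).
#' @return list with `mean_direction`, `mean_length`, `n` and
#'   `direction_defined`.
#' @export
circular_moments <- function(phases) {
  n <- length(phases)
  if (n < 1L) stop("empty sample")
  C <- sum(cos(phases)); S <- sum(sin(phases))
  R <- sqrt(C^2 + S^2) / n
  defined <- R > 1e-12
  list(mean_direction = if (defined) atan2(S, C) else NA_real_,
       mean_length = R, n = n, direction_defined = defined)
}

# Mean resultant length of the von Mises distribution, A(kappa) = I1/I0,
# evaluated with exponentially scaled Bessel functions for stability at
# large kappa.
vm_mean_length <- function(kappa) {
  ifelse(kappa == 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

# Bracketed solve of A(kappa) = r on [1e-8, cap].
solve_bessel_ratio <- function(r, cap = 1e4) {
  if (r <= 0) return(0)
  if (vm_mean_length(cap) <= r) return(cap)
  stats::uniroot(function(k) vm_mean_length(k) - r,
                 lower = 1e-8, upper = cap, tol = 1e-10)$root
}

#' Maximum-likelihood von Mises concentration from the mean length
#'
#' Solves A(kappa) = Rbar, where A is the ratio of modified Bessel functions
#' I1/I0, by monotone bracketed root-finding; kappa is capped at 1e4 as
#' Rbar approaches 1 (with a warning for Rbar >= 1).
#'
#' @param r_bar sample mean resultant length in `[0, 1)`.
#' @param n optional sample size (informational; the estimator itself is the
#'   plain maximum-likelihood solution).
#' @return concentration estimate kappa >= 0.
#' @export
fit_von_mises_kappa <- function(r_bar, n = NULL) {
  if (length(r_bar) != 1L || !is.finite(r_bar) || r_bar < 0)
    stop("r_bar must be a single value in [0, 1]")
  if (r_bar >= 1) {
    warning("mean length >= 1: concentration capped at 1e4")
    return(1e4)
  }
  solve_bessel_ratio(r_bar)
}

#' Joint amplitude/phase model for a structure-factor trajectory window
#'
#' Fits the independent Gaussian-on-amplitude, von Mises-on-phase model to
#' the trajectory of a single Fourier coefficient over a stationary window:
#' the Gaussian parameters are the sample mean and standard deviation of the
#' amplitudes; the von Mises location is the sample mean direction and the
#' concentration is the maximum-likelihood solution from the mean length.
#' The fitted joint density can be evaluated at any (F, phi) point, e.g. for
#' isocontour plots in the complex plane.
#'
#' @param amplitudes amplitude trajectory (length >= 3).
#' @param phases phase trajectory, aligned with `amplitudes`.
#' @return list with `amplitude` (`mu`, `sigma`), `circular` (a
#'   [circular_moments()] summary plus `kappa`), and `density`, a function of
#'   `(f, phi)` evaluating the joint PDF.  Zero amplitude variance is allowed
#'   (`sigma = 0`) but flagged via `degenerate`.
#' @export
fit_joint_sf_pdf <- function(amplitudes, phases) {
  n <- length(amplitudes)
  if (n < 3L) stop("window length must be >= 3")
  if (length(phases) != n) stop("amplitudes and phases must be aligned")
  mu <- mean(amplitudes)
  sigma <- stats::sd(amplitudes)
  cm <- circular_moments(phases)
  kappa <- if (cm$mean_length >= 1 - 1e-12) 1e4 else
    solve_bessel_ratio(cm$mean_length)
  mu_vm <- if (cm$direction_defined) cm$mean_direction else 0
  degenerate <- sigma == 0
  density <- function(f, phi) {
    pf <- if (degenerate) ifelse(f == mu, Inf, 0) else
      stats::dnorm(f, mean = mu, sd = sigma)
    pp <- exp(kappa * (cos(phi - mu_vm) - 1)) /
      (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
    pf * pp
  }
  list(amplitude = list(mu = mu, sigma = sigma),
       circular = c(cm, list(kappa = kappa)),
       degenerate = degenerate,
       density = density)
}
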