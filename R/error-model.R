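#' von Mises concentration for a target circular variance
#'
#' Inverts V = 1 - I1(kappa)/I0(kappa) by bracketed root-finding on the
#' Bessel-function ratio.  V = 1 corresponds to the uniform limit kappa = 0;
#' V = 0 would require infinite concentration and is an error (callers must
#' special-case exact phases).  For very small V the asymptotic branch
#' kappa = 1/(2V) is used.
#'
#' @param v circular variance in (0, 1].
#' @return concentration parameter kappa.
#' @export
kappa_from_variance <- function(v) {
  if (length(v) != 1L || !is.finite(v)) stop("v must be a single finite value")
  if (v <= 0) stop("V <= 0 implies infinite concentration; handle exact phases separately")
  if (v > 1) stop("circular variance cannot exceed 1")
  if (v == 1) return(0)
  if (v < 1e-3) return(1 / (2 * v))  # large-kappa asymptote: V ~ 1/(2 kappa)
  solve_bessel_ratio(1 - v)
}

#' Wrapped-Bernoulli success probability for a target circular variance
#'
#' The centric error distribution places probability p on the model phase and
#' q = 1 - p on the model phase plus pi.  Its mean resultant length is
#' |p - q| = |2p - 1|, so the circular variance is V = 1 - |2p - 1|.  Solving
#' for the branch p >= 1/2 gives p = 1 - V/2: p = 1 introduces no phase
#' error and p = 0.5 fully randomizes the centric phases.
#'
#' @param v circular variance in `[0, 1]`.
#' @return probability p in `[1/2, 1]`.
#' @export
p_from_variance <- function(v) {
  if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
    stop("v must be a single value in [0, 1]")
  1 - v / 2
}

#' Error specification for controlled phase corruption
#'
#' Bundles a circular variance with the derived von Mises concentration
#' (acentric errors) and wrapped-Bernoulli probability (centric errors) and a
#' seed.  The same distributions are applied to all resolution shells.
#'
#' @param v circular variance in `[0, 1]` shared by the acentric and centric
#'   error distributions.
#' @param seed integer seed for the per-reflection random substreams.
#' @return list of class `error_spec` with elements `v`, `kappa`, `p`, `seed`.
#' @export
error_spec <- function(v, seed = 1L) {
  if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
    stop("v must be a single value in [0, 1]")
  kappa <- if (v == 0) Inf else kappa_from_variance(v)
  structure(list(v = v, kappa = kappa, p = p_from_variance(v),
                 seed = as.integer(seed)),
            class = "error_spec")
}

# Precomputed Best-Fisher envelope constants for a given kappa.
best_fisher_setup <- function(kappa) {
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  list(r = (1 + rho^2) / (2 * rho))
}

# One Best-Fisher acceptance-rejection pass on n candidates; returns
# cos(theta) for accepted draws (NA where rejected).
best_fisher_pass <- function(n, kappa, r) {
  u1 <- stats::runif(n); u2 <- stats::runif(n)
  z <- cos(pi * u1)
  f <- (1 + r * z) / (r + z)
  c0 <- kappa * (r - f)
  ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
  f[!ok] <- NA_real_
  f
}

#' Sample from the von Mises distribution
#'
#' Generates i.i.d. von Mises(mu, kappa) variates from uniform random
#' variates using the Best-Fisher acceptance-rejection scheme; kappa = 0
#' falls back to the uniform distribution on (-pi, pi].  Draws from the
#' current R random number generator state.
#'
#' @param n number of samples.
#' @param mu location parameter (mean direction), radians.
#' @param kappa concentration parameter (>= 0).
#' @return numeric vector of phases in (-pi, pi].
#' @export
sample_von_mises <- function(n, mu = 0, kappa) {
  n <- as.integer(n)
  if (n < 1L) return(numeric(0))
  if (length(kappa) != 1L || !is.finite(kappa) || kappa < 0)
    stop("kappa must be a single finite value >= 0")
  if (kappa == 0) return(wrap_angle(stats::runif(n, -pi, pi)))
  st <- best_fisher_setup(kappa)
  out <- rep(NA_real_, n)
  need <- n
  while (need > 0L) {
    f <- best_fisher_pass(need, kappa, st$r)
    acc <- !is.na(f)
    if (any(acc)) {
      slots <- which(is.na(out))[seq_len(sum(acc))]
      u3 <- stats::runif(sum(acc))
      out[slots] <- sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f[acc])))
      need <- need - sum(acc)
    }
  }
  wrap_angle(mu + out)
}

# Deterministic positive substream key below 2^31 from (seed, h, k, l).
reflection_stream_key <- function(seed, h, k, l) {
  m <- 2147483629
  k0 <- (abs(as.numeric(seed)) + 11) %% m
  for (v in list(h, k, l)) {
    k0 <- (k0 * 69069 + (as.numeric(v) + 4096)) %% m
  }
  as.integer(k0)
}

#' Corrupt reference phases with a controlled circular error
#'
#' Replaces each acentric reference phase with a von Mises(phase_ref, kappa)
#' variate and flips each centric phase to phase_ref + pi with probability
#' q = 1 - p, with kappa and p derived from the common circular variance of
#' the error specification.  Amplitudes are untouched and the same error
#' distributions are applied at every resolution.  Each reflection draws from
#' its own random substream keyed by (seed, h, k, l), so the corruption is
#' independent of the storage order of the reflections.
#'
#' @param refl a [reflection_set()] with reference phases and centric flags.
#' @param spec an [error_spec()].
#' @return the reflection set with corrupted `phase_ref` column.
#' @export
corrupt_phases <- function(refl, spec) {
  stopifnot(inherits(spec, "error_spec"))
  if (any(is.na(refl$phase_ref))) stop("missing reference phases")
  n <- nrow(refl)
  if (spec$v == 0) return(refl)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })

  kappa <- spec$kappa
  q <- 1 - spec$p
  st <- if (kappa > 0 && is.finite(kappa)) best_fisher_setup(kappa) else NULL
  phases <- refl$phase_ref
  keys <- reflection_stream_key(spec$seed, refl$h, refl$k, refl$l)
  for (i in seq_len(n)) {
    set.seed(keys[i])
    if (refl$centric[i]) {
      if (stats::runif(1) < q) phases[i] <- wrap_angle(phases[i] + pi)
    } else if (kappa == 0) {
      phases[i] <- wrap_angle(stats::runif(1, -pi, pi))
    } else {
      repeat {
        f <- best_fisher_pass(1L, kappa, st$r)
        if (!is.na(f)) {
          u3 <- stats::runif(1)
          phases[i] <- wrap_angle(refl$phase_ref[i] +
                                    sign(u3 - 0.5) * acos(min(1, max(-1, f))))
          break
        }
      }
    }
  }
  refl$phase_ref <- phases
  refl
}
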