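#' Algorithm configuration for an iterative projection run
#'
#' Validates the adjustable parameter against the admissible range of each
#' algorithm: DM requires beta in (-1, 1) with beta != 0 (the update rule
#' involves 1/beta and is not defined at 0); RRR and revRRR require beta in
#' (0, 2); RAAR requires beta in (0, 1]; ER takes no beta.
#'
#' @param algorithm one of `"ER"`, `"DM"`, `"RRR"`, `"revRRR"`, `"RAAR"`.
#' @param beta adjustable parameter (ignored for ER).
#' @param n_iterations fixed run length (runs are never stopped early).
#' @param envelope_update re-estimate the envelope from the monitored
#'   solution estimate on every iteration (default `TRUE`).
#' @param monitored_estimate which solution estimate is recorded and scored:
#'   `"B"` (satisfying the Fourier amplitude constraints; the default for ER,
#'   DM, revRRR and RAAR) or `"A"` (satisfying the real-space constraints;
#'   the default for RRR, whose trajectory analysis follows the
#'   constraint-A-satisfying estimate).
#' @param seed integer seed controlling any randomness in the run setup.
#' @param trailing_window how many final iterations of complex structure
#'   factors to retain for trajectory analysis (default 30).
#' @param store_every optionally also keep every `store_every`-th iteration
#'   over the whole run (0 = none), for plotting.
#' @return object of class `ipa_config`.
#' @export
ipa_config <- function(algorithm = c("ER", "DM", "RRR", "revRRR", "RAAR"),
                       beta = NULL, n_iterations = 100L,
                       envelope_update = TRUE, monitored_estimate = NULL,
                       seed = 1L, trailing_window = 30L, store_every = 0L) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "ER") {
    if (!is.null(beta)) stop("ER has no adjustable parameter")
  } else {
    if (is.null(beta) || length(beta) != 1L || !is.finite(beta))
      stop(algorithm, " requires a finite beta")
    check_beta(algorithm, beta)
  }
  if (is.null(monitored_estimate))
    monitored_estimate <- if (algorithm == "RRR") "A" else "B"
  monitored_estimate <- match.arg(monitored_estimate, c("A", "B"))
  n_iterations <- as.integer(n_iterations)
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  structure(list(algorithm = algorithm, beta = beta,
                 n_iterations = n_iterations,
                 envelope_update = isTRUE(envelope_update),
                 monitored_estimate = monitored_estimate,
                 seed = as.integer(seed),
                 trailing_window = min(as.integer(trailing_window),
                                       n_iterations),
                 store_every = as.integer(store_every)),
            class = "ipa_config")
}

check_beta <- function(algorithm, beta) {
  switch(algorithm,
    DM = if (beta <= -1 || beta >= 1 || beta == 0)
      stop("DM requires beta in (-1, 1), beta != 0"),
    RRR = ,
    revRRR = if (beta <= 0 || beta >= 2)
      stop(algorithm, " requires beta in (0, 2)"),
    RAAR = if (beta <= 0 || beta > 1)
      stop("RAAR requires beta in (0, 1]"))
  invisible(TRUE)
}

#' Error-reduction (Gerchberg-Saxton) update
#'
#' One iteration of classical density modification: the Fourier-space
#' projection followed by the real-space projection, x' = P_A(P_B(x)).
#'
#' @param x current iterate (numeric array or vector).
#' @param p_a,p_b projection functions onto the real-space (A) and
#'   Fourier-space (B) constraint sets.
#' @return list with the new iterate `x` and the two solution estimates
#'   `estimate_A` (= x', satisfies A) and `estimate_B` (satisfies B).
#' @export
er_update <- function(x, p_a, p_b) {
  b <- p_b(x)
  a <- p_a(b)
  list(x = a, estimate_A = a, estimate_B = b)
}

#' Difference-map update
#'
#' The difference-map iteration with the estimate maps tied to 1/beta:
#' x' = x + beta * (P_A(f_B(x)) - P_B(f_A(x))), where
#' f_A(x) = (1 - 1/beta) P_A(x) + x/beta and
#' f_B(x) = (1 + 1/beta) P_B(x) - x/beta.  Changing the sign of beta swaps
#' the roles of the two constraints.  Four projection applications are used
#' per iteration.  When the iterate is stationary the two solution estimates
#' coincide and represent a solution satisfying both constraint sets.
#'
#' @inheritParams er_update
#' @param beta adjustable parameter in (-1, 1), nonzero.
#' @return list with `x`, `estimate_A` (satisfies A) and `estimate_B`
#'   (satisfies B; the estimate monitored against the known solution).
#' @export
dm_update <- function(x, p_a, p_b, beta) {
  check_beta("DM", beta)
  est <- dm_estimates(x, p_a, p_b, beta)
  list(x = x + beta * (est$estimate_A - est$estimate_B),
       estimate_A = est$estimate_A, estimate_B = est$estimate_B)
}

#' Difference-map solution estimates
#'
#' The two constraint-satisfying estimates of the difference map:
#' `estimate_A = P_A((1 + 1/beta) P_B(x) - x/beta)` and
#' `estimate_B = P_B((1 - 1/beta) P_A(x) + x/beta)`.
#'
#' @inheritParams dm_update
#' @return list with `estimate_A` and `estimate_B`.
#' @export
dm_estimates <- function(x, p_a, p_b, beta) {
  check_beta("DM", beta)
  g <- 1 / beta
  f_b <- (1 + g) * p_b(x) - g * x
  f_a <- (1 - g) * p_a(x) + g * x
  list(estimate_A = p_a(f_b), estimate_B = p_b(f_a))
}

#' Relaxed-reflect-reflect update
#'
#' x' = x + beta * (P_B(2 P_A(x) - x) - P_A(x)).  Exactly one application of
#' each projection per iteration (half the cost of the difference map).  At
#' beta = 1 the iteration is the Douglas-Rachford algorithm.
#'
#' @inheritParams er_update
#' @param beta adjustable parameter in (0, 2).
#' @return list with `x`, `estimate_A` (= P_A(x), satisfies A; followed for
#'   trajectory analysis) and `estimate_B` (= P_B(2 P_A(x) - x), satisfies
#'   B; monitored against the known solution).
#' @export
rrr_update <- function(x, p_a, p_b, beta) {
  check_beta("RRR", beta)
  a <- p_a(x)
  c <- p_b(2 * a - x)
  list(x = x + beta * (c - a), estimate_A = a, estimate_B = c)
}

#' Reversed relaxed-reflect-reflect update
#'
#' The RRR iteration with the projection roles interchanged:
#' x' = x + beta * (P_A(2 P_B(x) - x) - P_B(x)).
#'
#' @inheritParams rrr_update
#' @return list with `x`, `estimate_A` (= P_A(2 P_B(x) - x)) and
#'   `estimate_B` (= P_B(x)).
#' @export
revrrr_update <- function(x, p_a, p_b, beta) {
  check_beta("revRRR", beta)
  b <- p_b(x)
  d <- p_a(2 * b - x)
  list(x = x + beta * (d - b), estimate_A = d, estimate_B = b)
}

#' Relaxed averaged alternating reflections update
#'
#' x' = beta * (x + P_A(2 P_B(x) - x)) + (1 - 2 beta) * P_B(x), i.e. the
#' beta-relaxation of the averaged alternating reflections map toward the
#' Fourier-space projection.  At beta = 1 the iteration coincides with the
#' reversed RRR iteration at beta = 1; at beta = 0 it would reduce to the
#' Fourier-space projection alone (no real-space projection), which is why
#' small beta is unproductive.  Two projection applications per iteration.
#' The solution estimate satisfying the Fourier constraints is taken as
#' P_B(x) for every beta (the reversed-RRR estimate formula), the pragmatic
#' choice since for beta != 1 the iterate admits no exact estimate.
#'
#' @inheritParams er_update
#' @param beta adjustable parameter in (0, 1].
#' @return list with `x`, `estimate_A` (= P_A(2 P_B(x) - x)) and
#'   `estimate_B` (= P_B(x)).
#' @export
raar_update <- function(x, p_a, p_b, beta) {
  check_beta("RAAR", beta)
  b <- p_b(x)
  d <- p_a(2 * b - x)
  list(x = beta * (x + d) + (1 - 2 * beta) * b,
       estimate_A = d, estimate_B = b)
}

ipa_step <- function(config, x, p_a, p_b) {
  switch(config$algorithm,
         ER = er_update(x, p_a, p_b),
         DM = dm_update(x, p_a, p_b, config$beta),
         RRR = rrr_update(x, p_a, p_b, config$beta),
         revRRR = revrrr_update(x, p_a, p_b, config$beta),
         RAAR = raar_update(x, p_a, p_b, config$beta))
}

#' Run an iterative projection algorithm on reflection data
#'
#' Executes a fixed-length IPA run with the solvent-flatness +
#' histogram-equivalence projection in real space and the measured-amplitude
#' projection (with Wilson restraints) in Fourier space.  The molecular
#' envelope is re-estimated from the monitored solution estimate once per
#' iteration (iteration 0 may use a supplied starting envelope, e.g. the
#' known one).  Per iteration the run records the monitored estimate's
#' complex structure factors (full precision over a trailing window,
#' optionally decimated over the full run) and, when reference phases are
#' available, the real-space correlation with the reference map computed
#' from amplitudes and phase differences.
#'
#' @param refl a [reflection_set()] with measured amplitudes (and reference
#'   phases if agreement is to be scored).
#' @param prior a [density_prior()] with a known solvent fraction.
#' @param config an [ipa_config()].
#' @param start_phases starting phases aligned with `refl`; the starting map
#'   is then synthesized from the measured amplitudes with these phases.
#'   Alternatively supply `start_map`.
#' @param start_map a [density_map()] starting iterate.
#' @param window_radius envelope local-variance window radius in Angstrom.
#' @param envelope0 optional starting [envelope()] used at iteration 0
#'   instead of estimating one from the starting map.
#' @param c_w Wilson restraint multiplier for unmeasured terms.
#' @return object of class `trajectory_record`: a list with per-iteration
#'   `correlation`, the trailing-window complex structure factors `sf_window`
#'   (reflections x window), optional decimated record `sf_decimated`,
#'   the final monitored estimate map `final_map`, the final `envelope`, the
#'   `config`, the reflection set and the window iteration numbers.
#' @export
ipa_run <- function(refl, prior, config, start_phases = NULL,
                    start_map = NULL, window_radius = 4, envelope0 = NULL,
                    c_w = 2) {
  stopifnot(inherits(config, "ipa_config"))
  cell <- attr(refl, "cell")
  if (is.null(cell)) stop("reflection set carries no cell")
  fs <- prior$solvent_fraction
  if (is.null(fs)) stop("prior carries no solvent fraction")
  f000 <- f000_from_prior(prior, cell)

  if (is.null(start_map)) {
    if (is.null(start_phases)) stop("supply start_phases or start_map")
    if (length(start_phases) != nrow(refl)) stop("start_phases misaligned")
    amp <- ifelse(refl$is_measured, refl$f_measured, 0)
    start_map <- structure_factors_to_density(amp * exp(1i * start_phases),
                                              refl, cell, f000 = f000)
  }
  check_same_cell(cell, map_cell(start_map))

  kernel <- spherical_kernel_fft(cell, window_radius)
  wilson <- if (all(refl$is_measured)) NULL else wilson_expectations(refl)
  env <- if (is.null(envelope0))
    estimate_envelope(start_map, fs, window_radius, kernel = kernel)
  else envelope0

  hkl <- as.matrix(refl[, c("h", "k", "l")])
  idx <- grid_linear_index(hkl, cell$shape)
  sel <- refl$is_measured & is.finite(refl$phase_ref)
  have_ref <- any(sel)
  f_ref <- refl$f_measured[sel]
  ph_ref <- refl$phase_ref[sel]
  w_eps <- refl$epsilon[sel]

  n_it <- config$n_iterations
  w <- config$trailing_window
  sf_window <- matrix(complex(1), nrow(refl), w)
  win_iter <- integer(w)
  correlation <- rep(NA_real_, n_it)
  dec <- config$store_every > 0L
  sf_dec <- if (dec) list() else NULL

  x <- unclass(start_map)
  stash <- new.env(parent = emptyenv())
  for (it in seq_len(n_it)) {
    p_a <- local({
      env_now <- env
      function(z) unclass(project_real(density_map(z, cell), env_now, prior))
    })
    p_b <- function(z) {
      r <- project_fourier_coeffs(density_map(z, cell), refl,
                                  wilson = wilson, c_w = c_w)
      stash$coeffs <- r$coeffs
      unclass(r$map)
    }
    step <- ipa_step(config, x, p_a, p_b)
    x <- step$x
    if (any(!is.finite(x)))
      stop("iterate diverged (non-finite values) at iteration ", it)
    est <- if (config$monitored_estimate == "A") step$estimate_A else
      step$estimate_B
    # every update rule's B estimate is the output of its final Fourier
    # projection, whose coefficients are already in hand
    Fest <- if (config$monitored_estimate == "B") stash$coeffs else
      stats::fft(est, inverse = TRUE)[idx]
    if (have_ref)
      correlation[it] <- map_correlation(Mod(Fest[sel]), f_ref,
                                         dphi = Arg(Fest[sel]) - ph_ref,
                                         weights = w_eps)
    slot <- ((it - 1L) %% w) + 1L
    sf_window[, slot] <- Fest
    win_iter[slot] <- it
    if (dec && it %% config$store_every == 0L)
      sf_dec[[length(sf_dec) + 1L]] <- Fest
    if (config$envelope_update)
      env <- estimate_envelope(density_map(est, cell), fs, window_radius,
                               kernel = kernel)
  }
  ord <- order(win_iter)
  structure(list(correlation = correlation,
                 sf_window = sf_window[, ord, drop = FALSE],
                 window_iterations = win_iter[ord],
                 sf_decimated = if (dec) do.call(cbind, sf_dec) else NULL,
                 final_map = density_map(
                   if (config$monitored_estimate == "A") step$estimate_A
                   else step$estimate_B, cell),
                 final_iterate = density_map(x, cell),
                 envelope = env, config = config, refl = refl),
            class = "trajectory_record")
}

#' @export
print.trajectory_record <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("IPA trajectory: %s%s, %d iterations, window %d\n",
              cfg$algorithm,
              if (is.null(cfg$beta)) "" else sprintf(" (beta = %g)", cfg$beta),
              cfg$n_iterations, ncol(x$sf_window)))
  if (any(is.finite(x$correlation)))
    cat(sprintf("  map correlation vs reference: start %.3f, final %.3f\n",
                x$correlation[1], x$correlation[length(x$correlation)]))
  invisible(x)
}
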