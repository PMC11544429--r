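#' Per-reflection circular and amplitude summaries of a trajectory window
#'
#' For each reflection, computes the first trigonometric moment of the
#' phase-angle trajectory over the final `window` recorded iterations (sample
#' mean direction and mean length, valid for centric and acentric terms
#' alike) together with the sample mean and standard deviation of the
#' amplitudes, and the maximum-likelihood von Mises concentration implied by
#' the mean length.
#'
#' @param record a `trajectory_record` from [ipa_run()].
#' @param window number of final iterations to summarize (must not exceed the
#'   stored trailing window; >= 2).
#' @return data frame with one row per reflection: `h,k,l`,
#'   `mean_direction`, `mean_length`, `kappa`, `amp_mean`, `amp_sd`, `n`,
#'   `direction_defined`.
#' @export
trajectory_summaries <- function(record, window = NULL) {
  sfw <- record$sf_window
  if (is.null(window)) window <- ncol(sfw)
  if (window < 2L) stop("window must cover at least 2 iterations")
  if (window > ncol(sfw))
    stop("window exceeds the stored trailing window (", ncol(sfw), ")")
  sfw <- sfw[, ncol(sfw) - window + seq_len(window), drop = FALSE]
  amp <- Mod(sfw)
  Cs <- rowMeans(cos(Arg(sfw)))
  Ss <- rowMeans(sin(Arg(sfw)))
  R <- sqrt(Cs^2 + Ss^2)
  defined <- R > 1e-12
  kappa <- vapply(R, function(r)
    if (r >= 1 - 1e-12) 1e4 else solve_bessel_ratio(r), numeric(1))
  refl <- record$refl
  data.frame(h = refl$h, k = refl$k, l = refl$l,
             mean_direction = ifelse(defined, atan2(Ss, Cs), NA_real_),
             mean_length = R, kappa = kappa,
             amp_mean = rowMeans(amp),
             amp_sd = apply(amp, 1L, stats::sd),
             n = window, direction_defined = defined)
}

#' Fourier synthesis from trajectory-averaged phases
#'
#' Synthesizes a density map using the per-reflection mean direction of the
#' stationary trajectory window as the phase, combined with either the
#' unweighted measured amplitudes or the measured amplitudes weighted by the
#' mean length of the phase-angle distribution.  Reflections whose mean
#' direction is undefined (mean length numerically zero) are treated as
#' phase-unknown and given weight zero.
#'
#' @param summaries output of [trajectory_summaries()].
#' @param refl the [reflection_set()] the summaries are aligned to.
#' @param mode `"unweighted"` or `"weighted"` (by mean length).
#' @param f000 DC term for the synthesis (defaults to the set's `f000`).
#' @return a [density_map()].
#' @export
synthesize_averaged_map <- function(summaries, refl,
                                    mode = c("unweighted", "weighted"),
                                    f000 = NULL) {
  mode <- match.arg(mode)
  if (nrow(summaries) != nrow(refl)) stop("summaries misaligned with reflections")
  amp <- ifelse(refl$is_measured, refl$f_measured, 0)
  wgt <- if (mode == "weighted") summaries$mean_length else 1
  wgt <- wgt * as.numeric(summaries$direction_defined)
  phase <- ifelse(summaries$direction_defined, summaries$mean_direction, 0)
  structure_factors_to_density(amp * wgt * exp(1i * phase), refl,
                               f000 = f000)
}

#' Polish a density estimate with the error-reduction algorithm
#'
#' Applies a fixed number of ER (classical density-modification) iterations
#' to a final solution estimate to damp the fluctuations left by a
#' relaxation algorithm; the conventional baseline against which trajectory
#' averaging is compared.  Deterministic given its input.
#'
#' @param map starting [density_map()] (e.g. the final solution estimate).
#' @param refl the [reflection_set()].
#' @param prior the [density_prior()].
#' @param n_iter number of ER iterations (default 30).
#' @param window_radius envelope window radius in Angstrom.
#' @param envelope0 optional starting envelope.
#' @param envelope_update re-estimate the envelope each iteration (default
#'   `TRUE`, matching the main run loop).
#' @return the polished monitored-estimate [density_map()].
#' @export
er_polish <- function(map, refl, prior, n_iter = 30, window_radius = 4,
                      envelope0 = NULL, envelope_update = TRUE) {
  cfg <- ipa_config("ER", n_iterations = n_iter, trailing_window = 2L,
                    envelope_update = envelope_update)
  rec <- ipa_run(refl, prior, cfg, start_map = map,
                 window_radius = window_radius, envelope0 = envelope0)
  rec$final_map
}

#' Phase-retrieval transfer function
#'
#' Per reflection, the amplitude of the mean complex reconstructed
#' coefficient over the stationary window, normalized by the measured
#' amplitude; per shell, the epsilon-weighted mean over equal-count
#' resolution shells.  Values may slightly exceed 1 when reconstructed
#' amplitudes exceed the measured ones and are reported unclipped.
#' Reflections with zero (or missing) measured amplitude are excluded and
#' counted.
#'
#' @param record a `trajectory_record` from [ipa_run()].
#' @param window stationary window length (defaults to the stored window).
#' @param n_shells number of resolution shells for the shell means.
#' @return list with `per_reflection` (data frame `h,k,l,prtf,mean_length`),
#'   `per_shell` (data frame `shell,d_max,d_min,prtf`), and `n_excluded`.
#' @export
prtf <- function(record, window = NULL, n_shells = 8) {
  sfw <- record$sf_window
  if (is.null(window)) window <- ncol(sfw)
  if (window > ncol(sfw)) stop("window exceeds the stored trailing window")
  sfw <- sfw[, ncol(sfw) - window + seq_len(window), drop = FALSE]
  refl <- record$refl
  fmeas <- ifelse(refl$is_measured, refl$f_measured, NA_real_)
  ok <- is.finite(fmeas) & fmeas > 0
  mean_sf <- rowMeans(sfw)
  val <- rep(NA_real_, nrow(refl))
  val[ok] <- Mod(mean_sf[ok]) / fmeas[ok]
  per_refl <- data.frame(h = refl$h, k = refl$k, l = refl$l, prtf = val,
                         mean_length = sqrt(rowMeans(cos(Arg(sfw)))^2 +
                                              rowMeans(sin(Arg(sfw)))^2))
  per_shell <- NULL
  if (!all(is.na(refl$d))) {
    sh <- resolution_shells(refl, n_shells)
    w <- refl$epsilon
    agg <- vapply(seq_len(n_shells), function(s) {
      i <- sh$shell == s & ok
      if (!any(i)) return(NA_real_)
      sum(w[i] * val[i]) / sum(w[i])
    }, numeric(1))
    per_shell <- cbind(sh$limits, prtf = agg)
  }
  list(per_reflection = per_refl, per_shell = per_shell,
       n_excluded = sum(!ok))
}

#' Stationarity diagnostics for a trajectory record
#'
#' Splits the trailing window into halves and compares the per-reflection
#' mean directions between them; the run is flagged stationary when the
#' amplitude-weighted mean absolute direction shift is below `threshold`
#' radians and the global agreement metric shows no systematic drift across
#' the window.  Used for reporting only - runs are fixed-length and never
#' stopped early.
#'
#' @param record a `trajectory_record` from [ipa_run()].
#' @param threshold mean direction-shift threshold in radians (default 0.1).
#' @return list with `stationary` (flag), `mean_direction_shift` (radians,
#'   amplitude-weighted), `metric_drift` (change in the monitored correlation
#'   across the window, when available) and the per-reflection `shift`
#'   vector.
#' @export
stationarity_report <- function(record, threshold = 0.1) {
  sfw <- record$sf_window
  w <- ncol(sfw)
  if (w < 4L) stop("need a trailing window of at least 4 iterations")
  half <- w %/% 2L
  first <- sfw[, seq_len(half), drop = FALSE]
  second <- sfw[, (w - half + 1L):w, drop = FALSE]
  dir1 <- atan2(rowMeans(sin(Arg(first))), rowMeans(cos(Arg(first))))
  dir2 <- atan2(rowMeans(sin(Arg(second))), rowMeans(cos(Arg(second))))
  shift <- abs(wrap_angle(dir2 - dir1))
  amp <- rowMeans(Mod(sfw))
  msd <- sum(amp * shift) / sum(amp)
  drift <- NA_real_
  corr <- record$correlation
  if (any(is.finite(corr))) {
    iters <- record$window_iterations
    drift <- corr[iters[length(iters)]] - corr[iters[1]]
  }
  stationary <- msd < threshold &&
    (!is.finite(drift) || abs(drift) < 0.05)
  list(stationary = stationary, mean_direction_shift = msd,
       metric_drift = drift, shift = shift)
}
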