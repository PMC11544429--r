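---
title: "Iterative projection algorithms for crystallographic phase retrieval: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative projection algorithms for crystallographic phase retrieval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Crystallographic phase retrieval asks for an electron density map whose
Fourier amplitudes match the measured structure-factor amplitudes and which
simultaneously looks like a protein crystal: a flat solvent region occupying
a known volume fraction, and a protein region whose density values follow a
characteristic histogram. `ipaphase` treats this as a two-set feasibility
problem on the grid-sampled density. The Fourier-space constraint set *B*
contains every map whose amplitudes at the measured reflections equal the
measured values; the real-space constraint set *A* contains every map that
is constant over the solvent region of the current molecular envelope and
whose protein-region values realize the reference histogram. Because the
amplitude constraint is nonconvex, simple alternation between the two sets
(classical density modification) only works near the solution; the package
therefore implements the family of relaxation schemes that are used for
nonconvex feasibility problems, all built from the two projections:

* **ER** (error reduction / Gerchberg–Saxton): `x' = P_A(P_B(x))`.
* **DM** (difference map, one-parameter form with the estimate maps tied to
  `1/beta`): `x' = x + beta * (P_A(f_B(x)) - P_B(f_A(x)))` with
  `f_A(x) = (1 - 1/beta) P_A(x) + x/beta`,
  `f_B(x) = (1 + 1/beta) P_B(x) - x/beta`, `beta` in (-1, 1), nonzero.
  Changing the sign of `beta` swaps the constraint roles.
* **RRR** (relaxed reflect–reflect): `x' = x + beta * (P_B(2P_A(x) - x) - P_A(x))`,
  `beta` in (0, 2); at `beta = 1` it is the Douglas–Rachford iteration.
* **revRRR**: the same with the projections interchanged.
* **RAAR**: `x' = beta * (x + P_A(2P_B(x) - x)) + (1 - 2 beta) * P_B(x)`,
  `beta` in (0, 1]; at `beta = 1` it coincides with revRRR at `beta = 1`,
  and as `beta` decreases it relaxes toward the Fourier projection alone.

For DM, RRR, revRRR and RAAR the carried vector `x` is a surrogate — not
itself a density estimate. Each iteration produces two *solution estimates*,
one satisfying each constraint set exactly; when the iterate becomes
stationary the two estimates coincide and solve the problem. Following
standard practice, performance against a known solution is monitored on the
estimate satisfying the Fourier constraints (`estimate_B`), while
trajectory analysis for RRR follows the real-space-satisfying estimate
(`estimate_A`); both are configurable via `ipa_config(monitored_estimate=)`.

### Transcription and orientation of the update rules

The projection order inside RRR/revRRR/RAAR is fixed by three published
facts that must hold simultaneously: RAAR relaxes the averaged alternating
reflections map toward the *Fourier* projection (so at `beta = 0` no
real-space projection remains), RAAR at `beta = 1` equals revRRR at
`beta = 1`, and RRR/revRRR/RAAR each cost exactly one application of each
projection per iteration (DM costs four). The forms above are the unique
orientation satisfying all three, and the test suite asserts each property
numerically.

## The projections

**Fourier projection (`project_fourier`).** The map is transformed with the
`e^{+2*pi*i*h.x}` convention (phases in `(-pi, pi]`, `F(000)` carried
separately and never projected). Measured reflections have their amplitude
replaced by the measured value, keeping the phase (a zero-amplitude
coefficient is first assigned phase 0). Unmeasured reflections are
restrained by Wilson statistics: their amplitude is capped at
`c_w * <|F|>_shell` (default `c_w = 2`), the shell expectation estimated
from the measured reflections in the same equal-count resolution shell.
Coefficients outside the stored reflection list are left unchanged — they
are unconstrained, which keeps the operation an exact (idempotent,
distance-minimizing) projection and lets a full-resolution synthetic truth
be an exact fixed point. The cap multiplier 2 was chosen once as "a few
times the expected amplitude" (the restraint exists only to stop unmeasured
terms exploding); results are insensitive to it because unmeasured terms
are rare in the simulated data.

**Real-space projection (`project_real`).** Solvent voxels are set to the
mean of the input solvent values (the distance-minimizing way to make a
region flat); protein voxels are replaced by the reference quantile at
their input rank, i.e. an order-preserving transport onto the reference
histogram, with linear interpolation between order statistics and ties
broken by storage order so the result is deterministic and idempotent.

**Envelope determination (`estimate_envelope`).** The molecular envelope is
re-estimated each iteration by thresholding the local variance of the
monitored solution estimate, computed in a spherical window with periodic
wrap as smoothed-mean-of-squares minus squared smoothed mean. The threshold
is the solvent-fraction quantile of the local variance, with ties broken by
voxel index so that exactly `ceiling(f * n_voxels)` voxels become solvent.
The exported default window radius is 4 Å, the scale commonly used for
real protein maps; the package's toy-crystal experiments pass 1.7 Å
because the desk-scale protein sphere (radius 8–16 Å) requires a window
small relative to the molecular dimension — with a 4 Å window the
boundary shell that the window cannot classify is a large fraction of the
protein volume and envelope feedback destabilizes the runs.

## The circular error model

Controlled corruption replaces each acentric reference phase by a von
Mises variate centered on it, and flips each centric phase by pi with
probability `q = 1 - p`. Both distributions are parameterized by a common
circular variance `V`: the von Mises concentration solves
`1 - I1(kappa)/I0(kappa) = V` by bracketed bisection (asymptote
`kappa = 1/(2V)` below `V = 1e-3`), and the two-point distribution has mean
resultant length `|2p - 1|`, giving `p = 1 - V/2` (`p = 1`: no error;
`p = 0.5`: fully randomized centric phases). Sampling uses the Best–Fisher
acceptance–rejection scheme, falling back to the uniform circle at
`kappa = 0`. Each reflection draws from a substream keyed by
`(seed, h, k, l)`, so corruption commutes with reflection reordering and
replicates are reproducible term by term. Deliberately, the same error
distributions are applied at every resolution and amplitude.

Two consequences calibrate the whole simulation design: the mean absolute
phase difference after corruption is approximately 60, 68, 72 and 75
degrees at `V` = 0.6, 0.7, 0.75 and 0.8, and the amplitude-weighted map
correlation between original and corrupted data is approximately `1 - V`
(both expectations hold exactly for the first moment since
`E[cos(error)] = 1 - V` for either distribution).

## Agreement statistics

* `mean_abs_phase_diff`: mean unsigned phase difference, each difference
  placed in `[0, pi]` through its cosine, optionally epsilon-weighted.
* `map_correlation`: the real-space Pearson correlation of two maps
  computed in reciprocal space from amplitudes and phase differences,
  `sum(w F1 F2 cos dphi) / sqrt(sum(w F1^2) sum(w F2^2))` with `F(000)`
  excluded; it equals the voxel-space Pearson correlation identically, a
  property asserted against a direct-map oracle.
* `fisher_lee_correlation`: the circular correlation coefficient for paired
  angles, computed via the O(n) trigonometric-sum expansion of the pairwise
  sine estimator (the O(n^2) form is kept in the tests as an oracle). It is
  invariant to independent constant rotations of either phase set.
* `circular_moments` / `fit_von_mises_kappa`: first trigonometric moment
  (mean direction by the four-quadrant arctangent; mean length), and the
  maximum-likelihood concentration solving `A(kappa) = Rbar` by monotone
  bracketed root-finding (capped at `1e4` as `Rbar -> 1`). A mean length
  numerically zero leaves the mean direction flagged undefined rather than
  silently zeroed; downstream synthesis gives such reflections weight 0.
* `fit_joint_sf_pdf`: independent Gaussian-on-amplitude, von
  Mises-on-phase model of a stationary trajectory window, for isocontour
  visualization of structure-factor distributions in the complex plane.

In P1 with Friedel symmetry every epsilon factor is 1; imported data may
carry their own epsilon column, and every statistic accepts weights, with
the unweighted P1 behavior as default.

## Trajectory analysis

After an IPA converges, the solution estimate keeps fluctuating because the
two constraint sets do not intersect exactly (amplitude errors, approximate
priors). The run loop records the monitored estimate's complex structure
factors over a trailing window (default 30 iterations, the window also used
by the summaries). `trajectory_summaries` computes per-reflection mean
direction, mean length, concentration and amplitude moments;
`synthesize_averaged_map` rebuilds a map from the mean-direction phases
with measured amplitudes either unweighted or weighted by the mean length;
`er_polish` is the comparison baseline (30 ER iterations from the final
estimate); `prtf` evaluates the phase-retrieval transfer function — the
modulus of the window-averaged complex coefficient over the measured
amplitude — per reflection and epsilon-weighted per shell. PRTF values are
not clipped: for the real-space-satisfying estimate the reconstructed
amplitudes need not equal the measured ones, so values slightly above 1 are
reported as such. For the Fourier-satisfying estimate the per-reflection
PRTF equals the mean length exactly, which the tests assert. A simple
stationarity diagnostic compares mean directions between window halves
(flag threshold 0.1 rad, amplitude-weighted) and is used for reporting
only — runs are always fixed-length.

## The synthetic crystal

`make_toy_crystal` builds a cubic P1 cell containing a spherical protein
region sized for the requested solvent fraction (default 0.74, the
strong-constraint regime), filled with positive Gaussian blobs on an
exactly flat (zero) solvent background; the reference histogram prior is
taken from the truth's own protein region, isolating algorithm behavior
from prior misspecification. Two realism choices matter:

* **Atom-like texture.** Blobs default to sigma 1 Å at about one blob per
  28 Å^3, drawn over the whole protein sphere. Real protein density is
  strongly textured at a 2.5 Å resolution limit; with smooth sparse blobs
  the local-variance envelope signal disappears and envelope-coupled runs
  stall, which is a property of the toy, not of the algorithms.
* **Constraint infeasibility.** With exact amplitudes the constraint sets
  intersect exactly and post-convergence fluctuations vanish. The
  simulation experiments therefore add 10% multiplicative Gaussian
  amplitude noise (`simulate_data(amplitude_noise = 0.1)`), representative
  of good measured data, so that the algorithms exhibit the stationary
  fluctuations the trajectory machinery is designed to exploit.

Defaults are a 40 Å cell on a 48^3 grid at `d_min` 2.5 Å
(Shannon-adequate: spacing at most `d_min/2`). The packaged experiments and
tests run on a scaled-down instance — 27 Å cell, 32^3 grid, ~2600
reflections, envelope window 1.7 Å — which one CPU core iterates at
roughly 45 iterations per second; all replicated experiments (30
replicates per condition, fixed 150-iteration runs for the trajectory
sweep, 80 for the convergence-regime runs) fit in minutes at this size.
`make_phase_experiment_set` provides geometry-free reflection sets
(Rayleigh amplitudes normalized to unit mean square, uniform phases, a
stated centric fraction on the two-point set {0, pi}) for calibrating the
error model and statistics without any grid.

## What the synthetic experiments do and do not show

The packaged experiments reproduce, at desk scale: the error-model
calibration curves (mean absolute phase difference and starting map
correlation as near-linear functions of `V`); the algorithm identities
(RAAR/revRRR at `beta = 1`, RRR/Douglas–Rachford at `beta = 1`, DM
stationarity forcing estimate coincidence, joint fixed-point preservation);
recovery from moderate corruption (`V <= 0.5`) by DM and RRR in ≥ 90% of
replicates under the honest protocol (envelope estimated from the corrupted
density itself); and the exact PRTF/mean-length identity.

Three qualitative findings reported for deposited-structure data do **not**
reproduce on this toy, and the corresponding checks are allowed to fail
rather than being weakened. First, 30 iterations of ER polishing slightly
outperforms trajectory averaging here (margins of ~0.005–0.01 in map
correlation): the toy's priors are nearly exact, so the final estimates
land well inside ER's local convergence basin, whereas on real maps the
approximate priors are precisely what defeats ER. Trajectory averaging
still improves on the raw final iterate at every `beta`. Second, the mean
per-reflection circular variance of the stationary window peaks near
`beta = 0.5` instead of increasing monotonically in `beta`: in this small,
nearly-feasible problem the fluctuation width is dominated by envelope
re-estimation jitter and weak-reflection phase diffusion rather than by
the `beta`-scaled step size (a deterministic circle/line gap toy even
settles into a zero-variance cycle). Third, at `V = 0.8` the desk toy sits
beyond every algorithm's recovery basin — ER, DM and RRR all stay near zero
correlation even over 1000 iterations when the envelope must be determined
from the corrupted density — so the contrast "ER stagnates while DM/RRR
recover" cannot be exhibited at that error level here; it does appear one
notch down (`V = 0.7`), where DM and RRR reach correlation > 0.9 while ER
plateaus near 0.75. All three observations are properties of the synthetic
regime (small cell, crude envelope signal, nearly exact priors); users
applying the package to measured data should expect the behavior reported
for real crystals.

## Numerical choices

* Fourier transforms use the unnormalized DFT (`F(000)` = sum of density =
  mean density × number of grid points); Parseval and round-trip identities
  are asserted to 1e-8/1e-10.
* Grids are even-dimensioned; reflections are stored as one member of each
  Friedel pair (canonical hemisphere), sorted lexicographically so
  replicate runs align term by term; indices stay strictly inside the
  Nyquist box.
* Equal-count resolution shells are built on `1/d^3`; a reflection exactly
  on a boundary joins the lower-resolution shell.
* Root-finding on the Bessel ratio uses bisection on `[1e-8, 1e4]` with
  tolerance 1e-10.
* The stationarity diagnostic threshold (0.1 rad between half-window mean
  directions) and the divergence check (non-finite iterate aborts with a
  diagnostic) are reporting conveniences, never stopping rules.

## Limitations

Space-group machinery beyond P1 + Friedel symmetry is out of scope
(imported epsilon factors are passed through, never computed); there are no
amplitude- or resolution-dependent error models; no apodization /
resolution-extension schedules or variable-`beta` protocols; PRTF values
are reported for relative comparison only — no absolute resolution claims
are attached to any threshold.
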