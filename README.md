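# ipaphase

Iterative projection algorithms (IPAs) for crystallographic phase
retrieval, with a circular phase-error model, circular agreement
statistics, and post-convergence trajectory analysis — exercisable
entirely on synthetic toy crystals.

## Who this is for

Phase retrieval from diffraction amplitudes alone is possible when strong
real-space constraints exist — above all a flat solvent region occupying a
large volume fraction of the crystal. The problem is then a nonconvex
two-set feasibility problem: find a density `rho` whose Fourier amplitudes
`|F(h)|` equal the measured ones (constraint set *B*) and which is flat in
the solvent and histogram-matched in the protein region (constraint set
*A*). This package is for methods developers and students who want to
study, under fully controlled synthetic conditions, how the standard
relaxation algorithms behave on this problem:

| algorithm | update rule | parameter |
|---|---|---|
| ER | `x' = P_A(P_B(x))` | — |
| DM | `x' = x + b(P_A(f_B(x)) - P_B(f_A(x)))`, `f_A = (1-1/b)P_A + I/b`, `f_B = (1+1/b)P_B - I/b` | `b ∈ (-1,1), b ≠ 0` |
| RRR | `x' = x + b(P_B(2P_A(x)-x) - P_A(x))` | `b ∈ (0,2)` |
| revRRR | `x' = x + b(P_A(2P_B(x)-x) - P_B(x))` | `b ∈ (0,2)` |
| RAAR | `x' = b(x + P_A(2P_B(x)-x)) + (1-2b)P_B(x)` | `b ∈ (0,1]` |

Each iteration yields two solution estimates (one satisfying each
constraint set exactly); after convergence the iterate keeps fluctuating
whenever the two sets do not intersect exactly, and the package's
trajectory machinery turns those fluctuations into per-reflection circular
statistics: mean-direction phase estimates, mean-length figure-of-merit
weights, and the phase-retrieval transfer function (PRTF)
`|mean_i F_i(h)| / F_measured(h)` averaged in resolution shells.

Phase errors are introduced with a circular error model parameterized by a
single circular variance `V`: von Mises noise (concentration solving
`1 - I1(k)/I0(k) = V`) for acentric reflections, and a wrapped Bernoulli
flip (`p = 1 - V/2`) for centric ones.

## Worked example

Build a toy crystal (74% solvent), corrupt the true phases at circular
variance 0.75, run RRR, and average the stationary trajectory:

```r
library(ipaphase)

spec <- toy_crystal_spec(cell_length = 27, shape = 32, n_blobs = 170,
                         blob_width = 1, seed = 101)
xt   <- make_toy_crystal(spec)
refl <- simulate_data(xt$truth, amplitude_noise = 0.1, seed = 101)
refl
#> Reflection set: 2628 Friedel-unique reflections (2628 measured, 0 centric)
#>   resolution 27.00 - 2.51 A; F(000) = 3817

corrupted <- corrupt_phases(refl, error_spec(0.75, seed = 2))
mean_abs_phase_diff(refl$phase_ref, corrupted$phase_ref)
#> [1] 73.6     # degrees; ~70-75 deg is the hard regime

cfg <- ipa_config("RRR", beta = 0.8, n_iterations = 150)
rec <- ipa_run(refl, xt$prior, cfg, start_phases = corrupted$phase_ref,
               window_radius = 1.7, envelope0 = xt$envelope)
rec
#> IPA trajectory: RRR (beta = 0.8), 150 iterations, window 30
#>   map correlation vs reference: start 0.607, final 0.923

s   <- trajectory_summaries(rec, 30)
avg <- synthesize_averaged_map(s, refl, "weighted",
                               f000 = f000_from_prior(xt$prior, xt$cell))
Fa  <- density_to_structure_factors(avg, refl)
map_correlation(Mod(Fa), refl$f_measured, dphi = Arg(Fa) - refl$phase_ref)
#> [1] 0.925    # mean-length-weighted trajectory average

round(prtf(rec, n_shells = 5)$per_shell, 3)
#>   shell  d_max d_min  prtf
#> 1     1 27.000 4.217 0.918
#> 2     2  4.217 3.429 0.893
#> 3     3  3.375 2.964 0.855
#> 4     4  2.946 2.687 0.812
#> 5     5  2.673 2.507 0.772
```

The run starts at map correlation 0.61 (the corruption at `V = 0.75`
leaves roughly `1 - V` correlation on geometry-free data; on a real
crystal's amplitude spectrum the weighted statistic starts higher),
converges to 0.92, and the trajectory-averaged map does slightly better
than the final iterate. The PRTF decays with resolution, quantifying how
phase confidence falls off toward the 2.5 Å limit.

A thin command-line front end with subcommands `simulate`, `corrupt`,
`run`, `sweep`, `average`, `prtf` and `metrics` is installed at
`inst/cli/ipa-tool.R`:

```sh
Rscript inst/cli/ipa-tool.R simulate --cell 27 --grid 32 --seed 1 --out toy
Rscript inst/cli/ipa-tool.R corrupt --in toy.hkl --variance 0.6 --seed 2 --out noisy.hkl
Rscript inst/cli/ipa-tool.R metrics --ref toy.hkl --in noisy.hkl
```

Reflection data travel as plain-text `h k l F phi centric eps measured`
files; maps are written in CCP4/MRC mode-2 format.

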