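Package: ipaphase
Title: Iterative Projection Algorithms for Crystallographic Phase Retrieval
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying crystallographic phase retrieval as a nonconvex
    two-set feasibility problem. Implements the error-reduction (ER),
    difference-map (DM), relaxed-reflect-reflect (RRR and reversed RRR) and
    relaxed averaged alternating reflections (RAAR) iterative projection
    algorithms with solvent-flatness and histogram-equivalence constraints in
    real space and measured-amplitude constraints (with Wilson restraints on
    unmeasured terms) in Fourier space. Provides a circular phase-error model
    (von Mises for acentric reflections, wrapped Bernoulli for centric ones,
    parameterized by circular variance), circular agreement statistics (mean
    absolute phase difference, amplitude-weighted map correlation, Fisher-Lee
    circular correlation), post-convergence trajectory averaging and the
    phase-retrieval transfer function (PRTF), together with a synthetic
    toy-crystal generator so every component can be exercised without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
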