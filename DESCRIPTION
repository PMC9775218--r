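Package: pmfsolv
Title: Potential of Mean Force and Preferential Solvation Analysis for
    Peptide Dimer Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for umbrella-sampling and alchemical
    free-energy studies of peptide aggregation. Estimates potentials of
    mean force along a centre-of-mass separation coordinate with the
    weighted histogram analysis method (WHAM), including the radial
    Jacobian (entropy) correction and Bayesian-bootstrap errors; computes
    solvation and solvent-transfer free energies with the Bennett
    acceptance ratio; derives radius-of-gyration distributions and a
    Kabsch-Sander hydrogen-bond secondary-structure classification; and
    builds per-residue hydration, co-solvent solvation and interpeptide
    backbone contact maps along the reaction coordinate. Ships
    synthetic-data generators with analytic ground truth (biased sampling
    from known potentials, bead-peptide dimer scenes with controlled
    solvation shells, Crooks-consistent work samples) so every stage can
    be validated end-to-end without molecular-dynamics input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
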