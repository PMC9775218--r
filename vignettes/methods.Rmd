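---
title: "Free-energy and solvation analysis for peptide dimers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy and solvation analysis for peptide dimers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmfsolv)
```

# Scope and model

`pmfsolv` analyses the association of two short peptides — the motivating
system is an 11-residue amphiphilic segment from the α-synuclein NAC
domain, simulated in water and in 8 M aqueous urea — along the
centre-of-mass (COM) separation ξ. The package implements the estimators
only; it consumes umbrella-window sample series, alchemical
energy-difference tables and coordinate trajectories, and it ships
synthetic generators that produce all three with analytic ground truth.
Everything below states what each stage assumes, which knobs matter, and
where a design choice was genuinely open.

Energies are handled in kT internally and converted at I/O boundaries
with R = 0.0083144621 kJ mol⁻¹ K⁻¹; the default temperature is 298 K.
Coordinates are nm; boxes are orthorhombic only (triclinic input raises
an explicit unsupported-feature error rather than being wrapped
silently).

# PMF estimation

## WHAM

`wham()` bins all window samples on a common grid (default bin width
0.01 nm — a fifth of the customary 0.05 nm window spacing, fine enough
that bias variation within a bin is negligible for spring constants of
order 100 kT/nm²) and iterates the coupled equations for the unbiased
bin probabilities and per-window offsets until the largest offset change
falls below `tol` (default 1e-7 kT; `max_iter` 1e5). Probabilities are
renormalised to sum to one each sweep, which fixes the gauge of the
offsets. Bins with zero total counts are excluded from the returned
profile rather than assigned infinite free energy: an empty bin carries
no information, and excluding it avoids fabricating values.

Two error modes are checked eagerly. Windows whose histograms share no
occupied bin split the overlap graph into disconnected components, and
the error names the two groups, because WHAM free energies are only
determined up to a constant *per component*. Non-convergence at
`max_iter` reports the residual so the caller can distinguish a slow
solve from a broken one.

Window data are treated as independent draws from the biased ensemble.
The statistical inefficiency of real MD series is *not* estimated in
this version — the synthetic generator produces effectively independent
samples — and this is the main caveat when feeding real trajectories:
bootstrap errors will be optimistic by roughly the square root of the
correlation time in frames.

## Jacobian (entropy) correction and gauge

A radial COM coordinate gains sampling volume as ξ², so the raw profile
underestimates the free energy at large ξ. `entropy_correct()` adds
2RT ln(ξ) with ξ in nm; the implicit 1 nm reference length contributes
only an additive constant, which the subsequent tail shift absorbs, so
the choice of reference is immaterial. The correction requires ξ > 0 and
refuses grids that cross zero (a 1-D test coordinate spanning negative
values is simply not radial; the demo's harmonic fixture therefore runs
with `entropy = FALSE`).

`shift_to_zero_tail()` subtracts the mean of W over the trailing
fraction of the grid (default 0.1). A tail *average* was chosen over the
single last point because the last bin is the noisiest in any umbrella
set-up; the single-point variant is available via `use_last_point` for
callers who want the other convention. The operation is idempotent and
affine — interior differences are untouched.

## Bayesian bootstrap

Each replicate draws Dirichlet(1, …, 1) weights over *windows* and
reruns the full pipeline (WHAM, correction, shift), so the reported
per-bin standard deviation includes the error the corrections and the
shift propagate. Windows, not frames, are the resampling unit: frames
within a window are autocorrelated in real data, and window-level
weights are the natural unit for a window-structured estimator;
autocorrelation-aware frame-level weighting is deferred. A replicate
whose WHAM fails is dropped with a warning and at least 80% must
succeed. Fifty replicates are the default — bootstrap standard errors
stabilise well before that for the window counts used here.

`binding_depth()` returns the global minimum with ties broken toward
smaller ξ (the physically inner well), and flags a profile that is
positive everywhere as repulsive — the signature of a contact minimum
replaced by a repulsive state — instead of failing.

# BAR

`bar_pair()` solves the Bennett acceptance-ratio equation with
M = ln(n_f/n_r). The objective is monotone in ΔF, so a root always
exists and is unique; the solver brackets it with the two Zwanzig
exponential-averaging estimates — which provably bound the BAR estimate
— expands the bracket geometrically if needed, and bisects to `tol`
(default 1e-10 kT). Fermi factors are evaluated with `plogis`, so
extreme energy differences saturate instead of overflowing, and the
degenerate all-equal-samples case is handled exactly by the same path.
The standard error is Bennett's asymptotic variance expression evaluated
at the solution.

`solvation_free_energy()` sums pairs along a λ path and combines errors
in quadrature, mirroring the convention that each pair comes from an
independent simulation. `transfer_free_energy()` is the published
transfer arithmetic ΔΔG_hyd = ΔG_solv(urea) − ΔG_hyd(water) with the
same quadrature propagation. The λ protocol itself (number and spacing
of windows) is deliberately out of scope: the estimator is
protocol-agnostic.

# Secondary structure

The classifier implements the Kabsch–Sander electrostatic hydrogen-bond
energy, E = 27.888 (1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol with
distances in Å, and the criterion E < −0.5 kcal/mol (−2.09 kJ/mol).
Missing amide hydrogens are reconstructed 1.0 Å from N along the
direction opposite the bisector of the C(prev)–N and Cα–N bonds, the
standard practice for structures stripped of hydrogens; proline and
chain-initial residues cannot donate. Donor–acceptor pairs closer than
two residues apart in sequence are excluded (the peptide bond forbids
them chemically).

Only the classes that matter for short aggregating peptides are
assigned: E (β-sheet, with isolated bridges folded into E), G
(3₁₀-helix), H (α-helix), T (turn), C (coil); π-helices and bends are
omitted. Where patterns overlap the precedence is H over G over E over
T. Fraction profiles along ξ pool residues × frames within each ξ key,
so the five fractions sum to one at every separation; per-residue and
per-frame averaging orders would differ only for ragged chains, and the
pooled convention is documented here as the package's choice.

# Solvation maps

`rdf()` is a minimum-image pair-distance histogram normalised by the
ideal-gas shell count at the B-group density. `coordination_number()`
integrates ρ g(r) 4πr² by trapezoid; `first_minimum()` locates the first
shell boundary on a moving-average-smoothed g(r), with ties toward
smaller r, and *errors out* on monotone input so the caller must supply
an explicit cutoff rather than silently getting the grid edge (the
fallback radius used by the map functions is 0.55 nm, a typical
Cβ–water-oxygen first-minimum position).

`hydration_map()` counts solvent within each residue's first shell
around Cβ (Cα for glycine, which has no Cβ), averages the same residue
over the two chains, and normalises per residue. Two normalisations are
exposed because the two co-solvent figures this style of analysis feeds
use different conventions: `water_max` divides by the residue's maximum
hydration number in water (supplied as `norm_constants`, or the row's
own maximum when the map itself is the water map), `own_max` divides by
the map's own row maximum. Urea is counted as molecules via one
designated carbon atom per molecule, not as atoms. The ξ keys are
expected to come from binning frame-wise COM distances with the PMF bin
width so maps and PMFs share an axis.

`on_neighbor_map()` counts interchain backbone O–N pairs at r ≤ 0.35 nm
— the boundary is inclusive, matching the printed "r ≤ 3.5 Å" rule —
counting both O(A)–N(B) and N(A)–O(B) and averaging the two chains. All
qualifying pairs are counted (an oxygen with two nitrogen neighbours
contributes two), which was the open counting question; the alternative
(unique-pair capping) would only differ in saturated β-ladders.

`nonbonded_energy_profile()` evaluates 4ε((σ/r)¹² − (σ/r)⁶) +
138.935 q_iq_j/r kJ/mol with Lorentz–Berthelot combining and no cutoff —
appropriate for the toy systems it profiles, not for condensed-phase
electrostatics (no Ewald/PME, no reaction field).

# Synthetic generators: what they do and do not emulate

The generators define the package's study conditions.

* `sample_biased_window()` draws from exp(−[U + k_b/2(ξ−ξ₀)²]) exactly
  (Gaussian) for harmonic U; otherwise by Euler–Maruyama overdamped
  Langevin with the time step set so dt·|U''|max ≤ 0.01 over the
  thermally accessible range (within 15 kT of the minimum), burn-in of
  ten relaxation times, and retained samples spaced three relaxation
  times apart across up to 2048 independent walkers. Tabulated
  potentials get reflecting walls at their range. The reference
  conditions mirror the umbrella protocol of the motivating simulations:
  restraint spring constants around 5000 kJ mol⁻¹ nm⁻² (100 kT/nm² in
  the reduced fixtures), window spacings of 0.05–0.1 nm, 298 K.
* `build_dimer_scene()` places two 11-residue bead chains (N, H, Cα, C,
  O, Cβ; Cβ omitted for glycine-like residues) at an exact COM
  separation and solvent beads by rejection sampling so each residue's
  first-shell count *equals* its target — not merely in expectation —
  which is what makes the map tests deterministic. The scenes reproduce
  the dehydration-on-contact and urea-depletion patterns as step
  profiles; they have no force-field realism, no solvent structure, and
  no hydrogen-bond dynamics.
* `generate_work_samples()` draws forward work from N(ΔG + σ²/2, σ²)
  and reverse work from N(−ΔG + σ²/2, σ²), the unique Gaussian pair
  satisfying the Crooks relation with free-energy difference ΔG.
* `generate_secondary_structure_fixture()` builds idealised backbones
  (N–H 1.0 Å, C=O 1.23 Å) whose hydrogen-bond pattern realises a
  β-ladder (two antiparallel strands, every residue pair doubly bonded),
  a 3₁₀ helix (i+3→i bonds on a 120°/2 Å helix), or a coil (no donors in
  range). Bond lengths are ideal; backbone dihedral geometry is
  schematic, which is sufficient because the classifier consumes only
  N/H/C/O positions.

Passing tests on these generators demonstrates estimator correctness —
recovery of known PMFs, free energies, shell counts and hydrogen-bond
patterns — not robustness to force-field artefacts, autocorrelated
trajectories, or ragged real-world topologies.

All randomness flows from one integer seed per call through a local RNG
stream (the global `.Random.seed` is saved and restored), so identical
specifications produce byte-identical outputs and differing seeds change
coordinates but never the constructed counts.

# Problem sizes and reproducibility

The validation suite runs the WHAM fixture at 21 windows × 5000 samples
with 50 bootstrap replicates, BAR at 10⁴ + 10⁴ samples (with consistency
sweeps at 10²–10⁴), the Langevin stationarity check at 10⁵ samples, and
the ideal-gas RDF at 5 × 10⁷ pair observations — sizes at which the
recovery criteria (WHAM RMS < 0.15 kT with ≥ 95% 3σ coverage on bins
holding at least 10 counts, BAR within 3 SE, coordination numbers within
1% of (4/3)πr³ρ) have comfortable statistical margin. Recovery RMS is
evaluated on bins with at least 10 total counts because the handful of
near-empty edge bins carry ~1 kT of pure Poisson noise in −ln p, which
is sampling scarcity, not estimator error.

`run_demo()` chains every stage from one seed and writes per-figure TSV
tables rounded to 6 significant digits — the rounding is what makes
byte-identical reruns achievable across platforms — plus a JSON run
report with per-stage parameters, timings and output checksums.
`scripts/acceptance.R` recomputes the headline numbers from scratch for
any seed.

# Known limitations

* No frame-level autocorrelation handling (windows assumed internally
  independent); real-MD error bars require subsampling first.
* MBAR/binless estimators, 2-D reaction coordinates and umbrella
  integration are out of scope, as are Ewald electrostatics and binary
  trajectory formats (XTC/TRR/DCD).
* The COM selection defaults to all atoms of a chain, mass-weighted;
  heavy-atom COMs are available through explicit selections, and the
  choice is recorded in the run report so results stay auditable.
* The DSSP reduction omits π-helices, bends and chirality; isolated
  bridges are reported as E.
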