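# pmfsolv

Free-energy and solvation analysis for peptide-dimer aggregation studies.

Molecular-simulation studies of amyloidogenic peptides — for example the
11-residue C-terminal segment of the α-synuclein NAC domain and its
mutants, in water and in concentrated aqueous urea — characterise
aggregation through a standard battery of analyses: the potential of mean
force (PMF) along the peptide–peptide centre-of-mass separation from
umbrella sampling, solvation free energies from alchemical perturbation,
radius-of-gyration and secondary-structure statistics, and per-residue
hydration/co-solvent maps that resolve dehydration and urea depletion as
the peptides associate. `pmfsolv` implements that battery as a tested R
package, together with synthetic-data generators carrying analytic ground
truth, so every estimator can be validated end-to-end without running
molecular dynamics.

## What it computes

**PMF by WHAM.** Umbrella windows with harmonic restraints
u_i(ξ) = k_b/2 (ξ − ξ_i)² are combined by iterating the weighted
histogram analysis method to self-consistency:

    p_j ∝ Σ_i n_ij / Σ_i N_i exp(β(f_i − u_i(ξ_j))),
    f_i = −kT ln Σ_j p_j exp(−β u_i(ξ_j)),

with W(ξ) = −kT ln p(ξ). Because ξ is a radial centre-of-mass distance,
the sampling volume grows as ξ²; `entropy_correct()` removes it by adding
2RT ln(ξ), and `shift_to_zero_tail()` anchors W = 0 at the longest
separations. Errors come from a Bayesian bootstrap that reweights whole
windows with Dirichlet(1, …, 1) weights (`bayesian_bootstrap()`), and
`binding_depth()` reports the contact minimum.

**Solvation free energies by BAR.** `bar_pair()` solves the Bennett
acceptance ratio equation for each λ pair of forward/reverse
energy-difference samples by bracketed bisection (the Zwanzig
exponential-averaging estimates bound the root);
`solvation_free_energy()` sums a λ path, and `transfer_free_energy()`
forms the water→urea transfer free energy
ΔΔG_hyd = ΔG_solv(urea) − ΔG_hyd(water).

**Structure.** `radius_of_gyration()`/`rg_distribution()` measure
compactness; `assign_secondary_structure()` is a reduced Kabsch–Sander
classifier driven by the electrostatic hydrogen-bond energy
E = 27.888 (1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol with the
E < −0.5 kcal/mol (−2.09 kJ/mol) criterion, assigning
β-sheet/bridge (E), 3₁₀-helix (G), α-helix (H), turn (T) and coil (C).

**Solvation maps.** `rdf()`, `coordination_number()` (CN = ρ ∫ g(r) 4πr²
dr) and `first_minimum()` define per-residue first solvation shells;
`hydration_map()` builds residue × ξ maps of normalised coordination
numbers, CN_i^norm = CN_i / max CN_i, averaged over the two chains;
`on_neighbor_map()` counts interpeptide backbone O–N pairs within 3.5 Å;
`nonbonded_energy_profile()` gives toy LJ + Coulomb interaction profiles
along ξ.

**Synthetic ground truth.** `sample_biased_window()` draws biased samples
from analytic potentials (exact Gaussian sampling for harmonic ones,
overdamped Langevin otherwise); `build_dimer_scene()` constructs
bead-peptide dimers at an exact COM separation with exactly the requested
first-shell water/urea counts per residue; `generate_work_samples()`
makes Gaussian forward/reverse work samples obeying the Crooks relation
with a known ΔG; `generate_secondary_structure_fixture()` builds backbone
motifs with prescribed hydrogen-bond ladders.

## Worked example

Reconstruct a known PMF from 21 umbrella windows and estimate a known
free-energy difference from Crooks-consistent work samples:

```r
library(pmfsolv)

pot <- analytic_potential("harmonic", k = 10)       # U = 5 xi^2, in kT
centers <- seq(-1, 1, by = 0.1)
windows <- lapply(seq_along(centers), function(i)
  sample_umbrella_window(pot, centers[i], bias_k = 100, n = 5000,
                         seed = 1000 + i))
profile <- pmf_from_windows(windows, bin_width = 0.01, n_boot = 50,
                            seed = 1, entropy = FALSE)
profile
#> PMF profile: 247 bins, xi in [-1.27, 1.29] nm, T = 298 K
#>   entropy-corrected: FALSE; tail-shifted: TRUE
#>   WHAM: 283 iterations, residual 9.8e-08 kT
#>   minimum: W(-0.015 nm) = -15.36 kJ/mol

ws <- generate_work_samples(work_sample_spec(delta_g_true = 2, sigma = 1,
                                             n_forward = 1e4,
                                             n_reverse = 1e4, seed = 3))
bar_pair(lambda_pair(ws$forward, ws$reverse))
#> BAR: dF = 2.0056 +/- 0.0072 kT (n_f = 10000, n_r = 10000)
#>   Zwanzig bracket: [2.0005, 2.0286] kT; residual -4.38e-08
```

The PMF minimum sits at ξ ≈ 0 with depth ≈ −15.4 kJ/mol: the analytic
well depth of U = 5 ξ² kT relative to the tail of the sampled range
(≈ 6.2 kT ≈ 15.4 kJ/mol), and BAR recovers the true ΔG = 2 kT well
within one standard error. `run_demo(seed, out_dir)` chains every stage —
PMF, BAR, dimer-scene maps, secondary structure, RDF/CN — asserts each
module's recovery property and writes deterministic per-figure tables.

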