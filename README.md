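# loopmsm

Markov-state modelling of antibody CDR loop torsion dynamics in R.

Antibody complementarity-determining region (CDR) loops are usually
classified into static *canonical clusters* from crystallographic backbone
dihedrals. In solution, a loop is an exchanging ensemble: several canonical
cluster medians can occupy one free-energy basin, and dominant solution
conformations need not match any crystal structure. `loopmsm` implements the
kinetic analysis chain that turns backbone torsion trajectories into that
picture, for structural bioinformaticians who want the estimators without a
full MD analysis stack:

- **Featurization** — per-residue φ/ψ angles to periodic (sin θ, cos θ)
  features; φ/ψ extraction from (multi-model) PDB files; the North-style
  dihedral metric `d(a,b) = sqrt(mean_k 2(1 − cos Δθ_k))`.
- **Seed selection** — average-linkage clustering under a distance cutoff
  with medoid representatives.
- **tICA** — the generalized eigenproblem `C(τ) v = λ C₀ v` over
  within-trajectory frame pairs (symmetrized estimator), giving slow
  components tIC1, tIC2, … with unit equilibrium variance.
- **MSM** — k-means microstates (k-means++ with recorded seed, compiled
  Lloyd iterations), sliding transition counts, largest strongly connected
  set, reversible maximum-likelihood transition matrix under detailed
  balance, implied timescales `tᵢ = −τ/ln λᵢ₊₁`, Chapman–Kolmogorov test.
- **PCCA+** — inner-simplex metastable memberships, macrostate
  probabilities, mean first passage times (ns).
- **Landscapes & grouping** — stationary-reweighted free-energy surfaces
  `F = −kT ln(p/p_max)` on (tIC1, tIC2), projection of reference
  (canonical-median) conformations, and their assignment to kinetic minima:
  which references are kinetically the same state.
- **Synthetic generator** — a von Mises hidden-Markov torsion simulator
  with exactly known kinetics, so every stage is testable without MD.

## Worked example

Four metastable loop conformations, 200 seeded trajectories × 500 frames,
six reference conformations planted 2+2+1+1 into the basins:

```r
library(loopmsm)

spec <- default_synthetic_spec(seed = 1)          # 4 states, L = 11, kappa = 16
refs <- plant_reference_conformations(
  spec, list(L1_a = 1, L1_b = 1, L2_a = 2, L2_b = 2, L3 = 3, L4 = 4))
sim  <- generate_torsion_ensemble(spec)

cfg <- pipeline_config(lag_ns = 10, k = 150, n_macro = "auto")
rep <- run_pipeline(cfg, sim$trajectories, refs)

rep$summary$implied_timescales_ns[1:3]
#> [1] 62.47759 30.83734 29.58957
rep$summary$macro_probabilities
#> [1] 0.2690467 0.2481671 0.2421165 0.2406697
print(rep$grouping)
#> <kinetic_grouping: 6 references in 4 kinetic groups, 0 unsampled>
#>   minimum 1: L4
#>   minimum 2: L1_a, L1_b
#>   minimum 3: L2_a, L2_b
#>   minimum 4: L3
```

The three implied timescales (ns) match the generator's slow eigenvalues
(truth: 62.0, 30.7, 30.7 ns); the four macrostate probabilities recover the
uniform stationary distribution within sampling error; and the six
references collapse into four kinetic minima with exactly the planted
co-memberships — pairs planted in one basin are recognized as the same
kinetic state.

The numbered drivers under `analysis/` run the same study as a narrative:
`01_simulate.R` (ensemble + references), `02_seed_select.R` (cutoff
clustering and medoid seeds), `03_tica_msm.R` (tICA, MSM, implied-timescale
lag scan, CK test), `04_macrostates.R` (PCCA+, probabilities, MFPTs),
`05_landscape_report.R` (free-energy surface, reference projection, kinetic
grouping, nearest-neighbor distances). Each writes its tables under
`results/`.

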