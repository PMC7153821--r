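---
title: "Kinetic characterization of CDR loop ensembles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic characterization of CDR loop ensembles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopmsm)
```

## The problem

Antibody complementarity-determining region (CDR) loops are classically
described by *canonical clusters*: discrete main-chain conformation classes
assigned from backbone $\phi/\psi$ dihedrals of X-ray structures. That static
picture hides the solution behavior — a loop exchanges between conformations
on micro-to-millisecond timescales, several crystallographic cluster medians
can sit inside one free-energy basin, and dominant solution conformations
need not coincide with any crystal structure. `loopmsm` implements the
kinetic view: starting from backbone torsion trajectories it builds a
time-lagged independent component analysis (tICA) projection of the slow
conformational subspace, a reversible Markov-state model (MSM) on k-means
microstates, PCCA+ metastable macrostates with equilibrium probabilities and
mean first passage times, free-energy surfaces in tIC space, and — the
headline output — the assignment of reference (canonical-median) torsion
vectors to kinetic minima, showing which references are kinetically
equivalent.

Because microsecond MD ensembles cannot ship with a package, a synthetic
generator with exactly known kinetics stands in for the data; every
downstream claim is then checkable against ground truth.

## The synthetic generator

`generate_torsion_ensemble()` simulates a hidden Markov chain over
`n_states` metastable conformations. Each frame emits, independently per
backbone angle, a draw from a von Mises distribution centred on the hidden
state's mean torsion with concentration $\kappa$ (angular standard
deviation $\approx 1/\sqrt{\kappa}$ radians). The von Mises emission is the
simplest noise model consistent with unimodal torsion basins; real MD adds
correlated, multimodal within-basin structure that this generator does not
emulate, so passing tests demonstrate correct *estimator* behavior, not
force-field realism.

Default study conditions, chosen once as desk-scale analogues of a seeded
short-trajectory MD campaign (many ~100 ns runs started from diverse
cluster representatives):

| parameter | default | rationale |
|---|---|---|
| states | 4 | enough for a two-level kinetic hierarchy |
| loop length $L$ | 11 residues (22 angles) | the most common CDR-L1 length |
| $\kappa$ | 16 (~14° sd) | crystallographic basin widths |
| self-transition | 0.98 per frame | slowest process ~62 frames, resolvable at 500-frame trajectories |
| ensemble | 200 trajectories × 500 frames, 1 ns/frame | seeded-ensemble shape at testable size |
| start states | uniform | seeds from diverse exploratory clusters, not equilibrium |

The 4-state jump matrix is a paired hierarchy (within-pair exchange 3×
faster than between pairs), giving distinct slow eigenvalues
$\{0.984, 0.968, 0.968\}$ per frame rather than a fully degenerate triplet.
State means place ≥120° offsets on staggered 3-residue windows of a
polyproline-II-like baseline, so basins are separated by many times the
emission noise. Real per-state dwell times of CDR loops are far longer
(micro-to-millisecond); the defaults are chosen for testability, not to
match real kinetics.

## Featurization and the dihedral metric

All angles are degrees in $(-180, 180]$ at every interface (the convention
of the crystallographic databases); radians are internal. `featurize()` maps
each angle to $(\sin\theta, \cos\theta)$, removing the periodic
discontinuity; the map inverts exactly via `defeaturize()` (atan2). Features
are $\phi/\psi$ only — $\omega$ is excluded because cis/trans proline
states are encoded in canonical cluster names rather than re-derived, and
side-chain torsions are out of scope.

The dihedral distance between torsion vectors $a, b$ of length $n = 2L$ is

$$d(a,b) = \sqrt{\tfrac{1}{n}\sum_k 2\,(1 - \cos(a_k - b_k))},$$

the North-style metric with a per-angle average under the root so values
are comparable across loop lengths: identical vectors give 0, a single
180° flip in an 11-residue loop gives $\sqrt{4/2L}$, and an all-angle flip
gives the maximum 2. The literature leaves the normalization (sum vs mean)
unstated; the mean convention is declared here and used consistently in
clustering and the nearest-neighbor report.

`metadynamics_cv()` exposes the biased-sampling collective variable used to
diversify seeds — weighted sums $\sum_i w_i \sin\psi_i$ and
$\sum_i w_i \cos\psi_i$ over the $\psi$ angles of the loop (optionally
including a neighboring loop) — as a computable feature only; no biasing
dynamics are simulated.

## Seed selection

`average_linkage_cluster()` agglomerates frames by unweighted average
linkage and stops when the minimum inter-cluster linkage exceeds a distance
cutoff, yielding the "large number of clusters" whose medoids
(`pick_representatives()`, ties to the lowest frame index — the standard
cpptraj-compatible choice since no selection rule is documented for this
stage) act as seeds. On Cartesian coordinates the conventional cutoff is
1.2 Å RMSD after superposition; on torsion-only synthetic data the dihedral
metric is used with a default cutoff of 0.3 (dimensionless — about the
within-basin RMS distance at $\kappa = 16$), and outputs always state the
metric and units.

## tICA

`estimate_tica()` solves the generalized eigenproblem
$C(\tau)\,v = \lambda\, C_0\, v$ with both covariances accumulated over all
within-trajectory frame pairs $(t, t+\tau)$ — never across trajectory
boundaries. The symmetric estimator is used throughout (mean and $C_0$
average both pair members; $C(\tau)$ symmetrized), which guarantees real
eigenvalues and makes the model invariant to time reversal and trajectory
order. A variance floor (default $10^{-10}$) is added to the diagonal of
$C_0$ because sin/cos features of nearly rigid angles are rank-deficient.
Eigenvectors are $C_0$-orthonormal, so each tIC has unit equilibrium
variance; eigenvalues beyond $[-1, 1]$ (finite-sampling noise) trigger a
warning. Kinetic-map scaling is deliberately off: components are reported
in whitened units.

One consequence of whitening worth knowing: directions of near-zero
variance (e.g. the radial $\sin^2+\cos^2 = 1$ constraint) are amplified, so
a conformation's projection can sit a sizeable fraction of a whitened unit
away from the cloud center even when its torsions equal the basin mean.
Reference placement is therefore judged against the projected data cloud
(nearest microstate, nearest occupied bin), never by absolute distance from
the origin.

The default lag is 10 ns (converted to frames via `frame_dt`). Landscapes
use the top two tICs, matching the 2-D figures this analysis style
produces; *microstate clustering runs on the top three tICs* by default.
The extra component costs nothing and protects against a near-degenerate
slow spectrum, where an arbitrary 2-D slice of the 3-D slow subspace can
superpose distinct metastable states.

## Microstates and the reversible MSM

`kmeans_discretize()` is k-means++ with a fixed, recorded seed (default
42 — without it, landscape figures are not reproducible run-to-run)
followed by Lloyd iterations (compiled) to a relative inertia tolerance of
$10^{-6}$ or 500 iterations; ties in assignment break to the lowest center
index, and a center emptied during iteration is re-seeded from the point
farthest from its current center. The default microstate count is 150.

Transition counts (`count_transitions()`) use the sliding window at the
model lag and never cross trajectory boundaries. Probabilities are only
meaningful on a fully connected network, so estimation restricts to the
largest strongly connected component of the count graph
(`largest_connected_set()`, maximizing retained counts; the retained
fraction is always reported, not enforced against a threshold). Frames of
trimmed microstates are reassigned to the nearest active center for
weighting and coloring only.

`estimate_reversible_T()` maximizes the likelihood under detailed balance
by the standard fixed-point iteration on symmetric flux variables
$x_{ij} \propto (c_{ij}+c_{ji})\,/\,(c_i/x_i + c_j/x_j)$, to a relative
tolerance of $10^{-12}$ (cap $10^6$ iterations, error with residual on
failure). Row-stochasticity, stationarity and detailed balance are asserted
after every estimate. Implied timescales use
$t_i = -\tau/\ln\lambda_{i+1}$; eigenvalues at 1 yield `Inf` (flagged
disconnectivity), negative eigenvalues yield `NA` with a warning.
`ck_test()` compares set-occupation probabilities predicted by $T(\tau)^k$
with models re-estimated at lag $k\tau$, aggregated over macrostates when
available (the view used for model validation); factors without sufficient
data are skipped with a warning.

## PCCA+ and kinetics

`pcca_plus()` uses the inner-simplex (Deuflhard–Weber) construction on the
top $\pi$-orthonormal eigenvectors: vertex microstates are selected by
iterative farthest-point orthogonalization and memberships are barycentric
coordinates in that simplex. No membership-rotation optimization follows —
the inner-simplex result is deterministic, and for the metastable matrices
this pipeline produces the crisp partition is identical. Rows slightly
outside the simplex (imperfectly metastable chains) are clipped at zero and
renormalized. The macrostate count is user-set or chosen by a spectral-gap
rule (`choose_n_macro()`: smallest model explaining all timescale ratios
above 3 — configurable, since published analyses report 2–5 macrostates per
system without stating a selection rule).

Macrostate probabilities sum member stationary weights. The representative
frame of a macrostate is the frame nearest the center of its
highest-$\pi\chi$ microstate — a declared convention; figures in this
style show representatives without a selection formula. Mean first passage
times solve $m_i = \tau + \sum_{j \notin B} T_{ij} m_j$, $m|_B = 0$, with
$\pi$-weighted source averaging, reported in ns.

## Landscapes and kinetic grouping

`free_energy_surface()` histograms (tIC1, tIC2) on a 100×100 grid over the
data range padded 5% (binning is a convention; none is standard) and sets
$F = -\ln(p/p_{\max})$ in kT, optionally kcal/mol via $k_BT$ at 300 K
(default). The surface is stationary-reweighted by default — frame weight
$\propto \pi_{\text{microstate}}/n_{\text{frames in microstate}}$ — because
seeded short trajectories are not equilibrium samples; the raw histogram
remains available for comparison. Unoccupied bins are flagged, never
extrapolated, and the occupied-bin minimum is exactly 0.

References are featurized and projected by the identical map as trajectory
frames, then assigned to the nearest microstate center and its crisp
macrostate. "Not sampled" needs an operational definition: a reference
farther from every occupied bin center than 3× the median nearest-neighbor
spacing of occupied bin centers is reported as an outlier. The grouping —
references sharing a macrostate — is the package's headline output: planted
2+2+1+1 into four basins, six references resolve into exactly four kinetic
minima, i.e. fewer kinetic groups than references.

## Problem sizes and what the tests show

The test suite and the acceptance script run the full pipeline at the
default study conditions (200 × 500 frames, 150 microstates, 10 ns lag) and
closed-form checks at exact sizes; smaller ensembles (20–60 trajectories of
200–400 frames, 30–60 microstates) exercise properties where full scale
adds nothing. On these conditions the pipeline recovers hidden states at
~100% frame agreement, stationary probabilities within ±0.02, the slowest
timescale within a few percent, and Chapman–Kolmogorov deviations below
0.03. Those numbers certify estimator correctness on Markovian von Mises
data; real loop ensembles add non-Markovian memory, anharmonic basins and
sampling noise that only real trajectories can probe.

## Known limitations

- No biased-sampling dynamics, bias reweighting, Cartesian synthesis, or
  side-chain torsions in the generator.
- No Bayesian MSM error bars, hidden Markov models, variational scoring, or
  transition-path-theory fluxes; validation is CK + implied-timescale
  flatness.
- PCCA+ without the rotation-optimization step can differ from
  rotation-optimized memberships for weakly metastable spectra.
- The per-antibody landscapes of real CDR loops require the original
  microsecond trajectories and are outside what synthetic data can
  reproduce.
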