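---
title: "Conformational ensembles, separation coordinates and bending free energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational ensembles, separation coordinates and bending free energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bendrc)
```

This vignette is the methods account of `bendrc`: the models the package
implements, the assumptions behind them, the tunable parameters and their
defaults, the numerical choices made where the design was open, and what
the synthetic ground-truth generators do and deliberately do not emulate.
The running example is the bending of a flexible two-domain protein such
as the αβ-tubulin dimer, which interconverts between straight and kinked
conformations and whose bending can additionally proceed about two
distinct intramolecular anchor points.

## Ensembles, superposition and flattening

A `structure_ensemble` stores F frames of N atoms in nanometres (PDB
Ångström are converted on read and write). Before any covariance analysis,
rigid-body motion must be removed: `superpose()` performs unweighted
least-squares Kabsch superposition of every frame onto a reference frame
over the analysis mask. Mass weighting is deliberately not applied — for
backbone-level analyses of a single protein it changes little and adds a
parameter. The default mask on PDB input is the backbone (N, CA, C, O);
flexible termini should be excluded by the caller because they inflate the
apparent variance without carrying bending signal. Frames are assumed
complete: missing residues are a structure-preparation problem, not an
analysis one, and the readers fail loudly on atom-count mismatches.

Superposition of a hinged molecule is itself a modelling choice: the fit
distributes the bending motion across both arms rather than pinning one.
All downstream quantities (modes, reaction coordinates) live in this
superposed frame. `flatten()` concatenates masked coordinates per frame
into an F × 3N matrix in the order x1, y1, z1, x2, …, which every
downstream stage consumes.

## PCA of conformational ensembles

`compute_pca()` diagonalizes the covariance of the mean-centered rows.
Two conventions matter:

* **Normalization is 1/F** (population), not 1/(F−1), because the
  covariance is defined as an ensemble average. The difference is a factor
  (F−1)/F on eigenvalues only.
* **When 3N > F the decomposition runs through the F × F Gram matrix.**
  This is exact — the nonzero spectrum of X'X/F and XX'/F coincide — and
  is what makes a 91-structure set with tens of thousands of coordinates
  tractable. Eigenvalues below 10⁻¹² nm² are clipped to zero, and each
  eigenvector's sign is fixed (largest-magnitude component positive) so
  that repeated runs and scan averaging are reproducible.

`project()` uses the *basis* mean, not the projected ensemble's own mean,
so foreign ensembles (e.g. simulated trajectories projected onto an
experimental-structure basis) land in a consistent mode space.
`max_variance_orthogonal()` supplies the second axis of 2-D free-energy
planes: the leading principal axis after projecting out a given direction.

## The ensemble-separation reaction coordinate

Given two ensembles that occupy different regions of conformational
space, the separation search finds the unit vector n minimizing the
overlap integral O(n) = ∫ ρ̄₁(z,n) ρ̄₂(z,n) dz of the two projected
densities. Searching all of R^{3N} is hopeless, so n is expanded in the
first d eigenvectors of a PCA on the *combined* ensemble; d is a
regularization dimension to be increased until the answer stops changing
(`sweep_d()` automates this and flags the plateau at a cosine-similarity
threshold of 0.98 between consecutive solutions).

Each of `n_scans` independent scans draws `n_vectors` random unit vectors
(i.i.d. normal coordinates, normalized — uniform on the sphere), keeps the
best, and refines it with Nelder-Mead. Design choices made here:

* **Density model.** The projected densities are modelled as Gaussians by
  default: the overlap then has a closed form, which is smooth (good for
  the simplex) and fast. A shared-grid histogram model (Freedman-Diaconis
  bin width on the pooled samples, range padded by 3 bin widths) is
  retained as a cross-check; the original estimator choice is not
  documented in the source method, so both are provided.
* **Normalization inside the objective.** The simplex operates on
  unconstrained d-vectors and the objective evaluates O(n/|n|), avoiding
  constrained optimization on the sphere.
* **Sign alignment before averaging.** O(n) = O(−n), so averaging raw scan
  vectors would be ill-defined. Each scan vector is flipped to a positive
  dot product with the running mean; the first scan defines the
  orientation. Scans are unweighted in the average.
* **Convergence diagnostic.** The running per-coordinate variance of the
  aligned scan vectors is recorded (`variance_trace`); small final values
  mean the scans agree. When the two ensembles are perfectly separable the
  overlap can underflow to zero and the *direction* within the zero-overlap
  set is not unique — the diagnostic makes this visible.

Publication-scale defaults are 500 scans × 2000 vectors; the test-suite
and examples use 10-20 × 80-200, which recover planted directions in
30-dimensional spaces to |cos| > 0.99 within seconds.

## Functional mode analysis

FMA regresses a scalar functional quantity f on the coordinate
fluctuations, f = XᵀW_k β_k + ε, via single-response PLS (NIPALS with
deflation). Component count k is the regularization knob: `cross_validate()`
fits k = 1…k_max on the model-building half (frame-ordered split by
default, matching the usual first-half/second-half trajectory usage) and
evaluates the Pearson correlation R_v on the held-out half; the chosen k
is the smallest within 0.005 of the maximum (a parsimony rule — the
convergence tolerance is not pinned by the source method, 0.005 is this
package's choice). `validate_independent()` evaluates a fitted model on a
genuinely independent ensemble.

Numerical notes:

* At full rank PLS1 reproduces ordinary least squares; this equivalence is
  pinned by a test and is the correctness anchor for the implementation.
* At k = 1 a single latent component does not generally span the OLS
  solution, so even a noiseless linear target yields R_m slightly below 1
  at low k; R_m and R_v approach 1 as k grows. This is a property of PLS,
  not a defect.
* The "ensemble-weighted mode" is the normalized coefficient vector of the
  fitted linear map from centered coordinates to predictions — the
  direction whose motion correlates best with f.
* The intended f here is the RMSD to a straight reference conformation: a
  *nonlinear* functional of the coordinates fitted by a linear model.
  Adequacy is judged purely by R_m/R_v, as in the original application.

## Umbrella sampling, WHAM and errors

`wham()` implements the standard self-consistent iteration over window
free-energy constants f_i, in kT units throughout (kT = 2.494 kJ/mol at
the default 300 K; spring constants are supplied in kJ·mol⁻¹·nm⁻² and
converted). Per-window equilibration spans (`discard`) are dropped before
histogramming. Convergence is declared when the largest change in any f_i
falls below 10⁻⁷ kT (default); the default grid is 100 bins over the
occupied range — neither is pinned by the source method. Non-overlapping
adjacent windows trigger a warning naming the gap. A zero-bias window
reduces WHAM exactly to direct Boltzmann inversion (`pmf_from_projection`),
which is tested to 10⁻¹⁰.

**Bayesian bootstrap.** Replicas re-run WHAM with complete window
histograms reweighted by Dirichlet(1,…,1) weights over windows — whole
histograms, not individual samples, are the resampling unit. Each replica
is min-aligned to zero before the per-bin standard deviation is taken.
Because of that alignment, the global-minimum bin is the anchor of the
error estimate: uncertainties are small there by construction and largest
where window reweighting shifts relative level, typically the barrier.

**Block-average mean forces.** As an independent cross-check,
`mean_force_error()` estimates the standard error of each window's mean
position from block means and converts it to a mean-force error via the
spring constant. The block size follows T/(2τ+1) with τ in the convention
where that expression is the effective number of independent samples.
`autocorr_time()` returns the integrated autocorrelation time in the Sokal
convention τ_int = ½ + Σ_{t≥1} ρ(t) (white noise → 0.5), with a
self-consistent summation cutoff at the first lag ≥ 6 τ_int; the bridge
between the conventions is τ = τ_int − ½. Two practical guards: the block
size is capped so that at least 10 blocks remain (the literal formula
yields a single block for an uncorrelated series, leaving no spread
estimate), and windows too short for 2 blocks raise an error rather than
returning a fake uncertainty.

**Basins.** `basin_analysis()` smooths the profile with a 3-bin moving
average *only to locate* the two deepest minima and the highest interior
maximum between them (raw histogram profiles are noisy; reported depths
are read off the unsmoothed profile at the located bins). Depths are
negative numbers relative to the barrier, ΔΔG is their difference, and the
two-state population of the deeper basin is p = 1/(1+e^(−|ΔΔG|)).
`kink_energy()` reads the free-energy cost of holding a structure at a
given coordinate value (nearest occupied bin) relative to the profile
minimum.

## What the synthetic generators emulate — and what they do not

* `gen_two_gaussian_ensembles()` plants two multivariate Gaussians with
  means ±(gap/2) along a known unit vector. It emulates the *geometry* of
  two well-separated simulated ensembles (the planted default gap of 8σ
  mirrors ensembles with no overlap), not their kinetics, anharmonicity or
  atom-level structure.
* `gen_hinge_dimer()` builds a two-arm bead model whose bending angle is
  Boltzmann-distributed with stiffness κ (variance 1/κ in kT units,
  default κ = 10 kT/rad², θ₀ = 0.3 rad ≈ an intermediately kinked dimer)
  and whose far arm can occupy a second state displaced out of the bending
  plane (the "anchor shift"). Arms are built along fixed lab axes before
  jitter so the planted bending direction has a closed form, and frames
  need no superposition. By construction the state-separating direction is
  orthogonal to the bending mode — the package-level test that the
  separation search recovers this decoupling is a geometric validation,
  not evidence about any real protein.
* `gen_umbrella_windows()` samples window series by Metropolis Monte Carlo
  rather than Langevin dynamics: the stationary distribution is exact, so
  WHAM errors measure WHAM, not integrator bias. Defaults (11 windows over
  [−1.6, 1.6] nm for the 5 kT double well, k = 100 kJ·mol⁻¹·nm⁻², within
  the 45–150 kJ·mol⁻¹·nm⁻² range typical of such calculations) give
  well-overlapping histograms.

Passing tests on these generators show the estimators are correct on data
satisfying their assumptions. Real trajectory data add slow correlated
motions, anharmonic basins and incomplete sampling; none of those failure
modes are represented here, which is precisely why the published
landscape numbers for tubulin cannot be regenerated at desk scale — they
required tens of microseconds of atomistic MD.

## Problem sizes and determinism

Test and example problem sizes are chosen so the whole suite completes in
about a minute on one CPU: separation searches at 10–20 scans × 80–200
vectors in d ≤ 10, WHAM oracles at 11 windows × (6–30)×10³ Metropolis
steps, FMA at a few hundred frames × 10–20 coordinates. Every stochastic
stage takes an explicit seed; `run_pipeline()` derives per-stage sub-seeds
from one master seed and logs them in its summary, so a rerun with the
same configuration is bit-identical.

## Known limitations

* Reaction coordinates are linear; committor-based or nonlinear RC
  optimization is out of scope.
* WHAM is 1-D; 2-D surfaces come from unbiased projections only.
* The Gaussian density model understates overlap for strongly non-Gaussian
  projections; use the histogram model as a cross-check.
* `read_pdb_ensemble()` requires identical atom counts after selection —
  it does no sequence alignment or gap repair.
* Basin analysis assumes a double-well topology; profiles with more than
  two relevant minima should be split manually via the `split` argument.
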