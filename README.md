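# bendrc

Conformational-ensemble analysis of protein bending motions, built around
the workflow used to characterize the bending energetics of the αβ-tubulin
dimer: principal component analysis of structure ensembles, an
ensemble-separation reaction-coordinate search, partial-least-squares
functional mode analysis, and umbrella-sampling/WHAM free-energy
reconstruction with basin energetics.

## Who this is for

Structural bioinformaticians and molecular-simulation practitioners who
have (a) ensembles of structures — sets of PDB files or trajectory
coordinate matrices — and (b) optionally umbrella-sampling time series
along a reaction coordinate, and want to quantify collective motions and
the free-energy landscape connecting conformational states.

## The methods

**PCA of conformational ensembles.** After Kabsch superposition onto a
reference structure, the covariance matrix of atomic positions
C_ij = ⟨(x_i − ⟨x_i⟩)(x_j − ⟨x_j⟩)⟩ is diagonalized, C = QΛQᵀ. Projections
q_k = (x − ⟨x⟩)·v_k are the conformational modes; for structure sets with
far more coordinates than frames the decomposition runs exactly through the
F×F Gram matrix.

**Ensemble-separation reaction coordinate.** Given two ensembles, the
method seeks the unit vector n minimizing the overlap integral
O(n) = ∫ ρ̄₁(z, n) ρ̄₂(z, n) dz of the two projected densities, searching in
the span of the first d combined-PCA eigenvectors (d is a regularization
dimension). The search runs many independent scans — each picks the best
of thousands of random unit vectors and refines it by downhill simplex —
then sign-aligns and averages the scan vectors. For Gaussian density
models the overlap has the closed form
exp(−(μ₁−μ₂)²/(2(σ₁²+σ₂²)))/√(2π(σ₁²+σ₂²)).

**Functional mode analysis (FMA).** The regression f = XᵀW_k β_k + ε is
solved by single-response PLS (NIPALS); the component count k is chosen by
cross-validation against held-out frames, and the normalized coefficient
vector is the ensemble-weighted mode of motion maximally correlated with
the functional quantity f (here, RMSD to a straight reference structure).

**Free energies.** Umbrella windows with harmonic biases
V_i = ½k(z − x_i)² are combined by WHAM self-consistent iteration into a
profile G(z) in kT. Uncertainties come from Bayesian bootstrapping of
complete window histograms (Dirichlet weights over windows) and, as a
cross-check, block-average mean-force errors with block size T/(2τ+1).
Basin analytics report depths relative to the dividing barrier, ΔΔG, and
the two-state Boltzmann population p = 1/(1 + e^(−ΔΔG)).

A synthetic-data module (`gen_two_gaussian_ensembles`, `gen_hinge_dimer`,
`gen_umbrella_windows`, `analytic_pmf`) plants known ground truth for every
stage, so the whole pipeline is testable without MD trajectories.

## Worked example

```r
library(bendrc)

# two synthetic conformational ensembles separated along a planted direction
gg <- gen_two_gaussian_ensembles(dim = 30, n_frames = 2000, gap = 8, seed = 3)
sr <- search_separation_rc(gg$ens1, gg$ens2, d = 5, n_scans = 10,
                           n_vectors = 200, seed = 4)
abs(sum(sr$n_hat * gg$separation_vector))
#> [1] 0.9987893
sr$overlap_value
#> [1] 3.681307e-08

# umbrella sampling + WHAM on a quartic double well (barrier 5 kT)
pot  <- toy_potential("quartic_double_well", barrier_h = 5, width_w = 1)
wins <- gen_umbrella_windows(pot, centers = seq(-1.6, 1.6, length.out = 11),
                             spring_k = 100, n_steps = 20000,
                             discard = 1000, seed = 6)
profile <- wham(wins, bins = 80)
basin_analysis(profile)
#> basins: dG1 = -5.19 kT, dG2 = -5.11 kT, ddG = -0.07 kT
#> barrier at 0.0142 nm; deeper-basin population 0.5185
```

The recovered separation direction agrees with the planted one to
|cos| ≈ 0.999, the minimized ensemble overlap is ~3.7×10⁻⁸ (essentially
disjoint densities), and WHAM recovers the 5 kT barrier within sampling
noise with near-equal basin depths for the symmetric well, as it should.

End-to-end runs go through a single configuration:

```r
fx <- tempfile(); write_fixture_set(fx, master_seed = 21)
summary <- run_pipeline(list(out_dir = tempfile(), seed = 5,
                             ensembles = list(fixture_dir = fx)))
```

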