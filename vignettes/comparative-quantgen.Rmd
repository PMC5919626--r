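---
title: "Comparative quantitative genetics of protein shapes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative quantitative genetics of protein shapes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapeselect)
```

## The model

A protein structure is treated as a *shape phenotype*: one 3-D landmark per
homologous residue, the landmark being the unweighted centroid of the
residue's side-chain heavy atoms together with the alpha carbon (for
glycine, the CA itself). An ensemble of snapshots of one structure —
molecular-dynamics frames or NMR models — is a *population of repeated
measures* of that phenotype; a set of homologous structures is a sample of
diverging *taxa*. After Generalized Procrustes superimposition (GPS), the
concatenated (x, y, z) coordinates of the k homologous landmarks form the
phenotype matrix **P** (n observations × l = 3k traits), with one group
label per homolog.

Classical mixed-model estimators of the additive genetic covariance matrix
**G** (REML animal models, phylogenetic mixed models) are not usable at
this dimensionality: a modest protein has l near 900 while the number of
homologs is a few dozen. `shapeselect` instead uses the decomposition

* **V_P** — the sample covariance of all rows of **P**;
* **W** — the pooled within-group covariance: deviations from each group's
  own mean, cross-products summed over all observations, normalized by
  n − S. This is the *dynamic* matrix **M**, carrying thermodynamic
  flexibility;
* **B = V_P − W** — the between-structure component, the proxy for **G**.

The identity V_P = W + B holds exactly by construction. Two caveats are
inherent and documented rather than patched: the independent error term
cannot be separated (W absorbs within-group error, B between-group error),
and **B** is rank-deficient (rank at most S − 1) and not guaranteed
positive semidefinite. `psd_repair()` offers eigenvalue clipping for users
who need a PSD matrix, but every internal computation uses the raw
difference.

On top of the decomposition sit the breeder's-equation quantities:

* predicted response **Δz̄ = G β**;
* realized response **Δz̄ = μ_target − μ_source**, the difference between
  two mean shapes in the common Procrustes frame;
* long-term selection gradient **β_λ = G⁺ Δz̄** (and the *dynamic
  gradient*, the same construction with **M** in place of **G**);
* the constraint angle between Δz̄ and β (0° = unconstrained, 90° =
  absolute constraint), and the angle between a vector and the leading
  eigenspace of **G** holding a chosen share (default 99%) of its
  variation.

Fitness enters only through the choice of the target and source models.
The default proxy is stability — unfolding energy per residue, ΔG°/r,
since raw totals are not comparable across proteins of different size —
optionally multiplied by catalytic efficiency kcat/KM on a common
substrate. Any per-model scalar works; the framework is fitness-agnostic.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| GPA scaling | off | — | protein size in Å is physically meaningful and stability proxies are size-dependent; full similarity GPA is available via `scale = TRUE` |
| GPA tolerance | 1e-10 | Å² | objective change between sweeps; the objective is provably non-increasing |
| GPA max iterations | 100 | — | non-convergence warns and flags, never errors |
| pseudo-inverse tolerance | 1e-10 × l | relative | singular values below `tol × max(sv)` are truncated; an optional ridge (`G + εI`) is offered instead |
| eigenvalue share | 0.99 | — | subspace-angle cutoff over the positive spectrum |
| skewers | 1000 | — | common convention; the Monte-Carlo standard error of the mean response correlation is well below the differences of interest |
| ranking panel size | 5 | residues | mirrors the usual top-5 report tables |

Reflections are never allowed in superposition (protein chirality is
physical); rotations are proper by construction.

## What the simulator emulates — and what it does not

`simulate_dataset()` reproduces the *grouped* structure of
ensemble-derived shape data: taxon means drawn from MVN(0, B_true),
replicates around each mean with MVN(0, W_true), plus an independent
isotropic error term (default variance 5% of the mean within-group trait
variance, a small measurement-error share). Generating matrices default to
random PSD matrices with log-uniform eigenvalues spanning two decades —
enough anisotropy that random-skewer comparisons are informative (with a
flat spectrum every response is parallel to its skewer and the test is
trivially 1).

The generator does *not* emulate Procrustes-induced correlations, the
steeply decaying eigenvalue spectra of real shape covariances,
non-Gaussian dihedral flips, autocorrelation along an MD trajectory, or
phylogenetic structure among taxon means (an optional Brownian-motion
generator on a user-supplied tree, `simulate_means_bm()`, covers the last
point). Passing benchmarks on simulated data therefore demonstrates the
*estimators*, not the realism of any particular protein family analysis.

### The benchmark's truth basis

`feasibility_benchmark()` scores the estimated **B** against the
*realized* between-group covariance — the sample covariance of the taxon
means actually drawn — rather than the generating matrix, and the
estimated **W** against the generating W_true. This is a deliberate and
important choice:

* the pooled-within construction targets exactly the realized between
  structure; the iid error term cancels in the difference V_P − W, while
  it inflates W away from its generating matrix (which is why the
  within-accuracy column sits slightly below the between-accuracy one);
* with p traits above the number of taxa, the generating matrix is not
  identifiable from any estimator — the estimate has rank at most S − 1 —
  so a generating-basis score conflates estimator error with finite-taxon
  sampling noise that no method can remove.

Both bases are available (`truth = "generating"` exposes the other), and
the generating-basis score is the right tool for questions about
finite-taxon sampling (it rises steadily with the number of taxa, which is
one of the package's validation properties).

## Numerical choices

* Angles are computed with the `atan2` form of the angle between unit
  vectors, which is exact near 0° and 180° where `acos` of a clamped
  cosine loses half the available precision. All angles are reported in
  degrees.
* Multivariate normal draws use the symmetric eigen square root, not a
  Cholesky factor, so numerically singular PSD matrices (geometrically
  decaying spectra, rank-deficient user matrices) are valid inputs.
* Covariances are computed by two-pass centered cross-products in double
  precision; **B** is symmetrized as (B + Bᵀ)/2 to kill round-off
  asymmetry.
* Tie-breaks are deterministic everywhere: ambassador ties go to the
  lowest model id, fitness-extreme ties to the lexicographically lowest
  (structure, model), PCA eigenvector signs are fixed so the
  largest-magnitude loading is positive.
* Degenerate inputs fail loudly: fewer than 3 landmarks or collinear
  configurations, singleton groups, zero vectors in angle computations,
  and all-zero covariance matrices are errors, not NaNs. The one deliberate
  soft case: a pipeline run whose source equals its target returns zero
  response, zero gradients and `NA` angles.

## Design decisions that were genuinely open

* **Centroid atom set.** The heavy-atom description of the landmark rule
  can be read as carbon/oxygen/nitrogen only. We include *all*
  non-hydrogen side-chain atoms by default because silently excluding
  sulfur distorts cysteine and methionine centroids by up to an Ångström;
  `strict_con = TRUE` restores the narrow reading.
* **Ranking rules.** The two report panels use different orderings:
  directional-selection candidates are ranked by descending sum of
  absolute gradient components among residues with at least one positive
  component; purifying candidates by ascending sum of the raw components
  among residues with at least one negative component. A residue with
  mixed signs can legitimately appear in both panels.
* **Which vector is measured against the eigenspace.** Both the response
  and the gradient angle to the retained eigenspace are computed and
  reported; they answer different questions (is the *observed divergence*
  reachable, vs. is the *selection pressure* aligned with available
  variation).
* **Rank-deficient inversion.** Truncated pseudo-inverse by default — the
  annihilated directions are exactly those carrying no between-group
  variation — with an explicit ridge option for users who prefer
  shrinkage over truncation.

## Validation problem sizes

The shipped checks exercise the estimators at 100 taxa × 500 replicates
with 2 to 1024 traits and 1000 skewers — the reference simulation
conditions — plus exhaustive small-scale oracles: hand-computed
covariances, closed-form superposition RMSD on random pairs,
pseudo-inverse round trips on rank-deficient matrices, and a 10⁶-draw
Monte-Carlo oracle for the skewer correlation of anisotropic 2-D
matrices. At these conditions the between-group accuracy (realized basis)
stays above 0.998 for every trait count, with a slow decline at the
highest dimensionalities driven by the cross-covariance between taxon
means and the within-replicate noise — an intrinsic property of the
pooled estimator, not of its implementation.

## Known limitations

* The genetic interpretation of **B** is a proxy: no phylogeny enters the
  estimator, and shared ancestry among close homologs inflates apparent
  "genetic" covariance.
* W mixes flexibility with measurement error; nothing attempts to split
  them.
* Gradients are expressed in the Procrustes frame of the analyzed set;
  they are comparable within one run, not across runs with different
  landmark sets.
* The per-residue maps collapse signed 3-D gradients to magnitudes;
  candidate residues must be re-examined per coordinate (the ranking
  tables carry the signed components for exactly this reason).
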