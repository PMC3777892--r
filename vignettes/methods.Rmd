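---
title: "Methods: admixture range classification and residual-IBD surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: admixture range classification and residual-IBD surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical procedures implemented in
`spatgen`, the assumptions behind them, the defaults and why they were
chosen, and what the package's tests do and do not establish.

## The data model

The package works with three joined tables: a long genotype table
(sample × locus, unordered pairs of positive-integer allele labels,
missing calls allowed), planar sample coordinates in kilometres, and an
n × K admixture matrix Q whose rows sum to 1. Longitude/latitude input is
projected once on read with an equirectangular projection about the data
centroid; at a few hundred kilometres of extent the distortion is well
below the grid resolution, but users with larger or high-latitude study
areas should supply pre-projected coordinates. Missing genotype calls are
handled by locus-wise deletion everywhere: a sample contributes to every
statistic at the loci where it was scored, and is never dropped wholesale.

## Inverse-distance interpolation

All surfaces use inverse-distance weighting with the weight fixed at
w = 1/d (power 1, not configurable) over *all* data points, so the field
at grid point g is v(g) = Σᵢ vᵢ/d(g,i) / Σᵢ 1/d(g,i). A grid point within
`eps` (default 1e-6 km) of data points takes the plain mean of those
coincident values, which is the analytic limit of the weights. Because
interpolation is linear in the values, interpolating the K columns of a
row-normalised Q matrix yields fields that sum to exactly 1 at every grid
point; the tests assert this to 1e-9.

The default grid is the samples' bounding box padded by one spacing, at
5 km — the conventional resolution for regional-scale landscape genetics.
An optional polygon mask (even-odd ray casting) restricts the analysed
area, e.g. to land; coverage fractions are always reported over retained
points only.

## Range classification

For each genetic group, the observed interpolated membership field is
compared, at every grid point, with a null distribution obtained by
re-assigning the Q rows to the fixed sample locations `n_boot` times
(default 1000). Bounds are the empirical α/2 and 1−α/2 quantiles
(inverse-CDF, type 1) of the replicate values; a point is **core** if the
observed value strictly exceeds the upper bound, **outside** if strictly
below the lower bound, and **probable** otherwise — observed values
exactly on a bound fall in **probable**, the conservative tie-break.

**Resampling scheme.** The default re-assignment is a permutation of the
Q rows (without replacement). This was a genuinely open design choice:
resampling rows *with* replacement (a bootstrap null) looks equally
natural, and both are implemented (`resample = "bootstrap"`). The
permutation default was chosen because it makes the observed field
exchangeable with the null replicates — the observed arrangement is
itself one permutation — so under spatially unstructured Q the
classification attains its nominal pointwise error rate exactly. The
bootstrap null does not have this property: a with-replacement draw of n
rows has sampling variance Σwᵢ²·S², whereas a permutation field varies
only by the finite-population analogue Σwᵢ²·S² − (Σwᵢ)²·S²/n; the
bootstrap null is therefore over-dispersed (severely so where the IDW
weights are diffuse), and classification against it is conservative far
below the nominal α. The acceptance suite verifies the permutation
null's calibration empirically (non-probable rate within ±0.015 of
α = 0.05 over 200 unstructured datasets).

Inference is pointwise by design: no correction is applied across grid
points or groups, and the per-point error rate, not a family-wise rate,
is controlled. Neighbouring grid points share interpolation weights and
are strongly dependent, so the *count* of significant points is not a
test statistic. The per-group report also flags multi-part core areas by
counting 4-neighbour connected components of the core set.

## Distances

**D_LR** is the genotype likelihood ratio distance: with group allele
frequencies under Hardy–Weinberg proportions, log L(i|P) = Σ log10 pₐ²
(homozygote) or log10 2pₐp_b (heterozygote) over i's scored loci, and
D_LR(i,j) = ½[(logL(i|Pᵢ) − logL(i|P_j)) + (logL(j|P_j) − logL(j|Pᵢ))].
Conventions, all configurable where meaningful: log base 10; frequencies
from the individual's own group are computed leave-one-out (its two
allele copies removed) by default; zero or unobserved frequencies are
replaced by 1/(G_P + 1), G_P the group's gene-copy count at the locus,
applied after leave-one-out. Group labels default to the table's labels
or the per-row argmax of a supplied Q matrix. The strict formula gives
exactly 0 for same-group pairs; where within-group resolution matters,
the group-free **D_PS** (one minus mean proportion of shared alleles,
multiset intersection per locus) is the intended metric. D_LR may be
negative; it is not clamped.

## Isolation by distance

The IBD trend is fitted by least squares over all n(n−1)/2 pairs with the
reverse exponential asymptotic model ŷ(d) = a − b·e^(−c·d), constrained
b, c ≥ 0 so the expectation is monotone non-decreasing and saturating.
Initialisation is from distance-bin means (a₀ = max bin mean,
b₀ = a₀ − min bin mean, c₀ = 1/median distance), fitted with
Levenberg–Marquardt under box constraints; non-convergence falls back to
the linear model with a warning. Mantel significance uses joint
row/column permutations with the one-sided convention
p = (1 + #{r_perm ≥ r_obs})/(1 + n_perm), 999 permutations by default; an
exhaustive mode enumerates all n! relabellings for n ≤ 8.

## Residual surfaces (DResD)

Residuals (observed − fitted IBD) are attached to pair midpoints and
interpolated per geographic distance class. A single IBD curve is fitted
on the full distance range and residuals are then subset by class —
re-fitting per class is deliberately not the default, since the
correction represents one population-wide process. The default classes
20–80, 80–140 and 140–250 km separate within-home-range movements,
juvenile/solitary dispersal and long-range migration at the spatial scale
of a mobile terrestrial mammal; classes are half-open [d_min, d_max), so
no pair enters twice.

The null permutes residual values among the fixed midpoints of the class
(`n_iter` = 1000 by default) — permutation rather than bootstrap, for the
same exchangeability reason as above, and because it preserves the
residual distribution exactly. Per grid point the two tail proportions
p_hi = (1 + #{null ≥ obs})/(1 + n_iter) and p_lo likewise are computed;
the reported two-sided p is min(1, 2·min(p_hi, p_lo)), and a point is
labelled **high** when p_hi ≤ α/2, **low** when p_lo ≤ α/2, otherwise
**ns**. Defining labels from the rank-based p (rather than from raw
percentile bounds, which can disagree by one rank at finite n_iter)
guarantees that labelled points always satisfy p ≤ α. Classes with fewer
than 10 pairs are reported as `empty` rather than as a zero surface.

Two caveats are inherent to the published procedure and are carried over
deliberately: pairs sharing an individual are treated as independent by
the null, and inference is again pointwise. Pair bearings are emitted as
plotting metadata only.

## Diversity statistics

Per locus over scored individuals: H_O is the heterozygote fraction;
H_Eunb = 2n/(2n−1)·(1 − Σp²) (Nei's small-sample correction, so
H_Eunb ≥ 1 − Σp² always); N_A the allele count; allelic richness by
hypergeometric rarefaction A_R = Σᵢ[1 − C(G−Gᵢ, g)/C(G, g)] at
g = 2·raref_n gene copies, computed on log-binomials for stability.
`raref_n` is given in individuals (default: the smallest per-locus
sample size). F_IS defaults to Weir & Cockerham's f from variance
components summed over alleles and loci (the estimator classic
population-genetics software reports as Wright's F_IS), with
1 − H_O/H_Eunb available as `fis_mode = "nei"`; confidence limits come
from a percentile bootstrap over loci (1000 replicates), loci being the
exchangeable units of a multilocus estimate. Pairwise F_ST is
Weir & Cockerham's θ as a multilocus ratio of summed components. A table
monomorphic at every locus yields F_IS = NA with a warning.

## The synthetic generator

`synth_config()`/`simulate_dataset()` generate the datasets used by the
tests and the acceptance script: per-locus base allele spectra (flat
Dirichlet over 8 alleles), group frequencies drawn around them with
total concentration 15 — giving expected pre-admixture differentiation
near 1/(1+15), i.e. pairwise θ of a few percent as reported between
neighbouring genetic groups of mobile mammals — Gaussian spatial scatter
(60 km) about 4 group centres in a 600 × 300 km area, membership rows
from a distance softmax with 50 km blending width, and genotypes drawn
under HWE within each individual's q-weighted mixture frequency. With
166 individuals and 16 loci the defaults produce mean H_O ≈ 0.75,
H_Eunb ≈ 0.78, N_A ≈ 7.5 and pairwise θ ≈ 0.02–0.06 — the regime of a
regional microsatellite study of a structured but connected population.

What the generator does *not* emulate: null alleles, allelic dropout and
genotyping error; mutation processes (allele labels are arbitrary small
integers, not fragment lengths); pack/pedigree structure; anisotropic or
resistance-driven gene flow. Passing calibration and recovery tests on
these data therefore show that the methods are correct and calibrated
under clean HWE sampling with known structure — not that they are robust
to marker artefacts or family structure in real data.

## Problem sizes and determinism

Every stochastic routine takes an integer seed and is bit-reproducible
given it; the pipeline expands one global seed into per-stage seeds by a
fixed counter scheme. The test suite runs its calibration properties at
reduced sizes chosen to keep the full suite under a minute on one CPU
(e.g. 200 replicate datasets with n_boot = 500 for classification
calibration, n_iter = 200 for the DResD global null, 400 datasets for
Mantel type-I error); the acceptance script runs the full study-scale
configuration (n = 166, 5-km grid, 1000 iterations) in about half a
minute. Quantile type 1 is used for all percentile bounds so that bounds
are always attained replicate values and tie-breaks are exact.

## Known limitations

- Pointwise inference everywhere; no spatial multiple-testing control.
- The permutation nulls condition on the observed value sets; they test
  spatial arrangement, not the values' distribution.
- D_LR is exactly 0 within groups by construction; within-group spatial
  analysis should use D_PS.
- The equirectangular projection is adequate only at regional extents.
- IDW with power 1 never extrapolates beyond the data range and flattens
  toward the global mean far from samples; classifications far outside
  the sampled area reflect that shrinkage, not biology.
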