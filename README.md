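# spatgen

Individual-based spatial population genetics in R: where are the genetic
groups of a continuously distributed population, and where does the
landscape help or hinder gene flow?

`spatgen` is aimed at landscape and conservation geneticists working with
multilocus genotypes (microsatellites or any marker yielding individual
genetic distances) sampled at known locations. It implements two
grid-based inference methods along with the distance and diversity
statistics they depend on:

1. **Admixture range classification.** Given an n × K admixture matrix Q
   (each row the membership coefficients *q* of one individual, rows
   summing to 1) and sample coordinates, each cluster's *q* column is
   interpolated onto a regular grid by inverse-distance weighting,

   v(g) = Σᵢ qᵢ/d(g,i) / Σᵢ 1/d(g,i)  (weight w = 1/dist, power 1),

   and every grid point is classified per group against a resampling
   null that re-assigns the *q* rows to the fixed sample locations:
   **core** area (observed above the null's 97.5th percentile),
   **probable** range (between the 2.5th and 97.5th percentiles), or
   **outside** the range (below the 2.5th percentile). The result is a
   statistically explicit map of each genetic group's range.

2. **Residual-IBD surfaces (the DResD procedure).** Pairwise genetic
   distances are corrected for isolation by distance (IBD) by fitting a
   reverse exponential asymptotic curve ŷ(d) = a − b·e^(−c·d) over all
   pairs; the residuals (observed − ŷ) are interpolated at the pair
   *midpoints* within geographic distance classes (defaults 20–80,
   80–140, 140–250 km), with pointwise significance from permuting
   residuals among the fixed midpoints. Significantly **low** areas are
   candidate migration corridors (individuals more similar than IBD
   predicts); significantly **high** areas are candidate barriers or
   contact zones.

Supporting modules: the genotype likelihood ratio distance D_LR (log10
likelihood-ratio assignment index under HWE, with leave-one-out),
proportion-of-shared-alleles distance D_PS, Euclidean geographic
distances, Mantel tests (with exact enumeration at small n), observed and
Nei's unbiased expected heterozygosity, rarefied allelic richness (Petit
hypergeometric), Weir–Cockerham F_IS/F_ST, readers/writers for STRUCTURE
2-row, GenePop and wide-CSV genotype formats plus STRUCTURE ancestry
blocks, a seeded simulator of spatially structured genotype datasets, a
YAML-configured pipeline runner and a thin CLI
(`inst/cli/spatgen.R`).

## Worked example

Simulate a two-group landscape (80 individuals, 12 loci, group centres
360 km apart), then run the full workflow:

```r
library(spatgen)

sim <- simulate_dataset(synth_config(n = 80, k = 2, n_loci = 12, seed = 42,
                                     centers = rbind(c(120, 150), c(480, 150))))

diversity_summary(sim$genotypes, n_boot = 500, seed = 1)
#> <diversity_summary> 12 loci
#>   mean H_O = 0.676, mean H_Eunb = 0.718, mean N_A = 6.92, mean A_R(80) = 6.92
#>   multilocus F_IS (wc) = 0.0582 [0.028, 0.087] (95% bootstrap over loci)

dgen  <- dlr_distances(sim$genotypes, groups = sim$truth$group)
pairs <- build_pairs(sim$geo, dgen)
ibd   <- fit_ibd(pairs, "asymptotic_exp")
ibd   <- set_mantel(ibd, mantel_test(geographic_distances(sim$geo), dgen,
                                     n_perm = 999, seed = 2))
ibd
#> <ibd_model> asymptotic_exp, 3160 pairs, R^2 = 0.622
#>   parameters: a = 6.659, b = 8.05, c = 0.002194
#>   Mantel r = 0.775 (r^2 = 0.601), p = 0.001 [999 permutations]
```

The mean observed heterozygosity (0.68) sits just below the unbiased
expectation (0.72) — the mild heterozygote deficit (F_IS = 0.06, CI
excluding 0) is the Wahlund effect of pooling two diverged groups. The
Mantel test shows strong IBD, as built into the simulation: D_LR grows
with distance toward the asymptote a.

Classify the grid into core / probable / outside range per group, and map
where genetic distance deviates from the IBD expectation:

```r
rc <- classify_ranges(sim$membership, sim$geo,
                      grid = grid_from_samples(sim$geo, spacing = 10),
                      n_boot = 1000, seed = 3)
glance(rc)
#> # A tibble: 2 × 5
#>   group  core probable outside n_core_components
#> 1 G1    0.432   0.0541   0.514                 1
#> 2 G2    0.514   0.0541   0.432                 1

dr <- dresd_analysis(build_pairs(sim$geo, dgen, ibd_model = ibd),
                     grid_from_samples(sim$geo, spacing = 10),
                     n_iter = 1000, seed = 4)
glance(dr)
#> # A tibble: 3 × 7
#>   class_id d_min d_max n_pairs status frac_high frac_low
#> 1 20-80       20    80     427 used      0.0414   0.0336
#> 2 80-140      80   140     609 used      0.105    0.105
#> 3 140-250    140   250     562 used      0.308    0.551
```

Each group's core area covers ~43–51% of the grid, with a single
connected core per group, and each group's core is the other's
outside-range area — the planted spatial separation, recovered with
significance. In the residual surfaces, short-range pairs (20–80 km,
mostly within a group) sit near the nominal 5% rates, while the largest
distance class — dominated by between-group comparisons — shows large
significantly-low and significantly-high areas where the single global
IBD curve under- and over-predicts divergence around the two cores.
`autoplot()` renders the classified maps and residual surfaces;
`tidy()`/`glance()` return every result as a tibble.

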