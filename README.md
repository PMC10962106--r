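# episketch

Exhaustive two-dimensional (pairwise-epistasis) genome scans by
sketch-compressed ridge regression, with the simulation and evaluation
toolkit needed to validate them.

## The problem

A standard GWAS fits each SNP marginally; epistasis hides in the
interaction design `Z = X ⋆ X`, the face-splitting product holding one
column `x_i ∘ x_j` per unordered SNP pair. For a MAF-filtered *Arabidopsis*
panel of 346,094 SNPs that is 59,890,355,371 candidate interactions —
far beyond anything that can be materialized or tested term by term. This
package is for quantitative geneticists who want the full upper-triangle
map of estimated interaction effects

```
Y = X θ₁ + Z θ₂ + ε
```

without ever forming `Z`: a seeded random sketch `A` (gaussian or
rademacher, `E[AᵀA] = I`) compresses the Gram/kinship computation
(`W = Z̃Aᵀ`, cost `O(n·d·m)` for `d` terms sketched to dimension `m`), dual
weights come from ridge restricted to the sketch-captured subspace, and
effects are read out exactly as `θ̂ = Z̃ᵀα` in one `O(n·d)` pass. Estimates
are reported on the raw dosage scale, ranked by `|θ̂|` under a sparsity
budget (`N* = 50` by default), with no per-term p-values — selection is by
effect ranking, optionally calibrated by a permutation threshold.

Around the solver the package provides:

* a genotype/phenotype simulator with controlled narrow-sense heritability,
  sparse simple/pairwise/quadratic architectures, and the three Marchini
  two-locus interaction models at matched per-term variance;
* MAF and MIAF (minor *interaction* allele frequency) computation and
  strict `MAF > 0.3` prefiltering;
* truth-based evaluation (top-k recall, recovery %), and a brute-force
  exact-ridge oracle for small instances;
* principal-component-regression heritability curves comparing 1D,
  1D+2D, and 1D+random-2D feature sets (adjusted R² vs components);
* two-locus "2D-haplogroup" phenotype decomposition and a
  phenotype-classification harness (quantile classes, 50/50 split,
  best-class F1) comparing true against random interaction features;
* max-pooled pyramids of the interaction map for zoomable display
  (a level-11 pixel summarizes 4,194,304 SNP-pair cells).

## Worked example

```r
library(episketch)

# genotypes: 2000 inbred lines x 300 SNPs; one additive and two epistatic
# effects; noise tuned so that h2 = 0.4
X <- sample_genotypes(2000, 300, seed = 11)
arch <- architecture(
  simple = data.frame(i = 40L, theta = 1),
  pairs = data.frame(i = c(75L, 120L), j = c(210L, 280L),
                     theta = c(1, -1), type = "product"),
  target_h2 = 0.4, p = 300)
tr <- simulate_trait(X, arch, seed = 12)

flt <- filter_by_maf(X, 0.3)
em <- run_2d(flt$genotypes, tr$y,
             solver_config(block_size = 300L, sketch_dim = 1024L, seed = 1))
top_n_support(em, 5)
```

```
#> effect_map: 5 terms (3 singles, 2 pairs), p = 300
#>     kind   i   j      theta support_score
#> 1 single  40  NA  1.0708445     1.0708445
#> 2   pair  75 210  1.0545397     1.0545397
#> 3   pair 120 280 -0.9781327     0.9781327
#> 4 single 210  NA  0.5233649     0.5233649
#> 5 single 280  NA -0.5153273     0.5153273
```

The three planted effects head the ranking with estimates near their true
values (±1), followed by the real main-effect content (θ/2 ≈ 0.5) that a
raw-coding product interaction induces in its parent SNPs.
`recall_top_k(em, arch, 5)` returns 1: all three truths sit in the top 5.
`evaluate_scan(em, arch)` tabulates recall at several depths, and
`build_pyramid(em)` turns the map into max-pooled tiles.

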