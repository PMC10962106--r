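---
title: "Sketch-compressed exhaustive epistasis scans: model, solver and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sketch-compressed exhaustive epistasis scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Let $X$ be the $n \times p$ dosage matrix (individuals by SNPs) and $Y$ a
quantitative phenotype. The additive model

$$Y = X\theta_1 + \varepsilon$$

defines narrow-sense heritability $h^2 = \mathrm{var}(X\theta_1)/\mathrm{var}(Y)$.
Epistasis enters through the interaction design $Z = X \star X$, the partial
face-splitting (transposed Khatri–Rao) product holding one column
$z_{ij} = x_i \odot x_j$ per unordered SNP pair $i < j$ — self-products are
excluded, so $Z$ has $p(p-1)/2$ columns. The two-dimensional model

$$Y = X\theta_1 + Z\theta_2 + \varepsilon$$

is still linear, and the scan's output is the sparse vector of estimated
effects $\hat\theta$ over all singles and pairs, ranked by magnitude: no
per-term $p$-values are computed, so no multiple-testing correction applies;
selection is by effect ranking under an explicit sparsity budget, with an
optional permutation threshold for null calibration.

At genome scale this design is enormous (346,094 filtered SNPs give
59,890,355,371 pairs), which is why the solver never materializes $Z$.

## The compressed solver

`solve_block()` estimates a term set (singles and/or pairs) in four steps:

1. **Standardization.** Term columns are generated on demand from the raw
   dosages, centered and scaled to unit variance; $Y$ is centered.
   Estimates are rescaled to the raw coding afterwards, so $\hat\theta$
   reads as the effect of the variant (combination) against the reference
   coding.
2. **Sketching.** A seeded random matrix $A$ ($m \times d$, gaussian
   $N(0, 1/m)$ or rademacher $\pm 1/\sqrt m$, so $E[A^{\top}A] = I$) is
   applied implicitly: $W = \tilde Z A^{\top}$ costs $O(ndm)$ and `A` is
   regenerated per column chunk from a counter-based RNG rather than
   stored. $W W^{\top} = \tilde Z A^{\top} A \tilde Z^{\top}$ is the
   compressed estimate of the Gram/kinship structure of the term set.
3. **Subspace ridge.** With $W = U S V^{\top}$, the dual weights are
   $\alpha = U (S^2 + \lambda I)^{-1} U^{\top} Y$ — ridge regression
   restricted to the rank-$m$ subspace the sketch captured. Two closed
   forms avoid the SVD: $\alpha = (W W^{\top} + \lambda I)^{-1} Y$ when
   $m \ge n$ (full rank), and
   $\alpha = W\,(G(G + \lambda I))^{-1} W^{\top} Y$ with $G = W^{\top} W$
   when $m < n$. The naive alternative $(WW^{\top} + \lambda I)^{-1}Y$ at
   $m < n$ is *not* used: the rank-deficient kernel estimate would feed the
   orthogonal component $Y_\perp/\lambda$ — pure amplified noise — into
   every estimate.
4. **Read-out.** Two modes exist. The back-projection read-out
   $\hat\theta = A^{\top} c$ is the textbook decompression, but each
   coordinate picks up zero-mean cross-talk of order
   $\|v\|_2/\sqrt{mS}$ where $v$ spans *all* $d$ terms' marginal
   correlations; at $d \sim 5 \times 10^5$ this noise exceeds any
   realistic per-pair signal unless $mS \approx d$. The default
   `decompress = "exact"` read-out instead computes
   $\hat\theta = \tilde Z^{\top} \alpha$ in one exact $O(nd)$ pass: the
   sketch compresses only the quadratic (Gram) computation, which is the
   expensive part, while the linear read-out is done exactly. In the
   identity-sketch limit both modes coincide with ordinary ridge.

Independent sketches ($S$ = `n_sketches`) are averaged; because the exact
read-out is linear in $\alpha$, the average needs a single decompression
pass over the mean dual weights.

**Ridge penalty.** Default $\lambda = 0.1\,\mathrm{tr}(W^{\top}W)/m$, i.e.
a tenth of the mean compressed eigenvalue — large enough to stabilize the
rank-limited solve, small enough not to flatten the ranking. With
`lambda = "cv"` (used by the validation scenarios) the penalty is instead
selected per sketch by 5-fold cross-validated prediction error over a grid
of multiples of the mean compressed eigenvalue, computed entirely in the
compressed space (cost $O(nm^2)$, independent of $d$). $\lambda$ governs
the interpolation between kinship-whitened joint estimation (small
$\lambda$) and marginal screening (large $\lambda$); prediction-based
selection lets the data decide how much whitening the trait supports,
which matters because whitening costs detection power when no confounding
structure exists.

**Sketch dimension.** The package default follows the compressed-sensing
budget $m = \lceil c\,k_{\max}\log d\rceil$ with $c = 8$ and sparsity
budget $k_{\max} = 50$, capped at $d$ (at which point the solve is exact
and no averaging is needed). The scan scenarios below pin $m = 1024$
explicitly: the subspace argument says $m$ of the order of $n$ keeps the
captured sample subspace information-complete, and the single-core flop
budget ($2ndmS$ per block) then puts a full 500k-term scan at about a
minute per replicate.

## The genome-scale scan

`run_2d()` organizes the scan in three stages, after MAF filtering
(strictly greater than 0.3 by default — the observability of a product
column decays with the parents' minor allele frequencies, which is what the
minor *interaction* allele frequency, MIAF, quantifies):

* a genome-wide **singles pass** (identical to `run_1d()`) provides the
  diagonal. Singles are deliberately *not* estimated jointly with the pair
  columns: with $n \le d$ the minimum-norm solution prefers spreading a
  single SNP's signal over its $\sim p$ correlated product columns (each
  at correlation $\approx 0.58$ under Bernoulli-0.5 coding), burying the
  single while leaving pair signals concentrated;
* **pair blocks** following a block plan that covers every pair exactly
  once (diagonal pieces: intra-block pairs; off-diagonal pieces:
  cross-block pairs), each solved with the involved singles as covariate
  terms but reporting pairs only;
* a **debiasing refit**: the top-`n_star` singles and top-`n_star` pairs
  (pooled per kind — the two passes have different noise scales) are
  re-estimated by one joint hierarchical least-squares fit: support pair
  columns are residualized against the support singles, then $Y$ is
  regressed on singles plus residualized pairs. Singles report total main
  effects, pairs report pure interaction coefficients (for a planted raw
  product $\theta x_i x_j$ the pair coefficient is $\theta$ itself), and
  the residualization keeps the fit well-conditioned when the selected
  pairs crowd around one strong SNP's product columns — a naive joint OLS
  is nearly collinear there and its coefficients explode. The refit
  removes selection bias ("winner's curse") and compression attenuation
  from the retained terms.

The default sparsity budget `n_star = 50` reflects the very-high-dimension
constraint: reliable support recovery needs $k \log(p/k)$ small relative to
$n$, which caps the number of retrievable signals at a few tens for
genome-scale maps.

## The simulator

`sample_genotypes()` draws independent dosages — Bernoulli(0.5) in the
inbred coding (highly homozygous lines, the default) or Binomial(2, 0.5)
outbred. `sample_architecture()` dispatches non-null effects among simple,
pairwise and quadratic terms; `add_noise_for_h2()` adds Gaussian noise with
$\sigma^2 = \mathrm{var}(g)(1-h^2)/h^2$ so the realized heritability
converges to the target ("fixed" mode; "random" mode jitters $\sigma$
uniformly in $[0.8, 1.2]\sigma_0$ per replicate, emulating
replicate-to-replicate environmental variance — the two modes are named
but not defined in the sources this design follows, so the jitter band is
this package's choice). In inbred coding $x^2 = x$, so quadratic terms
alias with simple effects and are merged with a warning.

Pair effects come in four types: the raw `product` $\theta\, x_i x_j$ and
three Marchini two-locus models — multiplicative within and between loci
($\mu(1+\theta_m)^{a+b}$), interaction-multiplicative
($\mu(1+\theta_m)^{ab}$), and interaction-threshold ($\mu(1+\theta_m)$ iff
both dosages $\ge 1$). The exact constants behind the original tables are
not published; the tables here use $\mu = 1$ with configurable $\theta_m$,
and each Marchini contribution is baseline-centered and scaled so its
realized standard deviation equals $|\theta|$ — matched per-term variance,
so "type 1/2 are easier than type 3" comparisons are at equal signal
budget. $\theta_m = 0$ collapses all types to the null.

What the simulator does *not* emulate: linkage disequilibrium, population
structure, MAF spectra, or missingness. Passing recovery tests on these
independent-SNP conditions demonstrates the solver's statistical behavior,
not robustness to confounding in real cohorts.

## Validation scenarios and the numbers they target

* `scenario_small()`: $n = 5000$, $p = 100$, five planted terms (2 simple +
  3 pairs), $h^2 = 0.5$, full scan of all 5050 terms; the scan should place
  all five in the top 5. 20 replicates.
* `scenario_landscape(n)`: $p = 1000$ (500,500 candidate pairs), 10 planted
  pair effects, $h^2$ grid $\{0.05, 0.1, 0.2, 0.4\}$; the reference cell
  $n = 1000$, $h^2 = 0.2$ is scored by mean top-10 recall over at least 10
  replicates (the acceptance script recomputes this number). The
  $n = 10{,}000$ cell costs several minutes per replicate single-core; the
  test suite bounds it with a single reduced-budget replicate, and its
  detection power depends visibly on the sketch dimension relative to $n$
  (see limitations).
* `scenario_marchini()`: outbred coding, mixed interaction types at matched
  variance.

Planted effects have unit magnitude with random sign. This is the standard
recovery-study design once the signal budget is fixed by a target $h^2$;
with heterogeneous magnitudes the all-terms-in-top-$k$ condition is
structurally unattainable for a sizable fraction of draws under *any*
consistent estimator, because a strong pair's real induced main effect
($\theta/2$ per parent on raw coding) outranks a weak planted term.

Each replicate derives its generator and solver seeds deterministically
from the scenario root seed; all randomness in the package flows from such
derived seeds, and scenarios replay from their JSON serialization without
storing any matrix.

## Numerical choices and degenerate inputs

* Ranking ties are broken lexicographically by (kind, i, j).
* Constant term columns are excluded from solves and reported with
  $\hat\theta = 0$; a constant phenotype or a zero-variance genetic value
  is an error.
* Pair indexing is closed-form in both directions
  ($k = (i-1)p - i(i-1)/2 + (j-i)$ and its quadratic inverse, guarded
  against floating-point boundary slips); counts are exact in double
  precision since all products stay far below $2^{53}$.
* PCA in the heritability module is by SVD of the standardized feature
  matrix, components ordered by singular value with the sign fixed so the
  largest-magnitude loading is positive; variance explained is reported as
  adjusted $R^2$ ($q$ = number of components), in-sample, because the
  adjustment is what guards against dimensionality inflation.
* The pyramid max-pools $|\hat\theta|$ by factor 2 per level, padding odd
  axes with zeros; a level-$\ell$ pixel covers $4^{\ell}$ cells
  (4,194,304 at $\ell = 11$).

## Known limitations

* The subspace read-out attenuates when $m \ll n$: detection power at
  large $n$ requires $m$ to grow with $n$, and the flop cost $O(ndm)$ with
  it. This is the honest cost of compression on a single CPU; the block
  and sketch structure is what a GPU implementation would parallelize.
* The scan estimates effects, not uncertainty; `permutation_threshold()`
  calibrates the null maximum but is priced at a full re-solve per
  permutation, so it is practical for blocks, not for full genome maps.
* Recall targets quoted above are properties of these independent-SNP
  simulation conditions; LD would change both the difficulty and the
  meaning of an exact-match recall.
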