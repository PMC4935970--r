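---
title: "Methods: temperature dependence of soil microbial diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temperature dependence of soil microbial diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermodiv)
```

## The scientific question and the model

The metabolic theory of ecology (MTE) predicts that rates of biological
processes — and, through them, species richness — increase exponentially with
environmental temperature following Boltzmann–Arrhenius kinetics. For
richness the prediction specialises to

$$\ln S \;=\; a \;-\; E_a \cdot \frac{1}{kT},$$

with $S$ the (estimated) taxon richness, $T$ the absolute temperature in
kelvin, $k$ Boltzmann's constant ($8.617\times10^{-5}$ eV/K), and $E_a$ the
*activation energy* in electron-volts: the magnitude of temperature
dependence. On an Arrhenius plot of $\ln S$ against $1/(kT)$ the relationship
is a straight line, and $E_a$ is the fitted slope with its sign reversed.
`thermodiv` implements this analysis end to end for soil microbial OTU data:
alpha and phylogenetic diversity estimation, community-distance statistics
against environmental drivers, and activation-energy fitting with AIC model
comparison, plus a synthetic metacommunity generator with *known* $E_a$ so
that every stage can be validated against ground truth.

The analysis starts from an OTU count table (OTUs × samples), a sample
metadata table and, optionally, a rooted phylogeny with branch lengths over
the OTUs. Read-level processing (quality control, chimera removal, OTU
clustering, tree inference) is upstream of this package.

## Diversity estimators

**Chao1.** $\hat S = S_{obs} + f_1^2/(2 f_2)$, with $f_1$, $f_2$ the
singleton and doubleton counts. When $f_2 = 0$ the classic form divides by
zero; we use the standard bias-corrected fallback
$S_{obs} + f_1(f_1-1)/(2(f_2+1))$, which reduces to $S_{obs}$ when
$f_1 \le 1$. Zero-count rows are never counted as species. Site-level Chao1
pools the replicate samples' counts first (`pool_by_site()`), and by default
pools *raw* counts; rarefy first and pool the rarefied table if equal-effort
pooling is wanted. We default to raw pooled counts because pooling already
uses every read and Chao1's purpose is to extrapolate past sampling effort.

**Shannon** ($-\sum p_i \ln p_i$, natural log — convert before comparing with
log2-based outputs) and **inverse Simpson** ($1/\sum p_i^2$) weight evenness;
both are bounded by functions of $S_{obs}$ and tested against independent
recomputation on exhaustively enumerated small count vectors.

**Rarefaction** subsamples reads *without replacement* to a common depth
(the reads are a finite pool, so the retained counts are multivariate
hypergeometric; this is verified against the hypergeometric law in the
tests). Depth presets of 25,901 (16S), 13,688 (ITS) and 16,000 (*nifH*)
reads are shipped as `rarefaction_depths`. Samples below the requested depth
are an error by default; `drop_small = TRUE` drops them with a warning. Each
sample draws from its own RNG substream derived from the seed and the sample
id, so column order never changes results.

## Phylogenetic diversity

**Faith PD** is the branch-length sum over the union of root-to-tip paths of
the present OTUs — the *rooted* convention, so the stem to the root is
included (unrooted conventions differ; comparisons across software should
check this). PD is monotone under adding tips and equals the total tree
length for the full set.

**Abundance-weighted MPD and NRI.** The mean pairwise phylogenetic distance
weights each pair of distinct taxa by the product of relative abundances and
normalises by total off-diagonal weight,
$\mathrm{MPD} = \sum_{i\ne j} d_{ij} x_i x_j / \sum_{i\ne j} x_i x_j$
(the Phylocom abundance-weighted convention; an unnormalised variant is
available behind `normalize = FALSE` for sensitivity checks). The net
relatedness index compares observed MPD with a *phylogeny shuffle* null:
tip labels are permuted uniformly across the whole supplied tree — the
species pool is the tree, not just the observed taxa — holding abundances
fixed. Because a full-label permutation lands the observed taxa on a
uniformly random subset of tip positions, each null replicate is drawn by
sampling that many tip positions without replacement, which is exactly
equivalent and much cheaper. The default is 1,000 null communities; null
moments are accumulated in a single pass (Welford), and the full null vector
is only kept on request. NRI is the sign-reversed z-score,
$-(\mathrm{MPD}_{obs} - \overline{\mathrm{MPD}}_{null})/\mathrm{sd}$, so
positive values mean phylogenetic clustering. On trees where every shuffle
gives the same MPD (e.g. star trees) the null spread is zero and the result
is flagged `undefined` rather than reported as an arbitrary number. NRI is
computed per sample against the global tree for the table; per-site subtrees
are not used, because the null's species pool should be the same for every
community being compared.

## Distance-matrix statistics

Community dissimilarity is **Bray–Curtis** on counts as given (raw by
default — pass a rarefied table to work at equal depth). Environmental
distance is **Euclidean on z-scored variables**; joint factors such as
total C + total N are z-scored per variable and combined in one Euclidean
distance. The **Mantel test** correlates upper triangles and assesses
significance by jointly permuting rows and columns of the first matrix, with
the permutation-inclusive estimator $p = (1+\#\{r_{perm} \ge r_{obs}\})/(1+n_{perm})$,
so $p$ is never 0; the default 999 permutations and the one-tailed
("greater") alternative follow ecological convention, with a two-sided
option. The **partial Mantel** residualises both triangles on the control
matrices (plus intercept) by least squares and correlates residuals;
permutations relabel the first matrix and re-residualise against the fixed
controls (the simple residual-permutation scheme — one of several published
choices). When a matrix is numerically fully explained by the controls its
residual is a zero vector and the correlation is defined as 0. **BioENV**
searches all nonempty subsets of up to 15 candidate variables for the
subset whose z-scored Euclidean distance best rank-correlates (Spearman,
average ranks) with the community matrix. **Pearson tests** use the
$t = r\sqrt{(n-2)/(1-r^2)}$ statistic with $n-2$ degrees of freedom,
two-tailed.

## Activation-energy fitting and model comparison

`arrhenius_points()` converts Celsius to kelvin ($T = {}^\circ C + 273.15$)
and richness to $\ln S$ (richness must be $\ge 1$). Three model forms are
fitted by ordinary least squares:

* **linear** — $y = a + bx$; $E_a = -b$; 3 parameters. The sign-reversal
  definition of $E_a$ (not a reciprocal of the slope) is the one consistent
  with Boltzmann–Arrhenius algebra and with the magnitudes activation
  energies take in practice (tenths of an eV).
* **quadratic** — $y = a + bx + cx^2$; 4 parameters; no single $E_a$.
* **piecewise** — a continuous hinge
  $y = a + b_1 x + b_2 (x - x_0)_+$ with the breakpoint chosen by grid
  search over interior $x$ values (plus midpoints between adjacent values),
  each candidate keeping at least two points per side, minimising the
  residual sum of squares; 5 parameters. A continuous hinge, not two free
  intercepts: a discontinuous diversity–temperature response has no
  biological reading.

AIC is $-2\ln L + 2\,n_{par}$ with a Gaussian likelihood evaluated at the
maximum-likelihood residual variance $SS_{res}/n$; the residual variance is
counted as a parameter. That convention shifts all fits on the same data
equally, so AIC *differences* — the only quantity used — are unaffected by
it. For numerically exact fits the variance is floored at machine precision
relative to the response scale, so nested models that both interpolate the
data share one likelihood and differ only by the parameter penalty.
`select_model()` ranks fits by AIC, marks everything within 2 units of the
best as *competitive*, and breaks ties by higher $r^2$, then fewer
parameters. $Q_{10}$ conversion uses
$\exp(E_a\,\Delta T/(k T_1 T_2))$; 0.65 eV corresponds to a $Q_{10}$ near
2.5.

A caveat worth knowing: with very few observations (six site-level points),
plain AIC flags the extra-parameter models as competitive far more often
than the asymptotic ~5% excess would suggest, because the relevant
F-statistic has a heavy tail at 3 residual degrees of freedom. This is a
property of AIC at small $n$, not of the implementation; the acceptance
script measures the actual competitive rate on linear-generated data.
Small-sample corrections (AICc) would change the reported criterion and are
deliberately not applied.

## The synthetic metacommunity generator

`sim_config()` defaults encode the study design the package targets: 6 sites
at 2.5, 7, 12, 17, 21 and 25.7 °C, 21 samples per site (126 samples), with
site-level true richness on the exact Boltzmann line
$S = \mathrm{round}(\exp(a - E_a/(kT)))$, a default $E_a$ of 0.25 eV (within
the range reported for soil microbial taxa) and intercept $a = 16$, giving a
few hundred OTUs per site — a desk-scale stand-in for the tens to hundreds
of thousands of OTUs in real surveys (set $a \approx 6$ when $E_a = 0$ to
keep the same richness scale). Species abundances follow a lognormal
distribution (meanlog 0, sdlog 1.5) — the standard model for soil
communities, heavy-tailed enough that multinomial sampling at the default
20,000 reads per sample leaves singletons and doubletons, so Chao1 genuinely
extrapolates. Site pools are nested (warmer sites add species) so
between-site turnover is moderate; a disjoint-pool mode gives complete
turnover for Mantel power checks. The phylogeny is a random-join topology
with exponential branch lengths over the whole pool. Covariates
(precipitation, pH, moisture, total C, total N, plant richness) are linear
in site temperature plus Gaussian noise with standard deviation
`env_noise` × |slope| × sd(temperatures) — a noise-to-signal ratio, default
0.5 (covariate–temperature correlations near 0.9, the strong covariation
typical of continental gradients); 0 makes them perfectly collinear. All
randomness flows from one seed through named substreams (tree, abundances,
per-sample sampling, environment), so any component can be reproduced in
isolation.

`merge_sister_otus()` emulates re-clustering at a coarser similarity cutoff
by collapsing each cherry of the phylogeny into a single OTU. Warmer
(richer) sites hold both members of a cherry more often than cold sites, so
coarsening removes proportionally more richness where there is more of it
and flattens the Arrhenius slope — the mechanism behind fitted $E_a$ rising
with taxonomic resolution, which the acceptance checks exercise.

What the generator does *not* emulate: sequence-level noise (errors,
chimeras, clustering artefacts), spatially structured dispersal, interaction
between covariates and composition beyond the shared temperature driver, and
abundance distributions other than lognormal. Passing tests on this
generator therefore validate the estimators and the fitting machinery, not
the biology of any particular real survey.

## Numerical and design choices, in brief

* Chao1 with $f_2 = 0$: bias-corrected fallback (avoids infinities).
* Rarefaction is strictly without replacement; per-sample substreams.
* Cophenetic distances, Newick IO via `ape`; Bray–Curtis via `vegan`;
  everything statistical about Mantel/BioENV/NRI/MTE is implemented here and
  cross-checked in the tests against independent oracles (exhaustive
  permutation, brute-force subset search, normal equations) and, where
  applicable, `vegan`/`picante`.
* Mantel p-values use the +1 estimator; an exact mode enumerates all $n!$
  relabelings for $n \le 8$.
* Spearman ties: average ranks.
* Breakpoint ties in the piecewise grid: the smallest candidate wins
  (first-improvement search with a $10^{-12}$ tolerance).
* Temperatures are Celsius everywhere outside the Arrhenius machinery.
* Permutation and null-model functions require explicit seeds; nothing
  falls back to global RNG state silently.

## Problem sizes used in the shipped checks

The test suite and acceptance script run entirely on generated data: 50-seed
recovery studies at the full design (6 × 21 samples, depth 20,000), a
1,000-simulation Mantel calibration at $n = 15$ units with 999 permutations,
200-seed model-selection runs at $n = 6$, and exhaustive enumerations on
vectors of total ≤ 10, trees of ≤ 6 tips and $4!$ relabelings. These sizes
were chosen to make the Monte-Carlo standard errors small relative to the
tolerances being asserted while keeping a full run in the low minutes on a
single CPU.

## Limitations

* Chao1 is a lower-bound-style estimator; under very heavy-tailed abundance
  distributions it undercounts, and although the bias largely cancels across
  sites that share one abundance model, fitted $E_a$ can be attenuated when
  coverage differs systematically along the gradient.
* The partial-Mantel permutation scheme is one of several in the literature;
  schemes differ in small-sample behaviour.
* AIC at $n = 6$ is permissive towards extra parameters (see above).
* The pipeline reports raw p-values, as is conventional for Mantel panels;
  no multiplicity correction is applied.
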