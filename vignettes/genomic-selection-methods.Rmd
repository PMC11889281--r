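---
title: "Genomic selection in autotetraploid breeding populations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection in autotetraploid breeding populations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetraGS)
```

## The problem

Dioecious fruit crops such as kiwiberry express the commercially decisive
traits — fruit load, fruit weight, dry matter, soluble solids — only on
female vines. Male parents can therefore be ranked only through relatives,
classically by slow progeny testing. Genomic selection replaces the pedigree
with a marker-derived (realised) relationship matrix, so breeding values can
be predicted for every genotyped individual, phenotyped or not, including
males and parents.

`tetraGS` implements this analysis for autotetraploid populations scored as
allele dosages (0–4 at biallelic SNPs) arising from incomplete factorial
crossing designs that may mix intra-specific and inter-specific crosses. It
also ships a polysomic-inheritance simulator because populations of this
kind are rarely public: all statistical machinery is exercised and validated
on synthetic twins of such a design.

## The linear mixed model

For records $y$ (one per female × trait × year),

$$y = \mu + Xb + Za + e, \qquad
a \sim N(0,\, G\sigma^2_a), \qquad e \sim N(0,\, I\sigma^2_e),$$

where $X$ carries the intercept and optional fixed effects of year, cross
type (intra AA×AA vs inter AA×ME) and their interaction, $Z$ is the
record-to-individual incidence (repeated yearly records are modelled, never
pre-averaged), and $G$ is the realised relationship matrix.

### The tetraploid realised relationship matrix

With dosage matrix $M$ (individuals × markers), ploidy $m$ and allele
frequencies $p_j$,

$$Z_M = M - m\,\mathbf{1}p', \qquad
G = \frac{Z_M Z_M'}{m \sum_j p_j(1-p_j)} .$$

The denominator is the summed polysomic Hardy–Weinberg dosage variance
($\mathrm{Var}(m_{ij}) = m\,p_j q_j$ for a Binomial($m$, $p_j$) dosage), so
a non-inbred HWE panel has mean diagonal 1 and at $m=2$ the construction is
exactly the classical diploid VanRaden matrix — both are verified in the
test suite, the latter in closed form. Frequencies default to the full
genotyped set (parents plus all progeny), the convention when one matrix
serves the whole population; founder-only estimation is available via the
`ids` argument of `allele_frequencies()`. Monomorphic markers must be
filtered first (`filter_markers()`), both because they contribute nothing
and because $p_j \in \{0, 1\}$ breaks the denominator. Missing dosages are
mean-imputed per marker (`impute_missing()`): the package consumes dosage
calls, it does not produce them, and the paper trail of read-level filters
belongs to the genotyping pipeline, not here.

A relative ridge $\varepsilon = 10^{-6} \times \overline{\mathrm{diag}(G)}$
is recorded with the matrix and added to the diagonal by every solver, so
that the leave-one-out downdating and the mixed-model equations operate on
a numerically positive-definite matrix. All reported quantities (including
the oracle comparisons in the tests) use this same effective matrix.

### REML by spectral profiling

Only one variance ratio exists, so the restricted likelihood is profiled
over $\delta = \sigma^2_e/\sigma^2_a$ exactly: with
$S = I - X(X'X)^{-1}X'$ and the record-level kernel $K = ZGZ'$ written as
$CC'$ (through the Cholesky factor of the phenotyped block of $G$), the
non-zero eigenvalues of $SKS$ are those of $C'SC$ — a matrix of the size of
the *phenotyped individual* count, not the record count. The profiled
restricted log-likelihood is evaluated on a 41-point grid of
$\log_{10}\delta$ over $[-5, 5]$ and refined by Brent search
(tolerance $10^{-10}$); an optimum within $10^{-3}$ of either grid end is
flagged as a boundary estimate (reported, never an error — a pure-noise
trait legitimately ends at $\sigma^2_a \to 0$). The reported
log-likelihood uses the Patterson–Thompson normalisation (including the
$+\tfrac12\log|X'X|$ term), computed densely at the optimum; the test suite
requires agreement to $10^{-6}$ with an independent dense grid-search plus
explicit mixed-model-equation inversion on dozens of random small
fixtures.

Heritability is reported on an individual-record basis,
$h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_e)$.

### Predictions, PEV and accuracy

At the optimum, GEBVs for **all** individuals in $G$ are
$\hat a = \sigma^2_a\, G_{\cdot,\text{phen}} Z' P y$ with
$P = V^{-1} - V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}$ — unphenotyped males and
parents are predicted purely through their genomic relationships to
phenotyped females. Prediction error variances come from the equivalent
$P$-matrix identity
$\mathrm{PEV}_i = \sigma^2_a G_{ii} - \sigma^4_a\, w_i'Pw_i$
($w_i = Z G_{\text{phen}, i}$), which equals the
$\sigma^2_e\,C^{aa}_{ii}$ of Henderson's equations without forming
$G^{-1}$. Per-individual accuracy follows Henderson's definition

$$\mathrm{accuracy}_i = \sqrt{1 - \frac{\mathrm{PEV}_i}{\sigma^2_a G_{ii}}},$$

with $G_{ii} = 1 + F_i$ for inbreeding coefficient $F_i$. A marginally
negative radicand (possible when PEV sits at its ceiling) is clamped to 0
with a warning rather than propagating `NaN`.

### Wald tests

Fixed-effect structures are compared by sequential (incremental) Wald
chi-squared tests in the fitting order year → cross type → interaction:
after whitening by the Cholesky factor of $V$, the fitted sum of squares is
decomposed by term, each term contributing $\chi^2$ equal to its increment
with df equal to its estimable columns. Aliased columns are detected by a
rank scan and reported with df = 0, never silently dropped. Whether a
sequential or marginal decomposition is the right reading of such tables is
genuinely open; sequential was chosen because it matches the incremental
Wald statistics of the mixed-model software tradition this analysis
descends from, and the term ordering is stated so results are
reproducible.

## Cross-validation

`loo_predictive_ability()` masks each phenotyped female in turn — all her
yearly records at once, so nothing of her leaks into the right-hand side —
and re-solves her GEBV on the remaining data. Predictive ability is the
Pearson correlation between the masked predictions and the females'
unadjusted multi-year mean observations, overall and within cross types,
with the usual $t$ significance transform.

Two open choices were fixed as follows, and are exposed as flags:

* **Variance components** are estimated once on the full training data and
  held fixed across folds (`refit_vc = FALSE`). With many hundreds of
  folds this is the computationally standard policy; per-fold re-estimation
  is available and agrees closely at these sample sizes.
* **"Mean observation"** is the raw mean of the female's records across
  years, not a year-adjusted mean.

At fixed variance components each fold is solved by downdating the
precomputed $V^{-1}$ by the masked records (a rank-$\le 3$ correction),
making the whole LOO cost one Cholesky plus $O(n)$ per fold; the test suite
checks bit-level agreement with explicitly re-fitted folds.

`subpopulation_cv()` restricts training to AA×AA or AA×ME females, or — the
`AAxAA*` scheme — repeatedly draws random AA×AA subsets size-matched to the
AA×ME count (default 1,000 repeats, reducible for desk-scale work) to
separate the training-size effect from the population-structure effect.
`parent_accuracy_profile()` recomputes named parents' Henderson accuracies
under each training restriction; a scheme with no records returns accuracy
0 exactly (PEV at its ceiling $\sigma^2_a G_{ii}$).

## The synthetic-data generator

The simulator emulates the statistical structure such an analysis assumes,
with defaults shaped like a two-species kiwiberry programme:

* **Founders.** Ancestral allele frequencies uniform on (0.1, 0.9); the two
  species pools receive Balding–Nichols draws around them with
  $F_{st} = 0.05$ by default — deliberately low, emulating the weak
  differentiation reported between the two species of such complexes.
  Founder dosages are Binomial($m$, $p_{s,j}$), i.e. polysomic HWE.
* **Meiosis.** Bivalent pairing transmits hypergeometric gamete dosages;
  double reduction is a two-component mixture in which, with probability
  $\alpha \in [0, 1/6]$, the gamete carries two copies of one uniformly
  chosen homolog. The default is $\alpha = 0$: no rate is reported for
  these species, so the machinery exists (and is enumerated exactly in
  tests) but the headline simulations do not assume one.
* **Design.** Two incomplete factorials (2×13 fully realised; 13×3 with one
  inter-specific father, a balanced 7×3 block, and 8 further intra
  crosses), 55 crosses in all. Offspring-per-cross counts are a discretised
  Beta on [2, 80] with mean 33.3 — the reported range and mean of such
  seedling trials. Offspring sex is Bernoulli(0.5).
* **Phenotypes.** Records follow the additive model above: marker effects
  are drawn zero-mean normal and rescaled so the realised TBV variance hits
  the architecture's `genetic_var`; $\sigma^2_e$ derives from the target
  heritability as $\mathrm{var(TBV)}(1-h^2)/h^2$ computed on the phenotyped
  females; year and interaction effects are drawn once per year; records
  are clipped to the trait's plausible range (e.g. fruit weight 1.0–17.3 g)
  and exist for female offspring only. Dropout (default 0.05) removes all
  of a female's records for a trait, mimicking the exclusion of zero-score
  vines; no genotype dependence is modelled because none is documented.
* **Seeding.** A master seed spawns named sub-streams (founders, design,
  meiosis, one per trait) via `derive_seed()`, so stages are independently
  reproducible and every pipeline output is bit-stable under a fixed seed.

**What the generator does *not* emulate** — and hence what passing tests do
not establish about field data: linkage and LD (markers are unlinked; the
relationship-matrix machinery does not need a map, but LD-driven biases
cannot appear), genotyping error and dosage miscalls, non-additive genetic
variance, genotype-by-environment structure beyond an additive year effect,
and selection in the pedigree. Simulated traits are Gaussian up to
clipping, so the strong right skew of real fruit-load scores is only mildly
reproduced.

## Validation oracles

Two independent Monte-Carlo/dense oracles anchor the statistical claims:

* `gene_drop_relationship()` drops unique founder homolog labels through
  the pedigree under the same gamete model and averages IBD sharing,
  scaled so a non-inbred founder has self-relationship 1. At ploidy 4 this
  gives parent–offspring 0.5, full-sib 0.5 and half-sib 0.25, and the
  dosage-based $G$ must match these class means within Monte-Carlo error.
  For that comparison $G$ is centred at the *generating* founder
  frequencies: frequencies re-estimated from a handful of founders shift
  every pair down by $O(1/n)$, which is a property of frequency
  estimation, not of the construction under test.
* A dense REML grid-search plus explicit MME inversion (in the test
  helpers, sharing no code with the production path) arbitrates
  likelihoods, fixed effects, GEBVs and PEVs to $10^{-6}$.

## Numerical choices and problem sizes

Tolerances: REML Brent tolerance $10^{-10}$ on $\log_{10}\delta$; ridge
$10^{-6}$ relative; rank decisions at $10^{-10}$ of the largest eigenvalue.
Ties and degenerate inputs: single-level factors become empty (aliased)
blocks; correlation within a group is reported `NA` with a reason when a
margin is constant; an all-masked marker is an error, not a zero.

The validation suite runs the generator at up to ~1,000 phenotyped females
× 2,000 markers × 2 years for parameter recovery (20 replicates per
heritability level at 0.2/0.5/0.8), 20,000 offspring draws for
goodness-of-fit of the meiosis model, and 200-repeat subsampling for the
training-size contrast — sizes chosen to make Monte-Carlo error small
relative to the tolerances being asserted while keeping the whole suite
runnable on a laptop in a few minutes.

## Known limitations

* Double reduction is implemented for ploidy 4 only; other even ploidies
  are supported in the bivalent model.
* One random genetic effect only: no dominance/digenic matrices, no
  spatial field-trend correction, no multi-trait models.
* The Wald table is sequential; a marginal (type-III-like) decomposition
  is not provided.
* Dosages are hard calls; posterior-mean (probabilistic) dosages are out
  of scope.
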