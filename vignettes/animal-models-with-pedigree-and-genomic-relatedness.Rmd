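---
title: "Animal models with pedigree and genomic relatedness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Animal models with pedigree and genomic relatedness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its statistical machinery: the
models it fits, the estimators it implements, the synthetic data it uses to
validate them, and the judgement calls made where more than one reasonable
definition exists. It states no numbers that the test suite or
`scripts/acceptance.R` do not themselves compute.

## The model

Phenotypic records from a wild study population are modelled with the
animal model, a linear mixed model

$$\mathbf{y} = \mathbf{X}\boldsymbol\beta + \mathbf{Z}_1\mathbf{a} +
\mathbf{Z}_2\mathbf{m} + \sum_r \mathbf{Z}_r\mathbf{u}_r + \mathbf{e},$$

where $\mathbf{a} \sim N(0, \sigma^2_a \mathbf{K})$ holds each
individual's additive genetic value with covariance proportional to a
relatedness matrix $\mathbf{K}$, and the remaining random terms are
identity-covariance groupings (birth year; permanent environment and year
of capture for repeated adult measures). Two parameterisations of maternal
effects are supported, mirroring standard practice for juvenile size
traits:

* **Model 1** fits a single maternal term $\mathbf{m}$ indexed by dam
  identity with identity covariance — genetic and environmental maternal
  variance are not distinguished.
* **Model 2** splits it into a maternal *genetic* term
  $\mathbf{m}_a \sim N(0, \sigma^2_{ma}\mathbf{K}_{\text{dam}})$ (the
  dam's genotype, with covariance structured by relatedness among dams)
  and a maternal *environment* term
  $\mathbf{m}_e \sim N(0, \sigma^2_{me}\mathbf{I})$ (shared rearing
  conditions).

In Model 2 the maternal-genetic covariance source always matches the
direct-genetic source: a genomic analysis uses genomic relatedness among
dams too. No direct–maternal genetic covariance is fitted; with the data
structures this package targets that covariance is weakly identified, and
the univariate contracts deliberately omit it.

Every variance is also reported as a proportion of the total phenotypic
variance after fixed effects (the sum of all fitted components including
the residual): $h^2 = \sigma^2_a/\sigma^2_P$, $m^2_a$, $m^2_e$, and so on.
Standard errors of these ratios use the first-order delta method with the
full sampling covariance of the component estimates.

## Relatedness sources

**Pedigree.** `numerator_relatedness()` implements the tabular method in
topological order: $A_{ii} = 1 + \tfrac12 A_{ds}$ for parents $d,s$ (so
the diagonal is $1+F$) and $A_{ij} = \tfrac12(A_{jd} + A_{js})$. Missing
parents contribute zero; founders have diagonal 1. The matrix is
positive semidefinite by construction, and the tests verify it against an
independent gene-dropping kinship simulator ($10^5$ allele drops).

**Genomic.** `genomic_relatedness()` uses the 2pq-standardised IBS
estimator: off-diagonals average
$(x_{ij}-2p_i)(x_{ik}-2p_i)/2p_iq_i$ over loci, diagonals
$1 + (x^2_{ij}-(1+2p_i)x_{ij}+2p_i^2)/2p_iq_i$, with allele frequencies
taken from the full genotyped sample, monomorphic loci excluded and
pairwise-complete handling of missing genotypes (each pair's divisor is
the count of loci observed in both individuals, recorded for the GRM
file's nsnps column). No shrinkage toward the pedigree and no adjustment
for sampling error or allelic spectrum are applied: the estimator reports
the variance captured by the genotyped SNPs themselves.

Because frequencies are estimated from the sample, the GRM is implicitly
centred on that sample: entries track pedigree relatedness faithfully only
up to a shift of order the mean sample relatedness. Calibration checks
against the pedigree therefore use shallow pedigrees with low mean
relatedness, which is also the regime in which the estimator's textbook
unbiasedness statement applies.

## The REML engine

The restricted log-likelihood
$-\tfrac12(\log|\mathbf{V}| + \log|\mathbf{X}'\mathbf{V}^{-1}\mathbf{X}| +
\mathbf{y}'\mathbf{P}\mathbf{y})$ is maximised over components of
$\mathbf{V} = \sum_j \theta_j \mathbf{G}_j$. Writing the covariance as a
linear function of the parameters lets one engine serve both univariate
models (each $\mathbf{G}_j$ a $Z K Z'$ or the identity) and bivariate
models (each random term contributes three matrices, one per element of
its unstructured 2×2 block).

Numerical choices, in order of importance:

* **Updates.** The first two iterations use an EM-flavoured step (always
  ascent for variance parameters, never leaves the parameter space),
  after which Newton steps use the average-information matrix
  $\mathrm{AI}_{jk} = \tfrac12 \mathbf{y}'\mathbf{P}\mathbf{G}_j
  \mathbf{P}\mathbf{G}_k\mathbf{P}\mathbf{y}$ with step halving on the
  log-likelihood (up to 12 halvings, EM fallback if none is accepted and
  rejection of any step that lowers the likelihood).
* **Boundaries.** Variance components that would go negative are pinned at
  $10^{-8}\times$ the phenotypic variance and flagged; a parameter pinned
  with an outward-pointing gradient for three consecutive iterations is
  dropped from the update set until its gradient points back inside.
  Covariance parameters are clamped so every implied correlation stays
  inside $\pm(1-10^{-4})$; this keeps $\mathbf{V}$ invertible even for
  degenerate inputs (a trait paired with its own copy), for which the
  unconstrained likelihood is unbounded and the fit correctly reports a
  correlation at the clamp.
* **Scaling and convergence.** The response is internally scaled to unit
  variance so tolerances are scale-free; convergence requires relative
  parameter change below $10^{-8}$ together with gradient norm below
  $10^{-6}$, with a likelihood-stall exit (change below $10^{-9}$) for
  boundary-riding fits. Estimates, their sampling covariance (inverse
  average information) and the log-likelihood are reported on the original
  scale. Likelihood constants are omitted consistently, so only
  differences are meaningful — which is all the likelihood-ratio test
  needs.
* **Cost.** Each iteration is dominated by one Cholesky factorisation and
  one inverse of the dense $n\times n$ covariance; proposals during step
  halving use triangular solves only. Fits with $n\approx 2000$ records
  take a few seconds on one CPU.
* **Degenerate structures.** A model whose random terms imply identical
  covariance structures (for instance an identity-covariance term on
  individual id with single records, which duplicates the residual) is
  rejected up front as non-separable. Records with missing model variables
  or ids absent from a referenced relatedness matrix are dropped with a
  message and counted in the fit object.

**Likelihood-ratio tests** compare nested fits with identical fixed
effects and records (enforced, since REML likelihoods are not comparable
otherwise): statistic $2\Delta\ell$ floored at zero against
$\chi^2_1$. The $\chi^2_1$ reference is conservative for a variance
component on its boundary — the asymptotic null is the 50:50 mixture of a
point mass at zero and $\chi^2_1$, available via `mixture = TRUE` — and
the conventional $\chi^2_1$ is the default because it is what field
studies typically report. The acceptance tests verify the empirical null
rejection rate sits at or below the nominal level accordingly.

**Bivariate models** stack the two traits' records with separate fixed
effects per trait. Each random term carries an unstructured 2×2 block.
The residual is either unstructured (`"us"`, with the cross-trait
covariance linking records that share an id, requiring one record per
trait per individual) or heterogeneous-diagonal (`"idh"`) with no residual
covariance. The `idh` structure with one trait's residual variance fixed
near zero, plus a permanent-environment term on id, is the standard device
for pairing a repeated live measure with a single post-mortem measure:
the permanent-environment block then carries the non-genetic cross-trait
covariance. The genetic correlation
$r_G = \sigma_{a12}/\sqrt{\sigma^2_{a1}\sigma^2_{a2}}$ is reported with a
delta-method standard error.

## Marker QC and LD

`qc_filter()` removes markers in the fixed order call rate → MAF → HWE
with strict inequalities (retain call rate > 0.99, MAF > 0.01, HWE exact
p > 1e-5), counting each marker once at its first failing stage.
`hwe_exact_p()` is the standard two-sided conditional exact test: given
the allele counts, each possible heterozygote count has probability
$n!\,2^{n_{Aa}}/(n_{AA}!\,n_{Aa}!\,n_{aa}!)/\binom{2n}{n_A}$, and the
p-value sums all outcomes no more probable than the observed one (no
mid-p correction, matching the behaviour of the classic SNP-HWE routine).

`ld_decay()` computes r² as the squared Pearson correlation of dosage
vectors over complete pairs, for each focal marker against downstream
markers that pass the MAF > 0.05 screen, are fewer than 50 screened
markers away and lie within 1 Mb on the same chromosome, summarised as
means in 10 Kb distance bins. Genotype correlation is used rather than a
haplotype-EM estimator because it is deterministic, phase-free and equals
haplotype r² in expectation under random mating; the two can differ
slightly away from Hardy–Weinberg proportions. Rank distance is counted
after the MAF screen, the internally consistent choice when the screen
also defines which pairs exist.

## The synthetic study population

The simulator generates data with the statistical structure of an
intensively monitored, polygynous, overlapping-generation sheep
population — the setting in which pedigree-versus-genomic comparisons are
interesting — while making no attempt at coalescent realism.

* **Demography** (`simulate_pedigree()`): each year every adult female
  breeds with probability 0.9 (twinning 0.15); sires are drawn with
  gamma-distributed annual mating weights (shape 0.3), which produces
  the strong paternal-sibship skew of a polygynous system; survival is
  0.5 in the first year and 0.72 thereafter, capped at age 12. The
  default 450 founders and 30 seasons give a pedigree in the
  several-thousand-record range. These rates were chosen once as
  field-realistic for an unmanaged ungulate population and are not tuned
  thereafter.
* **Genotypes** (`gene_drop()`): the default map has 37 037 autosomal
  markers on 26 chromosomes with gamma-distributed spacings (mean 65.9 Kb,
  shape 1.4, hence median near 50 Kb) and 1.3 cM/Mb. Founder haplotypes
  come from a first-order Markov chain along each chromosome. Allele
  frequencies are marginally Uniform(0.01, 0.5) with autocorrelation along
  the chromosome (0.95), because the attainable correlation between two
  binary loci is capped by their frequency difference — local frequency
  similarity is what makes strong local LD possible at all. The
  requested adjacent-pair correlation decays exponentially with distance
  and is calibrated by deterministic root-finding on the generated
  frequency sequence so that mean adjacent r² at the median spacing hits
  the configured target (0.30 by default). Transmission is meiosis with
  Haldane (Poisson) crossovers on the genetic map; `unlinked = TRUE`
  switches to free recombination and independent founder loci for
  calibration studies.
* **Phenotypes** (`simulate_phenotypes()`): breeding values follow either
  the pedigree recursion $a_i = \tfrac12(a_d + a_s) + m_i$ with
  Mendelian-sampling variance $\tfrac12\sigma^2_a(1-(F_d+F_s)/2)$ (one
  known parent: $\tfrac34 - F/4$; founders: 1), or a causal-locus model
  with effects $\beta_i \sim N(0, \sigma^2_a/(M_c\,2p_iq_i))$ on a random
  marker subset. Maternal genetic values use the pedigree recursion on
  dams; maternal environment, birth-year, permanent-environment,
  capture-year and residual effects are independent normals. Every draw is
  stored in a truth bundle, and a test asserts the records reconstruct
  exactly from it. The default measurement schedule produces birth
  records for all individuals with known dams, August captures with
  probability 2/3 at ages 4 and 16 months, and repeated adult August
  captures — so repeated measures exist only for adults, and the same
  individual can appear in all four age classes.
* **Degradation** (`degrade_pedigree()`): independently per non-founder,
  parent links are dropped (defaults: 5.5% of maternities, 28% of
  paternities) or replaced with a random cohort-eligible parent of the
  right sex (2.7% / 4.4%), emulating the gap between a field pedigree
  with marker-assisted paternity and a fully SNP-assigned one. A
  kinship-weighted error model is a documented possibility but the
  default replacement is uniform; misassignments in real systems are
  often relatives, which would damp the resulting bias.

What the simulator does *not* emulate: coalescent ancestry and mutation,
selection and viability effects on genotypes, spatial environmental
structure, sex-specific genetic architecture, and measurement-type-specific
error. Tests passing on this synthetic population therefore demonstrate
the correctness of the estimators and pipeline under a known generative
model, not the field-data values of any particular study system.

## Age classes

Records are split into neonates (live capture within 5 days of birth),
lambs (August data near 4 months, or post-mortem before 14 months),
yearlings (August near 16 months, or post-mortem from 14 to under 26
months) and adults (August at 28 months or older, or post-mortem at 26
months or older). Live records between the August windows (for example
5–13 months) match no rule and are excluded with a logged count; the
boundary at exactly 26 months post-mortem is assigned to adults. Fixed
effects follow the standard design: sex and litter size for juveniles,
sex for yearlings, sex and age factor for adults; permanent-environment
and capture-year random terms are added only for adult August traits,
which are the only records with repeated measures.

## The comparison pipeline

`run_comparison()` fits every (age class × trait × relatedness source ×
model) cell, records per-component estimates, ratios, standard errors and
sample sizes, marks failed cells (too little data, non-convergence)
without aborting the grid, and can attach one-term-drop likelihood-ratio
tests against the same fixed effects. `pruned_comparison()` refits with
the phenotyped set restricted to a given id list while leaving the
relatedness matrices untouched, the standard check that differences
between sources are not explained by sample composition.
`marker_subsampling()` draws marker fractions without replacement
(`round(fraction × M)` markers — base R rounding reproduces the
half-even counts conventionally printed for such designs), rebuilds the
GRM, refits, and derives each replicate's seed deterministically from
(master seed, fraction index, replicate) so any single replicate can be
reproduced in isolation.

## Validation strategy and problem sizes

The test suite validates each stage against an independent route:
brute-force restricted-likelihood maximisation (grid plus Nelder–Mead on
the log scale) on small fixtures; the closed-form ANOVA sire component on
a balanced 200×20 half-sib design (an exact reparameterisation of the
animal model there); gene-dropping kinship for the tabular A; first
principles enumeration for the HWE test across every genotype
configuration up to n = 50; analytic haplotype-frequency r²; and
end-to-end parameter recovery with 2-standard-error coverage counted over
20 simulation seeds (about 2000 records for the maternal-effects model,
about 1500 per trait for the bivariate genetic correlation). The
likelihood-ratio null calibration uses 500 replicates on a compact
pedigree. These sizes keep the full suite under ten minutes on one CPU
while leaving each check statistically sharp; the vignette-level claims
above are exactly the properties those tests assert.

## Known limitations

* Dense-matrix REML: cost grows as n³ per iteration, practical to a few
  thousand records per fit; very large studies would want sparse
  mixed-model equations.
* No direct–maternal genetic covariance, no random-regression or
  sex-specific models, no more-than-two-trait multivariate fits, and no
  Bayesian alternatives.
* Delta-method standard errors for ratios and correlations are first
  order; they can be mildly optimistic in small or strongly blocked
  pedigrees (the tests quantify this for the structures they use).
* The GRM is the raw sample-frequency estimator; in strongly structured
  samples its implicit centring makes absolute levels of relatedness,
  though not their contrasts, hard to interpret.
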