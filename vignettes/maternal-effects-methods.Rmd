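---
title: "Maternal genetic effects: models, samplers and the synthetic design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maternal genetic effects: models, samplers and the synthetic design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A rabbit's intramuscular fat and fatty-acid profile depend not only on its
own genes but on its dam: through the uterine environment and milk, the
dam's genotype leaves a mark on every kit she raises.  This package
quantifies that maternal genetic contribution in pedigreed populations and
maps it to genomic regions.  It has two halves:

1. **Variance-component models** — five Bayesian animal models of
   increasing complexity, fitted by Gibbs sampling, which partition
   phenotypic variance into direct genetic, maternal genetic,
   common-litter, maternal-environment and residual components.
2. **Maternal GWAS (MGWA)** — a BayesB marker regression in which the
   *dam's* genotype is assigned to each of her offspring's phenotypes,
   with inference by 1-Mb window variance shares and per-SNP Bayes
   factors.

Because the motivating data are not public, a synthetic-data generator
reproduces the statistical structure of the divergent-selection design, so
every stage of the pipeline is testable against known truth.

## The animal models

All models share the fixed effects (e.g. sex, month of slaughter, parity)
and differ in their random terms.  For one trait, the most general
structures are

* Model 1: `y = Xb + Zd a_d + e`
* Model 2: `y = Xb + Zd a_d + Zm a_m + e`
* Model 3: `y = Xb + Zd a_d + Wc c + e`
* Model 4: `y = Xb + Zd a_d + Zm a_m + Wc c + e`
* Model 5: `y = Xb + Zd a_d + Zm a_m + Wme me + e`

with `a_d` the direct breeding values, `a_m` the maternal genetic effects
(carried by the dam, expressed in the offspring record via `Zm`, which
maps each record to its dam), `c` the common-litter effects
(litter = dam x parity), and `me` a permanent maternal environment effect
per dam.  Jointly,

```
(a_d, a_m) ~ N(0, A (x) G0),   c ~ N(0, I (x) Cc),
me ~ N(0, I (x) Cme),          e ~ N(0, I (x) R0),
```

where `A` is the additive relationship matrix from the pedigree and `G0`
is the (co)variance of direct and maternal effects (`2t x 2t` for `t`
traits; bivariate fits put the selection trait first so selection on it is
accounted for).  Flat priors are placed on the fixed effects and on all
covariance matrices.

Derived parameters are ratios to the total phenotypic variance,

```
sigma2_P = sigma2_d + sigma2_m + sigma_dm + sigma2_c + sigma2_me + sigma2_e
h2d = sigma2_d / sigma2_P,  h2m = sigma2_m / sigma2_P,
c2 = sigma2_c / sigma2_P,   me2 = sigma2_me / sigma2_P,
rho_dm = sigma_dm / (sigma_d sigma_m)
```

**The covariance term enters `sigma2_P` once.**  This convention makes a
reported table of ratios internally consistent even when `h2d + h2m + c2`
exceeds 1 with a negative `rho_dm` — which is exactly what happens for
traits with strong, negatively correlated direct and maternal effects —
and it makes `sigma2_P` the actual variance of a phenotype drawn from the
model.  Under the alternative (excluding `sigma_dm`) some published ratio
sets would be impossible to reproduce with any non-negative residual
variance.

## The Gibbs sampler

Location parameters are sampled Gauss–Seidel style against a running
residual: fixed-effect and litter columns as `t x t` blocks over traits,
and all `2t` genetic effects of one animal as a single block (direct and
maternal incidences of the same animal never hit the same record, so the
within-block data cross-terms vanish).  The genetic prior contribution
uses the sparse `A` inverse assembled directly by Henderson's rules with
inbreeding from the Meuwissen–Luo recursion.

Covariance matrices have inverse-Wishart full conditionals.  Under a flat
(constant-density) prior the conditional for `G0` is
`IW(q - m - 1, U' A^-1 U)` with `q` animals and `m = 2t` effect columns;
`Cc`, `Cme` and `R0` are analogous with their own level counts.  The
parameterization is `E[IW(df, S)] = S / (df - m - 1)`.  We deliberately do
**not** use `df = q` (a Jeffreys-type `|G0|^-(m+1)/2` prior): its density
spike at singular matrices can drive the chain into an absorbing
degenerate state in which the direct–maternal correlation pins at ±1 and
the maternal variance collapses — we observed exactly this pathology
before settling on the flat convention.

Numerical safeguards: a relative ridge of `1e-12` on the IW scale keeps
degenerate (zero-variance) data sampleable; a singular location-block
precision raises an error naming the offending effect.  Identifiability
uses treatment contrasts (first level of each fixed factor is the
reference).  The histogram-midpoint mode (50 bins) is a presentation-only
summary; HPD95 intervals are Chen–Shao shortest intervals.

Default chain settings are 300,000 iterations, 20,000 burn-in, thinning
200 (the reference analysis scale); tests and examples use shorter chains.

## The synthetic design

`sim_config()` defaults mirror the divergent-selection experiment: a base
population of 13 sires and 83 dams, two lines with 8 sires and 40 dams per
generation, each sire mated to 5 dams, litters around 8, and selection on
the first trait by ranking dams on the mean phenotype of two scored
first-parity offspring (one male, one female), the top 20% (High line) or
bottom 20% (Low line) providing the next generation's females.  Litter
sizes are `min + Poisson(mean - min)`, so `min = mean` gives constant
litters.  Breeding values propagate by Mendelian sampling with the
inbreeding-corrected variance `0.5 (1 - (F_s + F_d)/2) G0`, which makes
the realized covariance of all effects exactly `A (x) G0`.

Two parities per dam is the default: the paper's parity factor
("1st vs >=2nd") implies repeated litters, and repeated litters are what
separate the common-litter variance (within dam, between litters) from the
dam-level maternal terms.  With a single parity, litter and dam coincide
and `c2`, `me2` and `h2m` are nearly confounded — model 4 and model 5 then
behave identically, which is why those two models give interchangeable
results when litters per dam are few.

Genotypes are gene-dropped in linkage equilibrium (founders
`Binomial(2, p)`, each parent transmits an allele with probability
`genotype/2`), with uniform map positions on 21 autosomes.  Linkage
equilibrium keeps the expected per-window share of genomic variance
analytic (`100 / n_windows` percent).  What the generator deliberately
does *not* emulate: linkage disequilibrium and recombination maps,
measurement-platform error (NIRS vs chemical analysis), litter-size
selection, and non-Gaussian trait distributions.  Passing recovery tests
therefore show the estimators work when the model is true; they do not
certify behaviour under LD or model misspecification.

## Recovery studies: design choices

The package's acceptance studies simulate ~1,800 phenotyped animals: a
scored base population (13 sires, 83 dams) plus two generations in two
lines (16 sires and 18 dams per line, three parities, constant litters of
8, total phenotypic variance 1), refitted with model 4.  Four deliberate
choices:

* **The base cohort is phenotyped**, as in the motivating study (whose
  records included the base population).  Each base record receives a
  phantom founder dam — the standard device for records with unknown
  parents — so its maternal effect is defined.  This matters: with only
  two phenotyped generations there is a single phenotyped maternal-lineage
  covariance (dam–offspring) and the `(sigma2_d, sigma_dm)` ridge is
  nearly unidentified — occasional realizations then support `h2d`
  estimates 0.3 above truth.  Scoring the base adds granddam–offspring
  contrasts and collapses that ridge.
* **Three parities per dam** in these studies (not the default two):
  repeated litters are the only contrast separating `c2` from the
  dam-level maternal terms at this depth, and three litters sharpen it.
* **Selection off**: truncation selection shrinks the realized genetic
  variance (the Bulmer effect) and drifts line means, so estimates from a
  selected cohort are pulled away from the base-population generating
  values; recovery studies compare against those generating values and
  are run without selection.
* **Replicate averaging**: even so, the posterior of `h2d`/`h2m` is wide
  enough that the posterior mean of a single dataset scatters around the
  truth with a standard deviation near 0.05–0.09.  The headline recovery
  values therefore average the posterior means of replicate datasets
  (eight in the acceptance script, three in the test suite) — the same
  estimand with less data-realization noise.

## The maternal GWAS

The MGWA model is `y = 1 mu + X b + sum_j z_j alpha_j delta_j + e`, with
the dam's centered genotype `z_j` attached to each offspring record.
`delta_j` is 0 with probability `pi = 1 - n / (3k)` (n records, k SNPs;
0.9987 at the reference scale of 349 records and 88,512 SNPs), and
`alpha_j` has a `t_nu(0, sigma2_alpha)` prior implemented as a normal
with a scaled-inverse-chi-squared per-locus variance (`nu = 4` by
default).  The scale divides the trait's genetic variance across the
expected included heterozygosity:
`sigma2_alpha = V_g / ((1 - pi) sum_j 2 p_j (1 - p_j))`.

Genotypes are coded additively (0/1/2 copies of the reference allele) and
column-centered.  Per-SNP Bayes factors are posterior odds of inclusion
over prior odds; a window is associated when it explains at least 1% of
the genomic variance (posterior mean of
`Var_i(window value) / Var_i(total genomic value)`) *and* contains a SNP
with BF > 10, with a secondary tier at 0.5%.  The strict `> 10` rule is
used for calling; counts at the non-strict `>= 10` convention are
reported alongside.  Those 1% and 0.5% thresholds are 20x and 10x the
expected per-window share for 1,973 windows.  Constant genotype columns
carry no information once centered, so their inclusion probability stays
at the prior `1 - pi`; they are flagged with a warning.

Because a window share is a ratio of empirical variances, a single
retained sample can put a share marginally above 1 when windows are
anticorrelated in the realized genotypes; posterior-mean shares are well
inside [0, 1] and sum to about 1 under linkage equilibrium.

Window bins are `[m*1e6 + 1, (m+1)*1e6]` on 1-based positions; reported
window bounds are the min/max positions of member SNPs.  Consecutive
associated windows merge into regions, and genes from a user-supplied
GFF3 are attached by closed-coordinate interval overlap.  Haplotype
imputation is out of scope: `impute_naive()` fills the few post-QC
missing genotypes with the rounded expected code `2p`.

## Known limitations

* Single-site/small-block Gibbs mixes slowly along the
  `(sigma2_d, sigma_dm, sigma2_m)` ridge; chains an order of magnitude
  longer than burn-in are advisable, as in the 300k-iteration default.
* With two-generation pedigrees the direct–maternal covariance is weakly
  identified; occasional data realizations genuinely favour a
  reattribution between `h2d` and `h2m`.  Deeper pedigrees (the reference
  design had ten generations) identify it much better.
* The MGWA with `pi` fixed keeps roughly `(1 - pi) k` loci in the model
  regardless of signal, so window shares under the null are small but not
  zero; calibration should always be judged against the `100/n_windows`
  expectation.
* BayesB assumes imputed, complete genotypes; QC must run first.
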