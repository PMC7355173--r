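---
title: "Gene-based gene-environment interaction analysis with LD-adjusted Brown pooling"
author: "gxepool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based gene-environment interaction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxepool)
```

## The problem

Single-SNP gene-environment (G×E) interaction scans are underpowered in
cohorts of a few hundred to a few thousand individuals: interaction effects
are small, and correcting for thousands of SNPs is punishing. `gxepool`
implements the gene-based alternative: fit the per-SNP interaction model,
then pool each gene's SNP-level interaction p-values into a single
gene-level p-value that accounts for the linkage disequilibrium (LD) among
the gene's SNPs, and correct only for the number of genes. The package
targets candidate-pathway panels — a few hundred genes, a few thousand SNPs
— with a continuous symptom outcome, bounded ordinal-style environmental
exposures (e.g. 1–5 parenting scales), and age/sex covariates.

## The per-SNP model

For SNP $g$ (additive minor-allele dosage 0/1/2) and exposure $e$, the scan
fits by ordinary least squares

$$ y = \beta_0 + \beta_g g + \beta_e e + \beta_{g\times e}\, (g \cdot e)
   + \boldsymbol\beta_c^\top \mathbf{c} + \varepsilon $$

and reports the two-sided Student-$t$ p-value of $\hat\beta_{g\times e}$
with $n - q$ degrees of freedom. By default (`keller_terms = TRUE`) the
design also contains covariate-by-$g$ and covariate-by-$e$ products, so a
covariate that moderates either main effect cannot masquerade as a G×E
interaction. Whether the original style of adjustment includes these
product terms or only the covariate main effects is genuinely ambiguous in
the applied literature; both are supported, and the product-term design is
the default because it is the conservative choice for interaction
inference. Rows with any missing value among $y$, $g$, $e$ or the
covariates are dropped per SNP (complete-case); rank deficiency
(monomorphic SNP, constant exposure) is detected by a relative
singular-value tolerance of $10^{-10}$ and yields status
`skipped_degenerate` rather than an unstable fit.

## Pooling with Brown's method

Fisher's statistic $T = -2\sum_{i=1}^k \ln p_i$ is $\chi^2_{2k}$ only for
independent tests; SNPs within a gene are correlated through LD, and so are
their interaction p-values. Brown's method keeps $T$ but matches its first
two moments under dependence: $E[T] = 2k$ and

$$ \mathrm{Var}[T] = 4k + 2\sum_{i<j}
   \mathrm{cov}(-2\ln p_i, -2\ln p_j), $$

then refers $T$ to a scaled chi-square with scale $c =
\mathrm{Var}/(2E)$ and (non-integer) degrees of freedom $f = 2E^2 /
\mathrm{Var}$, evaluated through the gamma distribution
$\Gamma(f/2,\ \mathrm{scale} = 2c)$. The pairwise covariance is the
Kost–McDermott cubic in the test-statistic correlation $\rho$:

$$ \mathrm{cov}(-2\ln p_i, -2\ln p_j) \approx
   3.263\,\rho^* + 0.710\,{\rho^*}^2 + 0.027\,{\rho^*}^3, $$

clamped to $[0, 4]$ (the theoretical range for $\chi^2_2$ margins). The
statistic correlation is proxied by the dosage Pearson correlation $r$
(the PLINK `--r` convention), entered as $\rho^* = |r|$ by default: the
dependence of two-sided p-values is symmetric in the sign of the
underlying statistic correlation. A signed-$\rho$ variant
(`signed_rho = TRUE`) is available for comparison with implementations
that use the signed correlation.

Two limits pin the implementation down and are tested exactly: with
identity LD, $c = 1$, $f = 2k$ and Brown equals Fisher to $10^{-12}$; with
all pairwise $r = 1$ and equal p-values $p_0$, $c = k$, $f = 2$ and the
pooled p-value is exactly $p_0$.

Only genes with at least two usable SNPs are pooled (`min_snps = 2`);
significance is declared below the Bonferroni threshold $\alpha / m$ over
the $m$ genes actually tested.

**A calibration caveat, measured by this package's own simulations.** The
cubic approximation was fitted for one-sided test statistics. Applied to
two-sided p-values it over-states the covariance at moderate $|r|$, so the
pooled p-values are mildly conservative in the far tail: the null
simulations in the test suite (200-gene, 948-sample cohorts) measure a
gene-level type-I error of about 0.034–0.038 at nominal 0.05 under the
default LD range. The moment matching also slightly distorts the bulk of
the null distribution, so the median-based genomic-control $\lambda$ of
gene-level p-values sits a few percent above 1 even under the null. Both
effects shrink as LD weakens and vanish at $r = 0$.

## Quality control

`apply_qc()` removes SNPs in a fixed order, each threshold a strict
inequality: call rate below 0.98, folded minor allele frequency below
0.01, then Hardy–Weinberg equilibrium. The HWE filter uses the exact
conditional test (enumeration of all heterozygote counts given the allele
counts, no mid-p correction) with a default threshold of $10^{-6}$, the
conventional genome-wide value; `hwe_alpha = 0` disables it. The HWE
threshold is a package choice — the analysis this package supports treats
"all SNPs in HWE" as a property to verify, and the default reproduces that
all-pass behaviour on HWE-true data without being vacuous. Call rate
counts individuals; MAF counts alleles among non-missing genotypes.

## Permutation validation and genomic control

`permutation_test()` re-runs the scan-and-pool pipeline on permuted data
and reports, per gene, the add-one empirical p-value $(1 + b)/(1 + B)$,
which can never be zero. The default permutes the outcome vector — valid
under the complete null and the simplest scheme to reason about; permuting
the exposure instead (`strategy = "environment"`) preserves the
outcome-covariate linkage and is offered because either choice is
defensible. Outcome permutation with a complete outcome uses a vectorised
path that precomputes each SNP's design inverse and each gene's Brown
moments (LD does not change under outcome permutation), making 1,000
permutations of a ~100-gene panel a matter of seconds; results are
identical to the generic path and deterministic given the seed.

`genomic_control_lambda()` converts p-values to 1-df chi-square quantiles
and divides their median by the $\chi^2_1$ median (0.4549364...). It is
reported diagnostically, never used to rescale p-values. Note the sampling
variability of a median: over $m$ genes, $\mathrm{sd}(\lambda) \approx
0.166/\sqrt{m/200}$ under the null, so with a 200-gene panel values
anywhere in roughly $[0.7, 1.3]$ are unremarkable; $\lambda$ is only a
sharp diagnostic for panels of a thousand genes or more, or when it is far
from 1.

A substantive reason $\lambda$ matters for G×E scans specifically: a true
interaction anywhere in the panel makes the outcome heteroscedastic in the
exposure ($\mathrm{Var}(y \mid e)$ grows with $e^2$), which inflates the
interaction statistics of *null* SNPs genome-wide. The README's worked
example shows this: one injected G×E gene drives $\lambda$ far above 1 and
drags two null genes over the threshold. This is why the pipeline pairs
pooling with both a genomic-control check and a permutation test.

## Dichotomized-exposure sensitivity analysis

A strongly right-skewed exposure — most respondents at the scale floor —
is poorly served by a linear interaction term. `sensitivity_run()`
replaces the exposure with a binary version and re-runs the pipeline
unchanged. `median_split` codes values strictly above the median as 1,
with ties at the median going to 0; for a floor-massed variable whose
median *is* the floor this coincides with the presence/absence contrast
(`min_threshold`), which is the intended reading. The tie rule is chosen
precisely so that the coincidence holds.

## The synthetic-cohort generator

No public individual-level dataset accompanies this class of analysis, so
the generator is first-class, tested code: every downstream stage is
exercised on cohorts with the statistical structure the method assumes.

* **Genotypes.** Each individual receives two independent haplotypes per
  gene; a haplotype thresholds a latent Gaussian vector with AR(1)
  correlation `ld_rho` at the normal quantile of each SNP's MAF. Marginal
  allele frequencies therefore equal the drawn MAFs exactly and dosages
  are in Hardy–Weinberg equilibrium *by construction* — the
  haplotype-level construction was chosen over a genotype-level Gaussian
  copula precisely to guarantee this. AR(1) gives decaying LD blocks with
  a single parameter per gene; the realized dosage correlation is
  attenuated relative to `ld_rho` by the thresholding, which the LD tests
  check against an independently coded threshold-model oracle.
* **Exposures.** Bounded-normal dimensions are Gaussians clipped to
  [1, 5]. The right-skewed dimension places a point mass (default 0.55)
  exactly at the floor 1.0 with a gamma tail above it, so the sample
  median equals the minimum and a median split is a presence contrast —
  the scenario that motivates the sensitivity analysis.
* **Covariates and outcome.** Age ~ N(13.78, 0.92²), sex ~
  Bernoulli(0.505) — the cohort structure this analysis is designed
  around (a population cohort of 948 adolescents). The symptom score
  follows the linear model of `sim_effect()`; with a target gene set,
  every SNP of that gene contributes both a main effect and an
  interaction, summed. Missingness, when requested, is injected after the
  phenotype is generated so the phenotype always reflects the true
  genotypes.
* **Defaults.** Cohort size 948; desk-scale panels of 50 genes with 2–8
  SNPs each (`default_gene_panel()`), latent `ld_rho` uniform on
  [0.3, 0.9] and MAF uniform on [0.05, 0.5] — moderate-to-strong
  within-gene LD with realistic attenuation, spanning common variants.
  Larger panels (the tests use 200-gene cohorts; a full several-hundred
  -gene panel is a single argument) scale linearly. Exposure scale
  locations (e.g. support centred at 3.8, harsh punitive control
  floor-massed) are configurable placeholders chosen as realistic 1–5
  Likert means, not estimates of any particular cohort; the outcome
  intercept 2.2 and residual sd 0.6 likewise.

What the generator does **not** emulate: family structure and sibling
correlation, population stratification, item-level questionnaire scoring,
genotyping batch effects, and informative missingness. Passing tests on
these cohorts therefore demonstrate the statistical machinery —
calibration under the stated null, power against the stated alternative —
not robustness to those real-data complications.

## Numerical choices

* Rank deficiency: relative singular-value tolerance $10^{-10}$.
* Covariance clamp $[0, 4]$ (and $[-4, 4]$ for the signed variant), which
  also guards against negative variance from noisy $r$ estimates.
* p-values are floored at the smallest positive double before logging and
  reporting; $\ln(1) = 0$ needs no adjustment.
* $-\log_{10} p$ in Manhattan tables floors $p$ at $10^{-300}$.
* Median-split ties go to 0; the empirical permutation p-value uses the
  add-one estimator.
* LD matrices read from disk are symmetrized by averaging when the
  asymmetry is at most $10^{-6}$ and rejected beyond that; entries may
  exceed $[-1, 1]$ by at most $10^{-9}$.
* Effect-size calibration (`calibrate_gxe_effect()`) uses the normal
  approximation $\beta = (z_{1-\alpha/2} + z_{\mathrm{power}})\,\sigma /
  (s_{g\cdot e}\sqrt{n})$ with $s_{g\cdot e}$ estimated from a 20,000
  -individual calibration draw.

## Problem sizes used by the test suite

The suite runs desk-scale versions of each study: 100 replicate 200-gene
null cohorts of 948 individuals for type-I calibration, 1,000 outcome
permutations of a 100-gene independent-SNP cohort for permutation
consistency, 50 replicates of a 49-null-gene-plus-one-signal-gene design
for recovery, 100,000-draw brute-force nulls for the pooling
approximation, and 50,000–100,000-individual cohorts for marginal
frequency, HWE and LD oracles. These sizes were chosen so the whole suite
completes in minutes on one core while leaving Monte-Carlo error well
below each assertion's tolerance.

## Known limitations

* The cubic covariance makes far-tail gene p-values mildly conservative
  under strong LD (measured above); implementations that convert
  statistic correlations by numerical integration for two-sided margins
  would be closer to nominal.
* LD is estimated from the same cohort being analysed; no external
  reference-panel option.
* Continuous outcomes and OLS only — no logistic outcomes, robust errors
  or mixed models.
* The permutation test permutes one vector globally; schemes preserving
  covariate linkage under the phenotype strategy (e.g. permuting
  residuals) are not implemented.
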