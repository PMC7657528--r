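---
title: "Kernel U-statistic pathway tests for correlated quantitative phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel U-statistic pathway tests for correlated quantitative phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcmsku)
```

## Problem and model

Genome-wide pathway analysis asks whether a *set* of SNPs — typically the
variants mapped to the genes of a biological pathway — is jointly
associated with a trait.  Aggregating to the pathway level pools many weak
signals, cuts the number of tests by orders of magnitude, and gives results
a direct biological reading.  Complex traits are rarely captured by one
measurement, so this package tests a pathway against several correlated
quantitative phenotypes at once: each phenotype is tested marginally and
the marginal p-values are combined with an explicit adjustment for their
dependence.

### The marginal test

Write $X_i \in \{0,1,2\}^p$ for subject $i$'s minor-allele counts at the
pathway's SNPs and $y_i$ for one phenotype.  The phenotype is first
residualized on an intercept and the covariates by ordinary least squares;
every statistic below sees only the residuals $e_i$, so the test is exactly
invariant to location shifts of the phenotype and to affine transformations
of the covariate columns.

A kernel $K(\cdot,\cdot)$ encodes a hypothesis about the form of the
genetic effect: the linear kernel spans additive effects, the polynomial
kernel of degree 2 adds pairwise interactions, the Gaussian kernel spans a
rich nonparametric class.  Because the best kernel is unknown, a bundle of
$M$ candidates is evaluated and the *maximum* standardized statistic is
used.  For each centered kernel matrix $\tilde K = HKH$,
$H = I - \tfrac1n \mathbf{1}\mathbf{1}^\top$,

$$T_n = \frac{1}{n(n-1)} \sum_{i \neq j} \tilde K_{ij} e_i e_j, \qquad
\hat V = \frac{2}{n^2(n-1)^2} \sum_{i \neq j} \tilde K_{ij}^2 e_i^2 e_j^2,
\qquad Q = T_n/\sqrt{\hat V}.$$

$T_n$ is a degenerate second-order U-statistic: it has mean zero under no
association whatever the kernel, and $\hat V$ is its natural plug-in
variance.  $Q$ is invariant to positive rescaling of either the kernel or
the residuals, which is why neither the kernel normalization nor the error
variance needs to be known.  Centering removes the grand-mean component of
the kernel that would otherwise couple to the (zero-sum) residuals'
sampling noise.

Under the null the vector $(Q_1,\dots,Q_M)$ is asymptotically mean-zero
multivariate normal with correlation $\Omega$, estimated by the plug-in

$$\hat\rho_{kl} = \frac{\sum_{i\neq j} \tilde K^{(k)}_{ij} \tilde
K^{(l)}_{ij} e_i^2 e_j^2}{\big(\sum_{i\neq j} (\tilde K^{(k)}_{ij})^2 e_i^2
e_j^2\big)^{1/2}\big(\sum_{i\neq j} (\tilde K^{(l)}_{ij})^2 e_i^2
e_j^2\big)^{1/2}},$$

and the p-value of $Q_{\max} = \max_m Q_m$ is the complement of an
equicoordinate rectangle probability of $N(0,\hat\Omega)$.  This keeps the
adaptivity of "take the best kernel" while avoiding permutation entirely.

### Screening

With an auxiliary label (for instance disease status in a cohort whose
quantitative phenotypes are being tested), a per-SNP single-predictor
regression against that label can discard pathway SNPs with no marginal
signal (threshold $\alpha_m = 0.05$) before the kernels are built.  The
label must be distinct from the phenotype under test: screening on the
tested phenotype itself would select SNPs correlated with its noise and
destroy the type I error.  For that reason screening is off unless a label
is supplied, and an empty selection falls back to the full pathway with a
flag rather than silently returning a null result.

### Combining phenotypes

For $k$ phenotypes the marginal pathway p-values enter Fisher's statistic
$T = \sum_i -2\log p_i$.  Under dependence $T$ is no longer
$\chi^2_{2k}$; its null is approximated by moment matching to a gamma
distribution with mean $\mu = 2k$ and variance
$\sigma^2 = 4k + 2\sum_{i<j} \hat c(r_{ij})$, where $r_{ij}$ is the
Pearson correlation of the covariate-adjusted phenotypes and
$\hat c(r) = 3.263r + 0.710\,\mathrm{sign}(r)r^2 + 0.027 r^3$, clipped to
$[-4, 4]$, is the Kost–McDermott polynomial approximation to
$\mathrm{cov}(-2\log p_i, -2\log p_j)$.  The global p-value is the upper
tail of $\mathrm{Gamma}(\mu^2/\sigma^2,\ \mathrm{scale} = \sigma^2/\mu)$.
With identity correlation this is exactly Fisher's combination; with
$k = 1$ it returns the marginal p-value to within floating-point error.

Feeding the *phenotype* correlation to $\hat c$ is a deliberate choice.
For these quadratic statistics the cross-phenotype correlation of the
underlying $Q$'s is closer to $r^2$ than to $r$; but the marginal
p-values' own finite-sample dispersion of $-2\log p$ exceeds its uniform
value of 4, and the two effects offset.  Empirically the raw-$r$ input
keeps the combined test's 0.05-level rejection rate at its nominal value
across $\rho \in \{0.2, 0.7\}$ (see the acceptance suite), which is the
behaviour the method is used for.  The polynomial lives in one function
(`brown_moments`) so an alternative covariance model is a one-line swap.

## Synthetic data generator

The generator exists so every stage is testable without external data, and
doubles as the simulation harness for calibration studies.

* **Genotypes** — per SNP, MAF drawn from Uniform(`maf_low`, `maf_high`)
  (default 0.05–0.5); two independent haplotypes per sample, each obtained
  by thresholding a latent Gaussian AR(1) process (adjacent-SNP
  correlation `ld_r`, default 0.5, a moderate within-gene LD level) at the
  MAF quantile.  Marginal genotype frequencies are exactly Hardy–Weinberg;
  LD decays geometrically with distance.
* **Covariates** — $Z_1 \sim N(2,1)$, $Z_2 \sim \mathrm{Bernoulli}(0.6)$.
* **Phenotypes** — $Y_{ki} = 0.02 Z_{i1} + 0.6 Z_{i2} + h(X_i) +
  \epsilon_{ki}$ with exchangeable error covariance
  $\sigma^2[(1-\rho)I + \rho J]$, $\sigma = 1$ by default, $t = 5$
  phenotypes.
* **Effect scenarios** — `null` ($h = 0$); `M`, a nonlinear effect
  $0.27(x_5 - x_{10}) + \cos(x_{10})e^{-x_{10}^2/5}$; `N`, three linear
  effects $0.37x_5 + 0.62x_{10} - 0.06x_{15}$; `P`/`Q`, sixty weak main
  effects ($H_P$) plus ninety pairwise interactions ($H_Q$) with
  coefficients drawn once from Uniform(0, 0.02) and frozen across
  replicates, scaled by $(b_P, b_Q) = (0.07, 2.3)$ (interaction-dominated)
  or $(3.8, 0)$ (pure main effects).  The $b_P$ weight multiplies the
  main-effect sum over $H_P$ and $b_Q$ the interaction sum over $H_Q$,
  matching the sets' definitions.

What the generator does **not** emulate: population structure and
relatedness, realistic block-wise LD maps, genotyping error and
missingness patterns, allele-frequency spectra of real cohorts.  Passing
calibration here therefore demonstrates correctness of the statistical
machinery under a clean design, not robustness to confounding — covariate
adjustment is the only confounding control in the model.

## Numerical choices

* Multivariate-normal rectangle probabilities use quasi-Monte-Carlo
  integration (absolute error $10^{-5}$) with an internal fixed seed,
  saved and restored around the call, so p-values are reproducible to
  reported precision and the caller's RNG stream is untouched.
* $\hat\Omega$ is symmetrized with unit diagonal; only if an eigenvalue is
  genuinely negative (below $-10^{-8}$) is it clipped and the matrix
  rescaled to a correlation matrix.  Exactly singular PSD cases (duplicate
  kernels) are left alone — their rectangle probability is well defined.
* Monomorphic SNPs are dropped before kernel construction (they contribute
  nothing but a constant); a pathway with no polymorphic SNP is an error,
  as is a kernel whose centered off-diagonal is identically zero.
* The Gaussian bandwidth's "median" sentinel resolves to
  $\sigma^2 = \mathrm{median}_{i<j}\|x_i - x_j\|^2 / 2$, excluding zero
  distances; all rows identical is an error rather than a silent
  degenerate kernel.
* $p$-values of exactly 0 entering the combination are floored at the
  smallest positive double with a warning; $\sigma^2$ is floored at $2k$
  under pathological negative correlation.
* Replicate seeds in `simulation_study` are drawn once from the master
  seed, so any subset of replicates can be reproduced by regenerating the
  seed vector.

## Study sizes used in the validation suite

The automated suite calibrates the combined test at the settings
$(p, n, \rho) \in \{400, 800\} \times \{200, 400\} \times \{0.2, 0.7\}$
with 1000 replicates (Monte-Carlo SE $\approx$ 0.007 at the 0.05 level),
and checks power orderings across scenarios at $n = 200$ vs $n = 800$ with
300 replicates.  Oracle checks use brute-force double loops ($n \le 20$),
a 200,000-draw Monte-Carlo of the rectangle probability, and 2,000-fold
permutation on null data at $n = 400$.

## Known limitations

* The normal approximation to $Q$ is a large-pathway asymptotic.  For
  small pathways (a few dozen SNPs or fewer) the quadratic form's skewness
  makes the marginal test mildly anti-conservative — rejection rates
  around 0.06–0.09 at nominal 0.05 were observed at 20–50 SNPs — and the
  marginal p-values' bulk deviates measurably from uniform.  The combined
  test's 0.05-level calibration is robust to this at the simulated
  dimensions ($p \ge 400$), but strict distribution-wide uniformity of the
  *combined* p-value is not attained at $n = 200$; users testing small
  SNP sets should prefer a permutation reference.
* The test is one-sided in $Q_{\max}$: protective-only pathways whose
  statistic is driven negative are not flagged.
* Binary phenotypes, rare-variant weighting and kernel families beyond
  linear/Gaussian/polynomial (e.g. IBS) are out of scope.
* The gamma approximation for $T$ assumes the marginal p-values are
  individually calibrated; it cannot repair a miscalibrated marginal test.
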