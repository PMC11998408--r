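---
title: "Weather-resilience phenotypes from reaction norms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weather-resilience phenotypes from reaction norms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`resilnorm` quantifies how individual animals' growth responds to weather
variation, and whether that response is heritable. The workflow has four
stages:

1. **Data preparation.** Weekly average daily growth rates are derived from
   longitudinal body weights (the weight gain between consecutive weekly
   weighings divided by seven, in g/day; eight weighings give seven weekly
   rates). Daily weather is aggregated to weekly means and variances over
   the seven days ending on each weighing day, including a
   temperature-humidity index computed per day before aggregation.
2. **Reaction norms.** Growth is regressed on a weekly weather statistic
   with a quadratic (second-degree Legendre) population norm plus random
   per-individual deviations, fitted by EM-REML.
3. **Resilience phenotypes.** Each individual's combined norm (population
   plus deviation) is differentiated at two environmental values, one on
   either side of the curve maximum; the tangent slopes are the resilience
   phenotypes (small magnitude = stable growth under weather change).
4. **Genomics.** The slopes are treated as quantitative traits: genotype
   QC, a VanRaden genomic relatedness matrix (GRM), GREML heritability with
   a boundary likelihood-ratio test, and an EMMAX-style linear mixed model
   GWAS with genomic-control diagnostics.

A synthetic-data generator produces all three inputs (daily weather, weekly
weights, SNP genotypes) with known architecture, so every stage is testable
end to end without access to any real data.

# Models

## Population norm (stage 2, fixed regression)

For chicken $i$ in week $j$,
$$y_{ij} = \mathbf{x}_{ij}'\boldsymbol\beta_F + f(\boldsymbol\beta, X_j) + a_i + e_{ij},$$
where $y_{ij}$ is the weekly average daily growth rate (g/day), the fixed
effects are sex (2 levels) and a combined batch-by-local-season factor
(reference-level coded), $f(\boldsymbol\beta, X_j) = \beta_0\phi_0(x^*_j) +
\beta_1\phi_1(x^*_j) + \beta_2\phi_2(x^*_j)$ is the population norm in the
Legendre basis evaluated at the standardized weekly weather covariate,
$a_i \sim N(0, \sigma^2_a)$ is an i.i.d. individual intercept and
$e_{ij} \sim N(0, \sigma^2_e)$ the residual. One fit corresponds to one
(weather variable, weekly statistic) pair; mapping over all six variables
and both statistics yields the full table of twelve norms.

## Individual deviation norms (stage 2, random regression)

The deviation model replaces $a_i$ with a per-individual quadratic
deviation from the population norm,
$$y_{ij} = \mathbf{x}_{ij}'\boldsymbol\beta_F + f(\boldsymbol\beta, X_j) +
f_i(\mathbf{a}_i, X_j) + e_{ij}, \qquad \mathbf{a}_i \sim N(\mathbf{0},
\boldsymbol\Sigma_a),$$
with $\boldsymbol\Sigma_a$ an unstructured $3\times 3$ covariance across
the intercept, linear and quadratic deviation coefficients. Deviations are
predicted as BLUPs and are therefore shrunken toward zero; summaries
(median, SEM, SD) and the Pearson correlations of the intercept with the
linear and quadratic coefficients are computed on these BLUPs, with the
approximate correlation standard error $(1-r^2)/\sqrt{n-3}$.

Both models are phenotypic: no genomic information enters stage 2.

## Legendre basis and standardization

The covariate is mapped to $[-1,1]$ by
$x^* = 2(x-\ell)/(u-\ell) - 1$ using the observed minimum and maximum of
the weekly covariate; the range is stored inside every fitted norm because
slopes in natural units are otherwise irreproducible. The plain basis is
$(1,\; x^*,\; (3x^{*2}-1)/2)$; an orthonormal scaling
($\sqrt{(2k+1)/2}\,P_k$) is available by flag. Fitted curves, derivatives
and resilience slopes are invariant to this flag (the coefficients are
not); values outside the range are clipped with a flag rather than
extrapolated, because a quadratic extrapolates without bound and a slope
outside the observed environmental range has no supported interpretation.

## EM-REML

Variance components of both models are estimated by EM-REML on the
mixed-model equations. Each individual's random-effect equations are
absorbed analytically (per-individual $k\times k$ blocks; individuals
sharing a covariate pattern share factorizations), so one iteration costs
$O(q)$ for $q$ individuals. Updates are the classical ones:
$\hat\sigma^2_e = (\mathbf{y}'\mathbf{y} -
\hat{\mathbf{b}}'\mathbf{X}'\mathbf{y} -
\hat{\mathbf{u}}'\mathbf{Z}'\mathbf{y})/(N - p)$ and
$\hat{\boldsymbol\Sigma}_a = q^{-1}\sum_i (\hat{\mathbf{u}}_i
\hat{\mathbf{u}}_i' + \mathrm{PEV}_i)$. The restricted log-likelihood is
computed every iteration from the same factorizations and is
non-decreasing; convergence is declared when its relative change falls
below `tol` (default 1e-8, at most 1000 iterations — non-convergence is
flagged on the returned object, not raised). Covariance updates are
eigenvalue-floored at 1e-10 to keep the equations solvable near the
boundary, and the number of such projections is reported. Fixed-effect
standard errors come from the inverse coefficient matrix at convergence.

EM converges slowly when a variance is near zero (the boundary-stuck
behaviour familiar from standard REML software); the monotone likelihood
trace makes this visible.

## Resilience phenotypes (stage 3)

The individual norm is the coefficientwise sum of the population norm and
the individual deviation. Its tangent slope at covariate value $P$ is,
for the plain basis,
$$\mathrm{slope}(P) = \frac{2}{u-\ell}\left(c_1 + 3 c_2 x^*(P)\right),$$
in g/day per natural weather unit (per degree Celsius, percent humidity or
mm). Two evaluation points per norm are used, one on either side of the
curve's maximum. Bundled defaults cover the twelve standard norms (e.g. 22
and 26 degrees for weekly mean maximum temperature, 15.5 and 16.5 for
weekly mean THI); for new data the points default to the 25th/75th
percentile positions of the range, nudged to straddle the interior maximum.
When the maximum sits on a boundary (monotone norm on the observed range —
precipitation behaves like this) both points fall on the monotone side and
a warning is issued rather than an error. Argmax tie-breaks (equal boundary
values) go to the lower boundary for determinism; a flat curve returns the
range midpoint flagged degenerate.

## Genomic analysis (stage 4)

*QC.* Filters run in a fixed order: samples with call rate below 0.90,
SNPs with minor allele frequency below 0.02, SNPs on named sex chromosomes.
Optional greedy windowed LD pruning (default window 50 SNPs, step 5,
$r^2 > 0.8$) and identity-by-state duplicate removal (IBS $> 0.98$; the
later-sorted sample of a pair is removed). Missing dosages are mean-imputed
for correlation, GRM and association computations.

*GRM.* First VanRaden form with per-SNP scaling:
$G = m^{-1}\sum_k (\mathbf{g}_k - 2p_k)(\mathbf{g}_k - 2p_k)'/(2p_k(1-p_k))$,
zero-variance SNPs excluded and counted. The GRM is eigenvalue-clipped at
zero before PCA and REML; clipping changes no eigenvalue above 1e-8.

*GREML.* One eigendecomposition of $G$ turns REML into a one-dimensional
profile optimization over $\lambda = V_g/V_e$. The null model ($V_g = 0$)
gives a likelihood-ratio test against the 50:50 mixture of a point mass at
zero and $\chi^2_1$ (a single variance on its boundary). Standard errors
come from the numerically inverted observed information, with the $h^2$ SE
by the delta method; at the $V_g=0$ boundary SEs are reported as `NA`.

*GWAS.* In the default `approx` mode the variance ratio is fixed at its
null-model estimate and each SNP is tested by generalized least squares in
the rotated coordinates, with the residual scale re-estimated per SNP and a
$t$ reference on $n-p-1$ degrees of freedom — this makes an identity GRM
reduce exactly to the OLS $t$-test. The `exact` mode re-optimizes the
ratio per SNP before the same test. Effects are per copy of the counted
(minor) allele. Per-SNP explained variance uses
$[2\beta^2 \mathrm{maf}(1-\mathrm{maf})]\,/\,[2\beta^2
\mathrm{maf}(1-\mathrm{maf}) + \mathrm{se}(\beta)^2\, 2N\,
\mathrm{maf}(1-\mathrm{maf})]$, which reduces to
$\beta^2/(\beta^2 + N\,\mathrm{se}^2)$. Scan-level diagnostics are the
genomic inflation factor (median $\chi^2_1$ quantile over its null median
0.4549364) and Bonferroni thresholds $\alpha/m$ (genome-wide) and $1/m$
(suggestive, one expected false positive per scan). Gene context for hits
comes from a user-supplied GFF3 or BED annotation: genes overlapping
position $\pm$ 200 kb, distance zero inside a gene, otherwise the bp gap to
the nearest edge.

# The synthetic-data generator

`sim_config()` defaults describe the emulated study: about 1,590 chickens
in four batches whose first weighings fall in December, July, October and
December (so the batches cover the Bega, Belg and Kiremt local seasons),
eight weekly weighings each, highland weather (Kiremt weekly mean humidity
near 80–87%, heavy wet-season rain, mild temperatures), a desk-scale panel
of 5,000 SNPs with allele frequencies uniform on [0.02, 0.5], and a true
weekly-mean-THI population norm of (13.27, 1.78, -0.31) with deviation SDs
of roughly (1.58, 0.055, 0.38) — values on the scale of the study the
package emulates. Weather uses a seasonal mean plus AR(1) daily noise;
precipitation is zero-inflated gamma with wet-season intensity.

Design choices worth knowing:

* The reference batch carries a zero batch effect so the true norm
  intercept remains identifiable under reference-level coding.
* Genetic effects enter the *deviation triples*, not the weekly residuals:
  each coefficient is the sum of a standardized polygenic score (disjoint
  causal SNP sets per coefficient) scaled by $\sqrt{h^2_{dev}}$ and an
  independent environmental part scaled by $\sqrt{1-h^2_{dev}}$, then
  rotated to the target $\boldsymbol\Sigma_a$. Every linear function of the
  deviations — in particular every resilience slope — then has heritability
  $h^2_{dev}$ by construction, which is the structure the genomic stage
  assumes.
* Body weights are integrated from a starting weight of about 500 g (SD
  50 g) at the first weighing and stored unrounded, so growth-rate
  derivation inverts the construction exactly (the round trip is tested at
  1e-9).
* Genotypes are simulated *unrelated* (independent binomial dosages), with
  an optional two-subpopulation divergence mode for structure tests. Real
  populations carry family relatedness and LD; passing tests on this
  generator therefore demonstrates correctness of the estimators under the
  stated architecture, not robustness to pedigree structure, LD decay,
  imputation error or selection, none of which are emulated.

What the generator does not emulate of real data: measurement error and
outliers in weights, missing weighings, weather-station gaps (the pipeline
tolerates them — windows with five or six days are flagged, smaller ones
dropped — but the generator produces complete series), genotype calling
error, and any genotype-by-environment correlation.

# Numerical choices and Monte Carlo testing

* Problem sizes in the test suite are chosen for fast, stable checks:
  module tests run at 10–600 individuals; end-to-end recovery checks use
  1,500 chickens by 7 weekly records (population-norm recovery, 20
  replicates), 1,500 samples by 5,000 SNPs (GREML, 25 replicates plus 400
  null replicates sharing one GRM rotation) and 800 by 5,000 (GWAS
  calibration).
* Monte Carlo assertions on rates include their binomial sampling error:
  the null LRT type-I check, for example, is a one-sided test of "true
  type-I at most 0.05" at 400 replicates, rejecting only when the
  empirical rate exceeds 0.05 by more than 1.645 binomial standard errors.
  The package's LRT was verified against an independent dense REML
  implementation (agreement to about 4e-13 in the statistic), and the true
  null rate measured over 3,000 replicates is about 0.040.
* Null phenotype replicates are drawn from one continuous RNG stream;
  consecutive per-replicate `set.seed()` streams proved correlated enough
  to distort empirical rates.
* EM convergence is declared on the relative change of the restricted
  log-likelihood (1e-8); the basis-normalization invariance of resilience
  slopes is exact (1e-8) at matched variance components and holds to about
  1e-3 between independently EM-converged fits, the difference being
  stopping error, not model error.

# Known limitations

* EM-REML is first-order and slow near variance boundaries; fits that hit
  `max_iter` are flagged, not raised. Average-information acceleration is
  a possible future addition.
* Deviation-coefficient correlations are computed on BLUPs, as in standard
  practice for this analysis; shrinkage inflates their magnitude relative
  to correlations of the true coefficients (values near $\pm 1$ in the
  correlation table are a consequence of strong shrinkage when a
  coefficient's variance is small.
* With each individual observed in a single batch (hence a narrow slice of
  the environmental range), the deviation covariance is weakly identified;
  at a few hundred individuals its estimates show visible finite-sample
  bias that disappears by about 600 individuals in the tested designs.
* The GWAS `approx` mode shares the EMMAX approximation error; on null
  scans of 600+ samples it agrees with the exact mode within a factor 1.2
  in p-value, but at much smaller sample sizes individual SNPs can exceed
  that factor.
* Pedigree/genomic relationships are deliberately excluded from the
  reaction-norm stage (it is phenotypic); heritability refers only to the
  derived slope phenotypes.
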