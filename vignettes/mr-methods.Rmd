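---
title: "Summary-statistics Mendelian randomization along causal pathways: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Summary-statistics Mendelian randomization along causal pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpath)
```

## The problem

Observational associations between metabolic traits — obesity, circulating
lipids, serum urate — and disease endpoints such as gout are vulnerable to
confounding and reverse causation. Mendelian randomization (MR) sidesteps
much of this by using genetic variants as instrumental variables: genotypes
are fixed at conception, so a SNP reliably associated with an exposure
provides a randomized "dose" of it. In the two-sample design the SNP-exposure
effects $\hat\beta_{ZX,j}$ and SNP-outcome effects $\hat\beta_{ZY,j}$ come
from separate, non-overlapping GWA studies, and only published summary
statistics are needed.

`mrpath` implements the full analysis chain for this design: harmonization
of summary statistics, instrument selection, the univariable estimator
battery with its pleiotropy diagnostics, radial outlier filtering,
multivariable MR, mediation decomposition, and cross-trait genetic
correlation by LD-score regression — plus a generator of synthetic GWAS
summary statistics with known ground truth, so that every estimator in the
package is validated by parameter recovery rather than by comparison with
another implementation.

## Estimators

**Wald ratios and IVW.** Each instrument's causal estimate is
$\hat\beta_{XY,j} = \hat\beta_{ZY,j} / \hat\beta_{ZX,j}$ with first-order
standard error $se(\hat\beta_{ZY,j}) / |\hat\beta_{ZX,j}|$ — exposure-side
noise is ignored, which is the convention when instruments are strong and is
diagnosed by $I^2_{GX}$ when they are not. The inverse-variance weighted
(IVW) estimate pools the ratios with weights $w_j = se_j^{-2}$ and is
algebraically the weighted regression of outcome on exposure effects through
the origin (an identity the test suite asserts to $10^{-10}$). When
Cochran's $Q$ exceeds its degrees of freedom the standard error is inflated
by $\sqrt{Q/df}$ (multiplicative random effects); it is never deflated.
Confidence intervals and p-values use the normal reference for IVW and the
$t_{n-2}$ reference for MR-Egger, each method's convention.

**MR-Egger.** A weighted regression with a free intercept, exposure effects
oriented positive. The slope is robust to directional pleiotropy under the
InSIDE assumption; the intercept estimates the average pleiotropic effect
and its test (intercept consistent with zero) screens the IVW estimate.
Egger's slope requires negligible exposure-side measurement error;
$I^2_{GX} = (Q_{GX} - (n-1))/Q_{GX}$ quantifies the attenuation (values
near 1 are clean; 0.9 means roughly 10% dilution). When $I^2_{GX}$ falls
below 0.9 the pipeline triggers SIMEX: noise of variance
$\lambda \, se^2_{exp,j}$ is added at $\lambda \in \{0.5, 1, 1.5, 2\}$, the
slope re-estimated over $B$ replicates, a quadratic in $\lambda$ fitted
through the mean slopes, and the fit extrapolated to $\lambda = -1$. The
SIMEX standard error jackknifes the extrapolation over replicates, so it
reflects the stability of the extrapolation itself.

**Weighted median and weighted mode.** The interpolated weighted median of
the ratios is consistent while under half the total weight is on invalid
instruments; the weighted mode (normal-kernel density with the modified
Silverman bandwidth $\phi \cdot 0.9 \min(sd, IQR/1.349) n^{-1/5}$, mass
$w_j/\sum w$) is consistent when the largest group of agreeing instruments
is valid. Both take bootstrap standard errors from redrawing each ratio from
$N(\hat\beta_{XY,j}, se_j)$; 1000 replicates by default, and the seed is a
mandatory argument so every report is reproducible.

**Radial filter.** In radial coordinates the IVW fit decomposes Cochran's
$Q$ exactly into per-SNP contributions $w_j(\hat\beta_{XY,j} - \hat\beta)^2$,
each referred to $\chi^2_1$. Variants with $p < 0.05$ are flagged and, by
default, removal iterates to convergence (capped at 10 rounds) — re-testing
after removal is the natural reading of "remove outliers, then re-run", and
a single-pass mode is available by flag. Per-SNP p-values are deliberately
not multiplicity-corrected: the flat 0.05 threshold is the filter's
operating characteristic, not an inference.

**Multivariable MR and mediation.** Multivariable IVW regresses the outcome
effects on $K$ exposure-effect columns without intercept, weights
$se_{out}^{-2}$: coefficient $k$ is the direct effect of exposure $k$. The
mediation decomposition combines the univariable total effect, the
multivariable direct effect (exposure adjusted for mediator), and the
indirect effect by the product of coefficients
$\hat\beta_{EM}\hat\beta_{MO}$ with first-order delta-method standard error
$\sqrt{\hat\beta_{EM}^2 se_{MO}^2 + \hat\beta_{MO}^2 se_{EM}^2}$. The two
legs come from non-overlapping samples, so their covariance is taken as
zero, and the second-order $se^2 se^2$ term is omitted (standard first-order
delta). When direct and indirect effects disagree in sign the mediation is
*inconsistent* and no proportion mediated is reported — reporting one would
average two opposing mechanisms into a meaningless number.

**LD-score regression.** Per-SNP $\chi^2$ regressed on LD scores with a free
intercept gives the observed-scale SNP heritability
($h^2 = slope \cdot M/n$); the product $z_{1j} z_{2j}$ regressed on LD
scores gives the genetic covariance, and
$r_g = gencov/\sqrt{h^2_1 h^2_2}$. Intercepts are left unconstrained for
both regressions, as befits non-overlapping samples where the cross
intercept is expected near zero. Uncertainty comes from a delete-one block
jackknife over 200 contiguous SNP blocks, applied to the *full* $r_g$
statistic so that the correlation between numerator and denominators is
respected. The regression is homoskedastic OLS: the reference
implementation's heteroskedasticity weights are a known efficiency
refinement that we deliberately omit in this version — recovery tests must
and do pass without them — and liability-scale conversion is out of scope.

## Harmonization rules

Exposure and outcome effects must refer to the same effect allele.
Non-palindromic variants resolve by direct match, allele swap (sign flip,
frequency mirrored), or the same two patterns on the complementary strand;
anything else is dropped as incompatible. Palindromic variants (A/T, C/G)
carry no strand information in their allele labels, so frequency is the only
signal: when both studies report an effect-allele frequency outside the
ambiguity window [0.3, 0.7] (the convention of the established two-sample MR
tooling; configurable), matching frequency directions keep the row and
opposite directions flip it; inside the window, or with a missing frequency,
the variant is dropped — conservative, because frequency alignment is then
impossible. Multi-allelic records and indels are rejected at read time, and
variants are matched by identifier only (no genome-build handling). Every
row's fate is recorded: kept, flipped, dropped-palindromic,
dropped-incompatible, or absent from one study, and the counts must add up
to the union of variant ids — an invariant under test.

## The synthetic-data generator

The generator simulates summary statistics directly — per-SNP effects plus
sampling noise at the study's size — rather than individual-level genotypes;
that is sufficient for everything the estimators consume and orders of
magnitude faster. Defaults define the study conditions used throughout the
tests:

* 50 instruments, exposure and outcome samples of 100,000 (consortium
  scale), non-overlapping by construction;
* per-instrument variance explained drawn uniformly from 0.3–0.6%, the
  per-SNP strength implied by instrument sets whose printed totals are
  $R^2 \approx 0.06$–$0.08$ over 13–15 SNPs (per-SNP F of roughly 300–600
  at these sample sizes); true effects follow as
  $\beta = \sqrt{v / 2p(1-p)}$ with allele frequencies uniform on
  [0.1, 0.9];
* standard errors $se = 1/\sqrt{2p(1-p)n}$ for standardized continuous
  traits, with the $1/(v(1-v))$ log-odds inflation for a binary outcome of
  case fraction $v$ — an approximation whose adequacy is checked by
  calibration (CI coverage), not exactness;
* pleiotropy modes: none; balanced (zero-mean direct outcome effects on all
  SNPs, sd 0.01); directional (mean-shifted effects on an invalid fraction,
  default 30%); correlated (invalid-fraction effects proportional to
  instrument strength, violating InSIDE);
* mediation systems draw disjoint instrument sets for exposure and mediator
  and propagate effects through the path algebra, so the total effect is
  $\beta_{direct} + \beta_{EM}\beta_{MO}$ by construction;
* LD-score panels draw right-skewed LD scores ($1 + \Gamma(1.5, 40)$) and
  bivariate per-SNP effects with covariance $r_g\sqrt{h^2_1 h^2_2}\,\ell/M$,
  giving the regression structure $E[\chi^2] = 1 + n h^2 \ell/M$.

What the generator does *not* emulate: realistic allele-frequency spectra,
LD between instruments (simulated instruments are independent; clumping is
exercised through explicit LD matrices), population stratification, sample
overlap, and winner's curse from in-sample instrument discovery. Passing
recovery tests therefore demonstrate estimator correctness under the stated
generative model, not robustness to those real-data complications.

## Numerical and design choices

* **Weak-instrument attenuation.** With exposure-side noise in the
  generative model, IVW's estimand is attenuated by roughly $1/(1+1/\bar F)$
  — about 0.2–0.3% at the default instrument strength. This is a property
  of the estimator, visible in the calibration runs, and is exactly what
  $I^2_{GX}$/SIMEX exist to diagnose and correct at Egger scale.
* **Ties and determinism.** Clumping breaks p-value ties lexicographically
  by variant id; all bootstrap and SIMEX routines require seeds; pipeline
  reruns with the same seed write byte-identical reports.
* **Degenerate inputs.** Identical ratios give a zero kernel bandwidth — the
  weighted mode returns the common ratio with the IVW standard error and a
  log message. A single instrument degrades IVW to its Wald ratio with a
  message. Fewer than three instruments refuse Egger, median, mode and the
  radial filter with explicit errors. An all-zero total effect guards the
  proportion-mediated division.
* **Multiplicity.** The canonical plan charges ten tests (eight univariable,
  one multivariable, one mediation): stringent evidence at
  $p < 0.05/10 = 0.005$, suggestive below 0.05. Two-step chains gate step 2
  on step 1 reaching the *stringent* tier (the conservative reading of
  "only significant models are taken forward"; configurable).
* **SIMEX trigger.** Auto mode runs SIMEX when $I^2_{GX} < 0.9$,
  operationalizing the "about 10% bias near 90%" rule; an always/never flag
  overrides.
* **Problem sizes.** The recovery suites run at 1000 seeds (calibration),
  500 (robustness ordering, mediation), 200 (outlier detection), and 100
  (LD-score panels of 20k SNPs) — sizes at which Monte-Carlo bands are tight
  enough to detect implementation errors while the whole suite stays
  desk-scale.

## Limitations

Real summary statistics bring complications the package's validation cannot
certify: sample overlap between exposure and outcome studies, winner's
curse, mis-specified effect-allele columns upstream, LD mismatch with the
clumping reference, and binary-trait effect scales that vary across GWA
pipelines. The LDSC module reads a simple tab-delimited dialect, not the
reference `.l2.ldscore.gz` formats, omits heteroskedasticity weights and
partitioned heritability, and reports observed-scale heritability only.
MVMR provides no conditional weak-instrument diagnostics. These are
documented boundaries, not planned features.
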