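# mrpath

Two-sample Mendelian randomization (MR) along causal pathways, from GWAS
summary statistics only. `mrpath` is for epidemiologists and statistical
geneticists who want to move beyond a single exposure–outcome MR test to
the designs that probe *mechanism*: two-step MR, multivariable MR, and
formal mediation analysis (for example obesity → urate → gout), together
with cross-trait genetic correlations as a complementary line of evidence.

## What it computes

Given harmonized SNP–exposure effects β̂<sub>ZX,j</sub> and SNP–outcome
effects β̂<sub>ZY,j</sub> from non-overlapping samples:

* **Wald ratios** β̂<sub>XY,j</sub> = β̂<sub>ZY,j</sub>/β̂<sub>ZX,j</sub>
  with first-order weights w<sub>j</sub> = β̂<sub>ZX,j</sub>²/se(β̂<sub>ZY,j</sub>)²,
  pooled by the **inverse-variance weighted (IVW)** estimator
  (≡ weighted regression through the origin), with Cochran's Q and
  multiplicative random-effects inflation √(Q/df) when Q > df.
* The **sensitivity battery**: MR-Egger regression (slope + directional-
  pleiotropy intercept test, I²<sub>GX</sub> dilution diagnostic, SIMEX
  correction), the interpolated **weighted median**, and the kernel
  **weighted mode**, each with seeded bootstrap standard errors.
* **Radial-MR outlier removal**: Q decomposes exactly into per-SNP
  contributions w<sub>j</sub>(β̂<sub>XY,j</sub> − β̂)², referred to χ²₁ at a
  flat 0.05 threshold, iterated to convergence.
* **Multivariable MR**: weighted multiple regression of outcome effects on
  K exposure-effect columns, giving each exposure's direct effect.
* **Mediation**: total (univariable), direct (multivariable), and indirect
  effect by the product of coefficients β̂<sub>EM</sub>·β̂<sub>MO</sub> with
  delta-method SE √(β̂²<sub>EM</sub>se²<sub>MO</sub> + β̂²<sub>MO</sub>se²<sub>EM</sub>),
  plus inconsistent-mediation classification (opposite-sign direct and
  indirect effects → no proportion mediated).
* **LD-score regression**: observed-scale SNP heritability and cross-trait
  genetic correlation r<sub>g</sub> = gencov/√(h²₁h²₂), with delete-one
  block-jackknife uncertainty on the full r<sub>g</sub> statistic.
* A **synthetic-data generator** for two-sample datasets, mediation systems
  and LD-score panels with known ground truth — the package's validation
  backbone.

## Worked example

The mediation arithmetic on published-scale estimates — an exposure→mediator
effect of 0.127 (95% CI 0.098–0.157) and a mediator→outcome odds ratio of
1.030 (95% CI 1.028–1.032):

```r
library(mrpath)
ind <- product_of_coefficients(
  beta_em = 0.127, se_em = (0.157 - 0.098) / 3.92,
  beta_mo = log(1.030), se_mo = (log(1.032) - log(1.028)) / 3.92,
  binary = TRUE)
ind
#> indirect (product of coefficients): OR 1.004 (95% CI 1.003, 1.005), p = 4.68e-16
```

The indirect effect is OR 1.004: each unit of the exposure multiplies the
outcome odds by 1.004 *through the mediator*. And a full estimator run on a
simulated two-sample dataset with true causal effect 0.127:

```r
cfg <- sim_config(n_snps = 50, true_effect = 0.127, seed = 1)
d <- simulate_two_sample(cfg)
h <- harmonize(d$exposure, d$outcome)
mr_ivw(wald_ratios(h))$estimate
#> IVW: beta 0.1188 (95% CI 0.1055, 0.1320), p = 4.36e-69 [50 SNPs]
mr_egger(h)$intercept
#> Egger-intercept: beta 0.0009 (95% CI -0.0082, 0.0100), p = 0.851 [50 SNPs]
mr_weighted_median(wald_ratios(h), boot_reps = 1000, seed = 1)
#> weighted-median: beta 0.1186 (95% CI 0.0998, 0.1373), p = 2.6e-35 [50 SNPs]
```

The IVW interval covers the generative truth, the Egger intercept is
consistent with zero (no directional pleiotropy was simulated), and the
weighted median agrees — the qualitative screen one wants before trusting
an IVW estimate.

## The analysis workflow

`analysis/` holds the study-shaped workflow, each stage a thin driver over
the package that prints what it found and writes its tables under
`results/`:

1. `01_simulate_study.R` — generate the synthetic obesity/lipids/urate/gout
   datasets (tab-delimited, re-read by later stages).
2. `02_univariable_mr.R` — the univariable battery with two-step gating and
   Bonferroni tiers (0.05/10).
3. `03_mvmr_mediation.R` — multivariable MR of three exposures on urate;
   mediation decomposition of obesity on gout through urate.
4. `04_genetic_correlations.R` — LD-score genetic correlations for the
   trait pairs.

Run them in order from the repository root with `Rscript`.

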