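# mrivw

Two-sample Mendelian randomization (MR) from GWAS summary statistics, for
epidemiologists asking whether a circulating biomarker — the motivating
case is insulin-like growth factor 1 (IGF1) and its binding protein
IGFBP3 — causally affects a binary disease outcome such as Alzheimer
disease, using only published per-SNP association results.

## What it computes

Genetic variants that robustly determine the exposure serve as
instrumental variables. For each variant *j*, with exposure association
β<sub>GX,j</sub> (per SD of exposure) and outcome association
β<sub>GY,j</sub> (log-odds), the Wald ratio estimate of the causal
effect is

&nbsp;&nbsp;β̂<sub>IV,j</sub> = β<sub>GY,j</sub> / β<sub>GX,j</sub>,&nbsp;&nbsp;
se²<sub>IV,j</sub> = se²<sub>GY</sub>/β²<sub>GX</sub> + β²<sub>GY</sub>se²<sub>GX</sub>/β⁴<sub>GX</sub>
(first-order delta method).

Per-variant estimates *b<sub>j</sub>* (Wald ratios, or raw outcome
log-odds in causal-inference mode) are pooled by fixed-effects
inverse-variance weighting with w<sub>j</sub> = s<sub>j</sub><sup>−2</sup>:

&nbsp;&nbsp;β̂ = Σw<sub>j</sub>b<sub>j</sub> / Σw<sub>j</sub>,&nbsp;&nbsp;
se(β̂) = (Σw<sub>j</sub>)<sup>−1/2</sup>,&nbsp;&nbsp;
Q = Σw<sub>j</sub>(b<sub>j</sub> − β̂)²,&nbsp;&nbsp;
I² = max{0, (Q − (k−1))/Q}·100%.

Around that core the package provides: summary-statistics readers with
configurable column dialects and total row-level validation; allele
harmonization (swaps, strand complements, palindromic-SNP policies) with
a full flips audit; orientation of all effects to exposure-raising
alleles; instrument-subset and IGF1:IGFBP3 molar-ratio sensitivity
analyses; binary-outcome MR power calculations; and a synthetic
summary-statistics generator with known causal effect and optional
pleiotropic outliers for validation. See the methods vignette
(`vignettes/two-sample-mr-methods.Rmd`) for assumptions and design
choices.

## Worked example

The packaged synthetic fixture is a study-shaped dataset: 9 main
instruments (5 IGF1-only including the FOXO3-intron variant rs2153960,
2 IGFBP3-only, 2 affecting both) plus rs646776, which has opposite
effects on the two traits and enters only the molar-ratio analysis. The
simulated causal effect is null.

```r
library(mrivw)
dir <- system.file("extdata", "igf_synthetic", package = "mrivw")
report <- run_pipeline(list(
  exposure = file.path(dir, "exposure.tsv"),
  outcome = file.path(dir, "outcome.tsv"),
  instruments = file.path(dir, "instruments.tsv"),
  mode = "causal",
  power = list(n = 54162, case_fraction = 0.314, r2 = 0.065)))
report
```

prints (abridged):

```
Harmonization of 10 instrument(s): 10 pair(s) harmonized, 0 excluded
Sign-recoded to the raising allele: 5 beta pair(s)

Fixed-effects IVW Mendelian randomization (causal mode)
Analysis: main
Instruments: 9
Pooled OR per raising allele: 1.01 (95% CI 1.00-1.01); p = 0.279
Heterogeneity: Q = 4.819 on 8 df (p = 0.777); I2 = 0.0%

Fixed-effects IVW Mendelian randomization (causal mode)
Analysis: molar_ratio
Instruments: 8
Pooled OR per raising allele: 1.00 (95% CI 0.99-1.01); p = 0.72
Heterogeneity: Q = 2.697 on 7 df (p = 0.912); I2 = 0.0%

Binary-outcome MR power design
  n = 54,162, case fraction = 0.314, instrument R2 = 0.065
  alpha = 0.050 (two-sided), target power = 0.80
  Minimum detectable OR: 0.903 (protective), 1.107 (harmful)
```

Reading the output: exactly 5 of the 9 main betas had to be sign-recoded
so every result is expressed per exposure-raising allele; the pooled
odds ratio per raising allele is compatible with 1 (as it should be —
the fixture's true causal effect is zero); Q and I² show no
heterogeneity, i.e. no evidence that any single variant acts on the
outcome through a pathway other than the exposure; and a design of this
size could have detected a protective OR of ≈0.90 (or harmful ≈1.11) per
SD of exposure at 80% power, so a null is informative. Individual model
objects support the usual verbs: `coef()`, `confint()`, `residuals()`
(standardized residuals flag pleiotropic outliers), `weights()`,
`summary()` and `plot()` (forest plot).

A pleiotropic-outlier scenario, in which heterogeneity diagnostics must
single out the injected variant:

```r
sim <- make_foxo3_scenario(sim_config(seed = 77), outlier = 4, outlier_or = exp(0.5))
h   <- harmonize_pairs(sim$exposure, sim$outcome, sim$instruments)
fit <- mr_ivw(h, mode = "causal")
fit$pooled$Q_pvalue        # ~0: strong heterogeneity
which.max(abs(residuals(fit)))  # rs2153960, the injected outlier
```

A thin command-line wrapper lives at `inst/cli/mrivw.R`
(`run <config.yaml>`, `simulate`, `power`).

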