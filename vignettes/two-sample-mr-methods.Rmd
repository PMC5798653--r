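---
title: "Methods: two-sample Mendelian randomization with mrivw"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization with mrivw}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrivw)
```

## The design and its model

Mendelian randomization (MR) uses genetic variants as instrumental
variables for an exposure. If a variant robustly determines circulating
IGF1 or IGFBP3 (the instrument relevance assumption), is not associated
with confounders of the exposure–outcome relationship, and affects
Alzheimer disease risk only through the exposure (no horizontal
pleiotropy), then the variant–outcome associations carry information
about the causal effect of the exposure. In the two-sample flavour the
variant–exposure and variant–outcome associations come from two separate
GWAS samples, so only published summary statistics — per-allele betas,
standard errors and coded alleles — are needed.

`mrivw` implements two analysis modes.

**Causal-inference mode** pools the per-variant outcome log-odds
directly, after orienting every association to the exposure-*raising*
allele. The pooled estimate tests for and signs a causal effect but its
unit is "per raising allele", not per exposure unit; this mode needs no
variant–exposure betas beyond knowing which allele raises the exposure,
which is why it remains available when an exposure GWAS publishes only
z-scores.

**Magnitude mode** forms the per-variant Wald ratio
$\hat\beta_{IV,j} = \hat\beta_{GY,j} / \hat\beta_{GX,j}$, the outcome
log-odds per unit (here SD) of the exposure, with the first-order
delta-method standard error

$$ se_{IV,j}^2 = \frac{se_{GY,j}^2}{\beta_{GX,j}^2}
   + \frac{\beta_{GY,j}^2\, se_{GX,j}^2}{\beta_{GX,j}^4}. $$

Both variance terms are kept by default; `delta = "first_term"` gives the
common simplification $se_{GY}/|\beta_{GX}|$ for comparability with
software that ignores exposure-side uncertainty. No covariance term is
included because the two samples do not overlap appreciably — the
defensible approximation for a two-sample design.

Either way, per-variant estimates $b_j$ with standard errors $s_j$ are
pooled by fixed-effects inverse-variance weighting:
$w_j = s_j^{-2}$, $\hat\beta = \sum w_j b_j / \sum w_j$,
$se(\hat\beta) = (\sum w_j)^{-1/2}$. Heterogeneity is summarized by
Cochran's $Q = \sum w_j (b_j - \hat\beta)^2$ on $k-1$ degrees of freedom
and $I^2 = \max\{0, (Q - (k-1))/Q\} \times 100\%$. With a handful of
instruments, heterogeneity — and the variant with the largest absolute
standardized residual $(b_j - \hat\beta)/s_j$, see `residuals()` — is the
primary pleiotropy diagnostic. MR-Egger and related estimators are
deliberately out of scope: with fewer than ten instruments they are
underpowered and fragile, and a fixed-effects model is retained rather
than a random-effects fallback because the intended use is small,
carefully curated instrument sets where heterogeneity is investigated,
not averaged over.

## Harmonization rules

Two GWAS rarely code the same variant on the same allele or even the
same strand. `align_alleles()` reconciles an exposure and an outcome
record by, in order: direct match; effect/other swap (negate the outcome
beta, complement its allele frequency); strand complement (A↔T, C↔G);
complement plus swap. Anything else is a hard error naming both allele
pairs. Palindromic variants (A/T or C/G) cannot be resolved from alleles
alone; the default policy drops them when either coded-allele frequency
is missing or falls in [0.42, 0.58] (too close to 0.5 to tell strands
apart) and otherwise infers the strand by frequency concordance. The
window endpoints are a conventional compromise: wide enough that a few
percent of frequency estimation error cannot silently flip a strand
call, narrow enough not to discard clearly asymmetric variants. Both
source GWAS here are European-ancestry, which is what makes
frequency-matching defensible at all; `policy = "drop_all"` is the
conservative alternative.

`orient_to_raising_allele()` then recodes each aligned pair so the coded
allele raises the exposure (log-odds are subtracted from zero when the
coding flips). Additive allele effects are assumed throughout. Every
transformation is appended to a per-variant `flips` audit string, so the
mapping from published numbers to analysed numbers is reviewable; the
packaged study-shaped fixture recodes exactly 5 of its 9 main betas and
the audit proves it.

For the molar-ratio analysis (`code_molar_ratio()`), IGF1-only variants
keep their IGF1-raising orientation, IGFBP3-only variants are recoded to
their IGFBP3-*lowering* alleles (lowering the denominator raises the
IGF1:IGFBP3 ratio), and the one variant with inverse effects on the two
traits enters on its higher-IGF1/lower-IGFBP3 allele. Variants raising
both traits are rejected from this analysis — their net effect on the
ratio is undetermined.

## Power calculation

For a case-control outcome the IVW estimate is treated as Gaussian with
information $n \, R^2 \, K(1-K)$ per squared log-odds unit, where $n$ is
the total outcome sample size, $K$ the case fraction and $R^2$ the
exposure variance explained by the instruments. Two-sided power at odds
ratio $OR$ is
$\Phi\!\left(|\ln OR|\sqrt{n R^2 K(1-K)} - z_{1-\alpha/2}\right)$, and
the minimum detectable OR at target power $1-\beta$ solves
$|\ln OR| = (z_{1-\beta} + z_{1-\alpha/2}) / \sqrt{n R^2 K(1-K)}$.
This is the standard normal approximation used by published MR power
calculators for binary outcomes. At the design that motivated the
package (n = 54,162, K = 0.314, $R^2$ = 0.065, $\alpha$ = 0.05, power
0.80) it yields:

```{r power}
design <- mr_power_design(n = 54162, case_fraction = 0.314, r2 = 0.065)
min_detectable_or(design, "protective")
min_detectable_or(design, "harmful")
```

Protective and harmful bounds are exact reciprocals under this formula;
the harmful bound evaluates to 1.107, slightly below the ~1.12 sometimes
quoted from calculator output, a difference well inside the "approximate"
qualifier such numbers carry. `power_binary(design, min_detectable_or(design))`
returns the target power to machine precision — the two functions are
inverses by construction, and the test suite additionally checks the
prediction against Monte-Carlo rejection rates of the full simulated
pipeline (agreement within 3 percentage points at 2,000 replicates).

`sd_from_iqr()` converts a published interquartile range to an SD via
IQR/1.35, valid for approximately normal traits in large samples (the
exact normal divisor is $2\,\Phi^{-1}(0.75) = 1.3490$).

## What the synthetic generator emulates

`simulate_two_sample()` simulates at the *summary-statistics* level, not
individual genotypes. For SNP $j$ with effect-allele frequency $p_j$
explaining a fraction $r^2_j$ of an SD-scaled exposure, the true
per-allele effect is $b_j = \sqrt{r^2_j / (2p_jq_j)}$ and the observed
exposure beta is drawn from
$N(b_j,\, se_{x,j}^2)$ with $se_{x,j} = 1/\sqrt{2p_jq_j\,n_{exp}}$. The
observed outcome log-odds is drawn from
$N(\theta b_j + \gamma_j,\, se_{y,j}^2)$ with
$se_{y,j} = 1/\sqrt{2p_jq_j\,n\,K(1-K)}$, where $\theta$ is the causal
log-odds per SD and $\gamma_j$ a direct (pleiotropic) effect bypassing
the exposure. These are the standard GWAS information approximations;
reported standard errors equal the true sampling SDs. Exposure and
outcome noise use seeds derived independently from the single
configuration seed, reflecting the two-sample assumption, and identical
configurations give bit-identical tables.

Defaults are deliberately study-shaped: 9 instruments jointly explaining
6.5% of the exposure variance with allele frequencies spread over
0.15–0.55, an exposure GWAS of 30,884, and an outcome sample of 17,008
cases and 37,154 controls. `make_foxo3_scenario()` sets $\theta = 0$ and
gives exactly one SNP a pleiotropic effect (default per-allele OR 1.04),
the configuration in which heterogeneity diagnostics should, and in the
test suite do, single out the injected variant. `simulate_igf_study()`
adds the trait structure of the motivating instrument set — 5 IGF1-only,
2 IGFBP3-only, 2 shared variants plus one bivariate-opposite variant —
with 5 lowering-allele codings and 3 allele swaps for the harmonizer to
repair; the packaged `inst/extdata/igf_synthetic` fixture is this
simulation at seed 20180123, and all its rsids except the two
biologically meaningful anchors are synthetic placeholders.

The generator does **not** emulate linkage disequilibrium between
instruments, winner's curse in instrument discovery, population
stratification, sample overlap between the two GWAS, or non-collapsibility
of the odds ratio at large effects. Passing calibration tests on these
simulations therefore demonstrates the estimator's arithmetic and its
sampling-theory behaviour under the stated model, not robustness to
those real-data complications.

## Numerical choices and degenerate inputs

* A Wald ratio with $\beta_{GX} = 0$ is an error (weak-instrument
  degenerate case), not an `Inf` that would silently dominate weights.
* `ivw_meta()` with one estimate returns it unchanged with $Q = 0$,
  $I^2 = 0$ and an undefined (NA) heterogeneity p-value.
* $I^2$ is floored at zero and reported in percent.
* Odds-ratio CIs use exact normal quantiles at full double precision.
* Table writers serialize doubles with 17 significant digits, making
  write-then-read bit-exact; display formatting (OR to 2 decimals, p to
  3 significant figures) happens only at print time.
* P-values computed in the generator are floored at the smallest
  positive double so that validation's "p in (0, 1]" invariant holds
  even for extreme z-statistics.
* Report files contain no timestamps; identical configs give
  byte-identical outputs.

## Problem sizes used by the test suite

Monte-Carlo checks run the full generator → harmonization → IVW path:
2,000 replicates each for power concordance, null calibration (CI
coverage and Q size) and parameter recovery at $\theta = 0.1$; 500
replicates for pleiotropic-outlier detection; 1,000 random estimate sets
for the weighted-least-squares oracle equivalence; 100 random
configurations × 40,000 bootstrap draws for the delta-method check,
restricted to instrument-strength proxies $|\beta_{GX}|/se_{GX} \ge 10$
where the first-order approximation is known to be accurate to a few
percent. These sizes keep Monte-Carlo error comfortably below the
tolerances being asserted while completing in a couple of minutes.

## Known limitations

Magnitude-mode results are only as good as the exposure-side betas —
when a published exposure GWAS provides only z-scores, causal-inference
mode is the honest analysis, which is exactly the situation the package
mirrors. Only biallelic SNVs are supported (no indels, no multiallelic
records, no LD-proxy lookup for missing instruments). The power formula
is an approximation that ignores exposure-side estimation error; with
instrument F-statistics above ~10 the test suite shows the discrepancy
is within a few percentage points.
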