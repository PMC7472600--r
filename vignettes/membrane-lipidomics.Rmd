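---
title: "Membrane fatty-acid benchmarking: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane fatty-acid benchmarking: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidbench)
```

## The measurement model

Erythrocyte membrane fatty acids are measured as FAMEs (fatty acid methyl
esters) by gas chromatography after membrane isolation, lipid extraction and
transesterification. The computational pipeline starts where the instrument
stops: an integrated peak-area table per sample, plus calibration-standard
injections of reference compounds for the ten cluster acids.

The detector response for each acid is modelled as a straight line

$$\text{area} = a \cdot \text{conc} + b,$$

fitted by ordinary least squares per acid (`fit_calibration()`). The free
intercept absorbs small baseline offsets; `force_zero_intercept = TRUE`
forces the line through the origin for detectors known to be offset-free.
Sample quantities are the inverse map $(\text{area} - b)/a$ in μg/mL.
Assumptions: response linearity over the working range and identical
response in standards and samples. Curves with $R^2 < 0.995$ are kept but
flagged with a warning (`r_squared_warn`), since a mild misfit biases
quantities but a hard failure should be a human decision.

Quantities are then *closed*: each acid is expressed as a percentage of the
summed cluster quantities, so every profile lies on the 100% simplex. The
closure makes profiles compositional — only relative information survives —
which is the appropriate scale for membrane homeostasis questions and makes
the pipeline invariant to injection volume and total lipid content. Cluster
coverage (cluster area / total chromatogram area) is reported per sample
with a 0.97 pass threshold; failing samples are flagged, never dropped,
because low coverage signals interfering peaks rather than an invalid
composition.

## Derived parameters

From a closed profile, `lipid_panel()` derives ten parameters: the family
totals (SFA, MUFA, omega-3 and omega-6 PUFA, total PUFA), the SFA/MUFA and
omega-6/omega-3 ratios, the PUFA balance $100\,(\text{EPA} +
\text{DHA})/\text{PUFA}$, and two weighted sums over the unsaturated
members:

* unsaturation index, weights 1 (each MUFA), 2, 3, 4, 5, 6 (LA, DGLA, ARA,
  EPA, DHA) — double-bond density, range 0–600;
* peroxidation index, weights 0.025 (each MUFA), 1, 2, 4, 6, 8 —
  oxidizability, range 0–800.

Both are implemented as per-member weighted sums (each MUFA member carries
the lumped family coefficient), which is equivalent to the family-total
formulation because the indexes are linear in the summands. Linearity is
load-bearing: it implies the index of a mean composition equals the mean
index, so published per-sex mean columns are complete worked examples, and
it is asserted as a property test. No alternative index definitions
(double-bond-index variants, anti-inflammatory scores, an SFA/PUFA ratio)
are provided.

All derived values are kept at full precision internally; rounding to two
decimals happens only in CSV serialisation, the reporting precision of this
field's tables.

Degenerate inputs: a profile with zero omega-3 makes the omega-6/omega-3
ratio undefined; at panel level this becomes an `NA` with a warning (so
cohort summaries continue, with per-parameter `n` bookkeeping), while the
low-level `lipid_ratios(..., on_zero = "error")` aborts. Index functions
accept profiles whose percentages sum to 100 ± 0.5 without complaint, so
printed (2-decimal) tables can be analysed as-is; deviations beyond 0.5
warn and beyond 5 abort.

## Reference benchmark

`reference_interval()` reports the raw minimum–maximum interval and median
— the benchmark convention for healthy-cohort membrane profiles — rather
than a clinical-chemistry percentile reference range. Because min and max
are extreme order statistics, they are compared across cohorts by
containment, never by equality. When $n \ge 40$ the nonparametric 2.5–97.5
percentiles (linear interpolation, type-7 quantiles) are added as a
distribution band; we label it a percentile band, not a confidence
interval, since no distributional construction is assumed. Histograms use
Freedman–Diaconis bins by default (robust to the heavy right tails of the
omega-6/omega-3 ratio); the rule is configurable. Medians are not additive
across parameters, so the median of total SFA generally differs from the
sum of member medians — expected behaviour, not an error.

## Cohort statistics

The statistical protocol mirrors how small clinical cohorts are analysed:

* **Normality gate.** The D'Agostino–Pearson omnibus test combines
  standardized skewness and kurtosis into $K^2 = Z_s^2 + Z_k^2 \sim
  \chi^2_2$. It is implemented from the classical z-score transformations
  and verified against an independent reference implementation on frozen
  vectors. The test needs $n \ge 20$; below that the gate reports
  "untestable" and the caller falls back to the nonparametric branch
  (`assume_normal_if_untestable` flips that default). The gate is the sole
  normality decision — graphical checks are not mechanisable.
* **Two-group comparison.** Both groups normal → two-sided unpaired t-test,
  Welch's by default (`pooled_variance = TRUE` restores Student's; Welch is
  the safer default when only "unpaired t-test" is specified). Otherwise
  Mann–Whitney: exact two-sided p by exhaustive enumeration of all
  $\binom{n_a+n_b}{n_a}$ assignments when both groups have ≤ 8 values
  (midranks make it tie-capable; at most 12 870 assignments), else the
  tie-corrected normal approximation with continuity correction. The exact
  path is validated against an independent rank-sum enumeration oracle.
* **Correlation.** Both vectors normal → Pearson, else Spearman; two-sided
  p from the t approximation $t = r\sqrt{(n-2)/(1-r^2)}$ in both branches.
* **Sweep.** `run_study()` applies the comparison (M vs F) and both
  covariate correlations (age, bodyweight) to all 20 parameters at
  α = 0.05 with no multiplicity correction, matching the benchmarking
  protocol; `fdr = TRUE` appends Benjamini–Hochberg adjusted p-values as a
  clearly-separate extension.

Calibration of the gated procedure is part of the test suite: type-I error
at group sizes 30/38 over 1000 null replicates (normal and lognormal) must
stay within [0.03, 0.07], and the gated correlation at $n = 68$ must
recover a true coefficient of 0.4 within 0.03 in the mean over 500
replicates.

## The synthetic cohort generator

No raw per-dog data are published for the reference cohort, so the
generator emulates its reported structure: 68 dogs (30 males, 38 females),
ages 2–156 months with median near 41, bodyweights 2.6–43 kg, the per-sex
composition means and standard deviations of the reference tables, and the
reported covariate correlations (EPA increasing with age; palmitic,
palmitoleic and total SFA increasing and arachidonic acid decreasing with
bodyweight).

**Model.** Compositions follow an additive-logistic-normal law: a latent
Gaussian vector $z \in \mathbb{R}^{10}$ is exponentiated and closed,
$x_i = 100\,e^{z_i}/\sum_j e^{z_j}$. This guarantees positivity and exact
closure and, unlike a Dirichlet, admits a full covariance structure, which
is what lets covariate correlations be injected as linear terms
$z_i = \mu_i + \sigma_i(\rho_i c + \sqrt{1-\rho_i^2}\,\varepsilon_i)$ in
the latent mean ($c$ the standardized covariate).

**Calibration.** The map from latent moments to closed-composition moments
has no closed form, so the generator moment-matches numerically: a fixed
internally-seeded population of 20 000 draws is iterated 15 times, each
iteration nudging the per-sex latent means/scales toward the target
means/sds and each latent $\rho$ toward its target correlation. The result
is cached per spec, so repeated cohort generation pays the (sub-second)
calibration once. A residual correlation misfit above 0.05 aborts as an
infeasible spec.

**Correlation measure.** Injected associations are calibrated against the
Spearman rank correlation (`correlation_measure = "spearman"`), because the
gated protocol routes the right-skewed age and bodyweight covariates to
Spearman — the published coefficients came through the same gate, so
protocol consistency demands the rank measure. `"pearson"` is available for
users who want latent-scale fidelity instead.

**Direction of effects.** Published correlation magnitudes are stored
signed in the default spec, with the negative sign on arachidonic acid
(and, emergently, the omega-6 family, total PUFA, UI and PI) versus
bodyweight. The total-SFA–bodyweight association (target 0.402) is
specified at the family level and realised through the stearic-acid latent
coordinate, since palmitic acid's own target (0.385) does not by itself
reproduce the family value; the remaining family/index correlations are
left to emerge from the linear structure and are checked, not injected.

**Covariates.** Ages and bodyweights are truncated-lognormal: age
`meanlog = log(44)`, `sdlog = 0.85` truncated to [2, 156] months (median
≈ 41 under truncation), bodyweight `meanlog = log(14)`, `sdlog = 0.6`
truncated to [2.6, 43] kg. The sdlog values were chosen once as realistic
right-skew for a mixed-breed clinic population; only the ranges and the age
median are externally constrained. Neuter rates are 12/38 (F) and 6/30 (M).

**Measurement layer.** `make_peak_tables()` inverts the quantitation stage:
true slopes U(5, 50) and intercepts U(0, 2) per acid, five standard levels
spanning one decade centred on the typical per-acid quantity, per-sample
total cluster quantity U(50, 500) μg/mL, 1% relative Gaussian noise on
standard and sample areas (all configurable; the noise levels are generator
conventions, not measured instrument values), and an `"other"` peak keeping
coverage inside [0.975, 0.995]. The noise-free mode is the oracle path: the
round trip simulate → quantify → close reproduces ground truth to machine
precision, which the tests assert at 1e-9.

**What the generator does not emulate.** Breed structure (all records are
"mixed"), diet and supplementation effects, disease states, inter-batch
instrument drift, retention-time errors, and any dependence between the
composition and neuter status. Passing tests therefore validate the
pipeline's arithmetic and its statistical calibration under the stated
population structure — they do not certify performance on real
chromatograms with co-eluting peaks or non-lognormal covariates.

## Problem sizes and determinism

Tests run the generator at $n = 68$ (the reference cohort size), with 60
seeds for mean/correlation recovery in the unit suite, 200 seeds for
recovery and null-calibration checks, 1000 replicates for type-I error, and
one $n = 680$ cohort for tighter mean recovery — sizes chosen so each check
has adequate Monte-Carlo resolution. Every stochastic step is seeded: a
cohort is bit-reproducible from its spec and seed, and the calibration uses
its own fixed internal seed so cached and fresh calibrations agree exactly.
With the default 1% noise, about 98–99% of round-tripped percentage entries
land within 0.5 absolute percentage points of ground truth (the residual
errors concentrate in the largest component, arachidonic acid); the suite
asserts ≥ 97%.

## Known limitations

* The calibration-standard design (5 levels, one decade) is a convention;
  real laboratories may calibrate differently, and the OLS line has no
  weighting for heteroscedastic detector noise.
* The omnibus gate at α = 0.05 per variable is itself a test; its
  routing decisions on borderline data are seed-sensitive near the
  boundary, so per-parameter test choice is not a stable cohort property.
* Min–max interval values are extreme order statistics with high sampling
  variance at n = 68; they should be read as observed ranges, not
  population limits.
* The additive-logistic-normal cannot produce exact zeros; truly absent
  fatty acids would need a zero-inflated extension.
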