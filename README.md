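# lipidbench

Fatty-acid-based erythrocyte membrane lipidomics for cohort benchmarking,
built around gas-chromatography FAME (fatty acid methyl ester) analysis of
membrane glycerophospholipids. The package targets veterinary and clinical
lipidomics groups who quantify a fixed 10-fatty-acid membrane cluster —
palmitic (C16:0), palmitoleic (C16:1), stearic (C18:0), oleic (9c-C18:1),
cis-vaccenic (11c-C18:1), linoleic (LA), dihomo-gamma-linolenic (DGLA),
arachidonic (ARA), eicosapentaenoic (EPA) and docosahexaenoic (DHA) acids —
and want reproducible reference intervals and cohort statistics for healthy
populations.

## What it computes

Starting from integrated GC peak-area tables and calibration standards:

1. **Quantitation** — per-acid OLS calibration lines `area = a·conc + b`,
   back-calculation of μg/mL quantities, closure of the cluster to relative
   percentages (Σ = 100%), and a ≥ 97% cluster-coverage check.
2. **Lipid indexes** — family totals (SFA, MUFA, omega-3/omega-6 PUFA,
   total PUFA), SFA/MUFA and omega-6/omega-3 ratios, the PUFA balance
   `100·(EPA + DHA)/PUFA`, and the two weighted indexes

   UI = %MUFA·1 + %LA·2 + %DGLA·3 + %ARA·4 + %EPA·5 + %DHA·6

   PI = %MUFA·0.025 + %LA·1 + %DGLA·2 + %ARA·4 + %EPA·6 + %DHA·8

3. **Reference benchmark** — per-parameter min–max interval, median, and
   (for n ≥ 40) nonparametric 2.5–97.5 percentiles, with distribution
   histograms (`autoplot()`).
4. **Cohort statistics** — D'Agostino–Pearson-gated two-group comparison
   (Welch t or Mann–Whitney, exact enumeration for small groups) and gated
   Pearson/Spearman correlations against age and bodyweight, at α = 0.05
   with no multiplicity correction (Benjamini–Hochberg available opt-in).
5. **Synthetic cohorts** — an additive-logistic-normal generator calibrated
   to the published per-sex composition means/sds and covariate correlations
   of a 68-dog healthy reference cohort, so the full pipeline can be
   exercised and validated without raw study data.

## Worked example

The published female mean composition, analysed as a single profile:

```r
library(lipidbench)

profile <- tibble::tibble(
  sample_id = "dog001",
  `C16:0` = 15.38, `C16:1` = 0.24, `C18:0` = 21.09, `9c-C18:1` = 9.62,
  `11c-C18:1` = 2.06, `C18:2` = 14.11, `C20:3` = 1.28, `C20:4` = 34.33,
  `C20:5` = 0.70, `C22:6` = 1.20
)
round(lipid_panel(profile, keep_percentages = FALSE)[-1], 2)
#>   total_sfa total_mufa pufa_n3 pufa_n6 total_pufa sfa_mufa_ratio n6_n3_ratio
#> 1     36.47      11.92     1.9   49.72      51.62           3.06       26.17
#>   pufa_balance unsaturation_index peroxidation_index
#> 1         3.68                192             168.09
```

Total SFA 36.47% and total PUFA 51.62% describe the saturated/unsaturated
balance of the membrane; the omega-6/omega-3 ratio of 26.2 reflects the
naturally omega-6-dominated dog lipidome; UI = 192.00 and PI = 168.09
summarise double-bond content and oxidizability. Because UI and PI are
linear in the percentages, feeding a cohort's mean composition reproduces
the cohort's mean index exactly.

A full synthetic cohort through the whole pipeline:

```r
cohort <- generate_cohort(cohort_spec(seed = 1))   # 68 dogs, 30 M / 38 F
panel  <- lipid_panel(cohort$compositions)
bench  <- summarize_cohort(panel)                  # 20-parameter benchmark
study  <- run_study(panel, cohort$metadata)
study
#> Membrane fatty-acid cohort study
#>   samples: 68 (30 M / 38 F), alpha = 0.05
#>   comparisons: 20 parameters, 5 significant
#>   correlations: 40 tests, 1 significant
dplyr::filter(tidy(study, "correlations"), parameter == "C20:5")
#> # A tibble: 2 × 7
#>   parameter covariate     method       n      r p_value significant
#>   <chr>     <chr>         <chr>    <int>  <dbl>   <dbl> <lgl>
#> 1 C20:5     age_months    spearman    68 0.379  0.00143 TRUE
#> 2 C20:5     bodyweight_kg spearman    68 0.0741 0.548   FALSE
```

The single significant correlation is the injected EPA–age association; its
rank-based estimate (r = 0.38 in this cohort) recovers the generator's
target. `autoplot(bench, panel)` draws the 20 distribution histograms with
min/max (black) and median (green) annotations; `autoplot(study)` plots the
signed correlation coefficients.

`run_pipeline(out_dir, cohort_spec(seed = 1))` chains simulate → quantify →
profile → benchmark → compare/correlate and writes every artifact as CSV.

## Vignette

`vignettes/membrane-lipidomics.Rmd` documents the model and its
assumptions, every tunable parameter with units and defaults, the
calibration of the synthetic generator, numerical choices, and known
limitations.
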