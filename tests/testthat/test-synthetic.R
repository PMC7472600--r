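test_that("covariates honour the sex split, ranges and age median", {
  spec <- small_spec(seed = 14)
  meta <- generate_covariates(spec)
  expect_equal(nrow(meta), 68)
  expect_equal(sum(meta$sex == "F"), 38)
  expect_equal(sum(meta$sex == "M"), 30)
  expect_true(all(meta$age_months >= 2 & meta$age_months <= 156))
  expect_true(all(meta$bodyweight_kg >= 2.6 & meta$bodyweight_kg <= 43))

  meds <- purrr::map_dbl(1:60, function(s) {
    stats::median(generate_covariates(small_spec(seed = s))$age_months)
  })
  expect_gt(mean(meds), 41 - 6)
  expect_lt(mean(meds), 41 + 6)
})

test_that("cohorts are deterministic given spec and seed", {
  c1 <- generate_cohort(small_spec(seed = 77))
  c2 <- generate_cohort(small_spec(seed = 77))
  expect_identical(c1$metadata, c2$metadata)
  expect_identical(c1$compositions, c2$compositions)
  expect_identical(c1$standards, c2$standards)
  expect_identical(c1$peaks, c2$peaks)
  c3 <- generate_cohort(small_spec(seed = 78))
  expect_false(identical(c1$compositions, c3$compositions))
})

test_that("compositions close to 100 exactly and stay positive", {
  cohort <- generate_cohort(small_spec(seed = 15))
  pct <- as.matrix(cohort$compositions[fa_codes])
  expect_true(all(pct > 0))
  expect_lt(max(abs(rowSums(pct) - 100)), 1e-9)
})

test_that("per-sex composition targets are recovered in expectation", {
  targets <- default_composition_targets()
  mean_f_ara <- purrr::map_dbl(1:60, function(s) {
    co <- generate_cohort(small_spec(seed = s))
    mean(co$compositions[["C20:4"]][co$metadata$sex == "F"])
  })
  expect_equal(mean(mean_f_ara),
               targets$mean_f[targets$fa_code == "C20:4"],
               tolerance = 1.0 / 34)  # within 1 percentage point of ~34.33

  # full mean vectors of one large cohort stay within 2 sd / sqrt(n)
  big <- cohort_spec(seed = 16, n = 680, n_female = 380)
  co <- generate_cohort(big)
  for (s in c("M", "F")) {
    rows <- co$metadata$sex == s
    mu_hat <- colMeans(as.matrix(co$compositions[rows, fa_codes]))
    tgt <- if (s == "M") targets$mean_m else targets$mean_f
    sd_t <- if (s == "M") targets$sd_m else targets$sd_f
    expect_true(all(abs(mu_hat - tgt) <= 2 * sd_t / sqrt(sum(rows)) + 0.15))
  }
})

test_that("injected covariate correlations are recovered", {
  rs <- purrr::map_dfr(1:60, function(s) {
    co <- generate_cohort(small_spec(seed = s))
    tibble::tibble(
      epa_age = stats::cor(co$compositions[["C20:5"]],
                           co$metadata$age_months, method = "spearman"),
      c16_bw = stats::cor(co$compositions[["C16:0"]],
                          co$metadata$bodyweight_kg, method = "spearman"),
      ara_bw = stats::cor(co$compositions[["C20:4"]],
                          co$metadata$bodyweight_kg, method = "spearman")
    )
  })
  expect_equal(mean(rs$epa_age), 0.396, tolerance = 0.08 / 0.396)
  expect_equal(mean(rs$c16_bw), 0.385, tolerance = 0.08 / 0.385)
  expect_equal(mean(rs$ara_bw), -0.257, tolerance = 0.08 / 0.257)
})

test_that("zero sex effect yields null-calibrated group comparisons", {
  targets <- default_composition_targets()
  pooled <- targets
  pooled$mean_m <- pooled$mean_f <- (30 * targets$mean_m +
                                       38 * targets$mean_f) / 68
  pooled$sd_m <- pooled$sd_f <- (30 * targets$sd_m + 38 * targets$sd_f) / 68
  null_rej <- purrr::map_lgl(1:200, function(s) {
    spec <- cohort_spec(seed = s, composition_targets = pooled)
    co <- generate_cohort(spec)
    ara <- co$compositions[["C20:4"]]
    compare_groups(ara[co$metadata$sex == "M"],
                   ara[co$metadata$sex == "F"])$significant
  })
  expect_gte(mean(null_rej), 0.01)
  expect_lte(mean(null_rej), 0.10)
})

test_that("noisy peak tables still round-trip within half a percentage point", {
  n_entries <- 0
  n_close <- 0
  for (s in 1:10) {
    co <- generate_cohort(small_spec(seed = s))
    prof <- quantify_samples(co$peaks, co$standards)
    err <- abs(as.matrix(prof[fa_codes]) -
                 as.matrix(co$compositions[fa_codes]))
    n_entries <- n_entries + length(err)
    n_close <- n_close + sum(err < 0.5)
  }
  expect_gte(n_close / n_entries, 0.97)
})

test_that("infeasible specs are rejected", {
  expect_error(cohort_spec(n = 10, n_female = 12), "infeasible spec")
  bad_targets <- default_composition_targets()
  bad_targets$mean_m[1] <- -1
  expect_error(cohort_spec(composition_targets = bad_targets),
               "infeasible spec")
  dup_corr <- dplyr::bind_rows(default_covariate_correlations(),
                               tibble::tibble(measure = "C20:5",
                                              inject_on = "C20:5",
                                              covariate = "bodyweight_kg",
                                              target_r = 0.9))
  expect_error(cohort_spec(covariate_correlations = dup_corr),
               "infeasible spec")
  unreachable <- tibble::tibble(measure = "C20:5", inject_on = "C20:5",
                                covariate = "age_months", target_r = 0.999)
  spec <- cohort_spec(seed = 1, covariate_correlations = unreachable,
                      calib_n = 4000, calib_iter = 6)
  expect_error(generate_cohort(spec), "infeasible spec")
})
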