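test_that("family totals reproduce the published per-sex sums", {
  prof_m <- make_profile(printed_means$m, "m")
  prof_f <- make_profile(printed_means$f, "f")
  tm <- family_totals(prof_m)
  tf <- family_totals(prof_f)
  expect_equal(tm$total_sfa, 35.50, tolerance = 0.011)
  expect_equal(tm$total_mufa, 12.35, tolerance = 0.011)
  expect_equal(tf$total_mufa, 11.92, tolerance = 0.011)
  expect_equal(tf$pufa_n6, 49.72, tolerance = 0.011)
  uniform <- family_totals(make_profile(rep(10, 10)))
  expect_equal(unlist(uniform[c("total_sfa", "total_mufa", "pufa_n3",
                                "pufa_n6", "total_pufa")]),
               c(total_sfa = 20, total_mufa = 30, pufa_n3 = 20,
                 pufa_n6 = 30, total_pufa = 50))
})

test_that("ratios and PUFA balance follow their definitions", {
  tot <- tibble::tibble(sample_id = "x", total_sfa = 36.47,
                        total_mufa = 11.92, pufa_n3 = 1.90,
                        pufa_n6 = 49.72, total_pufa = 51.62)
  r <- lipid_ratios(tot)
  expect_equal(r$n6_n3_ratio, 49.72 / 1.90)  # ~26.168
  expect_equal(r$sfa_mufa_ratio, 36.47 / 11.92)
  tot2 <- tot |> dplyr::mutate(pufa_n3 = 2, total_pufa = 50)
  expect_equal(lipid_ratios(tot2)$pufa_balance, 4.0)
  tot3 <- tot |> dplyr::mutate(pufa_n3 = 0)
  expect_error(lipid_ratios(tot3, on_zero = "error"),
               "undefined ratio: omega-6/omega-3")
  expect_warning(r3 <- lipid_ratios(tot3), "undefined ratio")
  expect_true(is.na(r3$n6_n3_ratio))
})

test_that("unsaturation and peroxidation indexes match the weighted sums", {
  prof_f <- make_profile(printed_means$f, "f")
  expect_equal(unsaturation_index(prof_f), 192.00, tolerance = 1e-10)
  expect_equal(peroxidation_index(prof_f), 168.09, tolerance = 0.005)

  all_sfa <- make_profile(c(100, 0, 0, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(unsaturation_index(all_sfa), 0)
  expect_equal(peroxidation_index(all_sfa), 0)
  all_dha <- make_profile(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 100))
  expect_equal(unsaturation_index(all_dha), 600)
  expect_equal(peroxidation_index(all_dha), 800)

  # uniform profile: hand expansion of the footnote formulas at 10% each
  uniform <- make_profile(rep(10, 10))
  expect_equal(unsaturation_index(uniform),
               30 * 1 + 10 * 2 + 10 * 3 + 10 * 4 + 10 * 5 + 10 * 6)  # 230
  expect_equal(peroxidation_index(uniform),
               30 * 0.025 + 10 + 20 + 40 + 60 + 80)  # 210.75
})

test_that("full panel aggregates and flags undefined ratios as missing", {
  prof_m <- make_profile(printed_means$m, "m")
  pan <- lipid_panel(prof_m)
  expect_equal(pan$total_pufa, 52.15, tolerance = 0.011)
  no_n3 <- make_profile(c(20, 5, 20, 10, 5, 20, 5, 15, 0, 0))
  pan2 <- suppressWarnings(lipid_panel(no_n3))
  expect_true(is.na(pan2$n6_n3_ratio))
  expect_false(is.na(pan2$pufa_balance))  # total PUFA is positive here
  expect_equal(pan2$pufa_balance, 0)
})

test_that("indexes are linear, monotone in desaturation, and conserve closure", {
  a <- random_profiles(8, seed = 21)
  b <- random_profiles(8, seed = 22)
  for (lam in c(0, 0.3, 0.7, 1)) {
    mix <- a
    mix[fa_codes] <- lam * a[fa_codes] + (1 - lam) * b[fa_codes]
    expect_equal(unsaturation_index(mix),
                 lam * unsaturation_index(a) +
                   (1 - lam) * unsaturation_index(b))
    expect_equal(peroxidation_index(mix),
                 lam * peroxidation_index(a) +
                   (1 - lam) * peroxidation_index(b))
    expect_equal(family_totals(mix)$total_sfa,
                 lam * family_totals(a)$total_sfa +
                   (1 - lam) * family_totals(b)$total_sfa)
  }

  # moving mass from a saturated member to DHA strictly raises UI and PI
  delta <- pmin(1, a[["C16:0"]] / 2)
  shifted <- a
  shifted[["C16:0"]] <- a[["C16:0"]] - delta
  shifted[["C22:6"]] <- a[["C22:6"]] + delta
  expect_true(all(unsaturation_index(shifted) > unsaturation_index(a)))
  expect_true(all(peroxidation_index(shifted) > peroxidation_index(a)))

  tot <- family_totals(a)
  expect_equal(tot$total_sfa + tot$total_mufa + tot$total_pufa,
               rep(100, nrow(a)), tolerance = 1e-9)
  expect_equal(tot$total_pufa, tot$pufa_n3 + tot$pufa_n6, tolerance = 1e-9)
})

test_that("cohort mean of UI equals UI of the mean composition", {
  profs <- random_profiles(40, seed = 33)
  mean_prof <- make_profile(colMeans(as.matrix(profs[fa_codes])))
  expect_equal(mean(unsaturation_index(profs)),
               unsaturation_index(mean_prof))
  expect_equal(mean(peroxidation_index(profs)),
               peroxidation_index(mean_prof))
})
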