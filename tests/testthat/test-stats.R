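# Frozen reference values for the omnibus normality test were computed
# independently (skewness/kurtosis z-score formulation of D'Agostino,
# Anscombe & Glynn) on these exact vectors before the implementation.
ref_normal25 <- c(53.0472, 39.6002, 57.5045, 59.4056, 30.4896, 36.9782,
                  51.2784, 46.8376, 49.832, 41.4696, 58.794, 57.7779,
                  50.6603, 61.2724, 54.6751, 41.4071, 53.6875, 40.4112,
                  58.7845, 49.5007, 48.1514, 43.1907, 62.2254, 48.4547,
                  45.7167)
ref_lognorm30 <- c(2.0509, 4.1614, 3.6414, 3.7817, 3.8369, 15.0792, 1.9638,
                   1.8044, 1.4176, 4.4495, 6.7072, 2.4814, 1.388, 1.4055,
                   4.5744, 4.9264, 4.1976, 1.5961, 3.2731, 2.9843, 3.238,
                   5.4583, 3.2507, 4.6792, 2.8693, 3.4257, 4.5043, 0.8473,
                   2.1049, 1.8658)

test_that("omnibus normality statistic matches frozen reference values", {
  r1 <- dagostino_test(ref_normal25)
  expect_equal(r1$statistic, 0.9537093737, tolerance = 1e-8)
  expect_equal(r1$p_value, 0.6207327234, tolerance = 1e-8)
  expect_equal(r1$z_skew, -0.8980919038, tolerance = 1e-8)
  expect_equal(r1$z_kurt, -0.3835887198, tolerance = 1e-8)
  expect_true(r1$is_normal)

  r2 <- dagostino_test(ref_lognorm30)
  expect_equal(r2$statistic, 44.7704928089, tolerance = 1e-8)
  expect_equal(r2$p_value, 1.897628e-10, tolerance = 1e-5)
  expect_false(r2$is_normal)

  expect_error(dagostino_test(stats::rnorm(10)), "sample too small")
})

test_that("omnibus test holds its size and detects skewed alternatives", {
  withr::with_seed(202, {
    keep_normal <- mean(replicate(200, dagostino_test(stats::rnorm(500))$is_normal))
    flag_exp <- mean(replicate(200, !dagostino_test(stats::rexp(500))$is_normal))
  })
  expect_gte(keep_normal, 0.90)
  expect_gte(flag_exp, 0.99)
})

test_that("exact Mann-Whitney agrees with hand counts and null cases", {
  # identical groups: the observed statistic sits at the centre
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$test_used, "mann_whitney")
  expect_equal(same$p_value, 1.0)
  expect_false(same$significant)

  # complete separation of 3 vs 3: 2 of the 20 assignments are as extreme
  sep <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$p_value, 0.1)
})

test_that("exact Mann-Whitney equals exhaustive rank-sum enumeration", {
  # independent oracle: enumerate every assignment of the pooled sample and
  # compare the two-sided tail of the rank-sum statistic
  oracle_p <- function(a, b) {
    pooled <- c(a, b)
    n_a <- length(a)
    r <- rank(pooled)
    ew <- n_a * (length(pooled) + 1) / 2
    w_obs <- sum(r[seq_len(n_a)])
    ws <- apply(utils::combn(length(pooled), n_a), 2,
                function(idx) sum(r[idx]))
    mean(abs(ws - ew) >= abs(w_obs - ew) - 1e-9)
  }
  withr::with_seed(31, {
    for (i in 1:12) {
      n_a <- sample(3:8, 1)
      n_b <- sample(3:8, 1)
      # integer-valued draws so ties occur frequently
      a <- sample(1:6, n_a, replace = TRUE)
      b <- sample(1:6, n_b, replace = TRUE) + sample(0:1, 1)
      got <- compare_groups(a, b)
      expect_equal(got$test_used, "mann_whitney")
      expect_equal(got$p_value, oracle_p(a, b))
    }
  })
  # tie-free case also agrees with the exact distribution in wilcox.test
  a <- c(1.1, 2.3, 3.7, 5.2)
  b <- c(0.4, 2.9, 4.8, 6.1, 7.3)
  expect_equal(compare_groups(a, b)$p_value,
               stats::wilcox.test(a, b, exact = TRUE)$p.value)
})

test_that("comparison is symmetric in the groups and validates sizes", {
  withr::with_seed(17, {
    a <- stats::rlnorm(24)
    b <- stats::rlnorm(30, 0.3)
  })
  ab <- compare_groups(a, b)
  ba <- compare_groups(b, a)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$test_used, ba$test_used)
  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), "insufficient group")
})

test_that("normality gate routes to t-test for normal groups and
           Mann-Whitney for skewed ones", {
  withr::with_seed(41, {
    norm_a <- stats::rnorm(30)
    norm_b <- stats::rnorm(38, 0.2)
    skew_a <- stats::rexp(30)
    skew_b <- stats::rexp(38)
  })
  expect_equal(compare_groups(norm_a, norm_b)$test_used, "unpaired_t")
  expect_equal(compare_groups(skew_a, skew_b)$test_used, "mann_whitney")
  # pooled-variance option reproduces Student's t
  got <- compare_groups(norm_a, norm_b, pooled_variance = TRUE)
  expect_equal(got$p_value,
               stats::t.test(norm_a, norm_b, var.equal = TRUE)$p.value)
})

test_that("correlation detects exact linearity and monotone invariance", {
  x <- c(1, 3, 4, 6, 8, 9, 11, 14)
  lin <- correlate(x, 2 * x + 1)
  expect_equal(lin$r, 1.0)
  expect_lt(lin$p_value, 1e-12)

  # Spearman is invariant under strictly monotone transforms
  withr::with_seed(53, {
    u <- stats::rlnorm(40)
    v <- u^3 + stats::rlnorm(40, sd = 0.2)
  })
  s1 <- correlate(u, v)
  s2 <- correlate(u^3, exp(v))
  expect_equal(s1$method, "spearman")
  expect_equal(s1$r, s2$r)

  expect_error(correlate(1:3, c(2, 4, 6)), "insufficient pairs")
  expect_error(correlate(rep(1, 10), 1:10), "degenerate correlation")
})

test_that("full study emits 20 comparisons and 40 correlations", {
  cohort <- generate_cohort(small_spec(seed = 12))
  panel <- lipid_panel(cohort$compositions)
  study <- run_study(panel, cohort$metadata)
  expect_s3_class(study, "fa_study")
  comp <- tidy(study, "comparisons")
  corr <- tidy(study, "correlations")
  expect_equal(nrow(comp), 20)
  expect_equal(nrow(corr), 40)
  expect_equal(comp$n_m[1], 30)
  expect_equal(comp$n_f[1], 38)
  expect_true(all(corr$covariate %in% c("age_months", "bodyweight_kg")))
  expect_true(all(comp$significant == (comp$p_value < 0.05)))
  expect_equal(glance(study)$n, 68)
  expect_s3_class(autoplot(study), "ggplot")

  # opt-in BH adjustment appends a column without changing raw p-values
  study_fdr <- run_study(panel, cohort$metadata, fdr = TRUE)
  expect_true("p_adj" %in% names(tidy(study_fdr, "comparisons")))
  expect_equal(tidy(study_fdr, "comparisons")$p_value, comp$p_value)

  bad_meta <- cohort$metadata[-1, ]
  expect_error(run_study(panel, bad_meta), "incomplete metadata")
})
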