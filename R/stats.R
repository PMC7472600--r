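# Cohort statistics: omnibus normality test, normality-gated two-group
# comparison (Welch t vs Mann-Whitney), normality-gated correlation
# (Pearson vs Spearman), and the full study sweep over the 20 benchmark
# parameters.

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the standardized sample skewness and kurtosis into the omnibus
#' statistic `K2 = Z_skew^2 + Z_kurt^2`, distributed approximately chi-squared
#' with 2 degrees of freedom under normality. The skewness transformation is
#' D'Agostino's (1970) and the kurtosis transformation Anscombe and Glynn's
#' (1983), as in standard implementations of the omnibus test.
#'
#' @param values Numeric vector, at least 20 non-missing values (below that
#'   the chi-squared approximation is unreliable and the caller should fall
#'   back to a nonparametric procedure).
#' @param alpha Significance level for the `is_normal` verdict, default 0.05.
#' @return One-row tibble: `n`, `z_skew`, `z_kurt`, `statistic` (K2),
#'   `p_value`, `is_normal`.
#' @export
dagostino_test <- function(values, alpha = 0.05) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 20) {
    rlang::abort("sample too small for omnibus test: need n >= 20")
  }
  if (stats::sd(x) == 0) {
    rlang::abort("degenerate sample: zero variance")
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)

  # skewness z-score
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha_s <- sqrt(2 / (w2 - 1))
  z_skew <- delta * log(y / alpha_s + sqrt((y / alpha_s)^2 + 1))

  # kurtosis z-score
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqrt_b1_b2 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_b1_b2 *
    (2 / sqrt_b1_b2 + sqrt(1 + 4 / sqrt_b1_b2^2))
  z_kurt <- ((1 - 2 / (9 * a)) -
               ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z_skew^2 + z_kurt^2
  p <- stats::pchisq(k2, df = 2, lower.tail = FALSE)
  tibble::tibble(n = n, z_skew = z_skew, z_kurt = z_kurt,
                 statistic = k2, p_value = p, is_normal = p >= alpha)
}

# Is this sample compatible with normality at the gate level? NA when the
# omnibus test is not applicable (n < 20).
gate_normal <- function(values, alpha = 0.05) {
  x <- values[!is.na(values)]
  if (length(x) < 20 || stats::sd(x) == 0) return(NA)
  dagostino_test(x, alpha = alpha)$is_normal
}

# Exact two-sided Mann-Whitney p-value by exhaustive enumeration of all
# assignments of the pooled observations to the two groups. Handles ties
# through midranks. Feasible for small groups only (both n <= 8 by default
# in compare_groups).
mann_whitney_exact <- function(a, b) {
  n_a <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n_a * (n_a + 1) / 2
  u_obs <- u_of(seq_len(n_a))
  centre <- n_a * length(b) / 2
  combos <- utils::combn(length(pooled), n_a)
  u_all <- apply(combos, 2, u_of)
  eps <- 1e-9
  p <- mean(abs(u_all - centre) >= abs(u_obs - centre) - eps)
  list(statistic = u_obs, p_value = p)
}

#' Two-group comparison with a normality gate
#'
#' Compares two independent groups the way a distribution-gated protocol
#' does: when both groups pass the D'Agostino-Pearson omnibus test (and are
#' large enough for it, n >= 20), a two-sided unpaired t-test is used
#' (Welch's by default); otherwise a two-sided Mann-Whitney test, computed by
#' exhaustive enumeration when both groups have at most `exact_max` values
#' and by the tie-corrected normal approximation otherwise.
#'
#' @param values_a,values_b Numeric vectors, each with at least 3 non-missing
#'   values.
#' @param alpha Significance level, default 0.05.
#' @param pooled_variance Use the pooled-variance (Student) t-test instead of
#'   Welch's, default `FALSE`.
#' @param exact_max Largest group size for the exact Mann-Whitney path,
#'   default 8.
#' @param assume_normal_if_untestable When the gate cannot run (a group
#'   smaller than 20), treat the data as normal and use the t-test anyway;
#'   default `FALSE` (nonparametric fallback).
#' @return One-row tibble: per-group `n`, `mean`, `sd`, then `test_used`
#'   (`"unpaired_t"` or `"mann_whitney"`), `statistic`, `p_value`,
#'   `significant`.
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))
#' @export
compare_groups <- function(values_a, values_b, alpha = 0.05,
                           pooled_variance = FALSE, exact_max = 8,
                           assume_normal_if_untestable = FALSE) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) < 3 || length(b) < 3) {
    rlang::abort("insufficient group: need at least 3 values per group")
  }
  gates <- c(gate_normal(a, alpha), gate_normal(b, alpha))
  both_normal <- if (any(is.na(gates))) assume_normal_if_untestable else
    all(gates)

  if (both_normal) {
    ht <- stats::t.test(a, b, var.equal = pooled_variance)
    test_used <- "unpaired_t"
    statistic <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    test_used <- "mann_whitney"
    if (length(a) <= exact_max && length(b) <= exact_max) {
      mw <- mann_whitney_exact(a, b)
      statistic <- mw$statistic
      p <- mw$p_value
    } else {
      ht <- suppressWarnings(
        stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
      )
      statistic <- unname(ht$statistic)
      p <- ht$p.value
    }
  }
  tibble::tibble(
    n_a = length(a), mean_a = mean(a), sd_a = stats::sd(a),
    n_b = length(b), mean_b = mean(b), sd_b = stats::sd(b),
    test_used = test_used, statistic = statistic,
    p_value = p, significant = p < alpha
  )
}

#' Correlation with a normality gate
#'
#' Pearson correlation when both vectors pass the omnibus normality test
#' (and are large enough for it), Spearman rank correlation otherwise. The
#' two-sided p-value uses the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom for
#' both methods.
#'
#' @param parameter_values,covariate_values Paired numeric vectors, at least
#'   5 complete pairs; neither may be constant.
#' @param alpha Significance level, default 0.05.
#' @return One-row tibble: `method` (`"pearson"` or `"spearman"`), `n`, `r`,
#'   `p_value`, `significant`.
#' @examples
#' correlate(1:10, 2 * (1:10) + 1)
#' @export
correlate <- function(parameter_values, covariate_values, alpha = 0.05) {
  ok <- stats::complete.cases(parameter_values, covariate_values)
  x <- parameter_values[ok]
  y <- covariate_values[ok]
  n <- length(x)
  if (n < 5) rlang::abort("insufficient pairs: need n >= 5")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("degenerate correlation: constant input vector")
  }
  gates <- c(gate_normal(x, alpha), gate_normal(y, alpha))
  method <- if (!any(is.na(gates)) && all(gates)) "pearson" else "spearman"
  r <- stats::cor(x, y, method = method)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  tibble::tibble(method = method, n = n, r = r, p_value = p,
                 significant = p < alpha)
}

#' Full cohort study: sex comparison and covariate correlations
#'
#' Runs the whole statistical protocol over the 20 benchmark parameters
#' (10 fatty-acid percentages + 10 derived): a normality-gated male-female
#' comparison per parameter, and normality-gated correlations of each
#' parameter with age and bodyweight. No multiplicity correction is applied
#' by default (each test is read at `alpha`); `fdr = TRUE` appends
#' Benjamini-Hochberg adjusted p-values as an extension.
#'
#' @param panel Panel tibble from [lipid_panel()] (percentages kept).
#' @param metadata Tibble with `sample_id`, `sex` (`"M"`/`"F"`),
#'   `age_months`, `bodyweight_kg` (and optionally `neutered`, `breed`)
#'   covering every sample in `panel`.
#' @param alpha Significance level, default 0.05.
#' @param pooled_variance Passed to [compare_groups()].
#' @param fdr Append `p_adj` (Benjamini-Hochberg) columns, default `FALSE`.
#' @param registry Fatty-acid registry.
#' @return An object of class `fa_study`: a list with tibbles `comparisons`
#'   (one row per parameter) and `correlations` (one row per parameter x
#'   covariate), plus `alpha` and group sizes. Use [tidy()] / [glance()] /
#'   [autoplot()] on it.
#' @export
run_study <- function(panel, metadata, alpha = 0.05,
                      pooled_variance = FALSE, fdr = FALSE,
                      registry = fa_cluster()) {
  panel <- tibble::as_tibble(panel)
  metadata <- tibble::as_tibble(metadata)
  missing_meta <- setdiff(panel$sample_id, metadata$sample_id)
  if (length(missing_meta) > 0 || any(is.na(metadata$sex))) {
    rlang::abort("incomplete metadata: sex missing for some samples")
  }
  if (!all(metadata$sex %in% c("M", "F"))) {
    rlang::abort("incomplete metadata: sex must be 'M' or 'F'")
  }
  dat <- dplyr::inner_join(panel, metadata, by = "sample_id")
  params <- benchmark_parameters(registry)

  comparisons <- purrr::map_dfr(params, function(p) {
    dplyr::bind_cols(
      tibble::tibble(parameter = p),
      compare_groups(dat[[p]][dat$sex == "M"], dat[[p]][dat$sex == "F"],
                     alpha = alpha, pooled_variance = pooled_variance)
    )
  }) |>
    dplyr::rename(n_m = "n_a", mean_m = "mean_a", sd_m = "sd_a",
                  n_f = "n_b", mean_f = "mean_b", sd_f = "sd_b")

  correlations <- purrr::map_dfr(params, function(p) {
    purrr::map_dfr(c("age_months", "bodyweight_kg"), function(cv) {
      dplyr::bind_cols(
        tibble::tibble(parameter = p, covariate = cv),
        correlate(dat[[p]], dat[[cv]], alpha = alpha)
      )
    })
  })

  if (fdr) {
    comparisons$p_adj <- stats::p.adjust(comparisons$p_value, "BH")
    correlations$p_adj <- stats::p.adjust(correlations$p_value, "BH")
  }

  structure(
    list(comparisons = comparisons, correlations = correlations,
         alpha = alpha, n = nrow(dat),
         n_m = sum(dat$sex == "M"), n_f = sum(dat$sex == "F")),
    class = "fa_study"
  )
}

#' @export
print.fa_study <- function(x, ...) {
  cat("Membrane fatty-acid cohort study\n")
  cat(sprintf("  samples: %d (%d M / %d F), alpha = %g\n",
              x$n, x$n_m, x$n_f, x$alpha))
  cat(sprintf("  comparisons: %d parameters, %d significant\n",
              nrow(x$comparisons), sum(x$comparisons$significant)))
  cat(sprintf("  correlations: %d tests, %d significant\n",
              nrow(x$correlations), sum(x$correlations$significant)))
  invisible(x)
}

#' Tidy a cohort study
#'
#' @param x An `fa_study` from [run_study()].
#' @param type `"comparisons"` (default) or `"correlations"`.
#' @param ... Unused.
#' @return The requested result tibble.
#' @export
tidy.fa_study <- function(x, type = c("comparisons", "correlations"), ...) {
  type <- match.arg(type)
  x[[type]]
}

#' @export
glance.fa_study <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_m = x$n_m, n_f = x$n_f, alpha = x$alpha,
    sig_comparisons = sum(x$comparisons$significant),
    sig_correlations = sum(x$correlations$significant)
  )
}

#' Plot study correlations
#'
#' Dot plot of the signed correlation coefficients per parameter and
#' covariate, with significant correlations highlighted.
#'
#' @param object An `fa_study` from [run_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fa_study <- function(object, ...) {
  dat <- object$correlations |>
    dplyr::mutate(parameter = factor(.data$parameter,
                                     levels = rev(unique(.data$parameter))))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$r, y = .data$parameter,
                                    colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~covariate) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "red3")) +
    ggplot2::labs(x = "correlation (signed r)", y = NULL)
}
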