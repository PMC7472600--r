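# Synthetic healthy-dog cohort generator.
#
# Compositions are drawn from an additive-logistic-normal model: a latent
# Gaussian vector per sample (one coordinate per fatty acid) is exponentiated
# and closed to 100%, which guarantees positivity and exact closure while
# permitting a full covariance structure. Latent means/scales are calibrated
# numerically (moment matching against the per-sex target means and standard
# deviations) and covariate correlations are injected as linear terms in the
# latent mean, calibrated against the realized Pearson correlations.

#' Per-sex composition targets of the reference healthy-dog cohort
#'
#' The default generator targets: mean and standard deviation of each
#' fatty-acid percentage, separately for males and females, as published for
#' a 68-dog healthy reference cohort (30 males, 38 females). Mean vectors are
#' rescaled to close exactly to 100 at load.
#'
#' @return Tibble `fa_code`, `mean_m`, `sd_m`, `mean_f`, `sd_f`.
#' @export
default_composition_targets <- function() {
  t <- tibble::tibble(
    fa_code = fa_cluster()$code,
    mean_m = c(15.88, 0.35, 19.62, 10.07, 1.93, 15.29, 1.36, 33.65, 0.76, 1.10),
    sd_m   = c(3.52, 0.27, 2.45, 3.31, 0.35, 2.65, 0.35, 7.06, 0.39, 0.61),
    mean_f = c(15.38, 0.24, 21.09, 9.62, 2.06, 14.11, 1.28, 34.33, 0.70, 1.20),
    sd_f   = c(3.53, 0.10, 2.23, 1.85, 0.33, 1.84, 0.39, 5.25, 0.32, 0.67)
  )
  for (col in c("mean_m", "mean_f")) {
    s <- sum(t[[col]])
    if (abs(s - 100) > 0.5) {
      rlang::abort("infeasible spec: target means must close to 100 +/- 0.5")
    }
    t[[col]] <- t[[col]] * 100 / s
  }
  t
}

#' Default covariate correlation targets
#'
#' Signed correlations injected between fatty-acid percentages and the two
#' cohort covariates, matching the associations reported for the reference
#' cohort: EPA increases with age; palmitic and palmitoleic acid increase and
#' arachidonic acid decreases with bodyweight. The reported positive
#' bodyweight correlation of total SFA is targeted at the family level and
#' realised through the stearic-acid coordinate, since total SFA is the sum
#' of the palmitic and stearic percentages.
#'
#' @return Tibble `measure` (fatty-acid code or family total), `inject_on`
#'   (latent coordinate carrying the term), `covariate`, `target_r`.
#' @export
default_covariate_correlations <- function() {
  tibble::tribble(
    ~measure,    ~inject_on, ~covariate,      ~target_r,
    "C20:5",     "C20:5",    "age_months",     0.396,
    "C16:0",     "C16:0",    "bodyweight_kg",  0.385,
    "C16:1",     "C16:1",    "bodyweight_kg",  0.326,
    "C20:4",     "C20:4",    "bodyweight_kg", -0.257,
    "total_sfa", "C18:0",    "bodyweight_kg",  0.402
  )
}

#' Synthetic cohort specification
#'
#' Bundles every generator parameter: cohort size and sex split, covariate
#' distributions, per-sex composition targets, covariate correlation targets,
#' and the measurement-noise model for standards and peak areas. Defaults
#' emulate the reference healthy-dog cohort: 68 dogs (30 M / 38 F), ages 2 to
#' 156 months with median near 41, bodyweights 2.6 to 43 kg.
#'
#' @param n Cohort size, default 68.
#' @param n_female Number of females, default 38.
#' @param seed Integer seed; the whole cohort is deterministic given the spec
#'   and this seed.
#' @param age_range_months,bodyweight_range_kg Truncation ranges of the
#'   right-skewed (lognormal) covariate distributions.
#' @param age_meanlog,age_sdlog,bw_meanlog,bw_sdlog Lognormal parameters
#'   before truncation. The age defaults put the truncated median near 41
#'   months.
#' @param composition_targets Per-sex target means/sds, default
#'   [default_composition_targets()].
#' @param covariate_correlations Correlation targets, default
#'   [default_covariate_correlations()].
#' @param standards_rel_sd,area_rel_sd Relative (multiplicative) Gaussian
#'   noise on calibration-standard and sample peak areas, default 1% each.
#' @param total_lipid_range_ug_ml Range of the per-sample total cluster
#'   quantity, default 50-500 ug/mL.
#' @param coverage_range Range of the simulated cluster coverage fraction,
#'   default 0.975-0.995 (every sample passes the 97% check).
#' @param calib_n,calib_iter Monte-Carlo size and iteration count of the
#'   internal moment-matching calibration.
#' @param correlation_measure Correlation estimator the injected covariate
#'   associations are calibrated against: `"spearman"` (default) or
#'   `"pearson"`. The default matches the distribution-gated protocol of
#'   [correlate()], which routes right-skewed covariates such as age and
#'   bodyweight to the rank correlation.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 68, n_female = 38, seed = 1,
                        age_range_months = c(2, 156),
                        bodyweight_range_kg = c(2.6, 43),
                        age_meanlog = log(44), age_sdlog = 0.85,
                        bw_meanlog = log(14), bw_sdlog = 0.6,
                        composition_targets = default_composition_targets(),
                        covariate_correlations =
                          default_covariate_correlations(),
                        standards_rel_sd = 0.01, area_rel_sd = 0.01,
                        total_lipid_range_ug_ml = c(50, 500),
                        coverage_range = c(0.975, 0.995),
                        calib_n = 20000, calib_iter = 15,
                        correlation_measure = c("spearman", "pearson")) {
  correlation_measure <- match.arg(correlation_measure)
  if (n_female < 0 || n_female > n) {
    rlang::abort("infeasible spec: n_female must lie in [0, n]")
  }
  targets <- tibble::as_tibble(composition_targets)
  if (any(targets$mean_m <= 0) || any(targets$mean_f <= 0)) {
    rlang::abort("infeasible spec: target means must be positive")
  }
  corr <- tibble::as_tibble(covariate_correlations)
  if (nrow(corr) > 0 && anyDuplicated(corr$inject_on)) {
    rlang::abort("infeasible spec: one covariate term per latent coordinate")
  }
  structure(
    list(n = n, n_female = n_female, seed = seed,
         age_range_months = age_range_months,
         bodyweight_range_kg = bodyweight_range_kg,
         age_meanlog = age_meanlog, age_sdlog = age_sdlog,
         bw_meanlog = bw_meanlog, bw_sdlog = bw_sdlog,
         composition_targets = targets,
         covariate_correlations = corr,
         standards_rel_sd = standards_rel_sd, area_rel_sd = area_rel_sd,
         total_lipid_range_ug_ml = total_lipid_range_ug_ml,
         coverage_range = coverage_range,
         calib_n = calib_n, calib_iter = calib_iter,
         correlation_measure = correlation_measure),
    class = "cohort_spec"
  )
}

# Truncated lognormal sampler (inverse-CDF).
rtrunc_lnorm <- function(n, meanlog, sdlog, lower, upper) {
  lo <- stats::plnorm(lower, meanlog, sdlog)
  hi <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, lo, hi), meanlog, sdlog)
}

maybe_with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

#' Generate cohort covariates
#'
#' Draws the dog records of a synthetic cohort: the exact sex split of the
#' spec (in randomised order), ages from a truncated lognormal over the
#' stated range (median near 41 months under the defaults), bodyweights from
#' a truncated lognormal over the stated range, and neuter status at the
#' reference cohort's per-sex rates.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return Tibble `sample_id`, `sex`, `neutered`, `age_months`,
#'   `bodyweight_kg`, `breed`.
#' @export
generate_covariates <- function(spec, seed = spec$seed) {
  maybe_with_seed(seed, {
    sex <- sample(c(rep("F", spec$n_female), rep("M", spec$n - spec$n_female)))
    neut_p <- ifelse(sex == "F", 12 / 38, 6 / 30)
    tibble::tibble(
      sample_id = sprintf("dog%03d", seq_len(spec$n)),
      sex = sex,
      neutered = stats::runif(spec$n) < neut_p,
      age_months = rtrunc_lnorm(spec$n, spec$age_meanlog, spec$age_sdlog,
                                spec$age_range_months[1],
                                spec$age_range_months[2]),
      bodyweight_kg = rtrunc_lnorm(spec$n, spec$bw_meanlog, spec$bw_sdlog,
                                   spec$bodyweight_range_kg[1],
                                   spec$bodyweight_range_kg[2]),
      breed = "mixed"
    )
  })
}

# Resolve a correlation-target measure to a column of the closed composition
# matrix: a fatty-acid code, or a family total (sum of member codes).
measure_matrix <- function(x_pct, measure, registry = fa_cluster()) {
  if (measure %in% registry$code) return(x_pct[, measure])
  fam_codes <- switch(
    measure,
    total_sfa  = registry$code[registry$family == "SFA"],
    total_mufa = registry$code[registry$family == "MUFA"],
    pufa_n3    = registry$code[registry$family == "PUFA_n3"],
    pufa_n6    = registry$code[registry$family == "PUFA_n6"],
    total_pufa = registry$code[registry$family %in% c("PUFA_n3", "PUFA_n6")],
    rlang::abort(paste0("infeasible spec: unknown correlation measure ",
                        measure))
  )
  rowSums(x_pct[, fam_codes, drop = FALSE])
}

# Draw latent coordinates and close them to percentages.
# mu, sig: n x 10 matrices; cterm: n x 10 matrix of standardized covariate
# values scaled by rho; eps: n x 10 standard normals.
close_latent <- function(mu, sig, rho_mat, cstd_mat, eps, codes) {
  z <- mu + sig * (rho_mat * cstd_mat + sqrt(1 - rho_mat^2) * eps)
  g <- exp(z)
  x <- 100 * g / rowSums(g)
  colnames(x) <- codes
  x
}

# Assemble the per-sample mu/sig/rho/cstd matrices for a set of covariates.
latent_inputs <- function(calib, sex, age, bw, registry = fa_cluster()) {
  n <- length(sex)
  k <- nrow(registry)
  is_f <- sex == "F"
  mu <- matrix(rep(calib$mu_m, each = n), n, k)
  sig <- matrix(rep(calib$sig_m, each = n), n, k)
  mu[is_f, ] <- matrix(rep(calib$mu_f, each = sum(is_f)), sum(is_f), k)
  sig[is_f, ] <- matrix(rep(calib$sig_f, each = sum(is_f)), sum(is_f), k)
  rho_mat <- matrix(0, n, k)
  cstd_mat <- matrix(0, n, k)
  std <- function(v) (v - mean(v)) / stats::sd(v)
  cov_std <- list(age_months = std(age), bodyweight_kg = std(bw))
  corr <- calib$corr
  for (i in seq_len(nrow(corr))) {
    j <- match(corr$inject_on[i], registry$code)
    rho_mat[, j] <- corr$rho[i]
    cstd_mat[, j] <- cov_std[[corr$covariate[i]]]
  }
  list(mu = mu, sig = sig, rho_mat = rho_mat, cstd_mat = cstd_mat)
}

# Calibration cache: latent parameters are a deterministic function of the
# spec (minus its seed), so they are computed once and reused.
.calib_cache <- new.env(parent = emptyenv())

# Moment-matching calibration of the additive-logistic-normal model.
# Iteratively adjusts the per-sex latent means/scales toward the target
# composition means/sds and the latent correlation coefficients toward the
# target covariate correlations, measured on a large simulated population
# under a fixed internal seed.
calibrate_spec <- function(spec, registry = fa_cluster()) {
  key <- rlang::hash(list(spec$composition_targets,
                          spec$covariate_correlations,
                          spec$age_range_months, spec$bodyweight_range_kg,
                          spec$age_meanlog, spec$age_sdlog,
                          spec$bw_meanlog, spec$bw_sdlog,
                          spec$n_female / spec$n,
                          spec$calib_n, spec$calib_iter,
                          spec$correlation_measure))
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])

  t <- spec$composition_targets
  corr <- spec$covariate_correlations
  corr$rho <- corr$target_r
  k <- nrow(registry)
  calib <- list(
    mu_m = log(t$mean_m), sig_m = sqrt(log(1 + (t$sd_m / t$mean_m)^2)),
    mu_f = log(t$mean_f), sig_f = sqrt(log(1 + (t$sd_f / t$mean_f)^2)),
    corr = corr
  )

  withr::with_seed(20200821, {
    nc <- spec$calib_n
    sex <- ifelse(stats::runif(nc) < spec$n_female / spec$n, "F", "M")
    age <- rtrunc_lnorm(nc, spec$age_meanlog, spec$age_sdlog,
                        spec$age_range_months[1], spec$age_range_months[2])
    bw <- rtrunc_lnorm(nc, spec$bw_meanlog, spec$bw_sdlog,
                       spec$bodyweight_range_kg[1],
                       spec$bodyweight_range_kg[2])
    eps <- matrix(stats::rnorm(nc * k), nc, k)
    is_f <- sex == "F"

    for (it in seq_len(spec$calib_iter)) {
      li <- latent_inputs(calib, sex, age, bw, registry)
      x <- close_latent(li$mu, li$sig, li$rho_mat, li$cstd_mat, eps,
                        registry$code)
      for (s in c("m", "f")) {
        rows <- if (s == "f") is_f else !is_f
        mean_hat <- colMeans(x[rows, , drop = FALSE])
        sd_hat <- apply(x[rows, , drop = FALSE], 2, stats::sd)
        tgt_mean <- t[[paste0("mean_", s)]]
        tgt_sd <- t[[paste0("sd_", s)]]
        calib[[paste0("mu_", s)]] <-
          calib[[paste0("mu_", s)]] + log(tgt_mean / mean_hat)
        calib[[paste0("sig_", s)]] <- calib[[paste0("sig_", s)]] *
          pmin(pmax(tgt_sd / sd_hat, 0.7), 1.4)
      }
      if (nrow(calib$corr) > 0) {
        covs <- list(age_months = age, bodyweight_kg = bw)
        for (i in seq_len(nrow(calib$corr))) {
          v <- measure_matrix(x, calib$corr$measure[i], registry)
          r_hat <- stats::cor(v, covs[[calib$corr$covariate[i]]],
                              method = spec$correlation_measure)
          calib$corr$rho[i] <- pmin(pmax(
            calib$corr$rho[i] + 0.8 * (calib$corr$target_r[i] - r_hat),
            -0.98), 0.98)
        }
      }
    }

    # final fit check against the realized population
    if (nrow(calib$corr) > 0) {
      li <- latent_inputs(calib, sex, age, bw, registry)
      x <- close_latent(li$mu, li$sig, li$rho_mat, li$cstd_mat, eps,
                        registry$code)
      covs <- list(age_months = age, bodyweight_kg = bw)
      for (i in seq_len(nrow(calib$corr))) {
        v <- measure_matrix(x, calib$corr$measure[i], registry)
        r_hat <- stats::cor(v, covs[[calib$corr$covariate[i]]],
                            method = spec$correlation_measure)
        if (abs(r_hat - calib$corr$target_r[i]) > 0.05) {
          rlang::abort(paste0("infeasible spec: correlation target for ",
                              calib$corr$measure[i], " vs ",
                              calib$corr$covariate[i], " not reachable"))
        }
      }
    }
  })

  .calib_cache[[key]] <- calib
  calib
}

#' Generate membrane compositions
#'
#' Draws one 10-part composition per dog from the calibrated
#' additive-logistic-normal model: per-sex latent means/scales reproduce the
#' target composition means and standard deviations, linear covariate terms
#' in the latent mean inject the target correlations, and the closure to
#' 100% is exact by construction.
#'
#' @param spec A [cohort_spec()].
#' @param covariates Tibble from [generate_covariates()].
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @param registry Fatty-acid registry.
#' @return Wide profile tibble: `sample_id` plus ten percentage columns.
#' @export
generate_compositions <- function(spec, covariates, seed = spec$seed,
                                  registry = fa_cluster()) {
  calib <- calibrate_spec(spec, registry)
  maybe_with_seed(seed, {
    n <- nrow(covariates)
    eps <- matrix(stats::rnorm(n * nrow(registry)), n, nrow(registry))
    li <- latent_inputs(calib, covariates$sex, covariates$age_months,
                        covariates$bodyweight_kg, registry)
    x <- close_latent(li$mu, li$sig, li$rho_mat, li$cstd_mat, eps,
                      registry$code)
    dplyr::bind_cols(covariates["sample_id"], tibble::as_tibble(x))
  })
}

#' Generate calibration standards and peak tables
#'
#' Inverts the quantitation stage: draws a true linear detector response per
#' fatty acid, emits a 5-level calibration-standard table spanning one decade
#' of concentration, and converts each sample's ground-truth composition
#' (scaled by a random total cluster quantity) into peak areas through the
#' true curves, adding a non-cluster `"other"` peak that keeps cluster
#' coverage inside the spec's coverage range. With `noise_free = TRUE` the
#' tables invert exactly: quantitation recovers the ground-truth compositions
#' to machine precision.
#'
#' @param compositions Wide profile tibble from [generate_compositions()].
#' @param spec A [cohort_spec()].
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @param noise_free Disable all measurement noise, default `FALSE`.
#' @param registry Fatty-acid registry.
#' @return List with `standards` (`fa_code`, `concentration_ug_ml`, `area`),
#'   `peaks` (`sample_id`, `fa_code`, `area`, including `"other"` rows), and
#'   `true_curves` (`fa_code`, `slope`, `intercept`).
#' @export
make_peak_tables <- function(compositions, spec, seed = spec$seed,
                             noise_free = FALSE, registry = fa_cluster()) {
  maybe_with_seed(seed, {
    k <- nrow(registry)
    n <- nrow(compositions)
    pct <- as.matrix(compositions[registry$code])
    slope <- stats::runif(k, 5, 50)
    intercept <- stats::runif(k, 0, 2)
    true_curves <- tibble::tibble(fa_code = registry$code, slope = slope,
                                  intercept = intercept)

    # five standard levels spanning one decade around the typical quantity
    mid_total <- mean(spec$total_lipid_range_ug_ml)
    c_ref <- pmax(colMeans(pct), 0.05) * mid_total / 100
    level <- exp(seq(log(0.2), log(2), length.out = 5))
    standards <- tidyr::expand_grid(fa_code = registry$code, level = level) |>
      dplyr::mutate(
        concentration_ug_ml = c_ref[match(.data$fa_code, registry$code)] *
          .data$level,
        area = slope[match(.data$fa_code, registry$code)] *
          .data$concentration_ug_ml +
          intercept[match(.data$fa_code, registry$code)]
      ) |>
      dplyr::select(-"level")
    if (!noise_free && spec$standards_rel_sd > 0) {
      standards$area <- standards$area *
        (1 + stats::rnorm(nrow(standards), 0, spec$standards_rel_sd))
    }
    standards$area <- pmax(standards$area, 1e-6)

    total <- stats::runif(n, spec$total_lipid_range_ug_ml[1],
                          spec$total_lipid_range_ug_ml[2])
    conc <- pct * total / 100
    areas <- sweep(conc, 2, slope, `*`)
    areas <- sweep(areas, 2, intercept, `+`)
    if (!noise_free && spec$area_rel_sd > 0) {
      areas <- areas * (1 + matrix(stats::rnorm(n * k, 0, spec$area_rel_sd),
                                   n, k))
    }
    areas <- pmax(areas, 0)
    cluster_sum <- rowSums(areas)
    coverage <- stats::runif(n, spec$coverage_range[1], spec$coverage_range[2])
    other <- cluster_sum * (1 - coverage) / coverage

    peaks <- dplyr::bind_rows(
      tibble::tibble(
        sample_id = rep(compositions$sample_id, each = k),
        fa_code = rep(registry$code, n),
        area = as.vector(t(areas))
      ),
      tibble::tibble(sample_id = compositions$sample_id,
                     fa_code = "other", area = other)
    )
    list(standards = standards, peaks = peaks, true_curves = true_curves)
  })
}

#' Generate a full synthetic cohort
#'
#' Chains [generate_covariates()], [generate_compositions()] and
#' [make_peak_tables()] under a single seed: metadata, ground-truth
#' compositions, calibration standards and peak tables, all mutually
#' consistent (the peak tables invert to the compositions through the
#' standards' true curves).
#'
#' @param spec A [cohort_spec()].
#' @param noise_free Disable measurement noise in the peak tables.
#' @return A list of class `synthetic_cohort` with elements `metadata`,
#'   `compositions`, `standards`, `peaks`, `true_curves`, `spec`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(seed = 7))
#' head(cohort$compositions)
#' @export
generate_cohort <- function(spec = cohort_spec(), noise_free = FALSE) {
  calibrate_spec(spec)  # outside the seeded block: cached, internally seeded
  withr::with_seed(spec$seed, {
    covariates <- generate_covariates(spec, seed = NULL)
    compositions <- generate_compositions(spec, covariates, seed = NULL)
    tables <- make_peak_tables(compositions, spec, seed = NULL,
                               noise_free = noise_free)
    structure(
      list(metadata = covariates, compositions = compositions,
           standards = tables$standards, peaks = tables$peaks,
           true_curves = tables$true_curves, spec = spec),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d dogs (%d F / %d M), seed %d\n",
              nrow(x$metadata), sum(x$metadata$sex == "F"),
              sum(x$metadata$sex == "M"), x$spec$seed))
  invisible(x)
}
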