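# GC-FAME quantitation: calibration curves, back-calculation of ug/mL
# quantities from integrated peak areas, closure of the cluster to relative
# percentages, and the cluster-coverage check.

#' Fit per-analyte calibration curves
#'
#' Fits an ordinary-least-squares straight line `area = slope * concentration
#' + intercept` to the calibration standards of each fatty acid. The inverse
#' of this line converts sample peak areas to microgram-per-millilitre
#' quantities in [quantify_peaks()].
#'
#' @param standards Data frame with columns `fa_code`, `concentration_ug_ml`
#'   (> 0) and `area` (> 0); one row per standard injection. Codes are
#'   normalised through [normalize_fa_codes()].
#' @param force_zero_intercept Fit `area = slope * concentration` through the
#'   origin instead (default `FALSE`).
#' @param r_squared_warn Warn when a curve's coefficient of determination
#'   falls below this value (default 0.995). The curve is kept.
#' @return A tibble with one row per fatty acid: `fa_code`, `slope`,
#'   `intercept`, `r_squared`, `n_points`.
#' @details Each fatty acid needs at least 3 standard points at 2 or more
#'   distinct concentrations; a non-positive fitted slope (a calibration that
#'   does not increase with concentration) is an error.
#' @examples
#' std <- tibble::tibble(
#'   fa_code = "C16:0",
#'   concentration_ug_ml = c(1, 2, 3),
#'   area = c(10, 20, 30)
#' )
#' fit_calibration(std)
#' @export
fit_calibration <- function(standards, force_zero_intercept = FALSE,
                            r_squared_warn = 0.995) {
  standards <- tibble::as_tibble(standards)
  stopifnot(all(c("fa_code", "concentration_ug_ml", "area") %in%
                  names(standards)))
  if (any(standards$concentration_ug_ml <= 0) || any(standards$area <= 0)) {
    rlang::abort("calibration standards need positive concentrations and areas")
  }
  standards$fa_code <- normalize_fa_codes(standards$fa_code, strict = FALSE)

  fit_one <- function(df) {
    fa <- df$fa_code[[1]]
    if (nrow(df) < 3) {
      rlang::abort(paste0("insufficient standards for ", fa,
                          ": need at least 3 points"))
    }
    if (dplyr::n_distinct(df$concentration_ug_ml) < 2) {
      rlang::abort(paste0("insufficient standards for ", fa,
                          ": need at least 2 distinct concentrations"))
    }
    fml <- if (force_zero_intercept) area ~ 0 + concentration_ug_ml else
      area ~ concentration_ug_ml
    fit <- stats::lm(fml, data = df)
    slope <- unname(stats::coef(fit)[["concentration_ug_ml"]])
    intercept <- if (force_zero_intercept) 0 else
      unname(stats::coef(fit)[["(Intercept)"]])
    if (!is.finite(slope) || slope <= 0) {
      rlang::abort(paste0("non-monotone calibration for ", fa,
                          ": fitted slope is not positive"))
    }
    r2 <- stats::cor(stats::fitted(fit), df$area)^2
    if (isTRUE(r2 < r_squared_warn)) {
      rlang::warn(paste0("calibration for ", fa, ": r-squared ",
                         format(round(r2, 4)), " below ", r_squared_warn))
    }
    tibble::tibble(fa_code = fa, slope = slope, intercept = intercept,
                   r_squared = r2, n_points = nrow(df))
  }

  standards |>
    dplyr::group_by(.data$fa_code) |>
    dplyr::group_split() |>
    purrr::map_dfr(fit_one)
}

#' Back-calculate quantities from peak areas
#'
#' Inverts the calibration line of each fatty acid to turn integrated peak
#' areas into microgram-per-millilitre quantities:
#' `quantity = (area - intercept) / slope`. Areas below the intercept
#' back-calculate negative and are clipped to zero with a warning. Rows with
#' `fa_code == "other"` (non-cluster area) are ignored here; they only enter
#' the coverage check.
#'
#' @param peaks Data frame with columns `sample_id`, `fa_code`, `area`
#'   (>= 0); at most one row per (sample, cluster fatty acid).
#' @param curves Calibration tibble from [fit_calibration()].
#' @param registry Fatty-acid registry, default [fa_cluster()].
#' @return A tibble `sample_id`, `fa_code`, `quantity_ug_ml` with one row per
#'   sample and cluster fatty acid. Cluster acids with no peak row are
#'   reported as 0 with a warning.
#' @export
quantify_peaks <- function(peaks, curves, registry = fa_cluster()) {
  peaks <- tibble::as_tibble(peaks)
  stopifnot(all(c("sample_id", "fa_code", "area") %in% names(peaks)))
  if (any(peaks$area < 0)) rlang::abort("peak areas must be non-negative")
  peaks$fa_code <- normalize_fa_codes(peaks$fa_code, strict = FALSE)
  cluster <- peaks |> dplyr::filter(.data$fa_code %in% registry$code)
  if (anyDuplicated(cluster[c("sample_id", "fa_code")])) {
    rlang::abort("duplicate (sample_id, fa_code) rows in peak table")
  }
  uncal <- setdiff(unique(cluster$fa_code), curves$fa_code)
  if (length(uncal) > 0) {
    rlang::abort(paste0("uncalibrated peak: no curve for ",
                        paste(uncal, collapse = ", ")))
  }

  full <- tidyr::expand_grid(sample_id = unique(peaks$sample_id),
                             fa_code = registry$code) |>
    dplyr::left_join(cluster, by = c("sample_id", "fa_code"))
  n_absent <- sum(is.na(full$area))
  if (n_absent > 0) {
    rlang::warn(paste0(n_absent, " cluster peak(s) absent from the table; ",
                       "treated as quantity 0"))
  }

  out <- full |>
    dplyr::left_join(curves[c("fa_code", "slope", "intercept")],
                     by = "fa_code") |>
    dplyr::mutate(quantity_ug_ml = (.data$area - .data$intercept) / .data$slope)
  n_clip <- sum(out$quantity_ug_ml < 0, na.rm = TRUE)
  if (n_clip > 0) {
    rlang::warn(paste0(n_clip, " peak area(s) below the calibration ",
                       "intercept; quantities clipped to 0"))
  }
  out |>
    dplyr::mutate(
      quantity_ug_ml = dplyr::coalesce(pmax(.data$quantity_ug_ml, 0), 0)
    ) |>
    dplyr::select("sample_id", "fa_code", "quantity_ug_ml")
}

#' Close quantities to cluster-relative percentages
#'
#' Expresses each fatty-acid quantity as a percentage of the summed cluster
#' quantities of its sample (the cluster is closed to 100). The operation is
#' scale invariant: multiplying all of a sample's quantities by a positive
#' constant leaves its percentages unchanged.
#'
#' @param quantities Tibble `sample_id`, `fa_code`, `quantity_ug_ml` (>= 0),
#'   e.g. from [quantify_peaks()].
#' @param registry Fatty-acid registry, default [fa_cluster()].
#' @return A wide tibble: `sample_id` plus one percentage column per cluster
#'   fatty-acid code, each row summing to 100.
#' @export
relative_percentages <- function(quantities, registry = fa_cluster()) {
  quantities <- tibble::as_tibble(quantities)
  stopifnot(all(c("sample_id", "fa_code", "quantity_ug_ml") %in%
                  names(quantities)))
  quantities$fa_code <- normalize_fa_codes(quantities$fa_code, strict = FALSE)
  q <- quantities |>
    dplyr::filter(.data$fa_code %in% registry$code) |>
    dplyr::group_by(.data$sample_id)
  totals <- q |> dplyr::summarise(total = sum(.data$quantity_ug_ml))
  if (any(totals$total <= 0)) {
    bad <- totals$sample_id[totals$total <= 0]
    rlang::abort(paste0("empty profile: all-zero cluster quantities for ",
                        paste(bad, collapse = ", ")))
  }
  q |>
    dplyr::mutate(percent = 100 * .data$quantity_ug_ml /
                    sum(.data$quantity_ug_ml)) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "fa_code", "percent") |>
    tidyr::pivot_wider(names_from = "fa_code", values_from = "percent",
                       values_fill = 0) |>
    dplyr::select("sample_id", dplyr::all_of(registry$code))
}

#' Cluster coverage check
#'
#' Fraction of the total chromatogram area attributable to the cluster
#' peaks. A well-resolved run concentrates at least 97% of the area in the
#' cluster; samples below the threshold are flagged, not dropped.
#'
#' @param cluster_area_sum Summed area of the cluster peaks (> 0).
#' @param total_area_sum Summed area of all peaks (>= `cluster_area_sum`).
#' @param threshold Pass threshold as a fraction, default 0.97.
#' @return A tibble with `coverage_fraction` and logical `coverage_pass`.
#' @examples
#' coverage_check(97, 100)
#' @export
coverage_check <- function(cluster_area_sum, total_area_sum,
                           threshold = 0.97) {
  if (any(cluster_area_sum <= 0)) {
    rlang::abort("inconsistent areas: cluster area must be positive")
  }
  if (any(total_area_sum < cluster_area_sum)) {
    rlang::abort("inconsistent areas: total area below cluster area")
  }
  frac <- cluster_area_sum / total_area_sum
  tibble::tibble(coverage_fraction = frac,
                 coverage_pass = frac >= threshold)
}

#' Quantify a peak table end to end
#'
#' Convenience wrapper chaining [fit_calibration()], [quantify_peaks()],
#' [relative_percentages()] and the per-sample [coverage_check()] into one
#' profile table.
#'
#' @param peaks Peak table (`sample_id`, `fa_code`, `area`); non-cluster area
#'   may be supplied as rows with `fa_code = "other"`.
#' @param standards Calibration standards table (see [fit_calibration()]).
#' @param registry Fatty-acid registry.
#' @param coverage_threshold Coverage pass threshold, default 0.97.
#' @inheritParams fit_calibration
#' @return A wide profile tibble: `sample_id`, ten percentage columns,
#'   `coverage_fraction`, `coverage_pass`.
#' @export
quantify_samples <- function(peaks, standards, registry = fa_cluster(),
                             coverage_threshold = 0.97,
                             force_zero_intercept = FALSE) {
  peaks <- tibble::as_tibble(peaks)
  peaks$fa_code <- normalize_fa_codes(peaks$fa_code, strict = FALSE)
  curves <- fit_calibration(standards,
                            force_zero_intercept = force_zero_intercept)
  quantities <- quantify_peaks(peaks, curves, registry)
  profiles <- relative_percentages(quantities, registry)
  coverage <- peaks |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      cluster_area = sum(.data$area[.data$fa_code %in% registry$code]),
      total_area = sum(.data$area)
    )
  cov <- coverage_check(coverage$cluster_area, coverage$total_area,
                        threshold = coverage_threshold)
  profiles |>
    dplyr::left_join(
      dplyr::bind_cols(coverage["sample_id"], cov),
      by = "sample_id"
    )
}

# Closure check used by index functions: percentages of a wide profile table
# should sum near 100. Tolerance is loose on purpose so printed/rounded
# tables (which close to 100 +/- a last digit) can be analysed as-is.
check_closure <- function(profiles, registry = fa_cluster(),
                          tol_warn = 0.5, tol_abort = 5) {
  codes <- intersect(registry$code, names(profiles))
  if (length(codes) < nrow(registry)) {
    rlang::abort(paste0("profile table is missing percentage columns: ",
                        paste(setdiff(registry$code, codes), collapse = ", ")))
  }
  sums <- rowSums(as.matrix(profiles[codes]))
  dev <- abs(sums - 100)
  if (any(dev > tol_abort)) {
    rlang::abort("profile percentages do not close to 100")
  }
  if (any(dev > tol_warn)) {
    rlang::warn("some profiles deviate from 100% closure by more than 0.5")
  }
  invisible(profiles)
}
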