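# CSV readers/writers and the end-to-end pipeline driver.
#
# Dialect: UTF-8, comma-separated, '.' decimal, mandatory header row.
# Mean and sd are always separate columns; values are rounded to 2 decimals
# only at CSV serialisation (JSON keeps full precision).

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    rlang::abort(paste0("malformed header in ", basename(path),
                        ": missing column(s) ",
                        paste(missing, collapse = ", ")))
  }
  df
}

#' Read a peak-area table
#'
#' Reads `sample_id,fa_code,area` rows; fatty-acid labels are resolved
#' through the synonym map (comma spellings like `"9c,C18:1"` and PUFA
#' acronyms are accepted), non-cluster area may appear as `fa_code = "other"`
#' and unknown labels are rejected. Duplicate (sample, fatty acid) rows and
#' negative areas are reported with their line numbers.
#'
#' @param path CSV file path.
#' @return Tibble `sample_id`, `fa_code`, `area`.
#' @export
read_peaks_csv <- function(path) {
  df <- read_checked_csv(path, c("sample_id", "fa_code", "area"))
  df$fa_code <- normalize_fa_codes(df$fa_code)
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- which(df$area < 0)
  if (length(bad) > 0) {
    rlang::abort(paste0("negative area at line ",
                        paste(line[bad], collapse = ", "), " of ",
                        basename(path)))
  }
  cl <- df$fa_code != "other"
  dup <- which(cl & duplicated(df[c("sample_id", "fa_code")]))
  if (length(dup) > 0) {
    rlang::abort(paste0("duplicate (sample_id, fa_code) at line ",
                        paste(line[dup], collapse = ", "), " of ",
                        basename(path)))
  }
  tibble::as_tibble(df[c("sample_id", "fa_code", "area")])
}

#' Read a calibration-standards table
#'
#' Reads `fa_code,concentration_ug_ml,area` rows with synonym resolution;
#' non-positive concentrations or areas are reported with line numbers.
#'
#' @param path CSV file path.
#' @return Tibble `fa_code`, `concentration_ug_ml`, `area`.
#' @export
read_standards_csv <- function(path) {
  df <- read_checked_csv(path, c("fa_code", "concentration_ug_ml", "area"))
  df$fa_code <- normalize_fa_codes(df$fa_code)
  line <- seq_len(nrow(df)) + 1L
  bad <- which(df$concentration_ug_ml <= 0 | df$area <= 0)
  if (length(bad) > 0) {
    rlang::abort(paste0("non-positive standard at line ",
                        paste(line[bad], collapse = ", "), " of ",
                        basename(path)))
  }
  tibble::as_tibble(df[c("fa_code", "concentration_ug_ml", "area")])
}

#' Read a cohort metadata table
#'
#' Reads `sample_id,sex,neutered,age_months,bodyweight_kg,breed` rows;
#' sex must be `M` or `F`, ages and bodyweights positive.
#'
#' @param path CSV file path.
#' @return Metadata tibble.
#' @export
read_metadata_csv <- function(path) {
  df <- read_checked_csv(path, c("sample_id", "sex", "neutered",
                                 "age_months", "bodyweight_kg", "breed"))
  line <- seq_len(nrow(df)) + 1L
  bad <- which(!(df$sex %in% c("M", "F")) | df$age_months <= 0 |
                 df$bodyweight_kg <= 0)
  if (length(bad) > 0) {
    rlang::abort(paste0("invalid metadata at line ",
                        paste(line[bad], collapse = ", "), " of ",
                        basename(path)))
  }
  if (anyDuplicated(df$sample_id)) {
    rlang::abort(paste0("duplicate sample_id in ", basename(path)))
  }
  tibble::as_tibble(df)
}

#' Write a benchmark table
#'
#' Serialises an [summarize_cohort()] benchmark to CSV (2-decimal rounding,
#' the reporting precision) or JSON (full precision; round-trips through
#' [read_benchmark_json()] exactly).
#'
#' @param benchmark An `fa_benchmark` tibble.
#' @param path Output file path.
#' @param format `"csv"` or `"json"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(benchmark, path,
                            format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else
      "csv"
  }
  if (format == "csv") {
    out <- tidy(benchmark) |>
      dplyr::mutate(dplyr::across(dplyr::where(is.double), ~round(.x, 2)))
    readr::write_csv(out, path, na = "")
  } else {
    rlang::check_installed("jsonlite")
    jsonlite::write_json(tidy(benchmark), path, digits = NA, na = "null")
  }
  invisible(path)
}

#' Read a benchmark from JSON
#'
#' @param path JSON file written by [write_benchmark()].
#' @return An `fa_benchmark` tibble.
#' @export
read_benchmark_json <- function(path) {
  rlang::check_installed("jsonlite")
  out <- tibble::as_tibble(jsonlite::fromJSON(path))
  out$p2_5 <- as.numeric(out$p2_5)
  out$p97_5 <- as.numeric(out$p97_5)
  class(out) <- c("fa_benchmark", class(out))
  out
}

#' Run the full pipeline
#'
#' Chains the stages end to end: simulate (or load) the input tables,
#' quantify the peak tables through the calibration standards, derive the
#' lipid-index panel, build the cohort benchmark, and run the sex-comparison
#' and covariate-correlation study. All artifacts are written as CSV under
#' `out_dir`; the run is deterministic for a fixed spec and seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param spec A [cohort_spec()] used when simulating.
#' @param peaks,standards,metadata Optional input tibbles (or paths to CSV
#'   files); when any is `NULL` the cohort is simulated from `spec`.
#' @param noise_free Simulate without measurement noise.
#' @param alpha Significance level of the study, default 0.05.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with `profiles`, `panel`, `benchmark`, `study`
#'   and the paths written.
#' @export
run_pipeline <- function(out_dir, spec = cohort_spec(), peaks = NULL,
                         standards = NULL, metadata = NULL,
                         noise_free = FALSE, alpha = 0.05, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  as_tbl <- function(x, reader) {
    if (is.character(x)) reader(x) else tibble::as_tibble(x)
  }

  if (is.null(peaks) || is.null(standards) || is.null(metadata)) {
    if (!is.null(peaks) || !is.null(standards) || !is.null(metadata)) {
      missing <- c("peaks", "standards", "metadata")[
        c(is.null(peaks), is.null(standards), is.null(metadata))]
      rlang::abort(paste0("quantify: missing ",
                          paste(missing, collapse = ", "),
                          " (supply all three tables or none)"))
    }
    say("simulate: %d dogs, seed %d", spec$n, spec$seed)
    cohort <- generate_cohort(spec, noise_free = noise_free)
    peaks <- cohort$peaks
    standards <- cohort$standards
    metadata <- cohort$metadata
    readr::write_csv(cohort$compositions,
                     file.path(out_dir, "ground_truth_profiles.csv"))
    readr::write_csv(metadata, file.path(out_dir, "metadata.csv"))
    readr::write_csv(standards, file.path(out_dir, "standards.csv"))
    readr::write_csv(peaks, file.path(out_dir, "peaks.csv"))
  } else {
    peaks <- as_tbl(peaks, read_peaks_csv)
    standards <- as_tbl(standards, read_standards_csv)
    metadata <- as_tbl(metadata, read_metadata_csv)
  }

  say("quantify: %d samples", dplyr::n_distinct(peaks$sample_id))
  profiles <- quantify_samples(peaks, standards)
  n_flag <- sum(!profiles$coverage_pass)
  if (n_flag > 0) say("quantify: %d sample(s) below coverage threshold",
                      n_flag)
  readr::write_csv(profiles, file.path(out_dir, "profiles.csv"))

  say("profile: deriving lipid indexes")
  panel <- lipid_panel(profiles)
  readr::write_csv(panel, file.path(out_dir, "panel.csv"))

  say("benchmark: %d parameters", length(benchmark_parameters()))
  benchmark <- summarize_cohort(panel)
  write_benchmark(benchmark, file.path(out_dir, "benchmark.csv"))

  say("compare/correlate: alpha = %g", alpha)
  study <- run_study(panel, metadata, alpha = alpha)
  readr::write_csv(tidy(study, "comparisons"),
                   file.path(out_dir, "comparisons.csv"))
  readr::write_csv(tidy(study, "correlations"),
                   file.path(out_dir, "correlations.csv"))

  invisible(list(profiles = profiles, panel = panel, benchmark = benchmark,
                 study = study, out_dir = out_dir))
}
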