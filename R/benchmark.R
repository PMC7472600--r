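# Healthy-cohort benchmark: per-parameter interval values (min-max), medians,
# optional percentile bands, and distribution summaries for the ten
# fatty-acid percentages and the ten derived parameters.

# The twenty benchmark parameters in reporting order: the ten fatty-acid
# codes (GC elution order) followed by the ten derived parameters.
benchmark_parameters <- function(registry = fa_cluster()) {
  c(registry$code, index_names())
}

#' Reference interval for one parameter
#'
#' Minimum, maximum and median over a cohort of non-missing values; the
#' interval here is the raw min-max range (with the median), not a percentile
#' reference range. When at least 40 non-missing values are available, the
#' nonparametric 2.5th and 97.5th percentiles (linear interpolation) are
#' reported alongside as `p2_5` / `p97_5`.
#'
#' @param values Numeric vector; `NA`s are dropped (their count is reflected
#'   in `n`).
#' @param parameter Parameter name carried into the output.
#' @param percentile_min_n Minimum `n` for percentile reporting, default 40.
#' @return One-row tibble: `parameter`, `n`, `minimum`, `maximum`, `median`,
#'   `p2_5`, `p97_5` (the last two `NA` below `percentile_min_n`).
#' @examples
#' reference_interval(c(1, 2, 3, 4), "demo")
#' @export
reference_interval <- function(values, parameter = "value",
                               percentile_min_n = 40) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) {
    rlang::abort(paste0("insufficient cohort for ", parameter,
                        ": need at least 2 values"))
  }
  qs <- if (n >= percentile_min_n) {
    stats::quantile(values, c(0.025, 0.975), type = 7, names = FALSE)
  } else {
    c(NA_real_, NA_real_)
  }
  tibble::tibble(
    parameter = parameter,
    n = n,
    minimum = min(values),
    maximum = max(values),
    median = stats::median(values),
    p2_5 = qs[1],
    p97_5 = qs[2]
  )
}

#' Cohort benchmark table
#'
#' Builds the full healthy-cohort benchmark: one [reference_interval()] row
#' for each of the ten fatty-acid percentages and each of the ten derived
#' parameters, in reporting order. Samples with a flagged-missing ratio are
#' excluded from that parameter only; `n` records the per-parameter count.
#'
#' @param panel Panel tibble from [lipid_panel()] (percentages kept).
#' @param registry Fatty-acid registry, default [fa_cluster()].
#' @param percentile_min_n Passed to [reference_interval()].
#' @return A tibble of class `fa_benchmark` with 20 rows.
#' @export
summarize_cohort <- function(panel, registry = fa_cluster(),
                             percentile_min_n = 40) {
  panel <- tibble::as_tibble(panel)
  params <- benchmark_parameters(registry)
  missing_cols <- setdiff(params, names(panel))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("panel is missing parameter columns: ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (nrow(panel) < 2) rlang::abort("insufficient cohort: need >= 2 samples")
  out <- purrr::map_dfr(
    params,
    function(p) reference_interval(panel[[p]], p, percentile_min_n)
  )
  class(out) <- c("fa_benchmark", class(out))
  out
}

#' Histogram data for cohort distributions
#'
#' Computes per-parameter histogram data (Freedman-Diaconis bin widths by
#' default) for the long value table of a cohort, the data behind the
#' distribution plots of [autoplot.fa_benchmark()].
#'
#' @param panel Panel tibble from [lipid_panel()].
#' @param registry Fatty-acid registry.
#' @param breaks Passed to [graphics::hist()]; default `"FD"`.
#' @return A tibble `parameter`, `bin_left`, `bin_right`, `count`.
#' @export
export_distributions <- function(panel, registry = fa_cluster(),
                                 breaks = "FD") {
  long <- panel_values_long(panel, registry)
  long |>
    dplyr::group_by(.data$parameter) |>
    dplyr::group_split() |>
    purrr::map_dfr(function(df) {
      v <- df$value[!is.na(df$value)]
      if (length(unique(v)) == 1) {
        # degenerate distribution: a single occupied bin around the value
        return(tibble::tibble(parameter = df$parameter[[1]],
                              bin_left = v[1] - 0.5, bin_right = v[1] + 0.5,
                              count = length(v)))
      }
      h <- graphics::hist(v, breaks = breaks, plot = FALSE)
      tibble::tibble(parameter = df$parameter[[1]],
                     bin_left = utils::head(h$breaks, -1),
                     bin_right = utils::tail(h$breaks, -1),
                     count = h$counts)
    })
}

# Long (parameter, value) table over the 20 benchmark parameters.
panel_values_long <- function(panel, registry = fa_cluster()) {
  params <- benchmark_parameters(registry)
  panel |>
    dplyr::select("sample_id", dplyr::all_of(params)) |>
    tidyr::pivot_longer(-"sample_id", names_to = "parameter",
                        values_to = "value") |>
    dplyr::mutate(parameter = factor(.data$parameter, levels = params))
}

#' @export
tidy.fa_benchmark <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "fa_benchmark")
  out
}

#' @export
glance.fa_benchmark <- function(x, ...) {
  tibble::tibble(
    n_parameters = nrow(x),
    n_samples = max(x$n),
    n_missing_entries = sum(max(x$n) - x$n)
  )
}

#' Plot cohort distributions with interval annotations
#'
#' Facetted histograms of the 20 benchmark parameters with the minimum and
#' maximum (black) and the median (green) marked, plus an optional
#' nonparametric 2.5-97.5 percentile band (dashed) when percentiles are
#' present in the benchmark.
#'
#' @param object An `fa_benchmark` from [summarize_cohort()].
#' @param panel The panel tibble the benchmark was built from.
#' @param registry Fatty-acid registry.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fa_benchmark <- function(object, panel, registry = fa_cluster(),
                                  ...) {
  long <- panel_values_long(panel, registry)
  marks <- tidy(object) |>
    dplyr::mutate(parameter = factor(.data$parameter,
                                     levels = benchmark_parameters(registry)))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$minimum),
                        colour = "black") +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$maximum),
                        colour = "black") +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$median),
                        colour = "green4") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "count")
  if (any(!is.na(marks$p2_5))) {
    band <- marks |> dplyr::filter(!is.na(.data$p2_5))
    p <- p +
      ggplot2::geom_vline(data = band,
                          ggplot2::aes(xintercept = .data$p2_5),
                          linetype = "dashed", colour = "grey30") +
      ggplot2::geom_vline(data = band,
                          ggplot2::aes(xintercept = .data$p97_5),
                          linetype = "dashed", colour = "grey30")
  }
  p
}
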