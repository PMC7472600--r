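# Derived membrane lipid parameters: family totals, SFA/MUFA and
# omega-6/omega-3 ratios, PUFA balance, unsaturation index (UI) and
# peroxidation index (PI).
#
# All of them are linear in the fatty-acid percentages except the two ratios
# and the PUFA balance; linearity is what makes cohort means of UI/PI equal
# the UI/PI of the mean composition.

# Names of the ten derived columns, in reporting order.
index_names <- function() {
  c("total_sfa", "total_mufa", "pufa_n3", "pufa_n6", "total_pufa",
    "sfa_mufa_ratio", "n6_n3_ratio", "pufa_balance",
    "unsaturation_index", "peroxidation_index")
}

#' Fatty-acid family totals
#'
#' Sums the member percentages of each family: total SFA (palmitic +
#' stearic), total MUFA (palmitoleic + oleic + cis-vaccenic), omega-3 PUFA
#' (EPA + DHA), omega-6 PUFA (LA + DGLA + ARA) and total PUFA (all five
#' polyunsaturated members).
#'
#' @param profiles Wide profile tibble: `sample_id` plus one percentage
#'   column per cluster fatty acid (see [relative_percentages()]).
#' @param registry Fatty-acid registry, default [fa_cluster()].
#' @return Tibble `sample_id`, `total_sfa`, `total_mufa`, `pufa_n3`,
#'   `pufa_n6`, `total_pufa`.
#' @export
family_totals <- function(profiles, registry = fa_cluster()) {
  profiles <- tibble::as_tibble(profiles)
  check_closure(profiles, registry)
  pct <- as.matrix(profiles[registry$code])
  fam_sum <- function(fam) {
    rowSums(pct[, registry$code[registry$family %in% fam], drop = FALSE])
  }
  tibble::tibble(
    sample_id  = profiles$sample_id,
    total_sfa  = fam_sum("SFA"),
    total_mufa = fam_sum("MUFA"),
    pufa_n3    = fam_sum("PUFA_n3"),
    pufa_n6    = fam_sum("PUFA_n6"),
    total_pufa = fam_sum(c("PUFA_n3", "PUFA_n6"))
  )
}

#' Family ratios and PUFA balance
#'
#' From family totals, computes SFA/MUFA, omega-6/omega-3, and the PUFA
#' balance `100 * pufa_n3 / total_pufa` (the omega-3 share of total PUFA, in
#' percent). A zero denominator yields `NA` for that ratio with a warning
#' when `on_zero = "missing"` (the default used by [lipid_panel()]), or an
#' error when `on_zero = "error"`.
#'
#' @param totals Tibble from [family_totals()].
#' @param on_zero `"missing"` or `"error"`.
#' @return `totals` with columns `sfa_mufa_ratio`, `n6_n3_ratio`,
#'   `pufa_balance` appended.
#' @export
lipid_ratios <- function(totals, on_zero = c("missing", "error")) {
  on_zero <- match.arg(on_zero)
  totals <- tibble::as_tibble(totals)
  zero_of <- list(
    "SFA/MUFA" = totals$total_mufa <= 0,
    "omega-6/omega-3" = totals$pufa_n3 <= 0,
    "PUFA balance" = totals$total_pufa <= 0
  )
  for (nm in names(zero_of)) {
    if (any(zero_of[[nm]])) {
      msg <- paste0("undefined ratio: ", nm, " (zero denominator)")
      if (on_zero == "error") rlang::abort(msg) else rlang::warn(msg)
    }
  }
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  totals |>
    dplyr::mutate(
      sfa_mufa_ratio = safe_div(.data$total_sfa, .data$total_mufa),
      n6_n3_ratio    = safe_div(.data$pufa_n6, .data$pufa_n3),
      pufa_balance   = safe_div(100 * .data$pufa_n3, .data$total_pufa)
    )
}

# Weighted sum of percentages over the registry (UI and PI share this form).
weighted_index <- function(profiles, registry, weights) {
  pct <- as.matrix(profiles[registry$code])
  as.numeric(pct %*% weights)
}

#' Unsaturation index
#'
#' Double-bond-weighted sum of the unsaturated fatty-acid percentages:
#' each monounsaturated percent counts once, then LA x2, DGLA x3, ARA x4,
#' EPA x5, DHA x6. Saturated members contribute nothing. Ranges from 0
#' (fully saturated) to 600 (pure DHA).
#'
#' @inheritParams family_totals
#' @return Numeric vector, one value per profile row.
#' @export
unsaturation_index <- function(profiles, registry = fa_cluster()) {
  profiles <- tibble::as_tibble(profiles)
  check_closure(profiles, registry)
  weighted_index(profiles, registry, registry$ui_weight)
}

#' Peroxidation index
#'
#' Oxidizability-weighted sum of the unsaturated fatty-acid percentages:
#' 0.025 per monounsaturated percent, then LA x1, DGLA x2, ARA x4, EPA x6,
#' DHA x8. Ranges from 0 to 800 (pure DHA).
#'
#' @inheritParams family_totals
#' @return Numeric vector, one value per profile row.
#' @export
peroxidation_index <- function(profiles, registry = fa_cluster()) {
  profiles <- tibble::as_tibble(profiles)
  check_closure(profiles, registry)
  weighted_index(profiles, registry, registry$pi_weight)
}

#' Full derived-parameter panel
#'
#' Computes all ten derived membrane parameters for each profile: the five
#' family totals, the two family ratios, the PUFA balance, and the
#' unsaturation and peroxidation indexes. Undefined ratios (zero
#' denominators) become `NA` so cohort summaries can proceed sample-wise.
#'
#' @inheritParams family_totals
#' @param keep_percentages Keep the ten fatty-acid percentage columns in the
#'   output (default `TRUE`).
#' @return A tibble with `sample_id`, optionally the ten percentages, and the
#'   ten derived columns (`total_sfa` through `peroxidation_index`).
#' @examples
#' profile <- tibble::tibble(
#'   sample_id = "s1", `C16:0` = 10, `C16:1` = 10, `C18:0` = 10,
#'   `9c-C18:1` = 10, `11c-C18:1` = 10, `C18:2` = 10, `C20:3` = 10,
#'   `C20:4` = 10, `C20:5` = 10, `C22:6` = 10
#' )
#' lipid_panel(profile)
#' @export
lipid_panel <- function(profiles, registry = fa_cluster(),
                        keep_percentages = TRUE) {
  profiles <- tibble::as_tibble(profiles)
  panel <- family_totals(profiles, registry) |>
    lipid_ratios(on_zero = "missing") |>
    dplyr::mutate(
      unsaturation_index = unsaturation_index(profiles, registry),
      peroxidation_index = peroxidation_index(profiles, registry)
    )
  if (keep_percentages) {
    dplyr::left_join(profiles[c("sample_id", registry$code)], panel,
                     by = "sample_id")
  } else {
    panel
  }
}
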