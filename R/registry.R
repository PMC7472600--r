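# Canonical 10-fatty-acid cluster registry.
#
# All downstream formulas (family totals, ratios, unsaturation and
# peroxidation indexes) are driven by this table, never by hard-coded
# fatty-acid lists, so a user can supply an alternative cluster through
# `read_cluster_yaml()` and every operation keeps working.

.fa_families <- c("SFA", "MUFA", "PUFA_n6", "PUFA_n3")

.default_cluster <- tibble::tibble(
  code         = c("C16:0", "C16:1", "C18:0", "9c-C18:1", "11c-C18:1",
                   "C18:2", "C20:3", "C20:4", "C20:5", "C22:6"),
  common_name  = c("palmitic acid", "palmitoleic acid", "stearic acid",
                   "oleic acid", "cis-vaccenic acid", "linoleic acid",
                   "dihomo-gamma-linolenic acid", "arachidonic acid",
                   "eicosapentaenoic acid", "docosahexaenoic acid"),
  acronym      = c(NA, NA, NA, NA, NA, "LA", "DGLA", "ARA", "EPA", "DHA"),
  carbons      = c(16L, 16L, 18L, 18L, 18L, 18L, 20L, 20L, 20L, 22L),
  double_bonds = c(0L, 1L, 0L, 1L, 1L, 2L, 3L, 4L, 5L, 6L),
  family       = c("SFA", "MUFA", "SFA", "MUFA", "MUFA",
                   "PUFA_n6", "PUFA_n6", "PUFA_n6", "PUFA_n3", "PUFA_n3"),
  ui_weight    = c(0, 1, 0, 1, 1, 2, 3, 4, 5, 6),
  pi_weight    = c(0, 0.025, 0, 0.025, 0.025, 1, 2, 4, 6, 8)
)

#' The 10-fatty-acid membrane cluster
#'
#' Returns the definition of the fixed 10-fatty-acid cluster used for
#' erythrocyte membrane profiling: two saturated (palmitic, stearic), three
#' monounsaturated (palmitoleic, oleic, cis-vaccenic), three omega-6
#' polyunsaturated (LA, DGLA, ARA) and two omega-3 polyunsaturated (EPA, DHA)
#' fatty acids, in gas-chromatography elution order. Each row carries the
#' per-acid weights of the unsaturation index (number of double bonds on the
#' unsaturated members) and of the peroxidation index (oxidizability weights:
#' 0.025 per monounsaturated percent, then 1, 2, 4, 6, 8 for LA, DGLA, ARA,
#' EPA, DHA).
#'
#' @return A tibble with one row per fatty acid and columns `code`,
#'   `common_name`, `acronym`, `carbons`, `double_bonds`, `family`
#'   (one of `"SFA"`, `"MUFA"`, `"PUFA_n6"`, `"PUFA_n3"`), `ui_weight`,
#'   `pi_weight`.
#' @examples
#' fa_cluster()
#' @export
fa_cluster <- function() {
  .default_cluster
}

#' Validate a fatty-acid registry
#'
#' Checks the structural invariants every registry must satisfy: unique codes,
#' known families, saturated members carrying zero index weights and
#' unsaturated members carrying positive ones.
#'
#' @param registry A data frame shaped like [fa_cluster()].
#' @return The registry, invisibly, as a tibble; errors on violation.
#' @export
validate_registry <- function(registry) {
  registry <- tibble::as_tibble(registry)
  required <- c("code", "common_name", "family", "double_bonds",
                "ui_weight", "pi_weight")
  missing <- setdiff(required, names(registry))
  if (length(missing) > 0) {
    rlang::abort(paste0("invalid registry: missing columns ",
                        paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(registry$code)) {
    rlang::abort("invalid registry: duplicated fatty-acid codes")
  }
  if (!all(registry$family %in% .fa_families)) {
    rlang::abort("invalid registry: unknown fatty-acid family")
  }
  sat <- registry$family == "SFA"
  if (!all(registry$double_bonds[sat] == 0) ||
      !all(registry$ui_weight[sat] == 0) ||
      !all(registry$pi_weight[sat] == 0)) {
    rlang::abort("invalid registry: saturated members must carry zero weights")
  }
  if (!all(registry$double_bonds[!sat] > 0) ||
      !all(registry$ui_weight[!sat] > 0) ||
      !all(registry$pi_weight[!sat] > 0)) {
    rlang::abort("invalid registry: unsaturated members need positive weights")
  }
  invisible(registry)
}

# Synonym map: accepted spellings -> canonical code. Covers the comma forms
# used in printed tables ("9c,C18:1"), PUFA acronyms, and common names.
.fa_synonyms <- local({
  reg <- .default_cluster
  syn <- c(
    stats::setNames(reg$code, reg$code),
    stats::setNames(reg$code[!is.na(reg$acronym)],
                    reg$acronym[!is.na(reg$acronym)]),
    stats::setNames(reg$code, reg$common_name),
    "9c,C18:1"  = "9c-C18:1",
    "11c,C18:1" = "11c-C18:1",
    "AA"        = "C20:4",
    "vaccenic acid" = "11c-C18:1",
    "dihomogammalinolenic acid" = "C20:3"
  )
  syn[!duplicated(names(syn))]
})

#' Normalise fatty-acid codes
#'
#' Maps accepted spellings (comma-separated positional prefixes such as
#' `"9c,C18:1"`, PUFA acronyms such as `"ARA"`, and common names) to the
#' canonical hyphenated codes of [fa_cluster()]. The sentinel `"other"`
#' (any case), used in peak tables for non-cluster area, passes through
#' unchanged.
#'
#' @param codes Character vector of fatty-acid labels.
#' @param strict If `TRUE` (default), unknown labels raise an error; if
#'   `FALSE` they are returned unchanged.
#' @return Character vector of canonical codes.
#' @examples
#' normalize_fa_codes(c("9c,C18:1", "ARA", "C16:0"))
#' @export
normalize_fa_codes <- function(codes, strict = TRUE) {
  out <- as.character(codes)
  is_other <- tolower(out) == "other"
  out[is_other] <- "other"
  hit <- !is_other & out %in% names(.fa_synonyms)
  out[hit] <- unname(.fa_synonyms[out[hit]])
  unknown <- !is_other & !hit & !(out %in% .default_cluster$code)
  if (any(unknown) && strict) {
    rlang::abort(paste0("unknown fatty-acid code(s): ",
                        paste(unique(out[unknown]), collapse = ", ")))
  }
  out
}

#' Read a cluster definition from YAML
#'
#' Loads a fatty-acid registry from a YAML file holding a `cluster:` list of
#' entries with fields `code`, `common_name`, `acronym` (optional),
#' `carbons`, `double_bonds`, `family`, `ui_weight`, `pi_weight`. The file
#' shipped at `system.file("extdata", "cluster.yaml", package = "lipidbench")`
#' reproduces the default 10-acid cluster exactly.
#'
#' @param path Path to a YAML file.
#' @return A validated registry tibble.
#' @export
read_cluster_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$cluster)) {
    rlang::abort("invalid registry: YAML file has no `cluster:` block")
  }
  registry <- purrr::map_dfr(doc$cluster, function(e) {
    tibble::tibble(
      code         = as.character(e$code),
      common_name  = as.character(e$common_name %||% NA_character_),
      acronym      = as.character(e$acronym %||% NA_character_),
      carbons      = as.integer(e$carbons %||% NA_integer_),
      double_bonds = as.integer(e$double_bonds),
      family       = as.character(e$family),
      ui_weight    = as.numeric(e$ui_weight),
      pi_weight    = as.numeric(e$pi_weight)
    )
  })
  validate_registry(registry)
  registry
}

# Percent columns of a registry inside a wide profile table.
registry_codes <- function(registry = fa_cluster()) registry$code
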