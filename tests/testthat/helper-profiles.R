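# Shared fixtures, built in code.

fa_codes <- lipidbench::fa_cluster()$code

# A wide one-row profile tibble from a named or unnamed percentage vector.
make_profile <- function(pct, id = "s1") {
  if (is.null(names(pct))) names(pct) <- fa_codes
  dplyr::bind_cols(tibble::tibble(sample_id = id),
                   tibble::as_tibble(as.list(pct)))
}

# The published per-sex mean columns as printed (no closure rescale).
printed_means <- list(
  m = c(15.88, 0.35, 19.62, 10.07, 1.93, 15.29, 1.36, 33.65, 0.76, 1.10),
  f = c(15.38, 0.24, 21.09, 9.62, 2.06, 14.11, 1.28, 34.33, 0.70, 1.20)
)

# Random valid profile table (rows close to 100 exactly).
random_profiles <- function(n, seed = 1) {
  withr::with_seed(seed, {
    g <- matrix(stats::rexp(n * 10), n, 10)
    pct <- 100 * g / rowSums(g)
    colnames(pct) <- fa_codes
    dplyr::bind_cols(tibble::tibble(sample_id = sprintf("s%02d", seq_len(n))),
                     tibble::as_tibble(pct))
  })
}

small_spec <- function(seed = 1, ...) lipidbench::cohort_spec(seed = seed, ...)
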