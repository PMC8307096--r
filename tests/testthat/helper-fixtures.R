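# Shared fixture builders. Everything is generated in code; chain settings
# are kept small (n_kept = 1000-2000, thin = 2) so the posterior machinery
# is exercised at test scale without hour-long chains.

small_cohort <- function(seed = 1L, ...) {
  generate_cohort(synthetic_config(seed = seed, ...))
}

# Minimal hand-written two-row cohort data frame (one participant per group).
two_row_records <- function() {
  tibble::tibble(
    id = c("P1", "P2"), group = c("CHR", "HC"),
    gsh = c(1.8, 1.5), gsh_crlb = c(9, 12),
    sofas = c(65, 85), sops_total = c(10, NA),
    cast = c(12, 6), audit_c = c(5, 6),
    age = c(22.5, 21.0), gender = c("male", "female")
  )
}

fast_chain <- list(n_kept = 1000L, thin = 2L, burn_in = 300L)

# Cohort payload without the provenance attribute, for content comparisons.
cohort_data <- function(x) {
  d <- as.data.frame(x)
  attr(d, "provenance") <- NULL
  d
}
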