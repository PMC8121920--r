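# Shared settings for the analysis scripts. Every script regenerates the
# cohort deterministically from COHORT_SEED, so the scripts can be run
# independently or in order.

library(ascap)

COHORT_SEED <- 2024L
N_SNVS <- 20000L
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

cohort_config <- function() {
  sim_config(n_snvs = N_SNVS, fraction_causal = 0.05, p_shared = 0.5,
             seed = COHORT_SEED)
}

get_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(cohort_config())
    cache
  }
})

calls_at_level <- function(cohort, level) {
  pooled <- pool_counts(cohort$counts, cohort$scheme, level)
  nulls <- fit_nulls(pooled)
  call_imbalance(pooled, nulls, level = level)
}
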