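# Statistical benchmark of the imbalance caller on synthetic cohorts with
# known ground truth.

#' Empirical false-discovery proportion of the imbalance caller
#'
#' Generates synthetic cohorts with a known causal structure (default: 5%
#' truly imbalanced SNVs with effect magnitude at least 0.15, dispersion
#' matched between generator and test), runs the per-cell-type imbalance
#' analysis at its default thresholds, and measures the realized
#' false-discovery proportion among flagged calls: a flagged (SNV, cell
#' type) is a false positive when its true allelic ratio in that cell type
#' is 0.5.
#'
#' @param n_snvs SNVs per cohort (default 50000).
#' @param n_seeds Number of independent cohorts (default 20).
#' @param base_seed Seeds used are `base_seed + 0:(n_seeds-1)`.
#' @param fraction_causal,effect_range,rho Generator settings (defaults: 5%
#'   causal, `|theta - 0.5|` in `[0.15, 0.45]`, rho 0.02).
#' @param fdr,ratio,min_reads Caller thresholds (defaults 0.10, 0.70, 30).
#' @return List: `per_seed` (data.frame `seed`, `n_flagged`, `n_false`,
#'   `fdp`), `mean_fdp` (mean over seeds), `mc_se` (Monte-Carlo standard
#'   error of the per-seed mean).
#' @export
empirical_fdr_benchmark <- function(n_snvs = 50000, n_seeds = 20,
                                    base_seed = 1, fraction_causal = 0.05,
                                    effect_range = c(0.15, 0.45),
                                    rho = 0.02, fdr = 0.10, ratio = 0.70,
                                    min_reads = 30) {
  rows <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    seed <- base_seed + i - 1L
    cfg <- sim_config(n_snvs = n_snvs, fraction_causal = fraction_causal,
                      effect_range = effect_range, rho = rho, seed = seed)
    ch <- simulate_cohort(cfg)
    pooled <- pool_counts(ch$counts, ch$scheme, "cell_type")
    nulls <- fit_nulls(pooled)
    calls <- call_imbalance(pooled, nulls, fdr = fdr, ratio = ratio,
                            min_reads = min_reads, level = "cell_type")
    te <- ch$true_effects
    truth <- te$theta[match(paste(calls$snv_id, calls$group_id),
                            paste(te$snv_id, te$cell_type))]
    fl <- calls$imbalanced
    rows[[i]] <- data.frame(seed = seed, n_flagged = sum(fl),
                            n_false = sum(fl & truth == 0.5),
                            fdp = if (sum(fl)) mean(truth[fl] == 0.5) else
                              NA_real_)
  }
  per_seed <- do.call(rbind, rows)
  fdp <- per_seed$fdp[!is.na(per_seed$fdp)]
  list(per_seed = per_seed, mean_fdp = mean(fdp),
       mc_se = sd(fdp) / sqrt(length(fdp)))
}
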