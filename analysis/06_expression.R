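#!/usr/bin/env Rscript
# Linking allelic accessibility to allelic transcript levels: transcript
# counts coupled to nearby DHS effects through a 10-kb exponential kernel,
# transcript-level imbalance calls, and the Pearson correlation of DHS and
# transcript allelic ratios by signed distance to the TSS with a
# 1000-permutation 95% null band.

source("analysis/00_config.R")

ch <- get_cohort()

set.seed(COHORT_SEED)
n_tss <- 400L
i <- sample(nrow(ch$dhs), n_tss)
d <- ch$dhs[i, ]
tss <- data.frame(transcript_id = paste0("tx_", d$name), chrom = d$chrom,
                  tss = as.integer((d$start + d$end) / 2 +
                                     sample(-30000:30000, n_tss, TRUE)),
                  strand = sample(c("+", "-"), n_tss, TRUE),
                  stringsAsFactors = FALSE)

expr <- simulate_linked_expression(ch$true_effects, ch$snvs, ch$dhs, tss,
                                   kernel = 10000, depth_mu = 150,
                                   seed = COHORT_SEED + 1L)
rho_by_ct <- setNames(rep_len(ch$config$rho, length(ch$config$cell_types)),
                      ch$config$cell_types)
rna_calls <- call_rna_imbalance(expr$counts, rho = rho_by_ct)
message(sprintf("transcripts tested: %d; imbalanced: %d",
                nrow(rna_calls), sum(rna_calls$imbalanced)))

ct_calls <- calls_at_level(ch, "cell_type")
dhs_ratios <- ascap:::dhs_ratio_table(ch, ct_calls)
rna_ratios <- data.frame(transcript_id = rna_calls$snv_id,
                         condition_id = rna_calls$group_id,
                         tx_ratio = rna_calls$allelic_ratio,
                         stringsAsFactors = FALSE)
pairs <- pair_dhs_tss(dhs_ratios, tss, rna_ratios)
message(sprintf("DHS-TSS pairs within 500 kb: %d", nrow(pairs)))

curve <- distance_binned_correlation(pairs)
band <- permutation_band(pairs, n_perm = 1000, seed = COHORT_SEED)
out <- cbind(curve, band[c("band_lo", "band_hi")])
near <- out[abs(out$bin_lo) <= 10000 & out$bin_hi <= 10000 &
              out$bin_lo >= -10000, ]
message(sprintf("correlation within 10 kb of the TSS: %.2f to %.2f",
                min(near$r, na.rm = TRUE), max(near$r, na.rm = TRUE)))
print(out)

write_results(list(rna_calls = rna_calls, pairs = pairs,
                   distance_correlation = out),
              file.path(RESULTS_DIR, "expression"))
message("wrote expression tables under ", RESULTS_DIR, "/")
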