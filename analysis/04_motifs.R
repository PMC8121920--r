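#!/usr/bin/env Rscript
# TF-centric view of the imbalanced variation: per-position sensitivity
# profiles over each motif, the QC filter, core-vs-flank enrichment in
# aggregate and per cell type, footprint-stratified imbalance rates, and
# the overall fraction of imbalanced SNVs explained by motif matches.

source("analysis/00_config.R")

ch <- get_cohort()

agg <- calls_at_level(ch, "aggregate")
status <- merge(agg[c("snv_id", "imbalanced")],
                ch$snvs[c("snv_id", "chrom", "pos")], by = "snv_id")

profiles <- list(); enrich <- list(); qc <- list()
for (m in ch$motifs$motif_id) {
  w <- ch$motifs$width[ch$motifs$motif_id == m]
  prof <- build_position_profile(status, ch$motif_matches, m, width = w)
  profiles[[m]] <- prof
  qc[[m]] <- data.frame(motif_id = m, qc_pass = motif_qc_filter(prof))
  enrich[[m]] <- core_flank_enrichment(status, ch$motif_matches, m)
}
profiles <- do.call(rbind, profiles)
enrich <- do.call(rbind, enrich)
qc <- do.call(rbind, qc)
message(sprintf("%d / %d motifs pass the profile QC filter",
                sum(qc$qc_pass), nrow(qc)))
message(sprintf("median core-vs-flank log2 enrichment: %.2f",
                median(enrich$log2_enrichment)))

strat <- footprint_stratified_rates(status, ch$footprints, ch$motif_matches)
print(strat)

ov <- overall_motif_overlap(status, ch$motif_matches)
message(sprintf("%.1f%% of imbalanced SNVs overlap stringent motif matches (%d / %d)",
                100 * ov$fraction, ov$n_overlapping, ov$n_imbalanced))

write_results(list(profiles = profiles, qc = qc, enrichment = enrich,
                   stratified_rates = strat),
              file.path(RESULTS_DIR, "motifs"))
message("wrote motif tables under ", RESULTS_DIR, "/")
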