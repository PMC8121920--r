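#!/usr/bin/env Rscript
# Generate the synthetic F1-hybrid cohort that every downstream analysis
# consumes: SNVs in and out of DHS hotspots across 5 strains and 4 cell
# types, beta-binomial allele counts around condition-specific true ratios,
# and a motif architecture carrying the causal variants.

source("analysis/00_config.R")

ch <- get_cohort()

n_ct <- length(ch$config$cell_types)
message(sprintf("cohort: %d SNVs (%d in DHSs), %d samples, %d causal",
                nrow(ch$snvs), sum(ch$snvs$in_dhs), nrow(ch$scheme),
                sum(ch$true_effects$causal) / n_ct))

part <- restrict_to_hotspots(ch$snvs, ch$dhs)
message(sprintf("testable (in-hotspot) SNVs: %d; background: %d",
                nrow(part$testable), nrow(part$background)))

write_results(list(
  snvs = ch$snvs[c("chrom", "pos", "ref_allele", "alt_allele", "strain_id",
                   "snv_id")],
  counts = ch$counts,
  scheme = ch$scheme,
  true_effects = ch$true_effects,
  dhs = ch$dhs,
  motif_matches = ch$motif_matches,
  mappability = ch$mappability),
  file.path(RESULTS_DIR, "cohort"))

message("wrote cohort tables under ", RESULTS_DIR, "/")
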