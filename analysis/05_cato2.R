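#!/usr/bin/env Rscript
# Two-stage variant-impact scoring: a global logistic model on genomic
# annotations, per-TF motif-disruption models, and a lasso combiner;
# evaluated by precision-recall against the cohort's known causal labels,
# comparing cell-type-specific and aggregate training.

source("analysis/00_config.R")

ch <- get_cohort()

train_eval <- function(calls, label) {
  status <- merge(calls[c("snv_id", "imbalanced")],
                  ch$snvs[c("snv_id", "chrom", "pos")], by = "snv_id")
  ann <- ch$annotations[match(status$snv_id, ch$annotations$snv_id), ]
  tf <- ascap:::build_tf_features(ch, status)
  bundle <- train_cato2(ann, status$imbalanced, tf$feats, tf$labels,
                        nfolds = 10, seed = COHORT_SEED, min_rows = 25)
  sc <- score_variants(bundle, ann, tf$feats)
  te <- ch$true_effects[!duplicated(ch$true_effects$snv_id), ]
  truth <- te$causal[match(sc$snv_id, te$snv_id)]
  pr <- precision_recall(sc$score, truth)
  message(sprintf("%-10s AUPR %.3f (baseline %.3f; %d TF models, %d non-zero combiner terms)",
                  label, pr$auprc, pr$baseline, length(bundle$tf_models),
                  bundle$combiner$n_nonzero))
  list(scores = sc, pr = pr, bundle = bundle)
}

agg <- train_eval(calls_at_level(ch, "aggregate"), "aggregate")

# The value of cell-type-specific training shows on a cohort whose causal
# effects are private to single cell types (aggregation dilutes them);
# compare both training modes there against the cell type's own truth.
message("-- cell-type-specific architecture (no shared effects) --")
ch_ct <- simulate_cohort(sim_config(n_snvs = N_SNVS, fraction_causal = 0.08,
                                    p_shared = 0, depth_mu = 80,
                                    cell_types = c("liver", "kidney"),
                                    seed = COHORT_SEED + 2L))
eval_on <- function(cohort, calls, label, truth_ct) {
  status <- merge(calls[c("snv_id", "imbalanced")],
                  cohort$snvs[c("snv_id", "chrom", "pos")], by = "snv_id")
  ann <- cohort$annotations[match(status$snv_id,
                                  cohort$annotations$snv_id), ]
  tf <- ascap:::build_tf_features(cohort, status)
  bundle <- train_cato2(ann, status$imbalanced, tf$feats, tf$labels,
                        nfolds = 10, seed = COHORT_SEED, min_rows = 15)
  sc <- score_variants(bundle, ann, tf$feats)
  te <- cohort$true_effects[cohort$true_effects$cell_type == truth_ct, ]
  truth <- te$theta[match(sc$snv_id, te$snv_id)] != 0.5
  pr <- precision_recall(sc$score, truth)
  message(sprintf("%-10s AUPR %.3f (baseline %.3f)", label, pr$auprc,
                  pr$baseline))
  pr
}
ct_calls2 <- calls_at_level(ch_ct, "cell_type")
liver2 <- ct_calls2[ct_calls2$group_id == "liver", ]
pr_ct <- eval_on(ch_ct, liver2, "cell_type", "liver")
pr_agg <- eval_on(ch_ct, calls_at_level(ch_ct, "aggregate"), "aggregate",
                  "liver")

write_results(list(
  scores_aggregate = agg$scores,
  pr_aggregate = agg$pr$curve,
  pr_celltype_specific = pr_ct$curve,
  pr_aggregate_on_specific = pr_agg$curve),
  file.path(RESULTS_DIR, "cato2"))
message("wrote scoring tables under ", RESULTS_DIR, "/")
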