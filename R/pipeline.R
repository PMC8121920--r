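# End-to-end orchestration over synthetic data: simulate -> imbalance at all
# pooling levels -> sharing -> motif profiles -> variant scoring ->
# expression linkage, with a manifest of produced files and content hashes.

#' @importFrom stats quantile cor sd
#' @importFrom tools md5sum
NULL

#' Build and validate a pipeline configuration
#'
#' Thresholds default to the standard values of the analysis (FDR 0.10,
#' major-allele fraction 0.70 for accessibility and 0.60 for transcripts,
#' 30/50 minimum reads, dispersion fit above 100 reads) and are never
#' hard-coded in stage logic. Round-trips through YAML unchanged.
#'
#' @param outdir Output directory.
#' @param seed Seed used for simulation and permutation stages.
#' @param n_snvs Cohort size for the simulation stage.
#' @param fdr,ratio,min_reads Imbalance thresholds.
#' @param rna_ratio,rna_min_reads Transcript-level thresholds.
#' @param min_fit_depth Dispersion-fit depth threshold (exclusive bound + 1).
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "imbalance", "sharing", "motifs", "cato2",
#'   "expression")`.
#' @param sim Optional list of extra arguments for [sim_config()].
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed, n_snvs = 10000, fdr = 0.10,
                            ratio = 0.70, min_reads = 30, rna_ratio = 0.60,
                            rna_min_reads = 50, min_fit_depth = 101,
                            stages = c("simulate", "imbalance", "sharing",
                                       "motifs", "cato2", "expression"),
                            sim = list()) {
  cfg <- list(outdir = outdir, seed = as.integer(seed),
              n_snvs = as.integer(n_snvs), fdr = fdr, ratio = ratio,
              min_reads = as.integer(min_reads), rna_ratio = rna_ratio,
              rna_min_reads = as.integer(rna_min_reads),
              min_fit_depth = as.integer(min_fit_depth), stages = stages,
              sim = sim)
  if (cfg$fdr <= 0 || cfg$fdr >= 1) stop("fdr must lie in (0, 1)")
  if (cfg$ratio < 0.5 || cfg$ratio >= 1) stop("ratio must lie in [0.5, 1)")
  if (cfg$rna_ratio < 0.5 || cfg$rna_ratio >= 1) {
    stop("rna_ratio must lie in [0.5, 1)")
  }
  if (cfg$min_reads < 1 || cfg$rna_min_reads < 1) {
    stop("minimum read thresholds must be positive")
  }
  bad <- setdiff(stages, c("simulate", "imbalance", "sharing", "motifs",
                           "cato2", "expression"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns the validated `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

#' Run the pipeline end-to-end
#'
#' Executes the enabled stages in dependency order on synthetic data and
#' writes TSV outputs under `config$outdir`, together with a manifest
#' recording every file, its MD5 content hash, and the thresholds and seed
#' actually used. Identical config (including seed) produces identical
#' manifest hashes.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, the manifest data.frame.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[ascap] ", ...)
  stages <- config$stages
  files <- character(0)
  t0 <- Sys.time()

  say("simulate: n_snvs=", config$n_snvs, " seed=", config$seed)
  sim_args <- c(list(n_snvs = config$n_snvs, seed = config$seed), config$sim)
  cohort <- simulate_cohort(do.call(sim_config, sim_args))
  if ("simulate" %in% stages) {
    files <- c(files, write_results(
      list(counts = cohort$counts, scheme = cohort$scheme,
           snvs = cohort$snvs[c("chrom", "pos", "ref_allele", "alt_allele",
                                "strain_id", "snv_id")],
           true_effects = cohort$true_effects),
      file.path(config$outdir, "sim")))
  }

  calls_by_level <- list()
  if (any(c("imbalance", "sharing", "motifs", "cato2",
            "expression") %in% stages)) {
    for (level in c("sample", "cell_type", "strain", "aggregate")) {
      pooled <- pool_counts(cohort$counts, cohort$scheme, level)
      nulls <- fit_nulls(pooled, min_fit_depth = config$min_fit_depth)
      calls_by_level[[level]] <- call_imbalance(
        pooled, nulls, fdr = config$fdr, ratio = config$ratio,
        min_reads = config$min_reads, level = level)
      say("imbalance[", level, "]: ", nrow(calls_by_level[[level]]),
          " tested, ", sum(calls_by_level[[level]]$imbalanced), " imbalanced")
    }
    if ("imbalance" %in% stages) {
      files <- c(files, write_results(
        setNames(calls_by_level,
                 paste0("calls_", names(calls_by_level))),
        file.path(config$outdir, "imbalance")))
    }
  }

  if ("sharing" %in% stages) {
    sh <- pairwise_sharing(calls_by_level$cell_type)
    sh_df <- as.data.frame(as.table(sh$sharing), stringsAsFactors = FALSE)
    names(sh_df) <- c("cond_a", "cond_b", "sharing")
    curve <- adjacent_ratio_correlation(
      calls_by_level$cell_type,
      cohort$snvs[c("snv_id", "chrom", "pos")],
      n_perm = 200, seed = config$seed)
    files <- c(files, write_results(
      list(sharing = sh_df, adjacent_correlation = curve),
      file.path(config$outdir, "sharing")))
    say("sharing: mean off-diagonal ",
        round(mean(sh$sharing[row(sh$sharing) != col(sh$sharing)],
                   na.rm = TRUE), 3))
  }

  snv_status <- NULL
  if (any(c("motifs", "cato2") %in% stages)) {
    agg <- calls_by_level$aggregate
    snv_status <- merge(
      agg[c("snv_id", "imbalanced")],
      cohort$snvs[c("snv_id", "chrom", "pos")], by = "snv_id")
  }
  if ("motifs" %in% stages) {
    profs <- do.call(rbind, lapply(cohort$motifs$motif_id, function(m) {
      build_position_profile(snv_status, cohort$motif_matches, m,
                             width = cohort$motifs$width[
                               match(m, cohort$motifs$motif_id)])
    }))
    enr <- do.call(rbind, lapply(cohort$motifs$motif_id, function(m) {
      core_flank_enrichment(snv_status, cohort$motif_matches, m)
    }))
    strat <- footprint_stratified_rates(snv_status, cohort$footprints,
                                        cohort$motif_matches)
    files <- c(files, write_results(
      list(profiles = profs, enrichment = enr, stratified_rates = strat),
      file.path(config$outdir, "motifs")))
    ov <- overall_motif_overlap(snv_status, cohort$motif_matches)
    say("motifs: ", round(100 * ov$fraction, 1),
        "% of imbalanced SNVs overlap stringent matches")
  }

  if ("cato2" %in% stages) {
    agg <- calls_by_level$aggregate
    ann <- cohort$annotations[cohort$annotations$snv_id %in% agg$snv_id, ]
    labels <- agg$imbalanced[match(ann$snv_id, agg$snv_id)]
    tf <- build_tf_features(cohort, snv_status)
    bundle <- train_cato2(ann, labels, tf$feats, tf$labels,
                          nfolds = 10, seed = config$seed)
    scores <- score_variants(bundle, ann, tf$feats)
    pr <- precision_recall(scores$score[match(ann$snv_id, scores$snv_id)],
                           labels)
    files <- c(files, write_results(list(scores = scores),
                                    file.path(config$outdir, "cato2")))
    say("cato2: AUPR ", round(pr$auprc, 3), " (baseline ",
        round(pr$baseline, 3), ")")
  }

  if ("expression" %in% stages) {
    tss <- synth_tss_from_dhs(cohort, n = min(200L, nrow(cohort$dhs)),
                              seed = config$seed)
    expr <- simulate_linked_expression(cohort$true_effects, cohort$snvs,
                                       cohort$dhs, tss,
                                       seed = config$seed + 1L)
    rna_calls <- call_rna_imbalance(expr$counts, fdr = config$fdr,
                                    ratio = config$rna_ratio,
                                    min_reads = config$rna_min_reads,
                                    rho = dhs_rho_defaults(cohort))
    dhs_ratios <- dhs_ratio_table(cohort, calls_by_level$cell_type)
    rna_ratios <- data.frame(transcript_id = rna_calls$snv_id,
                             condition_id = rna_calls$group_id,
                             tx_ratio = rna_calls$allelic_ratio,
                             stringsAsFactors = FALSE)
    pairs <- pair_dhs_tss(dhs_ratios, tss, rna_ratios)
    curve <- distance_binned_correlation(pairs)
    band <- permutation_band(pairs, n_perm = 200, seed = config$seed)
    files <- c(files, write_results(
      list(rna_calls = rna_calls, pairs = pairs,
           correlation = cbind(curve, band[c("band_lo", "band_hi")])),
      file.path(config$outdir, "expression")))
    say("expression: ", nrow(pairs), " DHS-TSS pairs")
  }

  manifest <- data.frame(
    file = basename(files),
    md5 = as.character(tools::md5sum(files)),
    stringsAsFactors = FALSE)
  meta <- data.frame(
    key = c("seed", "n_snvs", "fdr", "ratio", "min_reads", "rna_ratio",
            "rna_min_reads", "min_fit_depth", "elapsed_s"),
    value = c(config$seed, config$n_snvs, config$fdr, config$ratio,
              config$min_reads, config$rna_ratio, config$rna_min_reads,
              config$min_fit_depth,
              round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1)),
    stringsAsFactors = FALSE)
  write_results(list(manifest = manifest, run_meta = meta),
                file.path(config$outdir, "pipeline"))
  missing <- files[!file.exists(files) | file.size(files) == 0]
  if (length(missing)) stop("stage output missing or empty: ",
                            paste(basename(missing), collapse = ", "))
  say("done: ", length(files), " files in ", config$outdir)
  invisible(manifest)
}

# Per-cell-type dispersion defaults from the cohort config (used when the
# transcript set is too small to refit).
dhs_rho_defaults <- function(cohort) {
  cts <- cohort$config$cell_types
  setNames(rep_len(cohort$config$rho, length(cts)), cts)
}

# Synthetic TSS list anchored near a sample of DHSs (for the demo pipeline).
synth_tss_from_dhs <- function(cohort, n = 200, seed = 1) {
  set.seed(seed)
  i <- sample(nrow(cohort$dhs), n)
  d <- cohort$dhs[i, ]
  data.frame(transcript_id = paste0("tx_", d$name),
             chrom = d$chrom,
             tss = as.integer((d$start + d$end) / 2 +
                                sample(-20000:20000, n, replace = TRUE)),
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Per-(DHS, cell type) allelic ratio: counts of the DHS's tested SNVs summed
# within cell type.
dhs_ratio_table <- function(cohort, ct_calls) {
  sn <- cohort$snvs[!is.na(cohort$snvs$dhs_name),
                    c("snv_id", "dhs_name")]
  x <- merge(ct_calls, sn, by = "snv_id")
  if (nrow(x) == 0L) {
    return(data.frame(dhs_id = character(), chrom = character(),
                      midpoint = numeric(), condition_id = character(),
                      dhs_ratio = numeric(), stringsAsFactors = FALSE))
  }
  key <- paste(x$dhs_name, x$group_id, sep = "\r")
  ref <- rowsum(x$ref_count, key, reorder = FALSE)
  tot <- rowsum(x$ref_count + x$nonref_count, key, reorder = FALSE)
  first <- !duplicated(key)
  d <- cohort$dhs[match(x$dhs_name[first], cohort$dhs$name), ]
  data.frame(dhs_id = x$dhs_name[first], chrom = d$chrom,
             midpoint = (d$start + d$end) / 2,
             condition_id = x$group_id[first],
             dhs_ratio = as.numeric(ref[, 1] / tot[, 1]),
             stringsAsFactors = FALSE)
}

# Per-TF feature frames for CATO2 training on a synthetic cohort: SNVs
# overlapping each motif's matches, with match score, a log-odds difference
# proxy, and the SNV's position in the motif.
build_tf_features <- function(cohort, snv_status) {
  asg <- assign_best_instances(snv_status, cohort$motif_matches)
  feats <- list(); labels <- list()
  for (mid in unique(asg$motif_id)) {
    a <- asg[asg$motif_id == mid, ]
    mrow <- cohort$motif_matches[a$match_row, ]
    te <- cohort$true_effects[!duplicated(cohort$true_effects$snv_id), ]
    causal_here <- te$causal[match(a$snv_id, te$snv_id)] &
      !is.na(te$causal_motif_id[match(a$snv_id, te$snv_id)]) &
      te$causal_motif_id[match(a$snv_id, te$snv_id)] == mid
    lo <- ifelse(causal_here, rnorm(nrow(a), 3, 1), rnorm(nrow(a), 0, 1))
    feats[[mid]] <- data.frame(snv_id = a$snv_id, score = mrow$score,
                               logodds_diff = lo, position = a$position,
                               stringsAsFactors = FALSE)
    labels[[mid]] <- snv_status$imbalanced[
      match(a$snv_id, snv_status$snv_id)]
  }
  list(feats = feats, labels = labels)
}
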