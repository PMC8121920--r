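#' @importFrom stats qnorm
NULL

# Intersection of tested SNVs with TF motif matches: per-position
# sensitivity profiles, core-vs-flank and per-cell-type enrichments,
# footprint-stratified imbalance rates, and overall motif overlap.

#' Deduplicate a union of motif-match sets
#'
#' Motif matches from reference and strain-specific genome scans are pooled;
#' duplicates sharing (motif_id, chrom, start, strand) are collapsed to a
#' single record (the one with the smallest match p-value).
#'
#' @param matches data.frame (`motif_id`, `chrom`, `start`, `end`, `strand`,
#'   `score`, `p_value`).
#' @return Deduplicated data.frame.
#' @export
dedupe_motif_matches <- function(matches) {
  o <- order(matches$motif_id, matches$chrom, matches$start, matches$strand,
             matches$p_value)
  m <- matches[o, , drop = FALSE]
  key <- paste(m$motif_id, m$chrom, m$start, m$strand, sep = "\r")
  m <- m[!duplicated(key), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Best motif instance for one SNV
#'
#' Among overlapping matches of one motif, returns the instance with the
#' smallest match p-value; exact ties broken by leftmost start, then `+`
#' strand.
#'
#' @param snv One-row SNV data.frame (`chrom`, `pos`).
#' @param matches data.frame of matches of a single motif.
#' @return The selected one-row match.
#' @export
best_instance_per_snv <- function(snv, matches) {
  ov <- matches[matches$chrom == snv$chrom & matches$start <= snv$pos &
                  snv$pos < matches$end, , drop = FALSE]
  if (nrow(ov) == 0L) stop("no overlapping motif instance for this SNV")
  o <- order(ov$p_value, ov$start, ov$strand != "+")
  ov[o[1L], , drop = FALSE]
}

# Vectorized (SNV, motif) -> best-instance assignment. Returns one row per
# (snv_id, motif_id) pair with the position of the SNV in motif orientation.
assign_best_instances <- function(snvs, matches) {
  if (nrow(snvs) == 0L || nrow(matches) == 0L) {
    return(data.frame(snv_id = character(), motif_id = character(),
                      match_row = integer(), position = integer(),
                      stringsAsFactors = FALSE))
  }
  q <- GenomicRanges::GRanges(snvs$chrom,
                              IRanges::IRanges(snvs$pos + 1L, width = 1L))
  s <- GenomicRanges::GRanges(matches$chrom,
                              IRanges::IRanges(matches$start + 1L,
                                               matches$end))
  hits <- GenomicRanges::findOverlaps(q, s)
  if (length(hits) == 0L) {
    return(data.frame(snv_id = character(), motif_id = character(),
                      match_row = integer(), position = integer(),
                      stringsAsFactors = FALSE))
  }
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  df <- data.frame(snv_i = qi, match_row = si,
                   motif_id = matches$motif_id[si],
                   p_value = matches$p_value[si],
                   start = matches$start[si],
                   plus = matches$strand[si] == "+")
  # best instance per (SNV, motif): min p, then leftmost, then + strand
  o <- order(df$snv_i, df$motif_id, df$p_value, df$start, !df$plus)
  df <- df[o, ]
  key <- paste(df$snv_i, df$motif_id, sep = "\r")
  df <- df[!duplicated(key), ]
  pos <- snvs$pos[df$snv_i]
  st <- matches$start[df$match_row]; en <- matches$end[df$match_row]
  position <- ifelse(matches$strand[df$match_row] == "-",
                     (en - 1L) - pos, pos - st)
  data.frame(snv_id = snvs$snv_id[df$snv_i], motif_id = df$motif_id,
             match_row = df$match_row, position = as.integer(position),
             stringsAsFactors = FALSE)
}

#' Per-position motif sensitivity profile
#'
#' Tallies tested and imbalanced SNVs at each position of one motif, in
#' motif orientation (positions of minus-strand matches are mirrored). For
#' SNVs overlapping multiple instances of the motif, the best instance by
#' match p-value is used. Positions with fewer than `min_tested` SNVs are
#' flagged as missing data.
#'
#' @param snv_status data.frame (`snv_id`, `chrom`, `pos`, `imbalanced`),
#'   one row per tested SNV at the analysis's pooling level.
#' @param matches Motif-match table (may contain several motifs).
#' @param motif_id The motif to profile.
#' @param width Motif width; default inferred from the matches.
#' @param min_tested Missing-data threshold per position (default 7).
#' @return data.frame: `motif_id`, `position` (0-based, motif orientation),
#'   `n_tested`, `n_imbalanced`, `missing`.
#' @export
build_position_profile <- function(snv_status, matches, motif_id,
                                   width = NULL, min_tested = 7) {
  mm <- matches[matches$motif_id == motif_id, , drop = FALSE]
  if (is.null(width)) {
    if (nrow(mm) == 0L) stop("no matches for motif ", motif_id,
                             " and no width given")
    w <- unique(mm$end - mm$start)
    if (length(w) > 1L) stop("inconsistent match widths for motif ", motif_id)
    width <- w
  }
  prof <- data.frame(motif_id = motif_id, position = 0:(width - 1L),
                     n_tested = 0L, n_imbalanced = 0L,
                     stringsAsFactors = FALSE)
  if (nrow(mm) > 0L && nrow(snv_status) > 0L) {
    asg <- assign_best_instances(snv_status, mm)
    if (nrow(asg) > 0L) {
      tt <- table(factor(asg$position, levels = 0:(width - 1L)))
      imb <- snv_status$imbalanced[match(asg$snv_id, snv_status$snv_id)]
      ti <- table(factor(asg$position[imb], levels = 0:(width - 1L)))
      prof$n_tested <- as.integer(tt)
      prof$n_imbalanced <- as.integer(ti)
    }
  }
  prof$missing <- prof$n_tested < min_tested
  prof
}

#' Motif profile quality filter
#'
#' A profile passes when the median over positions of tested SNVs is at
#' least `min_median_tested` and at least `min_positions` positions carry at
#' least `min_sig` significant (imbalanced) SNVs.
#'
#' @param profile Output of [build_position_profile()].
#' @param min_median_tested Default 40.
#' @param min_positions Default 3.
#' @param min_sig Default 7.
#' @return Logical.
#' @export
motif_qc_filter <- function(profile, min_median_tested = 40,
                            min_positions = 3, min_sig = 7) {
  if (nrow(profile) == 0L) return(FALSE)
  median(profile$n_tested) >= min_median_tested &&
    sum(profile$n_imbalanced >= min_sig) >= min_positions
}

# Tally tested/imbalanced SNVs in the +-flank_bp flanks outside the best
# matches of one motif (excluding positions inside any match of that motif).
flank_tallies <- function(snv_status, matches, motif_id, flank_bp = 10) {
  mm <- matches[matches$motif_id == motif_id, , drop = FALSE]
  if (nrow(mm) == 0L || nrow(snv_status) == 0L) {
    return(c(n_tested = 0L, n_imbalanced = 0L))
  }
  q <- GenomicRanges::GRanges(snv_status$chrom,
                              IRanges::IRanges(snv_status$pos + 1L,
                                               width = 1L))
  core <- GenomicRanges::GRanges(mm$chrom,
                                 IRanges::IRanges(mm$start + 1L, mm$end))
  fl <- GenomicRanges::GRanges(
    rep(mm$chrom, 2L),
    IRanges::IRanges(c(pmax(1L, mm$start - flank_bp + 1L), mm$end + 1L),
                     c(mm$start, mm$end + flank_bp)))
  in_flank <- IRanges::overlapsAny(q, fl) & !IRanges::overlapsAny(q, core)
  c(n_tested = sum(in_flank),
    n_imbalanced = sum(in_flank & snv_status$imbalanced))
}

#' Core-vs-flank enrichment of imbalance for one motif
#'
#' log2 ratio of the imbalance rate among tested SNVs inside the motif match
#' (core) versus the `+-flank_bp` flanking windows, with a Haldane-Anscombe
#' pseudocount keeping the statistic finite:
#' `log2[((imb_core + psi)/(tested_core + psi)) /
#'        ((imb_flank + psi)/(tested_flank + psi))]`.
#'
#' @param snv_status data.frame (`snv_id`, `chrom`, `pos`, `imbalanced`).
#' @param matches Motif-match table.
#' @param motif_id Motif to evaluate.
#' @param flank_bp Flank width outside the match (default 10).
#' @param pseudocount psi (default 0.5).
#' @param scope Label recorded in the output (default `"aggregate"`).
#' @return data.frame: `motif_id`, `scope`, `log2_enrichment`,
#'   `n_tested_core`, `n_imbalanced_core`, `n_tested_flank`,
#'   `n_imbalanced_flank`.
#' @export
core_flank_enrichment <- function(snv_status, matches, motif_id,
                                  flank_bp = 10, pseudocount = 0.5,
                                  scope = "aggregate") {
  mm <- matches[matches$motif_id == motif_id, , drop = FALSE]
  core <- c(n_tested = 0L, n_imbalanced = 0L)
  if (nrow(mm) > 0L && nrow(snv_status) > 0L) {
    asg <- assign_best_instances(snv_status, mm)
    imb <- snv_status$imbalanced[match(asg$snv_id, snv_status$snv_id)]
    core <- c(n_tested = nrow(asg), n_imbalanced = sum(imb))
  }
  fl <- flank_tallies(snv_status, matches, motif_id, flank_bp)
  psi <- pseudocount
  enr <- log2(((core["n_imbalanced"] + psi) / (core["n_tested"] + psi)) /
                ((fl["n_imbalanced"] + psi) / (fl["n_tested"] + psi)))
  data.frame(motif_id = motif_id, scope = scope,
             log2_enrichment = as.numeric(enr),
             n_tested_core = as.integer(core["n_tested"]),
             n_imbalanced_core = as.integer(core["n_imbalanced"]),
             n_tested_flank = as.integer(fl["n_tested"]),
             n_imbalanced_flank = as.integer(fl["n_imbalanced"]),
             stringsAsFactors = FALSE)
}

#' Per-cell-type motif enrichment and the model-training gate
#'
#' Computes the core-vs-flank enrichment statistic within each cell type's
#' calls, plus the boolean gate used to select cell types for per-TF model
#' training: log2 enrichment strictly greater than 1 (i.e. more than
#' two-fold). Cell types with no tested SNVs in the motif are masked.
#'
#' @param snv_status_by_ct Named list of per-cell-type `snv_status` frames.
#' @param matches Motif-match table.
#' @param motif_id Motif to evaluate.
#' @param flank_bp,pseudocount As in [core_flank_enrichment()].
#' @param gate_threshold Gate on log2 enrichment (default 1, strict).
#' @return data.frame with one row per cell type: enrichment columns plus
#'   `gate` (logical, `NA` when masked).
#' @export
celltype_enrichment <- function(snv_status_by_ct, matches, motif_id,
                                flank_bp = 10, pseudocount = 0.5,
                                gate_threshold = 1) {
  rows <- lapply(names(snv_status_by_ct), function(ct) {
    e <- core_flank_enrichment(snv_status_by_ct[[ct]], matches, motif_id,
                               flank_bp, pseudocount, scope = ct)
    if (e$n_tested_core == 0L) {
      e$log2_enrichment <- NA_real_
      e$gate <- NA
    } else {
      e$gate <- e$log2_enrichment > gate_threshold
    }
    e
  })
  do.call(rbind, rows)
}

# Wilson 95% score interval for a binomial proportion.
wilson_interval <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, center - half), min(1, center + half))
}

#' Imbalance frequency stratified by footprint presence and motif strength
#'
#' Cross-tabulates tested SNVs by DNase I footprint overlap and by the best
#' overlapping motif-match p-value (with an explicit no-motif stratum) and
#' reports the imbalance frequency per stratum with Wilson 95% intervals.
#'
#' @param snv_status data.frame (`snv_id`, `chrom`, `pos`, `imbalanced`).
#' @param footprints Interval data.frame (`chrom`, `start`, `end`).
#' @param matches Motif-match table (all motifs).
#' @param p_breaks Breaks for the best-match p-value strata (default
#'   `c(0, 1e-6, 1e-5, 1e-4, 1)`).
#' @return data.frame per (footprint, p-value stratum): `footprint`,
#'   `motif_stratum`, `n_tested`, `n_imbalanced`, `frequency`, `ci_lo`,
#'   `ci_hi`. Empty strata are omitted.
#' @export
footprint_stratified_rates <- function(snv_status, footprints, matches,
                                       p_breaks = c(0, 1e-6, 1e-5, 1e-4, 1)) {
  if (nrow(snv_status) == 0L) {
    return(data.frame(footprint = logical(), motif_stratum = character(),
                      n_tested = integer(), n_imbalanced = integer(),
                      frequency = numeric(), ci_lo = numeric(),
                      ci_hi = numeric(), stringsAsFactors = FALSE))
  }
  q <- GenomicRanges::GRanges(snv_status$chrom,
                              IRanges::IRanges(snv_status$pos + 1L,
                                               width = 1L))
  in_fp <- if (nrow(footprints)) {
    s <- GenomicRanges::GRanges(footprints$chrom,
                                IRanges::IRanges(footprints$start + 1L,
                                                 footprints$end))
    IRanges::overlapsAny(q, s)
  } else rep(FALSE, nrow(snv_status))
  best_p <- rep(NA_real_, nrow(snv_status))
  if (nrow(matches)) {
    s <- GenomicRanges::GRanges(matches$chrom,
                                IRanges::IRanges(matches$start + 1L,
                                                 matches$end))
    hits <- GenomicRanges::findOverlaps(q, s)
    if (length(hits)) {
      mp <- tapply(matches$p_value[S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits), min)
      best_p[as.integer(names(mp))] <- as.numeric(mp)
    }
  }
  stratum <- ifelse(is.na(best_p), "no_motif",
                    as.character(cut(best_p, breaks = p_breaks,
                                     include.lowest = TRUE)))
  rows <- list()
  for (fp in c(FALSE, TRUE)) for (st in unique(stratum)) {
    i <- which(in_fp == fp & stratum == st)
    if (length(i) == 0L) next
    x <- sum(snv_status$imbalanced[i]); n <- length(i)
    ci <- wilson_interval(x, n)
    rows[[length(rows) + 1L]] <- data.frame(
      footprint = fp, motif_stratum = st, n_tested = n, n_imbalanced = x,
      frequency = x / n, ci_lo = ci[1], ci_hi = ci[2],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Fraction of imbalanced SNVs overlapping a stringent motif match
#'
#' @param snv_status data.frame (`snv_id`, `chrom`, `pos`, `imbalanced`).
#' @param matches Motif-match table (all motifs).
#' @param p_threshold Stringent match threshold (default `1e-5`, strict).
#' @return List: `fraction`, `n_overlapping`, `n_imbalanced`.
#' @export
overall_motif_overlap <- function(snv_status, matches, p_threshold = 1e-5) {
  imb <- snv_status[snv_status$imbalanced, , drop = FALSE]
  if (nrow(imb) == 0L) return(list(fraction = NA_real_, n_overlapping = 0L,
                                   n_imbalanced = 0L))
  mm <- matches[matches$p_value < p_threshold, , drop = FALSE]
  if (nrow(mm) == 0L) return(list(fraction = 0, n_overlapping = 0L,
                                  n_imbalanced = nrow(imb)))
  q <- GenomicRanges::GRanges(imb$chrom,
                              IRanges::IRanges(imb$pos + 1L, width = 1L))
  s <- GenomicRanges::GRanges(mm$chrom,
                              IRanges::IRanges(mm$start + 1L, mm$end))
  ov <- IRanges::overlapsAny(q, s)
  list(fraction = mean(ov), n_overlapping = sum(ov), n_imbalanced = nrow(imb))
}
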