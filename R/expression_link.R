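# Allelic imbalance on transcript-level counts and its correlation with
# allelic DHS accessibility as a function of signed distance to the TSS.

#' Aggregate SNV-level RNA counts to transcripts
#'
#' Sums reference/non-reference counts of non-exonic SNVs overlapping each
#' transcript's span, per condition. Exonic SNVs are excluded; an SNV
#' overlapping two transcripts contributes to both.
#'
#' @param rna_counts SNV-level counts (`snv_id`, `condition_id`,
#'   `ref_count`, `nonref_count`).
#' @param snvs SNV table (`snv_id`, `chrom`, `pos`).
#' @param transcripts data.frame (`transcript_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`): transcript spans, 0-based half-open, with the TSS
#'   position.
#' @param exons data.frame (`transcript_id`, `start`, `end`): exon
#'   intervals, same convention.
#' @return data.frame (`transcript_id`, `condition_id`, `ref_count`,
#'   `nonref_count`).
#' @export
aggregate_transcript_counts <- function(rna_counts, snvs, transcripts,
                                        exons) {
  empty <- data.frame(transcript_id = character(), condition_id = character(),
                      ref_count = integer(), nonref_count = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(rna_counts) == 0L || nrow(transcripts) == 0L) return(empty)
  pos <- snvs$pos[match(rna_counts$snv_id, snvs$snv_id)]
  chrom <- snvs$chrom[match(rna_counts$snv_id, snvs$snv_id)]
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, width = 1L))
  tx <- GenomicRanges::GRanges(transcripts$chrom,
                               IRanges::IRanges(transcripts$start + 1L,
                                                transcripts$end))
  hits <- GenomicRanges::findOverlaps(q, tx)
  if (length(hits) == 0L) return(empty)
  qi <- S4Vectors::queryHits(hits); ti <- S4Vectors::subjectHits(hits)
  tid <- transcripts$transcript_id[ti]
  # exclude exonic SNVs (exon intervals of the assigned transcript)
  if (nrow(exons) > 0L) {
    exonic <- rep(FALSE, length(qi))
    for (u in unique(tid)) {
      i <- which(tid == u)
      ex <- exons[exons$transcript_id == u, , drop = FALSE]
      if (nrow(ex) == 0L) next
      p <- pos[qi[i]]
      for (e in seq_len(nrow(ex))) {
        exonic[i] <- exonic[i] | (p >= ex$start[e] & p < ex$end[e])
      }
    }
    qi <- qi[!exonic]; tid <- tid[!exonic]
  }
  if (length(qi) == 0L) return(empty)
  x <- data.frame(transcript_id = tid,
                  condition_id = rna_counts$condition_id[qi],
                  ref_count = rna_counts$ref_count[qi],
                  nonref_count = rna_counts$nonref_count[qi],
                  stringsAsFactors = FALSE)
  names(x)[1] <- "snv_id"  # reuse key-summing helper
  x <- aggregate_counts(x)
  names(x)[1] <- "transcript_id"
  x
}

#' Call allelic imbalance on transcript-level counts
#'
#' Same beta-binomial machinery as the accessibility analysis, with the
#' transcript-level thresholds: at least 50 total reads, FDR 10%, and a
#' strict greater-than-60% major-allele fraction.
#'
#' @param records Transcript counts (`transcript_id`, `condition_id`,
#'   `ref_count`, `nonref_count`).
#' @param fdr,ratio,min_reads Thresholds (defaults 0.10, 0.60, 50).
#' @param min_fit_depth,min_sites Dispersion-fit settings (see
#'   [fit_dispersion()]).
#' @param rho Optional fixed dispersion per condition (named vector),
#'   bypassing the fit (for small cohorts).
#' @return Calls data.frame as in [call_imbalance()], with `snv_id` holding
#'   the transcript id.
#' @export
call_rna_imbalance <- function(records, fdr = 0.10, ratio = 0.60,
                               min_reads = 50, min_fit_depth = 101,
                               min_sites = 50, rho = NULL) {
  x <- records
  names(x)[names(x) == "transcript_id"] <- "snv_id"
  nulls <- if (is.null(rho)) {
    fit_nulls(x, min_fit_depth = min_fit_depth, min_sites = min_sites)
  } else {
    data.frame(condition_id = names(rho), rho = as.numeric(rho),
               n_sites_used = NA_integer_, loglik = NA_real_,
               stringsAsFactors = FALSE)
  }
  call_imbalance(x, nulls, fdr = fdr, ratio = ratio, min_reads = min_reads,
                 level = "transcript")
}

#' Pair DHSs with TSSs within a distance limit
#'
#' Emits all (DHS, transcript) pairs of the same condition whose anchor
#' distance is at most `max_distance`. The DHS anchor is the hotspot
#' midpoint; the distance is signed in transcript orientation (positive =
#' DHS downstream of the TSS).
#'
#' @param dhs_ratios data.frame (`dhs_id`, `chrom`, `midpoint`,
#'   `condition_id`, `dhs_ratio`): per-condition DHS allelic ratios.
#' @param transcripts data.frame (`transcript_id`, `chrom`, `tss`,
#'   `strand`).
#' @param rna_ratios data.frame (`transcript_id`, `condition_id`,
#'   `tx_ratio`).
#' @param max_distance Default 500000 bp.
#' @return data.frame (`dhs_id`, `transcript_id`, `condition_id`,
#'   `distance`, `dhs_ratio`, `tx_ratio`).
#' @export
pair_dhs_tss <- function(dhs_ratios, transcripts, rna_ratios,
                         max_distance = 500000) {
  out <- list()
  for (t_i in seq_len(nrow(transcripts))) {
    tr <- transcripts[t_i, ]
    cand <- dhs_ratios[dhs_ratios$chrom == tr$chrom &
                         abs(dhs_ratios$midpoint - tr$tss) <= max_distance, ,
                       drop = FALSE]
    if (nrow(cand) == 0L) next
    rr <- rna_ratios[rna_ratios$transcript_id == tr$transcript_id, ,
                     drop = FALSE]
    if (nrow(rr) == 0L) next
    m <- merge(cand, rr, by = "condition_id")
    if (nrow(m) == 0L) next
    d <- m$midpoint - tr$tss
    if (tr$strand == "-") d <- -d
    out[[length(out) + 1L]] <- data.frame(
      dhs_id = m$dhs_id, transcript_id = tr$transcript_id,
      condition_id = m$condition_id, distance = d,
      dhs_ratio = m$dhs_ratio, tx_ratio = m$tx_ratio,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(dhs_id = character(), transcript_id = character(),
                      condition_id = character(), distance = numeric(),
                      dhs_ratio = numeric(), tx_ratio = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

default_signed_bins <- function() {
  b <- c(1000, 5000, 10000, 50000, 100000, 500000)
  c(-rev(b), 0, b)
}

#' Pearson correlation of DHS and transcript allelic ratios by distance bin
#'
#' @param pairs Output of [pair_dhs_tss()].
#' @param bin_edges Signed-distance bin edges (default mirrored log-spaced
#'   edges out to +-500 kb).
#' @param min_pairs Bins with fewer pairs are masked (default 10).
#' @return data.frame per bin: `bin_lo`, `bin_hi`, `n_pairs`, `r`.
#' @export
distance_binned_correlation <- function(pairs,
                                        bin_edges = default_signed_bins(),
                                        min_pairs = 10) {
  nb <- length(bin_edges) - 1L
  res <- data.frame(bin_lo = bin_edges[-length(bin_edges)],
                    bin_hi = bin_edges[-1L], n_pairs = 0L, r = NA_real_)
  if (nrow(pairs) == 0L) return(res)
  bin <- findInterval(pairs$distance, bin_edges, rightmost.closed = TRUE)
  bin[bin < 1L | bin > nb] <- NA_integer_
  for (b in seq_len(nb)) {
    i <- which(bin == b)
    res$n_pairs[b] <- length(i)
    if (length(i) < min_pairs) next
    if (sd(pairs$dhs_ratio[i]) == 0 || sd(pairs$tx_ratio[i]) == 0) next
    res$r[b] <- cor(pairs$dhs_ratio[i], pairs$tx_ratio[i])
  }
  res
}

#' Permutation null band for the distance-binned correlation
#'
#' Shuffles DHS allelic ratios among pairs within each condition and
#' recomputes the per-bin correlation; reports the per-bin 2.5 and 97.5
#' percentiles over permutations. Bins masked in the observed curve (too few
#' pairs or zero variance) are masked in the band.
#'
#' @param pairs Output of [pair_dhs_tss()].
#' @param bin_edges,min_pairs As in [distance_binned_correlation()].
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed (band is reproducible for a given seed).
#' @return data.frame per bin: `bin_lo`, `bin_hi`, `band_lo`, `band_hi`.
#' @export
permutation_band <- function(pairs, bin_edges = default_signed_bins(),
                             min_pairs = 10, n_perm = 1000, seed = 1) {
  nb <- length(bin_edges) - 1L
  res <- data.frame(bin_lo = bin_edges[-length(bin_edges)],
                    bin_hi = bin_edges[-1L],
                    band_lo = NA_real_, band_hi = NA_real_)
  if (nrow(pairs) == 0L) return(res)
  set.seed(seed)
  grp <- split(seq_len(nrow(pairs)), pairs$condition_id)
  bin <- findInterval(pairs$distance, bin_edges, rightmost.closed = TRUE)
  bin[bin < 1L | bin > nb] <- NA_integer_
  perm_r <- matrix(NA_real_, n_perm, nb)
  for (pp in seq_len(n_perm)) {
    dr <- pairs$dhs_ratio
    for (i in grp) dr[i] <- dr[i[sample.int(length(i))]]
    for (b in seq_len(nb)) {
      i <- which(bin == b)
      if (length(i) < min_pairs) next
      if (sd(dr[i]) == 0 || sd(pairs$tx_ratio[i]) == 0) next
      perm_r[pp, b] <- cor(dr[i], pairs$tx_ratio[i])
    }
  }
  for (b in seq_len(nb)) {
    pv <- perm_r[, b]
    pv <- pv[!is.na(pv)]
    if (length(pv) >= n_perm * 0.5) {
      res$band_lo[b] <- quantile(pv, 0.025, names = FALSE)
      res$band_hi[b] <- quantile(pv, 0.975, names = FALSE)
    }
  }
  res
}
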