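# Read- and site-level filters turning read records overlapping heterozygous
# SNVs into per-allele counts. Filter thresholds follow the conventions of
# allelic DNase-seq pipelines: strict inequalities at every boundary (base
# quality > 20, pass fraction > 0.60, mappable fraction > 0.95, indel
# distance > 72 bp).

#' Read-level filter parameters
#'
#' @param min_base_quality Base quality at the variant must strictly exceed
#'   this (default 20).
#' @param five_prime_exclusion_bp Reads whose variant lies within this many
#'   bp of the read's 5' end (in read orientation) are excluded, guarding
#'   against sequence-specific DNase I cut-rate bias (default 3).
#' @param max_extra_mismatches Mismatches permitted besides the known variant
#'   (default 2).
#' @param max_template_length_bp Inferred template length must be strictly
#'   below this (default 500).
#' @param min_mapq Minimum mapping quality (default 20, inclusive).
#' @param require_dual_genome_concordance Require identical unique mapping to
#'   both the reference and the strain-specific genome (default TRUE).
#' @return Object of class `read_filter_params`.
#' @export
read_filter_params <- function(min_base_quality = 20,
                               five_prime_exclusion_bp = 3,
                               max_extra_mismatches = 2,
                               max_template_length_bp = 500,
                               min_mapq = 20,
                               require_dual_genome_concordance = TRUE) {
  p <- list(min_base_quality = min_base_quality,
            five_prime_exclusion_bp = five_prime_exclusion_bp,
            max_extra_mismatches = max_extra_mismatches,
            max_template_length_bp = max_template_length_bp,
            min_mapq = min_mapq,
            require_dual_genome_concordance = require_dual_genome_concordance)
  if (any(unlist(p[1:5]) < 0)) stop("filter parameters must be non-negative")
  class(p) <- "read_filter_params"
  p
}

#' Site-level filter parameters
#'
#' @param indel_exclusion_bp SNVs within this many bp of a known indel are
#'   excluded (default 72; strictly greater distance retains).
#' @param min_pass_fraction Fraction of overlapping reads passing filters
#'   must strictly exceed this (default 0.60).
#' @param min_mappable_fraction Simulated-read mappable fraction must
#'   strictly exceed this (default 0.95).
#' @return Object of class `site_filter_params`.
#' @export
site_filter_params <- function(indel_exclusion_bp = 72,
                               min_pass_fraction = 0.60,
                               min_mappable_fraction = 0.95) {
  if (min_pass_fraction < 0 || min_pass_fraction > 1 ||
      min_mappable_fraction < 0 || min_mappable_fraction > 1) {
    stop("fractions must lie in [0, 1]")
  }
  p <- list(indel_exclusion_bp = indel_exclusion_bp,
            min_pass_fraction = min_pass_fraction,
            min_mappable_fraction = min_mappable_fraction)
  class(p) <- "site_filter_params"
  p
}

# 5' offset of the variant in read orientation: for minus-strand reads the
# 5' end is the rightmost aligned base.
five_prime_offset <- function(read, snv_pos) {
  ifelse(read$strand == "-",
         (read$start + read$read_len - 1L) - snv_pos,
         snv_pos - read$start)
}

#' Filter one read against one SNV
#'
#' Applies the read-level filters in a fixed decision order: mapping quality,
#' dual-genome concordance, template length, duplicate, 5' exclusion, base
#' quality, mismatches, allele identity. Exactly one reason code is returned.
#'
#' @param read One-row read record (see [simulate_reads_at_snv()]).
#' @param snv One-row SNV data.frame.
#' @param params [read_filter_params()].
#' @param duplicate Whether this read has been marked a duplicate of another
#'   passing read sharing its 5' position (resolved by [count_alleles()]).
#' @return List with `pass` (logical) and `reason` (one of `PASS`,
#'   `LOW_BASEQ`, `FIVE_PRIME`, `MISMATCHES`, `TEMPLATE_LEN`, `MAPQ`,
#'   `GENOME_DISCORDANT`, `DUPLICATE`, `ALLELE_OTHER`).
#' @export
filter_read <- function(read, snv, params = read_filter_params(),
                        duplicate = FALSE) {
  off <- five_prime_offset(read, snv$pos)
  if (off < 0 || off >= read$read_len) {
    stop("read does not overlap the SNV position")
  }
  reason <-
    if (read$mapq < params$min_mapq) "MAPQ"
    else if (params$require_dual_genome_concordance && !isTRUE(read$dual_ok))
      "GENOME_DISCORDANT"
    else if (read$tlen >= params$max_template_length_bp) "TEMPLATE_LEN"
    else if (duplicate) "DUPLICATE"
    else if (off < params$five_prime_exclusion_bp) "FIVE_PRIME"
    else if (read$baseq_at_variant <= params$min_base_quality) "LOW_BASEQ"
    else if (read$n_extra_mismatch > params$max_extra_mismatches) "MISMATCHES"
    else if (!read$base_at_variant %in%
               c(snv$ref_allele, snv$alt_allele)) "ALLELE_OTHER"
    else "PASS"
  list(pass = reason == "PASS", reason = reason)
}

#' Count alleles at one SNV from overlapping read records
#'
#' Applies [filter_read()] to every overlapping read, resolves duplicates
#' (among otherwise-passing reads sharing a 5' position on the reference,
#' exactly one is counted: the one with the highest base quality at the
#' variant, ties broken by deterministic (chrom, start, mate id) sort order,
#' independent of any duplicate flag), and counts each fragment once: a
#' proper pair whose mates both cover the SNV contributes a single count.
#' Mate pairs disagreeing on the allele are discarded entirely with reason
#' `PAIR_ALLELE_CONFLICT`.
#'
#' @param reads data.frame of read records overlapping the SNV.
#' @param snv One-row SNV data.frame.
#' @param params [read_filter_params()].
#' @return List: `ref_count`, `nonref_count`, `n_overlapping` (distinct
#'   fragments), `n_passing` (fragments counted), and `decisions` (per-read
#'   reason codes).
#' @export
count_alleles <- function(reads, snv, params = read_filter_params()) {
  if (nrow(reads) == 0L) {
    return(list(ref_count = 0L, nonref_count = 0L, n_overlapping = 0L,
                n_passing = 0L,
                decisions = data.frame(read_id = character(),
                                       reason = character(),
                                       stringsAsFactors = FALSE)))
  }
  # deterministic processing order
  ord <- order(reads$chrom, reads$start, reads$mate_id, reads$read_id)
  reads <- reads[ord, , drop = FALSE]
  reason <- vapply(seq_len(nrow(reads)), function(i) {
    filter_read(reads[i, ], snv, params)$reason
  }, character(1))
  # duplicate resolution among reads that pass all other filters and share a
  # 5' position (in read orientation) on the reference
  pass <- reason == "PASS"
  if (any(pass)) {
    fp_pos <- ifelse(reads$strand == "-",
                     reads$start + reads$read_len - 1L, reads$start)
    key <- paste(reads$chrom, fp_pos, reads$strand, sep = "\r")
    for (k in unique(key[pass])) {
      g <- which(pass & key == k)
      # distinct fragments only: mates of one fragment are not duplicates
      frags <- reads$fragment_id[g]
      cand <- g[!duplicated(frags)]
      if (length(cand) > 1L) {
        keep <- cand[which.max(reads$baseq_at_variant[cand])]
        drop_frag <- setdiff(unique(frags), reads$fragment_id[keep])
        reason[g[frags %in% drop_frag]] <- "DUPLICATE"
      }
    }
    pass <- reason == "PASS"
  }
  # fragment-level counting: each fragment contributes at most once
  frag <- reads$fragment_id
  ref_n <- 0L; nonref_n <- 0L; n_passing <- 0L
  for (f in unique(frag)) {
    i <- which(frag == f & pass)
    if (length(i) == 0L) next
    alleles <- unique(reads$base_at_variant[i])
    if (length(alleles) > 1L) {
      reason[i] <- "PAIR_ALLELE_CONFLICT"
      next
    }
    n_passing <- n_passing + 1L
    if (alleles == snv$ref_allele) ref_n <- ref_n + 1L
    else nonref_n <- nonref_n + 1L
  }
  list(ref_count = ref_n, nonref_count = nonref_n,
       n_overlapping = length(unique(frag)), n_passing = n_passing,
       decisions = data.frame(read_id = reads$read_id, reason = reason,
                              stringsAsFactors = FALSE))
}

#' Apply site-level filters to per-SNV counts
#'
#' Retains SNVs whose distance to the nearest known indel strictly exceeds
#' the exclusion window, whose fraction of overlapping reads passing filters
#' strictly exceeds the pass-fraction threshold, and whose simulated-read
#' mappable fraction strictly exceeds the mappability threshold. SNVs missing
#' from the mappability table fail closed. Idempotent.
#'
#' @param site_counts data.frame with `snv_id`, `chrom`, `pos`,
#'   `n_overlapping`, `n_passing` (and any count columns, carried through).
#' @param indels data.frame (`chrom`, `pos`, `length`).
#' @param mappability data.frame (`snv_id`, `mappable_fraction`).
#' @param params [site_filter_params()].
#' @return List: `retained` (filtered `site_counts`) and `rejections`
#'   (`snv_id`, `reason` in `{INDEL_PROXIMITY, LOW_PASS_FRACTION,
#'   LOW_MAPPABILITY}`, one reason per removed SNV, first failing filter in
#'   the order indel, pass fraction, mappability).
#' @export
apply_site_filters <- function(site_counts, indels, mappability,
                               params = site_filter_params()) {
  n <- nrow(site_counts)
  if (n == 0L) {
    return(list(retained = site_counts,
                rejections = data.frame(snv_id = character(),
                                        reason = character(),
                                        stringsAsFactors = FALSE)))
  }
  # distance to nearest indel span on the same chromosome
  near_indel <- rep(FALSE, n)
  if (nrow(indels) > 0L) {
    span_lo <- indels$pos
    span_hi <- indels$pos + pmax(0L, -indels$length)  # deletion footprint
    for (ch in unique(site_counts$chrom)) {
      i <- which(site_counts$chrom == ch)
      j <- which(indels$chrom == ch)
      if (length(j) == 0L) next
      for (ii in i) {
        p <- site_counts$pos[ii]
        d <- pmax(0L, pmax(span_lo[j] - p, p - span_hi[j]))
        near_indel[ii] <- any(d <= params$indel_exclusion_bp)
      }
    }
  }
  pass_frac <- ifelse(site_counts$n_overlapping > 0,
                      site_counts$n_passing / site_counts$n_overlapping, 0)
  map_frac <- mappability$mappable_fraction[
    match(site_counts$snv_id, mappability$snv_id)]
  map_frac[is.na(map_frac)] <- 0  # fail closed
  reason <- rep(NA_character_, n)
  reason[near_indel] <- "INDEL_PROXIMITY"
  fail_pf <- is.na(reason) & pass_frac <= params$min_pass_fraction
  reason[fail_pf] <- "LOW_PASS_FRACTION"
  fail_map <- is.na(reason) & map_frac <= params$min_mappable_fraction
  reason[fail_map] <- "LOW_MAPPABILITY"
  keep <- is.na(reason)
  list(retained = site_counts[keep, , drop = FALSE],
       rejections = data.frame(snv_id = site_counts$snv_id[!keep],
                               reason = reason[!keep],
                               stringsAsFactors = FALSE))
}

#' Partition SNVs into testable (in-hotspot) and background sets
#'
#' An SNV is testable when its position falls inside a DHS hotspot interval
#' (0-based half-open: `pos` in `[start, end)`); all other SNVs form the
#' background set of mappable SNVs in inaccessible DNA. The partition is
#' exhaustive.
#'
#' @param snvs SNV data.frame (`chrom`, `pos`, ...).
#' @param dhs Interval data.frame (`chrom`, `start`, `end`).
#' @return List: `testable`, `background` (both subsets of `snvs`).
#' @export
restrict_to_hotspots <- function(snvs, dhs) {
  if (nrow(snvs) == 0L || nrow(dhs) == 0L) {
    return(list(testable = snvs[integer(0), , drop = FALSE],
                background = snvs))
  }
  q <- GenomicRanges::GRanges(snvs$chrom,
                              IRanges::IRanges(snvs$pos + 1L, width = 1L))
  s <- GenomicRanges::GRanges(dhs$chrom,
                              IRanges::IRanges(dhs$start + 1L, dhs$end))
  hit <- IRanges::overlapsAny(q, s)
  list(testable = snvs[hit, , drop = FALSE],
       background = snvs[!hit, , drop = FALSE])
}
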