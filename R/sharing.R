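#' @importFrom stats ecdf aggregate
NULL

# Cross-condition sharing of allelic imbalance (1 - pi0), spatial
# correlation of allelic ratios at adjacent SNVs, and the cell-type activity
# spectrum of imbalanced sites.

#' Pairwise sharing of imbalance between conditions
#'
#' For each ordered pair of conditions (A, B): take the SNVs flagged
#' imbalanced in A that were also tested in B, and estimate the fraction of
#' non-null hypotheses among B's p-values on that set as `1 - pi0` (Storey).
#' Entries with fewer than `min_snvs` SNVs in the intersection are masked
#' (`NA`) with a reason.
#'
#' @param calls Imbalance calls at one pooling level (data.frame from
#'   [call_imbalance()]: `snv_id`, `group_id`, `p_value`, `imbalanced`).
#' @param min_snvs Minimum intersection size per entry (default 50).
#' @return List: `sharing` (square matrix over conditions, entries in
#'   `[0, 1]` or `NA`), `n_snvs` (matrix of intersection sizes), `masked`
#'   (data.frame of masked entries with reasons).
#' @export
pairwise_sharing <- function(calls, min_snvs = 50) {
  conds <- sort(unique(calls$group_id))
  k <- length(conds)
  sharing <- matrix(NA_real_, k, k, dimnames = list(conds, conds))
  n_mat <- matrix(0L, k, k, dimnames = list(conds, conds))
  masked <- list()
  by_cond <- split(calls, calls$group_id)
  for (a in conds) {
    flagged_a <- by_cond[[a]]$snv_id[by_cond[[a]]$imbalanced]
    for (b in conds) {
      cb <- by_cond[[b]]
      i <- match(flagged_a, cb$snv_id)
      p_b <- cb$p_value[i[!is.na(i)]]
      n_mat[a, b] <- length(p_b)
      if (length(p_b) < min_snvs) {
        masked[[length(masked) + 1L]] <- data.frame(
          cond_a = a, cond_b = b, n = length(p_b),
          reason = if (length(p_b) == 0L) "empty intersection" else
            "below minimum SNV count", stringsAsFactors = FALSE)
        next
      }
      pi0 <- storey_pi0_small_ok(p_b)
      sharing[a, b] <- min(1, max(0, 1 - pi0))
    }
  }
  list(sharing = sharing, n_snvs = n_mat,
       masked = if (length(masked)) do.call(rbind, masked) else
         data.frame(cond_a = character(), cond_b = character(), n = integer(),
                    reason = character(), stringsAsFactors = FALSE))
}

# pi0 for sharing entries: the smoother needs enough p-values, but sharing
# sets can legitimately sit between min_snvs and 100; fall back to a single
# fixed-lambda Storey estimate there rather than the BH limit pi0 = 1.
storey_pi0_small_ok <- function(p, lambda0 = 0.5) {
  if (length(p) >= 100L) return(storey_pi0(p))
  min(1, max(0, mean(p > lambda0) / (1 - lambda0)))
}

#' Mean sharing by sample relationship
#'
#' Averages [pairwise_sharing()] entries over ordered pairs (excluding
#' self-pairs) grouped by relationship: same cell type, same strain only
#' (same strain, different cell type), or unrelated (neither shared).
#'
#' @param sharing Square sharing matrix with sample ids as dimnames.
#' @param scheme data.frame (`sample_id`, `cell_type`, `strain`).
#' @return data.frame: `relationship`, `mean`, `sd` (`NA` when fewer than 2
#'   pairs), `n_pairs`.
#' @export
mean_sharing_by_relationship <- function(sharing, scheme) {
  ids <- rownames(sharing)
  i <- match(ids, scheme$sample_id)
  if (anyNA(i)) stop("sharing matrix rows missing from scheme")
  ct <- scheme$cell_type[i]; st <- scheme$strain[i]
  rel <- function(a, b) {
    if (ct[a] == ct[b]) "same_cell_type"
    else if (st[a] == st[b]) "same_strain_only"
    else "unrelated"
  }
  vals <- list(same_cell_type = numeric(0), same_strain_only = numeric(0),
               unrelated = numeric(0))
  for (a in seq_along(ids)) for (b in seq_along(ids)) {
    if (a == b) next
    v <- sharing[a, b]
    if (is.na(v)) next
    r <- rel(a, b)
    vals[[r]] <- c(vals[[r]], v)
  }
  data.frame(
    relationship = names(vals),
    mean = vapply(vals, function(v) if (length(v)) mean(v) else NA_real_,
                  numeric(1)),
    sd = vapply(vals, function(v) if (length(v) >= 2) sd(v) else NA_real_,
                numeric(1)),
    n_pairs = vapply(vals, length, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlation of allelic ratios at adjacent SNVs, by distance
#'
#' Within each condition, tested SNVs are sorted along each chromosome and
#' each is paired with its immediate downstream tested neighbor. Pairs are
#' binned by distance and the Pearson correlation of the two allelic ratios
#' is computed per bin, together with a 95% permutation band obtained by
#' shuffling ratios among tested SNVs within condition.
#'
#' @param calls Imbalance calls (`snv_id`, `group_id`, `allelic_ratio`).
#' @param positions data.frame (`snv_id`, `chrom`, `pos`).
#' @param bin_edges Distance bin edges in bp (default
#'   `c(0, 50, 100, 250, 500, 1000, 2500, 5000, 10000)`).
#' @param min_pairs Bins with fewer pairs are masked (default 10).
#' @param n_perm Number of permutations for the null band (default 1000).
#' @param seed RNG seed for the permutation band.
#' @return data.frame per bin: `bin_lo`, `bin_hi`, `n_pairs`, `r`,
#'   `band_lo`, `band_hi` (masked bins have `NA` statistics).
#' @export
adjacent_ratio_correlation <- function(calls, positions,
                                       bin_edges = c(0, 50, 100, 250, 500,
                                                     1000, 2500, 5000, 10000),
                                       min_pairs = 10, n_perm = 1000,
                                       seed = 1) {
  x <- merge(calls, positions, by = "snv_id")
  x <- x[order(x$group_id, x$chrom, x$pos), ]
  nb <- length(bin_edges) - 1L
  res <- data.frame(bin_lo = bin_edges[-length(bin_edges)],
                    bin_hi = bin_edges[-1L],
                    n_pairs = 0L, r = NA_real_,
                    band_lo = NA_real_, band_hi = NA_real_)
  if (nrow(x) < 2L) return(res)
  # nearest-neighbor chaining: consecutive tested SNVs within
  # (condition, chromosome); the pairing is fixed under permutation of
  # ratios, so pair indices are computed once
  m <- nrow(x)
  same <- x$group_id[-m] == x$group_id[-1L] & x$chrom[-m] == x$chrom[-1L]
  i1 <- which(same); i2 <- i1 + 1L
  d <- x$pos[i2] - x$pos[i1]
  # bin k is (lo, hi]; zero-distance pairs fall outside the first bin
  bin <- findInterval(d, bin_edges, rightmost.closed = TRUE, left.open = TRUE)
  bin[bin < 1L | bin > nb] <- NA_integer_
  for (b in seq_len(nb)) res$n_pairs[b] <- sum(bin == b, na.rm = TRUE)
  bin_cor <- function(ratio) {
    vapply(seq_len(nb), function(b) {
      i <- which(bin == b)
      if (length(i) < min_pairs) return(NA_real_)
      a <- ratio[i1[i]]; v <- ratio[i2[i]]
      if (sd(a) == 0 || sd(v) == 0) return(NA_real_)
      cor(a, v)
    }, numeric(1))
  }
  res$r <- bin_cor(x$allelic_ratio)
  set.seed(seed)
  grp <- split(seq_len(m), x$group_id)
  perm_r <- matrix(NA_real_, n_perm, nb)
  for (pp in seq_len(n_perm)) {
    ratio <- x$allelic_ratio
    for (i in grp) ratio[i] <- ratio[i[sample.int(length(i))]]
    perm_r[pp, ] <- bin_cor(ratio)
  }
  for (b in seq_len(nb)) {
    pv <- perm_r[, b]
    pv <- pv[!is.na(pv)]
    if (length(pv) >= 100 && !is.na(res$r[b])) {
      res$band_lo[b] <- quantile(pv, 0.025, names = FALSE)
      res$band_hi[b] <- quantile(pv, 0.975, names = FALSE)
    }
  }
  res
}

#' Cell-type activity spectrum of classified SNVs
#'
#' Computes, per SNV class (reference-higher, non-reference-higher,
#' not-imbalanced, not-tested), the cumulative distribution of cell-type
#' activity (MCV, the fraction of reference catalogs with a DHS at the site,
#' scaled to `[0, 1]`) and per-catalog overlap proportions.
#'
#' @param snv_classes data.frame (`snv_id`, `class`); classes must be
#'   disjoint by construction (one row per SNV).
#' @param catalog data.frame (`snv_id`, `catalog_id`, `present` logical/0-1).
#' @param n_catalogs Total number of catalogs (denominator of MCV); default
#'   the number of distinct `catalog_id`s.
#' @return List: `mcv` (per SNV: `snv_id`, `class`, `mcv`), `cdf` (long:
#'   `class`, `mcv`, `cdf`, monotone from 0 to 1), `catalog_overlap`
#'   (`class`, `catalog_id`, `proportion`).
#' @export
activity_spectrum <- function(snv_classes, catalog, n_catalogs = NULL) {
  if (anyDuplicated(snv_classes$snv_id)) {
    stop("snv_classes must contain one row per SNV (disjoint classes)")
  }
  if (is.null(n_catalogs)) n_catalogs <- length(unique(catalog$catalog_id))
  pres <- catalog[as.logical(catalog$present), ]
  cnt <- table(factor(pres$snv_id, levels = snv_classes$snv_id))
  mcv <- as.numeric(cnt) / n_catalogs
  mcv_df <- data.frame(snv_id = snv_classes$snv_id,
                       class = snv_classes$class, mcv = mcv,
                       stringsAsFactors = FALSE)
  cdf_rows <- lapply(split(mcv_df$mcv, mcv_df$class), function(v) {
    grid <- sort(unique(c(0, v, 1)))
    data.frame(mcv = grid, cdf = ecdf(v)(grid))
  })
  cdf <- do.call(rbind, Map(function(cl, d) cbind(class = cl, d),
                            names(cdf_rows), cdf_rows))
  rownames(cdf) <- NULL
  ov <- merge(catalog, snv_classes, by = "snv_id")
  agg <- aggregate(as.logical(ov$present),
                   by = list(class = ov$class, catalog_id = ov$catalog_id),
                   FUN = mean)
  names(agg)[3] <- "proportion"
  list(mcv = mcv_df, cdf = cdf, catalog_overlap = agg)
}
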