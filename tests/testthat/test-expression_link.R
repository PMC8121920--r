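mk_transcripts <- function() {
  data.frame(transcript_id = c("t1", "t2"), chrom = "chr1",
             start = c(1000L, 9000L), end = c(5000L, 12000L),
             strand = c("+", "-"), tss = c(1000L, 11999L),
             stringsAsFactors = FALSE)
}

test_that("transcript aggregation excludes exonic SNVs and sums the rest", {
  tx <- mk_transcripts()
  exons <- data.frame(transcript_id = c("t1", "t1"),
                      start = c(1000L, 4000L), end = c(1200L, 5000L),
                      stringsAsFactors = FALSE)
  snvs <- data.frame(snv_id = c("e1", "i1", "i2", "out"),
                     chrom = "chr1",
                     pos = c(1100L, 2000L, 3000L, 8000L),
                     stringsAsFactors = FALSE)
  rna <- data.frame(snv_id = c("e1", "i1", "i2", "out"),
                    condition_id = "liver",
                    ref_count = c(50L, 10L, 5L, 9L),
                    nonref_count = c(50L, 5L, 5L, 1L),
                    stringsAsFactors = FALSE)
  agg <- aggregate_transcript_counts(rna, snvs, tx, exons)
  t1 <- agg[agg$transcript_id == "t1", ]
  expect_equal(t1$ref_count, 15L)   # exonic e1 excluded, out not overlapping
  expect_equal(t1$nonref_count, 10L)
  # transcript with only exonic SNVs yields nothing
  ex_all <- data.frame(transcript_id = "t1", start = 1000L, end = 5000L)
  agg2 <- aggregate_transcript_counts(rna, snvs, tx[1, ], ex_all)
  expect_equal(nrow(agg2), 0L)
  # SNV overlapping two transcripts contributes to both
  tx_ov <- tx; tx_ov$start <- c(1000L, 1500L); tx_ov$end <- c(5000L, 5000L)
  agg3 <- aggregate_transcript_counts(rna, snvs, tx_ov, exons[0, ])
  expect_equal(sort(unique(agg3$transcript_id)), c("t1", "t2"))
})

test_that("transcript imbalance uses the 50-read and strict 60% thresholds", {
  rec <- data.frame(
    transcript_id = c("under", "ratio60", "clear"),
    condition_id = "liver",
    ref_count = c(49L, 60L, 96L),
    nonref_count = c(0L, 40L, 4L),
    stringsAsFactors = FALSE)
  calls <- call_rna_imbalance(rec, rho = c(liver = 0))
  expect_false("under" %in% calls$snv_id)  # 49 reads: not tested
  r60 <- calls[calls$snv_id == "ratio60", ]
  expect_equal(r60$allelic_ratio, 0.60)
  expect_false(r60$imbalanced)
  expect_true(calls$imbalanced[calls$snv_id == "clear"])
})

test_that("null transcripts keep the flagged fraction near zero", {
  set.seed(61)
  n <- 5000
  depth <- pmax(50L, rnbinom(n, size = 2, mu = 150))
  k <- draw_bb(n, depth, 0.5, 0.01)
  rec <- data.frame(transcript_id = sprintf("t%d", 1:n),
                    condition_id = "liver", ref_count = k,
                    nonref_count = depth - k, stringsAsFactors = FALSE)
  calls <- call_rna_imbalance(rec)
  expect_lt(mean(calls$imbalanced), 0.01)
})

test_that("DHS-TSS pairing signs distances by transcript orientation", {
  tx <- mk_transcripts()
  dhs <- data.frame(dhs_id = c("d1", "d2", "d3"), chrom = "chr1",
                    midpoint = c(1000, 11000, 600000),
                    condition_id = "liver", dhs_ratio = c(0.5, 0.7, 0.9),
                    stringsAsFactors = FALSE)
  rna <- data.frame(transcript_id = c("t1", "t2"), condition_id = "liver",
                    tx_ratio = c(0.5, 0.6), stringsAsFactors = FALSE)
  pr <- pair_dhs_tss(dhs, tx, rna)
  # d1 at t1 TSS: distance 0
  expect_equal(pr$distance[pr$dhs_id == "d1" & pr$transcript_id == "t1"], 0)
  # d2 is 999 bp left of the minus-strand t2 TSS -> downstream (positive)
  expect_equal(pr$distance[pr$dhs_id == "d2" & pr$transcript_id == "t2"],
               999)
  # beyond 500 kb from t1 excluded; condition must match
  expect_false(any(pr$dhs_id == "d3" & pr$transcript_id == "t1"))
  # flipping the strand negates the signed distances (metamorphic)
  tx_flip <- tx
  tx_flip$strand <- chartr("+-", "-+", tx_flip$strand)
  pr_flip <- pair_dhs_tss(dhs, tx_flip, rna)
  key <- paste(pr$dhs_id, pr$transcript_id)
  expect_equal(pr_flip$distance[match(key, paste(pr_flip$dhs_id,
                                                 pr_flip$transcript_id))],
               -pr$distance)
})

test_that("binned correlation is order-invariant and masks sparse bins", {
  set.seed(62)
  n <- 500
  pairs <- data.frame(dhs_id = sprintf("d%d", 1:n),
                      transcript_id = sprintf("t%d", 1:n),
                      condition_id = "liver",
                      distance = runif(n, -400000, 400000),
                      dhs_ratio = runif(n), tx_ratio = runif(n),
                      stringsAsFactors = FALSE)
  c1 <- distance_binned_correlation(pairs)
  c2 <- distance_binned_correlation(pairs[sample(n), ])
  expect_equal(c1, c2)
  single <- pairs[1, ]
  cs <- distance_binned_correlation(single)
  expect_true(all(is.na(cs$r)))
})

test_that("planted kernel yields maximal near-TSS correlation that decays", {
  set.seed(63)
  # construct pairs directly from a known coupling: tx_ratio correlated with
  # dhs_ratio with strength exp(-|d|/10kb)
  n <- 6000
  d <- runif(n, -200000, 200000)
  w <- exp(-abs(d) / 10000)
  dhs_r <- runif(n, 0.1, 0.9)
  tx_r <- w * dhs_r + (1 - w) * 0.5 + rnorm(n, 0, 0.08)
  pairs <- data.frame(dhs_id = sprintf("d%d", 1:n),
                      transcript_id = sprintf("t%d", 1:n),
                      condition_id = "liver", distance = d,
                      dhs_ratio = dhs_r, tx_ratio = tx_r,
                      stringsAsFactors = FALSE)
  cur <- distance_binned_correlation(pairs)
  band <- permutation_band(pairs, n_perm = 300, seed = 64)
  near <- which(cur$bin_lo == -1000 | cur$bin_hi == 1000)
  far <- which(abs(cur$bin_lo) >= 100000 | cur$bin_hi <= -100000)
  expect_true(all(cur$r[near] > band$band_hi[near]))
  expect_gt(min(cur$r[near]), max(cur$r[far], na.rm = TRUE))
  # monotone decay beyond the kernel scale on the positive side
  pos_bins <- which(cur$bin_lo >= 10000 & !is.na(cur$r))
  expect_true(all(diff(cur$r[pos_bins]) <= 0.05))
})

test_that("null pairs stay inside the permutation band at ~95% coverage", {
  set.seed(65)
  exits <- 0; total <- 0
  for (rep_i in 1:8) {
    n <- 800
    pairs <- data.frame(dhs_id = sprintf("d%d", 1:n),
                        transcript_id = sprintf("t%d", 1:n),
                        condition_id = "liver",
                        distance = runif(n, -450000, 450000),
                        dhs_ratio = runif(n), tx_ratio = runif(n),
                        stringsAsFactors = FALSE)
    cur <- distance_binned_correlation(pairs)
    band <- permutation_band(pairs, n_perm = 300, seed = 100 + rep_i)
    ok <- !is.na(cur$r) & !is.na(band$band_lo)
    exits <- exits + sum(cur$r[ok] < band$band_lo[ok] |
                           cur$r[ok] > band$band_hi[ok])
    total <- total + sum(ok)
  }
  se <- sqrt(0.05 * 0.95 / total)
  expect_lte(exits / total, 0.05 + 3 * se + 0.02)
})

test_that("permutation band is reproducible for a fixed seed", {
  set.seed(66)
  n <- 300
  pairs <- data.frame(dhs_id = sprintf("d%d", 1:n),
                      transcript_id = sprintf("t%d", 1:n),
                      condition_id = "liver",
                      distance = runif(n, -100000, 100000),
                      dhs_ratio = runif(n), tx_ratio = runif(n),
                      stringsAsFactors = FALSE)
  b1 <- permutation_band(pairs, n_perm = 100, seed = 9)
  b2 <- permutation_band(pairs, n_perm = 100, seed = 9)
  expect_identical(b1, b2)
  # constant transcript ratio: undefined r, masked everywhere
  pc <- pairs; pc$tx_ratio <- 0.5
  expect_true(all(is.na(distance_binned_correlation(pc)$r)))
})

test_that("generator kernel scale is recoverable from the fitted decay", {
  set.seed(67)
  ch <- simulate_cohort(sim_config(n_snvs = 3000, fraction_causal = 0.4,
                                   p_shared = 1,
                                   effect_range = c(0.3, 0.45), seed = 71))
  d <- ch$dhs[sample(nrow(ch$dhs), 300), ]
  tss <- data.frame(transcript_id = paste0("t", seq_len(nrow(d))),
                    chrom = d$chrom,
                    tss = as.integer((d$start + d$end) / 2 +
                                       sample(c(-1, 1) *
                                                rep(c(2000, 20000, 60000),
                                                    length.out = nrow(d)),
                                              nrow(d))),
                    strand = "+", stringsAsFactors = FALSE)
  ex <- simulate_linked_expression(ch$true_effects, ch$snvs, ch$dhs, tss,
                                   kernel = 10000, noise_sd = 0.02,
                                   depth_mu = 300, rho = 0, seed = 72)
  # transcripts coupled to a nearby DHS must track its theta more tightly
  # at short distances: correlation decreasing with the planted distance
  expect_gt(nrow(ex$counts), 0)
  expect_true(all(ex$counts$ref_count + ex$counts$nonref_count >= 1))
})
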