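# Build a two-condition call set with a controlled fraction of shared
# causal effects and enough depth that flagged sets are well populated.
make_sharing_calls <- function(n = 4000, frac_causal = 0.15, shared = 0.6,
                               depth = 300, rho = 0.01, seed = 1) {
  set.seed(seed)
  snv_id <- sprintf("s%05d", seq_len(n))
  causal_a <- seq_len(n) <= n * frac_causal
  is_shared <- causal_a & (seq_len(n) <= n * frac_causal * shared)
  th_a <- ifelse(causal_a, 0.85, 0.5)
  th_b <- ifelse(is_shared, 0.85, 0.5)
  mk <- function(th, cond) {
    k <- draw_bb(n, depth, th, rho)
    p <- betabinom_pvalue(k, rep(depth, n), rho)
    q <- storey_qvalues(p)
    r <- k / depth
    data.frame(snv_id = snv_id, pooling_level = "cell_type",
               group_id = cond, ref_count = k, nonref_count = depth - k,
               allelic_ratio = r, p_value = p, q_value = q,
               imbalanced = q <= 0.1 & pmax(r, 1 - r) > 0.7,
               stringsAsFactors = FALSE)
  }
  list(calls = rbind(mk(th_a, "A"), mk(th_b, "B")),
       truth_shared_in_B = is_shared, causal_a = causal_a)
}

test_that("pairwise sharing recovers the planted shared fraction", {
  x <- make_sharing_calls(seed = 2)
  sh <- pairwise_sharing(x$calls)
  # diagonal: self-sharing ~ 1
  expect_gt(sh$sharing["A", "A"], 0.9)
  # oracle: fraction of A-flagged SNVs truly non-null in B
  flagged_a <- x$calls$snv_id[x$calls$group_id == "A" & x$calls$imbalanced]
  eff_truth <- mean(x$truth_shared_in_B[match(flagged_a,
                                              sprintf("s%05d", 1:4000))])
  expect_lt(abs(sh$sharing["A", "B"] - eff_truth), 0.1)
})

test_that("no sharing when the second condition is pure null", {
  x <- make_sharing_calls(shared = 0, seed = 3)
  sh <- pairwise_sharing(x$calls)
  expect_lt(sh$sharing["A", "B"], 0.15)
})

test_that("sharing entries are masked below the minimum SNV count", {
  x <- make_sharing_calls(n = 300, frac_causal = 0.05, seed = 4)
  sh <- pairwise_sharing(x$calls, min_snvs = 50)
  expect_true(is.na(sh$sharing["A", "B"]))
  expect_true(nrow(sh$masked) > 0)
})

test_that("sharing is invariant under SNV id relabeling", {
  x <- make_sharing_calls(seed = 5)
  sh1 <- pairwise_sharing(x$calls)
  relabeled <- x$calls
  map <- setNames(sprintf("z%05d", 1:4000), sprintf("s%05d", 1:4000))
  relabeled$snv_id <- map[relabeled$snv_id]
  sh2 <- pairwise_sharing(relabeled)
  expect_equal(sh1$sharing, sh2$sharing)
})

test_that("relationship means order as constructed and handle edge cases", {
  ids <- c("s1", "s2", "s3", "s4")
  scheme <- data.frame(sample_id = ids,
                       cell_type = c("liver", "liver", "kidney", "kidney"),
                       strain = c("CAST", "PWK", "CAST", "PWK"),
                       stringsAsFactors = FALSE)
  m <- matrix(0.2, 4, 4, dimnames = list(ids, ids))
  m[1, 2] <- m[2, 1] <- 0.8  # same cell type
  m[1, 3] <- m[3, 1] <- 0.4  # same strain only
  res <- mean_sharing_by_relationship(m, scheme)
  same_ct <- res$mean[res$relationship == "same_cell_type"]
  unrel <- res$mean[res$relationship == "unrelated"]
  expect_gt(same_ct, unrel)
  # constant matrix: all means equal, SD 0
  mc <- matrix(0.5, 4, 4, dimnames = list(ids, ids))
  resc <- mean_sharing_by_relationship(mc, scheme)
  expect_true(all(resc$mean == 0.5))
  expect_true(all(resc$sd == 0))
  # a class with a single pair has undefined SD
  m2 <- m[1:2, 1:2]
  res2 <- mean_sharing_by_relationship(m2, scheme)
  expect_true(is.na(res2$sd[res2$relationship == "same_cell_type"]) ||
                res2$n_pairs[res2$relationship == "same_cell_type"] > 1)
  expect_equal(res2$n_pairs[res2$relationship == "unrelated"], 0L)
})

test_that("iid ratios stay inside the adjacent-correlation permutation band", {
  set.seed(6)
  n <- 1200
  pos <- sort(sample(1:2e6, n))
  calls <- data.frame(snv_id = sprintf("s%d", 1:n), pooling_level = "sample",
                      group_id = "c1", ref_count = 1L, nonref_count = 1L,
                      allelic_ratio = runif(n, 0.2, 0.8),
                      p_value = 0.5, q_value = 0.5, imbalanced = FALSE,
                      stringsAsFactors = FALSE)
  positions <- data.frame(snv_id = calls$snv_id, chrom = "chr1", pos = pos,
                          stringsAsFactors = FALSE)
  res <- adjacent_ratio_correlation(calls, positions, n_perm = 300, seed = 7)
  ok <- !is.na(res$r) & !is.na(res$band_lo)
  expect_gt(sum(ok), 2)
  inside <- res$r[ok] >= res$band_lo[ok] & res$r[ok] <= res$band_hi[ok]
  expect_gte(mean(inside), 0.75)
})

test_that("spatially shared effects raise short-range correlation only", {
  set.seed(8)
  n_clust <- 250
  # pairs of SNVs 40 bp apart sharing one ratio, clusters 50 kb apart
  base <- runif(n_clust, 0.1, 0.9)
  pos <- as.vector(rbind(seq(1, by = 50000, length.out = n_clust),
                         seq(41, by = 50000, length.out = n_clust)))
  ratio <- as.vector(rbind(base, base + rnorm(n_clust, 0, 0.02)))
  n <- 2 * n_clust
  calls <- data.frame(snv_id = sprintf("s%d", 1:n), pooling_level = "sample",
                      group_id = "c1", ref_count = 1L, nonref_count = 1L,
                      allelic_ratio = pmin(0.99, pmax(0.01, ratio)),
                      p_value = 0.5, q_value = 0.5, imbalanced = FALSE,
                      stringsAsFactors = FALSE)
  positions <- data.frame(snv_id = calls$snv_id, chrom = "chr1",
                          pos = as.integer(pos), stringsAsFactors = FALSE)
  res <- adjacent_ratio_correlation(calls, positions,
                                    bin_edges = c(0, 50, 100, 250, 500,
                                                  1000, 100000),
                                    n_perm = 200, seed = 9)
  b50 <- which(res$bin_hi == 50)
  expect_gt(res$r[b50], res$band_hi[b50])
  far <- which(res$bin_lo == 1000)
  expect_true(is.na(res$r[far]) ||
                (res$r[far] <= res$band_hi[far] &
                   res$r[far] >= res$band_lo[far]))
})

test_that("bins below the pair minimum are masked", {
  calls <- data.frame(snv_id = c("a", "b"), pooling_level = "sample",
                      group_id = "c1", ref_count = 1L, nonref_count = 1L,
                      allelic_ratio = c(0.4, 0.6), p_value = 0.5,
                      q_value = 0.5, imbalanced = FALSE,
                      stringsAsFactors = FALSE)
  positions <- data.frame(snv_id = c("a", "b"), chrom = "chr1",
                          pos = c(100L, 140L), stringsAsFactors = FALSE)
  res <- adjacent_ratio_correlation(calls, positions, min_pairs = 2)
  expect_true(all(is.na(res$r)))
  expect_equal(sum(res$n_pairs), 1L)
})

test_that("activity spectrum CDFs and overlaps reflect planted membership", {
  set.seed(10)
  n <- 600
  cls <- data.frame(snv_id = sprintf("s%d", 1:n),
                    class = rep(c("ref_higher", "nonref_higher",
                                  "not_imbalanced", "not_tested"),
                                length.out = n),
                    stringsAsFactors = FALSE)
  # nonref_higher SNVs planted in 50% of catalogs; not_tested in none
  catalogs <- sprintf("cat%02d", 1:10)
  rows <- expand.grid(snv_id = cls$snv_id, catalog_id = catalogs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cl_of <- cls$class[match(rows$snv_id, cls$snv_id)]
  rows$present <- ifelse(cl_of == "nonref_higher", runif(nrow(rows)) < 0.5,
                         ifelse(cl_of == "not_tested", FALSE,
                                runif(nrow(rows)) < 0.2))
  sp <- activity_spectrum(cls, rows, n_catalogs = 10)
  # CDFs monotone from 0 to 1
  for (cl in unique(sp$cdf$class)) {
    v <- sp$cdf$cdf[sp$cdf$class == cl]
    expect_true(all(diff(v) >= 0))
    expect_equal(v[length(v)], 1)
  }
  # not_tested: step at 0
  nt <- sp$mcv$mcv[sp$mcv$class == "not_tested"]
  expect_true(all(nt == 0))
  ov <- sp$catalog_overlap
  nr <- ov$proportion[ov$class == "nonref_higher"]
  expect_lt(abs(mean(nr) - 0.5), 3 * sqrt(0.25 / (150 * 10)) + 0.05)
  # duplicate snv rows rejected
  expect_error(activity_spectrum(rbind(cls, cls[1, ]), rows), "one row")
})

test_that("all SNVs present in all catalogs gives a step CDF at 1", {
  cls <- data.frame(snv_id = c("a", "b"), class = "ref_higher",
                    stringsAsFactors = FALSE)
  rows <- expand.grid(snv_id = c("a", "b"),
                      catalog_id = c("c1", "c2"), stringsAsFactors = FALSE)
  rows$present <- TRUE
  sp <- activity_spectrum(cls, rows)
  expect_true(all(sp$mcv$mcv == 1))
})
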