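#' @importFrom stats dbinom pbinom optimize smooth.spline predict rbeta
#'   rbinom rnbinom runif cor
NULL

# Beta-binomial parameterized by (mean mu, dispersion rho) with
# rho = 1/(alpha + beta + 1); rho -> 0 recovers the binomial. With mu = 0.5
# (the allelic null) alpha = beta = (1 - rho) / (2 * rho).

bb_shape <- function(mu, rho) {
  s <- (1 - rho) / rho
  c(alpha = mu * s, beta = (1 - mu) * s)
}

#' Beta-binomial probability mass function
#'
#' Density of the beta-binomial distribution with mean `mu` and dispersion
#' `rho` (`rho = 1/(alpha+beta+1)`; `rho = 0` reduces exactly to the
#' binomial). Computed in log space via `lbeta`/`lchoose` for numerical
#' stability at large `n`.
#'
#' @param k Number of reference-allele reads (vectorized).
#' @param n Total reads (vectorized).
#' @param mu Mean allelic ratio, default 0.5.
#' @param rho Dispersion in `[0, 1)`.
#' @param log If `TRUE` return log density.
#' @return Numeric vector of (log) probabilities.
#' @export
dbetabinom <- function(k, n, mu = 0.5, rho = 0, log = FALSE) {
  stopifnot(all(rho >= 0), all(rho < 1), all(mu > 0), all(mu < 1))
  m <- max(length(k), length(n), length(mu), length(rho))
  k <- rep_len(k, m); n <- rep_len(n, m)
  mu <- rep_len(mu, m); rho <- rep_len(rho, m)
  out <- numeric(m)
  bin <- rho < .Machine$double.eps
  if (any(bin)) out[bin] <- dbinom(k[bin], n[bin], mu[bin], log = TRUE)
  if (any(!bin)) {
    i <- !bin
    s <- (1 - rho[i]) / rho[i]
    a <- mu[i] * s; b <- (1 - mu[i]) * s
    out[i] <- lchoose(n[i], k[i]) + lbeta(k[i] + a, n[i] - k[i] + b) -
      lbeta(a, b)
  }
  if (log) out else exp(out)
}

#' Two-sided beta-binomial p-value against a 50/50 null
#'
#' Tests the observed reference-allele count `k` of `n` total reads against a
#' beta-binomial null with mean 0.5 and dispersion `rho`, by tail doubling:
#' `p = min(1, 2 * min(P(X <= k), P(X >= k)))`. The null is symmetric about
#' `n/2`, so `p(k, n) = p(n - k, n)` exactly. Tails are accumulated from the
#' extreme end inward; the pmf is evaluated in log space.
#'
#' @param k Reference counts (vectorized).
#' @param n Total counts (vectorized), `n >= 1`.
#' @param rho Dispersion in `[0, 1)`, scalar or vectorized.
#' @return p-values in `(0, 1]`.
#' @export
betabinom_pvalue <- function(k, n, rho) {
  if (any(rho < 0) || any(rho >= 1)) stop("rho must lie in [0, 1)")
  m <- max(length(k), length(n), length(rho))
  k <- rep_len(as.numeric(k), m)
  n <- rep_len(as.numeric(n), m)
  rho <- rep_len(rho, m)
  stopifnot(all(n >= 1), all(k >= 0), all(k <= n))
  lo <- pmin(k, n - k)  # by symmetry both tails equal P(X <= lo)
  p <- numeric(m)
  bin <- rho < .Machine$double.eps
  if (any(bin)) p[bin] <- pmin(1, 2 * pbinom(lo[bin], n[bin], 0.5))
  if (any(!bin)) {
    i <- which(!bin)
    a <- (1 - rho[i]) / (2 * rho[i])
    len <- lo[i] + 1
    idx <- rep.int(seq_along(i), len)
    j <- sequence(len) - 1
    lp <- lchoose(n[i][idx], j) +
      lbeta(j + a[idx], n[i][idx] - j + a[idx]) - lbeta(a[idx], a[idx])
    tail <- rowsum(exp(lp), idx, reorder = TRUE)[, 1L]
    p[i] <- pmin(1, 2 * tail)
  }
  p
}

#' Fit the beta-binomial null dispersion for one condition
#'
#' Maximum-likelihood fit of the dispersion `rho` with the mean fixed at 0.5
#' (so that genuine imbalance is not absorbed into the null), over sites
#' deep enough to be informative about overdispersion (more than 100 reads by
#' default). Bounded search on `rho` in `[0, 0.5]`.
#'
#' @param k Reference counts for sites of one condition.
#' @param n Total counts.
#' @param min_fit_depth Minimum total reads for a site to enter the fit
#'   (default 101, i.e. more than 100 reads).
#' @param min_sites Minimum number of qualifying sites (default 50); fewer
#'   is an error suggesting aggregation or an explicit `rho`.
#' @return Object of class `betabinom_null`: list with `rho`,
#'   `n_sites_used`, `loglik`.
#' @export
fit_dispersion <- function(k, n, min_fit_depth = 101, min_sites = 50) {
  stopifnot(length(k) == length(n))
  use <- which(n >= min_fit_depth)
  if (length(use) < min_sites) {
    stop("only ", length(use), " sites with depth >= ", min_fit_depth,
         " (need ", min_sites, "); pool conditions or supply rho explicitly")
  }
  kk <- as.numeric(k[use]); nn <- as.numeric(n[use])
  nll <- function(rho) {
    -sum(dbetabinom(kk, nn, mu = 0.5, rho = rho, log = TRUE))
  }
  opt <- optimize(nll, interval = c(1e-8, 0.5))
  ll_bin <- sum(dbinom(kk, nn, 0.5, log = TRUE))
  if (ll_bin >= -opt$objective) {
    res <- list(rho = 0, n_sites_used = length(use), loglik = ll_bin)
  } else {
    res <- list(rho = opt$minimum, n_sites_used = length(use),
                loglik = -opt$objective)
  }
  class(res) <- "betabinom_null"
  res
}

#' Fit per-condition beta-binomial nulls on a count table
#'
#' @param counts Long count table (`snv_id`, `condition_id`, `ref_count`,
#'   `nonref_count`).
#' @param min_fit_depth,min_sites Passed to [fit_dispersion()].
#' @return data.frame with one row per condition: `condition_id`, `rho`,
#'   `n_sites_used`, `loglik`.
#' @export
fit_nulls <- function(counts, min_fit_depth = 101, min_sites = 50) {
  conds <- sort(unique(counts$condition_id))
  total <- counts$ref_count + counts$nonref_count
  rows <- lapply(conds, function(cc) {
    i <- counts$condition_id == cc
    f <- fit_dispersion(counts$ref_count[i], total[i],
                        min_fit_depth = min_fit_depth, min_sites = min_sites)
    data.frame(condition_id = cc, rho = f$rho, n_sites_used = f$n_sites_used,
               loglik = f$loglik, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Estimate the proportion of true nulls (Storey's pi0)
#'
#' Storey's smoother estimate: `pi0(lambda) = #{p > lambda} / (m (1-lambda))`
#' over the standard lambda grid, smoothed with a cubic smoothing spline
#' (df = 3) and evaluated at the largest lambda; the result is clipped to
#' `[0, 1]`. With fewer than 100 p-values the estimator is unreliable and
#' `pi0 = 1` is returned (the Benjamini-Hochberg limit).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param lambda Evaluation grid (default `seq(0.05, 0.95, 0.05)`).
#' @return Scalar pi0 estimate in `[0, 1]`.
#' @export
storey_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m < 100L) return(1)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- predict(fit, x = max(lambda))$y
  min(max(pi0, 0), 1)
}

#' Storey q-values
#'
#' q-values with pi0 estimated by [storey_pi0()] (with fewer than 100
#' p-values, pi0 falls back to 1 and the result equals Benjamini-Hochberg
#' adjusted p-values). Monotone non-decreasing in p, capped at 1.
#'
#' @param p p-values in `[0, 1]`.
#' @param pi0 Optional fixed pi0 override (e.g. `pi0 = 1` for BH).
#' @return Numeric vector of q-values aligned with `p`.
#' @export
storey_qvalues <- function(p, pi0 = NULL) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  if (is.null(pi0)) pi0 <- storey_pi0(p)
  pi0 <- max(pi0, 1e-8)
  o <- order(p, decreasing = TRUE)
  q <- pi0 * m * p[o] / rank(p, ties.method = "max")[o]
  q <- pmin(1, cummin(q))
  out <- numeric(m)
  out[o] <- q
  out
}

#' Pool an allele-count table to a coarser analysis level
#'
#' Sums reference/non-reference counts within groups of samples defined by a
#' pooling scheme. Grand totals are conserved.
#'
#' @param counts Long count table at the sample level (`condition_id` =
#'   sample id).
#' @param scheme data.frame mapping `sample_id` to `cell_type` and `strain`;
#'   every sample must map to exactly one pair.
#' @param level One of `"sample"`, `"cell_type"`, `"strain"`, `"aggregate"`.
#' @return Pooled count table with `condition_id` set to the group label
#'   (sample id, cell type, strain, or `"all"`).
#' @export
pool_counts <- function(counts, scheme,
                        level = c("sample", "cell_type", "strain",
                                  "aggregate")) {
  level <- match.arg(level)
  if (level == "sample") return(aggregate_counts(counts))
  if (anyDuplicated(scheme$sample_id)) {
    stop("pooling scheme maps a sample to more than one (cell_type, strain)")
  }
  i <- match(counts$condition_id, scheme$sample_id)
  if (anyNA(i)) {
    stop("sample(s) missing from pooling scheme: ",
         paste(head(unique(counts$condition_id[is.na(i)]), 5), collapse = ", "))
  }
  group <- switch(level,
                  cell_type = scheme$cell_type[i],
                  strain = scheme$strain[i],
                  aggregate = rep("all", nrow(counts)))
  pooled <- counts
  pooled$condition_id <- group
  aggregate_counts(pooled)
}

#' Call allelic imbalance on a pooled count table
#'
#' For each (SNV, condition) entry with at least `min_reads` total reads,
#' computes a two-sided beta-binomial p-value against a 50/50 null using the
#' condition's fitted dispersion, q-values over all tested entries of the
#' pooling analysis jointly, and flags imbalance when `q <= fdr` and the
#' major-allele fraction strictly exceeds `ratio`.
#'
#' @param pooled Count table at the chosen pooling level.
#' @param nulls data.frame from [fit_nulls()] (one row per condition present
#'   in `pooled`); a condition without a fitted null is an error.
#' @param fdr q-value threshold (default 0.10).
#' @param ratio Major-allele fraction threshold, strict (default 0.70).
#' @param min_reads Minimum total reads for an entry to be tested
#'   (default 30).
#' @param level Label recorded in the output (`pooling_level` column).
#' @return data.frame of tested entries: `snv_id`, `pooling_level`,
#'   `group_id`, `ref_count`, `nonref_count`, `allelic_ratio`, `p_value`,
#'   `q_value`, `imbalanced`. Entries below `min_reads` are not tested and
#'   not returned; their number is available as attribute `n_untested`.
#' @export
call_imbalance <- function(pooled, nulls, fdr = 0.10, ratio = 0.70,
                           min_reads = 30, level = "condition") {
  miss <- setdiff(unique(pooled$condition_id), nulls$condition_id)
  if (length(miss)) {
    stop("no fitted null for condition(s): ", paste(miss, collapse = ", "))
  }
  total <- pooled$ref_count + pooled$nonref_count
  tested <- total >= min_reads
  x <- pooled[tested, , drop = FALSE]
  total <- total[tested]
  rho <- nulls$rho[match(x$condition_id, nulls$condition_id)]
  p <- if (nrow(x)) betabinom_pvalue(x$ref_count, total, rho) else numeric(0)
  q <- storey_qvalues(p)
  r <- x$ref_count / total
  out <- data.frame(
    snv_id = x$snv_id,
    pooling_level = if (nrow(x)) level else character(0),
    group_id = x$condition_id,
    ref_count = x$ref_count,
    nonref_count = x$nonref_count,
    allelic_ratio = r,
    p_value = p,
    q_value = q,
    imbalanced = q <= fdr & pmax(r, 1 - r) > ratio,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_untested") <- sum(!tested)
  out
}
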