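# Shared fixtures, built in code at test time.

snv1 <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                 id = "s1") {
  data.frame(chrom = chrom, pos = pos, ref_allele = ref, alt_allele = alt,
             strain_id = "CAST", snv_id = id, stringsAsFactors = FALSE)
}

# Independent oracle for the two-sided beta-binomial p-value: naive non-log
# pmf summation with choose() and beta().
oracle_betabinom_p <- function(k, n, rho) {
  if (rho == 0) {
    pmf <- dbinom(0:n, n, 0.5)
  } else {
    a <- (1 - rho) / (2 * rho)
    pmf <- vapply(0:n, function(j) choose(n, j) * beta(j + a, n - j + a) /
                    beta(a, a), numeric(1))
  }
  lo <- min(k, n - k)
  min(1, 2 * sum(pmf[seq_len(lo + 1)]))
}

# Draw beta-binomial counts (mean mu, dispersion rho) for test cohorts.
draw_bb <- function(m, size, mu, rho) {
  if (rho == 0) return(rbinom(m, size, mu))
  s <- (1 - rho) / rho
  p <- rbeta(m, mu * s, (1 - mu) * s)
  rbinom(m, size, p)
}

tmp_file <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}

# A small two-cell-type count table with known per-(snv, cell type) truth.
toy_cohort <- function(n = 400, depth = 80, rho = 0.02, seed = 1,
                       frac_causal = 0.2, theta_alt = 0.85) {
  set.seed(seed)
  snv_id <- sprintf("s%04d", seq_len(n))
  causal <- seq_len(n) <= n * frac_causal
  rows <- list()
  truth <- list()
  for (ct in c("ctA", "ctB")) {
    th <- ifelse(causal, theta_alt, 0.5)
    k <- draw_bb(n, depth, th, rho)
    rows[[ct]] <- data.frame(snv_id = snv_id, condition_id = ct,
                             ref_count = k, nonref_count = depth - k,
                             stringsAsFactors = FALSE)
    truth[[ct]] <- data.frame(snv_id = snv_id, condition_id = ct,
                              theta = th, stringsAsFactors = FALSE)
  }
  list(counts = do.call(rbind, rows), truth = do.call(rbind, truth),
       causal = causal)
}
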