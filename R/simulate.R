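#' @importFrom stats rgamma rnorm rlnorm rpois
NULL

# Synthetic cohort generator. Emulates the statistical structure of an
# allelic DNase-seq study in F1 hybrids: heterozygous SNVs inside and outside
# DHS hotspots across strains and cell types, beta-binomial allele counts
# around condition-specific true ratios, cell-type-specific causal effects
# concentrated at motif core positions, and transcript counts coupled to
# nearby DHS effects by a distance-decaying kernel.

#' Construct a simulation configuration
#'
#' Defaults describe a desk-scale cohort with the structure of an F1-hybrid
#' allelic accessibility study: 4 cell types x 5 strains, 2 replicates per
#' condition, heavy-tailed read depths (truncated negative binomial on
#' `[10, 2000]`, spanning both the 30-read test threshold and the 100-read
#' dispersion-fit threshold), beta-binomial counts with per-condition
#' dispersion, 5% causal SNVs with effect magnitude `|theta - 0.5| ~
#' Uniform(0.15, 0.45)`, and causal effects preferentially placed at motif
#' core positions.
#'
#' @param n_snvs Number of SNVs.
#' @param cell_types Character vector of cell/tissue type labels.
#' @param strains Character vector of non-reference strain labels.
#' @param replicates Samples per (strain, cell type) condition.
#' @param depth_mu,depth_size Negative-binomial depth parameters (mean, size).
#' @param depth_range Truncation bounds for depth.
#' @param rho Per-condition beta-binomial dispersion; scalar or one value per
#'   cell type.
#' @param fraction_causal Fraction of in-DHS SNVs with a true effect.
#' @param effect_range Range of `|theta - 0.5|` for causal SNVs.
#' @param p_shared Probability that a causal effect is active in all cell
#'   types (otherwise a random proper subset).
#' @param fraction_in_dhs Fraction of SNVs placed inside DHS hotspots.
#' @param p_causal_in_motif Probability a causal SNV sits at a core position
#'   of a motif instance.
#' @param n_motifs Number of TF motifs in the synthetic motif architecture.
#' @param motif_width_range Inclusive range of motif widths (bp).
#' @param dhs_width_mean DHS hotspot mean width (bp).
#' @param n_indels Number of indels scattered over the genome.
#' @param fraction_low_mappability Fraction of SNVs given a mappable fraction
#'   below the 0.95 threshold.
#' @param p_dhs_propagate Probability that a causal SNV's allelic effect is
#'   copied to every other SNV in its DHS (in the same cell types),
#'   emulating the perfect linkage of variants within one accessibility
#'   element in an F1 hybrid. Default 0: each effect stays private to its
#'   SNV, so the truly-imbalanced fraction equals `fraction_causal`.
#' @param expression_scale Distance scale (bp) of the DHS-to-TSS coupling
#'   kernel used by [simulate_linked_expression()].
#' @param seed Mandatory RNG seed.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_snvs = 10000,
                       cell_types = c("liver", "kidney", "lung", "bcell"),
                       strains = c("129", "C3H", "CAST", "PWK", "SPRET"),
                       replicates = 2,
                       depth_mu = 60, depth_size = 1.2,
                       depth_range = c(10, 2000),
                       rho = 0.02,
                       fraction_causal = 0.05,
                       effect_range = c(0.15, 0.45),
                       p_shared = 0.5,
                       fraction_in_dhs = 0.6,
                       p_causal_in_motif = 0.6,
                       n_motifs = 12,
                       motif_width_range = c(8, 14),
                       dhs_width_mean = 250,
                       n_indels = 50,
                       fraction_low_mappability = 0.02,
                       p_dhs_propagate = 0,
                       expression_scale = 10000,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("sim_config: seed is mandatory")
  cfg <- list(n_snvs = as.integer(n_snvs), cell_types = cell_types,
              strains = strains, replicates = as.integer(replicates),
              depth_mu = depth_mu, depth_size = depth_size,
              depth_range = depth_range, rho = rho,
              fraction_causal = fraction_causal, effect_range = effect_range,
              p_shared = p_shared, fraction_in_dhs = fraction_in_dhs,
              p_causal_in_motif = p_causal_in_motif,
              n_motifs = as.integer(n_motifs),
              motif_width_range = as.integer(motif_width_range),
              dhs_width_mean = dhs_width_mean, n_indels = as.integer(n_indels),
              fraction_low_mappability = fraction_low_mappability,
              p_dhs_propagate = p_dhs_propagate,
              expression_scale = expression_scale, seed = as.integer(seed))
  probs <- c(cfg$fraction_causal, cfg$p_shared, cfg$fraction_in_dhs,
             cfg$p_causal_in_motif, cfg$fraction_low_mappability,
             cfg$p_dhs_propagate)
  if (any(probs < 0 | probs > 1)) {
    stop("sim_config: all probabilities must lie in [0, 1]")
  }
  if (any(cfg$rho < 0 | cfg$rho >= 1)) stop("sim_config: rho must be in [0, 1)")
  if (cfg$n_snvs < 1) stop("sim_config: n_snvs must be >= 1")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a full synthetic cohort
#'
#' Generates every input the downstream pipeline consumes: SNVs (inside and
#' outside DHSs), indels, DHS hotspot intervals, motif matches with core
#' positions, footprints, per-(SNV, cell type) true allelic ratios,
#' a sample-level allele-count matrix, a pooling scheme, per-SNV genomic
#' annotations, and a mappability table. Deterministic for a given seed.
#'
#' Counts at SNV i in sample s of cell type c are drawn beta-binomial with
#' mean `theta_ic` and the cell type's dispersion `rho_c`; null SNVs have
#' `theta = 0.5` everywhere.
#'
#' @param config A [sim_config()] object.
#' @return List with elements `snvs`, `indels`, `dhs`, `motifs` (motif
#'   catalog with widths and core positions), `motif_matches`, `footprints`,
#'   `true_effects` (long: `snv_id`, `cell_type`, `theta`, plus per-SNV
#'   `causal`, `causal_motif_id`, `causal_position`), `counts`, `scheme`,
#'   `annotations`, `mappability`, and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_snvs
  cts <- config$cell_types
  n_ct <- length(cts)
  rho_ct <- rep_len(config$rho, n_ct)

  ## --- genome layout: DHSs spaced along autosomes -------------------------
  n_dhs <- max(2L, ceiling(n * config$fraction_in_dhs / 2))
  chroms <- paste0("chr", 1:19)
  dhs_chrom <- sample(chroms, n_dhs, replace = TRUE)
  dhs_width <- pmax(150L, as.integer(round(rnorm(n_dhs, config$dhs_width_mean,
                                                 50))))
  # space starts out within each chromosome so hotspots never overlap
  dhs_start <- integer(n_dhs)
  for (ch in unique(dhs_chrom)) {
    i <- which(dhs_chrom == ch)
    dhs_start[i] <- cumsum(dhs_width[i] + sample(2000:20000, length(i),
                                                 replace = TRUE))
  }
  dhs <- data.frame(chrom = dhs_chrom, start = dhs_start,
                    end = dhs_start + dhs_width,
                    name = sprintf("dhs%05d", seq_len(n_dhs)),
                    score = round(rgamma(n_dhs, shape = 2, scale = 30), 3),
                    strand = ".", stringsAsFactors = FALSE)

  ## --- motif catalog and instances ----------------------------------------
  widths <- sample(config$motif_width_range[1]:config$motif_width_range[2],
                   config$n_motifs, replace = TRUE)
  motifs <- data.frame(
    motif_id = sprintf("TF%02d", seq_len(config$n_motifs)),
    width = widths, stringsAsFactors = FALSE)
  motifs$core_start <- pmax(0L, as.integer(floor(widths / 3)))
  motifs$core_end <- pmin(widths, as.integer(ceiling(2 * widths / 3)))
  # one motif instance inside ~60% of DHSs
  has_inst <- runif(n_dhs) < 0.6
  inst_dhs <- which(has_inst)
  inst_motif <- sample(seq_len(config$n_motifs), length(inst_dhs),
                       replace = TRUE)
  w <- motifs$width[inst_motif]
  slack <- pmax(1L, dhs_width[inst_dhs] - w)
  inst_start <- dhs_start[inst_dhs] + as.integer(floor(runif(length(inst_dhs)) * slack))
  motif_matches <- data.frame(
    motif_id = motifs$motif_id[inst_motif],
    chrom = dhs_chrom[inst_dhs],
    start = inst_start,
    end = inst_start + w,
    strand = sample(c("+", "-"), length(inst_dhs), replace = TRUE),
    score = round(runif(length(inst_dhs), 5, 20), 3),
    p_value = 10^-runif(length(inst_dhs), 4, 9),
    dhs_name = dhs$name[inst_dhs],
    stringsAsFactors = FALSE)

  ## --- SNV placement ------------------------------------------------------
  in_dhs <- runif(n) < config$fraction_in_dhs
  snv_dhs <- ifelse(in_dhs, sample(n_dhs, n, replace = TRUE), NA_integer_)
  pos <- integer(n)
  i_in <- which(in_dhs)
  pos[i_in] <- dhs_start[snv_dhs[i_in]] +
    as.integer(floor(runif(length(i_in)) * dhs_width[snv_dhs[i_in]]))
  i_out <- which(!in_dhs)
  # background SNVs sit in the gaps between hotspots
  bg_dhs <- sample(n_dhs, length(i_out), replace = TRUE)
  pos[i_out] <- dhs$end[bg_dhs] + sample(500:1500, length(i_out),
                                         replace = TRUE)
  chrom <- character(n)
  chrom[i_in] <- dhs_chrom[snv_dhs[i_in]]
  chrom[i_out] <- dhs_chrom[bg_dhs]
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  strain <- sample(config$strains, n, replace = TRUE)

  ## --- causal architecture ------------------------------------------------
  causal <- in_dhs & runif(n) < config$fraction_causal
  causal_motif <- rep(NA_character_, n)
  causal_pos <- rep(NA_integer_, n)
  i_c <- which(causal)
  if (length(i_c)) {
    # move a fraction of causal SNVs onto a core position of a motif
    # instance inside their DHS (creating the instance where absent)
    at_motif <- runif(length(i_c)) < config$p_causal_in_motif
    for (j in i_c[at_motif]) {
      d <- snv_dhs[j]
      mi <- which(motif_matches$dhs_name == dhs$name[d])
      if (length(mi) == 0L) {
        mid <- sample(config$n_motifs, 1)
        w1 <- motifs$width[mid]
        st <- dhs_start[d] +
          as.integer(floor(runif(1) * max(1L, dhs_width[d] - w1)))
        motif_matches <- rbind(motif_matches, data.frame(
          motif_id = motifs$motif_id[mid], chrom = dhs_chrom[d], start = st,
          end = st + w1, strand = sample(c("+", "-"), 1),
          score = round(runif(1, 5, 20), 3), p_value = 10^-runif(1, 5, 9),
          dhs_name = dhs$name[d], stringsAsFactors = FALSE))
        mi <- nrow(motif_matches)
      } else {
        mi <- mi[1L]
      }
      mrow <- motif_matches[mi, ]
      mdef <- motifs[match(mrow$motif_id, motifs$motif_id), ]
      core <- seq(mdef$core_start, mdef$core_end - 1L)
      offset <- sample(core, 1)  # position in motif orientation
      pos[j] <- if (mrow$strand == "+") mrow$start + offset else
        (mrow$end - 1L) - offset
      chrom[j] <- mrow$chrom
      causal_motif[j] <- mrow$motif_id
      causal_pos[j] <- offset
    }
  }

  snv_id <- sprintf("snv%06d", seq_len(n))
  snvs <- data.frame(chrom = chrom, pos = pos, ref_allele = ref,
                     alt_allele = alt, strain_id = strain, snv_id = snv_id,
                     in_dhs = in_dhs,
                     dhs_name = ifelse(in_dhs, dhs$name[snv_dhs], NA),
                     stringsAsFactors = FALSE)

  ## --- true effects -------------------------------------------------------
  theta <- matrix(0.5, n, n_ct, dimnames = list(snv_id, cts))
  if (length(i_c)) {
    mag <- runif(length(i_c), config$effect_range[1], config$effect_range[2])
    sgn <- sample(c(-1, 1), length(i_c), replace = TRUE)
    shared <- runif(length(i_c)) < config$p_shared
    for (u in seq_along(i_c)) {
      act <- if (shared[u] || n_ct == 1L) seq_len(n_ct) else
        sample(n_ct, sample(max(1L, n_ct - 1L), 1))
      theta[i_c[u], act] <- 0.5 + sgn[u] * mag[u]
    }
  }
  # optional linkage: a causal SNV's effect spans its whole DHS
  if (config$p_dhs_propagate > 0) {
    for (j in i_c) {
      if (is.na(snv_dhs[j]) || runif(1) >= config$p_dhs_propagate) next
      same <- which(snv_dhs == snv_dhs[j] & seq_len(n) != j)
      if (length(same)) theta[same, ] <- rep(theta[j, ], each = length(same))
    }
  }
  true_effects <- data.frame(
    snv_id = rep(snv_id, each = n_ct),
    cell_type = rep(cts, times = n),
    theta = as.vector(t(theta)),
    causal = rep(causal, each = n_ct),
    causal_motif_id = rep(causal_motif, each = n_ct),
    causal_position = rep(causal_pos, each = n_ct),
    stringsAsFactors = FALSE)

  ## --- sample scheme and counts -------------------------------------------
  scheme <- expand.grid(strain = config$strains, cell_type = cts,
                        rep = seq_len(config$replicates),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  scheme$sample_id <- sprintf("%s_%s_r%d", scheme$strain, scheme$cell_type,
                              scheme$rep)
  scheme <- scheme[, c("sample_id", "cell_type", "strain")]

  # each SNV is heterozygous in one strain only: counts exist for samples of
  # that strain, across all cell types and replicates
  # order: for snv i, (ct1 r1, ct1 r2, ct2 r1, ...)
  rep_per_snv <- n_ct * config$replicates
  idx <- rep(seq_len(n), each = rep_per_snv)
  rep_idx <- rep(rep(seq_len(config$replicates), times = n_ct), times = n)
  ct_idx <- rep(rep(seq_len(n_ct), each = config$replicates), times = n)
  depth <- draw_depth(length(idx), config)
  th <- theta[cbind(idx, ct_idx)]
  rr <- rho_ct[ct_idx]
  refc <- rbetabinom(length(idx), depth, th, rr)
  counts <- data.frame(
    snv_id = snv_id[idx],
    condition_id = sprintf("%s_%s_r%d", strain[idx], cts[ct_idx], rep_idx),
    ref_count = refc,
    nonref_count = depth - refc,
    stringsAsFactors = FALSE)

  ## --- footprints: sub-intervals of DHSs holding motif instances ---------
  fp <- motif_matches
  footprints <- data.frame(chrom = fp$chrom,
                           start = pmax(0L, fp$start - 5L),
                           end = fp$end + 5L,
                           name = paste0("fp_", seq_len(nrow(fp))),
                           stringsAsFactors = FALSE)

  ## --- annotations (CATO2 global-model inputs) ---------------------------
  dist_tss <- as.integer(round(rlnorm_trunc(n, log(20000), 1.5, 0, 5e5)))
  in_fp <- causal & !is.na(causal_motif)
  footprint_flag <- in_fp | (in_dhs & runif(n) < 0.3)
  annotations <- data.frame(
    snv_id = snv_id,
    mcv = pmin(1, pmax(0, rbeta(n, 1.2, 2.5))),
    intron = as.integer(runif(n) < 0.45),
    intergenic = as.integer(runif(n) < 0.35),
    dist_tss = dist_tss,
    dhs_strength = ifelse(in_dhs, dhs$score[snv_dhs], 0) +
      abs(rnorm(n, 0, 2)),
    dhs_width = ifelse(in_dhs, dhs_width[snv_dhs],
                       as.integer(config$dhs_width_mean)),
    footprint = as.integer(footprint_flag),
    n_nearby_sites = rpois(n, 2),
    conservation = pmin(1, pmax(0, rbeta(n, 1.5, 3) +
                                  0.15 * causal)),
    stringsAsFactors = FALSE)

  ## --- indels and mappability ---------------------------------------------
  ind_dhs <- sample(n_dhs, min(config$n_indels, n_dhs))
  indels <- data.frame(
    chrom = dhs_chrom[ind_dhs],
    pos = dhs$end[ind_dhs] + sample(100:400, length(ind_dhs), replace = TRUE),
    length = sample(c(-5:-1, 1:5), length(ind_dhs), replace = TRUE),
    stringsAsFactors = FALSE)
  mappability <- simulate_mappability(
    snvs, low_fraction = config$fraction_low_mappability, seed = NULL)

  list(snvs = snvs, indels = indels, dhs = dhs, motifs = motifs,
       motif_matches = motif_matches, footprints = footprints,
       true_effects = true_effects, counts = counts, scheme = scheme,
       annotations = annotations, mappability = mappability, config = config)
}

# Truncated negative-binomial depth draw.
draw_depth <- function(m, config) {
  d <- rnbinom(m, size = config$depth_size, mu = config$depth_mu)
  lo <- config$depth_range[1]; hi <- config$depth_range[2]
  bad <- d < lo | d > hi
  while (any(bad)) {
    d[bad] <- rnbinom(sum(bad), size = config$depth_size, mu = config$depth_mu)
    bad <- d < lo | d > hi
  }
  as.integer(d)
}

# Beta-binomial deviates with mean mu and dispersion rho (rho = 0: binomial).
rbetabinom <- function(m, size, mu, rho) {
  m <- as.integer(m)
  mu <- rep_len(mu, m); rho <- rep_len(rho, m); size <- rep_len(size, m)
  out <- integer(m)
  bin <- rho < .Machine$double.eps
  if (any(bin)) out[bin] <- rbinom(sum(bin), size[bin], mu[bin])
  if (any(!bin)) {
    i <- !bin
    s <- (1 - rho[i]) / rho[i]
    p <- rbeta(sum(i), mu[i] * s, (1 - mu[i]) * s)
    out[i] <- rbinom(sum(i), size[i], p)
  }
  out
}

rlnorm_trunc <- function(m, meanlog, sdlog, lo, hi) {
  d <- rlnorm(m, meanlog, sdlog)
  pmin(pmax(d, lo), hi)
}

#' Simulate read records at one SNV for filter testing
#'
#' Generates synthetic read records overlapping an SNV, each labeled with the
#' ground-truth filter outcome it should receive from the counting stage.
#' Scenario flags inject specific violations; `"clean"` reads pass every
#' filter.
#'
#' @param snv One-row SNV data.frame (`chrom`, `pos`, `ref_allele`,
#'   `alt_allele`, `snv_id`).
#' @param n_reads Number of reads (must be non-negative).
#' @param scenario One of `"clean"`, `"low_baseq"`, `"five_prime_offsets"`
#'   (one read per 5' offset `0..n_reads-1`), `"duplicates"` (all reads share
#'   one 5' position; exactly one should be counted), `"mismatches"`,
#'   `"template_long"`, `"mapq_low"`, `"discordant"` (fails dual-genome
#'   concordance), `"other_allele"`.
#' @param read_len Read length in bp.
#' @param seed Optional RNG seed.
#' @return data.frame of read records with fields `read_id`, `mate_id`,
#'   `fragment_id`, `chrom`, `start`, `read_len`, `strand`, `mapq`, `tlen`,
#'   `dual_ok`, `n_extra_mismatch`, `base_at_variant`, `baseq_at_variant`,
#'   `duplicate_of`, and the ground-truth `truth_label` (a
#'   [filter_read()] reason code, or `PASS`).
#' @export
simulate_reads_at_snv <- function(snv, n_reads, scenario = "clean",
                                  read_len = 36, seed = NULL) {
  if (n_reads < 0) stop("n_reads must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  scenario <- match.arg(scenario,
                        c("clean", "low_baseq", "five_prime_offsets",
                          "duplicates", "mismatches", "template_long",
                          "mapq_low", "discordant", "other_allele"))
  if (n_reads == 0L) {
    return(empty_reads())
  }
  pos <- snv$pos
  # default: plus-strand reads with the variant at a safe interior offset
  offset <- sample(3:(read_len - 1), n_reads, replace = TRUE)
  start <- pos - offset
  base <- sample(c(snv$ref_allele, snv$alt_allele), n_reads, replace = TRUE)
  r <- data.frame(
    read_id = sprintf("%s_rd%04d", scenario, seq_len(n_reads)),
    mate_id = sprintf("%s_frag%04d/1", scenario, seq_len(n_reads)),
    fragment_id = sprintf("%s_frag%04d", scenario, seq_len(n_reads)),
    chrom = snv$chrom, start = start, read_len = read_len, strand = "+",
    mapq = 30L, tlen = 150L, dual_ok = TRUE, n_extra_mismatch = 0L,
    base_at_variant = base, baseq_at_variant = 35L,
    duplicate_of = NA_character_,
    truth_label = "PASS", stringsAsFactors = FALSE)
  switch(scenario,
    clean = NULL,
    low_baseq = {
      r$baseq_at_variant <- 20L  # pass requires > 20, strict
      r$truth_label <- "LOW_BASEQ"
    },
    five_prime_offsets = {
      off <- seq_len(n_reads) - 1L
      r$start <- pos - off
      r$truth_label <- ifelse(off < 3L, "FIVE_PRIME", "PASS")
    },
    duplicates = {
      r$start <- pos - 5L
      r$base_at_variant <- snv$ref_allele
      # highest base quality at the variant survives; first in sort on ties
      r$baseq_at_variant <- c(40L, rep(30L, n_reads - 1L))
      r$truth_label <- c("PASS", rep("DUPLICATE", n_reads - 1L))
      r$duplicate_of <- c(NA_character_, rep(r$read_id[1L], n_reads - 1L))
    },
    mismatches = {
      r$n_extra_mismatch <- 3L  # 2 permitted besides the known variant
      r$truth_label <- "MISMATCHES"
    },
    template_long = {
      r$tlen <- 600L
      r$truth_label <- "TEMPLATE_LEN"
    },
    mapq_low = {
      r$mapq <- 10L
      r$truth_label <- "MAPQ"
    },
    discordant = {
      r$dual_ok <- FALSE
      r$truth_label <- "GENOME_DISCORDANT"
    },
    other_allele = {
      others <- setdiff(c("A", "C", "G", "T"),
                        c(snv$ref_allele, snv$alt_allele))
      r$base_at_variant <- sample(others, n_reads, replace = TRUE)
      r$truth_label <- "ALLELE_OTHER"
    })
  r
}

empty_reads <- function() {
  data.frame(read_id = character(), mate_id = character(),
             fragment_id = character(), chrom = character(), start = integer(),
             read_len = integer(), strand = character(), mapq = integer(),
             tlen = integer(), dual_ok = logical(),
             n_extra_mismatch = integer(), base_at_variant = character(),
             baseq_at_variant = integer(), duplicate_of = character(),
             truth_label = character(), stringsAsFactors = FALSE)
}

#' Simulate per-SNV mappability fractions
#'
#' Emulates the output of a read-simulation mappability screen: most SNVs are
#' fully mappable; a configurable fraction receive a mappable fraction at or
#' below the 0.95 retention threshold.
#'
#' @param snvs SNV data.frame with `snv_id`.
#' @param low_fraction Fraction of SNVs given low mappability.
#' @param seed Optional seed (`NULL` to use the current RNG state).
#' @return data.frame (`snv_id`, `mappable_fraction`).
#' @export
simulate_mappability <- function(snvs, low_fraction = 0.02, seed = NULL) {
  if (low_fraction < 0 || low_fraction > 1) {
    stop("low_fraction must lie in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(snvs)
  frac <- rep(1, n)
  low <- runif(n) < low_fraction
  frac[low] <- runif(sum(low), 0.5, 0.95)
  data.frame(snv_id = snvs$snv_id, mappable_fraction = frac,
             stringsAsFactors = FALSE)
}

#' Simulate transcript-level allelic counts coupled to DHS effects
#'
#' Transcript allelic ratios are a kernel-weighted mixture of the true
#' allelic ratios of nearby DHSs plus independent noise; counts are drawn
#' beta-binomially around the resulting ratio. The kernel maps |DHS - TSS|
#' distance to a mixing weight and must be monotone non-increasing.
#'
#' @param true_effects Long true-effect table from [simulate_cohort()].
#' @param snvs SNV table (to locate each SNV's DHS).
#' @param dhs DHS interval table.
#' @param tss data.frame of transcripts: `transcript_id`, `chrom`, `tss`
#'   (0-based position), `strand`.
#' @param kernel Function of distance in bp returning a weight in `[0, 1]`,
#'   or a scale in bp for the default exponential kernel `exp(-d / scale)`.
#' @param noise_sd SD of independent Gaussian noise added to the transcript
#'   ratio (on the ratio scale), default 0.05.
#' @param depth_mu,depth_size,rho Count-generation parameters.
#' @param max_distance Maximum DHS-TSS distance considered (bp).
#' @param cell_types Cell types to emit (defaults to those in
#'   `true_effects`).
#' @param seed RNG seed.
#' @return List with `counts` (transcript-level: `transcript_id`,
#'   `condition_id`, `ref_count`, `nonref_count`), `truth` (`transcript_id`,
#'   `cell_type`, `theta`), and `tss`.
#' @export
simulate_linked_expression <- function(true_effects, snvs, dhs, tss,
                                       kernel = 10000, noise_sd = 0.05,
                                       depth_mu = 120, depth_size = 2,
                                       rho = 0.01, max_distance = 500000,
                                       cell_types = NULL, seed) {
  set.seed(seed)
  if (is.numeric(kernel)) {
    scale <- kernel
    kernel <- function(d) exp(-d / scale)
  }
  if (is.null(cell_types)) cell_types <- unique(true_effects$cell_type)
  # per-DHS mean true theta by cell type (mean over its SNVs)
  sn <- snvs[!is.na(snvs$dhs_name), c("snv_id", "dhs_name")]
  te <- merge(true_effects, sn, by = "snv_id")
  key <- paste(te$dhs_name, te$cell_type, sep = "\r")
  dhs_theta <- tapply(te$theta, key, mean)
  dhs_mid <- (dhs$start + dhs$end) / 2

  rows_counts <- list(); rows_truth <- list()
  warned <- FALSE
  for (t_i in seq_len(nrow(tss))) {
    tr <- tss[t_i, ]
    on_chr <- which(dhs$chrom == tr$chrom &
                      abs(dhs_mid - tr$tss) <= max_distance)
    w <- if (length(on_chr)) kernel(abs(dhs_mid[on_chr] - tr$tss)) else
      numeric(0)
    for (ct in cell_types) {
      th_d <- dhs_theta[paste(dhs$name[on_chr], ct, sep = "\r")]
      ok <- !is.na(th_d) & w > 0
      base <- if (any(ok)) sum(w[ok] * th_d[ok]) / sum(w[ok]) else 0.5
      mix <- if (any(ok)) min(1, max(w[ok])) else 0
      th <- mix * base + (1 - mix) * 0.5 + rnorm(1, 0, noise_sd)
      th <- min(0.99, max(0.01, th))
      depth <- max(1L, as.integer(rnbinom(1, size = depth_size,
                                          mu = depth_mu)))
      refc <- rbetabinom(1, depth, th, rho)
      rows_counts[[length(rows_counts) + 1L]] <- data.frame(
        transcript_id = tr$transcript_id, condition_id = ct,
        ref_count = refc, nonref_count = depth - refc,
        stringsAsFactors = FALSE)
      rows_truth[[length(rows_truth) + 1L]] <- data.frame(
        transcript_id = tr$transcript_id, cell_type = ct, theta = th,
        coupled = any(ok), stringsAsFactors = FALSE)
    }
    if (length(on_chr) == 0L && !warned) {
      warning("TSS with no DHS in range; independent transcripts generated")
      warned <- TRUE
    }
  }
  list(counts = do.call(rbind, rows_counts),
       truth = do.call(rbind, rows_truth), tss = tss)
}
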