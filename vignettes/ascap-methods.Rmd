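---
title: "Methods: allele-specific accessibility analysis in ascap"
author: "ascap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific accessibility analysis in ascap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascap)
```

# The measurement and its null model

In an F1 hybrid of two inbred strains, every strain-distinguishing variant
is heterozygous and phased by parent of origin. A DNase-seq read overlapping
such an SNV inside a DNase I-hypersensitive site (DHS) can be assigned to
one parental allele by the base it carries at the variant. Under the null
hypothesis that local sequence does not affect accessibility, reads split
50/50 between alleles; a *cis*-acting variant shifts that split.

Raw binomial sampling understates the variance of real allele counts:
library preparation, cleavage-site preference and residual mapping effects
add extra-binomial noise that varies by sample and condition. `ascap`
therefore models the reference-allele count $k$ of $n$ overlapping reads as
beta-binomial with mean fixed at $\tfrac12$ and dispersion $\rho$,
parameterized as $\rho = 1/(\alpha + \beta + 1)$ so that $\rho \to 0$
recovers the binomial exactly. The generator and the test share this one
parameterization, which makes parameter-recovery round-trips meaningful.

**Dispersion fitting** (`fit_dispersion()`): $\rho_c$ is estimated per
condition by bounded maximum likelihood on $\rho \in [0, 0.5]$, using only
sites with more than 100 reads — shallow sites carry almost no information
about overdispersion — and with the mean held at $\tfrac12$, so that true
imbalance inflates neither the null mean nor, materially, the dispersion.
The fitted $\rho_c$ is then applied to all tested sites (30 reads and up).
A binomial fit is reported ($\rho = 0$) whenever it attains at least the
beta-binomial likelihood. Fewer than 50 qualifying sites is an error that
asks the caller to pool conditions or pass $\rho$ explicitly.

**Testing** (`betabinom_pvalue()`): two-sided p-values by tail doubling,
$p = \min\{1,\, 2\min(P(X \le k), P(X \ge k))\}$. The null is symmetric
about $n/2$, so the doubled statistic is exact up to the center term and
$p(k, n) = p(n - k, n)$ holds identically. The pmf is evaluated in log
space via `lgamma`, and tails are accumulated from the extreme end inward,
keeping the computation stable up to the depth cap of 2000 reads. A
brute-force summation oracle in the test suite agrees to $10^{-10}$ for all
$n \le 200$.

**Multiple testing** (`storey_pi0()`, `storey_qvalues()`): Storey's
estimator of the true-null proportion, $\hat\pi_0(\lambda) =
\#\{p > \lambda\} / (m(1-\lambda))$ over $\lambda = 0.05, \dots, 0.95$,
smoothed with a cubic spline (df = 3) and read off at $\lambda = 0.95$.
With fewer than 100 p-values the smoother is unreliable and the estimator
falls back to $\pi_0 = 1$, which makes the q-values identical to
Benjamini-Hochberg adjusted p-values (this equality is oracle-tested).
Q-values are computed within each pooling analysis jointly — all SNVs of
the per-cell-type analysis form one multiple-testing universe — matching
how per-analysis counts are usually reported.

**Calling** (`call_imbalance()`): an entry is *tested* when its pooled
total reaches 30 reads, and *imbalanced* when $q \le 0.10$ and the
major-allele fraction strictly exceeds 0.70. The strict inequality matters
at the boundary: a site at exactly 70/30 is never flagged regardless of
significance. The magnitude threshold makes the caller deliberately
conservative relative to the nominal FDR: on null-calibrated synthetic
cohorts the realized false-discovery proportion is far below 10%, because
weak-effect false positives rarely clear the 70% bar.

## Pooling levels

Counts are pooled by summing within groups of samples (`pool_counts()`):
per sample (identity), per cell type, per strain, or aggregate. Pooling
reduces sampling variance but dilutes effects private to one condition —
the motivating observation for per-cell-type analysis. Note that pooling
beta-binomial draws from independent samples yields counts that are less
overdispersed *relative to their larger total* than the per-sample draws,
which is why fitted $\rho$ shrinks from the sample level to the aggregate
level on synthetic data; the per-condition fit absorbs this automatically.

# Read and site filters

`filter_read()` applies, in a fixed order: mapping quality $\ge 20$;
concordant unique mapping to both the reference and the strain-specific
genome (represented as a boolean on the read record; the alignment itself
is upstream of this package); template length $< 500$ bp; duplicate
resolution; exclusion of the first 3 bp at the read's 5$'$ end (in read
orientation — for minus-strand reads the 5$'$ end is the rightmost aligned
base), guarding against sequence-specific cleavage-rate bias at the cut
site; base quality $> 20$ at the variant; at most 2 mismatches beyond the
known variant; and the base at the variant must equal one of the two
alleles. Exactly one reason code is recorded per read.

`count_alleles()` counts each *fragment* once: a proper pair whose mates
both cover the SNV contributes a single count, and mates that disagree on
the allele discard the whole fragment (the conservative reading). Among
otherwise-passing reads sharing a 5$'$ position, exactly one is counted —
the one with the highest base quality at the variant, ties broken by a
deterministic (chrom, start, mate id) sort — independent of any upstream
duplicate flag.

`apply_site_filters()` removes SNVs within 72 bp of a known indel, with at
most 60% of overlapping reads passing, or with at most 95% of simulated
reads mappable; all three boundaries are strict on the retention side, and
an SNV missing from the mappability table fails closed. The filter is
idempotent. Indel distance is measured to the indel's affected span (the
deleted interval for deletions, the anchor base for insertions).

# The synthetic cohort generator

`simulate_cohort()` generates every input the pipeline consumes, under one
seed, with these study conditions as defaults:

* 4 cell types $\times$ 5 strains, 2 replicates per condition; each SNV
  heterozygous in exactly one strain.
* Read depth per (SNV, sample): negative binomial (mean 60, size 1.2)
  truncated to $[10, 2000]$ — heavy-tailed like DNase coverage, spanning
  both the 30-read testing threshold and the 100-read dispersion-fit
  threshold.
* Dispersion $\rho = 0.02$ per condition, a typical magnitude for allelic
  DNase data.
* 5% of in-DHS SNVs causal, with effect magnitude
  $|\theta - 0.5| \sim \mathrm{Uniform}(0.15, 0.45)$ and random sign, so
  effects span the 70% calling threshold in both directions.
* Each causal effect is active in all cell types with probability 0.5,
  otherwise in a random proper subset — the knob (`p_shared`) that creates
  cell-type context sensitivity.
* 60% of SNVs fall inside DHS hotspots (width $\sim$ 250 bp); 60% of
  causal SNVs sit at a designated core position of a TF motif instance
  inside their DHS, which is what per-position profiles recover as peaks.

Counts are drawn beta-binomially around the condition's true ratio with the
condition's dispersion, so generator and test agree on the null by
construction; a goodness-of-fit test in the suite confirms the marginal
calibration. `simulate_reads_at_snv()` produces read-record fixtures in
which every record carries the ground-truth filter outcome it should
receive, enabling an exhaustive confusion-matrix test of the filters (all
off-diagonals zero). `simulate_linked_expression()` couples transcript
allelic ratios to nearby DHS effects through a monotone distance kernel
(default exponential, 10 kb scale) plus independent noise.

Two structural simplifications deserve note. First, each synthetic SNV is
heterozygous in a single strain, so cross-strain sharing is not estimable
on these cohorts (real diverged strains share a sizable minority of
variants); relationship-level sharing summaries on synthetic data rest on
replicate and same-strain pairs. Second, causal effects are by default
private to their SNV, so adjacent-SNV ratio correlation is null; setting
`p_dhs_propagate = 1` copies each causal effect across its whole DHS,
emulating the perfect linkage of variants within one accessibility element,
and produces the expected sub-250-bp correlation structure. The default
stays 0 so that the truly-imbalanced fraction equals `fraction_causal`
exactly.

What passing tests on these cohorts do **not** show: robustness to
reference-mapping bias beyond the modeled filters, to alignment artifacts,
to cut-bias profiles, or to mis-specified dispersion families — real data
can violate the beta-binomial in ways the generator cannot.

# Sharing, spatial correlation, and the activity spectrum

Sharing between conditions A and B is estimated as $1 - \hat\pi_0$ of B's
p-values restricted to SNVs flagged in A (`pairwise_sharing()`); entries
with fewer than 50 jointly tested SNVs are masked. Between 50 and 100
p-values a single fixed-$\lambda$ Storey estimate ($\lambda = 0.5$) is used
instead of the smoother. Because the discrete, tail-doubled test statistic
is mildly conservative near $p = 1$ — exactly where the smoother evaluates
— $1 - \pi_0$ carries a small downward bias (a few percentage points at
depth 1000, more at low depth); the recovery tests budget for this within
their $\pm 0.1$ tolerance.

Adjacent-SNV correlation (`adjacent_ratio_correlation()`) chains each
tested SNV to its immediate downstream tested neighbor within (condition,
chromosome), bins pairs by distance (default log-spaced edges up to 10 kb),
and reports per-bin Pearson correlation with a 95% band from permuting
ratios among tested SNVs within condition. The pairing is fixed under that
permutation, so pair indices are computed once.

The activity spectrum (`activity_spectrum()`) summarizes per-class
cell-type activity as MCV — the fraction of reference DHS catalogs
containing the site, scaled to $[0,1]$ — as a CDF per SNV class, plus
per-catalog overlap proportions.

# Motif profiles and enrichment

SNVs are assigned to the best overlapping instance per motif (smallest
match p-value; ties to the leftmost start, then + strand), with positions
expressed in motif orientation (minus-strand matches mirrored). Profiles
tally tested and imbalanced SNVs per position; positions with fewer than 7
SNVs are missing data, and a motif passes QC with a median of at least 40
tested SNVs per position and at least 3 positions with 7 or more imbalanced
SNVs. Core-vs-flank enrichment is
$\log_2$ of the imbalance-rate ratio between the match and its $\pm$10 bp
flanks with a Haldane-Anscombe pseudocount of 0.5; the flank width is a
configurable choice (kept within the footprint-scale neighborhood), and the
per-cell-type gate for model training is strict: $\log_2$ enrichment $> 1$,
i.e. more than two-fold. Footprint-stratified rates carry Wilson 95%
intervals. The "stringent match" threshold for overall motif overlap is
$p < 10^{-5}$.

# Two-stage variant scoring

Stage one is a logistic regression of imbalance labels on standardized
genomic annotations — cell-type activity (MCV), intron/intergenic flags,
log distance to TSS, DHS strength and log width, footprint presence,
nearby-binding-site count, conservation — with squared columns added for
MCV, log TSS distance, DHS strength and the nearby-site count (the
polynomial-expansion reading of squared formula terms). Distances and
widths use $\log(x+1)$ to admit zeros. Standardization is two-step:
quantitative columns of one cohort are first rescaled by the ratio of mean
annotation values against a reference cohort (so that cohorts measured on
different genomes share units), then all columns are z-scored with the
pooled training mean/SD; both parameter sets are stored in the model bundle
and reused verbatim at scoring time.

Stage two fits, per TF, a logistic model on SNVs overlapping the motif:
global-model probability, log match score (linear and squared), the
ref-vs-alt log-odds difference, and per-position indicator covariates for
positions with at least 7 rows (the same missing-data rule as the
profiles). Training rows are restricted to cell types passing the
enrichment gate; TFs below a minimum row count are skipped. The identity of
the per-motif covariates beyond score and log-odds difference is a design
choice here: per-position indicators encode where in the motif the variant
falls, which is the dominant axis of disruption severity.

The combiner is a lasso-penalized logistic regression (glmnet) over the
best per-TF-cluster scores at each SNV, with the global probability as its
own column — which is also the fallback pathway scoring SNVs that overlap
no motif. Folds (default 50) are assigned by seeded permutation stratified
by label, the penalty is chosen at maximum cross-validated AUC
(`lambda.min`; the 1-SE rule was considered and rejected as needlessly
conservative at these cohort sizes), and a structural all-zero column pads
degenerate one-feature cases. Evaluation is by precision-recall with the
prevalence baseline reported alongside; the area is a trapezoid on the
recall grid and is checked against an exhaustive threshold sweep.

# Expression linkage

Transcript-level counts aggregate non-exonic SNVs per transcript and
condition (exonic SNVs excluded to avoid allele-specific expression of the
transcript contaminating the accessibility readout; an SNV overlapping two
transcripts counts for both). Transcript calls use the same beta-binomial
machinery with thresholds of 50 total reads and a strict 60% major-allele
fraction at FDR 10%. DHS-TSS pairs are formed for all combinations within
500 kb in the same condition — all pairs, not nearest-gene — with the DHS
anchored at its hotspot midpoint and distance signed in transcript
orientation (positive downstream). Per-bin Pearson correlations use
mirrored log-spaced signed bins out to $\pm$500 kb, and the null band is
the 2.5-97.5 percentile range of 1000 permutations of DHS ratios among
pairs within condition.

# Numerical and engineering choices

* All internal coordinates are 0-based half-open; VCF converts at the
  boundary, BED is native. Chromosome names are opaque strings.
* Duplicate count-table keys are summed (replicate pooling), never
  rejected; negative counts are a hard error.
* Autosomes only by default in the synthetic genome; chrX handling is left
  to the caller's input preparation.
* Degenerate inputs: empty files parse to empty tables; zero-variance bins
  and sub-minimum bins are masked `NA`, never silently dropped rows;
  constant model columns are dropped with a warning.
* Problem sizes in the shipped tests and drivers (cohorts of 2,000-50,000
  SNVs, 20 benchmark seeds, 200-1000 permutations) were chosen so each
  analysis completes in seconds to a few minutes on one CPU while leaving
  Monte-Carlo error well inside the asserted tolerances.

# Known limitations

* The mapping stage (trimming, alignment, strain-genome construction,
  peak calling, motif scanning) is out of scope; the package consumes
  their outputs.
* $1 - \pi_0$ sharing is mildly conservative for discrete tests at low
  depth (see above).
* The per-TF covariate block is a stand-in for richer motif-disruption
  features (e.g. binding-energy models).
* Synthetic cohorts cannot certify behavior under mapping bias or
  dispersion misspecification; on real data, inspect the genome-wide
  allelic-ratio histogram for symmetry about 0.5 before trusting calls.
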