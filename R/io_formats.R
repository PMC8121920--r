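#' @importFrom utils read.table write.table head
#' @importFrom stats median sd quantile setNames
NULL

# All internal coordinates are 0-based half-open. VCF input (1-based) is
# converted at the boundary; BED is consumed verbatim.

#' Read variants from a minimal VCF-like file
#'
#' Parses the first five whitespace-delimited columns (CHROM, POS, ID, REF,
#' ALT) of a VCF-like file. Multi-allelic records (comma-separated ALT) are
#' split into one record per alternate allele. Records where both REF and ALT
#' are single bases become SNVs; all others become indels with signed length
#' (insertion > 0, deletion < 0). Positions are converted from VCF 1-based to
#' the package-internal 0-based convention.
#'
#' @param path Path to a VCF-like file. Header lines starting with `#` are
#'   skipped.
#' @param strain_id Optional strain label attached to every SNV.
#' @return A list with elements `snvs` (data.frame: `chrom`, `pos`,
#'   `ref_allele`, `alt_allele`, `strain_id`, `snv_id`) and `indels`
#'   (data.frame: `chrom`, `pos`, `length`). SNV records with a non-ACGT
#'   allele are dropped with a warning reporting how many were rejected.
#' @export
read_variants <- function(path, strain_id = NA_character_) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(list(
      snvs = data.frame(chrom = character(), pos = integer(),
                        ref_allele = character(), alt_allele = character(),
                        strain_id = character(), snv_id = character(),
                        stringsAsFactors = FALSE),
      indels = data.frame(chrom = character(), pos = integer(),
                          length = integer(), stringsAsFactors = FALSE)))
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 5L)) {
    stop("malformed VCF record at line ", which(nf < 5L)[1L],
         ": fewer than 5 columns")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  pos1 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  if (anyNA(pos1)) {
    stop("malformed VCF record at line ", which(is.na(pos1))[1L],
         ": non-integer POS")
  }
  id <- vapply(fields, `[[`, character(1), 3L)
  ref <- toupper(vapply(fields, `[[`, character(1), 4L))
  alt_raw <- toupper(vapply(fields, `[[`, character(1), 5L))

  # split multi-allelic records
  alt_list <- strsplit(alt_raw, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  idx <- rep.int(seq_along(chrom), n_alt)
  chrom <- chrom[idx]; pos1 <- pos1[idx]; id <- id[idx]; ref <- ref[idx]
  alt <- unlist(alt_list, use.names = FALSE)

  pos0 <- pos1 - 1L
  is_snv <- nchar(ref) == 1L & nchar(alt) == 1L
  bases <- c("A", "C", "G", "T")
  ok_allele <- ref %in% bases & alt %in% bases
  bad_snv <- is_snv & !ok_allele
  if (any(bad_snv)) {
    warning(sum(bad_snv), " SNV record(s) rejected: non-ACGT allele")
  }
  keep_snv <- is_snv & ok_allele
  snv_id <- ifelse(id == "." | !nzchar(id),
                   paste0(chrom, ":", pos0, ":", ref, ":", alt), id)
  snvs <- data.frame(
    chrom = chrom[keep_snv], pos = pos0[keep_snv],
    ref_allele = ref[keep_snv], alt_allele = alt[keep_snv],
    strain_id = rep_len(strain_id, sum(keep_snv)),
    snv_id = snv_id[keep_snv],
    stringsAsFactors = FALSE)
  ind <- !is_snv
  indels <- data.frame(
    chrom = chrom[ind], pos = pos0[ind],
    length = nchar(alt[ind]) - nchar(ref[ind]),
    stringsAsFactors = FALSE)
  indels <- indels[indels$length != 0L, , drop = FALSE]
  rownames(snvs) <- rownames(indels) <- NULL
  list(snvs = snvs, indels = indels)
}

#' Read genomic intervals from a BED file
#'
#' BED3+ input, 0-based half-open, preserved verbatim. Optional 4th/5th/6th
#' columns are carried as `name`, `score`, `strand`. Records with
#' `start >= end` are rejected with a warning.
#'
#' @param path Path to a BED file.
#' @return data.frame with columns `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track") &
                 nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "[ \t]+")
  if (min(lengths(fields)) < 3L) {
    stop("BED record with fewer than 3 columns")
  }
  nf <- max(lengths(fields))
  col <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[[i]] else NA_character_, character(1))
  out <- data.frame(
    chrom = col(1L), start = as.integer(col(2L)), end = as.integer(col(3L)),
    stringsAsFactors = FALSE)
  if (nf >= 4L) out$name <- col(4L)
  if (nf >= 5L) out$score <- as.numeric(col(5L))
  if (nf >= 6L) out$strand <- col(6L)
  bad <- out$start >= out$end
  if (any(bad)) {
    warning(sum(bad), " BED record(s) rejected: start >= end")
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Read an allele-count table
#'
#' Reads a TSV with columns `snv_id`, `condition_id`, `ref_count`,
#' `nonref_count` into the long-format allele-count matrix used throughout the
#' package. Rows sharing a (snv_id, condition_id) key are summed, matching the
#' pooling of replicate samples.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return data.frame keyed by (`snv_id`, `condition_id`) with integer
#'   `ref_count`, `nonref_count`.
#' @export
read_count_table <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("snv_id", "condition_id", "ref_count", "nonref_count")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("count table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(x) == 0L) {
    return(data.frame(snv_id = character(), condition_id = character(),
                      ref_count = integer(), nonref_count = integer(),
                      stringsAsFactors = FALSE))
  }
  if (any(x$ref_count < 0 | x$nonref_count < 0)) {
    stop("negative allele count in ", path)
  }
  aggregate_counts(x)
}

# Sum duplicate (snv_id, condition_id) keys in a long count table.
aggregate_counts <- function(x) {
  key <- paste(x$snv_id, x$condition_id, sep = "\r")
  if (anyDuplicated(key)) {
    ref <- rowsum(x$ref_count, key, reorder = FALSE)
    nonref <- rowsum(x$nonref_count, key, reorder = FALSE)
    first <- !duplicated(key)
    x <- data.frame(snv_id = x$snv_id[first],
                    condition_id = x$condition_id[first],
                    ref_count = as.integer(ref[, 1L]),
                    nonref_count = as.integer(nonref[, 1L]),
                    stringsAsFactors = FALSE)
  }
  rownames(x) <- NULL
  x
}

#' Write result tables with deterministic layout
#'
#' Writes each named data.frame in `tables` to `<prefix>_<name>.tsv` with a
#' fixed column order (as given) and a deterministic row sort: if the columns
#' `chrom`/`pos`/`condition_id` are present the rows are ordered by them,
#' otherwise by the first column. Numeric columns are serialized with enough
#' significant digits that reading the file back reproduces the values to
#' 1e-6 (integers exactly).
#'
#' @param tables Named list of data.frames.
#' @param prefix Path prefix for output files.
#' @return Invisibly, the character vector of files written.
#' @export
write_results <- function(tables, prefix) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  written <- character(0)
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    stopifnot(is.data.frame(tab))
    sort_cols <- intersect(c("chrom", "pos", "condition_id"), names(tab))
    if (length(sort_cols) == 0L && ncol(tab) > 0L) sort_cols <- names(tab)[1L]
    if (nrow(tab) > 1L && length(sort_cols) > 0L) {
      tab <- tab[do.call(order, tab[sort_cols]), , drop = FALSE]
    }
    num <- vapply(tab, is.double, logical(1))
    tab[num] <- lapply(tab[num], function(v) signif(v, 9))
    path <- paste0(prefix, "_", nm, ".tsv")
    ok <- tryCatch({
      write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
      TRUE
    }, error = function(e) stop("cannot write ", path, ": ",
                                conditionMessage(e)))
    written <- c(written, path)
  }
  invisible(written)
}

#' Read back a result table written by [write_results()]
#'
#' @param path Path to a TSV produced by [write_results()].
#' @return data.frame.
#' @export
read_results_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
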