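#' Quality-control configuration
#'
#' Thresholds of the post-alignment QC cascade applied to platelet RNA-seq
#' count matrices: a coverage filter dropping genes with fewer than
#' `min_reads_per_gene` intron-spanning reads in more than
#' `min_fraction_below` of samples, a complexity filter dropping samples
#' with fewer than `min_detected_rnas` detected RNAs, and a
#' leave-one-sample-out cross-correlation filter with threshold
#' `crosscorr_threshold`. All boundaries are strict: a gene at exactly the
#' fraction boundary, or a sample at exactly the detected-RNA or
#' correlation threshold, is kept.
#'
#' @param min_reads_per_gene Read-count threshold per gene (default 30).
#' @param min_fraction_below Fraction of samples allowed below it (default 0.90).
#' @param min_detected_rnas Minimum number of genes with at least one read
#'   (default 750).
#' @param crosscorr_threshold Leave-one-out correlation below which a sample
#'   is removed (default 0.3).
#' @param excluded_genes Optional gene ids (e.g. mitochondrially encoded
#'   RNAs) dropped before any statistic is computed.
#' @return A `qc_config` list.
#' @export
qc_config <- function(min_reads_per_gene = 30,
                      min_fraction_below = 0.90,
                      min_detected_rnas = 750,
                      crosscorr_threshold = 0.3,
                      excluded_genes = NULL) {
  stopifnot(min_reads_per_gene >= 0,
            min_fraction_below > 0, min_fraction_below < 1,
            crosscorr_threshold >= -1, crosscorr_threshold <= 1,
            min_detected_rnas >= 0)
  structure(list(min_reads_per_gene = min_reads_per_gene,
                 min_fraction_below = min_fraction_below,
                 min_detected_rnas = min_detected_rnas,
                 crosscorr_threshold = crosscorr_threshold,
                 excluded_genes = excluded_genes),
            class = "qc_config")
}

#' Remove genes with insufficient coverage
#'
#' A gene is removed iff the fraction of samples in which its count falls
#' below `min_reads_per_gene` strictly exceeds `min_fraction_below`.
#' Genes listed in `cfg$excluded_genes` are dropped first.
#'
#' @param counts Count matrix (genes x samples).
#' @param cfg A [qc_config()].
#' @return The filtered count matrix (same samples).
#' @export
filter_low_coverage_genes <- function(counts, cfg = qc_config()) {
  check_counts(counts)
  if (length(cfg$excluded_genes)) {
    counts <- counts[!rownames(counts) %in% cfg$excluded_genes, , drop = FALSE]
  }
  frac_below <- rowMeans(counts < cfg$min_reads_per_gene)
  keep <- frac_below <= cfg$min_fraction_below
  if (!any(keep)) abort("Coverage filter removed every gene.")
  counts[keep, , drop = FALSE]
}

#' Remove low-complexity samples
#'
#' A sample is removed iff the number of genes with at least one read is
#' strictly below `min_detected_rnas`.
#'
#' @inheritParams filter_low_coverage_genes
#' @return The filtered count matrix (same genes).
#' @export
filter_low_complexity_samples <- function(counts, cfg = qc_config()) {
  check_counts(counts)
  detected <- colSums(counts >= 1)
  keep <- detected >= cfg$min_detected_rnas
  if (!any(keep)) abort("Complexity filter removed every sample.")
  counts[, keep, drop = FALSE]
}

loo_crosscorr <- function(logcpm) {
  n <- ncol(logcpm)
  vapply(seq_len(n), function(i) {
    ref <- apply(logcpm[, -i, drop = FALSE], 1, median)
    suppressWarnings(cor(logcpm[, i], ref))
  }, numeric(1))
}

#' Remove outlier samples by leave-one-sample-out cross-correlation
#'
#' Each sample's log2(cpm + 1) profile is correlated (Pearson) with the
#' median profile of all other samples; samples whose correlation falls
#' strictly below `crosscorr_threshold` are removed. The per-sample values
#' are returned so that the decision is auditable.
#'
#' @inheritParams filter_low_coverage_genes
#' @return List with `counts` (filtered matrix) and `report` (tibble with
#'   `sample_id`, `crosscorr`, `removed`).
#' @export
filter_outlier_samples_crosscorr <- function(counts, cfg = qc_config()) {
  check_counts(counts)
  if (ncol(counts) < 3) abort("Cross-correlation filter needs at least 3 samples.")
  cpm <- sweep(counts, 2, pmax(colSums(counts), 1), `/`) * 1e6
  logcpm <- log2(cpm + 1)
  cc <- loo_crosscorr(logcpm)
  cc[is.na(cc)] <- -1  # constant profile: maximally dissimilar
  removed <- cc < cfg$crosscorr_threshold
  report <- tibble(sample_id = colnames(counts), crosscorr = cc, removed = removed)
  if (all(removed)) abort("Cross-correlation filter removed every sample.")
  list(counts = counts[, !removed, drop = FALSE], report = report)
}

#' Run the full QC cascade
#'
#' Applies, in order: the optional gene-exclusion list, the gene coverage
#' filter, the detected-RNA sample filter and the leave-one-sample-out
#' cross-correlation filter.
#'
#' @inheritParams filter_low_coverage_genes
#' @return List of class `tep_qc` with `counts` (clean matrix) and `report`.
#' @export
run_qc <- function(counts, cfg = qc_config()) {
  check_counts(counts)
  n_genes_in <- nrow(counts); n_samples_in <- ncol(counts)
  m1 <- filter_low_coverage_genes(counts, cfg)
  detected <- colSums(m1 >= 1)
  m2 <- filter_low_complexity_samples(m1, cfg)
  cc <- filter_outlier_samples_crosscorr(m2, cfg)
  report <- list(
    genes_in = n_genes_in, samples_in = n_samples_in,
    genes_removed = n_genes_in - nrow(m1),
    samples_removed_low_complexity = ncol(m1) - ncol(m2),
    samples_removed_crosscorr = ncol(m2) - ncol(cc$counts),
    detected_rnas = tibble(sample_id = colnames(m1), detected_rnas = detected),
    crosscorr = cc$report,
    config = cfg)
  structure(list(counts = cc$counts, report = report), class = "tep_qc")
}

#' @export
print.tep_qc <- function(x, ...) {
  r <- x$report
  cat("TEP QC report\n")
  cat(sprintf("  genes:   %d -> %d (%d removed by coverage filter)\n",
              r$genes_in, nrow(x$counts), r$genes_removed))
  cat(sprintf("  samples: %d -> %d (%d low-complexity, %d low cross-correlation)\n",
              r$samples_in, ncol(x$counts),
              r$samples_removed_low_complexity, r$samples_removed_crosscorr))
  invisible(x)
}

#' @export
glance.tep_qc <- function(x, ...) {
  r <- x$report
  tibble(genes_in = r$genes_in, genes_kept = nrow(x$counts),
         genes_removed = r$genes_removed,
         samples_in = r$samples_in, samples_kept = ncol(x$counts),
         samples_removed_low_complexity = r$samples_removed_low_complexity,
         samples_removed_crosscorr = r$samples_removed_crosscorr)
}
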