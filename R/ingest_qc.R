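#' Quality-control thresholds for samples and genes
#'
#' Container for the filtering thresholds applied to the per-cell QC metrics
#' table and to the gene-by-cell count matrix. Defaults are the study
#' criteria: at least 1,309,921 mapped reads, under 44% unmapped reads,
#' under 18% ERCC reads, at least 6292 genes detected, at least one EGFP
#' molecule (the reporter transgene must be transcribed), genes capped at
#' 6^4 = 1296 total molecules, and a minimum mean CPM of 2.
#'
#' @param min_mapped_reads,max_pct_unmapped,max_pct_ercc,min_genes_detected,min_egfp_molecules
#'   Sample-level thresholds.
#' @param max_gene_total_molecules,min_gene_mean_cpm Gene-level thresholds.
#' @return A named list of class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(min_mapped_reads = 1309921,
                          max_pct_unmapped = 0.44,
                          max_pct_ercc = 0.18,
                          min_genes_detected = 6292,
                          min_egfp_molecules = 1,
                          max_gene_total_molecules = 6^4,
                          min_gene_mean_cpm = 2) {
  th <- list(min_mapped_reads = min_mapped_reads,
             max_pct_unmapped = max_pct_unmapped,
             max_pct_ercc = max_pct_ercc,
             min_genes_detected = min_genes_detected,
             min_egfp_molecules = min_egfp_molecules,
             max_gene_total_molecules = max_gene_total_molecules,
             min_gene_mean_cpm = min_gene_mean_cpm)
  bad <- names(th)[vapply(th, function(x) !is.numeric(x) || x < 0, logical(1))]
  if (length(bad)) stop("thresholds must be nonnegative: ",
                        paste(bad, collapse = ", "))
  structure(th, class = "qc_thresholds")
}

metadata_required_cols <- c(
  "cell_id", "cells_in_well", "egfp_molecules",
  "verified_individual_on_chip", "mapped_reads", "pct_unmapped",
  "pct_ercc", "genes_detected")

#' Select cells passing the sample-level quality filters
#'
#' A cell passes iff exactly one cell was observed in its well, at least one
#' molecule mapped to the EGFP transgene, its assigned individual was
#' verified to be on the chip, and its mapping metrics clear the thresholds
#' (mapped reads and genes detected at-or-above their minima; unmapped and
#' ERCC fractions strictly below their maxima).
#'
#' @param metadata Data frame with one row per cell and columns `cell_id`,
#'   `cells_in_well`, `egfp_molecules`, `verified_individual_on_chip`,
#'   `mapped_reads`, `pct_unmapped`, `pct_ercc`, `genes_detected`.
#' @param thresholds A [qc_thresholds()] object.
#' @return Character vector of passing `cell_id`s, in input order.
#' @export
apply_sample_filters <- function(metadata, thresholds = qc_thresholds()) {
  missing_cols <- setdiff(metadata_required_cols, names(metadata))
  if (length(missing_cols))
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(metadata$cell_id))
    stop("metadata must have one row per cell_id")
  if (nrow(metadata) == 0) return(character(0))
  frac_cols <- c("pct_unmapped", "pct_ercc")
  for (fc in frac_cols)
    if (any(metadata[[fc]] < 0 | metadata[[fc]] > 1))
      stop(fc, " must be a fraction in [0, 1]")
  pass <- metadata$cells_in_well == 1 &
    metadata$egfp_molecules >= thresholds$min_egfp_molecules &
    as.logical(metadata$verified_individual_on_chip) &
    metadata$mapped_reads >= thresholds$min_mapped_reads &
    metadata$pct_unmapped < thresholds$max_pct_unmapped &
    metadata$pct_ercc < thresholds$max_pct_ercc &
    metadata$genes_detected >= thresholds$min_genes_detected
  as.character(metadata$cell_id[pass])
}

#' Select genes passing the expression filters
#'
#' A gene is excluded iff its total molecule count across the (retained)
#' cells exceeds `max_gene_total_molecules` (overexpressed) or its mean CPM
#' is strictly below `min_gene_mean_cpm` (lowly expressed). CPM here is
#' computed from the supplied matrix's own column totals.
#'
#' @param counts Genes-by-cells nonnegative integer matrix with gene
#'   identifiers as row names.
#' @param thresholds A [qc_thresholds()] object.
#' @return Character vector of passing gene identifiers, in input order.
#' @export
apply_gene_filters <- function(counts, thresholds = qc_thresholds()) {
  counts <- validate_counts(counts)
  totals <- colSums(counts)
  if (all(totals == 0)) stop("all-zero count matrix: CPM undefined")
  cpm <- compute_cpm(counts, pmax(totals, 1L))
  cpm[, totals == 0] <- 0
  gene_total <- rowSums(counts)
  mean_cpm <- rowMeans(cpm)
  keep <- !(gene_total > thresholds$max_gene_total_molecules |
              mean_cpm < thresholds$min_gene_mean_cpm)
  rownames(counts)[keep]
}

#' Counts per million
#'
#' Scales each column by its per-cell total molecule count times 1e6. The
#' totals are supplied separately so that they can be the pre-gene-filter
#' per-cell sums (the denominator is the full library, even after genes
#' have been dropped).
#'
#' @param counts Genes-by-cells matrix.
#' @param per_cell_totals Strictly positive per-cell totals, one per column.
#' @return A genes-by-cells numeric matrix.
#' @export
compute_cpm <- function(counts, per_cell_totals) {
  counts <- validate_counts(counts)
  if (length(per_cell_totals) != ncol(counts))
    stop("per_cell_totals must have one entry per cell")
  zero <- which(per_cell_totals <= 0)
  if (length(zero)) {
    ids <- colnames(counts)[zero]
    if (is.null(ids)) ids <- zero
    stop("zero per-cell total for cell(s): ",
         paste(utils::head(ids, 5), collapse = ", "))
  }
  sweep(counts, 2, per_cell_totals, "/") * 1e6
}

#' Quantile-normalize each gene to a standard normal
#'
#' Replaces each gene's values by standard-normal plotting-position
#' quantiles \eqn{\Phi^{-1}((r - 0.5)/n)}, where `r` is the within-gene rank
#' (1 = smallest). Ties — in particular the block of zero counts, which
#' receives the lowest ranks — are broken uniformly at random under the
#' supplied seed, so the result is reproducible.
#'
#' @param mat Genes-by-cells numeric matrix (e.g. CPM).
#' @param seed Integer seed for tie-breaking.
#' @return Matrix of the same shape on the standard-normal quantile scale.
#' @export
quantile_normalize <- function(mat, seed = 1) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  n <- ncol(mat)
  if (n < 2) stop("need at least 2 cells")
  qq <- stats::qnorm((seq_len(n) - 0.5) / n)
  out <- with_seed(seed, {
    t(apply(mat, 1, function(x) qq[rank(x, ties.method = "random")]))
  })
  dimnames(out) <- dimnames(mat)
  out
}

# Coerce/validate a genes-by-cells count matrix: nonnegative, no duplicate
# identifiers.
validate_counts <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative entries in count matrix")
  if (!is.null(rownames(counts)) && anyDuplicated(rownames(counts)))
    stop("duplicated gene identifiers")
  if (!is.null(colnames(counts)) && anyDuplicated(colnames(counts)))
    stop("duplicated cell identifiers")
  counts
}
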