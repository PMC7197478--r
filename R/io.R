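#' Read a gene-by-cell count matrix
#'
#' Reads either MatrixMarket format (`.mtx`, with gene and cell identifier
#' sidecar files, one identifier per line) or a dense tab-separated table
#' (genes as rows, first column gene identifiers, header = cell
#' identifiers). The format is chosen by file extension.
#'
#' @param path Path to the `.mtx` or `.tsv` file.
#' @param genes_path,cells_path Sidecar identifier files; default
#'   `<path>.genes.txt` / `<path>.cells.txt` next to an `.mtx` file.
#' @return A genes-by-cells integer matrix with dimnames.
#' @export
read_count_matrix <- function(path, genes_path = NULL, cells_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    if (is.null(genes_path)) genes_path <- paste0(path, ".genes.txt")
    if (is.null(cells_path)) cells_path <- paste0(path, ".cells.txt")
    for (p in c(genes_path, cells_path))
      if (!file.exists(p)) stop("missing identifier sidecar file: ", p)
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(genes_path)
    colnames(m) <- readLines(cells_path)
  } else {
    df <- utils::read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
  }
  storage.mode(m) <- "integer"
  validate_counts(m)
}

#' Write a gene-by-cell count matrix
#'
#' Inverse of [read_count_matrix()]; the format follows the extension.
#'
#' @param counts Genes-by-cells matrix with dimnames.
#' @param path Output `.mtx` or `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  counts <- validate_counts(counts)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(path, ".genes.txt"))
    writeLines(colnames(counts), paste0(path, ".cells.txt"))
  } else {
    df <- data.frame(gene_id = rownames(counts), counts,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read the per-cell QC metrics table
#'
#' Tab-separated with a header; must contain the columns required by
#' [apply_sample_filters()].
#'
#' @param path Path to the TSV file.
#' @return A data frame with one row per cell.
#' @export
read_cell_metadata <- function(path) {
  md <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(metadata_required_cols, names(md))
  if (length(missing_cols))
    stop("metadata file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  md$verified_individual_on_chip <-
    as.logical(md$verified_individual_on_chip)
  md
}

#' Write a table with a provenance header
#'
#' Writes a TSV preceded by `#`-prefixed provenance lines (package version,
#' seeds, configuration) so that every output records how it was produced.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param provenance Named list of provenance values.
#' @return `path`, invisibly.
#' @export
write_tsv_provenance <- function(df, path, provenance = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  prov <- c(list(package = paste0("fuccicycle ",
                                  as.character(utils::packageVersion("fuccicycle"))),
                 written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            provenance)
  for (nm in names(prov))
    writeLines(sprintf("# %s: %s", nm,
                       paste(format(prov[[nm]]), collapse = ",")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
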