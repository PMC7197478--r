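#' Map a cyclic ordering of cells to equidistant angles
#'
#' The i-th cell of the ordering (0-based) is assigned
#' `theta = 2*pi*i/n`, placing the inferred cyclic order at equidistant
#' points on the unit circle.
#'
#' @param ordering Character vector of cell identifiers (a permutation of
#'   the cell set).
#' @return Named numeric vector of angles in `[0, 2*pi)`.
#' @export
ordering_to_angles <- function(ordering) {
  if (length(ordering) < 1) stop("empty ordering")
  if (anyDuplicated(ordering)) stop("duplicated cell ids in ordering")
  n <- length(ordering)
  stats::setNames(2 * pi * (seq_len(n) - 1) / n, ordering)
}

#' Map discrete-phase score columns to circular angles
#'
#' Applies the same construction used to derive FUCCI phase from reporter
#' scores. With two score columns, each column is mean-centered and the
#' angle is `atan2(col2, col1)` wrapped to `[0, 2*pi)`. With three columns,
#' the centered scores are projected onto their first two principal axes
#' and the angle is taken on the projections (so the result is defined up
#' to a global rotation/reflection of the circle).
#'
#' @param score_matrix Cells-by-2 or cells-by-3 numeric matrix.
#' @return Numeric vector of angles; a cell lying exactly at the column
#'   means gets `NA` with a warning.
#' @export
scores_to_angles <- function(score_matrix) {
  score_matrix <- as.matrix(score_matrix)
  p <- ncol(score_matrix)
  if (!p %in% c(2, 3)) stop("score matrix must have 2 or 3 columns")
  sds <- apply(score_matrix, 2, stats::sd)
  if (any(sds == 0)) stop("constant score column(s): angle undefined")
  ctr <- scale(score_matrix, center = TRUE, scale = FALSE)
  if (p == 3) ctr <- stats::prcomp(ctr, center = FALSE)$x[, 1:2, drop = FALSE]
  degenerate <- rowSums(ctr^2) == 0
  theta <- atan2(ctr[, 2], ctr[, 1]) %% (2 * pi)
  if (any(degenerate)) {
    warning(sum(degenerate), " cell(s) at the column means: angle undefined")
    theta[degenerate] <- NA_real_
  }
  if (!is.null(rownames(score_matrix))) names(theta) <- rownames(score_matrix)
  theta
}

#' Per-class misclassification rates against a reference labeling
#'
#' For each reference class, the fraction of its cells assigned a different
#' label by the prediction.
#'
#' @param pred_labels,ref_labels Vectors of labels in `{G1, S, G2M}`,
#'   aligned by cell.
#' @return Named numeric vector of rates for G1, S and G2M; a class absent
#'   from the reference yields `NA`.
#' @export
misclassification_rates <- function(pred_labels, ref_labels) {
  classes <- c("G1", "S", "G2M")
  pred_labels <- as.character(pred_labels)
  ref_labels <- as.character(ref_labels)
  if (length(pred_labels) != length(ref_labels))
    stop("label vectors must be aligned (same cells)")
  bad <- unique(c(pred_labels, ref_labels))
  bad <- bad[!bad %in% classes]
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  vapply(classes, function(cl) {
    in_cl <- ref_labels == cl
    if (!any(in_cl)) return(NA_real_)
    mean(pred_labels[in_cl] != cl)
  }, numeric(1))
}

#' Variance in FUCCI scores explained by a candidate phase
#'
#' Orders the reporter scores by the candidate phase, fits a cyclic trend
#' to each score column ([fit_cyclic_trend()]), and reports the proportion
#' of variance explained for each. A phase assignment that truly tracks
#' the cell cycle should explain most of the reporter oscillation; an
#' arbitrary ordering should explain very little.
#'
#' @param fucci_scores Data frame or matrix with columns `egfp_score` and
#'   `mcherry_score`.
#' @param candidate_phase Angles in `[0, 2*pi)`, aligned with the rows.
#' @param ... Passed to [fit_cyclic_trend()].
#' @return Named vector `c(pve_egfp, pve_mcherry)`.
#' @export
pve_of_scores_given_phase <- function(fucci_scores, candidate_phase, ...) {
  e <- fucci_scores[, "egfp_score"]
  m <- fucci_scores[, "mcherry_score"]
  if (length(candidate_phase) != length(e))
    stop("candidate_phase must be aligned with the score rows")
  c(pve_egfp = fit_cyclic_trend(e, candidate_phase, ...)$pve,
    pve_mcherry = fit_cyclic_trend(m, candidate_phase, ...)$pve)
}
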