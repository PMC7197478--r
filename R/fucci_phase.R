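#' Correct FUCCI scores for plate effects
#'
#' Fits, for each score column independently, the additive two-factor model
#' `score ~ plate + individual` with sum-to-zero contrasts and subtracts the
#' estimated plate effect from each cell's score, leaving individual effects
#' and residuals in place. Type III F-tests (plate controlling for
#' individual, and vice versa) are reported for each column before and
#' after correction.
#'
#' @param scores Data frame with numeric columns `egfp_score`,
#'   `mcherry_score` (optionally `dapi_score`) and factors `plate_id`,
#'   `individual_id`.
#' @return The data frame with corrected score columns; attributes
#'   `"corrected"` (`TRUE`), `"plate_effects"` (matrix of estimated
#'   per-plate offsets per score column, with standard errors in
#'   `"plate_effect_se"`), and `"anova_pvalues"` (F-test p-values).
#' @export
correct_batch <- function(scores) {
  score_cols <- intersect(c("egfp_score", "mcherry_score", "dapi_score"),
                          names(scores))
  if (length(score_cols) == 0)
    stop("no score columns (egfp_score/mcherry_score/dapi_score) found")
  for (cc in c("plate_id", "individual_id"))
    if (is.null(scores[[cc]])) stop("missing required column: ", cc)
  plate <- factor(scores$plate_id)
  indiv <- factor(scores$individual_id)
  if (nlevels(plate) < 2) {
    warning("only one plate: nothing to correct, scores returned unchanged")
    attr(scores, "corrected") <- TRUE
    return(scores)
  }
  # plate fully confounded with individual <=> the additive design matrix is
  # rank-deficient beyond the usual one-per-factor aliasing
  X <- stats::model.matrix(~ plate + indiv,
                           contrasts.arg = list(plate = "contr.sum",
                                                indiv = "contr.sum"))
  if (qr(X)$rank < ncol(X))
    stop("plate is confounded with individual (design matrix is rank ",
         qr(X)$rank, " < ", ncol(X), "); plate effects are not estimable")
  cross <- table(plate, indiv)
  if (any(rowSums(cross > 0) < 2))
    warning("some plate contains fewer than 2 individuals; ",
            "plate and individual effects may be poorly separated")

  effects <- ses <- matrix(NA_real_, nlevels(plate), length(score_cols),
                           dimnames = list(levels(plate), score_cols))
  pvals <- matrix(NA_real_, 2, length(score_cols),
                  dimnames = list(c("plate", "individual"), score_cols))
  out <- scores
  for (sc in score_cols) {
    dat <- data.frame(y = scores[[sc]], plate = plate, indiv = indiv)
    fit <- stats::lm(y ~ plate + indiv, data = dat,
                     contrasts = list(plate = "contr.sum",
                                      indiv = "contr.sum"))
    # for the additive model, drop1 F-tests are the Type III tests
    an <- stats::drop1(fit, scope = ~ plate + indiv, test = "F")
    pvals["plate", sc] <- an["plate", "Pr(>F)"]
    pvals["individual", sc] <- an["indiv", "Pr(>F)"]
    cf <- stats::coef(fit)
    ip <- grep("^plate", names(cf))
    eff <- c(cf[ip], -sum(cf[ip]))  # sum-to-zero: last level is minus the rest
    names(eff) <- levels(plate)
    vc <- stats::vcov(fit)[ip, ip, drop = FALSE]
    se <- c(sqrt(diag(vc)), sqrt(sum(vc)))
    effects[, sc] <- eff
    ses[, sc] <- se
    out[[sc]] <- scores[[sc]] - eff[as.character(plate)]
  }
  attr(out, "corrected") <- TRUE
  attr(out, "plate_effects") <- effects
  attr(out, "plate_effect_se") <- ses
  attr(out, "anova_pvalues") <- pvals
  out
}

#' Infer circular FUCCI phase from corrected scores
#'
#' Maps each cell's corrected `(EGFP, mCherry)` scores to an angle on the
#' unit circle: both score columns are mean-centered, and the phase is the
#' quadrant-aware inverse tangent `atan2(EGFP_centered, mCherry_centered)`,
#' wrapped to `[0, 2*pi)` (mCherry on the x-axis, EGFP on the y-axis). An
#' optional global rotation can be added, since the zero-angle anchor is a
#' convention; training and prediction must simply share it.
#'
#' @param scores Plate-corrected score table (see [correct_batch()]).
#' @param rotation Global rotation offset in radians (default 0).
#' @param require_corrected Refuse raw (uncorrected) scores (default TRUE).
#' @return Numeric vector of angles in `[0, 2*pi)`, named by `cell_id` when
#'   present. Centering constants are stored in attribute `"centers"`.
#' @export
infer_fucci_phase <- function(scores, rotation = 0,
                              require_corrected = TRUE) {
  if (require_corrected && !isTRUE(attr(scores, "corrected")))
    stop("scores are not batch-corrected; run correct_batch() first ",
         "(or set require_corrected = FALSE)")
  e <- scores$egfp_score - mean(scores$egfp_score)
  m <- scores$mcherry_score - mean(scores$mcherry_score)
  degenerate <- e == 0 & m == 0
  if (any(degenerate))
    stop("angle undefined (both centered scores zero) for cell(s): ",
         paste(utils::head(which(degenerate), 5), collapse = ", "))
  theta <- (atan2(e, m) + rotation) %% (2 * pi)
  if (!is.null(scores$cell_id)) names(theta) <- scores$cell_id
  attr(theta, "centers") <- c(egfp = mean(scores$egfp_score),
                              mcherry = mean(scores$mcherry_score))
  theta
}

#' Discrete G1/S/G2M assignment by partition around medoids
#'
#' Clusters cells in the 2-D `(EGFP, mCherry)` score plane with PAM
#' (k = 3, Euclidean distance) and labels the clusters by medoid position:
#' the medoid maximizing `mCherry - EGFP` is G1 (CDT1 high), the medoid
#' maximizing `EGFP - mCherry` is G2M (geminin high), and the remaining
#' cluster is S.
#'
#' @param scores Score table with `egfp_score` and `mcherry_score`.
#' @return Factor of labels in `{G1, S, G2M}`, one per cell, with per-class
#'   counts in attribute `"counts"` and the medoid coordinates in
#'   `"medoids"`.
#' @export
classify_pam <- function(scores) {
  xy <- cbind(egfp = scores$egfp_score, mcherry = scores$mcherry_score)
  if (nrow(xy) < 3) stop("need at least 3 cells")
  if (nrow(unique(xy)) < 3) stop("need at least 3 distinct score points")
  pm <- cluster::pam(xy, k = 3, metric = "euclidean")
  med <- pm$medoids
  lab <- rep(NA_character_, 3)
  lab[which.max(med[, "mcherry"] - med[, "egfp"])] <- "G1"
  lab[which.max(med[, "egfp"] - med[, "mcherry"])] <- "G2M"
  lab[is.na(lab)] <- "S"
  labels <- factor(lab[pm$clustering], levels = c("G1", "S", "G2M"))
  attr(labels, "counts") <- table(labels)
  attr(labels, "medoids") <- med
  labels
}
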