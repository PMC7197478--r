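#' Grid of candidate cell-cycle phases
#'
#' `K` equally spaced angles `2*pi*k/K`, `k = 0, ..., K-1`.
#'
#' @param K Number of grid points (default 100).
#' @return List with `K` and `angles`.
#' @export
phase_grid <- function(K = 100) {
  K <- as.integer(K)
  if (K < 2) stop("K must be at least 2")
  list(K = K, angles = 2 * pi * (0:(K - 1)) / K)
}

#' Train the continuous phase predictor
#'
#' Learns, for each predictor gene, the cyclic expression trend
#' \eqn{\hat f_g} and residual scale \eqn{\hat\sigma_g} over the training
#' cells' FUCCI phases ([fit_cyclic_trend()]), together with a grid of K
#' candidate phases for likelihood evaluation. The resulting model is a
#' naive-Bayes predictor: per-gene Gaussian likelihoods around the trends,
#' multiplied across genes.
#'
#' @param normalized Genes-by-cells quantile-normalized matrix with gene
#'   identifiers as row names.
#' @param thetas Training FUCCI phases in `[0, 2*pi)`, one per column.
#' @param gene_ids Genes to use. Default: when `cyclic_report` is supplied,
#'   its top `n_genes` by rank; otherwise all rows.
#' @param K Number of candidate phases (default 100).
#' @param cyclic_report Optional ranked cyclic-gene report from
#'   [permutation_test()].
#' @param n_genes Number of top-ranked genes taken from `cyclic_report`
#'   (default 5).
#' @param individuals Optional per-cell individual labels stored in the
#'   training manifest.
#' @param normalization_seed Seed recorded as normalization provenance.
#' @param ... Passed to [fit_cyclic_trend()].
#' @return An object of class `"trained_predictor"`.
#' @export
train_predictor <- function(normalized, thetas, gene_ids = NULL, K = 100,
                            cyclic_report = NULL, n_genes = 5,
                            individuals = NULL, normalization_seed = NA,
                            ...) {
  if (is.null(gene_ids)) {
    gene_ids <- if (!is.null(cyclic_report)) {
      cyclic_report$gene_id[order(cyclic_report$rank)][
        seq_len(min(n_genes, nrow(cyclic_report)))]
    } else rownames(normalized)
  }
  if (length(gene_ids) < 2)
    stop("need at least 2 genes: phase is unidentifiable from one")
  missing_g <- setdiff(gene_ids, rownames(normalized))
  if (length(missing_g))
    stop("gene(s) absent from matrix: ", paste(missing_g, collapse = ", "))
  if (ncol(normalized) < 10) stop("need at least 10 training cells")
  if (length(thetas) != ncol(normalized))
    stop("thetas must have one angle per cell")

  trends <- lapply(gene_ids, function(g) {
    fit_cyclic_trend(normalized[g, ], thetas, gene_id = g, ...)
  })
  names(trends) <- gene_ids
  structure(list(
    trends = trends,
    grid = phase_grid(K),
    genes = gene_ids,
    manifest = list(cell_ids = colnames(normalized),
                    individuals = individuals),
    normalization = list(seed = normalization_seed,
                         plotting_position = "qnorm((r - 0.5)/n)")),
    class = "trained_predictor")
}

#' @export
print.trained_predictor <- function(x, ...) {
  cat(sprintf("trained_predictor: %d genes (%s%s), K = %d, %d training cells\n",
              length(x$genes),
              paste(utils::head(x$genes, 5), collapse = ", "),
              if (length(x$genes) > 5) ", ..." else "",
              x$grid$K, length(x$manifest$cell_ids)))
  invisible(x)
}

#' Evaluate a cyclic trend at arbitrary angles
#'
#' Circular linear interpolation between the two flanking training points,
#' wrapping across the 0 / 2-pi seam.
#'
#' @param trend A `"cyclic_trend"` object.
#' @param theta Angles in `[0, 2*pi)` (vectorized).
#' @return Interpolated trend values.
#' @export
evaluate_trend_at <- function(trend, theta) {
  tt <- trend$train_thetas
  ff <- trend$fitted_values
  if (length(tt) == 0) stop("empty trend")
  if (any(theta < 0 | theta >= 2 * pi)) stop("theta must lie in [0, 2*pi)")
  n <- length(tt)
  # pad with wrapped copies of the extreme points so approx() covers [0, 2pi)
  x <- c(tt[n] - 2 * pi, tt, tt[1] + 2 * pi)
  y <- c(ff[n], ff, ff[1])
  stats::approx(x, y, xout = theta, ties = "ordered")$y
}

#' Predict continuous phase by grid likelihood maximization
#'
#' For each cell, evaluates the log-likelihood
#' \deqn{\log L(k) = \sum_g \log \phi\left(\frac{y_g - \hat f_g(\theta_k)}
#'   {\hat\sigma_g}\right) - \log \hat\sigma_g}
#' at each of the K grid angles (uniform prior over the grid) and returns
#' the maximizing angle; ties break to the smallest grid index. Cells are
#' predicted independently, so batch prediction equals per-cell prediction.
#'
#' @param expression Named numeric vector over the model genes (one cell),
#'   or a genes-by-cells matrix, quantile-normalized by the model's stored
#'   convention.
#' @param model A `"trained_predictor"`.
#' @return Data frame with one row per cell: `cell_id`, `theta_hat`,
#'   `max_loglik`; the full K-column log-likelihood profile matrix is in
#'   attribute `"loglik_profile"`.
#' @export
predict_phase <- function(expression, model) {
  if (!inherits(model, "trained_predictor")) stop("model must be a trained_predictor")
  if (is.null(dim(expression)))
    expression <- matrix(expression, ncol = 1,
                         dimnames = list(names(expression), "cell_1"))
  missing_g <- setdiff(model$genes, rownames(expression))
  if (length(missing_g))
    stop("expression is missing model gene(s): ",
         paste(missing_g, collapse = ", "))
  angles <- model$grid$angles
  G <- length(model$genes)
  # G x K matrix of trend values on the grid
  FK <- t(vapply(model$genes, function(g) {
    evaluate_trend_at(model$trends[[g]], angles)
  }, numeric(length(angles))))
  sig <- vapply(model$genes, function(g) model$trends[[g]]$sigma, numeric(1))
  Y <- expression[model$genes, , drop = FALSE]
  if (any(!is.finite(Y))) stop("nonfinite expression values")
  M <- ncol(Y)
  ll <- matrix(NA_real_, M, length(angles))
  for (k in seq_along(angles))
    ll[, k] <- colSums(stats::dnorm(Y, FK[, k], sig, log = TRUE))
  idx <- apply(ll, 1, which.max)  # ties -> smallest index
  out <- data.frame(
    cell_id = colnames(Y) %||% paste0("cell_", seq_len(M)),
    theta_hat = angles[idx],
    max_loglik = ll[cbind(seq_len(M), idx)])
  attr(out, "loglik_profile") <- ll
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Circular prediction error as a fraction of the cycle
#'
#' `min(|d|, 2*pi - |d|) / (2*pi)` for `d = theta_pred - theta_true`;
#' ranges over `[0, 0.5]`, where 0.5 means diametrically opposite.
#'
#' @param theta_pred,theta_true Angles in `[0, 2*pi)` (vectorized).
#' @return Errors in `[0, 0.5]`.
#' @export
circular_error <- function(theta_pred, theta_true) {
  d <- abs(theta_pred - theta_true) %% (2 * pi)
  pmin(d, 2 * pi - d) / (2 * pi)
}

#' Leave-one-individual-out cross-validation of the phase predictor
#'
#' One fold per individual: the predictor is trained on all other
#' individuals' cells (re-ranking candidate genes by training-set PVE, since
#' with a shared permutation null the empirical p-value is monotone in PVE)
#' and evaluated on the held-out individual's cells by mean circular error.
#'
#' @param normalized Genes-by-cells quantile-normalized matrix.
#' @param thetas FUCCI phases per cell.
#' @param individuals Individual labels per cell.
#' @param gene_ids Candidate genes (default all rows).
#' @param n_top_genes_list Integer vector of predictor sizes to evaluate
#'   (default 5).
#' @param K Grid size (default 100).
#' @param ... Passed to [fit_cyclic_trend()].
#' @return Data frame with one row per (individual, n_genes): `individual`,
#'   `n_genes`, `n_cells`, `mean_error` (fraction of cycle), `se`
#'   (`sd/sqrt(n_cells)`).
#' @export
cross_validate_by_individual <- function(normalized, thetas, individuals,
                                         gene_ids = NULL,
                                         n_top_genes_list = 5, K = 100,
                                         ...) {
  if (is.null(gene_ids)) gene_ids <- rownames(normalized)
  individuals <- as.character(individuals)
  folds <- unique(individuals)
  if (length(folds) < 2) stop("need at least 2 individuals")
  if (length(individuals) != ncol(normalized) ||
      length(thetas) != ncol(normalized))
    stop("individuals and thetas must have one entry per cell")

  res <- list()
  for (ind in folds) {
    test <- individuals == ind
    if (sum(test) < 5)
      warning("individual ", ind, " has fewer than 5 cells; fold still run")
    tr_mat <- normalized[, !test, drop = FALSE]
    tr_theta <- thetas[!test]
    fits <- lapply(gene_ids, function(g) {
      fit_cyclic_trend(tr_mat[g, ], tr_theta, gene_id = g, ...)
    })
    names(fits) <- gene_ids
    ranked <- gene_ids[order(-vapply(fits, `[[`, numeric(1), "pve"))]
    for (ng in n_top_genes_list) {
      top <- ranked[seq_len(min(ng, length(ranked)))]
      model <- structure(list(
        trends = fits[top], grid = phase_grid(K), genes = top,
        manifest = list(cell_ids = colnames(tr_mat),
                        individuals = individuals[!test]),
        normalization = list(seed = NA,
                             plotting_position = "qnorm((r - 0.5)/n)")),
        class = "trained_predictor")
      pred <- predict_phase(normalized[, test, drop = FALSE], model)
      err <- circular_error(pred$theta_hat, thetas[test])
      res[[length(res) + 1]] <- data.frame(
        individual = ind, n_genes = length(top), n_cells = sum(test),
        mean_error = mean(err), se = stats::sd(err) / sqrt(sum(test)))
    }
  }
  do.call(rbind, res)
}
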