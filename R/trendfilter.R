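#' Order-2 (quadratic) trend filtering
#'
#' Solves the L1 trend-filtering problem on an evenly spaced series,
#' \deqn{\min_\beta \frac{1}{2}\sum_i (y_i - \beta_i)^2 +
#'       \lambda \|D^{(3)}\beta\|_1,}
#' where \eqn{D^{(3)}} is the third-order discrete difference operator
#' (stencil \eqn{-1, 3, -3, 1}), yielding a piecewise-quadratic fit. The
#' solver is a specialized ADMM with an exact total-variation proximal step.
#'
#' @param y Numeric vector (finite values, length at least 4).
#' @param lambda Nonnegative penalty. May be a vector, in which case the
#'   path is solved with warm starts (fastest when sorted decreasing).
#' @param order Trend-filter order; only `2` (quadratic) is supported.
#' @param max_iter Maximum ADMM iterations per penalty value.
#' @param tol Convergence tolerance on the primal/dual residuals.
#' @return For scalar `lambda`, the fitted vector; otherwise a matrix with
#'   one column per penalty value.
#' @examples
#' y <- cos(seq(0, 2 * pi, length.out = 50)) + rnorm(50, sd = 0.2)
#' f <- trendfilter_solve(y, lambda = 5)
#' @export
trendfilter_solve <- function(y, lambda, order = 2, max_iter = 5000,
                              tol = 1e-8) {
  if (order != 2)
    stop("only order-2 (quadratic) trend filtering is implemented")
  y <- as.numeric(y)
  if (length(y) < order + 2)
    stop("need at least ", order + 2, " points")
  if (any(!is.finite(y))) stop("nonfinite values in input series")
  if (any(lambda < 0)) stop("lambda must be nonnegative")
  fit <- .tf_admm_path(y, as.numeric(lambda), 1.0, as.integer(max_iter), tol)
  if (length(lambda) == 1L) drop(fit) else fit
}

#' Smallest penalty at which the trend-filter fit is the quadratic polynomial
#'
#' Returns \eqn{\lambda_{max} = \|(D D^\top)^{-1} D y\|_\infty} for the
#' third-order difference operator \eqn{D}; for any larger penalty the
#' solution equals the least-squares quadratic in the index.
#'
#' @param y Numeric vector, length at least 4.
#' @return A nonnegative scalar.
#' @export
trendfilter_lambda_max <- function(y) {
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop("nonfinite values in input series")
  .tf_lambda_max(y)
}

# Log-spaced penalty grid, descending from lambda_max.
tf_lambda_grid <- function(y, n_lambda = 50, lambda_min_ratio = 1e-5) {
  lmax <- trendfilter_lambda_max(y)
  if (lmax <= 0) lmax <- 1e-12
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

#' Deterministic ordered fold assignment
#'
#' The point at 1-based ordered position `i` goes to fold
#' `((i - 1) mod n_folds) + 1`: every k-th data point of the ordered series
#' lands in the k-th fold, so each fold is an ordered subsample.
#'
#' @param n Number of points.
#' @param n_folds Number of folds.
#' @return Integer vector of fold labels in `1..n_folds`.
#' @export
cv_fold_assignment <- function(n, n_folds = 5) {
  ((seq_len(n) - 1L) %% as.integer(n_folds)) + 1L
}

#' Cross-validated penalty selection for trend filtering
#'
#' Selects the trend-filter penalty by ordered k-fold cross-validation with
#' the one-standard-error rule. Folds are deterministic: the point at
#' 1-based position `i` of the ordered series goes to fold
#' `((i - 1) mod n_folds) + 1`, so each fold is an ordered subsample.
#' Held-out points are predicted by linear interpolation between the fitted
#' values at the flanking training positions (constant extrapolation at the
#' series ends). The returned penalty is the largest value on the grid whose
#' mean CV error is within one standard error of the minimum.
#'
#' @param y Ordered numeric series.
#' @param n_folds Number of folds (default 5).
#' @param n_lambda Grid size (default 50 log-spaced values spanning
#'   `[lambda_max * lambda_min_ratio, lambda_max]`).
#' @param lambda_min_ratio Ratio of the smallest to the largest grid value.
#' @param max_iter,tol Solver controls passed to [trendfilter_solve()].
#' @return A list with `lambda_1se` and `cv_table` (a data frame with
#'   columns `lambda`, `cv_mean`, `cv_se`).
#' @export
cv_select_lambda <- function(y, n_folds = 5, n_lambda = 50,
                             lambda_min_ratio = 1e-5, max_iter = 2000,
                             tol = 1e-6) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 2 * n_folds)
    stop("need at least ", 2 * n_folds, " points for ", n_folds, "-fold CV")
  lambdas <- tf_lambda_grid(y, n_lambda, lambda_min_ratio)
  folds <- cv_fold_assignment(n, n_folds)

  fold_mse <- matrix(NA_real_, n_folds, length(lambdas))
  for (f in seq_len(n_folds)) {
    train <- which(folds != f)
    test <- which(folds == f)
    fit <- .tf_admm_path(y[train], lambdas, 1.0, as.integer(max_iter), tol)
    # interpolate fitted training values at held-out positions
    pred <- vapply(seq_along(lambdas), function(l) {
      stats::approx(x = train, y = fit[, l], xout = test, rule = 2)$y
    }, numeric(length(test)))
    if (length(test) == 1L) pred <- matrix(pred, nrow = 1L)
    fold_mse[f, ] <- colMeans((pred - y[test])^2)
  }
  cv_mean <- colMeans(fold_mse)
  cv_se <- apply(fold_mse, 2, stats::sd) / sqrt(n_folds)
  i_min <- which.min(cv_mean)
  ok <- cv_mean <= cv_mean[i_min] + cv_se[i_min]
  lambda_1se <- max(lambdas[ok])  # grid is descending; max = most smoothing
  list(lambda_1se = lambda_1se,
       cv_table = data.frame(lambda = lambdas, cv_mean = cv_mean,
                             cv_se = cv_se))
}

#' Proportion of variance explained by a fit
#'
#' `1 - RSS/TSS`, clamped to `[0, 1]`. A zero-variance response returns 0.
#'
#' @param y Observed values.
#' @param fitted Fitted values of the same length.
#' @return Scalar in `[0, 1]`.
#' @export
compute_pve <- function(y, fitted) {
  if (length(y) != length(fitted)) stop("y and fitted lengths differ")
  if (length(y) < 2) stop("need at least 2 points")
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(0)
  max(0, min(1, 1 - sum((y - fitted)^2) / tss))
}

#' Estimate a gene's cyclic expression trend over circular phase
#'
#' Orders the cells by phase, concatenates the ordered series three times,
#' applies quadratic trend filtering with CV-selected penalty
#' ([cv_select_lambda()]) to the concatenated series, and extracts the
#' middle third as the cyclic trend. Repeating the series forces the
#' estimate to be continuous across the 0 / 2-pi seam. The residual scale
#' is the root-mean-square residual with a floor of `1e-3`.
#'
#' @param y Numeric vector of (normalized) expression values, one per cell.
#' @param thetas Phase angles in `[0, 2*pi)`, aligned with `y`. Ties are
#'   broken by a jitter of at most 1e-9 radians (stable order).
#' @param gene_id Optional identifier stored in the result.
#' @param n_folds,n_lambda,max_iter,tol Passed to the CV and solver.
#' @return An object of class `"cyclic_trend"`: a list with `gene_id`,
#'   `train_thetas` (sorted), `fitted_values` (same length as `y`),
#'   `sigma`, `pve`, and `lambda`.
#' @export
fit_cyclic_trend <- function(y, thetas, gene_id = NULL, n_folds = 5,
                             n_lambda = 50, max_iter = 2000, tol = 1e-6) {
  y <- as.numeric(y)
  thetas <- as.numeric(thetas)
  n <- length(y)
  if (length(thetas) != n) stop("y and thetas lengths differ")
  if (n < 10) stop("need at least 10 cells")
  if (any(!is.finite(y)) || any(!is.finite(thetas)))
    stop("nonfinite values in input")
  if (any(thetas < 0 | thetas >= 2 * pi))
    stop("thetas must lie in [0, 2*pi)")

  ord <- order(thetas)
  th <- thetas[ord]
  dup <- duplicated(th)
  if (any(dup)) th <- th + cumsum(dup * 1e-9) - 1e-9 * 0  # stable tie jitter
  yo <- y[ord]

  if (stats::var(yo) < .Machine$double.eps) {
    return(structure(list(
      gene_id = gene_id, train_thetas = th,
      fitted_values = rep(mean(yo), n),
      sigma = max(1e-3, stats::sd(yo)), pve = 0, lambda = NA_real_),
      class = "cyclic_trend"))
  }

  y3 <- rep(yo, 3)
  cv <- cv_select_lambda(y3, n_folds = n_folds, n_lambda = n_lambda,
                         max_iter = max_iter, tol = tol)
  fit3 <- trendfilter_solve(y3, cv$lambda_1se, max_iter = max_iter * 2,
                            tol = tol / 10)
  fitted <- fit3[(n + 1):(2 * n)]
  sigma <- max(1e-3, sqrt(mean((yo - fitted)^2)))
  structure(list(gene_id = gene_id, train_thetas = th,
                 fitted_values = fitted, sigma = sigma,
                 pve = compute_pve(yo, fitted), lambda = cv$lambda_1se),
            class = "cyclic_trend")
}

#' @export
print.cyclic_trend <- function(x, ...) {
  cat(sprintf(
    "cyclic_trend%s: %d cells, PVE = %.3f, sigma = %.3f, lambda = %.3g\n",
    if (is.null(x$gene_id)) "" else paste0(" [", x$gene_id, "]"),
    length(x$fitted_values), x$pve, x$sigma, x$lambda))
  invisible(x)
}

#' Permutation significance test for cyclic trends
#'
#' Builds an empirical null distribution of PVE by permuting the expression
#' values of a single template gene `B` times and refitting the cyclic trend
#' each time. The template is drawn uniformly at random among genes whose
#' detection rate exceeds `min_detection` (detection rates are computed
#' upstream, e.g. the fraction of cells with CPM >= 1, since the
#' quantile-normalized matrix no longer carries that information). Each
#' gene's empirical p-value uses the add-one convention
#' `(1 + #\{null PVE >= observed PVE\}) / (B + 1)`.
#'
#' @param normalized Genes-by-cells matrix of quantile-normalized expression
#'   with gene identifiers as row names.
#' @param thetas Phase angles aligned with the columns.
#' @param B Number of permutations (default 1000).
#' @param seed Integer seed for template choice and permutations.
#' @param detection_rates Optional named per-gene detection-rate vector used
#'   for template eligibility; when `NULL` every gene is eligible (a message
#'   is emitted).
#' @param min_detection Minimum detection rate for the null template
#'   (default 0.9).
#' @param ... Passed to [fit_cyclic_trend()].
#' @return A data frame with columns `gene_id`, `pve`, `empirical_p`, and
#'   `rank` (ranked by p-value, then by descending PVE), with the null PVE
#'   draws in attribute `"null_pves"` and the template gene in
#'   `"template_gene"`.
#' @export
permutation_test <- function(normalized, thetas, B = 1000, seed = 1,
                             detection_rates = NULL, min_detection = 0.9,
                             ...) {
  if (B < 1) stop("B must be a positive integer")
  if (is.null(rownames(normalized)))
    stop("normalized matrix must have gene identifiers as row names")
  genes <- rownames(normalized)
  if (is.null(detection_rates)) {
    message("no detection rates supplied; all genes eligible as template")
    eligible <- genes
  } else {
    if (is.null(names(detection_rates)))
      detection_rates <- stats::setNames(detection_rates, genes)
    eligible <- genes[detection_rates[genes] > min_detection]
    if (length(eligible) == 0)
      stop("no gene with detection rate > ", min_detection,
           "; the permutation null requires one")
  }

  n <- ncol(normalized)
  res <- with_seed(seed, {
    template <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
    tvals <- normalized[template, ]
    null_pves <- vapply(seq_len(B), function(b) {
      fit_cyclic_trend(sample(tvals), thetas, ...)$pve
    }, numeric(1))
    list(template = template, null_pves = null_pves)
  })

  obs <- vapply(genes, function(g) {
    fit_cyclic_trend(normalized[g, ], thetas, gene_id = g, ...)$pve
  }, numeric(1))
  pvals <- vapply(obs, function(p) {
    (1 + sum(res$null_pves >= p)) / (B + 1)
  }, numeric(1))

  out <- data.frame(gene_id = genes, pve = obs, empirical_p = pvals,
                    row.names = NULL)
  out$rank <- order(order(out$empirical_p, -out$pve))
  attr(out, "null_pves") <- res$null_pves
  attr(out, "template_gene") <- res$template
  out
}

#' Enrichment of hits in an annotated gene set
#'
#' Forms the 2x2 table of hit/miss by annotated/unannotated over a gene
#' universe and reports the sample odds ratio `ad/bc` (with a Haldane 0.5
#' correction only when some cell is zero) together with the two-sided
#' exact hypergeometric p-value.
#'
#' @param hit_genes,annotation_genes Character vectors, subsets of
#'   `universe_genes`.
#' @param universe_genes Character vector of all tested genes.
#' @return A list with `odds_ratio`, `p_value`, and the 2x2 `table`.
#' @export
enrichment_odds_ratio <- function(hit_genes, annotation_genes,
                                  universe_genes) {
  universe_genes <- unique(universe_genes)
  if (length(universe_genes) == 0) stop("empty gene universe")
  hit_genes <- unique(hit_genes)
  annotation_genes <- unique(annotation_genes)
  if (!all(hit_genes %in% universe_genes))
    stop("hit genes must be a subset of the universe")
  if (!all(annotation_genes %in% universe_genes))
    stop("annotation genes must be a subset of the universe")
  hit <- universe_genes %in% hit_genes
  ann <- universe_genes %in% annotation_genes
  a <- sum(hit & ann); b <- sum(hit & !ann)
  c_ <- sum(!hit & ann); d <- sum(!hit & !ann)
  tab <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE,
                dimnames = list(c("hit", "miss"),
                                c("annotated", "not_annotated")))
  if (any(tab == 0)) {
    or <- (a + 0.5) * (d + 0.5) / ((b + 0.5) * (c_ + 0.5))
  } else {
    or <- a * d / (b * c_)
  }
  p <- stats::fisher.test(tab)$p.value
  list(odds_ratio = or, p_value = p, table = tab)
}
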