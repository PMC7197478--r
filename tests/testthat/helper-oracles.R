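# Independent oracles and small utilities shared across tests.

# Dense third-order difference operator (stencil -1, 3, -3, 1).
d3_matrix <- function(n) {
  m <- n - 3
  D <- matrix(0, m, n)
  for (i in seq_len(m)) D[i, i:(i + 3)] <- c(-1, 3, -3, 1)
  D
}

tf_objective <- function(y, beta, lambda) {
  0.5 * sum((y - beta)^2) + lambda * sum(abs(d3_matrix(length(y)) %*% beta))
}

# Generic convex-programming oracle for the trend-filtering objective:
# the dual is a box-constrained smooth QP,
#   min_u (1/2) ||y - D'u||^2  s.t.  |u_i| <= lambda,
# solved with projected quasi-Newton (L-BFGS-B); beta = y - D'u.
tf_oracle <- function(y, lambda) {
  n <- length(y)
  D <- d3_matrix(n)
  m <- nrow(D)
  fn <- function(u) { r <- y - drop(crossprod(D, u)); 0.5 * sum(r^2) }
  gr <- function(u) -drop(D %*% (y - drop(crossprod(D, u))))
  o <- stats::optim(rep(0, m), fn, gr, method = "L-BFGS-B",
                    lower = -lambda, upper = lambda,
                    control = list(maxit = 20000, factr = 1e1))
  y - drop(crossprod(D, o$par))
}

# Fisher-Lee T-linear circular correlation (pairwise form; well defined
# even for uniform marginals, where the mean-direction form degenerates).
circ_cor <- function(a, b) {
  sa <- outer(a, a, function(x, y) sin(x - y))
  sb <- outer(b, b, function(x, y) sin(x - y))
  sum(sa * sb) / sqrt(sum(sa^2) * sum(sb^2))
}

# A small cyclic_trend built directly (no fitting), for predictor tests.
make_trend <- function(fun, sigma = 0.1, n = 200, gene_id = "g") {
  th <- 2 * pi * (seq_len(n) - 1) / n
  structure(list(gene_id = gene_id, train_thetas = th,
                 fitted_values = fun(th), sigma = sigma, pve = NA_real_,
                 lambda = NA_real_),
            class = "cyclic_trend")
}

make_model <- function(funs, sigma = 0.1, K = 100, n = 200) {
  trends <- lapply(names(funs), function(g)
    make_trend(funs[[g]], sigma = sigma, n = n, gene_id = g))
  names(trends) <- names(funs)
  structure(list(trends = trends, grid = phase_grid(K),
                 genes = names(funs),
                 manifest = list(cell_ids = NULL, individuals = NULL),
                 normalization = list(seed = NA,
                                      plotting_position = "qnorm((r - 0.5)/n)")),
            class = "trained_predictor")
}

# CPM + per-gene standard-normal quantile normalization of a count matrix.
normalize_counts <- function(counts, seed = 1) {
  quantile_normalize(compute_cpm(counts, colSums(counts)), seed = seed)
}
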