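test_that("lambda = 0 returns the data and huge lambda the quadratic fit", {
  set.seed(11)
  y <- rnorm(40)
  expect_identical(trendfilter_solve(y, 0), y)
  lam <- trendfilter_lambda_max(y)
  f <- trendfilter_solve(y, lam * 1.001, max_iter = 20000, tol = 1e-11)
  quad <- fitted(lm(y ~ poly(seq_along(y), 2)))
  expect_lt(max(abs(f - quad)), 1e-4)
})

test_that("solver agrees with the convex-programming dual oracle", {
  set.seed(12)
  for (r in 1:12) {
    n <- sample(10:60, 1)
    y <- rnorm(n)
    lam <- sample(c(0.1, 1, 10), 1)
    f <- trendfilter_solve(y, lam, max_iter = 20000, tol = 1e-10)
    expect_lt(max(abs(f - tf_oracle(y, lam))), 1e-4)
  }
})

test_that("roughness of the fit is nonincreasing in the penalty", {
  set.seed(13)
  y <- cos(seq(0, 4 * pi, length.out = 60)) + rnorm(60, sd = 0.3)
  lams <- exp(seq(log(trendfilter_lambda_max(y)), log(0.01),
                  length.out = 12))
  fits <- trendfilter_solve(y, lams, max_iter = 20000, tol = 1e-10)
  D <- d3_matrix(60)
  rough <- apply(fits, 2, function(b) sum(abs(D %*% b)))
  # grid is descending in lambda, so roughness must be nondecreasing
  expect_true(all(diff(rough) >= -1e-6))
})

test_that("CV folds follow the every-kth-point rule", {
  expect_identical(cv_fold_assignment(10, 5),
                   rep(1:5, 2))
  expect_identical(cv_fold_assignment(7, 3), c(1L, 2L, 3L, 1L, 2L, 3L, 1L))
})

test_that("noiseless quadratic data selects the largest penalty", {
  x <- seq_len(30)
  y <- 0.02 * (x - 15)^2 - 1
  sel <- cv_select_lambda(y)
  expect_equal(sel$lambda_1se, max(sel$cv_table$lambda))
})

test_that("one-SE rule beats the grid extremes on a noisy sinusoid", {
  set.seed(14)
  y <- sin(seq(0, 6 * pi, length.out = 300)) + rnorm(300, sd = 0.4)
  sel <- cv_select_lambda(y)
  tab <- sel$cv_table
  at <- tab$cv_mean[tab$lambda == sel$lambda_1se]
  expect_lt(at, tab$cv_mean[1])
  expect_lt(at, tab$cv_mean[nrow(tab)])
})

test_that("proportion of variance explained has its closed forms", {
  y <- c(1, 2, 3)
  expect_equal(compute_pve(y, y), 1)
  expect_equal(compute_pve(y, rep(mean(y), 3)), 0)
  expect_equal(compute_pve(y, c(1.5, 2, 2.5)), 0.75)
  expect_equal(compute_pve(rep(2, 5), rnorm(5)), 0)  # zero-variance response
  expect_error(compute_pve(1:3, 1:4), "lengths differ")
})

test_that("cyclic trend fit returns the middle third, seam-continuous", {
  set.seed(15)
  th <- runif(80, 0, 2 * pi)
  y <- cos(th)
  fit <- fit_cyclic_trend(y, th)
  n <- length(y)
  expect_length(fit$fitted_values, n)
  expect_lt(max(abs(fit$fitted_values - cos(fit$train_thetas))), 0.15)
  expect_lt(abs(fit$fitted_values[1] - fit$fitted_values[n]), 0.15)
  expect_gt(fit$pve, 0.9)
  expect_gte(fit$sigma, 1e-3)
})

test_that("constant input yields a flat trend with zero PVE", {
  th <- simulate_phases(30, seed = 16)
  fit <- fit_cyclic_trend(rep(1.7, 30), th)
  expect_equal(unique(fit$fitted_values), 1.7)
  expect_equal(fit$pve, 0)
  expect_equal(fit$sigma, 1e-3)  # floored
})

test_that("trend fit is stable under circular rotation of the phases", {
  set.seed(17)
  th <- runif(60, 0, 2 * pi)
  y <- cos(th) + rnorm(60, sd = 0.2)
  f1 <- fit_cyclic_trend(y, th)
  f2 <- fit_cyclic_trend(y, (th + 1.3) %% (2 * pi))
  expect_lt(abs(f1$pve - f2$pve), 0.1)
})

test_that("tied phases are accepted via jitter and remain ordered", {
  th <- rep(c(0.5, 1.5, 2.5), each = 5)
  y <- rnorm(15)
  fit <- fit_cyclic_trend(y, th)
  expect_true(!is.unsorted(fit$train_thetas, strictly = TRUE))
})

test_that("permutation p-values use the add-one convention", {
  set.seed(18)
  n <- 40
  th <- simulate_phases(n, seed = 18)
  mat <- rbind(cyclic = cos(th),
               flat1 = rnorm(n),
               flat2 = rnorm(n))
  det <- c(cyclic = 1, flat1 = 1, flat2 = 0.5)
  res <- permutation_test(mat, th, B = 30, seed = 5, detection_rates = det)
  # the cyclic gene's PVE should beat every permuted-null PVE
  expect_equal(res$empirical_p[res$gene_id == "cyclic"], 1 / 31)
  expect_true(all(res$empirical_p >= 1 / 31))
  expect_equal(res$rank[res$gene_id == "cyclic"], 1L)
  # template must be an eligible gene
  expect_true(attr(res, "template_gene") %in% c("cyclic", "flat1"))
})

test_that("permutation test rejects degenerate requests", {
  th <- simulate_phases(20, seed = 1)
  mat <- matrix(rnorm(40), 2, dimnames = list(c("a", "b"), NULL))
  expect_error(permutation_test(mat, th, B = 0), "positive")
  expect_error(
    permutation_test(mat, th, B = 10, detection_rates = c(a = 0.1, b = 0.2)),
    "detection rate")
  expect_message(permutation_test(mat, th, B = 2, seed = 1), "all genes")
})

test_that("enrichment odds ratio matches the 2x2 arithmetic", {
  universe <- sprintf("g%04d", 1:1000)
  ann <- universe[c(1:10, 101)]        # 11 annotated
  hits <- universe[1:100]              # a = 10, b = 90, c = 1, d = 899
  res <- enrichment_odds_ratio(hits, ann, universe)
  expect_equal(res$odds_ratio, 10 * 899 / (90 * 1), tolerance = 1e-12)
  expect_lt(res$p_value, 0.001)
  # disjoint hits and annotation, all cells nonzero -> OR < 1
  res2 <- enrichment_odds_ratio(universe[1:100], universe[101:200], universe)
  expect_lt(res2$odds_ratio, 1)
  expect_error(enrichment_odds_ratio("x", "g0001", universe), "subset")
  expect_error(enrichment_odds_ratio("g0001", "g0002", character(0)),
               "empty")
})
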