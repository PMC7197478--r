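test_that("trend evaluation interpolates circularly", {
  tr <- structure(list(gene_id = "g", train_thetas = c(0.5, 1.5, 6.0),
                       fitted_values = c(1, 2, 3), sigma = 0.1,
                       pve = NA_real_, lambda = NA_real_),
                  class = "cyclic_trend")
  expect_equal(evaluate_trend_at(tr, c(0.5, 1.5, 6.0)), c(1, 2, 3))
  expect_equal(evaluate_trend_at(tr, 1.0), 1.5)  # midpoint -> mean
  # wraparound: between 6.0 and 0.5 + 2*pi the trend heads back toward 1
  gap <- (0.5 + 2 * pi) - 6.0
  mid <- ((6.0 + 0.5 + 2 * pi) / 2) %% (2 * pi)  # seam midpoint
  expect_equal(evaluate_trend_at(tr, mid), 2)
  # theta = 0 is the seam: interpolate between (6.0, 3) and (0.5 + 2*pi, 1)
  expect_equal(evaluate_trend_at(tr, 0),
               3 + (2 * pi - 6.0) / gap * (1 - 3))
  expect_error(evaluate_trend_at(tr, 7), "2\\*pi")
})

test_that("prediction maximizes the grid likelihood at the truth", {
  model <- make_model(list(g1 = cos, g2 = sin), sigma = 0.1)
  k0 <- 18
  th0 <- model$grid$angles[k0]
  y <- c(g1 = cos(th0), g2 = sin(th0))
  pred <- predict_phase(y, model)
  expect_equal(pred$theta_hat, th0)
  ll <- attr(pred, "loglik_profile")
  expect_equal(ncol(ll), 100)
  expect_equal(which.max(ll[1, ]), k0)
})

test_that("two quadrature genes recover random phases within 2% of cycle", {
  model <- make_model(list(g1 = cos, g2 = sin), sigma = 0.1)
  th0 <- simulate_phases(100, seed = 41)
  Y <- rbind(g1 = cos(th0), g2 = sin(th0))
  pred <- predict_phase(Y, model)
  expect_lt(mean(circular_error(pred$theta_hat, th0)), 0.02)
  expect_true(all(pred$theta_hat %in% model$grid$angles))
})

test_that("prediction error grows with observation noise", {
  model <- make_model(list(g1 = cos, g2 = sin,
                           g3 = function(t) cos(t + pi / 3)), sigma = 0.3)
  th0 <- simulate_phases(200, seed = 42)
  err <- vapply(c(0.3, 1.2), function(s) {
    set.seed(43)
    Y <- rbind(g1 = cos(th0) + rnorm(200, 0, s),
               g2 = sin(th0) + rnorm(200, 0, s),
               g3 = cos(th0 + pi / 3) + rnorm(200, 0, s))
    mean(circular_error(predict_phase(Y, model)$theta_hat, th0))
  }, numeric(1))
  expect_lt(err[1], err[2])
  expect_true(all(err <= 0.5))
})

test_that("rotating the training phases rotates the predictions", {
  shift_k <- 7
  delta <- 2 * pi * shift_k / 100
  model <- make_model(list(g1 = cos, g2 = sin), sigma = 0.1)
  rotated <- make_model(list(g1 = function(t) cos(t - delta),
                             g2 = function(t) sin(t - delta)), sigma = 0.1)
  th0 <- simulate_phases(50, seed = 44)
  Y <- rbind(g1 = cos(th0), g2 = sin(th0))
  p1 <- predict_phase(Y, model)$theta_hat
  p2 <- predict_phase(Y, rotated)$theta_hat
  expect_equal((p1 + delta) %% (2 * pi), p2, tolerance = 1e-12)
})

test_that("batch prediction equals per-cell prediction bit for bit", {
  model <- make_model(list(g1 = cos, g2 = sin), sigma = 0.2)
  th0 <- simulate_phases(20, seed = 45)
  set.seed(46)
  Y <- rbind(g1 = cos(th0) + rnorm(20, 0, 0.2),
             g2 = sin(th0) + rnorm(20, 0, 0.2))
  colnames(Y) <- sprintf("c%d", 1:20)
  batch <- predict_phase(Y, model)
  single <- vapply(seq_len(20), function(i)
    predict_phase(Y[, i], model)$theta_hat, numeric(1))
  expect_identical(batch$theta_hat, single)
})

test_that("circular error metric honors wraparound and its range", {
  expect_equal(circular_error(0, pi), 0.5)
  expect_equal(circular_error(0.1, 2 * pi - 0.1), 0.2 / (2 * pi))
  expect_equal(circular_error(1.234, 1.234), 0)
  th <- simulate_phases(1000, seed = 47)
  th2 <- simulate_phases(1000, seed = 48)
  expect_true(all(circular_error(th, th2) <= 0.5))
})

test_that("training learns tight trends on noiseless sinusoids", {
  th <- simulate_phases(500, seed = 49)
  offs <- seq(0, 2 * pi, length.out = 6)[1:5]
  Y <- t(vapply(offs, function(o) cos(th + o), numeric(500)))
  rownames(Y) <- sprintf("g%d", 1:5)
  model <- train_predictor(Y, th)
  sig <- vapply(model$genes, function(g) model$trends[[g]]$sigma, numeric(1))
  expect_true(all(sig < 0.15))
})

test_that("training validates genes and uses ranked reports", {
  th <- simulate_phases(30, seed = 50)
  Y <- rbind(a = cos(th), b = sin(th), c = rnorm(30), d = rnorm(30),
             e = rnorm(30), f = rnorm(30), g = rnorm(30))
  report <- data.frame(gene_id = letters[1:7], pve = 7:1 / 10,
                       empirical_p = 1:7 / 100, rank = 1:7)
  model <- train_predictor(Y, th, cyclic_report = report, n_genes = 5)
  expect_identical(model$genes, letters[1:5])
  expect_error(train_predictor(Y[1, , drop = FALSE], th), "at least 2")
  expect_error(train_predictor(Y, th, gene_ids = c("a", "zz")), "zz")
  model2 <- train_predictor(Y[1:2, ], th)
  expect_error(predict_phase(c(a = 0.5), model2), "missing model gene")
})

test_that("leave-one-individual-out folds behave on exchangeable data", {
  th <- simulate_phases(160, seed = 51)
  set.seed(52)
  Y <- rbind(g1 = cos(th) + rnorm(160, 0, 0.3),
             g2 = sin(th) + rnorm(160, 0, 0.3),
             g3 = cos(th + 1) + rnorm(160, 0, 0.3))
  colnames(Y) <- sprintf("c%d", 1:160)
  ind <- rep(c("A", "B"), 80)  # interleaved: identical distributions
  cv <- cross_validate_by_individual(Y, th, ind, n_top_genes_list = 3)
  expect_equal(nrow(cv), 2)
  expect_true(all(cv$mean_error < 0.15))
  expect_lt(abs(cv$mean_error[1] - cv$mean_error[2]),
            2 * (cv$se[1] + cv$se[2]))
  expect_error(cross_validate_by_individual(Y, th, rep("A", 160)),
               "at least 2")
})

test_that("the phase grid contract holds", {
  g <- phase_grid()
  expect_equal(g$K, 100)
  expect_equal(length(g$angles), 100)
  expect_equal(unique(round(diff(g$angles), 12)), round(2 * pi / 100, 12))
  expect_error(phase_grid(1), "at least 2")
})
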