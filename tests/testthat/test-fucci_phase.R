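balanced_scores <- function(plate_off, indiv_off, noise_sd = 0.1,
                            n_per = 10, seed = 31) {
  plates <- rep(names(plate_off), each = length(indiv_off) * n_per)
  indivs <- rep(rep(names(indiv_off), each = n_per), length(plate_off))
  th <- simulate_phases(length(plates), seed = seed)
  simulate_fucci_scores(th, plates, indivs, noise_sd = noise_sd,
                        plate_offsets = plate_off,
                        individual_offsets = indiv_off, seed = seed + 1)
}

test_that("plate offsets are recovered and removed by batch correction", {
  plate_off <- c(p1 = 0.4, p2 = -0.3, p3 = 0.1, p4 = -0.2)
  indiv_off <- c(i1 = 0.5, i2 = -0.1, i3 = -0.4)
  raw <- balanced_scores(plate_off, indiv_off)
  corr <- correct_batch(raw)
  eff <- attr(corr, "plate_effects")
  se <- attr(corr, "plate_effect_se")
  truth_centered <- plate_off - mean(plate_off)
  for (sc in c("egfp_score", "mcherry_score"))
    expect_true(all(abs(eff[names(plate_off), sc] - truth_centered) <
                      3 * se[names(plate_off), sc]))
  # pre-correction the plate effect is detectable; afterwards it is not
  expect_lt(attr(corr, "anova_pvalues")["plate", "egfp_score"], 0.01)
  recheck <- correct_batch(corr)
  expect_gt(attr(recheck, "anova_pvalues")["plate", "egfp_score"], 0.01)
  expect_gt(attr(recheck, "anova_pvalues")["plate", "mcherry_score"], 0.01)
})

test_that("zero plate offsets leave the scores essentially unchanged", {
  raw <- balanced_scores(c(p1 = 0, p2 = 0, p3 = 0),
                         c(i1 = 0.3, i2 = -0.3), seed = 32)
  corr <- correct_batch(raw)
  se <- attr(corr, "plate_effect_se")
  expect_lt(max(abs(corr$egfp_score - raw$egfp_score)),
            3 * max(se[, "egfp_score"]))
})

test_that("degenerate batch designs are flagged", {
  raw <- balanced_scores(c(p1 = 0), c(i1 = 0, i2 = 0), seed = 33)
  expect_warning(out <- correct_batch(raw), "one plate")
  expect_equal(out$egfp_score, raw$egfp_score)
  # plate completely confounded with individual
  th <- simulate_phases(40, seed = 34)
  conf <- simulate_fucci_scores(th, plates = rep(c("p1", "p2"), each = 20),
                                individuals = rep(c("i1", "i2"), each = 20),
                                seed = 34)
  expect_error(correct_batch(conf), "confounded")
})

test_that("phase is the quadrant-aware inverse tangent of centered scores", {
  scores <- data.frame(egfp_score = c(0, 1, 0, -1),
                       mcherry_score = c(1, 0, -1, 0))
  attr(scores, "corrected") <- TRUE
  th <- infer_fucci_phase(scores)
  expect_equal(as.numeric(th), c(0, pi / 2, pi, 3 * pi / 2))
  # global rotation offset shifts every angle
  th2 <- infer_fucci_phase(scores, rotation = pi / 4)
  expect_equal(as.numeric(th2), (as.numeric(th) + pi / 4) %% (2 * pi))
  expect_error(infer_fucci_phase(data.frame(egfp_score = 1,
                                            mcherry_score = 1)),
               "not batch-corrected")
})

test_that("phase inference recovers simulated quadrature phases", {
  th0 <- simulate_phases(300, seed = 35)
  raw <- simulate_fucci_scores(th0, rep("p1", 300), rep("i1", 300),
                               noise_sd = 0.05, seed = 36)
  attr(raw, "corrected") <- TRUE  # no batch structure to remove
  th <- infer_fucci_phase(raw)
  expect_gt(abs(circ_cor(th, th0)), 0.99)
  expect_lt(mean(circular_error(th, th0)), 0.02)
})

test_that("phase is invariant to common positive rescaling of the scores", {
  scores <- data.frame(egfp_score = c(0.2, 1.3, -0.4, 0.8),
                       mcherry_score = c(1.0, -0.2, 0.5, -0.9))
  attr(scores, "corrected") <- TRUE
  scaled <- scores
  scaled$egfp_score <- mean(scores$egfp_score) +
    3.7 * (scores$egfp_score - mean(scores$egfp_score))
  scaled$mcherry_score <- mean(scores$mcherry_score) +
    3.7 * (scores$mcherry_score - mean(scores$mcherry_score))
  attr(scaled, "corrected") <- TRUE
  expect_equal(as.numeric(infer_fucci_phase(scaled)),
               as.numeric(infer_fucci_phase(scores)))
})

test_that("batch correction then phase inference undoes plate offsets", {
  th0 <- simulate_phases(240, seed = 37)
  plates <- rep(c("p1", "p2", "p3", "p4"), 60)
  indivs <- rep(c("i1", "i2", "i3"), 80)
  clean <- simulate_fucci_scores(th0, plates, indivs, noise_sd = 0.05,
                                 seed = 38)
  shifted <- simulate_fucci_scores(th0, plates, indivs, noise_sd = 0.05,
                                   plate_offsets = c(p1 = 0.6, p2 = -0.4,
                                                     p3 = 0.2, p4 = -0.4),
                                   seed = 38)
  attr(clean, "corrected") <- TRUE
  err_clean <- mean(circular_error(infer_fucci_phase(clean), th0))
  err_corr <- mean(circular_error(infer_fucci_phase(correct_batch(shifted)),
                                  th0))
  expect_lt(abs(err_corr - err_clean), 0.01)
})

test_that("PAM recovers three planted score clusters with fixed labels", {
  set.seed(39)
  n <- 120
  blob <- function(e, m) cbind(rnorm(n, e, 0.07), rnorm(n, m, 0.07))
  pts <- rbind(blob(-1, 1),   # CDT1 high, geminin low: G1
               blob(1, 1),    # both high: S
               blob(1, -1))   # geminin high: G2M
  scores <- data.frame(egfp_score = pts[, 1], mcherry_score = pts[, 2])
  labels <- classify_pam(scores)
  truth <- rep(c("G1", "S", "G2M"), each = n)
  expect_gt(mean(as.character(labels) == truth), 0.99)
  expect_equal(sum(attr(labels, "counts")), 3 * n)
})

test_that("PAM degenerate inputs behave as specified", {
  tri <- data.frame(egfp_score = rep(c(0, 1, 0), times = c(5, 5, 5)),
                    mcherry_score = rep(c(0, 0, 1), times = c(5, 5, 5)))
  labels <- classify_pam(tri)
  med <- attr(labels, "medoids")
  expect_equal(nrow(unique(med)), 3)  # each distinct point is a medoid
  expect_error(classify_pam(data.frame(egfp_score = c(1, 1, 1),
                                       mcherry_score = c(2, 2, 2))),
               "distinct")
  expect_error(classify_pam(data.frame(egfp_score = 1, mcherry_score = 1)),
               "at least 3")
})
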