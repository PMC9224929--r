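test_that("single-Gaussian fit is the closed-form MLE", {
  m <- fit_single_gaussian(rep(c(-1, 0, 1), 10))
  expect_equal(m$components$mu, 0)
  expect_equal(m$components$sigma, sqrt(2 / 3))
  expect_equal(m$components$weight, 1)
  set.seed(42)
  big <- fit_single_gaussian(rnorm(1e5, -1.0, 0.2))
  expect_lt(abs(big$components$mu - (-1.0)), 0.005)
  expect_lt(abs(big$components$sigma - 0.2), 0.005)
  expect_error(fit_single_gaussian(rep(1, 100)), "degenerate-fit")
  expect_error(fit_single_gaussian(rnorm(10)), "at least 30")
})

test_that("EM recovers a rare high-power mixture at realistic n", {
  set.seed(7)
  n <- 17996
  k <- rbinom(1, n, 0.05)
  x <- c(rnorm(n - k, -1.0, 0.15), rnorm(k, -0.3, 0.12))
  m <- fit_two_gaussian(x)
  expect_true(m$converged)
  expect_equal(m$components$mu, c(-1.0, -0.3), tolerance = 0.05)
  expect_equal(m$components$weight, c(0.95, 0.05), tolerance = 0.02 / 0.95)
  expect_lt(abs(sum(m$components$weight) - 1), 1e-9)
  expect_true(all(diff(m$components$mu) > 0))
  expect_error(fit_two_gaussian(rnorm(50)), "at least 100")
})

test_that("EM agrees with an independent mixture fitter on shared data", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  set.seed(19)
  x <- c(rnorm(4000, -1.0, 0.15), rnorm(300, -0.35, 0.1))
  m <- fit_two_gaussian(x)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(m$components$mu), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.01)
  expect_equal(m$log_likelihood, mc$loglik, tolerance = 1e-4)
})

test_that("single-Gaussian data rarely pass the AUC gate when overfit
           with two components", {
  aucs <- vapply(1:40, function(s) {
    set.seed(1000 + s)
    m <- fit_two_gaussian(rnorm(17996, -1, 0.2))
    gaussian_pair_auc(as.list(m$components[1, ]), as.list(m$components[2, ]))
  }, numeric(1))
  expect_gte(mean(aucs < 0.9), 0.95)
})

test_that("pair AUC matches the numeric-integration oracle", {
  expect_equal(gaussian_pair_auc(list(mu = 0, sigma = 1),
                                 list(mu = 0, sigma = 1)), 0.5)
  expect_equal(gaussian_pair_auc(list(mu = 0, sigma = 1),
                                 list(mu = 3, sigma = 1)),
               oracle_pair_auc(0, 1, 3, 1), tolerance = 1e-9)
  expect_equal(gaussian_pair_auc(list(mu = 0, sigma = 1),
                                 list(mu = 3, sigma = 1)),
               pnorm(3 / sqrt(2)), tolerance = 1e-12)
  # near-degenerate sigmas approach perfect separation
  expect_gt(gaussian_pair_auc(list(mu = 0, sigma = 1e-9),
                              list(mu = 1, sigma = 1e-9)), 1 - 1e-12)
  expect_error(gaussian_pair_auc(list(mu = 0, sigma = 0),
                                 list(mu = 1, sigma = 1)), "positive")
  set.seed(55)
  for (k in 1:10) {
    mu1 <- runif(1, -2, 0); mu2 <- mu1 + runif(1, 0.1, 3)
    s1 <- runif(1, 0.05, 0.5); s2 <- runif(1, 0.05, 0.5)
    expect_equal(gaussian_pair_auc(list(mu = mu1, sigma = s1),
                                   list(mu = mu2, sigma = s2)),
                 oracle_pair_auc(mu1, s1, mu2, s2), tolerance = 1e-8)
  }
})

test_that("parametric ROC runs (0,0) to (1,1) and integrates to the AUC", {
  same <- roc_curve(list(mu = 0, sigma = 1), list(mu = 0, sigma = 1))
  expect_equal(same$fpr[1], 0); expect_equal(same$tpr[1], 0)
  expect_equal(same$fpr[nrow(same)], 1); expect_equal(same$tpr[nrow(same)], 1)
  expect_equal(attr(same, "auc"), 0.5, tolerance = 1e-3)
  expect_true(all(diff(same$fpr) >= 0) && all(diff(same$tpr) >= 0))
  set.seed(99)
  for (k in 1:10) {
    c1 <- list(mu = runif(1, -2, 0), sigma = runif(1, 0.05, 0.6))
    c2 <- list(mu = c1$mu + runif(1, 0.05, 2), sigma = runif(1, 0.05, 0.6))
    roc <- roc_curve(c1, c2)
    expect_lt(abs(attr(roc, "auc") - gaussian_pair_auc(c1, c2)), 1e-3)
  }
  expect_error(roc_curve(list(mu = 0, sigma = 1), list(mu = 1, sigma = 1),
                         n_points = 2), "at least 16")
})

test_that("model selection takes the 3-SD path on unimodal data", {
  set.seed(4)
  x <- rnorm(17996, -1.0, 0.2)
  sr <- select_model_and_threshold(x)
  expect_equal(sr$mode, "unimodal_3sd")
  m1 <- sr$model$components
  expect_equal(sr$threshold_log10, m1$mu + 3 * m1$sigma)
  expect_equal(sr$threshold_log10, -0.4, tolerance = 0.02)
})

test_that("model selection takes the ROC path on well-separated mixtures", {
  set.seed(5)
  n <- 17996
  k <- rbinom(1, n, 0.05)
  x <- c(rnorm(n - k, -1.0, 0.15), rnorm(k, -0.3, 0.12))
  # true-component AUC pnorm(0.7 / sqrt(0.15^2 + 0.12^2)) > 0.99
  expect_gt(pnorm(0.7 / sqrt(0.15^2 + 0.12^2)), 0.99)
  sr <- select_model_and_threshold(x)
  expect_equal(sr$mode, "bimodal_roc")
  expect_gt(sr$auc, 0.9)
  expect_lt(sr$bic_2, sr$bic_1)
  # threshold is the weighted-density crossing between the means
  cmp <- sr$model$components
  expect_gt(sr$threshold_log10, cmp$mu[1])
  expect_lt(sr$threshold_log10, cmp$mu[2])
  d1 <- cmp$weight[1] * dnorm(sr$threshold_log10, cmp$mu[1], cmp$sigma[1])
  d2 <- cmp$weight[2] * dnorm(sr$threshold_log10, cmp$mu[2], cmp$sigma[2])
  expect_equal(d1, d2, tolerance = 1e-6 * d1)
  # ROC invariants on the accepted fit
  expect_equal(attr(sr$roc, "auc"), sr$auc, tolerance = 1e-3)
})

test_that("an unreachable AUC gate forces the 3-SD fallback", {
  set.seed(6)
  n <- 5000
  x <- c(rnorm(round(n * 0.95), -1.0, 0.15), rnorm(round(n * 0.05), -0.3, 0.12))
  sr <- select_model_and_threshold(x, analysis_config(auc_min = 1.0))
  expect_equal(sr$mode, "unimodal_3sd")
  m1 <- sr$model$components
  expect_equal(sr$threshold_log10, m1$mu + 3 * m1$sigma)
})

test_that("thresholds move monotonically with their drivers", {
  set.seed(8)
  x <- rnorm(2000, -1, 0.2)
  thr <- vapply(c(2, 3, 4, 5), function(k)
    select_model_and_threshold(x, analysis_config(sd_multiplier = k))$threshold_log10,
    numeric(1))
  expect_true(all(diff(thr) > 0))
  # density-crossing threshold rises as the minor component moves right
  c_low <- list(mu = -1, sigma = 0.15, weight = 0.95)
  cross <- vapply(seq(-0.5, 0.1, by = 0.1), function(mu_hi)
    lfpburst:::.density_crossing(c_low, list(mu = mu_hi, sigma = 0.12,
                                             weight = 0.05)),
    numeric(1))
  expect_true(all(diff(cross) > 0))
})

test_that("separation results serialize to JSON with the model fields", {
  withr::local_file("sep.json")
  set.seed(9)
  sr <- select_model_and_threshold(rnorm(1000, -1, 0.2))
  write_separation_result(sr, "sep.json")
  j <- jsonlite::read_json("sep.json")
  expect_equal(j$mode, sr$mode)
  expect_equal(j$threshold_log10, sr$threshold_log10, tolerance = 1e-12)
  expect_equal(length(j$components), nrow(sr$model$components))
})
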