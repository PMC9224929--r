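# Short recordings (60-180 s at 1 kHz) keep unit tests fast; full-length
# behavior is exercised by the acceptance suite.

test_that("identical seeds give bit-identical recordings and truth", {
  cfg <- sim_config("mutant", duration_s = 60, sampling_rate = 1000,
                    seed = 31)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth, b$truth)
})

test_that("wt profiles never contain seizure-class truth", {
  for (s in 1:5) {
    sim <- simulate_recording(sim_config("wt", duration_s = 120,
                                         sampling_rate = 1000, seed = s))
    expect_false(any(sim$truth$klass == "seizure_like"))
  }
  expect_error(sim_config("wt", seizure = list(rate_per_min = 1)),
               "zero seizure rate")
})

test_that("truth intervals are sorted, non-overlapping and class-consistent", {
  sim <- simulate_recording(sim_config("mutant", duration_s = 300,
                                       sampling_rate = 1000, seed = 32))
  tr <- sim$truth
  expect_true(all(diff(tr$start_s) > 0))
  expect_true(all(tr$start_s[-1] >= tr$end_s[-nrow(tr)]))
  expect_equal(tr$klass == "seizure_like", tr$end_s - tr$start_s > 1)
})

test_that("seizure counts follow the configured Poisson rate", {
  counts <- vapply(1:20, function(s) {
    sim <- simulate_recording(sim_config("mutant", sampling_rate = 250,
                                         seed = 600 + s))
    sum(sim$truth$klass == "seizure_like")
  }, numeric(1))
  # rate 0.2/min over 15 min -> Poisson(3); central 95% band is {0..7}
  expect_gte(mean(counts >= qpois(0.025, 3) & counts <= qpois(0.975, 3)),
             0.8)
  expect_equal(mean(counts), 3, tolerance = 0.45)
})

test_that("background spectral slope matches the configured exponent", {
  for (alpha in c(0.5, 1.0)) {
    sim <- simulate_recording(sim_config("custom", duration_s = 120,
                                         sampling_rate = 1000,
                                         background = list(alpha = alpha,
                                                           sd = 1),
                                         seed = 33))
    x <- sim$recording$samples
    n <- length(x)
    pxx <- Mod(fft(x))[2:(n / 2)]^2
    f <- (1:(n / 2 - 1)) * 1000 / n
    keep <- f >= 1 & f <= 200
    # average the periodogram in log-spaced bins before regression
    bins <- cut(log10(f[keep]), 40)
    lp <- tapply(log10(pxx[keep]), bins, mean)
    lf <- tapply(log10(f[keep]), bins, mean)
    slope <- coef(lm(lp ~ lf))[2]
    expect_equal(unname(slope), -alpha, tolerance = 0.2)
  }
})

test_that("an infeasible event load is rejected", {
  cfg <- sim_config("custom", duration_s = 60, sampling_rate = 1000,
                    interictal = list(rate_per_min = 200, amp_mult = 2),
                    seed = 34)
  expect_error(simulate_recording(cfg), "infeasible-config")
})

test_that("cohorts are reproducible, jittered and extensible", {
  a <- simulate_cohort("mutant", 3, base_seed = 35, duration_s = 30,
                       sampling_rate = 500)
  b <- simulate_cohort("mutant", 3, base_seed = 35, duration_s = 30,
                       sampling_rate = 500)
  expect_identical(lapply(a, function(s) s$recording$samples),
                   lapply(b, function(s) s$recording$samples))
  # extensibility: subject k unchanged by cohort size
  c2 <- simulate_cohort("mutant", 2, base_seed = 35, duration_s = 30,
                        sampling_rate = 500)
  expect_identical(a[[2]]$recording$samples, c2[[2]]$recording$samples)
  expect_equal(a[[1]]$recording$subject_id, "mutant_01")
  single <- simulate_cohort("wt", 1, base_seed = 36, duration_s = 30,
                            sampling_rate = 500)
  expect_length(single, 1L)
})

test_that("simulated endpoints honor group means and nonnegativity", {
  tbl <- simulate_endpoints(
    list(wt = list(mean = 100, sd = 20, n = 60),
         mut = list(mean = 70, sd = 20, n = 60)),
    endpoint_name = "distance_traveled", seed = 37)
  expect_s3_class(tbl, "endpoint_table")
  expect_true(all(tbl$value >= 0))
  m <- tapply(tbl$value, tbl$group, mean)
  expect_gt(m[["wt"]], m[["mut"]])
  const <- simulate_endpoints(list(g = list(mean = 5, sd = 0, n = 4)),
                              seed = 38)
  expect_true(all(const$value == 5))
  again <- simulate_endpoints(
    list(wt = list(mean = 100, sd = 20, n = 60),
         mut = list(mean = 70, sd = 20, n = 60)),
    endpoint_name = "distance_traveled", seed = 37)
  expect_identical(tbl$value, again$value)
})

test_that("profiles steer the model-selection path: wt unimodal, mutant
           bimodal with AUC above the gate", {
  modes <- vapply(1:12, function(s) {
    wt <- detect_events(simulate_recording(
      sim_config("wt", sampling_rate = 1000, seed = 700 + s))$recording)
    mut <- detect_events(simulate_recording(
      sim_config("mutant", sampling_rate = 1000, seed = 700 + s))$recording)
    c(wt = wt$separation$mode == "unimodal_3sd",
      mut = mut$separation$mode == "bimodal_roc" && mut$separation$auc > 0.9)
  }, logical(2))
  expect_gte(mean(modes["wt", ]), 0.9)
  expect_gte(mean(modes["mut", ]), 0.9)
})

test_that("a 30% endpoint deficit is detected by Kruskal-Wallis across
           seeds", {
  ps <- vapply(1:10, function(s) {
    tbl <- simulate_endpoints(
      list(wt = list(mean = 100, sd = 20, n = 90),
           wt_treat = list(mean = 100, sd = 20, n = 90),
           mut = list(mean = 70, sd = 20, n = 90),
           mut_treat = list(mean = 90, sd = 20, n = 90)),
      seed = 800 + s)
    run_compare(tbl)$p_value
  }, numeric(1))
  expect_true(all(ps < 0.05))
})

test_that("simulation configs round-trip through their TOML flattening", {
  withr::local_file("sim.toml")
  cfg <- sim_config("mutant", duration_s = 120, sampling_rate = 1000,
                    seed = 41)
  write_sim_config(cfg, "sim.toml")
  vals <- parse_flat_toml("sim.toml")
  expect_equal(vals$profile, "mutant")
  expect_equal(vals$duration_s, 120)
  expect_equal(vals$`interictal.rate_per_min`, cfg$interictal$rate_per_min)
  expect_equal(vals$`seizure.amp_mult`, cfg$seizure$amp_mult)
  expect_equal(vals$band, c(30, 95))
})

test_that("detection scoring handles perfect, empty and marginal cases", {
  tr <- data.frame(start_s = c(1, 5), end_s = c(2, 7),
                   klass = c("interictal_like", "seizure_like"))
  perfect <- score_detection(tr, tr)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
  none <- score_detection(tr[0, ], tr)
  expect_equal(none$recall, 0)
  expect_equal(none$precision, 1)   # undefined -> 1, flagged
  expect_true(none$zero_detected)
  # shifted by half duration: IoU = 0.5/1.5 = 1/3 < 0.5 -> no match;
  # IoU threshold exactly at the oracle value -> match
  det <- data.frame(start_s = 1.5, end_s = 2.5)
  expect_equal(score_detection(det, tr[1, ])$n_matched, 0L)
  iou <- oracle_iou(1.5, 2.5, 1, 2)
  expect_equal(score_detection(det, tr[1, ], min_overlap = iou)$n_matched, 1L)
})

test_that("greedy matching is one-to-one by decreasing IoU", {
  tr <- data.frame(start_s = c(0, 10), end_s = c(4, 14))
  det <- data.frame(start_s = c(0, 0.5), end_s = c(4.2, 4.5))  # both near tr 1
  s <- score_detection(det, tr)
  expect_equal(s$n_matched, 1L)
  expect_equal(s$matches$truth, 1L)
  expect_equal(s$matches$detected, 1L)  # higher-IoU detection wins
  expect_equal(s$precision, 0.5)
  expect_equal(s$recall, 0.5)
})

test_that("truth tables survive a TSV round trip", {
  withr::local_file("truth.tsv")
  sim <- simulate_recording(sim_config("mutant", duration_s = 120,
                                       sampling_rate = 500, seed = 39))
  write_sim_truth(sim$truth, "truth.tsv")
  back <- read_sim_truth("truth.tsv")
  expect_equal(back$start_s, sim$truth$start_s)
  expect_equal(back$klass, sim$truth$klass)
})
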