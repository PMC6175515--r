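test_that("encounter trials respect the flush/detection logic", {
  cfg <- encounter_config(n_trials = 5000, seed = 3)
  # threshold = arena radius: every trial flushes
  tr <- simulate_encounters(125, cfg)
  expect_true(all(tr$flushed))
  # threshold 0: nothing happens
  tr0 <- simulate_encounters(0, cfg)
  expect_false(any(tr0$flushed))
  expect_false(any(tr0$detected))
  # threshold at f_close: every flushed trial is detected
  tr5 <- simulate_encounters(5, cfg)
  expect_true(all(tr5$detected[tr5$flushed]))
  # detected implies flushed, both geometries
  for (model in c("stationary_uniform", "transect")) {
    cfg2 <- encounter_config(n_trials = 5000, seed = 4, predator_model = model)
    tr2 <- simulate_encounters(40, cfg2)
    expect_true(all(tr2$flushed[tr2$detected]))
    expect_true(all(tr2$predator_nest_distance >= 0 &
                      tr2$predator_nest_distance <= 125))
  }
  expect_error(simulate_encounters(-5, cfg))
})

test_that("identical configuration and seed reproduce identical trials", {
  cfg <- encounter_config(n_trials = 2000, seed = 42)
  expect_identical(simulate_encounters(30, cfg), simulate_encounters(30, cfg))
  cfgb <- encounter_config(n_trials = 2000, seed = 43)
  expect_false(identical(simulate_encounters(30, cfg),
                         simulate_encounters(30, cfgb)))
  pop <- simulate_population(500, threshold_sampler("uniform", min = 0, max = 125),
                             encounter_config(seed = 9))
  pop2 <- simulate_population(500, threshold_sampler("uniform", min = 0, max = 125),
                              encounter_config(seed = 9))
  expect_identical(pop, pop2)
})

test_that("Monte Carlo frequencies match the analytic square law and risk", {
  cfg <- encounter_config(n_trials = 2e4, seed = 11)
  est <- estimate_risk_curve(c(62.5, 200 / 3, 10, 50), cfg)
  expect_equal(nrow(est), 4L)
  for (i in seq_len(nrow(est))) {
    r <- est$threshold[i]
    expect_lt(abs(est$p_flush[i] - flush_probability(r)), 4 * est$se_flush[i])
    expect_lt(abs(est$p_detect[i] - flush_risk(r)), 4 * est$se_detect[i])
  }
  # analytic risk ordering 10 < 50, and 120 gives zero detections
  est2 <- estimate_risk_curve(c(10, 50, 120), cfg)
  expect_equal(which.max(est2$p_detect), 2L)
  expect_identical(est2$p_detect[3], 0)
  expect_error(estimate_risk_curve(numeric(0), cfg))
})

test_that("a moving predator sweeps more area than a stationary one", {
  for (r in c(20, 50, 90)) {
    pf_t <- mean(simulate_encounters(
      r, encounter_config(n_trials = 2e4, seed = 5, predator_model = "transect"))$flushed)
    pf_s <- mean(simulate_encounters(
      r, encounter_config(n_trials = 2e4, seed = 5))$flushed)
    expect_gt(pf_t, pf_s)
    expect_equal(pf_t, r / 125, tolerance = 0.03)
  }
})

test_that("population simulation links strategies to nest fate", {
  pop0 <- simulate_population(300, threshold_sampler("fixed", value = 0),
                              encounter_config(seed = 2))
  expect_false(any(pop0$depredated))
  popL <- simulate_population(300, threshold_sampler("fixed", value = 100),
                              encounter_config(seed = 2))
  expect_identical(sum(popL$depredated), 0L)
  # uniform thresholds: fate regression recovers a concave predation curve
  # peaking near the analytic argmax 66.7
  pop <- simulate_population(5000, threshold_sampler("uniform", min = 0, max = 125),
                             encounter_config(seed = 21))
  fit <- stats::glm(depredated ~ flush_threshold + I(flush_threshold^2),
                    family = stats::binomial(), data = pop)
  b <- stats::coef(fit)
  expect_lt(b[3], 0)
  vertex <- -b[2] / (2 * b[3])
  expect_gt(vertex, 45)
  expect_lt(vertex, 90)
  expect_error(simulate_population(100, threshold_sampler("fixed", value = 1),
                                   encounter_config(seed = 1),
                                   encounters_per_nest = 0))
  expect_error(.draw_thresholds(structure(list(dist = "zeta", args = list()),
                                          class = "threshold_sampler"), 5))
})

test_that("observer discovery bias retains intermediate flush distances", {
  popL <- data.frame(flush_threshold = rep(100, 200))
  expect_identical(nrow(observer_discovery_filter(popL, seed = 1)), 0L)
  # equal thresholds: simple binomial subsample at the analytic retention rate
  pope <- data.frame(flush_threshold = rep(50, 20000))
  kept <- observer_discovery_filter(pope, seed = 2)
  p_keep <- flush_risk(50) / flush_risk(argmax_risk(risk_params()))
  expect_equal(unique(kept$retention_prob), p_keep, tolerance = 1e-6)
  expect_lt(abs(nrow(kept) / 20000 - p_keep),
            3 * sqrt(p_keep * (1 - p_keep) / 20000))
  # uniform thresholds: retained fraction inside the 30-80 m band matches the
  # renormalised risk mass there
  set.seed(31)
  popu <- data.frame(flush_threshold = runif(2e4, 0, 125))
  fl <- observer_discovery_filter(popu, seed = 3)
  rc <- risk_curve(grid_step = 0.1)
  expfrac <- sum(rc$risk[rc$distance >= 30 & rc$distance <= 80]) / sum(rc$risk)
  empfrac <- mean(fl$flush_threshold >= 30 & fl$flush_threshold <= 80)
  expect_lt(abs(empfrac - expfrac),
            4 * sqrt(expfrac * (1 - expfrac) / nrow(fl)))
})
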