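test_that("ordinal fit recovers generating coefficients and reports LR tests", {
  cfg <- synthetic_config(n_per_species = c(sandpiper = 3e4, phalarope = 2e4),
                          seed = 8)
  d <- generate_nests(cfg)
  fit <- fit_defence_ordinal(d)
  expect_true(fit$converged)
  se <- sqrt(diag(stats::vcov(fit$fit)))[names(fit$coefficients)]
  expect_lt(abs(fit$coefficients[["speciessandpiper"]] - 2.8),
            2 * se[["speciessandpiper"]])
  expect_lt(abs(fit$coefficients[["flush_distance_m"]] - (-0.05)),
            2 * se[["flush_distance_m"]])
  expect_true(all(fit$term_tests$chisq >= 0))
  expect_true(all(fit$term_tests$p_value >= 0 & fit$term_tests$p_value <= 1))
  expect_setequal(fit$term_tests$term, c("species", "flush_distance_m"))
  # strong effects on this sample size are overwhelmingly significant
  expect_lt(max(fit$term_tests$p_value), 1e-6)
  # Wald variant agrees in order of magnitude
  fw <- fit_defence_ordinal(d, chi_square = "wald")
  expect_equal(log(fw$term_tests$chisq), log(fit$term_tests$chisq),
               tolerance = 0.35)
})

test_that("ordinal likelihood is maximised at the reported optimum", {
  cfg <- synthetic_config(n_per_species = c(sandpiper = 400, phalarope = 300),
                          seed = 9)
  d <- generate_nests(cfg)
  fit <- fit_defence_ordinal(d)
  theta <- c(fit$cutpoints, fit$coefficients)
  ll <- function(th) polr_loglik(th, d)
  expect_equal(ll(theta), fit$log_likelihood, tolerance = 1e-6)
  g <- num_gradient(ll, theta)
  expect_lt(max(abs(g)), 0.05)
  # perturbations only decrease the likelihood
  set.seed(2)
  for (i in 1:5) expect_lt(ll(theta + rnorm(5, sd = 0.05)), ll(theta))
  # refit from a different start reaches the same optimum (concave likelihood)
  alt <- MASS::polr(factor(defence_category, ordered = TRUE) ~
                      factor(species, levels = c("phalarope", "sandpiper")) +
                      flush_distance_m,
                    data = d, start = c(1, -0.01, 0.5, 1.5, 3), Hess = FALSE)
  expect_equal(as.numeric(stats::logLik(alt)), fit$log_likelihood,
               tolerance = 1e-5)
})

test_that("ordinal per-term type-I error is near nominal under the null", {
  cfg0 <- synthetic_config(n_per_species = c(sandpiper = 90, phalarope = 60),
                           ordinal_model = list(cutpoints = c(0, 1, 2.5),
                                                beta_species = 1.5,
                                                beta_flush = 0))
  set.seed(4)
  reps <- 150
  pvals <- vapply(seq_len(reps), function(i) {
    cfg0$seed <- 1000L + i
    d <- generate_nests(cfg0)
    f <- tryCatch(suppressWarnings(fit_defence_ordinal(d)),
                  error = function(e) NULL)
    if (is.null(f)) return(NA_real_)
    f$term_tests$p_value[f$term_tests$term == "flush_distance_m"]
  }, numeric(1))
  pvals <- pvals[!is.na(pvals)]
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / length(pvals)) + 0.01)
})

test_that("fate regression recovers the quadratic coefficients", {
  cfg <- synthetic_config(n_per_species = c(sandpiper = 12000, phalarope = 8000),
                          seed = 6)
  d <- generate_nests(cfg)
  fit <- fit_fate_logistic(d)
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients[["beta_flush"]] - (-0.141)),
            3 * fit$standard_errors[["beta_flush"]])
  expect_lt(abs(fit$coefficients[["beta_flush_sq"]] - 0.002),
            3 * fit$standard_errors[["beta_flush_sq"]])
  expect_true(all(fit$standard_errors > 0))
  # unknown fates are excluded from the fit
  expect_identical(fit$n, sum(d$fate != "unknown"))
  # logistic score vanishes at the optimum
  dat <- d[d$fate != "unknown", ]
  X <- cbind(1, dat$flush_distance_m, dat$flush_distance_m^2)
  y <- as.integer(dat$fate == "hatched")
  p <- plogis(drop(X %*% fit$coefficients))
  expect_lt(max(abs(crossprod(X, y - p))), 1e-4 * nrow(X))
  expect_error(fit_fate_logistic(make_records(fate = rep("hatched", 10))),
               "both fates")
})

test_that("predicted fate curve locates the predation maximum at the vertex", {
  fit <- fate_logistic(0, -0.141, 0.002)
  pc <- predicted_fate_curve(fit, distances = seq(0, 100, 0.5),
                             range = c(0, 100))
  expect_equal(pc$max_predation_distance, 35.25)
  expect_true(pc$max_predation_distance >= 20 && pc$max_predation_distance <= 70)
  expect_equal(pc$curve$p_predation, 1 - pc$curve$p_hatch)
  expect_equal(pc$curve$p_hatch[1], plogis(0))
  # hatching probability is minimised exactly at the vertex
  expect_equal(which.min(pc$curve$p_hatch),
               which.min(abs(pc$curve$distance - 35.25)))
  # beta1 = 0 with positive curvature: maximum predation at distance 0
  fit0 <- fate_logistic(1, 0, 0.003)
  expect_equal(predicted_fate_curve(fit0, range = c(0, 200))$max_predation_distance, 0)
  # negative curvature falls back to a grid search
  fitn <- fate_logistic(0, 0.1, -0.002)
  pcn <- predicted_fate_curve(fitn, range = c(0, 100))
  expect_true(pcn$max_predation_distance %in% c(0, 100))
  expect_error(predicted_fate_curve(fate_logistic(0, 1, 1, converged = FALSE)))
})

test_that("pooled t statistic matches the hand-computed formula", {
  g1 <- moment_matched(62, 15.3, 18.8, seed = 1)
  g2 <- moment_matched(38, 13.8, 19.0, seed = 2)
  rec <- data.frame(nest_id = as.character(1:100),
                    species = rep(c("sandpiper", "phalarope"), c(62, 38)),
                    flush_distance_m = c(g1, g2),
                    defence_category = 1L, fate = "hatched")
  tt <- flush_t_test(rec)
  sp2 <- (61 * 18.8^2 + 37 * 19^2) / 98
  t_hand <- (15.3 - 13.8) / sqrt(sp2 * (1 / 62 + 1 / 38))
  expect_equal(unname(tt$statistic), t_hand, tolerance = 1e-9)
  expect_lt(abs(unname(tt$statistic) - 0.38), 0.01)
  expect_identical(unname(tt$parameter), 98)
  # identical groups: t = 0, p = 1
  rec2 <- rec
  rec2$flush_distance_m <- rep(c(1, 2, 3, 4, 5), 20)
  rec2$species <- rep(c("sandpiper", "phalarope"), each = 50)
  expect_equal(unname(flush_t_test(rec2)$statistic), 0)
  expect_equal(flush_t_test(rec2)$p.value, 1)
  # swapping labels negates t, keeps p
  rec3 <- rec
  rec3$species <- ifelse(rec$species == "sandpiper", "phalarope", "sandpiper")
  expect_equal(unname(flush_t_test(rec3)$statistic), -t_hand, tolerance = 1e-9)
  expect_equal(flush_t_test(rec3)$p.value, tt$p.value)
  # Welch variant has non-integer df
  tw <- flush_t_test(rec, variant = "welch")
  expect_false(tw$parameter == 98)
})

test_that("linear-regression R2 matches hand OLS", {
  x <- c(0, 1, 2); y <- c(1, 3, 2)
  expect_equal(linreg_r2(x, y), 0.25)
  xx <- 1:50
  expect_equal(suppressWarnings(linreg_r2(xx, 2 * xx + 1)), 1)
  set.seed(3)
  expect_lt(linreg_r2(rnorm(5000), rnorm(5000)), 0.01)
  expect_error(linreg_r2(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(linreg_r2(1:2, 1:2), "at least 3")
})

test_that("summaries report per-species moments, categories, bins and success", {
  r1 <- make_records(n = 1, species = "sandpiper", flush = 10, category = 1,
                     fate = "hatched")
  s1 <- summarize_nests(r1)
  expect_equal(s1$per_species$mean_flush[1], 10)
  expect_equal(s1$per_species$hatch_success[1], 1)
  expect_equal(unname(s1$category_proportions["sandpiper", "category1"]), 1)
  # boundary convention: 5.0 falls in the middle bin
  r2 <- make_records(n = 4, flush = rep(5, 4))
  expect_equal(unname(summarize_nests(r2)$bin_proportions), c(0, 1, 0))
  # sample SD uses the n-1 denominator; unknown fates count in the denominator
  r3 <- make_records(n = 3, species = rep("sandpiper", 3), flush = c(1, 2, 9),
                     fate = c("hatched", "hatched", "unknown"))
  s3 <- summarize_nests(r3)
  expect_equal(s3$per_species$sd_flush[1], sd(c(1, 2, 9)))
  expect_equal(s3$per_species$hatch_success[1], 2 / 3)
  # bins partition everything
  cfg <- synthetic_preset("paper_like", seed = 2)
  s4 <- summarize_nests(generate_nests(cfg))
  expect_equal(sum(s4$bin_proportions), 1)
  expect_true(all(abs(rowSums(s4$category_proportions) - 1) < 1e-12))
})
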