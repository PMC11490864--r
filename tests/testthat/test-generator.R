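test_that("generated cohorts have the requested size and cluster structure", {
  cfg <- soar_config(n_children = 100L, n_clusters = 5L, missing = FALSE)
  tab <- generate_cohort(cfg)
  expect_equal(nrow(tab), 100L)
  expect_equal(length(unique(tab$cluster_id)), 5L)
  expect_false(anyNA(tab))
  expect_false(anyDuplicated(tab$child_id) > 0)
  expect_true(all(tab$A %in% 0:1) && all(tab$M %in% 0:1))
})

test_that("generation is byte-identical given config and seed", {
  cfg <- tiny_config(seed = 13L)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  expect_false(identical(generate_cohort(cfg, seed = 13L),
                         generate_cohort(cfg, seed = 14L)))
})

test_that("a zero outcome model yields 50% prevalence", {
  cfg <- soar_config(n_children = 50000L, n_clusters = 10L, missing = FALSE)
  cfg$coef_Y$Y_mh[] <- 0
  cfg$cluster_sd <- 0   # so only binomial noise remains around logistic(0)
  tab <- generate_cohort(cfg, seed = 2L)
  # logistic(0) = 0.5; 3 binomial SEs at n = 50 000
  expect_lt(abs(mean(tab$Y_mh) - 0.5), 3 * sqrt(0.25 / 50000))
})

test_that("a log(4) odds-ratio exposure effect on the mediator reproduces the inverted-logit prevalence", {
  # baseline P(M=1|A=0) = 0.10; odds 4 * (0.1/0.9) = 4/9 -> P = 0.3077
  cfg <- soar_config(n_children = 50000L, n_clusters = 10L, missing = FALSE)
  cfg$p_exposed <- 0.5
  cfg$cluster_sd <- 0
  cfg$coef_L[, ] <- c(-20, 0, 0, 0, 0)       # L essentially never 1
  cfg$coef_M[] <- 0
  cfg$coef_M[1] <- qlogis(0.10)
  cfg$coef_M[2] <- log(4)
  tab <- generate_cohort(cfg, seed = 3L)
  p_target <- (4 / 9) / (1 + 4 / 9)
  p_hat <- mean(tab$M[tab$A == 1])
  expect_lt(abs(p_hat - p_target),
            3 * sqrt(p_target * (1 - p_target) / sum(tab$A == 1)))
  expect_lt(abs(mean(tab$M[tab$A == 0]) - 0.10),
            3 * sqrt(0.1 * 0.9 / sum(tab$A == 0)))
})

test_that("coefficient arity errors name the offending vector", {
  expect_error(cohort_config(
    n_children = 10L, n_clusters = 2L, p_exposed = 0.5,
    coef_L = matrix(0, 1, 5), coef_M = c(0, 0), coef_Y = list(Y = rep(0, 8))),
    "coef_M")
  expect_error(cohort_config(
    n_children = 10L, n_clusters = 2L, p_exposed = 0.5,
    coef_L = matrix(0, 1, 5), coef_M = rep(0, 6), coef_Y = list(Y = rep(0, 3))),
    "coef_Y")
})

test_that("missingness: zero rates are the identity, rate one blanks everything", {
  cfg <- tiny_config()
  tab <- generate_cohort(cfg)
  cfg$missing_rates <- list(M = 0, Y_mh = 0)
  expect_identical(apply_missingness(tab, cfg), tab)
  cfg$missing_rates <- list(M = 1)
  out <- apply_missingness(tab, cfg)
  expect_true(all(is.na(out$M)))
  expect_false(anyNA(out$Y_mh))
})

test_that("missingness can never be requested for id, cluster or exposure", {
  cfg <- tiny_config()
  cfg$missing_rates <- list(A = 0.1)
  expect_error(generate_cohort(cfg), "always observed")
})

test_that("the realized any-missing fraction matches the analytic rate implied by the per-variable probabilities", {
  cfg <- soar_config(n_children = 20000L, n_clusters = 20L, seed = 5L)
  tab <- generate_cohort(cfg)
  p <- missing_probabilities(tab, cfg)
  expected <- mean(1 - apply(1 - p, 1, prod))
  masked <- apply_missingness(tab, cfg)
  observed <- mean(!stats::complete.cases(masked))
  expect_lt(abs(observed - expected), 3 * sqrt(0.25 / nrow(tab)) + 0.002)
})

test_that("true effects: null exposure gives a zero decomposition; no mediator pathway gives zero reduction", {
  cfg <- null_config()
  te <- true_effects(cfg, "Y_mh", n_std = 2e4)
  # with zero exposure coefficients the two natural-course regimes are
  # computed from identical draws, so the overall inequity is exactly zero;
  # eliminating a mediator that still affects the outcome benefits the
  # exposed, so reduction and remaining cancel rather than vanish
  expect_identical(te$overall, 0)
  expect_identical(te$reduction, -te$remaining)
  cfg_null_med <- cfg
  cfg_null_med$coef_Y$Y_mh[7] <- 0
  te0 <- true_effects(cfg_null_med, "Y_mh", n_std = 2e4)
  expect_identical(te0$overall, 0)
  expect_equal(te0$reduction, 0, tolerance = 1e-12)
  expect_equal(te0$remaining, 0, tolerance = 1e-12)

  cfg2 <- tiny_config()
  cfg2$coef_Y$Y_mh[7:8] <- 0             # mediator and exposure:mediator
  te2 <- true_effects(cfg2, "Y_mh", n_std = 2e4)
  expect_equal(te2$reduction, 0, tolerance = 1e-12)
  expect_equal(te2$remaining, te2$overall, tolerance = 1e-12)
  expect_gt(te2$overall, 0)
})

test_that("montecarlo and enumerate oracles agree within Monte Carlo error", {
  cfg <- tiny_config()
  te_en <- true_effects(cfg, "Y_mh", n_std = 1e5, seed = 11L)
  te_mc <- true_effects(cfg, "Y_mh", mode = "montecarlo", draws = 4e5,
                        seed = 12L)
  tol <- 3 * (sqrt(0.25 / 4e5) + sqrt(0.25 / 1e5))
  for (q in c("p1", "p0", "p_int"))
    expect_lt(abs(te_en[[q]] - te_mc[[q]]), tol)
  expect_error(true_effects(cfg, "Y_mh", mode = "montecarlo", draws = 500),
               "1000")
})

test_that("raising the mediator-outcome coefficient never lowers the true reduction", {
  cfg <- tiny_config()
  red <- vapply(c(0, 0.5, 1, 1.5), function(cm) {
    cfg$coef_Y$Y_mh[7] <- cm
    true_effects(cfg, "Y_mh", n_std = 2e4, seed = 4L)$reduction
  }, 0)
  expect_true(all(diff(red) >= 0))
})

test_that("cohort and config round-trip through their text formats", {
  cfg <- tiny_config(n = 60L, clusters = 4L)
  cfg$missing_rates <- list(M = list(rate = 0.2, on_exposure = 0.4))
  tab <- apply_missingness(generate_cohort(cfg), cfg)
  f <- tempfile(fileext = ".csv")
  write_cohort(tab, f)
  expect_equal(read_cohort(f), tab, tolerance = 1e-12)
  fc <- tempfile(fileext = ".yaml")
  write_config(cfg, fc)
  cfg2 <- read_config(fc)
  expect_equal(cfg2$coef_L, cfg$coef_L)
  expect_identical(generate_cohort(cfg2), generate_cohort(cfg))
})
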