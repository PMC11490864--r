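test_that("equal risks in both groups give a risk ratio of one", {
  tab <- toy_2x2(n_exposed = 20, n_unexposed = 20,
                 events_exposed = 8, events_unexposed = 8,
                 singleton_clusters = FALSE)
  rr <- fit_rr_gee(tab, "Y", "A", cluster = "cluster_id")
  expect_equal(rr$rr, 1, tolerance = 1e-6)
})

test_that("the saturated exposure-only log-Poisson fit equals the empirical risk ratio", {
  # risks 0.4 vs 0.2, one observation per cluster -> RR exactly 2
  tab <- toy_2x2()
  rr <- fit_rr_gee(tab, "Y", "A")
  expect_equal(rr$rr, 2, tolerance = 1e-6)
  expect_equal(rr$log_rr, log(2), tolerance = 1e-6)
  expect_true(rr$ci_low <= rr$rr && rr$rr <= rr$ci_high)
  # symmetric log-scale CI: rr^2 = ci_low * ci_high
  expect_equal(rr$ci_low * rr$ci_high, rr$rr^2, tolerance = 1e-8)
})

test_that("exchangeable and independence working correlations coincide for singleton clusters", {
  tab <- generate_cohort(tiny_config(n = 250L, clusters = 5L, seed = 31L))
  tab$cluster_id <- tab$child_id     # every cluster a singleton
  f <- Y_mh ~ A + age + sex
  fe <- gee_fit(f, tab, id = tab$cluster_id, corstr = "exchangeable")
  fi <- gee_fit(f, tab, id = tab$cluster_id, corstr = "independence")
  expect_equal(fe$coefficients, fi$coefficients, tolerance = 1e-8)
  expect_equal(fe$vcov, fi$vcov, tolerance = 1e-8)
})

test_that("with singleton clusters the sandwich variance matches the HC0 robust variance of the log-Poisson GLM", {
  skip_if_not_installed("sandwich")
  tab <- generate_cohort(tiny_config(n = 300L, clusters = 6L, seed = 17L))
  tab$cluster_id <- tab$child_id
  fit <- gee_fit(Y_mh ~ A + age, tab, id = tab$cluster_id)
  g <- glm(Y_mh ~ A + age, data = tab, family = poisson())
  expect_equal(unname(fit$coefficients), unname(coef(g)), tolerance = 1e-7)
  expect_equal(unname(fit$vcov), unname(sandwich::vcovHC(g, type = "HC0")),
               tolerance = 1e-6)
})

test_that("the exchangeable fit reproduces an independently computed reference on a frozen cohort", {
  # reference values computed once with an independent GEE implementation on
  # the identical seeded cohort (log-Poisson, exchangeable, robust SE)
  tab <- generate_cohort(tiny_config(n = 400L, clusters = 8L, seed = 42L))
  fit <- gee_fit(Y_mh ~ A + age + sex, tab, id = tab$cluster_id)
  expect_equal(fit$coefficients[["A"]], 0.4161906485, tolerance = 1e-6)
  expect_equal(sqrt(fit$vcov["A", "A"]), 0.1748994829, tolerance = 1e-6)
  expect_equal(fit$alpha, -0.00725496, tolerance = 1e-5)
})

test_that("pooling identical datasets returns the single-dataset risk ratio with no between-imputation variance", {
  tab <- generate_cohort(tiny_config(n = 300L, clusters = 6L, seed = 9L))
  st <- stub_stack(list(tab, tab))
  single <- fit_rr_gee(tab, "Y_mh", "A", c("age", "sex"))
  pooled <- pooled_rr(st, "Y_mh", "A", c("age", "sex"))
  expect_equal(pooled$rr, single$rr, tolerance = 1e-10)
  expect_identical(pooled$pooled$B, 0)
  expect_equal(pooled$var_log_rr, single$var_log_rr, tolerance = 1e-10)
})

test_that("pooled risk ratios from a stub fitter match the Rubin worked example back-transformed", {
  st <- stub_stack(list(data.frame(x = 1), data.frame(x = 2)))
  stub <- local({
    i <- 0L
    function(d) {
      i <<- i + 1L
      structure(list(rr = exp(c(1, 3)[i]), log_rr = c(1, 3)[i],
                     var_log_rr = 1,
                     model = list(outcome = "Y", exposure_term = "A",
                                  adjustment = character())),
                class = "rr_result")
    }
  })
  pooled <- pooled_rr(st, "Y", fitter = stub)
  expect_equal(pooled$log_rr, 2)
  expect_equal(pooled$var_log_rr, 4)   # T = W + (1 + 1/2) B = 1 + 1.5*2
  expect_equal(pooled$rr, exp(2))
})

test_that("adjusted mediator-outcome models control for exposure and the intermediate confounder", {
  cfg <- soar_config(n_children = 500L, n_clusters = 8L, seed = 3L,
                     missing = FALSE)
  tab <- generate_cohort(cfg)
  st <- stub_stack(list(tab, tab))
  assoc <- association_table(st, outcomes = "Y_mh")
  adj_med <- assoc[assoc$term == "M" & assoc$adjusted == "adjusted", ]
  expect_true(grepl("A", adj_med$adjustment))
  expect_true(grepl("L_1", adj_med$adjustment))
  expect_true(all(assoc$ci_low <= assoc$rr & assoc$rr <= assoc$ci_high))
  expect_true(all(assoc$rr > 0))
})

test_that("a non-positive-definite or aliased design is reported as an estimation error", {
  tab <- toy_2x2()
  tab$dup <- tab$A
  expect_error(
    suppressMessages(fit_rr_gee(tab, "Y", "A", covariates = "dup")),
    "aliasing|singular")
})
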