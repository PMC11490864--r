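test_that("the inequity decomposition reproduces hand arithmetic", {
  d <- decompose_inequity(0.4, 0.2, 0.3)
  expect_equal(d$overall, 20)
  expect_equal(d$reduction, 10)
  expect_equal(d$remaining, 10)
  expect_equal(d$proportion_eliminated, 50.0)

  d2 <- decompose_inequity(0.37, 0.21, 0.37)   # identity intervention
  expect_equal(d2$reduction, 0)
  expect_equal(d2$remaining, d2$overall)

  d3 <- decompose_inequity(0.265, 0.135, 0.160)
  expect_equal(d3$overall, 13.0)
  expect_equal(d3$reduction, 10.5)
  expect_equal(d3$remaining, 2.5)
  expect_equal(d3$proportion_eliminated, 80.8)

  expect_error(decompose_inequity(1.2, 0.1, 0.1), "0, 1")
})

test_that("proportion eliminated reproduces the published worked examples", {
  expect_equal(proportion_eliminated(26.4, 11.2), 42.4)
  expect_equal(proportion_eliminated(9.7, 4.7), 48.5)
  expect_equal(proportion_eliminated(21.5, 5.5), 25.6)
  expect_equal(proportion_eliminated(6.1, 0.1), 1.6)
  expect_equal(proportion_eliminated(17.3, 0), 0.0)
  expect_error(proportion_eliminated(0, 5), "zero")
})

test_that("model fits match an independent likelihood-maximization oracle on a tiny dataset", {
  set.seed(101)
  n <- 60
  tab <- data.frame(
    child_id = as.character(1:n), cluster_id = rep(c("a", "b", "c"), 20),
    A = rbinom(n, 1, 0.4), age = rnorm(n, 12, 1.5), sex = rbinom(n, 1, 0.5))
  tab$L_1 <- rbinom(n, 1, plogis(-1 + 0.8 * tab$A))
  tab$M <- rbinom(n, 1, plogis(-0.5 + 0.7 * tab$A + 0.4 * tab$L_1))
  tab$Y_mh <- rbinom(n, 1, plogis(-1 + 0.5 * tab$A + 0.6 * tab$M))
  spec <- mediation_spec("Y_mh", interactions = "none")
  fit <- fit_mediation_models(tab, spec)
  # oracle: generic optimizer on the hand-written Bernoulli log-likelihood
  X <- cbind(1, tab$A, tab$age, tab$sex, tab$L_1, tab$M)
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(tab$Y_mh * eta - log1p(exp(eta)))
  }
  opt <- optim(rep(0, ncol(X)), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  expect_equal(unname(coef(fit$models$Y)), opt$par, tolerance = 1e-4)
})

test_that("on null data every non-intercept outcome coefficient is within 3 SEs of zero", {
  cfg <- tiny_config(n = 4000L, clusters = 10L, seed = 55L)
  cfg$coef_Y$Y_mh[2:8] <- 0
  tab <- generate_cohort(cfg)
  fit <- fit_mediation_models(tab, mediation_spec("Y_mh"))
  sm <- summary(fit$models$Y)$coefficients
  z <- abs(sm[-1, "Estimate"] / sm[-1, "Std. Error"])
  expect_true(all(z < 3))
})

test_that("a six-intermediate-confounder specification fits and enumerates", {
  cfg <- multi_L_config(K = 6L, n = 4000L)
  tab <- generate_cohort(cfg)
  spec <- mediation_spec("Y_mh", intermediate = paste0("L_", 1:6))
  fit <- fit_mediation_models(tab, spec)
  est <- gcomp_estimate(fit)
  expect_true(all(c(est$p1, est$p0, est$p_int) >= 0 &
                  c(est$p1, est$p0, est$p_int) <= 1))
  expect_identical(est$overall, est$reduction + est$remaining)
})

test_that("zeroed mediator coefficients give zero reduction; zeroed exposure coefficients give zero overall", {
  tab <- generate_cohort(tiny_config(n = 1500L, seed = 23L))
  fit <- fit_mediation_models(tab, mediation_spec("Y_mh"))

  fit_nm <- fit
  cy <- coef(fit_nm$models$Y)
  cy[grepl("(^|:)M($|:)", names(cy))] <- 0
  fit_nm$models$Y$coefficients <- cy
  est <- gcomp_estimate(fit_nm)
  expect_equal(est$reduction, 0, tolerance = 1e-12)
  expect_equal(est$remaining, est$overall, tolerance = 1e-12)

  fit_na <- fit
  for (part in c("Y", "M")) {
    cc <- coef(fit_na$models[[part]])
    cc[grepl("(^|:)A($|:)", names(cc))] <- 0
    fit_na$models[[part]]$coefficients <- cc
  }
  cl <- coef(fit_na$models$L[[1]])
  cl[grepl("(^|:)A($|:)", names(cl))] <- 0
  fit_na$models$L[[1]]$coefficients <- cl
  est2 <- gcomp_estimate(fit_na)
  expect_equal(est2$overall, 0, tolerance = 1e-12)
})

test_that("Monte Carlo g-computation agrees with exact enumeration", {
  cfg <- multi_L_config(K = 2L, n = 3000L)
  tab <- generate_cohort(cfg)
  spec <- mediation_spec("Y_mh", intermediate = c("L_1", "L_2"))
  fit <- fit_mediation_models(tab, spec)
  en <- gcomp_estimate(fit, mode = "enumerate")
  mc <- gcomp_estimate(fit, mode = "montecarlo", draws = 1e5, seed = 5L)
  for (q in c("p1", "p0", "p_int")) {
    se <- sqrt(en[[q]] * (1 - en[[q]]) / 1e5)
    expect_lt(abs(en[[q]] - mc[[q]]), 3 * se + 1e-4)
  }
  expect_error(gcomp_estimate(fit, mode = "montecarlo", draws = 50), "100")
})

test_that("an irrelevant intermediate confounder collapses to the no-L computation", {
  tab <- generate_cohort(tiny_config(n = 1200L, seed = 61L))
  fit <- fit_mediation_models(tab, mediation_spec("Y_mh",
                                                  interactions = "none"))
  # zero every L term in the mediator and outcome models
  for (part in c("Y", "M")) {
    cc <- coef(fit$models[[part]])
    cc[grepl("L_1", names(cc))] <- 0
    fit$models[[part]]$coefficients <- cc
  }
  est_with_L <- gcomp_estimate(fit)
  # structurally L-free fit carrying the same mediator/outcome laws
  fit0 <- fit_mediation_models(tab, mediation_spec(
    "Y_mh", intermediate = character(), interactions = "none"))
  for (part in c("Y", "M")) {
    cc <- coef(fit$models[[part]])
    shared <- intersect(names(coef(fit0$models[[part]])), names(cc))
    fit0$models[[part]]$coefficients[shared] <- cc[shared]
  }
  est_no_L <- gcomp_estimate(fit0)
  for (q in c("p1", "p0", "p_int", "overall", "reduction", "remaining"))
    expect_equal(est_with_L[[q]], est_no_L[[q]], tolerance = 1e-10)
})

test_that("the fitted design contains exactly the declared interaction terms", {
  tab <- generate_cohort(tiny_config(n = 500L, seed = 2L))
  fit <- fit_mediation_models(tab, mediation_spec("Y_mh"))
  terms_y <- attr(terms(fit$models$Y), "term.labels")
  expect_setequal(terms_y, c("A", "age", "sex", "L_1", "M",
                             "A:age", "A:sex", "A:L_1", "A:M"))
  fit0 <- fit_mediation_models(tab, mediation_spec("Y_mh",
                                                   interactions = "none"))
  expect_false(any(grepl(":", attr(terms(fit0$models$Y), "term.labels"))))
})

test_that("the decomposition is exactly additive for every fit and mode", {
  for (s in c(3L, 8L)) {
    tab <- generate_cohort(tiny_config(n = 800L, seed = s))
    fit <- fit_mediation_models(tab, mediation_spec("Y_mh"))
    en <- gcomp_estimate(fit)
    mc <- gcomp_estimate(fit, mode = "montecarlo", draws = 2000, seed = s)
    expect_identical(en$overall, en$reduction + en$remaining)
    expect_identical(mc$overall, mc$reduction + mc$remaining)
  }
})

test_that("incomplete data and causally out-of-order inputs are refused", {
  tab <- generate_cohort(tiny_config(n = 200L))
  tab$M[1] <- NA
  expect_error(fit_mediation_models(tab, mediation_spec("Y_mh")),
               "complete data")
  expect_error(fit_mediation_models(tab[-1, ],
               mediation_spec("Y_mh", intermediate = "L_9")), "L_9")
})
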