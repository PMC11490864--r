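#' Specification of the mediation model series
#'
#' Declares the causally ordered series of regression models used by extended
#' g-computation: one logistic model per intermediate confounder \code{L_k}
#' (regressed on exposure, baseline confounders and the prior
#' \code{L_1..L_{k-1}} in the declared order), a logistic mediator model
#' (exposure, baseline confounders, all L) and a logistic outcome model
#' (exposure, baseline confounders, all L, mediator). The default interaction
#' policy makes every model "richly specified" by crossing exposure with every
#' other predictor; \code{"none"} fits main effects only.
#'
#' @param outcome outcome column name.
#' @param mediator mediator column name.
#' @param exposure exposure column name.
#' @param baseline character vector of baseline-confounder columns.
#' @param intermediate character vector of intermediate-confounder columns, in
#'   causal order.
#' @param interactions \code{"exposure"} (all exposure-by-covariate two-way
#'   interactions, the default) or \code{"none"}.
#' @return object of class \code{mediation_spec}.
#' @export
mediation_spec <- function(outcome, mediator = "M", exposure = "A",
                           baseline = c("age", "sex"),
                           intermediate = "L_1",
                           interactions = c("exposure", "none")) {
  interactions <- match.arg(interactions)
  # an empty intermediate set is allowed: the series then degenerates to a
  # mediator + outcome model pair (no exposure-induced confounding)
  structure(list(outcome = outcome, mediator = mediator, exposure = exposure,
                 baseline = baseline, intermediate = intermediate,
                 interactions = interactions),
            class = "mediation_spec")
}

# rhs with the declared interaction policy: A + x1 + ... (+ A:x1 + ...)
spec_rhs <- function(spec, covariates) {
  if (!length(covariates)) return(spec$exposure)
  if (spec$interactions == "exposure")
    paste0(spec$exposure, " * (", paste(covariates, collapse = " + "), ")")
  else paste(c(spec$exposure, covariates), collapse = " + ")
}

spec_formulas <- function(spec) {
  K <- length(spec$intermediate)
  fl <- lapply(seq_len(K), function(k) stats::as.formula(paste(
    spec$intermediate[k], "~",
    spec_rhs(spec, c(spec$baseline, spec$intermediate[seq_len(k - 1L)])))))
  names(fl) <- spec$intermediate
  list(
    L = fl,
    M = stats::as.formula(paste(spec$mediator, "~",
          spec_rhs(spec, c(spec$baseline, spec$intermediate)))),
    Y = stats::as.formula(paste(spec$outcome, "~",
          spec_rhs(spec, c(spec$baseline, spec$intermediate, spec$mediator))))
  )
}

#' Fit the mediation model series by maximum likelihood
#'
#' Fits every model of a [mediation_spec()] by logistic regression on complete
#' data and retains the baseline-confounder records of the analysis sample for
#' later standardization.
#'
#' @param table complete cohort table (no missing values in model variables).
#' @param spec a [mediation_spec()].
#' @return object of class \code{mediation_fit} holding the fitted models, the
#'   spec, and the standardization records.
#' @export
fit_mediation_models <- function(table, spec) {
  vars <- unique(c(spec$outcome, spec$mediator, spec$exposure,
                   spec$baseline, spec$intermediate))
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols))
    stopf("table lacks model variables: %s", paste(missing_cols, collapse = ", "))
  if (anyNA(table[vars]))
    stopf("mediation models require complete data; impute first")
  fs <- spec_formulas(spec)
  fit1 <- function(f, label) {
    m <- suppressWarnings(stats::glm(f, data = table, family = stats::binomial()))
    if (!m$converged)
      stopf("model for %s did not converge (possible separation)", label)
    bad <- names(stats::coef(m))[!is.finite(stats::coef(m))]
    if (length(bad))
      stopf("model for %s has non-estimable term(s): %s", label,
            paste(bad, collapse = ", "))
    m
  }
  models_L <- lapply(names(fs$L), function(nm) fit1(fs$L[[nm]], nm))
  names(models_L) <- names(fs$L)
  structure(list(
    spec = spec,
    models = list(L = models_L,
                  M = fit1(fs$M, spec$mediator),
                  Y = fit1(fs$Y, spec$outcome)),
    standardization = table[, unique(c(spec$baseline, spec$exposure)),
                            drop = FALSE]
  ), class = "mediation_fit")
}

#' Interventional-effect estimates by extended g-computation
#'
#' Standardized outcome prevalences under exposure (\code{p1}), no exposure
#' (\code{p0}) and exposure with the mediator set to zero (\code{p_int}),
#' computed from a fitted model series by averaging model predictions over the
#' standardization population:
#' \deqn{p(a) = E_c \sum_{l} \sum_{m} P(Y{=}1|a,c,l,m) P(M{=}m|a,c,l) P(L{=}l|a,c)}
#' with \eqn{p_{int}} fixing \eqn{m = 0} under \eqn{a = 1}. \code{"enumerate"}
#' sums exactly over all \code{2^K x 2} combinations of (L, M);
#' \code{"montecarlo"} replaces the sums by sequential draws from the fitted
#' models over a resampled standardization population.
#'
#' @param fit a [fit_mediation_models()] result.
#' @param mode \code{"enumerate"} (exact, default; K <= 12) or
#'   \code{"montecarlo"}.
#' @param draws Monte Carlo draws (montecarlo mode), at least 100.
#' @param seed RNG seed (montecarlo mode only).
#' @param standardize_to \code{"all"} (default): the empirical
#'   baseline-confounder distribution of the full analysis sample;
#'   \code{"exposed"}: the exposed subsample only.
#' @return object of class \code{mediation_estimates}: the three prevalences,
#'   the inequity decomposition in percentage points (overall, reduction,
#'   remaining; overall = reduction + remaining exactly) and the proportion of
#'   the inequity eliminated.
#' @export
gcomp_estimate <- function(fit, mode = c("enumerate", "montecarlo"),
                           draws = 1e5, seed = 1L,
                           standardize_to = c("all", "exposed")) {
  stopifnot(inherits(fit, "mediation_fit"))
  mode <- match.arg(mode)
  standardize_to <- match.arg(standardize_to)
  spec <- fit$spec
  K <- length(spec$intermediate)
  pop <- fit$standardization
  if (standardize_to == "exposed")
    pop <- pop[pop[[spec$exposure]] == 1L, , drop = FALSE]

  if (mode == "enumerate") {
    if (K > 12L) stopf("enumeration over 2^%d intermediate-confounder patterns is infeasible; use mode = 'montecarlo'", K)
    p_for <- function(a, intervene_m0 = FALSE) {
      nd <- pop
      nd[[spec$exposure]] <- a
      lgrid <- if (K == 0L) matrix(0, 1L, 0L)
               else as.matrix(expand.grid(rep(list(0:1), K)))
      acc <- 0
      for (i in seq_len(nrow(lgrid))) {
        l <- lgrid[i, ]
        for (k in seq_len(K)) nd[[spec$intermediate[k]]] <- l[k]
        # model k conditions only on the prior L_j, already set to l_j in nd
        w_l <- rep(1, nrow(nd))
        for (k in seq_len(K)) {
          pk <- stats::predict(fit$models$L[[k]], newdata = nd,
                               type = "response")
          w_l <- w_l * (if (l[k] == 1) pk else 1 - pk)
        }
        pM <- stats::predict(fit$models$M, newdata = nd, type = "response")
        nd[[spec$mediator]] <- 0L
        py0 <- stats::predict(fit$models$Y, newdata = nd, type = "response")
        if (intervene_m0) {
          acc <- acc + w_l * py0
        } else {
          nd[[spec$mediator]] <- 1L
          py1 <- stats::predict(fit$models$Y, newdata = nd, type = "response")
          acc <- acc + w_l * ((1 - pM) * py0 + pM * py1)
        }
      }
      mean(acc)
    }
    probs <- c(p1 = p_for(1L), p0 = p_for(0L),
               p_int = p_for(1L, intervene_m0 = TRUE))
  } else {
    if (draws < 100) stopf("montecarlo mode needs draws >= 100")
    probs <- with_seed(seed, {
      idx <- sample.int(nrow(pop), draws, replace = TRUE)
      sim <- function(a, intervene_m0 = FALSE) {
        nd <- pop[idx, , drop = FALSE]
        nd[[spec$exposure]] <- a
        for (k in seq_len(K)) {
          pk <- stats::predict(fit$models$L[[k]], newdata = nd,
                               type = "response")
          nd[[spec$intermediate[k]]] <- stats::rbinom(draws, 1L, pk)
        }
        m <- if (intervene_m0) rep(0L, draws) else
          stats::rbinom(draws, 1L, stats::predict(fit$models$M, newdata = nd,
                                                  type = "response"))
        nd[[spec$mediator]] <- m
        mean(stats::predict(fit$models$Y, newdata = nd, type = "response"))
      }
      c(p1 = sim(1L), p0 = sim(0L), p_int = sim(1L, intervene_m0 = TRUE))
    })
  }
  out <- decompose_inequity(probs[["p1"]], probs[["p0"]], probs[["p_int"]])
  out$outcome <- spec$outcome
  out$source <- "g-computation"
  out$mode <- mode
  out$n <- nrow(pop)
  out
}

#' Proportion of the inequity eliminated by the mediator intervention
#'
#' @param overall overall inequity (percentage points).
#' @param reduction reduction achieved by the intervention (percentage points).
#' @return \code{100 * reduction / overall}, rounded half away from zero to one
#'   decimal place.
#' @examples
#' proportion_eliminated(26.4, 11.2) # 42.4
#' @export
proportion_eliminated <- function(overall, reduction) {
  if (overall == 0) stopf("proportion eliminated undefined: overall inequity is zero")
  round_half_up(100 * reduction / overall, 1)
}

#' Decompose standardized prevalences into the inequity components
#'
#' @param p1,p0,p_int standardized prevalences in [0, 1]: exposed natural
#'   course, unexposed natural course, exposed with mediator eliminated.
#' @return object of class \code{mediation_estimates} with \code{overall},
#'   \code{reduction} and \code{remaining} in percentage points
#'   (\code{overall = reduction + remaining} exactly) and
#'   \code{proportion_eliminated} (NA when the overall inequity is zero).
#' @examples
#' decompose_inequity(0.4, 0.2, 0.3)
#' @export
decompose_inequity <- function(p1, p0, p_int) {
  for (p in c(p1, p0, p_int))
    if (!is.finite(p) || p < 0 || p > 1)
      stopf("prevalences must lie in [0, 1]")
  reduction <- 100 * (p1 - p_int)
  remaining <- 100 * (p_int - p0)
  overall <- reduction + remaining
  structure(list(
    p1 = p1, p0 = p0, p_int = p_int,
    overall = overall, reduction = reduction, remaining = remaining,
    proportion_eliminated = if (overall == 0) NA_real_
      else proportion_eliminated(overall, reduction)
  ), class = "mediation_estimates")
}

#' @export
print.mediation_estimates <- function(x, ...) {
  cat(sprintf("Interventional-effect estimates%s%s\n",
              if (!is.null(x$outcome)) paste0(" [", x$outcome, "]") else "",
              if (!is.null(x$source)) paste0(" (", x$source, ")") else ""))
  cat(sprintf("  prevalence: exposed %.3f | unexposed %.3f | exposed, mediator eliminated %.3f\n",
              x$p1, x$p0, x$p_int))
  cat(sprintf("  overall inequity   %6.1f pp\n", x$overall))
  cat(sprintf("  reduction          %6.1f pp\n", x$reduction))
  cat(sprintf("  remaining          %6.1f pp\n", x$remaining))
  cat(sprintf("  proportion eliminated %5.1f%%\n", x$proportion_eliminated))
  invisible(x)
}
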