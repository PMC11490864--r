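#' Generate a clustered synthetic cohort
#'
#' Draws a complete child-level table under the structural law of a
#' [cohort_config()]: children are assigned to clusters, each cluster receives
#' a shared normal disturbance added to every model's linear predictor, and
#' exposure, baseline confounders, intermediate confounder(s), mediator and
#' outcomes are drawn sequentially from logistic models in causal order
#' (exposure and baseline confounders, then L, then M, then each outcome).
#'
#' @param config a [cohort_config()].
#' @param seed RNG seed; defaults to the seed stored in the config.
#' @return a \code{data.frame} with columns \code{child_id}, \code{cluster_id},
#'   \code{A}, \code{age}, \code{sex}, (\code{cohort} if configured),
#'   \code{L_1..L_K}, \code{M} and one column per outcome. No missing values;
#'   use [apply_missingness()] to blank values afterwards.
#' @examples
#' cfg <- soar_config(n_children = 200, n_clusters = 5)
#' head(generate_cohort(cfg))
#' @export
generate_cohort <- function(config, seed = config$seed) {
  validate_config(config)
  n <- config$n_children
  nc <- config$n_clusters
  K <- n_intermediate(config)
  with_seed(seed, {
    # every cluster non-empty, remainder spread uniformly, order shuffled
    cl <- sample(c(seq_len(nc), sample.int(nc, max(0L, n - nc), replace = TRUE)))
    u <- stats::rnorm(nc, 0, config$cluster_sd)
    A <- stats::rbinom(n, 1L, config$p_exposed)
    age <- stats::rnorm(n, config$age_mean, config$age_sd)
    sex <- stats::rbinom(n, 1L, config$p_female)
    cohort <- if (config$has_cohort) stats::rbinom(n, 1L, config$p_cohort)
              else rep(0L, n)
    base <- cbind(1, A, age - config$age_mean, sex, cohort)
    uc <- u[cl]
    L <- matrix(0L, n, K)
    for (k in seq_len(K))
      L[, k] <- stats::rbinom(n, 1L, stats::plogis(
        drop(base %*% config$coef_L[k, ]) + uc))
    lp_m <- drop(base %*% config$coef_M[1:5]) +
      drop(L %*% config$coef_M[5L + seq_len(K)]) + uc
    M <- stats::rbinom(n, 1L, stats::plogis(lp_m))
    out <- data.frame(
      child_id = sprintf("c%05d", seq_len(n)),
      cluster_id = sprintf("s%03d", cl),
      A = A, age = age, sex = sex, stringsAsFactors = FALSE)
    if (config$has_cohort) out$cohort <- cohort
    for (k in seq_len(K)) out[[paste0("L_", k)]] <- L[, k]
    out$M <- M
    for (nm in names(config$coef_Y)) {
      cy <- config$coef_Y[[nm]]
      lp_y <- drop(base %*% cy[1:5]) + drop(L %*% cy[5L + seq_len(K)]) +
        cy[5L + K + 1L] * M + cy[5L + K + 2L] * A * M + uc
      out[[nm]] <- stats::rbinom(n, 1L, stats::plogis(lp_y))
    }
    out
  })
}

#' Per-record missingness probabilities implied by a configuration
#'
#' For each variable with a configured missingness rate, computes the
#' missing-at-random probability for every record:
#' \code{plogis(qlogis(rate) + b_A (A - p_exposed) + b_sex (sex - p_female))}.
#' Centring the exposure and sex indicators keeps the marginal rate close to
#' the nominal one while letting missingness depend on always-observed fields.
#'
#' @param table a complete cohort table.
#' @param config the [cohort_config()] holding \code{missing_rates}.
#' @return numeric matrix, one row per record, one column per maskable
#'   variable named in the config.
#' @export
missing_probabilities <- function(table, config) {
  vars <- names(config$missing_rates)
  p <- matrix(0, nrow(table), length(vars), dimnames = list(NULL, vars))
  for (nm in vars) {
    mr <- normalize_missing_rate(config$missing_rates[[nm]], nm)
    if (mr$rate %in% c(0, 1)) {
      p[, nm] <- mr$rate
    } else {
      p[, nm] <- stats::plogis(stats::qlogis(mr$rate) +
        mr$on_exposure * (table$A - config$p_exposed) +
        mr$on_sex * (table$sex - config$p_female))
    }
  }
  p
}

#' Blank values under the configured missing-at-random mechanism
#'
#' @inheritParams missing_probabilities
#' @param seed RNG seed; defaults to the config seed plus one so that the same
#'   config can drive generation and masking without reusing a stream.
#' @return the table with masked entries set to \code{NA}; \code{child_id},
#'   \code{cluster_id} and the exposure are never blanked.
#' @export
apply_missingness <- function(table, config, seed = config$seed + 1L) {
  validate_config(config)
  if (anyNA(table)) stopf("apply_missingness expects a complete table")
  p <- missing_probabilities(table, config)
  with_seed(seed, {
    for (nm in colnames(p)) {
      if (!nm %in% names(table)) next
      drop_mask <- stats::runif(nrow(table)) < p[, nm]
      table[[nm]][drop_mask] <- NA
    }
  })
  table
}

#' True interventional effects of a generative configuration
#'
#' Brute-force oracle for the estimands targeted by the mediation analysis:
#' the standardized outcome prevalence under exposure (\code{p1}), under no
#' exposure (\code{p0}), and under exposure with the mediator set to zero
#' (\code{p_int}), marginalized over the baseline-confounder distribution and
#' the cluster disturbance of the configuration. From these, the overall
#' inequity \code{p1 - p0}, the reduction achievable by eliminating the
#' mediator \code{p1 - p_int}, the remaining inequity \code{p_int - p0}
#' (all in percentage points) and the proportion of the inequity eliminated.
#'
#' \code{mode = "enumerate"} integrates age, sex, cohort and the cluster
#' disturbance by fixed-seed Monte Carlo (\code{n_std} draws) and sums exactly
#' over all \code{2^K x 2} combinations of (L, M). \code{mode = "montecarlo"}
#' simulates the full law forward under each regime.
#'
#' @param config a [cohort_config()].
#' @param outcome outcome name (a name of \code{config$coef_Y}).
#' @param mode \code{"enumerate"} (default) or \code{"montecarlo"}.
#' @param draws Monte Carlo sample size (montecarlo mode); at least 1000.
#' @param n_std standardization draws for the enumerate mode.
#' @param seed RNG seed for the integration draws.
#' @return object of class \code{mediation_estimates} (the same container the
#'   analysis returns), with \code{source = "generator-truth"}.
#' @export
true_effects <- function(config, outcome = names(config$coef_Y)[1],
                         mode = c("enumerate", "montecarlo"),
                         draws = 1e6, n_std = 1e5, seed = config$seed) {
  validate_config(config)
  mode <- match.arg(mode)
  if (!outcome %in% names(config$coef_Y))
    stopf("unknown outcome '%s'; config defines: %s", outcome,
          paste(names(config$coef_Y), collapse = ", "))
  K <- n_intermediate(config)
  cy <- config$coef_Y[[outcome]]

  if (mode == "enumerate") {
    probs <- with_seed(seed, {
      age_c <- stats::rnorm(n_std, 0, config$age_sd)
      sex <- stats::rbinom(n_std, 1L, config$p_female)
      cohort <- if (config$has_cohort)
        stats::rbinom(n_std, 1L, config$p_cohort) else rep(0L, n_std)
      u <- stats::rnorm(n_std, 0, config$cluster_sd)
      p_for <- function(a, intervene_m0 = FALSE) {
        base <- cbind(1, a, age_c, sex, cohort)
        pL <- sapply(seq_len(K), function(k)
          stats::plogis(drop(base %*% config$coef_L[k, ]) + u))
        pL <- matrix(pL, nrow = n_std)
        acc <- 0
        lgrid <- as.matrix(expand.grid(rep(list(0:1), K)))
        for (i in seq_len(nrow(lgrid))) {
          l <- lgrid[i, ]
          w_l <- rep(1, n_std)
          for (k in seq_len(K))
            w_l <- w_l * (if (l[k] == 1) pL[, k] else 1 - pL[, k])
          lp_m <- drop(base %*% config$coef_M[1:5]) +
            sum(config$coef_M[5L + seq_len(K)] * l) + u
          pM <- stats::plogis(lp_m)
          lp_y0 <- drop(base %*% cy[1:5]) + sum(cy[5L + seq_len(K)] * l) + u
          py <- function(m) stats::plogis(
            lp_y0 + cy[5L + K + 1L] * m + cy[5L + K + 2L] * a * m)
          acc <- acc + if (intervene_m0) w_l * py(0)
                       else w_l * ((1 - pM) * py(0) + pM * py(1))
        }
        mean(acc)
      }
      c(p1 = p_for(1), p0 = p_for(0), p_int = p_for(1, intervene_m0 = TRUE))
    })
  } else {
    if (draws < 1000) stopf("montecarlo mode needs draws >= 1000 for a reliable oracle")
    probs <- with_seed(seed, {
      sim <- function(a, intervene_m0 = FALSE) {
        age_c <- stats::rnorm(draws, 0, config$age_sd)
        sex <- stats::rbinom(draws, 1L, config$p_female)
        cohort <- if (config$has_cohort)
          stats::rbinom(draws, 1L, config$p_cohort) else rep(0L, draws)
        u <- stats::rnorm(draws, 0, config$cluster_sd)
        base <- cbind(1, a, age_c, sex, cohort)
        L <- matrix(0L, draws, K)
        for (k in seq_len(K))
          L[, k] <- stats::rbinom(draws, 1L, stats::plogis(
            drop(base %*% config$coef_L[k, ]) + u))
        m <- if (intervene_m0) rep(0L, draws) else
          stats::rbinom(draws, 1L, stats::plogis(
            drop(base %*% config$coef_M[1:5]) +
            drop(L %*% config$coef_M[5L + seq_len(K)]) + u))
        mean(stats::plogis(drop(base %*% cy[1:5]) +
          drop(L %*% cy[5L + seq_len(K)]) +
          cy[5L + K + 1L] * m + cy[5L + K + 2L] * a * m + u))
      }
      c(p1 = sim(1), p0 = sim(0), p_int = sim(1, intervene_m0 = TRUE))
    })
  }
  out <- decompose_inequity(probs[["p1"]], probs[["p0"]], probs[["p_int"]])
  out$outcome <- outcome
  out$source <- "generator-truth"
  out$mode <- mode
  out$n <- if (mode == "enumerate") n_std else draws
  out
}
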