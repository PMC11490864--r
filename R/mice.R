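#' Multiple imputation by chained equations
#'
#' Produces \code{m} completed copies of a cohort table by cycling univariate
#' imputation models: linear regression for continuous variables, logistic
#' regression for binary ones. Each univariate model includes every other
#' study variable, all two-way interactions amongst the study variables
#' (exposure, mediator, outcomes, baseline and intermediate confounders) not
#' involving the target, and the cluster membership indicator as a categorical
#' fixed-effect predictor. Imputation is "proper": each redraw uses
#' coefficients sampled from the approximate posterior of the fitted model
#' (normal on the coefficient scale; scaled inverse chi-square residual
#' variance for linear models), so between-imputation variance reflects
#' estimation uncertainty. Interactions are recomputed from current values at
#' every refit (impute-then-transform).
#'
#' Variables are visited in order of ascending missingness. Missing entries
#' are initialized by random draws from the observed marginal of each
#' variable. If every cluster-level of a record needing imputation is absent
#' from the records where the target is observed, the cluster indicator is
#' dropped from that variable's model with a warning.
#'
#' @param table cohort table with missing values (NA) in imputable columns;
#'   \code{child_id}, \code{cluster_id} and the exposure must be complete.
#' @param m number of completed datasets (>= 2).
#' @param n_iterations chained-equation cycles per dataset.
#' @param seed RNG seed.
#' @param id_col,cluster_col identifier columns (never imputed; the cluster
#'   column enters models as a factor).
#' @return object of class \code{imputed_stack}: \code{m}, \code{datasets}
#'   (list of completed data.frames), \code{n_iterations}, \code{seed},
#'   \code{visit_order} and \code{predictors} (per-variable model formulas).
#' @export
mice_impute <- function(table, m, n_iterations = 10L, seed = 1L,
                        id_col = "child_id", cluster_col = "cluster_id") {
  if (!is_count(m, 2L)) stopf("m must be an integer >= 2")
  if (!is_count(n_iterations)) stopf("n_iterations must be a positive integer")
  study_vars <- setdiff(names(table), c(id_col, cluster_col))
  if (anyNA(table[[id_col]]) || anyNA(table[[cluster_col]]))
    stopf("identifier columns must be complete")
  n_miss <- vapply(table[study_vars], function(x) sum(is.na(x)), 0L)
  targets <- study_vars[n_miss > 0L]
  is_binary <- vapply(table[study_vars], function(x)
    all(stats::na.omit(x) %in% c(0, 1)), TRUE)
  for (v in targets) {
    obs <- stats::na.omit(table[[v]])
    if (length(obs) == 0L) stopf("'%s' has no observed values", v)
    if (is_binary[[v]] && length(unique(obs)) < 2L)
      stopf("'%s' is observed at a single level; its imputation model is inestimable (perfect separation)", v)
  }
  visit <- targets[order(n_miss[targets])]
  cluster_f <- factor(table[[cluster_col]])

  # per-target formula: all other study variables, their two-way interactions,
  # and the cluster factor
  rhs_of <- function(v, with_cluster = TRUE) {
    others <- setdiff(study_vars, v)
    paste0("(", paste(others, collapse = " + "), ")^2",
           if (with_cluster) " + .cluster" else "")
  }
  predictors <- stats::setNames(lapply(visit, function(v)
    paste(v, "~", rhs_of(v))), visit)

  stack <- structure(list(m = m, datasets = vector("list", m),
                          n_iterations = n_iterations, seed = as.integer(seed),
                          visit_order = visit, predictors = predictors),
                     class = "imputed_stack")
  if (length(visit) == 0L) {
    stack$datasets <- replicate(m, table, simplify = FALSE)
    return(stack)
  }

  obs_mask <- lapply(stats::setNames(visit, visit),
                     function(v) !is.na(table[[v]]))
  with_seed(seed, {
    for (imp in seq_len(m)) {
      cur <- table
      for (v in visit) {
        mis <- !obs_mask[[v]]
        cur[[v]][mis] <- sample(cur[[v]][obs_mask[[v]]], sum(mis),
                                replace = TRUE)
      }
      for (cycle in seq_len(n_iterations)) {
        for (v in visit) {
          cur[[v]] <- impute_one(cur, v, obs_mask[[v]], rhs_of, cluster_f,
                                 binary = is_binary[[v]])
        }
      }
      stack$datasets[[imp]] <- cur
    }
  })
  stack
}

# one univariate redraw for target v on current completed data
impute_one <- function(cur, v, obs, rhs_of, cluster_f, binary) {
  mis <- !obs
  dat <- cur
  dat$.cluster <- cluster_f
  with_cluster <- TRUE
  if (length(setdiff(unique(cluster_f[mis]), unique(cluster_f[obs])))) {
    warning(sprintf(
      "cluster(s) with no observed '%s'; dropping the cluster indicator from its imputation model", v),
      call. = FALSE)
    with_cluster <- FALSE
  }
  f <- stats::as.formula(paste(v, "~", rhs_of(v, with_cluster)))
  fit <- suppressWarnings(if (binary)
    stats::glm(f, data = dat[obs, , drop = FALSE], family = stats::binomial())
  else
    stats::lm(f, data = dat[obs, , drop = FALSE]))
  beta <- stats::coef(fit)
  ok <- is.finite(beta)
  beta_star <- beta
  V <- suppressWarnings(stats::vcov(fit))   # covers non-aliased coefs only
  keep <- intersect(names(beta)[ok], rownames(V))
  ch <- tryCatch(chol(V[keep, keep, drop = FALSE]), error = function(e) NULL)
  if (!is.null(ch))
    beta_star[keep] <- beta[keep] +
      drop(crossprod(ch, stats::rnorm(length(keep))))
  X <- stats::model.matrix(stats::delete.response(stats::terms(fit)),
                           dat[mis, , drop = FALSE])
  X <- X[, names(beta), drop = FALSE]
  eta <- drop(X[, ok, drop = FALSE] %*% beta_star[ok])
  out <- cur[[v]]
  if (binary) {
    out[mis] <- stats::rbinom(sum(mis), 1L, stats::plogis(eta))
  } else {
    df_res <- fit$df.residual
    sigma_star <- stats::sigma(fit) *
      sqrt(df_res / stats::rchisq(1L, df_res))
    out[mis] <- stats::rnorm(sum(mis), eta, sigma_star)
  }
  out
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat(sprintf("<imputed_stack> m = %d datasets, %d chained-equation cycles, seed %d\n",
              x$m, x$n_iterations, x$seed))
  cat(sprintf("  imputed variables (visit order): %s\n",
              if (length(x$visit_order)) paste(x$visit_order, collapse = ", ")
              else "none (input complete)"))
  invisible(x)
}

#' Pool estimates across imputations with Rubin's rules
#'
#' @param estimates per-imputation point estimates (length m >= 2).
#' @param variances per-imputation variances (same length, non-negative).
#' @return object of class \code{pooled_estimate}: \code{q_bar} (pooled
#'   estimate), \code{W} (mean within-imputation variance), \code{B}
#'   (between-imputation variance), \code{T} (total variance
#'   \code{W + (1 + 1/m) B}), \code{df} (Rubin degrees of freedom; \code{Inf}
#'   when B = 0) and \code{m}.
#' @examples
#' pool_rubin(c(1, 3), c(1, 1)) # q_bar 2, W 1, B 2, T 4
#' @export
pool_rubin <- function(estimates, variances) {
  if (length(estimates) != length(variances))
    stopf("estimates and variances must have equal length")
  m <- length(estimates)
  if (m < 2L) stopf("pooling requires m >= 2")
  if (any(variances < 0)) stopf("variances must be non-negative")
  q_bar <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  Tt <- W + (1 + 1 / m) * B
  df <- if (B == 0) Inf else (m - 1) * (1 + W / ((1 + 1 / m) * B))^2
  structure(list(q_bar = q_bar, W = W, B = B, T = Tt, df = df, m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Pooled estimate (m = %d): %.4f (SE %.4f; W %.4g, B %.4g, df %.1f)\n",
              x$m, x$q_bar, sqrt(x$T), x$W, x$B, x$df))
  invisible(x)
}

#' Write an imputed stack as delimited text plus a provenance sidecar
#'
#' One CSV per completed dataset (\code{imp_01.csv}, ...) and a JSON sidecar
#' recording m, the cycle count, the seed and the per-variable model formulas.
#'
#' @param stack an [mice_impute()] result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_imputed_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(stack$m))
    write_cohort(stack$datasets[[i]], file.path(dir, sprintf("imp_%02d.csv", i)))
  jsonlite::write_json(
    list(m = stack$m, n_iterations = stack$n_iterations, seed = stack$seed,
         visit_order = stack$visit_order,
         predictors = lapply(stack$predictors, identity)),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
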