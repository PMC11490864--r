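#' Clustered bootstrap of an estimator
#'
#' Resamples whole clusters with replacement, holding the number of clusters
#' fixed at the original count (record count varies across replicates), and
#' re-runs the estimator on the concatenated records. Resampled copies of the
#' same cluster receive distinct cluster identifiers so that downstream
#' cluster-aware estimators treat them as independent.
#'
#' @param table cohort table.
#' @param estimator function(table) returning a named numeric vector of
#'   estimands.
#' @param B replicate count (>= 50).
#' @param seed RNG seed.
#' @param cluster cluster identifier column.
#' @return object of class \code{bootstrap_distribution}: \code{B},
#'   \code{replicates} (matrix, one stored row per successful replicate),
#'   \code{se} (per-estimand SDs over stored replicates), \code{failures},
#'   \code{seed}, \code{cluster}. A warning is raised if more than 5\% of
#'   replicates fail; an error if more than half do.
#' @export
cluster_bootstrap <- function(table, estimator, B = 1000L, seed = 1L,
                              cluster = "cluster_id") {
  if (!is_count(B, 50L)) stopf("B must be an integer >= 50")
  rows_by_cluster <- split(seq_len(nrow(table)), table[[cluster]])
  k <- length(rows_by_cluster)
  if (k < 2L) stopf("need at least 2 clusters to bootstrap")
  reps <- vector("list", B)
  failures <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      pick <- sample.int(k, k, replace = TRUE)
      res <- table[unlist(rows_by_cluster[pick], use.names = FALSE), ,
                   drop = FALSE]
      res[[cluster]] <- rep(paste0(names(rows_by_cluster)[pick], ".",
                                   seq_along(pick)),
                            lengths(rows_by_cluster)[pick])
      reps[b] <- list(tryCatch(estimator(res), error = function(e) NULL))
      if (is.null(reps[[b]])) failures <- failures + 1L
    }
  })
  if (failures > B / 2)
    stopf("estimator failed on %d of %d bootstrap replicates", failures, B)
  if (failures > 0.05 * B)
    warning(sprintf("estimator failed on %d of %d bootstrap replicates",
                    failures, B), call. = FALSE)
  replicates <- do.call(rbind, reps[!vapply(reps, is.null, TRUE)])
  structure(list(
    B = B, replicates = replicates,
    se = apply(replicates, 2, stats::sd),
    failures = failures, seed = as.integer(seed), cluster = cluster
  ), class = "bootstrap_distribution")
}

#' @export
print.bootstrap_distribution <- function(x, ...) {
  cat(sprintf("Clustered bootstrap: B = %d (%d failed), resampling '%s'\n",
              x$B, x$failures, x$cluster))
  print(round(rbind(mean = colMeans(x$replicates), se = x$se), 4))
  invisible(x)
}

#' Combine multiple imputation with clustered-bootstrap variances
#'
#' For each completed dataset: the point estimate comes from the full data and
#' the within-imputation variance from a clustered bootstrap. Across
#' imputations, estimates are pooled with Rubin's rules (bootstrap variances
#' as within-imputation variances); 95\% CIs are normal-approximation
#' \code{point +/- 1.96 sqrt(T)}.
#'
#' @param stack an [mice_impute()] result.
#' @param estimator function(table) returning a named numeric vector.
#' @param B bootstrap replicates per imputation.
#' @param seed RNG seed (per-imputation bootstrap seeds are derived from it).
#' @param cluster cluster identifier column.
#' @return data.frame, one row per estimand: \code{estimate}, \code{se},
#'   \code{ci_low}, \code{ci_high}, and the Rubin components \code{W},
#'   \code{B_between}, \code{T_total}, \code{df}.
#' @export
mi_boot_combine <- function(stack, estimator, B = 1000L, seed = 1L,
                            cluster = "cluster_id") {
  stopifnot(inherits(stack, "imputed_stack"))
  points <- vars <- NULL
  for (i in seq_len(stack$m)) {
    d <- stack$datasets[[i]]
    pt <- tryCatch(estimator(d), error = function(e)
      stopf("estimator failed on imputation %d: %s", i, conditionMessage(e)))
    bd <- cluster_bootstrap(d, estimator, B = B, seed = seed + 1000L + i,
                            cluster = cluster)
    points <- rbind(points, pt)
    vars <- rbind(vars, bd$se[names(pt)]^2)
  }
  out <- lapply(colnames(points), function(nm) {
    p <- pool_rubin(points[, nm], vars[, nm])
    se <- sqrt(p$T)
    data.frame(estimand = nm, estimate = p$q_bar, se = se,
               ci_low = p$q_bar - 1.96 * se, ci_high = p$q_bar + 1.96 * se,
               W = p$W, B_between = p$B, T_total = p$T, df = p$df,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
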