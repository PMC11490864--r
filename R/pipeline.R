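#' Build a mediation estimator closure for one outcome
#'
#' Convenience wrapper used by the bootstrap and the pipeline: returns a
#' function(table) that fits the mediation model series and returns the named
#' estimand vector \code{(p1, p0, p_int, overall, reduction, remaining)}.
#'
#' @param spec a [mediation_spec()].
#' @param mode,standardize_to passed to [gcomp_estimate()].
#' @return function(table) -> named numeric vector.
#' @export
mediation_estimator <- function(spec, mode = "enumerate",
                                standardize_to = "all") {
  force(spec); force(mode); force(standardize_to)
  function(table) {
    est <- gcomp_estimate(fit_mediation_models(table, spec), mode = mode,
                          standardize_to = standardize_to)
    c(p1 = est$p1, p0 = est$p0, p_int = est$p_int,
      overall = est$overall, reduction = est$reduction,
      remaining = est$remaining)
  }
}

pipeline_defaults <- function() list(
  seed = 1L,
  generator = list(preset = "soar"),
  input = NULL,
  imputation = list(m = 20L, n_iterations = 10L),
  bootstrap = list(B = 1000L),
  mediation = list(outcomes = NULL, mode = "enumerate",
                   standardize_to = "all", interactions = "exposure")
)

load_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("config must be a list or a YAML file path")
  defaults <- pipeline_defaults()
  merged <- utils::modifyList(defaults, config)
  for (key in c("imputation", "bootstrap", "mediation"))
    if (!is.list(merged[[key]]))
      stopf("config key '%s' must be a mapping", key)
  if (is.null(merged$input) && is.null(merged$generator))
    stopf("config needs either 'input' (cohort file) or a 'generator' block")
  merged
}

generator_from_block <- function(block, seed) {
  preset <- block$preset %||% "soar"
  extra <- block[setdiff(names(block), "preset")]
  cfg <- switch(preset,
    soar = soar_config(seed = seed),
    lsac = lsac_config(seed = seed),
    stopf("unknown generator preset '%s' (use 'soar' or 'lsac')", preset))
  if (length(extra)) {
    x <- unclass(cfg)
    x[names(extra)] <- extra
    cfg <- do.call(cohort_config, x)
  }
  cfg
}

#' Run the full inequity-mediation pipeline
#'
#' Generate-or-load a cohort, describe it, multiply impute, fit the pooled
#' risk-ratio associations, estimate the interventional mediation effects per
#' outcome with MI + clustered-bootstrap inference, and (optionally) write the
#' three report tables, a provenance sidecar and a timestamped log. Every
#' random stage is seeded deterministically from the single master seed.
#'
#' @param config a YAML file path or a list with keys \code{seed},
#'   \code{generator} (\code{preset: soar|lsac} plus [cohort_config()]
#'   overrides) or \code{input} (cohort CSV path), \code{imputation}
#'   (\code{m}, \code{n_iterations}), \code{bootstrap} (\code{B}) and
#'   \code{mediation} (\code{outcomes}, \code{mode}, \code{standardize_to},
#'   \code{interactions}).
#' @param out_dir output directory; \code{NULL} writes nothing.
#' @param seed master seed override (defaults to the config's).
#' @param quiet suppress progress messages.
#' @return object of class \code{pipeline_report} with elements
#'   \code{cohort}, \code{description}, \code{stack}, \code{associations},
#'   \code{mediation} (the inequity table, one row per outcome and quantity)
#'   and \code{provenance}.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL, quiet = FALSE) {
  cfg <- load_pipeline_config(config)
  seed <- as.integer(seed %||% cfg$seed)
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }

  if (!is.null(cfg$input)) {
    say("loading cohort from %s", cfg$input)
    cohort <- read_cohort(cfg$input)
    gen_cfg <- NULL
  } else {
    gen_cfg <- generator_from_block(cfg$generator, seed)
    say("generating %s cohort: n=%d, %d clusters",
        cfg$generator$preset %||% "soar", gen_cfg$n_children,
        gen_cfg$n_clusters)
    cohort <- generate_cohort(gen_cfg, seed = seed)
    if (length(gen_cfg$missing_rates)) {
      cohort <- apply_missingness(cohort, gen_cfg, seed = seed + 1L)
      say("applied missingness: %.1f%% of records have >= 1 missing value",
          100 * mean(!stats::complete.cases(cohort)))
    }
  }

  say("describing cohort (N=%d)", nrow(cohort))
  description <- describe_cohort(cohort)

  m <- cfg$imputation$m
  say("imputing m=%d datasets (%d cycles)", m, cfg$imputation$n_iterations)
  stack <- mice_impute(cohort, m = m,
                       n_iterations = cfg$imputation$n_iterations,
                       seed = seed + 2L)

  outcomes <- cfg$mediation$outcomes %||%
    grep("^Y_", names(cohort), value = TRUE)
  baseline <- intersect(c("age", "sex", "cohort"), names(cohort))
  intermediate <- grep("^L_", names(cohort), value = TRUE)

  say("fitting pooled GEE risk-ratio associations")
  associations <- association_table(stack, outcomes = outcomes,
                                    baseline = baseline,
                                    intermediate = intermediate[1])

  B <- cfg$bootstrap$B
  med_rows <- list()
  for (y in outcomes) {
    say("mediation g-computation for %s (B=%d bootstrap replicates)", y, B)
    spec <- mediation_spec(outcome = y, baseline = baseline,
                           intermediate = intermediate,
                           interactions = cfg$mediation$interactions)
    estr <- mediation_estimator(spec, mode = cfg$mediation$mode,
                                standardize_to = cfg$mediation$standardize_to)
    res <- mi_boot_combine(stack, estr, B = B, seed = seed + 10L)
    res <- res[res$estimand %in% c("overall", "reduction", "remaining"), ]
    prop <- proportion_eliminated(
      res$estimate[res$estimand == "overall"],
      res$estimate[res$estimand == "reduction"])
    med_rows[[y]] <- rbind(
      data.frame(outcome = y, quantity = res$estimand,
                 estimate = res$estimate, ci_low = res$ci_low,
                 ci_high = res$ci_high, stringsAsFactors = FALSE),
      data.frame(outcome = y, quantity = "proportion_eliminated",
                 estimate = prop, ci_low = NA_real_, ci_high = NA_real_,
                 stringsAsFactors = FALSE))
  }
  mediation <- do.call(rbind, med_rows)
  rownames(mediation) <- NULL

  provenance <- list(
    seed = seed, m = m, n_iterations = cfg$imputation$n_iterations, B = B,
    outcomes = outcomes, mode = cfg$mediation$mode,
    standardize_to = cfg$mediation$standardize_to,
    n_children = nrow(cohort),
    n_clusters = length(unique(cohort$cluster_id)),
    config_digest = digest_config(cfg),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    write_description(description, file.path(out_dir, "table_descriptive.csv"))
    utils::write.csv(associations, file.path(out_dir, "table_associations.csv"),
                     row.names = FALSE)
    utils::write.csv(mediation, file.path(out_dir, "table_mediation.csv"),
                     row.names = FALSE)
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "log.txt"))
    say("report written to %s", out_dir)
  }

  structure(list(cohort = cohort, description = description, stack = stack,
                 associations = associations, mediation = mediation,
                 provenance = provenance, log = log_lines),
            class = "pipeline_report")
}

# stable digest of the resolved config (no external digest dependency)
digest_config <- function(cfg) {
  txt <- paste(utils::capture.output(utils::str(cfg, digits.d = 10)),
               collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_len(nchar(txt, "bytes")) %% 997)) %% .Machine$integer.max)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report: N=%d, %d clusters, m=%d imputations, B=%d\n\n",
              x$provenance$n_children, x$provenance$n_clusters,
              x$provenance$m, x$provenance$B))
  cat("Interventional mediation estimates (percentage points):\n")
  print(transform(x$mediation,
                  estimate = round(estimate, 1),
                  ci_low = round(ci_low, 1), ci_high = round(ci_high, 1)),
        row.names = FALSE)
  invisible(x)
}
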