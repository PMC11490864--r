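#' Dichotomize an SDQ total score with group-specific cutoffs
#'
#' The Strengths and Difficulties Questionnaire total (0-40) is not
#' conceptually equivalent across groups, so elevated mental-health symptoms
#' are coded with a lower cutoff in the exposed group: exposed children are
#' flagged at scores 16-40, unexposed children at 20-40.
#'
#' @param total_score integer SDQ total in [0, 40] (vectorized).
#' @param exposed binary/logical group indicator (vectorized).
#' @return integer 0/1 vector.
#' @examples
#' dichotomize_sdq(16, exposed = 1) # 1
#' dichotomize_sdq(16, exposed = 0) # 0
#' @export
dichotomize_sdq <- function(total_score, exposed) {
  if (any(total_score < 0 | total_score > 40, na.rm = TRUE))
    stopf("SDQ total score must lie in [0, 40]")
  cut <- ifelse(as.integer(exposed) == 1L, 16L, 20L)
  as.integer(total_score >= cut)
}

#' Prevalence as a percentage from yes/no counts
#'
#' @param n_yes,n_no non-negative counts.
#' @return percentage \code{100 n_yes / (n_yes + n_no)}, rounded half away
#'   from zero to one decimal place.
#' @examples
#' prevalence(198, 197) # 50.1
#' @export
prevalence <- function(n_yes, n_no) {
  if (n_yes + n_no < 1) stopf("prevalence undefined: no observations")
  round_half_up(100 * n_yes / (n_yes + n_no), 1)
}

#' Describe a cohort table, stratified by exposure
#'
#' Observed-data counts and percentages for every study variable, overall and
#' within the exposed and unexposed strata, with per-variable missing counts.
#' Percentages use observed (non-missing) denominators. Continuous age is
#' summarized as mean (SD).
#'
#' @param table a cohort table (possibly with missing values).
#' @return object of class \code{cohort_description}: a list with
#'   \code{$binary} (one row per variable/level), \code{$continuous} and
#'   \code{$n} (overall and per-stratum sizes).
#' @export
describe_cohort <- function(table) {
  if (nrow(table) == 0L) stopf("cannot describe an empty table")
  strata <- list(overall = rep(TRUE, nrow(table)),
                 unexposed = table$A == 0L, exposed = table$A == 1L)
  bin_vars <- c("A", "sex",
                if ("cohort" %in% names(table)) "cohort",
                grep("^L_", names(table), value = TRUE), "M",
                grep("^Y_", names(table), value = TRUE))
  bin_vars <- intersect(bin_vars, names(table))
  rows <- list()
  for (v in bin_vars) {
    x <- table[[v]]
    n_missing <- sum(is.na(x))
    for (lev in c(0L, 1L)) {
      cell <- function(s) {
        xs <- x[strata[[s]] & !is.na(x)]
        n <- sum(xs == lev)
        c(n = n, pct = if (length(xs)) round_half_up(100 * n / length(xs), 1)
                       else NA_real_)
      }
      o <- cell("overall"); u <- cell("unexposed"); e <- cell("exposed")
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = lev,
        n_overall = o[["n"]], pct_overall = o[["pct"]],
        n_unexposed = u[["n"]], pct_unexposed = u[["pct"]],
        n_exposed = e[["n"]], pct_exposed = e[["pct"]],
        n_missing = n_missing,
        pct_missing = round_half_up(100 * n_missing / nrow(table), 1),
        stringsAsFactors = FALSE)
    }
  }
  cont <- NULL
  if ("age" %in% names(table)) {
    x <- table$age
    cont <- do.call(rbind, lapply(names(strata), function(s) {
      xs <- x[strata[[s]] & !is.na(x)]
      data.frame(variable = "age", stratum = s,
                 mean = mean(xs), sd = stats::sd(xs),
                 n_missing = sum(is.na(x[strata[[s]]])),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(
    binary = do.call(rbind, rows), continuous = cont,
    n = c(overall = nrow(table),
          unexposed = sum(strata$unexposed), exposed = sum(strata$exposed))
  ), class = "cohort_description")
}

#' @export
print.cohort_description <- function(x, ...) {
  cat(sprintf("Cohort description: N = %d (%d exposed, %d unexposed)\n\n",
              x$n[["overall"]], x$n[["exposed"]], x$n[["unexposed"]]))
  b <- x$binary
  cat(sprintf("%-10s %-5s %14s %14s %14s %10s\n", "variable", "level",
              "overall", "unexposed", "exposed", "missing"))
  for (i in seq_len(nrow(b))) {
    cat(sprintf("%-10s %-5d %8d (%5.1f) %8d (%5.1f) %8d (%5.1f) %4d (%.1f)\n",
                b$variable[i], b$level[i],
                b$n_overall[i], b$pct_overall[i],
                b$n_unexposed[i], b$pct_unexposed[i],
                b$n_exposed[i], b$pct_exposed[i],
                b$n_missing[i], b$pct_missing[i]))
  }
  if (!is.null(x$continuous)) {
    cat("\n")
    for (i in seq_len(nrow(x$continuous)))
      cat(sprintf("age [%s]: mean %.2f (SD %.2f), %d missing\n",
                  x$continuous$stratum[i], x$continuous$mean[i],
                  x$continuous$sd[i], x$continuous$n_missing[i]))
  }
  invisible(x)
}

#' Write a cohort description as delimited text
#'
#' @param description a [describe_cohort()] result.
#' @param path output CSV path (binary-variable block; the continuous block is
#'   written alongside with suffix \code{_continuous.csv} if present).
#' @return \code{path}, invisibly.
#' @export
write_description <- function(description, path) {
  utils::write.csv(description$binary, path, row.names = FALSE)
  if (!is.null(description$continuous))
    utils::write.csv(description$continuous,
                     sub("\\.csv$", "_continuous.csv", path), row.names = FALSE)
  invisible(path)
}

#' Read or write a cohort table as delimited text
#'
#' Comma-separated with header; empty fields are missing values. Identifier
#' columns are read as character, all others as numeric.
#'
#' @param table a cohort data.frame.
#' @param path file path.
#' @return \code{read_cohort} returns the data.frame; \code{write_cohort}
#'   returns \code{path} invisibly.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  for (nm in intersect(c("child_id", "cluster_id"), names(x)))
    x[[nm]] <- as.character(x[[nm]])
  x
}
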