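# shared fixtures: all built in code, deterministic given their seeds

# small, fast SOAR-like configuration without missingness
tiny_config <- function(n = 400L, clusters = 8L, seed = 42L) {
  soar_config(n_children = n, n_clusters = clusters, seed = seed,
              missing = FALSE)
}

# exposure has no effect anywhere (null inequity); light MAR missingness
null_config <- function(n = 500L, clusters = 10L, seed = 1L) {
  cfg <- soar_config(n_children = n, n_clusters = clusters, seed = seed)
  cfg$coef_L[, 2] <- 0
  cfg$coef_M[2] <- 0
  for (nm in names(cfg$coef_Y)) cfg$coef_Y[[nm]][c(2, 8)] <- 0
  cfg$missing_rates <- list(M = list(rate = 0.05, on_exposure = 0.3),
                            Y_mh = list(rate = 0.05, on_exposure = 0.3))
  cfg
}

# configuration with K intermediate confounders (sensitivity-analysis shape)
multi_L_config <- function(K = 2L, n = 3000L, seed = 7L) {
  base <- soar_config(missing = FALSE)
  coef_L <- do.call(rbind, lapply(seq_len(K), function(k)
    c(-1.2 + 0.1 * k, 0.8, -0.02, 0.05, 0)))
  cohort_config(
    n_children = n, n_clusters = 15L, cluster_sd = 0.2,
    p_exposed = 0.145, age_mean = 12.35, age_sd = 1.48,
    coef_L = coef_L,
    coef_M = c(-1.05, 0.8, 0.03, -0.1, 0, rep(0.3, K)),
    coef_Y = list(Y_mh = c(-2, 0.85, 0.05, 0.15, 0, rep(0.25, K), 0.9, 0.2)),
    seed = seed)
}

# build an imputed_stack by hand (for composition/stub tests)
stub_stack <- function(datasets) {
  structure(list(m = length(datasets), datasets = datasets,
                 n_iterations = 0L, seed = 0L,
                 visit_order = character(), predictors = list()),
            class = "imputed_stack")
}

# toy clustered table with known risks: k clusters, each n_per records,
# P(Y=1) = risk1 for exposed rows, risk0 otherwise (deterministic fractions)
toy_2x2 <- function(n_exposed = 10L, n_unexposed = 10L,
                    events_exposed = 4L, events_unexposed = 2L,
                    singleton_clusters = TRUE) {
  y <- c(rep(1L, events_exposed), rep(0L, n_exposed - events_exposed),
         rep(1L, events_unexposed), rep(0L, n_unexposed - events_unexposed))
  a <- rep(c(1L, 0L), c(n_exposed, n_unexposed))
  n <- length(y)
  data.frame(child_id = sprintf("c%03d", seq_len(n)),
             cluster_id = if (singleton_clusters) sprintf("s%03d", seq_len(n))
                          else rep(c("s1", "s2"), length.out = n),
             A = a, Y = y, stringsAsFactors = FALSE)
}
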