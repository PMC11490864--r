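---
title: "Interventional-effects mediation analysis of health inequities: models and methods"
author: "ineqmed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interventional-effects mediation analysis of health inequities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ineqmed)
```

## The scientific problem

Children from a structurally marginalized group (the *exposed* group, indexed
by a binary indicator $A$) often show a higher prevalence of adverse binary
health outcomes $Y$ — here elevated mental-health symptoms and sleep
problems — than their peers. Part of that gap may run through a modifiable
binary mediator $M$ such as interpersonal racial discrimination. The policy
question this package answers is *interventional*: how much of the observed
inequity would disappear under a hypothetical intervention that eliminated
the mediator in the exposed group?

Two features make this harder than textbook mediation:

* an *exposure-induced intermediate confounder* $L$ (low socioeconomic
  position): it is affected by $A$ and confounds the $M$–$Y$ relation, which
  invalidates natural direct/indirect effect decompositions but not
  interventional effects;
* children are sampled in clusters (schools or postcodes), so all inference
  must respect within-cluster correlation.

## Estimands

Let $C$ denote baseline confounders (age, sex, optionally a study-cohort
indicator). Writing $p_a$ for the standardized outcome prevalence under
exposure level $a$ and $p_{\mathrm{int}}$ for the prevalence under exposure
with the mediator forced to zero,

$$
p_a = E_C \sum_{l} \sum_{m} P(Y{=}1 \mid a, C, l, m)\,
      P(M{=}m \mid a, C, l)\, P(L{=}l \mid a, C), \qquad
p_{\mathrm{int}} = E_C \sum_{l} P(Y{=}1 \mid 1, C, l, M{=}0)\,
      P(L{=}l \mid 1, C),
$$

the package reports (in percentage points)

* **overall inequity** $= 100(p_1 - p_0)$,
* **reduction** achievable by eliminating the mediator $= 100(p_1 - p_{\mathrm{int}})$,
* **remaining inequity** $= 100(p_{\mathrm{int}} - p_0)$,
* **proportion eliminated** $= 100 \cdot \mathrm{reduction} / \mathrm{overall}$.

The overall inequity is stored as `reduction + remaining`, so the
decomposition is additive to the last bit in every output. One consequence
of the estimand definitions worth keeping in mind: if exposure has no effect
anywhere, the overall inequity is exactly zero, but eliminating a mediator
that still affects the outcome makes the exposed *better* off than the
unexposed, so reduction and remaining cancel ($r = -s$) rather than vanish
individually. Only when the mediator–outcome pathway is also null do all
three components vanish.

## Extended g-computation

`fit_mediation_models()` fits a causally ordered series of logistic
regressions on complete data: each $L_k$ on exposure, baseline confounders
and the prior $L_1..L_{k-1}$ (in the user-declared order); $M$ on exposure,
baseline confounders and all $L$; $Y$ on all of those plus $M$. "Richly
specified" is operationalized by the default interaction policy: every model
crosses exposure with each of its other predictors, which in particular
includes the exposure-by-mediator interaction in the outcome model. The
policy is configurable (`interactions = "none"` for main effects), because
the exact interaction set such analyses use in practice varies; the fitted
designs are asserted structurally in the test suite.

`gcomp_estimate()` then standardizes. With binary $L$ and $M$ the inner sums
are computed **exactly** by enumerating all $2^K \times 2$ combinations
(default, refused for $K > 12$); a sequential Monte Carlo sampler
(`mode = "montecarlo"`) is kept for generality and as a cross-check — the
two agree within Monte Carlo error on every fitted model, which the tests
assert at 3 Monte Carlo standard errors.

Two genuinely open design choices and how they were settled:

* **Standardization population.** The estimands average $C$ over the
  empirical baseline-confounder distribution of the *full* analysis sample
  (exposed + unexposed), matching the idea of comparing outcome prevalences
  under exposure and no exposure for one common population. Standardizing to
  the exposed subsample only is exposed via `standardize_to = "exposed"`;
  with it, "overall" becomes the inequity experienced by the exposed group
  itself. The two differ only through confounder-distribution differences
  between groups and were numerically close in all our simulations.
* **Model family.** All component models are logistic. The log-Poisson
  choice in the preliminary analyses exists to report risk ratios; for
  g-computation only fitted probabilities are needed, and logistic models
  keep them in $[0,1]$ by construction.

## Preliminary association models

`fit_rr_gee()` implements the modified-Poisson risk-ratio approach for
clustered data: a log-link Poisson-family GEE with an exchangeable working
correlation (moment estimator on Pearson residuals) and a robust sandwich
covariance, reported regardless of the working structure. The solver applies
the exchangeable inverse in closed form per cluster, so large clusters cost
only $O(n_i p)$. Binary outcomes in a Poisson-variance model can yield
fitted means above 1; they are accepted without truncation, as is standard
for this estimator. If the exchangeable fit fails, the model is refitted
with an independence working correlation and a downgrade notice is emitted.
Unadjusted and adjusted models alike use the GEE (the clustering is a
property of the design, not of the adjustment set); adjusted
mediator–outcome models additionally control for exposure status and the
intermediate confounder.

## Missing data

`mice_impute()` is a chained-equations imputer written for this pipeline:
univariate linear (continuous) and logistic (binary) models, each including
every other study variable, **all two-way interactions** among the study
variables not involving the target, and cluster membership as fixed-effect
dummies. Choices the method description leaves open, settled as follows:

* *Cycles*: 10 by default — a conventional burn-in at this scale (the m
  completed datasets are what matters, not long chains).
* *Visit order*: ascending missingness fraction.
* *Draw mechanism*: proper imputation — coefficients are drawn from the
  normal approximation to their sampling distribution (and the residual SD
  from its scaled inverse-chi-square) before each redraw, so Rubin's rules
  see genuine between-imputation variability.
* *Degenerate clusters*: if some cluster has no observed values of a target
  variable, the cluster dummies are dropped from that variable's model with
  a warning (predictions for unseen levels would otherwise be undefined).

Rubin's rules (`pool_rubin()`) use $\bar q = m^{-1}\sum q_i$,
$T = W + (1 + 1/m)B$ and $\nu = (m-1)\,(1 + W/((1+1/m)B))^2$, with
$\nu = \infty$ when $B = 0$.

## Bootstrap inference and its combination with imputation

`cluster_bootstrap()` resamples whole clusters with replacement, holding the
cluster count fixed (the standard cluster bootstrap; record counts vary
across replicates). Duplicated clusters get distinct identifiers so the GEE
and any cluster-aware stage treat them as independent.

The method description specifies imputation and a clustered bootstrap but
not their nesting. `mi_boot_combine()` nests **bootstrap within
imputation**: per completed dataset, the point estimate comes from the full
data and the variance from $B$ cluster-bootstrap replicates; Rubin's rules
then pool across imputations. The alternative (re-imputing inside every
bootstrap draw) is statistically attractive but multiplies cost by $B$ and
is out of scope. Consequences of the chosen nesting:

* CIs are normal-approximation $\hat\theta \pm 1.96\sqrt{T}$ (percentile
  intervals would require the re-imputation nesting);
* no CI is attached to the proportion eliminated — it is a ratio of two
  pooled point estimates and is reported as a point estimate only;
* $B$ defaults to 1000 and is reduced in tests and demonstrations.

Under a null inequity this machinery attains close to nominal coverage: in
the packaged specificity suite (100 replicate runs at reduced scale,
$n = 500$, $m = 2$, $B = 50$) the 95% CI for the overall inequity covered
zero in 94% of runs.

## The synthetic-cohort generator

Real data of this kind are restricted, so every stage is exercised against
`generate_cohort()`, which draws clustered cohorts with the causal ordering
above: exposure and baseline confounders first, then $L$, $M$ and the
outcomes from logistic models, all sharing one normal cluster-level
disturbance on the logit scale — the simplest mechanism that produces the
within-cluster correlation the GEE and the cluster bootstrap are meant to
absorb. `true_effects()` computes the generator-truth estimands by brute
force (exact sums over $(L, M)$, fixed-seed Monte Carlo over age, sex,
cohort and the cluster disturbance), giving an oracle for parameter-recovery
testing: over 200 synthetic cohorts of $n = 5000$, the mean estimated
overall/reduction/remaining each sit within 3 empirical standard errors of
the truth.

Calibration of the two presets (`soar_config()`, `lsac_config()`) was done
analytically on the logit scale so that observed strata approximate the
emulated studies' descriptive tables — e.g. in the SOAR-like preset,
mediator prevalence ≈50% among exposed vs ≈28% among unexposed, elevated
mental-health symptoms ≈41% vs ≈17%, low socioeconomic position ≈47% vs
≈23%. Two caveats are deliberate:

* The cluster disturbance SD defaults to 0.2 (ICC ≈ 0.01 for binary
  outcomes) — a plausible school/postcode value, but a guess: neither
  emulated study reports its within-cluster correlation.
* Missingness rates are configured per variable (the directly reported
  marginal quantities) and applied conditionally independently given
  exposure and sex; real missingness co-occurs within children, so the
  any-missing fraction implied by the SOAR-like preset (~16%) exceeds the
  12% joint rate such studies report. The missingness is MAR given
  always-observed variables by construction, which is what makes the
  imputation-recovery tests fair.

What passing tests therefore show: the estimator chain is consistent and
correctly implemented *under its own assumptions* (logistic structural
models, MAR missingness, exchangeable-ish cluster correlation). What they
cannot show: robustness to model misspecification, to informative
missingness, or to measurement error in the mediator — all real concerns in
applications.

## Numerical conventions and degenerate inputs

* Percentages are rounded half away from zero, only at reporting
  (`round_half_up()`); internal arithmetic is full precision.
* `overall` is computed as `reduction + remaining`, making additivity exact.
* The proportion eliminated is undefined at `overall == 0`
  (`proportion_eliminated()` errors; `decompose_inequity()` stores `NA`).
* Enumeration mode has no randomness; every Monte Carlo path takes an
  explicit seed, and the pipeline derives all stage seeds from one master
  seed, so identical config + seed reproduces reports byte for byte.
* Imputation refuses binary targets observed at a single level (perfect
  separation); mediation fits refuse incomplete data and non-converged
  models by name.

## Problem sizes used in the packaged checks

The test and demonstration scales are package choices balancing Monte Carlo
precision against convenience: 200 recovery cohorts of $n = 5000$; 100
specificity runs at $n = 500$, $m = 2$, $B = 50$; imputation-recovery at
$n = 4000$ with 20% masking and $m = 10$; the acceptance demonstration runs
the full SOAR-size pipeline ($n = 2818$, 23 clusters) at $m = 5$, $B = 100$.
The pipeline defaults themselves ($m = 20$, $B = 1000$) match a full
analysis.
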