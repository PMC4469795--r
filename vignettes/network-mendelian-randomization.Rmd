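---
title: "Estimating direct and indirect causal effects with two genetic instruments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating direct and indirect causal effects with two genetic instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netmr)
```

## The problem

Mendelian randomization uses genetic variants as instrumental variables
(IVs) to estimate causal effects of exposures on outcomes from
observational data, exploiting the fact that genotypes are fixed at
conception and therefore unaffected by confounding or reverse causation.
`netmr` extends this to a small causal *network*: an exposure $X$ whose
effect on an outcome $Y$ may be partially transmitted through a mediator
$Z$. With an instrument $G_X$ for the exposure and a separate instrument
$G_Z$ for the mediator, the total effect of $X$ on $Y$ can be decomposed
into a direct effect (not through $Z$) and an indirect effect (through
$Z$), even when the $X$–$Z$, $X$–$Y$ and $Z$–$Y$ relationships are all
confounded by unmeasured variables.

## Assumptions

All estimators in the package rely on:

* **IV validity** for both instruments: each is associated with the
  variable it instruments, independent of the unmeasured confounders,
  and affects downstream variables only through that variable.
* **Linearity without interaction**: the effects of $X$ on $Z$ and of
  $(X, Z)$ on $Y$ are linear, with no $X \times Z$ interaction in the
  outcome model. Under no interaction, controlled and natural direct
  effects coincide, so the package does not distinguish them.
* **Homogeneity**: the per-individual causal effects are constant across
  the population. This is the assumption that makes the product
  $\beta_{X \to Z}\,\beta_{Z \to Y}$ a valid indirect effect; when
  effects vary between individuals with opposite signs in subgroups, the
  product decomposition can mislead. The package's simulation study
  machinery exists precisely to probe how much *random* heterogeneity
  these estimators tolerate (empirically: a great deal — random
  zero-centred heterogeneity in the effects leaves the estimators
  unbiased in the scenarios the study runner covers, which the test
  suite verifies at Monte Carlo precision).

Exposure, mediator and outcome are treated as continuous; binary
variables raise non-collapsibility issues that are out of scope.

## Estimators

### Ratio and two-stage least squares

For a single path, the ratio (Wald) estimate is
$\hat\beta_{X \to Y} = \hat\beta_{Y|G_X} / \hat\beta_{X|G_X}$, the
reduced-form slope over the first-stage slope. Its default standard
error is the first-order delta approximation
$\mathrm{se}(\hat\beta_{Y|G_X})/|\hat\beta_{X|G_X}|$, which ignores
first-stage uncertainty; this is the standard convention with strong
instruments, and the composite estimators below do not depend on it
because they bootstrap the whole pipeline. A second-order form that
propagates first-stage uncertainty (treating the two slopes as
independent) is available via `se_type = "delta"`.
`two_stage_least_squares()` generalizes to several instruments and
covariates, with residuals computed from observed (not fitted)
exposures, and warns when a first-stage partial $F$ falls below 10.
Estimation is refused outright when the first-stage $t$ statistic is
numerically zero (below $10^{-6}$).

### Ratio-difference decomposition

`mediation_ratio_difference()` estimates total $= \hat\beta_{Y|G_X} /
\hat\beta_{X|G_X}$, the constituent effects $X \to Z$ (with $G_X$) and
$Z \to Y$ (with $G_Z$), and sets indirect $=$ product, direct $=$ total
$-$ indirect. The identity total $=$ direct $+$ indirect is exact by
construction, and the unit tests assert it to $10^{-12}$.

Standard errors come from a nonparametric bootstrap. Design choices:

* the resampling unit is the **individual** (i.i.d. rows);
* **1000 resamples** by default — the usual reporting convention; a
  warning fires below 100;
* any covariate residualization is **redone inside every resample**, the
  conservative choice that propagates adjustment uncertainty;
* resamples on which the pipeline fails (e.g. a weak-instrument guard)
  are dropped and counted — a warning above 1% failures, an error above
  10% — rather than retried, which keeps results reproducible under a
  fixed seed;
* confidence intervals are normal-theory by default (`ci_type =
  "percentile"` switches), since the bootstrap is primarily an SE
  device here.

### Multiple-stage least squares

`multi_stage_least_squares()` chains fitted-value regressions:
$\hat X$ from $X \sim G_X$; $\hat Z$ from $Z \sim G_Z + \hat X$; then
$Y \sim \hat X + \hat Z$. The coefficient on $\hat X$ in the last stage
is the direct effect and the stage-2 coefficient of $\hat X$ times the
stage-3 coefficient of $\hat Z$ is the indirect effect. Naive stage-3
standard errors would ignore that the regressors are estimated, so only
bootstrap SEs are offered. If the fitted exposure and fitted mediator
are numerically collinear ($|r| > 0.999$ or a dropped coefficient), the
instruments cannot separate the two paths and estimation stops.

### Linear path model (SEM)

`fit_sem()` estimates the five-variable system over the order
$(G_X, G_Z, X, Z, Y)$ with free paths $G_X \to X$, $G_Z \to Z$,
$X \to Z$, $X \to Y$, $Z \to Y$, and a freely correlated $3 \times 3$
error covariance for $(X, Z, Y)$ that absorbs unmeasured confounding.
The excluded instrument–outcome paths are the identifying restrictions.
The model-implied covariance is
$\Sigma(\theta) = (I - B)^{-1} \Psi (I - B)^{-\top}$ with $B$ strictly
lower triangular, and the fit maximizes the multivariate normal
likelihood. Choices worth knowing:

* The mean structure is saturated, so the likelihood reduces to the
  sample covariance (ML divisor $n$); on complete data this coincides
  with full-information ML, and the dataset is complete by validation.
* **Profile likelihood**: for fixed paths, the optimal $\Psi$ blocks are
  the corresponding blocks of $(I-B) S (I-B)^\top$ in closed form, so
  the optimizer works on just the five path coefficients (BFGS, relative
  tolerance $10^{-12}$, at most 500 iterations, start values from
  sequential least squares). The convergence flag additionally requires
  the numeric gradient norm of the concentrated discrepancy to fall
  below $10^{-4}$; the achieved norm is reported in the fit.
* The parameter covariance is the inverse **observed information** of
  the covariance-structure likelihood, differentiated numerically in the
  natural parameterization (paths plus covariance entries), so the
  delta-method blocks for the effects read directly off it. Error
  variances approaching zero trigger a Heywood-case warning.
* The instrument covariance is a **free parameter** by default (robust
  to stratification-induced instrument correlation);
  `instrument_covariance = "zero"` fixes it. Setting
  `correlated_errors = FALSE` collapses the fit to sequential least
  squares — only appropriate for unconfounded data, and used in the test
  suite as an algebraic cross-check against `lm()`.
* Genotypes are discrete, violating multivariate normality; the point
  estimates remain consistent as pseudo-ML and this is accepted. The
  likelihood-ratio statistic against the saturated covariance (1 df for
  the default model) is reported for goodness-of-fit orientation; model
  selection across topologies is out of scope.

`sem_effects()` returns direct $= \hat d$ (the $X \to Y$ path), indirect
$= \hat c \hat e$ with delta-method variance $\hat e^2 \mathrm{var}(\hat
c) + \hat c^2 \mathrm{var}(\hat e) + 2 \hat c \hat e\,\mathrm{cov}(\hat
c, \hat e)$, and total $= \hat d + \hat c \hat e$. At $\hat c = \hat e =
0$ the delta method degenerates (zero SE at an interior point) and a
warning is raised.

### Direction of effect

`reciprocal_mr()` runs the two ratio analyses $X \to Z$ (with $G_X$) and
$Z \to X$ (with $G_Z$) and classifies the $2 \times 2$ significance
pattern. Significance is judged on the reduced-form coefficient (the
ratio's numerator) by default: for a strong instrument this test is
equivalent to the Wald test on the ratio, and it avoids any dependence
on the ratio-SE convention; `test = "ratio"` is provided for comparison
and the study runner reports both. The verdict is descriptive — a
"bidirectional" pattern may reflect effects in different directions at
different ages, which long-term genetic instruments cannot separate —
and the result object carries that caveat.

## The simulator

`simulate_dataset()` draws from a confounded linear system designed to
mimic a realistic two-instrument mediation setting:

\[
\begin{aligned}
x_i &= \alpha_{G,i}\, g_{X,i} + u^{XZ}_i + u^{XY}_i + \varepsilon_{X,i} \\
z_i &= \beta_{G,i}\, g_{Z,i} + \beta_{X,i}\, x_i + u^{XZ}_i + u^{ZY}_i +
  \varepsilon_{Z,i} \\
y_i &= \gamma_{X,i}\, x_i + \gamma_{Z,i}\, z_i + \delta_i\, x_i z_i +
  u^{XY}_i + u^{ZY}_i + \varepsilon_{Y,i}
\end{aligned}
\]

with $g_X, g_Z \sim \mathrm{Binomial}(2, 0.3)$ (biallelic variants in
Hardy–Weinberg proportions), three shared confounders $u^{XZ}, u^{XY},
u^{ZY} \sim N(0,1)$ — one per pair of phenotypes, so that every pairwise
relationship is confounded — and standard normal residuals. The
per-individual causal effects $(\beta_{X,i}, \gamma_{X,i},
\gamma_{Z,i})$ are multivariate normal with means $(\mu_{\beta X},
\mu_{\gamma X}, \mu_{\gamma Z})$, common variance $\tau^2$ and common
pairwise correlation `effect_corr`; $\tau = 0$ is homogeneity. Optional
extensions: per-individual genetic effects ($\alpha_{G,i}, \beta_{G,i}$
normal around their means with SD `genetic_effect_sd`) and an
individual-level interaction coefficient $\delta_i \sim
N(\texttt{interaction\_mean}, \texttt{interaction\_sd}^2)$; sensible
reconstruction values for interaction experiments are $(0, 0.2)$ for
interaction-at-the-individual-level-only and $(0.2, 0.2)$ for a
systematic interaction.

Defaults: $n = 5000$, $\alpha_G = 0.3$, and $\beta_G = 0.5$ when
$\mu_{\beta X} \ge 0$, $0.36$ when negative. With unit confounder and
error scales these give an instrument-explained variance
($R^2$) of about 1.3% for both the exposure and the mediator — the
$\beta_G$ switch exists exactly to hold the mediator's $R^2$ fixed when
the $X \to Z$ effect flips sign, since $X$'s contribution to
$\mathrm{var}(Z)$ changes with that sign — and a mean first-stage $F$
near 65 at $n = 5000$, comfortably clear of weak-instrument territory.
The closed forms and simulation checks behind these constants are in
`scripts/calibrate_generator.R`. `scenario_grid()` returns the twelve
reference scenarios: $\mu_{\beta X}, \mu_{\gamma Z} \in \{1, -1\}$
crossed with $\tau^2 \in \{0, 0.2^2, 0.4^2\}$, $\mu_{\gamma X} = 1$
throughout, so the true direct effect is 1 and the true average indirect
effect is $\mu_{\beta X}\mu_{\gamma Z}$.

What the generator does **not** emulate: linkage disequilibrium between
the two instruments, population stratification, selection, assortative
mating, non-normal phenotype errors, binary traits, and measurement
error in $X$ or $Z$. Passing simulation-based tests therefore shows
correctness of the estimators under the stated model, not robustness to
those real-data features.

A diagnostic do-operator (`x_intervention`) adds a constant to every
individual's exposure after its structural equation is evaluated; the
contrast of mean outcomes under a common seed measures the average
interventional total effect $\mu_{\gamma X} + \mu_{\beta X}\mu_{\gamma
Z}$ directly, which the test suite uses to pin the generator's causal
semantics. Setting `confounder_sd = 0` switches all confounding off, the
basis of several oracle comparisons (ordinary least squares is then
consistent and serves as an independent reference).

## The study runner

`run_scenario()` simulates replicate datasets (replicate $r$ seeded
`base_seed + r`, so any replicate can be regenerated in isolation), runs
the ratio-difference estimator, the path model and the direction tests
on each, and reports per estimator and estimand the mean estimate, mean
standard error, SD of estimates and the Monte Carlo SE of the mean
(SD$/\sqrt{\text{replicates}}$). Failed replicates are dropped with
their seeds recorded; more than 1% failing is an error.
`run_table1()` maps this over the twelve scenarios with disjoint seed
streams and writes a long-format table at full precision (the printed
rendering rounds to 2 decimals).

Problem sizes: the packaged tests exercise the homogeneous reference
scenario at 250 replicates of $n = 5000$ with 200 bootstrap resamples,
and the direction calibration at 500 replicates — sizes chosen so the
whole suite runs in a few minutes while keeping Monte Carlo bands (3
$\times$ SD$/\sqrt{\text{reps}}$, about $\pm 0.04$) tight enough to
detect any real bias. At these settings the mean estimates reproduce the
reference values, the mean bootstrap/analytic SEs track the empirical
SDs within 15%, the path-model SEs are uniformly the smaller, and the
projected Monte Carlo SE at 1000 replicates is about 0.005–0.006. The
full-scale study (1000 replicates, 1000 resamples) is available through
`run_table1()` or the CLI's `study` subcommand.

## Degenerate inputs and numerical conventions

* Instruments with zero sample variance are rejected at dataset
  validation; rows with any missing primary value are dropped with a
  logged count (listwise deletion).
* Allele-score calibration refuses scores whose calibration slope has
  $|t| < 1$ (such a score is not a usable instrument). The calibration
  regression adjusts for covariates when they are supplied, matching the
  convention of adjusting every regression for the same covariate set;
  pass `covariates = NULL` for an unadjusted calibration.
* Residualization is idempotent and errors on rank-deficient covariate
  designs, naming the collinear columns.
* All simple regressions run on closed-form centered sums (verified
  against `lm()` in the tests); multi-column fits use QR.
* Dataset writing uses 17 significant digits so files round-trip doubles
  bit-for-bit.

## Limitations

Individual-level data only (no two-sample summary-statistic mode); no
binary traits; no weak-instrument bias corrections beyond guards and
warnings; no goodness-of-fit-driven model selection among path
topologies; bootstrap and Monte Carlo runs are single-threaded. The
homogeneity and no-interaction assumptions are untestable from the data
alone and should be argued from subject-matter knowledge; the simulation
machinery quantifies sensitivity only to the departures it models.
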