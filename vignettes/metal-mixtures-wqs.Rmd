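---
title: "Two-index WQS regression for prenatal metal mixtures: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-index WQS regression for prenatal metal mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wqsmix)
```

## The scientific problem

Pregnant women are exposed to a mixture of urinary-measurable trace metals.
Eight of them (Mg, Cr, Mn, Mo, Co, Cu, Zn, Se) are essential to
neurobiological processes but can harm at deficient or excessive levels; six
(As, Cd, Sb, Hg, Pb, Ni) are toxicants with no beneficial role. Treating all
fourteen as a single mixture conflates these biologies. `wqsmix` implements a
two-index Weighted Quantile Sum (WQS) analysis that estimates the joint
effect of the essential-metal mixture and the toxic-metal mixture on child
neurodevelopmental scores in one regression, together with the screening
steps that precede it and a calibrated synthetic cohort generator that makes
the whole chain testable without access to cohort data.

## The model

Exposures are creatinine-adjusted urinary concentrations (µg/g creatinine),
each recoded to its decile rank $q_{ij} \in \{0, \dots, 9\}$ on the full
analytic sample. For an index $g$ (essential or toxic) with simplex weights
$w^{(g)}$ ($w_i \ge 0$, $\sum_i w_i = 1$), the index value of subject $j$ is

$$ S_{gj} = \sum_{i \in g} w^{(g)}_i q_{ij}. $$

The validation regression is ordinary least squares of the outcome on both
indices jointly,

$$ y_j = \beta_0 + \beta_E S_{Ej} + \beta_{E2} S_{Ej}^2 \,[\text{if flagged}]
   + \beta_T S_{Tj} + \beta_{T2} S_{Tj}^2 \,[\text{if flagged}]
   + \phi^\top x_j + \varepsilon_j, $$

with covariates $x_j$: maternal age, BMI, social class, smoking,
Mediterranean-diet score, child sex and feeding type. Quadratic index terms
are switched on per outcome by the non-linearity screen (below).

### Weight training

Each index's weights are trained separately, in a model containing only that
index plus covariates, on the training portion of a random 60/40 split. For
each of `n_boot` bootstrap resamples the package minimizes

$$ \tfrac{1}{2} \mathrm{RSS}(\beta_0, \beta_1, w, \phi) + \lambda \sum_i w_i^2,
   \qquad \lambda = 100 \text{ by default}, $$

over simplex weights (softmax parameterization) with the index coefficient
$\beta_1$ sign-constrained to the index's direction. $\tfrac12\mathrm{RSS}$
is the Gaussian negative log-likelihood at unit dispersion; with this scale
the default $\lambda$ gives a mild ridge pull toward uniform weights, while
$\lambda \to \infty$ forces exactly uniform weights and $\lambda = 0$
recovers the unpenalized estimator (both limits are tested). The penalty is
a ridge on the weights because an $L_1$ penalty is constant on the simplex
and therefore vacuous there.

Numerically, $\beta_0$, $\phi$ and $\beta_1$ are profiled out: after
projecting the outcome and decile columns off $[1, X]$, the profile RSS is
$y^\top y - (b^\top w)^2 / (w^\top A w)$ — two quadratic forms of dimension
at most 8 — so each objective evaluation is $O(m^2)$ regardless of sample
size, and a sign-violating profile slope is pinned to the boundary
$\beta_1 = 0$. The search is quasi-Newton (BFGS) with an analytic gradient
and three starts: uniform, proportional to squared marginal
direction-consistent $t$ statistics, and random. Non-convergence is recorded
per bootstrap; training aborts loudly if fewer than 10% of bootstraps
converge.

Converged bootstrap weight vectors are averaged with mixing proportions
equal to their squared index-coefficient $t$ statistics (an uninformative
bootstrap at the $\beta_1 = 0$ boundary contributes nothing); uniform
averaging is available via `signal = "uniform"`, and an all-boundary
training step falls back to uniform averaging with a classed warning.

### Repeated holdout and inference

The split/train/validate cycle is repeated `n_holdout` times (default 100)
with fresh random splits. The reported estimate of every term is the mean
over holdout validation estimates and its 95% interval the 2.5/97.5
percentiles of that distribution (a Wald-style alternative, mean estimate
± 1.96 × mean SE, is kept as an option; which of the two a published table
shows is generally not recoverable, so the percentile form is the default).
A term is significant when the interval excludes zero. Final index weights
are the across-holdout means, renormalized. Failed holdouts are skipped and
counted; more than 20% failures aborts.

### Direction selection

Both signs of each index's association are explored: a reduced-replication
pre-pass (defaults: 20 bootstraps × 10 holdouts) runs the full procedure for
every direction combination and keeps the lowest mean validation AIC.
Selection happens once, before the full run, rather than per holdout —
per-holdout switching would mix estimands. Ties within $10^{-6}$ resolve to
the negative direction, deterministically. The pre-pass defaults were fixed
after checking selection stability on strong-signal simulations (one
marginal flip in 30 cohorts at 10 holdouts, none at 20; the cheaper setting
was kept because the flip reflected a genuinely ~0.3-AIC data-level margin).

## The non-linearity screen

Before WQS, each metal × outcome pair is screened with a penalized-spline
additive model: outcome on a cubic regression spline of the decile rank
(basis dimension 10) plus linear covariates, smoothing parameter by REML —
more stable than GCV near $n = 200$. A pair is flagged when the smooth's
effective degrees of freedom reach `edf_threshold` (default 1.5) **and** its
approximate test against the zero function has $p < 0.05$. The edf cutoff of
1.5 operationalizes "suggests curvature": reported non-linear smooths in
this literature sit around edf 1.7–1.9, while a purely linear signal drives
edf to ~1–1.3. Flagged pairs are re-fit with a restricted cubic spline
(truncated-power basis, 4 knots at the 5/35/65/95% exposure quantiles;
3- and 5-knot variants available) whose $k-2$ non-linear coefficients admit
a joint F test of non-linearity; the RCS fit is exported as a 100-point
curve with pointwise bands and is linear beyond its boundary knots by
construction (verified to $10^{-8}$ in the tests). An outcome receives a
quadratic essential-index term in the WQS stage when at least one essential
metal is flagged for it; screening uses decile ranks, consistent with
quantization preceding all modeling (raw-scale screening is a switch).

Two ambiguities are worth surfacing: the screen tests the smooth against the
zero function (not against linearity) and couples that with the edf
threshold — an explicit test against linearity is what the RCS confirmation
step provides; and no multiple-testing correction is applied across the 154
pairs by default (a Benjamini–Hochberg option exists), matching a fixed
α = 0.05 convention.

## The synthetic cohort generator

The generator emulates the structure the analysis assumes, with defaults
calibrated to the published cohort summaries:

* **Exposures.** A Gaussian copula on the log scale with log-normal
  marginals per metal: median equal to the published geometric mean and
  log-SD solved so the theoretical IQR matches the published IQR (the
  solution is `asinh(IQR/(2·GM))/qnorm(0.75)` exactly). The default Spearman
  target is exchangeable — 0.15 within the essential and toxic groups, 0.05
  between — reflecting the weak, mostly modest cross-metal correlations such
  panels show; any valid rank-correlation matrix can be supplied, and the
  target is mapped to the latent Gaussian scale by $2\sin(\pi\rho/6)$.
* **LOD censoring.** Concentrations are converted back to µg/L with a
  simulated creatinine (log-normal, median 1.0 g/L, log-SD 0.4 — a typical
  spot-urine range; the source cohort reports no creatinine distribution),
  compared against each assay's limit of detection, and below-LOD values
  substituted by LOD/√2 (default), LOD/2 or 0. Published percentiles showing
  a 0.00 lower quartile for Mn motivate the zero rule; no substitution rule
  is claimed to be the source cohort's own.
* **Covariates.** Independent draws matching the published marginals (age
  truncated-normal 31.58 ± 4.72 on [18, 45], BMI 24.68 ± 4.27 truncated
  positive, social class/smoking/sex/feeding Bernoulli at the published
  frequencies, diet score normal 9.65 ± 2.44).
* **Outcomes.** Generated from the analysis model itself — linear/quadratic
  in the two decile-based indices plus linear covariate terms and Gaussian
  noise — so that parameter recovery is well-posed. WPPSI-type outcomes use
  the truth as given (intercept 100, residual SD 15 by default); NEPSY-type
  outcomes are produced on the mean-10/SD-3 convention with coefficients
  scaled by 3/15 so standardized effects carry over. Covariate effects
  default to zero because no covariate effect sizes are published.

What passing tests on these cohorts do **not** show: robustness to
exposure-measurement error, to informative missingness, to covariate-exposure
confounding structure, or to a true data-generating process outside the
index-model family. The generator is a test bed for the machinery, not a
replica of the cohort.

## Problem sizes and benchmark choices

The simulation-based checks in the test suite use the following sizes,
chosen to make each property measurable while keeping a full run modest:
calibration at 50,000–100,000 draws (Monte-Carlo error well under the 2–3%
tolerances), 200 null cohorts of n = 201 at 20 bootstraps × 20 holdouts for
the size of the toxic-index test, 20 cohorts of n = 500 for signal recovery
and direction selection, and 100 seeds for the screen's power and size.

The recovery and direction benchmarks use a truth with toxic weights
Cd 0.5 / Sb 0.3 / others 0.05, $\beta_T = -1$, and residual SD **5**, under
which the two indices explain roughly 13% of outcome variance — a strong but
epidemiologically plausible mixture signal. The choice of 5 rather than the
WPPSI instrument SD of 15 is deliberate: at n = 500 with SD 15 the per-metal
slope standard error (~0.25) equals the Sb-vs-background weight gap, so the
weight *ordering* is not identifiable by any estimator and a recovery
benchmark would measure noise. The index *coefficient* is recovered without
bias at either noise level.

## Numerical and design notes

* Decile thresholds are type-7 empirical quantiles; a value's rank is the
  number of thresholds strictly below it, so threshold ties share the lower
  bin and the top bin is closed. Coding is invariant under strictly
  increasing transforms, idempotent on rank-coded data, and computed once on
  the full sample — training/validation subsets reuse it, never recompute.
* Constant exposure columns cannot be quantized and raise a classed error;
  heavily tied columns (an LOD-substitution signature) yield unbalanced bins
  and a warning carrying the occupancy vector.
* A Spearman correlation involving a constant column is reported as `NA`,
  never silently zeroed.
* Splits are simple random without stratification; all randomness (splits,
  bootstraps, restarts) derives from one master seed, and every stage is
  reproducible bit-for-bit under it.
* Quadratic terms enter the validation regression only; the training
  objective stays linear in the index, because a sign constraint on
  $\beta_1$ alone does not identify a direction for a quadratic response.
* Gaussian outcomes only — all eleven scores are continuous composites.

## A worked example

```{r example, eval = FALSE}
library(wqsmix)

truth <- effect_truth(
  weights_toxic = c(As = 0.05, Cd = 0.5, Sb = 0.3,
                    Hg = 0.05, Pb = 0.05, Ni = 0.05),
  beta1_tox = -1, resid_sd = 5)
coh <- generate_cohort(n = 500, truth = truth, seed = 1)

cfg <- wqs_config(n_boot = 20, n_holdout = 20,
                  direction_ess = "negative", direction_tox = "negative")
fit <- repeated_holdout(coh$data, "VCI", config = cfg, seed = 1)
tidy(fit)              # per-term estimates with 95% holdout intervals
tidy(fit, "weights")   # per-metal mixture weights
autoplot(fit)          # weight bar chart with holdout IQRs
```

## Known limitations

* The ridge-on-weights reading of the penalty, and its unit-dispersion
  likelihood scale, are reconstructions; other implementations may penalize
  differently, and coefficient shrinkage behavior will differ accordingly.
* AIC direction selection on weak signals is near coin-flip by construction
  (the two directions differ only through the trained weights).
* With fewer distinct exposure values than the spline basis dimension the
  screen reduces the basis with a warning rather than failing.
* Percentile intervals over a small number of holdouts are coarse; with
  fewer than ~40 holdouts they are effectively min/max bands.
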