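#' Default cross-metal rank-correlation target
#'
#' Urinary metal panels in pregnancy cohorts typically show weak, mostly
#' positive rank correlations, somewhat stronger within the essential and
#' toxic groups than across them. The default target is exchangeable: 0.15
#' between metals of the same group, 0.05 between groups, 1 on the diagonal.
#'
#' @param specs Metal specification tibble, see [default_metal_specs()].
#' @param within Spearman correlation between metals sharing a group.
#' @param between Spearman correlation between metals of different groups.
#' @return A symmetric matrix with metal dimnames and unit diagonal.
#' @export
default_rank_corr <- function(specs = default_metal_specs(),
                              within = 0.15, between = 0.05) {
  check_metal_specs(specs)
  same <- outer(specs$group, specs$group, "==")
  r <- ifelse(same, within, between)
  diag(r) <- 1
  dimnames(r) <- list(specs$metal, specs$metal)
  r
}

check_rank_corr <- function(rank_corr, n_metal) {
  if (!is.matrix(rank_corr) || nrow(rank_corr) != n_metal ||
      ncol(rank_corr) != n_metal) {
    abort(sprintf("`rank_corr` must be a %d x %d matrix", n_metal, n_metal))
  }
  if (max(abs(rank_corr - t(rank_corr))) > 1e-10) {
    abort("`rank_corr` must be symmetric")
  }
  if (max(abs(diag(rank_corr) - 1)) > 1e-10) {
    abort("`rank_corr` must have a unit diagonal")
  }
  ev <- eigen(rank_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort(sprintf(
      "`rank_corr` is not positive semi-definite: smallest eigenvalue %.6g",
      min(ev)))
  }
  invisible(rank_corr)
}

#' Sample correlated log-normal exposures via a Gaussian copula
#'
#' Draws an `n` x 14 matrix of creatinine-adjusted urinary concentrations
#' (ug/g creatinine). Dependence is a Gaussian copula on the log scale: the
#' target Spearman matrix `rank_corr` is converted to the latent Pearson
#' correlation through `2*sin(pi*r/6)`, latent normals are drawn, and each
#' column is mapped to a log-normal with median `gm_target` and log-SD
#' `log_sigma`. Because the map is strictly increasing, the empirical
#' Spearman correlations converge to `rank_corr` as `n` grows.
#'
#' @param specs Metal specification tibble ([default_metal_specs()]).
#' @param rank_corr Target Spearman correlation matrix (symmetric, unit
#'   diagonal, positive semi-definite); default [default_rank_corr()].
#' @param n Number of subjects.
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return A tibble of exposures with one column per metal, in canonical
#'   metal order.
#' @examples
#' x <- sample_exposures(n = 500, seed = 1)
#' exp(mean(log(x$As)))  # close to the As geometric-mean target
#' @export
sample_exposures <- function(specs = default_metal_specs(),
                             rank_corr = default_rank_corr(specs),
                             n, seed = NULL) {
  check_metal_specs(specs)
  check_scalar_number(n, "n", lower = 1)
  m <- nrow(specs)
  check_rank_corr(rank_corr, m)
  if (!is.null(dimnames(rank_corr)[[1]]) &&
      !identical(rownames(rank_corr), specs$metal)) {
    perm <- match(specs$metal, rownames(rank_corr))
    if (anyNA(perm)) abort("`rank_corr` dimnames do not match the metal specs")
    rank_corr <- rank_corr[perm, perm]
  }
  # latent Pearson correlation giving the requested Spearman under normality
  latent <- 2 * sin(pi * rank_corr / 6)
  diag(latent) <- 1
  ed <- eigen(latent, symmetric = TRUE)
  vals <- pmax(ed$values, 0)
  root <- ed$vectors %*% (sqrt(vals) * t(ed$vectors))
  with_seed(seed, {
    z <- matrix(rnorm(n * m), nrow = n) %*% root
    x <- sweep(exp(sweep(z, 2, specs$log_sigma, "*")), 2, specs$gm_target, "*")
    colnames(x) <- specs$metal
    tibble::as_tibble(x)
  })
}

#' Simulate urinary creatinine
#'
#' Log-normal with median `median_g_per_L` (default 1.0 g/L) and log-SD
#' `log_sd` (default 0.4), covering the usual spot-urine range.
#'
#' @param n Number of subjects.
#' @param median_g_per_L Median creatinine in g/L.
#' @param log_sd Log-scale standard deviation.
#' @param seed Optional integer seed.
#' @return Numeric vector of creatinine concentrations (g/L).
#' @export
simulate_creatinine <- function(n, median_g_per_L = 1.0, log_sd = 0.4,
                                seed = NULL) {
  check_scalar_number(n, "n", lower = 1)
  check_scalar_number(median_g_per_L, "median_g_per_L", lower = 1e-12)
  check_scalar_number(log_sd, "log_sd", lower = 0)
  with_seed(seed, exp(rnorm(n, log(median_g_per_L), log_sd)))
}

#' Apply the limit-of-detection substitution rule
#'
#' Concentrations are stored in ug/g creatinine but the assay LOD is defined
#' in ug/L, so each value is converted back to ug/L with the subject's
#' creatinine, compared to the metal's LOD, and - when below - replaced by
#' the rule's substitute (0, LOD/sqrt(2), or LOD/2, in ug/L), then
#' re-divided by creatinine. Values at or above the LOD pass through
#' unchanged.
#'
#' @param exposures Tibble or matrix of exposures in ug/g creatinine with
#'   metal-named columns.
#' @param specs Metal specification tibble supplying each metal's `lod`.
#' @param creatinine_g_per_L Per-subject creatinine (g/L), all positive.
#' @param rule Substitution rule: `"lod_over_sqrt2"` (default), `"lod_over_2"`
#'   or `"zero"`.
#' @return A tibble of censored exposures, same shape and column order.
#' @examples
#' specs <- default_metal_specs()
#' x <- sample_exposures(n = 100, seed = 1)
#' censor_at_lod(x, specs, creatinine_g_per_L = rep(1, 100))
#' @export
censor_at_lod <- function(exposures, specs = default_metal_specs(),
                          creatinine_g_per_L,
                          rule = c("lod_over_sqrt2", "lod_over_2", "zero")) {
  rule <- match.arg(rule)
  check_metal_specs(specs)
  x <- as.matrix(exposures)
  if (any(!is.finite(creatinine_g_per_L)) || any(creatinine_g_per_L <= 0)) {
    bad <- which(!is.finite(creatinine_g_per_L) | creatinine_g_per_L <= 0)
    abort(sprintf("creatinine must be positive and finite (subject %d: %s)",
                  bad[1], format(creatinine_g_per_L[bad[1]])))
  }
  if (length(creatinine_g_per_L) != nrow(x)) {
    abort("`creatinine_g_per_L` must have one value per subject")
  }
  idx <- match(colnames(x), specs$metal)
  if (anyNA(idx)) {
    abort(paste0("unknown metal columns: ",
                 paste(colnames(x)[is.na(idx)], collapse = ", ")))
  }
  lod <- specs$lod[idx]
  sub_ugL <- switch(rule,
    zero = 0 * lod,
    lod_over_sqrt2 = lod / sqrt(2),
    lod_over_2 = lod / 2
  )
  for (j in seq_len(ncol(x))) {
    ugL <- x[, j] * creatinine_g_per_L
    below <- ugL < lod[j]
    if (any(below)) {
      x[below, j] <- sub_ugL[j] / creatinine_g_per_L[below]
    }
  }
  tibble::as_tibble(x)
}

#' Ground-truth coefficients of the synthetic data-generating process
#'
#' Bundles the generating weights and coefficients of the two-index WQS
#' process used by [generate_outcomes()] and [generate_cohort()]: outcome =
#' intercept + beta1_ess * S_ess + beta2_ess * S_ess^2 + beta1_tox * S_tox +
#' beta2_tox * S_tox^2 + covariate terms + Gaussian noise, where each index
#' S is the weighted sum of that group's decile ranks.
#'
#' @param weights_essential Non-negative weights over the 8 essential
#'   metals; normalised to sum to 1. Default uniform.
#' @param weights_toxic Non-negative weights over the 6 toxic metals;
#'   normalised to sum to 1. Default uniform.
#' @param beta1_ess,beta2_ess,beta1_tox,beta2_tox Linear and quadratic index
#'   coefficients on the outcome scale (default 0).
#' @param covariate_coefs Named numeric vector of covariate coefficients
#'   (default: all 0).
#' @param intercept Outcome-scale constant (default 100, the WPPSI centre).
#' @param resid_sd Residual standard deviation (default 15, the WPPSI SD).
#' @return An object of class `effect_truth`.
#' @export
effect_truth <- function(weights_essential = rep(1 / 8, 8),
                         weights_toxic = rep(1 / 6, 6),
                         beta1_ess = 0, beta2_ess = 0,
                         beta1_tox = 0, beta2_tox = 0,
                         covariate_coefs = NULL,
                         intercept = 100, resid_sd = 15) {
  norm_w <- function(w, len, what) {
    if (length(w) != len) {
      abort(sprintf("`%s` must have length %d", what, len))
    }
    if (any(!is.finite(w)) || any(w < 0) || sum(w) <= 0) {
      abort(sprintf("`%s` must be non-negative with a positive sum", what))
    }
    w / sum(w)
  }
  if (is.null(covariate_coefs)) {
    covariate_coefs <- setNames(numeric(length(covariate_names())),
                                covariate_names())
  }
  check_scalar_number(resid_sd, "resid_sd", lower = 0)
  structure(list(
    weights_essential = setNames(norm_w(weights_essential, 8, "weights_essential"),
                                 metal_names("essential")),
    weights_toxic = setNames(norm_w(weights_toxic, 6, "weights_toxic"),
                             metal_names("toxic")),
    beta1_ess = beta1_ess, beta2_ess = beta2_ess,
    beta1_tox = beta1_tox, beta2_tox = beta2_tox,
    covariate_coefs = covariate_coefs,
    intercept = intercept, resid_sd = resid_sd
  ), class = "effect_truth")
}

#' Covariate set used throughout the analyses
#'
#' Maternal age (years), early-pregnancy BMI (kg/m^2), social class (1 =
#' low/medium), smoking (1 = ever), Mediterranean diet adherence score,
#' child sex (1 = female) and feeding type (1 = mixed/formula).
#'
#' @return Character vector of covariate column names.
#' @export
covariate_names <- function() {
  c("age", "bmi", "social_class", "smoking", "meddiet", "child_sex", "feeding")
}

#' Simulate covariates matching the cohort's marginal summaries
#'
#' Age ~ Normal(31.58, 4.72^2) truncated to \[18, 45\]; BMI ~ Normal(24.68,
#' 4.27^2) truncated positive; social class Bernoulli(0.746 low/medium);
#' smoking Bernoulli(0.323 ever); Mediterranean diet score Normal(9.65,
#' 2.44^2); child sex Bernoulli(0.468 female); feeding Bernoulli(0.229
#' mixed/formula).
#'
#' @param n Number of subjects.
#' @param seed Optional integer seed.
#' @return Tibble with the columns of [covariate_names()].
#' @export
simulate_covariates <- function(n, seed = NULL) {
  check_scalar_number(n, "n", lower = 1)
  rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
    x <- rnorm(n, mean, sd)
    while (any(bad <- x < lower | x > upper)) {
      x[bad] <- rnorm(sum(bad), mean, sd)
    }
    x
  }
  with_seed(seed, tibble::tibble(
    age = rtruncnorm(n, 31.58, 4.72, 18, 45),
    bmi = rtruncnorm(n, 24.68, 4.27, lower = 1e-6),
    social_class = rbinom(n, 1, 1 - 0.254),   # 1 = low/medium
    smoking = rbinom(n, 1, 0.323),            # 1 = smoker or ex-smoker
    meddiet = rnorm(n, 9.65, 2.44),
    child_sex = rbinom(n, 1, 0.468),          # 1 = female
    feeding = rbinom(n, 1, 0.229)             # 1 = mixed feeding / formula
  ))
}

#' Generate outcome scores from the two-index WQS process
#'
#' Computes `y = intercept + beta1_ess*S_ess + beta2_ess*S_ess^2 +
#' beta1_tox*S_tox + beta2_tox*S_tox^2 + X phi + e`, with
#' `S_g = sum_i w_i q_i` over the group's decile columns and
#' `e ~ N(0, resid_sd^2)`. With all coefficients zero the marginal
#' distribution is `N(intercept, resid_sd^2)`, i.e. the instrument's score
#' convention when `intercept`/`resid_sd` are set to it (100/15 for WPPSI
#' composite indices, 10/3 for NEPSY subtests).
#'
#' @param deciles Decile-rank tibble/matrix containing the 14 metal columns
#'   (integer ranks 0-9), e.g. the `ranks` element of [quantize_deciles()].
#' @param covariates Covariate tibble with the columns named in
#'   `truth$covariate_coefs`.
#' @param truth An [effect_truth()] object.
#' @param scale `"wppsi"` or `"nepsy"`; recorded convention of the score
#'   (used for validation messages only - the intercept and residual SD come
#'   from `truth`).
#' @param seed Optional integer seed for the residual draw.
#' @return Numeric outcome vector.
#' @export
generate_outcomes <- function(deciles, covariates, truth,
                              scale = c("wppsi", "nepsy"), seed = NULL) {
  scale <- match.arg(scale)
  if (!inherits(truth, "effect_truth")) abort("`truth` must be an effect_truth")
  q <- as.matrix(deciles)
  ess <- names(truth$weights_essential)
  tox <- names(truth$weights_toxic)
  missing <- setdiff(c(ess, tox), colnames(q))
  if (length(missing)) {
    abort(paste0("decile matrix lacks columns: ", paste(missing, collapse = ", ")))
  }
  s_ess <- drop(q[, ess, drop = FALSE] %*% truth$weights_essential)
  s_tox <- drop(q[, tox, drop = FALSE] %*% truth$weights_toxic)
  mu <- truth$intercept +
    truth$beta1_ess * s_ess + truth$beta2_ess * s_ess^2 +
    truth$beta1_tox * s_tox + truth$beta2_tox * s_tox^2
  phi <- truth$covariate_coefs
  if (length(phi)) {
    cx <- as.matrix(covariates[, names(phi), drop = FALSE])
    mu <- mu + drop(cx %*% phi)
  }
  with_seed(seed, mu + rnorm(length(mu), 0, truth$resid_sd))
}

#' Outcome column names
#'
#' Eight WPPSI composite indices (mean 100, SD 15) and three NEPSY subtests
#' (mean 10, SD 3).
#'
#' @param scale `"all"`, `"wppsi"` or `"nepsy"`.
#' @return Character vector of outcome column names.
#' @export
outcome_names <- function(scale = c("all", "wppsi", "nepsy")) {
  scale <- match.arg(scale)
  wppsi <- c("VCI", "FRI", "WMI", "PSI", "FSIQ", "VAI", "NVI", "GAI")
  nepsy <- c("verbal_fluency", "visuomotor_precision", "emotion_recognition")
  switch(scale, all = c(wppsi, nepsy), wppsi = wppsi, nepsy = nepsy)
}

#' Generate a complete synthetic cohort
#'
#' Orchestrates the full data-generating process: correlated log-normal
#' exposures ([sample_exposures()]), creatinine draw and LOD substitution
#' ([censor_at_lod()]), covariates ([simulate_covariates()]), full-sample
#' decile coding, and all 11 outcome scores from the two-index WQS truth.
#' WPPSI outcomes use `truth` as given; NEPSY outcomes are generated on the
#' mean-10/SD-3 scale with the index and covariate coefficients scaled by
#' 3/15 so standardized effect sizes carry over.
#'
#' @param n Number of mother-infant pairs; default 201, the analytic sample
#'   size the defaults emulate (see [study_attrition()]). Must be >= 30 so a
#'   60/40 split leaves a usable validation set.
#' @param truth An [effect_truth()]; default: null effects.
#' @param specs Metal specifications ([default_metal_specs()]).
#' @param rank_corr Target Spearman matrix ([default_rank_corr()]).
#' @param lod_rule LOD substitution rule, see [censor_at_lod()].
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   `(parameters, seed)`.
#' @return An object of class `synthetic_cohort`: a list with elements
#'   `data` (tibble: `subject_id`, 14 metal columns, covariates, outcomes),
#'   `deciles` (the [quantize_deciles()] result), `truth`, `specs`, `seed`.
#' @examples
#' coh <- generate_cohort(n = 201, seed = 1)
#' dim(coh$data)
#' @export
generate_cohort <- function(n = analytic_sample_size(),
                            truth = effect_truth(),
                            specs = default_metal_specs(),
                            rank_corr = default_rank_corr(specs),
                            lod_rule = "lod_over_sqrt2",
                            seed = NULL) {
  check_scalar_number(n, "n", lower = 30)
  if (!inherits(truth, "effect_truth")) abort("`truth` must be an effect_truth")
  with_seed(seed, {
    raw <- sample_exposures(specs, rank_corr, n)
    creat <- simulate_creatinine(n)
    exposures <- censor_at_lod(raw, specs, creat, rule = lod_rule)
    covars <- simulate_covariates(n)
    dec <- quantize_deciles(exposures, metals = specs$metal, quiet = TRUE)
    nepsy_truth <- truth
    sc <- 3 / 15
    nepsy_truth$beta1_ess <- truth$beta1_ess * sc
    nepsy_truth$beta2_ess <- truth$beta2_ess * sc
    nepsy_truth$beta1_tox <- truth$beta1_tox * sc
    nepsy_truth$beta2_tox <- truth$beta2_tox * sc
    nepsy_truth$covariate_coefs <- truth$covariate_coefs * sc
    nepsy_truth$intercept <- 10
    nepsy_truth$resid_sd <- truth$resid_sd * sc
    outs <- lapply(outcome_names("wppsi"), function(o) {
      generate_outcomes(dec$ranks, covars, truth, scale = "wppsi")
    })
    outs <- c(outs, lapply(outcome_names("nepsy"), function(o) {
      generate_outcomes(dec$ranks, covars, nepsy_truth, scale = "nepsy")
    }))
    names(outs) <- outcome_names("all")
    data <- dplyr::bind_cols(
      tibble::tibble(subject_id = seq_len(n)),
      exposures, covars, tibble::as_tibble(outs)
    )
    structure(list(data = data, deciles = dec, truth = truth,
                   specs = specs, seed = seed),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d metals, %d outcomes\n",
              nrow(x$data), nrow(x$specs), length(outcome_names())))
  invisible(x)
}

#' Write / read a cohort and its generating truth
#'
#' The cohort table is written as a comma-separated file with a header row:
#' `subject_id`, the 14 metal columns (ug/g creatinine), the covariates, and
#' the 11 outcome columns. The generating truth is written as a YAML
#' key-value side-car so parameter-recovery checks can reload it.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param path Path of the CSV file to create.
#' @param truth_path Optional path for the truth side-car; default
#'   `"<path>.truth.yml"`. Use `NULL` to skip.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path,
                         truth_path = paste0(path, ".truth.yml")) {
  data <- if (inherits(cohort, "synthetic_cohort")) cohort$data else cohort
  readr::write_csv(data, path)
  if (!is.null(truth_path) && inherits(cohort, "synthetic_cohort")) {
    write_truth(cohort$truth, truth_path)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @param truth An [effect_truth()] object.
#' @export
write_truth <- function(truth, path) {
  yaml::write_yaml(lapply(unclass(truth), function(x) {
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x
  }), path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_truth <- function(path) {
  raw <- yaml::read_yaml(path)
  effect_truth(
    weights_essential = unlist(raw$weights_essential),
    weights_toxic = unlist(raw$weights_toxic),
    beta1_ess = raw$beta1_ess, beta2_ess = raw$beta2_ess,
    beta1_tox = raw$beta1_tox, beta2_tox = raw$beta2_tox,
    covariate_coefs = unlist(raw$covariate_coefs),
    intercept = raw$intercept, resid_sd = raw$resid_sd
  )
}
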