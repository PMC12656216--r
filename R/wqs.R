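#' Configuration of the two-index WQS procedure
#'
#' Collects every tunable of the training/validation machinery. The
#' defaults follow the analysis the package emulates: decile-coded
#' exposures, a 60/40 training-validation split, 100 bootstrap samples per
#' training step, 100 repeated holdouts, a ridge penalty multiplier of 100
#' on the weights, and AIC-based exploration of both index directions.
#'
#' @param n_quantiles Number of exposure quantile bins (10 = deciles).
#' @param split_fraction Fraction of subjects in the training portion.
#' @param n_boot Bootstrap resamples per training step.
#' @param n_holdout Number of repeated random holdout splits.
#' @param penalty Ridge penalty multiplier lambda on `sum(w^2)` added to the
#'   training objective; `0` recovers the unpenalized estimator and large
#'   values shrink the weights toward uniform.
#' @param direction_ess,direction_tox Sign constraint of each index
#'   coefficient: `"positive"`, `"negative"` or `"auto_aic"` (explore both,
#'   keep the lower mean validation AIC).
#' @param signal Bootstrap aggregation weighting: `"squared_t"` (default,
#'   each converged bootstrap weight vector weighted by the squared t
#'   statistic of its index coefficient) or `"uniform"`.
#' @param summary Point estimate across holdouts: `"mean"` (default) or
#'   `"median"`.
#' @param ci Interval across holdouts: `"percentile"` (2.5/97.5 percentiles,
#'   default) or `"wald"` (mean estimate +/- 1.96 x mean SE).
#' @param n_boot_select,n_holdout_select Reduced repetition counts used by
#'   the AIC direction pre-pass.
#' @param n_starts Multi-start count for the training optimizer (uniform,
#'   signal-proportional, random).
#' @param maxit,reltol Optimizer iteration cap and relative tolerance.
#' @param min_validation_n Minimum usable validation rows per holdout.
#' @param seed Master seed driving splits, bootstraps and optimizer
#'   restarts.
#' @return A list of class `wqs_config`.
#' @export
wqs_config <- function(n_quantiles = 10, split_fraction = 0.6,
                       n_boot = 100, n_holdout = 100, penalty = 100,
                       direction_ess = c("auto_aic", "negative", "positive"),
                       direction_tox = c("auto_aic", "negative", "positive"),
                       signal = c("squared_t", "uniform"),
                       summary = c("mean", "median"),
                       ci = c("percentile", "wald"),
                       n_boot_select = 20, n_holdout_select = 10,
                       n_starts = 3, maxit = 200, reltol = 1e-10,
                       min_validation_n = 20, seed = NULL) {
  check_scalar_number(split_fraction, "split_fraction")
  if (split_fraction <= 0 || split_fraction >= 1) {
    abort("`split_fraction` must be strictly between 0 and 1")
  }
  check_scalar_number(n_boot, "n_boot", lower = 1)
  check_scalar_number(n_holdout, "n_holdout", lower = 1)
  check_scalar_number(penalty, "penalty", lower = 0)
  check_scalar_number(n_starts, "n_starts", lower = 1)
  structure(list(
    n_quantiles = n_quantiles, split_fraction = split_fraction,
    n_boot = as.integer(n_boot), n_holdout = as.integer(n_holdout),
    penalty = penalty,
    direction_ess = match.arg(direction_ess),
    direction_tox = match.arg(direction_tox),
    signal = match.arg(signal), summary = match.arg(summary),
    ci = match.arg(ci),
    n_boot_select = as.integer(n_boot_select),
    n_holdout_select = as.integer(n_holdout_select),
    n_starts = as.integer(n_starts), maxit = maxit, reltol = reltol,
    min_validation_n = min_validation_n, seed = seed
  ), class = "wqs_config")
}

#' Weighted quantile sum index
#'
#' `S = sum_i w_i q_i` over an index's decile columns; with ranks in
#' `0..n_quantiles-1` and weights on the simplex, `S` stays in the same
#' range.
#'
#' @param deciles Matrix/tibble of integer ranks restricted to the index's
#'   member metals.
#' @param weights Simplex weight vector, one entry per column of `deciles`
#'   (matched by name when both are named).
#' @return Numeric per-subject index values.
#' @examples
#' q <- cbind(Cd = c(0L, 5L, 9L), Sb = c(9L, 5L, 0L))
#' compute_wqs_index(q, c(Cd = 0.25, Sb = 0.75))
#' @export
compute_wqs_index <- function(deciles, weights) {
  q <- as.matrix(deciles)
  if (length(weights) != ncol(q)) {
    abort(sprintf("length(weights) = %d but deciles has %d columns",
                  length(weights), ncol(q)))
  }
  if (!is.null(names(weights)) && !is.null(colnames(q))) {
    if (!setequal(names(weights), colnames(q))) {
      abort("weight names do not match decile columns")
    }
    weights <- weights[colnames(q)]
  }
  check_simplex(weights)
  drop(q %*% weights)
}

# Training objective machinery -------------------------------------------

# Precompute, for one (bootstrap) sample, the quadratic forms that make the
# profile objective O(m^2): project y and the decile columns off [1, X],
# leaving RSS(w) = yty - (b'w)^2 / (w'Aw) for an admissible index slope.
profile_setup <- function(q, y, x) {
  z0 <- cbind(1, x)
  qrz <- qr(z0)
  yt <- qr.resid(qrz, y)
  qt <- qr.resid(qrz, q)
  list(A = crossprod(qt), b = drop(crossprod(qt, yt)), yty = sum(yt^2),
       n = length(y), p = ncol(z0))
}

# Penalized Gaussian profile negative log-likelihood (constants dropped)
# over softmax-parameterized simplex weights, with the index slope
# sign-constrained to `direction` (+1/-1); slope is profiled out, and a
# direction-violating profile slope is pinned to the boundary beta1 = 0.
profile_objective <- function(theta, setup, direction, penalty) {
  w <- softmax(theta)
  num <- sum(setup$b * w)
  aw <- drop(setup$A %*% w)
  den <- sum(w * aw)
  rss <- setup$yty
  if (den > 1e-12 && direction * num / den > 0) rss <- rss - num^2 / den
  0.5 * rss + penalty * sum(w^2)
}

profile_gradient <- function(theta, setup, direction, penalty) {
  w <- softmax(theta)
  num <- sum(setup$b * w)
  aw <- drop(setup$A %*% w)
  den <- sum(w * aw)
  admissible <- den > 1e-12 && direction * num / den > 0
  rss <- setup$yty - if (admissible) num^2 / den else 0
  g_rss <- if (admissible) {
    -(2 * num * setup$b / den - 2 * num^2 * aw / den^2)
  } else {
    numeric(length(w))
  }
  g_w <- 0.5 * g_rss + 2 * penalty * w
  # chain rule through softmax: J = diag(w) - w w'
  w * (g_w - sum(w * g_w))
}

# Unpenalized profile estimate of the index slope at fixed weights
profile_beta <- function(setup, w, direction) {
  num <- sum(setup$b * w)
  aw <- drop(setup$A %*% w)
  den <- sum(w * aw)
  if (den <= 1e-12 || direction * num / den <= 0) {
    return(list(beta1 = 0, tstat = 0, rss = setup$yty, den = den))
  }
  beta1 <- num / den
  rss <- setup$yty - num^2 / den
  df <- setup$n - setup$p - 1
  sigma2 <- max(rss, 1e-12) / max(df, 1)
  list(beta1 = beta1, tstat = beta1 / sqrt(sigma2 / den), rss = rss, den = den)
}

train_one <- function(setup, direction, penalty, n_starts, maxit, reltol) {
  m <- length(setup$b)
  s2 <- setup$yty / max(setup$n - setup$p, 1)
  tmarg <- setup$b / sqrt(pmax(diag(setup$A), 1e-12) * s2)
  w0 <- pmax(direction * tmarg, 0)^2
  starts <- list(rep(0, m))
  if (n_starts >= 2) {
    starts <- c(starts, list(
      if (sum(w0) > 0) log(w0 / sum(w0) + 1e-3) else rep(0, m)))
  }
  if (n_starts >= 3) {
    starts <- c(starts, replicate(n_starts - 2, rnorm(m), simplify = FALSE))
  }
  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      optim(th0, profile_objective, profile_gradient, setup = setup,
            direction = direction, penalty = penalty, method = "BFGS",
            control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(list(w = rep(1 / m, m), beta1 = NA_real_, tstat = NA_real_,
                converged = FALSE, objective = NA_real_))
  }
  w <- softmax(best$par)
  pb <- profile_beta(setup, w, direction)
  list(w = w, beta1 = pb$beta1, tstat = pb$tstat,
       converged = best$convergence == 0, objective = best$value)
}

#' Bootstrap training of one index's weights
#'
#' For each bootstrap resample of the training rows, minimizes the Gaussian
#' negative log-likelihood of `outcome ~ intercept + beta1 * S(w) +
#' covariates` plus the ridge penalty `penalty * sum(w^2)` over the simplex
#' weights `w` (softmax-parameterized) with `beta1` constrained to the
#' index's direction; the intercept, covariate coefficients and `beta1` are
#' profiled out by least squares at each `w`, and a profile slope violating
#' the sign constraint is pinned to the boundary `beta1 = 0`. A multi-start
#' quasi-Newton search (uniform, marginal-signal-proportional, random
#' starts) guards against local minima.
#'
#' @param deciles Decile matrix restricted to the index's metals (training
#'   rows).
#' @param outcome Outcome values for the training rows.
#' @param covariates Covariate matrix/tibble for the training rows.
#' @param direction `+1` or `-1` (or `"positive"`/`"negative"`): sign
#'   constraint of the index coefficient.
#' @param config A [wqs_config()]; `n_boot`, `penalty`, `n_starts`, `maxit`
#'   and `reltol` are used.
#' @param seed Optional seed for the bootstrap and random starts.
#' @return An object of class `wqs_boot`: list with `weights` (n_boot x m
#'   matrix), `beta1`, `tstat`, `converged`, `objective` (per bootstrap),
#'   `boot_indices` (list of resampled row indices) and `direction`.
#' @export
train_weights <- function(deciles, outcome, covariates = NULL,
                          direction, config = wqs_config(), seed = NULL) {
  direction <- resolve_direction(direction)
  q <- as.matrix(deciles)
  m <- ncol(q)
  n <- nrow(q)
  x <- if (is.null(covariates)) {
    matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    as.matrix(covariates)
  }
  if (length(outcome) != n) abort("outcome length does not match deciles")
  if (n < 10 * m) {
    abort(sprintf("training needs >= %d rows for %d metals (got %d)",
                  10 * m, m, n))
  }
  with_seed(seed, {
    nb <- config$n_boot
    weights <- matrix(NA_real_, nb, m, dimnames = list(NULL, colnames(q)))
    beta1 <- tstat <- objective <- rep(NA_real_, nb)
    converged <- logical(nb)
    idx_list <- vector("list", nb)
    for (b in seq_len(nb)) {
      idx <- sample.int(n, n, replace = TRUE)
      idx_list[[b]] <- idx
      setup <- profile_setup(q[idx, , drop = FALSE], outcome[idx],
                             x[idx, , drop = FALSE])
      r <- train_one(setup, direction, config$penalty, config$n_starts,
                     config$maxit, config$reltol)
      weights[b, ] <- r$w
      beta1[b] <- r$beta1
      tstat[b] <- r$tstat
      converged[b] <- r$converged
      objective[b] <- r$objective
    }
    if (mean(converged) < 0.10) {
      abort(sprintf(
        "weight training failed: only %d/%d bootstraps converged",
        sum(converged), nb), class = "wqsmix_training_failure")
    }
    structure(list(weights = weights, beta1 = beta1, tstat = tstat,
                   converged = converged, objective = objective,
                   boot_indices = idx_list, direction = direction),
              class = "wqs_boot")
  })
}

resolve_direction <- function(direction) {
  if (is.character(direction)) {
    direction <- switch(direction, positive = 1, negative = -1,
                        abort("direction must be 'positive' or 'negative'"))
  }
  if (!direction %in% c(-1, 1)) abort("direction must be +1 or -1")
  direction
}

#' Aggregate bootstrap weight vectors into the index weights
#'
#' Weighted mean of the converged bootstrap rows, each row weighted by the
#' squared t statistic of its index coefficient (default) or uniformly,
#' renormalized to the simplex. With zero total signal (every converged
#' bootstrap at the `beta1 = 0` boundary) aggregation falls back to the
#' uniform mean with a warning.
#'
#' @param boot A `wqs_boot` from [train_weights()].
#' @param signal `"squared_t"` or `"uniform"`.
#' @return Named simplex weight vector.
#' @export
aggregate_weights <- function(boot, signal = c("squared_t", "uniform")) {
  signal <- match.arg(signal)
  keep <- boot$converged & is.finite(boot$tstat)
  if (!any(keep)) abort("no converged bootstraps to aggregate")
  w <- boot$weights[keep, , drop = FALSE]
  lam <- if (signal == "squared_t") boot$tstat[keep]^2 else rep(1, nrow(w))
  if (sum(lam) <= 0) {
    warn("zero aggregation signal; falling back to uniform row weighting",
         class = "wqsmix_zero_signal")
    lam <- rep(1, nrow(w))
  }
  agg <- drop(lam %*% w) / sum(lam)
  agg / sum(agg)
}

#' Joint validation regression of both indices
#'
#' Ordinary least squares of the outcome on the essential and toxic WQS
#' indices (quadratic terms where flagged) plus covariates, on the held-out
#' validation rows; coefficients, standard errors and Gaussian AIC are
#' returned.
#'
#' @param deciles Full decile matrix (validation rows) containing both
#'   indices' metal columns.
#' @param outcome Validation outcome values.
#' @param weights_ess,weights_tox Aggregated simplex weights per index
#'   (named by metal).
#' @param covariates Optional covariate tibble/matrix (validation rows).
#' @param quadratic Logical 2-vector `c(ess = , tox = )`: include the
#'   squared index term.
#' @param min_n Minimum validation rows.
#' @return A list: `estimates` (tibble `term`, `estimate`, `se`), `aic`,
#'   `n`, plus the `lm` object.
#' @export
validate_model <- function(deciles, outcome, weights_ess, weights_tox,
                           covariates = NULL,
                           quadratic = c(ess = FALSE, tox = FALSE),
                           min_n = 20) {
  q <- as.matrix(deciles)
  n <- nrow(q)
  if (n < min_n) {
    abort(sprintf("validation set too small (%d < %d rows)", n, min_n))
  }
  s_ess <- compute_wqs_index(q[, names(weights_ess), drop = FALSE], weights_ess)
  s_tox <- compute_wqs_index(q[, names(weights_tox), drop = FALSE], weights_tox)
  df <- data.frame(..y = outcome, wqs_ess = s_ess, wqs_tox = s_tox)
  terms <- c("wqs_ess",
             if (isTRUE(quadratic[["ess"]])) "I(wqs_ess^2)",
             "wqs_tox",
             if (isTRUE(quadratic[["tox"]])) "I(wqs_tox^2)")
  covnames <- character()
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    covariates <- as.data.frame(covariates)
    covnames <- names(covariates)
    df <- cbind(df, covariates)
  }
  fit <- lm(stats::reformulate(c(terms, covnames), "..y"), data = df)
  cf <- coef(fit)
  if (anyNA(cf)) {
    abort(paste0("validation design is rank deficient; aliased column(s): ",
                 paste(names(cf)[is.na(cf)], collapse = ", ")),
          class = "wqsmix_rank_deficient")
  }
  sm <- summary(fit)$coefficients
  list(
    estimates = tibble::tibble(term = rownames(sm),
                               estimate = sm[, "Estimate"],
                               se = sm[, "Std. Error"]),
    aic = AIC(fit), n = n, model = fit
  )
}

# One holdout split: train both indices separately (each with its own index
# plus covariates only), aggregate, validate jointly.
run_one_holdout <- function(q_ess, q_tox, y, x, config, dir_ess, dir_tox,
                            quadratic, seed) {
  with_seed(seed, {
    n <- length(y)
    n_train <- floor(config$split_fraction * n)
    train <- sample.int(n, n_train)
    valid <- setdiff(seq_len(n), train)
    boot_seeds <- draw_seeds(2)
    boot_ess <- train_weights(q_ess[train, , drop = FALSE], y[train],
                              x[train, , drop = FALSE], dir_ess, config,
                              seed = boot_seeds[1])
    boot_tox <- train_weights(q_tox[train, , drop = FALSE], y[train],
                              x[train, , drop = FALSE], dir_tox, config,
                              seed = boot_seeds[2])
    w_ess <- aggregate_weights(boot_ess, config$signal)
    w_tox <- aggregate_weights(boot_tox, config$signal)
    val <- validate_model(
      cbind(q_ess, q_tox)[valid, , drop = FALSE], y[valid],
      w_ess, w_tox, x[valid, , drop = FALSE],
      quadratic = quadratic, min_n = config$min_validation_n)
    list(estimates = val$estimates, aic = val$aic, n_valid = val$n,
         w_ess = w_ess, w_tox = w_tox)
  })
}

#' Repeated-holdout two-index WQS estimation
#'
#' The core inference loop: for each of `n_holdout` random
#' `split_fraction`/(1-`split_fraction`) splits, train the essential and
#' toxic index weights separately on the training portion (each in a model
#' containing only its own index plus covariates), aggregate the bootstrap
#' weights, and estimate the joint validation regression on the held-out
#' portion; then summarise the per-term validation estimates across
#' holdouts (mean or median point estimate; 2.5/97.5 percentile or Wald
#' interval) and average the per-index weights.
#'
#' Failed holdouts are skipped and counted; more than 20% failures aborts.
#'
#' @param data Cohort tibble containing metal, covariate and outcome
#'   columns.
#' @param outcome Name of the outcome column.
#' @param covariates Covariate column names (default [covariate_names()]).
#' @param config A [wqs_config()].
#' @param deciles Optional precomputed [quantize_deciles()] result (computed
#'   on the full analytic sample when `NULL`).
#' @param quadratic Logical 2-vector `c(ess = , tox = )` adding squared
#'   index terms to the validation regression (training stays linear in the
#'   index).
#' @param directions Optional resolved directions `c(ess = , tox = )` in
#'   `{-1, 1}`; when `NULL` they come from `config` (with `"auto_aic"`
#'   resolved by [select_direction()]).
#' @param seed Master seed; overrides `config$seed`.
#' @return An object of class `wqs_fit`; see [tidy.wqs_fit()] and
#'   [glance.wqs_fit()].
#' @examples
#' coh <- generate_cohort(n = 201, seed = 1)
#' cfg <- wqs_config(n_boot = 5, n_holdout = 5, direction_ess = "negative",
#'                   direction_tox = "negative")
#' fit <- repeated_holdout(coh$data, "VCI", config = cfg, seed = 1)
#' tidy(fit)
#' @export
repeated_holdout <- function(data, outcome, covariates = covariate_names(),
                             config = wqs_config(), deciles = NULL,
                             quadratic = c(ess = FALSE, tox = FALSE),
                             directions = NULL, seed = config$seed) {
  prep <- prepare_wqs_data(data, outcome, covariates, deciles)
  if (is.null(directions)) {
    directions <- resolve_directions(prep, config, seed = seed,
                                     quadratic = quadratic)
  }
  fit <- holdout_engine(prep, config, directions, quadratic, seed)
  fit$call <- match.call()
  fit
}

prepare_wqs_data <- function(data, outcome, covariates, deciles = NULL) {
  if (!outcome %in% names(data)) {
    abort(sprintf("outcome column '%s' not found", outcome))
  }
  metals_ess <- intersect(metal_names("essential"), names(data))
  metals_tox <- intersect(metal_names("toxic"), names(data))
  if (!length(metals_ess) || !length(metals_tox)) {
    abort("data must contain essential and toxic metal columns")
  }
  covariates <- intersect(covariates, names(data))
  if (is.null(deciles)) {
    deciles <- quantize_deciles(data, c(metals_ess, metals_tox), quiet = TRUE)
  }
  q <- as.matrix(deciles$ranks)
  keep <- is.finite(data[[outcome]]) &
    complete.cases(data[, covariates, drop = FALSE])
  list(
    q_ess = q[keep, metals_ess, drop = FALSE],
    q_tox = q[keep, metals_tox, drop = FALSE],
    y = data[[outcome]][keep],
    x = as.matrix(data[keep, covariates, drop = FALSE]),
    outcome = outcome, n_dropped = sum(!keep), deciles = deciles
  )
}

resolve_directions <- function(prep, config, seed, quadratic) {
  auto <- c(ess = config$direction_ess == "auto_aic",
            tox = config$direction_tox == "auto_aic")
  if (!any(auto)) {
    return(c(ess = resolve_direction(config$direction_ess),
             tox = resolve_direction(config$direction_tox)))
  }
  sel <- select_direction_impl(prep, config, seed = seed, quadratic = quadratic)
  sel$directions
}

holdout_engine <- function(prep, config, directions, quadratic, seed,
                           keep_provenance = NULL) {
  quadratic <- c(ess = isTRUE(quadratic[["ess"]]),
                 tox = isTRUE(quadratic[["tox"]]))
  zero_signal <- 0L
  est_list <- list(); aic <- numeric(); n_valid <- integer()
  w_ess_mat <- NULL; w_tox_mat <- NULL
  failures <- character()
  with_seed(seed, {
    holdout_seeds <- draw_seeds(config$n_holdout)
    for (h in seq_len(config$n_holdout)) {
      res <- withCallingHandlers(
        tryCatch(
          run_one_holdout(prep$q_ess, prep$q_tox, prep$y, prep$x, config,
                          directions[["ess"]], directions[["tox"]],
                          quadratic, holdout_seeds[h]),
          error = function(e) e
        ),
        wqsmix_zero_signal = function(w) {
          zero_signal <<- zero_signal + 1L
          rlang::cnd_muffle(w)
        }
      )
      if (inherits(res, "error")) {
        failures <- c(failures, conditionMessage(res))
        next
      }
      est_list[[length(est_list) + 1L]] <-
        dplyr::mutate(res$estimates, holdout = h)
      aic <- c(aic, res$aic)
      n_valid <- c(n_valid, res$n_valid)
      w_ess_mat <- rbind(w_ess_mat, res$w_ess)
      w_tox_mat <- rbind(w_tox_mat, res$w_tox)
    }
  })
  if (length(failures) > 0.2 * config$n_holdout) {
    abort(paste0("more than 20% of holdouts failed; first error: ",
                 failures[1]), class = "wqsmix_holdout_failure")
  }
  if (!length(est_list)) abort("no successful holdouts")
  holdouts <- dplyr::bind_rows(est_list)
  point <- if (config$summary == "median") stats::median else mean
  terms <- holdouts |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      conf.low = unname(quantile(.data$estimate, 0.025, type = 7)),
      conf.high = unname(quantile(.data$estimate, 0.975, type = 7)),
      mean_se = mean(.data$se),
      estimate = point(.data$estimate),
      .groups = "drop"
    ) |>
    dplyr::select("term", "estimate", "conf.low", "conf.high", "mean_se")
  if (config$ci == "wald") {
    terms$conf.low <- terms$estimate - 1.96 * terms$mean_se
    terms$conf.high <- terms$estimate + 1.96 * terms$mean_se
  }
  # keep the model's term ordering rather than alphabetical
  terms <- terms[match(unique(holdouts$term), terms$term), ]
  summarise_w <- function(mat, index) {
    w <- colMeans(mat)
    tibble::tibble(index = index, metal = colnames(mat),
                   weight = w / sum(w),
                   q25 = apply(mat, 2, quantile, 0.25),
                   q75 = apply(mat, 2, quantile, 0.75))
  }
  weights <- dplyr::bind_rows(summarise_w(w_ess_mat, "essential"),
                              summarise_w(w_tox_mat, "toxic"))
  fit <- structure(list(
    outcome = prep$outcome,
    terms = terms,
    weights = weights,
    holdouts = holdouts,
    holdout_weights = list(essential = w_ess_mat, toxic = w_tox_mat),
    directions = directions,
    quadratic = quadratic,
    aic = aic, mean_aic = mean(aic), n_valid = n_valid,
    n_holdout_done = length(aic), n_failed = length(failures),
    zero_signal_count = zero_signal,
    n_dropped = prep$n_dropped,
    config = config, seed = seed,
    provenance = keep_provenance
  ), class = "wqs_fit")
  fit$terms$significant <- wqs_significance(fit)$significant
  fit
}

#' AIC-based selection of the index directions
#'
#' Runs the repeated-holdout procedure at reduced repetition counts
#' (`n_boot_select` x `n_holdout_select`) for every direction combination of
#' the indices in `auto_aic` mode and keeps the combination with the lowest
#' mean validation AIC. Ties within `1e-6` resolve deterministically in
#' favour of the negative direction (combinations are explored
#' negative-first).
#'
#' @inheritParams repeated_holdout
#' @return A list: `directions` (named `c(ess, tox)` in -1/1) and
#'   `aic_table` (tibble of every combination's mean AIC).
#' @export
select_direction <- function(data, outcome, covariates = covariate_names(),
                             config = wqs_config(), deciles = NULL,
                             quadratic = c(ess = FALSE, tox = FALSE),
                             seed = config$seed) {
  prep <- prepare_wqs_data(data, outcome, covariates, deciles)
  select_direction_impl(prep, config, seed = seed, quadratic = quadratic)
}

select_direction_impl <- function(prep, config, seed, quadratic) {
  auto <- c(ess = config$direction_ess == "auto_aic",
            tox = config$direction_tox == "auto_aic")
  dirs_for <- function(which) {
    if (auto[[which]]) c(-1, 1) else {
      resolve_direction(config[[paste0("direction_", which)]])
    }
  }
  combos <- expand.grid(ess = dirs_for("ess"), tox = dirs_for("tox"),
                        KEEP.OUT.ATTRS = FALSE)
  sub_config <- config
  sub_config$n_boot <- config$n_boot_select
  sub_config$n_holdout <- config$n_holdout_select
  aics <- vapply(seq_len(nrow(combos)), function(i) {
    fit <- holdout_engine(prep, sub_config,
                          c(ess = combos$ess[i], tox = combos$tox[i]),
                          quadratic, seed)
    fit$mean_aic
  }, numeric(1))
  aic_table <- tibble::tibble(direction_ess = combos$ess,
                              direction_tox = combos$tox, mean_aic = aics)
  best <- which(aics <= min(aics) + 1e-6)[1]  # negative-first tie break
  list(directions = c(ess = combos$ess[best], tox = combos$tox[best]),
       aic_table = aic_table)
}

#' Term significance from the holdout interval
#'
#' A term is significant at the two-sided level `alpha = 0.05` when its 95%
#' holdout interval excludes 0; a degenerate interval touching 0 is not
#' significant.
#'
#' @param fit A `wqs_fit`.
#' @param alpha Significance level; only 0.05 (the 95% interval stored in
#'   the fit) is supported without refitting.
#' @return Tibble with `term` and logical `significant`.
#' @export
wqs_significance <- function(fit, alpha = 0.05) {
  if (!inherits(fit, "wqs_fit")) abort("`fit` must be a wqs_fit")
  if (abs(alpha - 0.05) > 1e-12) {
    abort("only alpha = 0.05 is supported (the stored interval is 95%)")
  }
  tibble::tibble(
    term = fit$terms$term,
    significant = fit$terms$conf.low > 0 | fit$terms$conf.high < 0
  )
}

#' @export
print.wqs_fit <- function(x, ...) {
  cat(sprintf("<wqs_fit> outcome %s: %d/%d holdouts, directions ess=%+d tox=%+d\n",
              x$outcome, x$n_holdout_done, x$config$n_holdout,
              x$directions[["ess"]], x$directions[["tox"]]))
  print(x$terms, ...)
  invisible(x)
}
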