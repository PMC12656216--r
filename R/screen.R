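#' Penalized-spline smooth fit for one metal-outcome pair
#'
#' Fits `outcome ~ s(exposure) + covariates` with a cubic regression spline
#' basis (dimension 10) and a quadratic roughness penalty, selecting the
#' smoothing parameter by restricted maximum likelihood (REML) via
#' [mgcv::gam()]. The effective degrees of freedom (edf) of the smooth
#' summarise its complexity - edf near 1 means essentially linear, larger
#' values indicate curvature - and the reported p-value is mgcv's
#' approximate test of the smooth term against the zero function.
#'
#' @param exposure Numeric vector (typically decile ranks 0-9).
#' @param outcome Numeric outcome scores.
#' @param covariates Optional tibble/data.frame of adjustment covariates
#'   entering linearly.
#' @param k Basis dimension (default 10); reduced automatically (with a
#'   warning) when the exposure has fewer distinct values.
#' @param sp Optional fixed smoothing parameter; `NULL` (default) selects it
#'   by REML.
#' @return A tibble row: `edf`, `p_value`, `converged`, `k`, plus the fitted
#'   `gam` object in the `fit` list-column.
#' @examples
#' set.seed(1)
#' x <- rep(0:9, each = 20)
#' y <- 2 * x + rnorm(length(x))
#' fit_gam_smooth(x, y)$edf  # close to 1: linear
#' @export
fit_gam_smooth <- function(exposure, outcome, covariates = NULL, k = 10,
                           sp = NULL) {
  n <- length(exposure)
  if (n < 50) abort("smooth screening needs at least 50 subjects")
  if (length(outcome) != n) abort("exposure and outcome lengths differ")
  n_unique <- length(unique(exposure))
  if (n_unique < k) {
    warn(sprintf("reducing basis dimension from %d to %d distinct values",
                 k, n_unique))
    k <- n_unique
  }
  df <- data.frame(..y = outcome, ..x = exposure)
  rhs <- sprintf("s(..x, k = %d, bs = \"cr\")", k)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (qr(cbind(1, as.matrix(covariates)))$rank < ncol(covariates) + 1) {
      abort("covariates are not full rank")
    }
    df <- cbind(df, covariates)
    rhs <- paste(c(rhs, names(covariates)), collapse = " + ")
  }
  form <- stats::as.formula(paste("..y ~", rhs))
  fit <- tryCatch(
    mgcv::gam(form, data = df, method = "REML", sp = sp),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(tibble::tibble(edf = NA_real_, p_value = NA_real_,
                          converged = FALSE, k = k,
                          fit = list(conditionMessage(fit))))
  }
  sm <- summary(fit)$s.table
  tibble::tibble(
    edf = unname(sm[1, "edf"]),
    p_value = unname(sm[1, "p-value"]),
    converged = isTRUE(fit$converged),
    k = k,
    fit = list(fit)
  )
}

#' Restricted cubic spline basis (truncated power form)
#'
#' Builds the k-2 non-linear basis columns of a restricted cubic spline with
#' the given knots: a natural cubic spline constrained to be linear beyond
#' the boundary knots. Terms are normalised by the squared knot span.
#'
#' @param x Numeric vector.
#' @param knots Strictly increasing knot locations (>= 3).
#' @return Matrix with `length(knots) - 2` columns.
#' @export
rcs_basis <- function(x, knots) {
  k <- length(knots)
  if (k < 3) abort("restricted cubic splines need at least 3 knots")
  if (any(diff(knots) <= 0)) abort("knots must be strictly increasing")
  tk <- knots[k]; tk1 <- knots[k - 1]
  norm <- (knots[k] - knots[1])^2
  p3 <- function(u) pmax(u, 0)^3
  out <- sapply(seq_len(k - 2), function(j) {
    tj <- knots[j]
    (p3(x - tj) -
       p3(x - tk1) * (tk - tj) / (tk - tk1) +
       p3(x - tk) * (tk1 - tj) / (tk - tk1)) / norm
  })
  matrix(out, nrow = length(x))
}

rcs_knot_quantiles <- function(n_knots) {
  switch(as.character(n_knots),
         "3" = c(0.10, 0.50, 0.90),
         "4" = c(0.05, 0.35, 0.65, 0.95),
         "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
         abort("`n_knots` must be 3, 4 or 5"))
}

#' Restricted cubic spline fit for one metal-outcome pair
#'
#' Secondary characterisation of a non-linear association: ordinary least
#' squares of the outcome on a linear term plus the restricted-cubic
#' non-linear basis (knots at standard quantiles of the exposure), adjusted
#' for covariates. Non-linearity is assessed by the joint F test of the
#' `n_knots - 2` non-linear coefficients against the nested linear model.
#'
#' @inheritParams fit_gam_smooth
#' @param n_knots Number of knots: 3, 4 (default) or 5; knots sit at the
#'   exposure quantiles (0.10, 0.50, 0.90), (0.05, 0.35, 0.65, 0.95) or
#'   (0.05, 0.275, 0.50, 0.725, 0.95) respectively. Coincident knots (heavy
#'   ties) are deduplicated; fewer than 3 distinct knots is degenerate.
#' @param grid_n Number of grid points for the exported fitted curve.
#' @return An object of class `rcs_fit`: list with `knots`, `coefficients`,
#'   `p_nonlinear`, `curve` (tibble `x`, `fit`, `lower`, `upper` over a
#'   `grid_n`-point grid) and the underlying `lm` fits.
#' @export
fit_rcs <- function(exposure, outcome, covariates = NULL, n_knots = 4,
                    grid_n = 100) {
  probs <- rcs_knot_quantiles(n_knots)
  knots <- unique(unname(quantile(exposure, probs, type = 7)))
  if (length(knots) < 3) {
    abort("fewer than 3 distinct knots after deduplication; exposure too tied",
          class = "wqsmix_degenerate_knots")
  }
  nl <- rcs_basis(exposure, knots)
  colnames(nl) <- paste0("rcs", seq_len(ncol(nl)))
  df <- data.frame(..y = outcome, ..x = exposure, nl)
  covnames <- character()
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    covnames <- names(covariates)
    df <- cbind(df, covariates)
  }
  full <- lm(stats::reformulate(c("..x", colnames(nl), covnames), "..y"),
             data = df)
  lin <- lm(stats::reformulate(c("..x", covnames), "..y"), data = df)
  p_nonlinear <- anova(lin, full)[2, "Pr(>F)"]
  grid <- seq(min(exposure), max(exposure), length.out = grid_n)
  nd <- data.frame(..x = grid, rcs_basis(grid, knots))
  names(nd)[-1] <- colnames(nl)
  for (v in covnames) nd[[v]] <- mean(df[[v]])
  pr <- predict(full, newdata = nd, se.fit = TRUE)
  structure(list(
    knots = knots,
    coefficients = coef(full),
    p_nonlinear = p_nonlinear,
    curve = tibble::tibble(x = grid, fit = unname(pr$fit),
                           lower = unname(pr$fit - 1.96 * pr$se.fit),
                           upper = unname(pr$fit + 1.96 * pr$se.fit)),
    model = full, linear_model = lin
  ), class = "rcs_fit")
}

#' @export
print.rcs_fit <- function(x, ...) {
  cat(sprintf("<rcs_fit> %d knots at %s; p(non-linear) = %.4g\n",
              length(x$knots), paste(signif(x$knots, 3), collapse = ", "),
              x$p_nonlinear))
  invisible(x)
}

#' Screen every metal-outcome pair for non-linearity
#'
#' Runs [fit_gam_smooth()] for each metal x outcome combination (exposures
#' as decile ranks by default), flags a pair as non-linear when
#' `edf >= edf_threshold` and `p_value < alpha`, confirms flagged pairs with
#' [fit_rcs()], and derives the quadratic-term configuration for the WQS
#' stage: an outcome gets a quadratic essential-index term when at least one
#' essential metal is flagged for it.
#'
#' @param data Cohort tibble (metal columns plus covariates and outcomes),
#'   e.g. `generate_cohort(...)$data`.
#' @param outcomes Outcome columns to screen; default all 11.
#' @param covariates Covariate columns; default [covariate_names()].
#' @param deciles Optional precomputed [quantize_deciles()] object; computed
#'   from `data` when `NULL`.
#' @param edf_threshold Minimum edf for a curvilinear flag (default 1.5).
#' @param alpha Significance level for the smooth-term test (default 0.05).
#' @param p_adjust Multiple-testing adjustment across the metal x outcome
#'   grid: `"none"` (default) or `"BH"`.
#' @param use_deciles Model decile ranks (default) or raw concentrations.
#' @return An object of class `screen_table`: tibble with one row per metal
#'   x outcome (`metal`, `group`, `outcome`, `edf`, `p_value`, `converged`,
#'   `nonlinear`, `rcs_p`) plus attributes `quadratic_outcomes` (character)
#'   and `rcs_fits` (named list for flagged pairs).
#' @export
run_screen <- function(data, outcomes = outcome_names(),
                       covariates = covariate_names(),
                       deciles = NULL,
                       edf_threshold = 1.5, alpha = 0.05,
                       p_adjust = c("none", "BH"),
                       use_deciles = TRUE) {
  p_adjust <- match.arg(p_adjust)
  specs <- default_metal_specs()
  metals <- intersect(specs$metal, names(data))
  if (!length(metals)) abort("no canonical metal columns in `data`")
  missing_out <- setdiff(outcomes, names(data))
  if (length(missing_out)) {
    abort(paste0("missing outcome columns: ", paste(missing_out, collapse = ", ")))
  }
  covs <- data[, intersect(covariates, names(data)), drop = FALSE]
  if (use_deciles) {
    if (is.null(deciles)) deciles <- quantize_deciles(data, metals, quiet = TRUE)
    expo <- deciles$ranks
  } else {
    expo <- data[, metals, drop = FALSE]
  }
  grid <- tidyr::expand_grid(metal = metals, outcome = outcomes)
  res <- purrr::pmap_dfr(grid, function(metal, outcome) {
    keep <- is.finite(data[[outcome]])
    r <- tryCatch(
      fit_gam_smooth(expo[[metal]][keep], data[[outcome]][keep],
                     covariates = covs[keep, , drop = FALSE]),
      error = function(e) tibble::tibble(edf = NA_real_, p_value = NA_real_,
                                         converged = FALSE, k = NA_real_,
                                         fit = list(conditionMessage(e)))
    )
    tibble::tibble(metal = metal, outcome = outcome,
                   edf = r$edf, p_value = r$p_value, converged = r$converged)
  })
  res$group <- specs$group[match(res$metal, specs$metal)]
  p_use <- if (p_adjust == "BH") stats::p.adjust(res$p_value, "BH") else res$p_value
  res$nonlinear <- !is.na(res$edf) & !is.na(p_use) &
    res$edf >= edf_threshold & p_use < alpha
  res$rcs_p <- NA_real_
  rcs_fits <- list()
  for (i in which(res$nonlinear)) {
    keep <- is.finite(data[[res$outcome[i]]])
    rf <- tryCatch(
      fit_rcs(expo[[res$metal[i]]][keep], data[[res$outcome[i]]][keep],
              covariates = covs[keep, , drop = FALSE]),
      error = function(e) NULL
    )
    if (!is.null(rf)) {
      res$rcs_p[i] <- rf$p_nonlinear
      rcs_fits[[paste(res$metal[i], res$outcome[i], sep = ".")]] <- rf
    }
  }
  res <- res[, c("metal", "group", "outcome", "edf", "p_value", "converged",
                 "nonlinear", "rcs_p")]
  quad <- sort(unique(res$outcome[res$nonlinear & res$group == "essential"]))
  structure(res, class = c("screen_table", class(res)),
            quadratic_outcomes = quad,
            rcs_fits = rcs_fits,
            edf_threshold = edf_threshold, alpha = alpha)
}

#' Outcomes whose WQS model gets a quadratic essential-index term
#'
#' @param screen A `screen_table` from [run_screen()].
#' @return Character vector of outcome names.
#' @export
quadratic_outcomes <- function(screen) {
  if (!inherits(screen, "screen_table")) abort("`screen` must be a screen_table")
  attr(screen, "quadratic_outcomes")
}
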