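#' Canonical urinary metal panel with calibration constants
#'
#' The package works with a fixed panel of 14 urinary metals measured in
#' first-trimester maternal urine: 8 essential (Mg, Cr, Mn, Mo, Co, Cu, Zn,
#' Se) and 6 toxic (As, Cd, Sb, Hg, Pb, Ni). Each metal carries the
#' calibration constants the synthetic cohort generator needs: the target
#' geometric mean (GM) and interquartile range (IQR) of its
#' creatinine-adjusted concentration (ug/g creatinine) in the study
#' population, the assay limit of detection (LOD, ug/L), and the log-scale
#' standard deviation of a log-normal whose median equals the GM and whose
#' IQR equals the target IQR.
#'
#' `log_sigma` solves `exp(mu + sigma*z_.75) - exp(mu + sigma*z_.25) = IQR`
#' with `mu = log(GM)`; because the normal quantiles are symmetric this is
#' `asinh(IQR / (2*GM)) / qnorm(0.75)` exactly.
#'
#' @return A tibble with one row per metal and columns `metal`, `group`
#'   (`"essential"` or `"toxic"`), `gm_target` (ug/g creatinine),
#'   `iqr_target` (ug/g creatinine), `lod` (ug/L) and `log_sigma`.
#' @examples
#' specs <- default_metal_specs()
#' specs[specs$metal == "As", ]
#' @export
default_metal_specs <- function() {
  specs <- tibble::tribble(
    ~metal, ~group,      ~gm_target, ~iqr_target, ~lod,
    "Mg",   "essential",    7.43e4,     4.27e4,    2,
    "Cr",   "essential",    0.26,       0.21,      0.05,
    "Mn",   "essential",    0.11,       0.23,      0.04,
    "Mo",   "essential",   39.87,      26.78,      0.02,
    "Co",   "essential",    0.35,       0.39,      0.004,
    "Cu",   "essential",    6.71,       4.88,      0.1,
    "Zn",   "essential",  271.80,     233.81,      1,
    "Se",   "essential",   26.67,       8.80,      1,
    "As",   "toxic",       30.44,      67.62,      0.1,
    "Cd",   "toxic",        0.22,       0.19,      0.02,
    "Sb",   "toxic",        0.05,       0.04,      0.03,
    "Hg",   "toxic",        0.50,       0.63,      0.03,
    "Pb",   "toxic",        0.37,       0.45,      0.07,
    "Ni",   "toxic",        1.70,       1.33,      0.2
  )
  specs$log_sigma <- lognormal_sigma_from_iqr(specs$gm_target, specs$iqr_target)
  specs
}

# sigma of a log-normal with median gm whose IQR equals iqr
lognormal_sigma_from_iqr <- function(gm, iqr) {
  stopifnot(all(gm > 0), all(iqr > 0))
  asinh(iqr / (2 * gm)) / qnorm(0.75)
}

#' Names of the canonical metals
#'
#' @param group `"all"` (default), `"essential"` or `"toxic"`.
#' @return Character vector of metal symbols in canonical order.
#' @export
metal_names <- function(group = c("all", "essential", "toxic")) {
  group <- match.arg(group)
  specs <- default_metal_specs()
  if (group != "all") specs <- specs[specs$group == group, ]
  specs$metal
}

check_metal_specs <- function(specs) {
  req <- c("metal", "group", "gm_target", "iqr_target", "lod", "log_sigma")
  missing <- setdiff(req, names(specs))
  if (length(missing)) {
    abort(paste0("metal specs are missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(specs$metal)) abort("duplicated metal names in specs")
  if (!all(specs$group %in% c("essential", "toxic"))) {
    abort("metal group must be 'essential' or 'toxic'")
  }
  with(specs, {
    if (!all(gm_target > 0)) abort("gm_target must be > 0")
    if (!all(iqr_target > 0)) abort("iqr_target must be > 0")
    if (!all(lod >= 0)) abort("lod must be >= 0")
    if (!all(log_sigma > 0)) abort("log_sigma must be > 0")
  })
  invisible(specs)
}

#' Recruitment and attrition accounting of the source cohort
#'
#' Recomputes the analytic sample size from the recruitment and follow-up
#' stage counts of the pregnancy cohort the package's defaults emulate:
#' women recruited at the first prenatal visit, losses before the third
#' trimester (voluntary withdrawal, miscarriage, exclusion criteria,
#' unknown), children with a psychological assessment at 4 years, and pairs
#' lacking a first-trimester urine sample.
#'
#' @return A tibble with columns `stage` and `n`; the final row
#'   (`"analytic_sample"`) is the derived number of mother-infant pairs with
#'   both exposure and outcome data.
#' @examples
#' study_attrition()
#' analytic_sample_size()
#' @export
study_attrition <- function() {
  recruited <- 791L
  lost <- c(voluntary_withdrawal = 180L, miscarriage = 13L,
            met_exclusion = 46L, unknown = 18L)
  completed <- recruited - sum(lost)
  psych_4y <- 231L
  no_urine <- 30L
  tibble::tibble(
    stage = c("recruited", names(lost), "completed_third_trimester",
              "psychological_assessment_4y", "missing_urine_metals",
              "analytic_sample"),
    n = c(recruited, unname(lost), completed, psych_4y, no_urine,
          psych_4y - no_urine)
  )
}

#' @rdname study_attrition
#' @export
analytic_sample_size <- function() {
  att <- study_attrition()
  as.integer(att$n[att$stage == "analytic_sample"])
}
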