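#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration describing a full analysis run: the input
#' cohort (a CSV path, or a `simulate:` block with `n`, `seed` and optional
#' truth coefficients), covariate and outcome column lists, screen settings
#' and WQS settings. Unset WQS fields fall back to the procedure defaults
#' (100 bootstraps, 100 holdouts, penalty 100, 60/40 split, deciles).
#' Validation problems are collected and reported in a single aggregated
#' error.
#'
#' @param path Path to a YAML file, or a named list with the same shape.
#' @return A list of class `pipeline_config` with elements `input`,
#'   `covariates`, `outcomes`, `screen` (edf_threshold, alpha, n_knots),
#'   `wqs` (a [wqs_config()]), `out_dir`, `seed`.
#' @export
load_config <- function(path) {
  raw <- if (is.character(path)) {
    if (!file.exists(path)) abort(sprintf("config file '%s' not found", path))
    yaml::read_yaml(path)
  } else if (is.list(path)) path else {
    abort("`path` must be a file path or a list")
  }
  if (is.null(raw)) raw <- list()
  known <- c("input", "covariates", "outcomes", "screen", "wqs", "out_dir",
             "seed")
  problems <- character()
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    problems <- c(problems, paste0("unknown keys: ",
                                   paste(unknown, collapse = ", ")))
  }
  screen_defaults <- list(edf_threshold = 1.5, alpha = 0.05, n_knots = 4)
  screen <- modifyList(screen_defaults, raw$screen %||% list())
  if (!screen$n_knots %in% 3:5) {
    problems <- c(problems, "screen.n_knots must be 3, 4 or 5")
  }
  if (screen$alpha <= 0 || screen$alpha >= 1) {
    problems <- c(problems, "screen.alpha must be in (0, 1)")
  }
  wqs_args <- raw$wqs %||% list()
  bad_wqs <- setdiff(names(wqs_args), names(formals(wqs_config)))
  if (length(bad_wqs)) {
    problems <- c(problems, paste0("unknown wqs settings: ",
                                   paste(bad_wqs, collapse = ", ")))
  }
  wqs <- tryCatch(
    do.call(wqs_config, wqs_args[setdiff(names(wqs_args), bad_wqs)]),
    error = function(e) {
      problems <<- c(problems, paste0("wqs: ", conditionMessage(e)))
      NULL
    }
  )
  outcomes <- raw$outcomes %||% outcome_names()
  if (!length(outcomes)) problems <- c(problems, "outcomes must be non-empty")
  input <- raw$input %||% list(simulate = list(n = analytic_sample_size()))
  if (is.character(input)) input <- list(path = input)
  if (is.null(input$path) && is.null(input$simulate)) {
    problems <- c(problems,
                  "input must give a `path` or a `simulate` block")
  }
  if (length(problems)) {
    abort(paste0("invalid configuration:\n- ",
                 paste(problems, collapse = "\n- ")),
          class = "wqsmix_config_error")
  }
  structure(list(
    input = input,
    covariates = raw$covariates %||% covariate_names(),
    outcomes = outcomes,
    screen = screen,
    wqs = wqs,
    out_dir = raw$out_dir %||% ".",
    seed = raw$seed %||% wqs$seed
  ), class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a cohort table from the documented CSV contract
#'
#' Expects the column contract of [write_cohort()]: `subject_id`, the 14
#' metal columns (any order; reordered canonically), the covariates and any
#' subset of the outcome columns. Non-numeric cells and missing mandatory
#' columns are rejected with coordinates; rows with missing values are kept
#' here and handled complete-case per outcome by the modeling stages.
#'
#' @param path CSV file path.
#' @param covariates Required covariate columns.
#' @return A tibble with metals in canonical order.
#' @export
read_cohort <- function(path, covariates = covariate_names()) {
  if (!file.exists(path)) abort(sprintf("cohort file '%s' not found", path))
  data <- readr::read_csv(path, show_col_types = FALSE,
                          na = c("", "NA"))
  metals <- metal_names()
  mandatory <- c(metals, covariates)
  missing <- setdiff(mandatory, names(data))
  if (length(missing)) {
    abort(paste0("cohort file lacks mandatory columns: ",
                 paste(missing, collapse = ", ")))
  }
  numeric_cols <- intersect(c(metals, covariates, outcome_names()),
                            names(data))
  for (cl in numeric_cols) {
    if (!is.numeric(data[[cl]])) {
      bad <- which(!is.na(data[[cl]]) &
                     is.na(suppressWarnings(as.numeric(data[[cl]]))))
      abort(sprintf("non-numeric value in column '%s', row %s", cl,
                    paste(head(bad, 3), collapse = ", ")))
    }
  }
  ordered <- c(intersect("subject_id", names(data)), metals,
               intersect(covariates, names(data)),
               intersect(outcome_names(), names(data)))
  data[, c(ordered, setdiff(names(data), ordered))]
}

# atomic write: temp file in the same directory, then rename
write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full mixture analysis end to end
#'
#' Executes, in order: the Spearman correlation screen, the GAM/RCS
#' non-linearity screen (deriving which outcomes get a quadratic
#' essential-index term), and - per outcome - AIC direction selection (when
#' configured) followed by repeated-holdout two-index WQS estimation with
#' significance flags. Per-outcome failures are recorded in the bundle
#' rather than aborting the run.
#'
#' @param data Cohort tibble (e.g. from [read_cohort()] or
#'   [generate_cohort()]`$data`).
#' @param config A `pipeline_config` from [load_config()] (or a plain list
#'   accepted by it).
#' @return An object of class `report_bundle`: list with `correlation`
#'   (Spearman matrix), `screen` (screen_table), `fits` (named list of
#'   `wqs_fit` or error messages), `failures`, and `provenance`.
#' @export
run_full_analysis <- function(data, config = load_config(list())) {
  if (!inherits(config, "pipeline_config")) config <- load_config(config)
  seed <- config$seed
  correlation <- spearman_matrix(data)
  deciles <- quantize_deciles(data, quiet = TRUE)
  screen <- run_screen(data, outcomes = intersect(config$outcomes, names(data)),
                       covariates = config$covariates, deciles = deciles,
                       edf_threshold = config$screen$edf_threshold,
                       alpha = config$screen$alpha)
  quad_out <- quadratic_outcomes(screen)
  fits <- list(); failures <- list()
  outcome_seeds <- with_seed(seed, draw_seeds(length(config$outcomes)))
  for (i in seq_along(config$outcomes)) {
    out <- config$outcomes[i]
    quad <- c(ess = out %in% quad_out, tox = FALSE)
    fit <- tryCatch(
      repeated_holdout(data, out, covariates = config$covariates,
                       config = config$wqs, deciles = deciles,
                       quadratic = quad, seed = outcome_seeds[i]),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      failures[[out]] <- conditionMessage(fit)
    } else {
      fits[[out]] <- fit
    }
  }
  structure(list(
    correlation = correlation,
    screen = screen,
    fits = fits,
    failures = failures,
    provenance = list(
      seed = seed, config = unclass(config),
      quadratic_outcomes = quad_out,
      package_version = as.character(utils::packageVersion("wqsmix")),
      n_subjects = nrow(data),
      holdout_failures = vapply(fits, function(f) f$n_failed, integer(1))
    )
  ), class = "report_bundle")
}

#' Write a report bundle to disk
#'
#' Emits, under `dir`: `correlation.csv` (labeled Spearman matrix),
#' `screen.csv`, per-outcome `wqs_<outcome>.csv` (term, estimate, lower,
#' upper, significant) and `weights_<outcome>.csv` (metal, mean weight,
#' holdout IQR), and `provenance.json`. All writes are atomic (temp file +
#' rename).
#'
#' @param bundle A `report_bundle` from [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  corr <- tibble::as_tibble(bundle$correlation, rownames = "metal")
  write_atomic(function(p) readr::write_csv(corr, p),
               file.path(dir, "correlation.csv"))
  write_atomic(function(p) readr::write_csv(tidy(bundle$screen), p),
               file.path(dir, "screen.csv"))
  for (out in names(bundle$fits)) {
    fit <- bundle$fits[[out]]
    write_atomic(function(p) readr::write_csv(tidy(fit), p),
                 file.path(dir, paste0("wqs_", out, ".csv")))
    write_atomic(function(p) readr::write_csv(tidy(fit, "weights"), p),
                 file.path(dir, paste0("weights_", out, ".csv")))
  }
  prov <- bundle$provenance
  prov$failures <- bundle$failures
  write_atomic(function(p) jsonlite::write_json(prov, p, auto_unbox = TRUE,
                                                pretty = TRUE, digits = NA,
                                                force = TRUE),
               file.path(dir, "provenance.json"))
  invisible(dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d fits, %d failures, %d screened pairs\n",
              length(x$fits), length(x$failures), nrow(x$screen)))
  invisible(x)
}
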