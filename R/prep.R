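#' Creatinine adjustment of a urinary concentration
#'
#' Divides a urinary analyte concentration (ug/L) by urinary creatinine
#' (g/L) to correct for urine dilution, giving ug per g creatinine.
#'
#' @param conc_ug_per_L Concentration in ug/L (>= 0).
#' @param creatinine_g_per_L Creatinine in g/L (> 0); recycled against
#'   `conc_ug_per_L`.
#' @param subject_id Optional identifiers used in error messages.
#' @return Concentration in ug/g creatinine.
#' @examples
#' creatinine_adjust(10, 0.5)  # 20 ug/g creatinine
#' @export
creatinine_adjust <- function(conc_ug_per_L, creatinine_g_per_L,
                              subject_id = seq_along(conc_ug_per_L)) {
  bad <- !is.finite(creatinine_g_per_L) | creatinine_g_per_L <= 0
  if (any(bad)) {
    i <- which(bad)[1]
    id <- subject_id[min(i, length(subject_id))]
    abort(sprintf(
      "creatinine must be > 0; subject %s has creatinine %s g/L",
      format(id), format(creatinine_g_per_L[i])))
  }
  if (any(conc_ug_per_L < 0, na.rm = TRUE)) {
    abort("concentrations must be >= 0")
  }
  conc_ug_per_L / creatinine_g_per_L
}

#' Decile coding of one exposure column
#'
#' Replaces each concentration with its decile rank in 0-9. The nine
#' thresholds are the empirical deciles computed by linear interpolation of
#' order statistics (`quantile(type = 7)`); a value's rank is the number of
#' thresholds strictly below it, so values tied with a threshold all fall in
#' the lower bin and the top bin is closed. The coding is invariant under
#' strictly increasing transformations of the input.
#'
#' @param values Numeric vector of one metal's concentrations (>= 10 finite
#'   values).
#' @param quiet Suppress the unbalanced-occupancy warning heavy ties can
#'   trigger.
#' @return Integer vector of ranks in 0-9 with attribute `thresholds` (the
#'   9 non-decreasing cut points).
#' @examples
#' decile_transform(1:10)
#' @export
decile_transform <- function(values, quiet = FALSE) {
  x <- values[is.finite(values)]
  if (length(x) < 10) abort("decile coding needs at least 10 finite values")
  if (length(x) != length(values)) abort("values must all be finite")
  if (max(x) == min(x)) {
    abort("constant exposure column cannot be quantized into deciles",
          class = "wqsmix_constant_column")
  }
  thresholds <- unname(quantile(x, probs = seq(0.1, 0.9, by = 0.1), type = 7))
  ranks <- vapply(x, function(v) sum(thresholds < v), integer(1))
  occ <- tabulate(ranks + 1L, nbins = 10L)
  if (!quiet && (max(occ) - min(occ)) > 1L) {
    warn(paste0("tied values produce unbalanced decile occupancies: ",
                paste(occ, collapse = " ")),
         class = "wqsmix_unbalanced_deciles")
  }
  structure(as.integer(ranks), thresholds = thresholds)
}

#' Decile-code the full exposure table
#'
#' Applies [decile_transform()] to each metal column on the full analytic
#' sample; the resulting coding (and its thresholds) is reused unchanged for
#' any training/validation subsets downstream, never recomputed per split.
#'
#' @param data Tibble with one column per metal (ug/g creatinine).
#' @param metals Metal columns to code; default: the canonical 14 present in
#'   `data`.
#' @param quiet Suppress tie warnings.
#' @return An object of class `decile_matrix`: list with `ranks` (tibble of
#'   integer ranks 0-9) and `thresholds` (named list of 9-point cut vectors).
#' @export
quantize_deciles <- function(data, metals = intersect(metal_names(), names(data)),
                             quiet = FALSE) {
  if (!length(metals)) abort("no metal columns to quantize")
  missing <- setdiff(metals, names(data))
  if (length(missing)) {
    abort(paste0("missing metal columns: ", paste(missing, collapse = ", ")))
  }
  coded <- lapply(metals, function(m) decile_transform(data[[m]], quiet = quiet))
  thresholds <- lapply(coded, attr, "thresholds")
  names(thresholds) <- metals
  ranks <- tibble::as_tibble(lapply(coded, as.integer), .name_repair = "minimal")
  names(ranks) <- metals
  structure(list(ranks = ranks, thresholds = thresholds),
            class = "decile_matrix")
}

#' @export
print.decile_matrix <- function(x, ...) {
  cat(sprintf("<decile_matrix> %d subjects x %d metals (ranks 0-9)\n",
              nrow(x$ranks), ncol(x$ranks)))
  invisible(x)
}

#' Spearman correlation matrix of the exposures
#'
#' Pairwise Spearman rank correlations (average ranks for ties) between the
#' metal concentration columns - the multicollinearity screen run before any
#' modeling. A constant column has no defined rank correlation; its pairs
#' are reported as `NA` rather than zeroed.
#'
#' @param data Tibble with metal concentration columns.
#' @param metals Columns to correlate; default: canonical metals present.
#' @return Symmetric correlation matrix with metal dimnames, unit diagonal.
#' @examples
#' x <- sample_exposures(n = 100, seed = 1)
#' round(spearman_matrix(x)[1:4, 1:4], 2)
#' @export
spearman_matrix <- function(data, metals = intersect(metal_names(), names(data))) {
  x <- as.matrix(data[, metals, drop = FALSE])
  if (nrow(x) < 3) abort("Spearman screening needs at least 3 subjects")
  rho <- suppressWarnings(cor(x, method = "spearman"))
  diag(rho) <- 1
  rho
}
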