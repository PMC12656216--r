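#' @importFrom rlang abort warn .data :=
#' @importFrom stats qnorm quantile rnorm runif rbinom lm lm.fit AIC coef vcov
#'   predict anova pf pt sd cor complete.cases setNames optim median
#' @importFrom utils modifyList head
NULL

# softmax on the weight simplex; shift-invariant, guarded against overflow
softmax <- function(theta) {
  e <- exp(theta - max(theta))
  e / sum(e)
}

is_simplex <- function(w, tol = 1e-8) {
  all(is.finite(w)) && all(w >= -tol) && abs(sum(w) - 1) <= tol
}

check_simplex <- function(w, what = "weights") {
  if (!is_simplex(w)) {
    abort(sprintf("%s must be non-negative and sum to 1 (sum = %.10g)",
                  what, sum(w)))
  }
  invisible(w)
}

#' @noRd
check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

# Draw independent substream seeds from the current RNG state. Keeping seeds
# below .Machine$integer.max keeps them valid 32-bit integers.
draw_seeds <- function(n) {
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

# Evaluate `expr` under `seed` (when non-NULL) without clobbering the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}
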