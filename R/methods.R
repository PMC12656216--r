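#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a two-index WQS fit
#'
#' @param x A `wqs_fit` from [repeated_holdout()].
#' @param what `"terms"` (default: per-term estimate and 95% holdout
#'   interval) or `"weights"` (per-metal mean final weights with holdout
#'   interquartile range).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy wqs_fit
#' @export
tidy.wqs_fit <- function(x, what = c("terms", "weights"), ...) {
  what <- match.arg(what)
  if (what == "weights") return(x$weights)
  dplyr::mutate(x$terms, outcome = x$outcome, .before = 1)
}

#' One-row summary of a two-index WQS fit
#'
#' @param x A `wqs_fit`.
#' @param ... Unused.
#' @return A tibble with the outcome, resolved directions, mean validation
#'   AIC, holdout accounting and dropped-row count.
#' @method glance wqs_fit
#' @export
glance.wqs_fit <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome,
    direction_ess = x$directions[["ess"]],
    direction_tox = x$directions[["tox"]],
    quadratic_ess = x$quadratic[["ess"]],
    quadratic_tox = x$quadratic[["tox"]],
    mean_aic = x$mean_aic,
    n_holdout = x$n_holdout_done,
    n_failed = x$n_failed,
    n_dropped = x$n_dropped
  )
}

#' Tidy a non-linearity screen
#'
#' @param x A `screen_table` from [run_screen()].
#' @param ... Unused.
#' @return The underlying tibble (metal, outcome, edf, p-value, flags).
#' @method tidy screen_table
#' @export
tidy.screen_table <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Plot the final mixture weights of a WQS fit
#'
#' Bar chart of each metal's mean final weight per index, with the holdout
#' interquartile range and the equal-weight reference line (the null
#' contribution under which every metal matters equally).
#'
#' @param object A `wqs_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wqs_fit
#' @export
autoplot.wqs_fit <- function(object, ...) {
  w <- dplyr::group_by(object$weights, .data$index) |>
    dplyr::mutate(ref = 1 / dplyr::n()) |>
    dplyr::ungroup()
  ggplot2::ggplot(w, ggplot2::aes(
    x = stats::reorder(.data$metal, -.data$weight), y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                           width = 0.3) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$ref),
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~index, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "mean weight",
                  title = paste0("WQS index weights: ", object$outcome)) +
    ggplot2::theme_minimal()
}

#' Plot a restricted cubic spline fit
#'
#' Fitted exposure-response curve with pointwise 95% band and knot
#' positions.
#'
#' @param object An `rcs_fit` from [fit_rcs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rcs_fit
#' @export
autoplot.rcs_fit <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$x, .data$fit)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$knots, linetype = "dotted") +
    ggplot2::labs(x = "exposure (decile rank)", y = "fitted outcome") +
    ggplot2::theme_minimal()
}

#' Plot the non-linearity screen as an edf heat map
#'
#' @param object A `screen_table` from [run_screen()].
#' @param ... Unused.
#' @return A ggplot object; flagged pairs are outlined.
#' @method autoplot screen_table
#' @export
autoplot.screen_table <- function(object, ...) {
  d <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(d, ggplot2::aes(.data$outcome, .data$metal,
                                  fill = .data$edf)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = d[d$nonlinear, , drop = FALSE],
                       colour = "black", linewidth = 0.8, fill = NA) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "edf") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
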