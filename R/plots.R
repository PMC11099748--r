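#' Scatter plot of a harmonized instrument set
#'
#' Outcome effects against exposure effects with one-standard-error bars;
#' a fitted causal slope can be overlaid by passing an `mr_result`.
#'
#' @param object A single-exposure `mr_harmonized` set.
#' @param fit Optional `mr_result` whose slope (and Egger intercept, when
#'   present) is drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_harmonized
#' @export
autoplot.mr_harmonized <- function(object, fit = NULL, ...) {
  d <- tibble::tibble(bx = h_bx(object), sx = h_sx(object),
                      by = h_by(object), sy = h_sy(object))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$bx, y = .data$by)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$by - .data$sy, ymax = .data$by + .data$sy),
      linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$bx - .data$sx, xmax = .data$bx + .data$sx),
      linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(
      x = paste0("effect on ", object$exposure_ids[1]),
      y = paste0("effect on ", object$outcome_id)) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_abline(
      intercept = fit$egger_intercept %||% 0, slope = fit$beta,
      colour = "firebrick")
  }
  p
}

#' Forest plot of MR estimates
#'
#' One row per method (or per adjustment/exposure pair for multivariable
#' tables), point estimate with 95 percent interval. Odds-ratio columns are
#' used when present, otherwise the beta scale.
#'
#' @param results Tibble as returned by [run_uvmr_phase()] /
#'   [run_mvmr_phase()], or `tidy()` output bound across methods. Must
#'   contain `method`, `beta`, `ci_low`, `ci_high`.
#' @param or_scale Plot odds ratios when available, default `TRUE`.
#' @return A ggplot object.
#' @export
plot_forest <- function(results, or_scale = TRUE) {
  use_or <- or_scale && "or_" %in% names(results) &&
    any(is.finite(results$or_))
  d <- dplyr::mutate(
    results,
    est = if (use_or) .data$or_ else .data$beta,
    lo = if (use_or) .data$or_low else .data$ci_low,
    hi = if (use_or) .data$or_high else .data$ci_high,
    label = if ("exposure" %in% names(results)) {
      paste(.data$exposure, .data$method, sep = " | ")
    } else {
      .data$method
    }
  )
  d <- d[is.finite(d$est), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$est, y = .data$label)) +
    ggplot2::geom_vline(xintercept = if (use_or) 1 else 0,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi), height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = if (use_or) "odds ratio (95% CI)" else
      "causal estimate (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Radial plot of per-variant contributions
#'
#' The radial representation: `ratio * sqrt(w)` against `sqrt(w)`, the
#' fitted slope through the origin, outliers highlighted.
#'
#' @param object An `mr_radial` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_radial
#' @export
autoplot.mr_radial <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$sqrt_w, y = .data$product,
                               colour = .data$outlier)) +
    ggplot2::geom_abline(intercept = 0, slope = object$estimate$beta,
                         colour = "grey40") +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(sqrt(w[j])),
                  y = expression(hat(beta)[j] * sqrt(w[j])),
                  colour = "outlier") +
    ggplot2::theme_minimal()
}

#' Mediated-proportion plot
#'
#' Ranked bar chart of the proportion of the total effect carried by each
#' passing mediator, with truncated 95 percent intervals.
#'
#' @param object An `mr_mediation` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_mediation
#' @export
autoplot.mr_mediation <- function(object, ...) {
  d <- object$results
  if (nrow(d) == 0) abort("no passing mediators to plot")
  d$mediator_id <- factor(d$mediator_id, levels = rev(d$mediator_id))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$proportion,
                                  y = .data$mediator_id)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low_trunc, xmax = .data$ci_high_trunc),
      height = 0.2) +
    ggplot2::scale_x_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "mediated proportion", y = NULL) +
    ggplot2::theme_minimal()
}
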