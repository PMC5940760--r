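#' Plot a scattering profile
#'
#' Log-intensity versus momentum transfer, with error bars when sigmas are
#' present. Non-positive intensities (possible after background subtraction)
#' are dropped from the log plot.
#'
#' @param object A [saxs_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.saxs_profile <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), .data$intensity > 0)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$s, y = .data$intensity)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(s ~ ("Å"^-1)), y = "I(s) (arb.)",
                  title = profile_label(object)) +
    ggplot2::theme_minimal()
  if (has_sigma(object)) {
    gg <- gg + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$intensity - .data$sigma, .Machine$double.xmin),
                   ymax = .data$intensity + .data$sigma),
      linewidth = 0.2, alpha = 0.3)
  }
  gg
}

#' Plot a mass posterior with MAP and credibility interval
#'
#' @param object An `mm_posterior`.
#' @param ... Unused.
#' @return A ggplot object: posterior mass per bin on a log mass axis, the
#'   MAP bin marked, the credibility interval shaded.
#' @export
autoplot.mm_posterior <- function(object, ...) {
  df <- tidy.mm_posterior(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mm_center, y = .data$posterior)) +
    ggplot2::annotate("rect", xmin = object$ci_low, xmax = object$ci_high,
                      ymin = 0, ymax = Inf, alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_col(width = 0.01) +
    ggplot2::geom_vline(xintercept = object$map_mm, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "MM (kDa)", y = "posterior probability",
                  subtitle = sprintf("MAP %.3g kDa, %d%% CI [%.3g, %.3g] kDa",
                                     object$map_mm, round(100 * object$ci_mass),
                                     object$ci_low, object$ci_high)) +
    ggplot2::theme_minimal()
}

#' Plot one or more ROC-like accuracy curves
#'
#' @param curves A tibble with columns `abs_error`, `frequency` and
#'   optionally `method` (to overlay several curves; see [roc_curve()]).
#' @return A ggplot object (log error axis; upper-left is better).
#' @export
plot_mm_roc <- function(curves) {
  stopifnot(all(c("abs_error", "frequency") %in% names(curves)))
  aes <- if ("method" %in% names(curves)) {
    ggplot2::aes(x = pmax(.data$abs_error, 1e-4), y = .data$frequency,
                 colour = .data$method)
  } else {
    ggplot2::aes(x = pmax(.data$abs_error, 1e-4), y = .data$frequency)
  }
  ggplot2::ggplot(curves, aes) +
    ggplot2::geom_step() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "|relative error|", y = "cumulative frequency") +
    ggplot2::theme_minimal()
}

#' Plot the best-method heatmap
#'
#' @param object An `mm_heatmap` from [best_method_heatmap()].
#' @param ... Unused.
#' @return A ggplot tile map of best-method fractions per shape class.
#' @export
autoplot.mm_heatmap <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$method, y = .data$shape_class,
                                       fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "best fraction") +
    ggplot2::theme_minimal()
}
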