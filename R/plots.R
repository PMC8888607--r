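# ggplot2 views of the evaluation results and LoA paths.

#' @describeIn bland_altman Bland-Altman plot: paired means against
#'   differences, with bias (solid) and limits of agreement (dashed).
#' @param object A `bland_altman` result.
#' @param ... Ignored.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
    ggplot2::geom_hline(
      yintercept = c(object$loa_low, object$loa_high),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::labs(
      x = "Mean of methods", y = "Difference (a - b)",
      title = sprintf(
        "Bland-Altman: bias %.3g +/- %.3g", object$bias, object$ci_half_width
      )
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn ols_fit Method-comparison scatter with the line of equality
#'   (dashed) and the fitted regression (red).
#' @param object An `ols_fit` result.
#' @param ... Ignored.
#' @method autoplot ols_fit
#' @export
autoplot.ols_fit <- function(object, ...) {
  ggplot2::ggplot(
    object$data,
    ggplot2::aes(x = .data[[object$a]], y = .data[[object$b]])
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_abline(
      slope = object$slope, intercept = object$intercept, colour = "red"
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      title = sprintf(
        "y = %.4g x + %.4g; adj. R2 = %.4f",
        object$slope, object$intercept, object$adjusted_r2
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a line of action in projection
#'
#' Shows the threaded centroid path (and the smoothed curve, if present)
#' projected onto a coordinate plane.
#'
#' @param object A `line_of_action`.
#' @param plane Projection plane: `"xy"`, `"xz"` or `"yz"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot line_of_action
#' @export
autoplot.line_of_action <- function(object, plane = c("xz", "xy", "yz"), ...) {
  plane <- match.arg(plane)
  ax <- strsplit(plane, "")[[1]]
  cols <- match(ax, c("x", "y", "z"))
  df <- tibble::tibble(
    h = object$points[, cols[1]], v = object$points[, cols[2]]
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$h, y = .data$v)) +
    ggplot2::geom_path(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = sprintf("%s (%s)", ax[1], object$unit),
      y = sprintf("%s (%s)", ax[2], object$unit),
      title = sprintf("Line of action (arc length %.4g %s)", object$arc_length, object$unit)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(object$smoothed)) {
    sm <- tibble::tibble(
      h = object$smoothed[, cols[1]], v = object$smoothed[, cols[2]]
    )
    p <- p + ggplot2::geom_path(data = sm, colour = "red")
  }
  p
}
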