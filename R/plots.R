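#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a conditional distance-delay curve
#'
#' Normalized mean topological distance against the delay bound on a
#' log10 x axis, with the fitted increasing-part slope overlaid when
#' `slope = TRUE`.
#'
#' @param object An `hg_distance_curve`.
#' @param slope Overlay the [fit_increasing_slope()] line (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hg_distance_curve
#' @export
autoplot.hg_distance_curve <- function(object, slope = TRUE, ...) {
  df <- object[!is.na(object$normalized), , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dt_steps, y = .data$normalized)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point(size = 0.8, colour = "#2c7fb8") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = expression(Delta * t ~ "(steps)"),
      y = "normalized mean topological distance",
      title = sprintf("%s distance-delay curve, d = %s",
                      sub("_", "-", attr(object, "kind")), attr(object, "d"))
    ) +
    ggplot2::theme_minimal()
  if (slope && sum(!is.na(object$normalized)) >= 3L) {
    fit <- fit_increasing_slope(object)
    rng <- object$dt_steps[fit$fit_range]
    seg <- tibble::tibble(
      x = seq(log10(rng[1L]), log10(rng[2L]), length.out = 20L)
    )
    seg$y <- fit$intercept + fit$m * seg$x
    p <- p + ggplot2::geom_line(
      data = seg, ggplot2::aes(x = 10^.data$x, y = .data$y),
      linetype = "dashed", colour = "grey30"
    ) +
      ggplot2::labs(subtitle = sprintf("slope m = %.3g per decade", fit$m))
  }
  p
}

#' Plot a binned cross-order or strength-degree relation
#'
#' Bin means with the reference diagonal `y = x` dashed. Axes follow the
#' curve's scale attribute (log-log for cross-order relations, linear for
#' strength versus degree).
#'
#' @param object An `hg_binned_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hg_binned_curve
#' @export
autoplot.hg_binned_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x_mean, y = .data$y_mean)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_line(colour = "#d95f02") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), colour = "#d95f02",
                        show.legend = FALSE) +
    ggplot2::scale_size_area(max_size = 3) +
    ggplot2::theme_minimal()
  if (identical(attr(object, "scale"), "log")) {
    p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      ggplot2::labs(
        x = sprintf("normalized %s (d = %s)", attr(object, "which"), attr(object, "d")),
        y = sprintf("normalized %s (d = %s)", attr(object, "which"), attr(object, "d2"))
      )
  } else {
    p <- p + ggplot2::labs(
      x = sprintf("degree k_%s", attr(object, "d")),
      y = sprintf("strength / omega (d = %s)", attr(object, "d"))
    )
  }
  p
}

#' Plot a center-active train-size distribution
#'
#' Empirical probabilities on log-log axes, annotated with the mean size.
#'
#' @param object An `hg_train_dist`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hg_train_dist
#' @export
autoplot.hg_train_dist <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$size, y = .data$prob)) +
    ggplot2::geom_point(colour = "#1b9e77") +
    ggplot2::geom_line(colour = "#1b9e77", alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "train size s", y = "Pr[S* = s]",
      title = sprintf("center-active trains, d = %s, delta_t = %s",
                      attr(object, "d"), attr(object, "delta_t")),
      subtitle = sprintf("mean size %.3g over %d trains",
                         attr(object, "mean_size"), attr(object, "n_trains"))
    ) +
    ggplot2::theme_minimal()
}
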