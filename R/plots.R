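#' @export
autoplot.fsi_result <- function(object, ...) {
  if (isTRUE(object$degenerate)) abort("Cannot plot a degenerate FSI result.")
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$omega, y = .data$r)) +
    ggplot2::geom_step(direction = "hv", colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(
      x = expression(omega ~ "(Hz)"),
      y = expression(R[omega]),
      title = sprintf("Frequency stability index = %.3f", object$fsi),
      subtitle = sprintf("Peak at %.3f Hz, band %g-%g Hz",
                         object$peak_freq, object$band[1], object$band[2])
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot the respiratory scalar, its envelopes and detected dips
#'
#' @param env An `envelope_pair` from [rm_envelopes()].
#' @param dips Optional dip tibble ([detect_dips()] / [find_dips()]) to
#'   shade.
#' @param xlim Optional time window in seconds.
#' @return A ggplot.
#' @export
plot_envelopes <- function(env, dips = NULL, xlim = NULL) {
  pl <- ggplot2::ggplot(env, ggplot2::aes(x = .data$t))
  if (!is.null(dips) && nrow(dips) > 0) {
    pl <- pl + ggplot2::geom_rect(
      data = dips,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey85"
    )
  }
  pl <- pl +
    ggplot2::geom_line(ggplot2::aes(y = .data$rms), colour = "grey50",
                       linewidth = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fast), colour = "forestgreen") +
    ggplot2::geom_line(ggplot2::aes(y = .data$slow), colour = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "respiratory scalar",
                  title = "Fast (green, 3 s) and slow (red, 20 s) 95th-percentile envelopes") +
    ggplot2::theme_minimal()
  if (!is.null(xlim)) pl <- pl + ggplot2::coord_cartesian(xlim = xlim)
  pl
}

#' @export
autoplot.envelope_pair <- function(object, dips = NULL, xlim = NULL, ...) {
  plot_envelopes(object, dips = dips, xlim = xlim)
}

#' @export
autoplot.subject_eval <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$ahi, y = .data$rei)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = c(15, 30), linetype = "dashed",
                        colour = "grey70") +
    ggplot2::geom_point(colour = "steelblue", size = 2) +
    ggplot2::labs(x = "reference AHI (events/h)",
                  y = "estimated REI (epochs/h)",
                  title = sprintf("Per-subject severity estimation (r = %.2f, n = %d)",
                                  object$r, object$n)) +
    ggplot2::theme_minimal()
}

#' Bar chart of scaled feature importance
#'
#' @param importance Tibble from [feature_importance()].
#' @return A ggplot.
#' @export
plot_feature_importance <- function(importance) {
  ggplot2::ggplot(importance,
                  ggplot2::aes(x = .data$importance,
                               y = stats::reorder(.data$feature, .data$importance))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "importance (0-100)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rfe_result <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$k, y = .data$accuracy)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$accuracy - .data$se,
                                          ymax = .data$accuracy + .data$se)) +
    ggplot2::labs(x = "number of features", y = "bootstrap accuracy",
                  title = "Recursive feature elimination profile") +
    ggplot2::theme_minimal()
}
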