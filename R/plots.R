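#' Two-panel trajectory figure
#'
#' Top panel: odds ratio over accrual with its confidence band and a
#' reference line at OR = 1 (log scale). Bottom panel: the two-sided P value
#' with the significance reference line at `alpha`. Optional vertical lines
#' mark interim events (for instance a planned recruitment end or an interim
#' analysis).
#'
#' @param traj a [trajectory].
#' @param events optional numeric vector of look sizes to mark with vertical
#'   lines.
#' @return A patchwork object (two stacked ggplots).
#' @export
plot_trajectory <- function(traj, events = NULL) {
  alpha <- attr(traj, "alpha") %||% 0.05
  df <- as.data.frame(traj)
  p_or <- ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$or)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "Odds ratio", x = NULL) +
    ggplot2::theme_minimal()
  if (nrow(df) > 0L) {
    p_or <- p_or + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      alpha = 0.2, fill = "steelblue")
  }
  p_p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$p)) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::geom_line(colour = "grey20") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(y = "P value", x = "Responders") +
    ggplot2::theme_minimal()
  if (!is.null(events)) {
    p_or <- p_or + ggplot2::geom_vline(xintercept = events, colour = "grey50")
    p_p <- p_p + ggplot2::geom_vline(xintercept = events, colour = "grey50")
  }
  patchwork::wrap_plots(p_or, p_p, ncol = 1)
}

#' Three-panel monitoring figure
#'
#' Stacked panels over accrual: median posterior odds ratio (reference line
#' at OR = 1), posterior probability of success, and posterior probability of
#' futility, the latter two with reference lines at their decision
#' thresholds.
#'
#' @param result a `monitoring_result` from [monitor()].
#' @param events optional look sizes to mark with vertical lines.
#' @return A patchwork object (three stacked ggplots).
#' @export
plot_monitoring <- function(result, events = NULL) {
  df <- result$looks
  rule <- result$rule
  panel <- function(y, ref, ylab, colour) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data[[y]])) +
      ggplot2::geom_hline(yintercept = ref, linetype = "dashed",
                          colour = "grey40") +
      ggplot2::geom_line(colour = colour) +
      ggplot2::labs(y = ylab, x = NULL) +
      ggplot2::theme_minimal()
    if (!is.null(events)) {
      p <- p + ggplot2::geom_vline(xintercept = events, colour = "grey50")
    }
    p
  }
  p1 <- panel("median_or", 1, "Median posterior OR", "steelblue") +
    ggplot2::scale_y_log10()
  p2 <- panel("prob_success", rule$success_prob_threshold,
              "P(success)", "darkgreen") +
    ggplot2::coord_cartesian(ylim = c(0, 1))
  p3 <- panel("prob_futility", rule$futility_prob_threshold,
              "P(futility)", "firebrick") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Responders")
  patchwork::wrap_plots(p1, p2, p3, ncol = 1)
}
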