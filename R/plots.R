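#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the segmented dose-response
#'
#' Scatter of the raw data with the fitted broken-stick mean and a
#' vertical line at the estimated breakpoint.
#'
#' @param object A `breakpoint_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot breakpoint_fit
#' @export
autoplot.breakpoint_fit <- function(object, ...) {
  df <- tibble::tibble(x = object$lm$model$xv, y = object$lm$model$yv)
  grid <- tibble::tibble(x = seq(min(df$x), max(df$x), length.out = 200))
  grid$y <- object$intercept + object$slope_below * grid$x +
    object$hinge_coef * pmax(grid$x - object$breakpoint, 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.35, colour = "grey30") +
    ggplot2::geom_line(data = grid, colour = "darkgreen",
                       linewidth = 1) +
    ggplot2::geom_vline(xintercept = object$breakpoint,
                        linetype = "dashed") +
    ggplot2::labs(x = object$x, y = object$y,
                  title = sprintf("Breakpoint at %.1f h", object$breakpoint))
}

#' Plot simulated trajectories
#'
#' Mean daily PSQI and PHQ-9 paths with +/- 1 SD ribbons and the clinical
#' threshold lines (PSQI > 7 insomnia, PHQ-9 >= 10 probable depression).
#'
#' @param object A `trajectory_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot trajectory_set
#' @export
autoplot.trajectory_set <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(day = object$day, score = "PSQI",
                   mean = object$mean_psqi, sd = object$sd_psqi,
                   threshold = 7),
    tibble::tibble(day = object$day, score = "PHQ-9",
                   mean = object$mean_phq9, sd = object$sd_phq9,
                   threshold = 10)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$threshold),
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~score, scales = "free_y") +
    ggplot2::labs(x = "Day", y = "Score")
}

#' Spearman correlation heatmap
#'
#' @param long Long-form output of [spearman_matrix()].
#' @return A ggplot mirroring the published correlation heatmap.
#' @export
plot_spearman <- function(long) {
  ggplot2::ggplot(long, ggplot2::aes(x = .data$var1, y = .data$var2,
                                     fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rho)),
                       size = 2.7) +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "rho") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Scenario dose-response panel
#'
#' Mean PSQI trajectories per adaptability group and demand multiplier.
#'
#' @param scenarios A [scenario_run()] result.
#' @param score `"psqi"` or `"phq9"`.
#' @return A ggplot.
#' @export
plot_scenarios <- function(scenarios, score = c("psqi", "phq9")) {
  score <- match.arg(score)
  ycol <- paste0("mean_", score)
  thr <- if (score == "psqi") 7 else 10
  ggplot2::ggplot(scenarios$trajectories,
                  ggplot2::aes(x = .data$day, y = .data[[ycol]],
                               colour = factor(.data$multiplier))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "Day", y = toupper(score),
                  colour = "Demand multiplier")
}
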