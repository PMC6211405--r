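#' Plot the population and park temperature trajectories
#' @param fit A `trajectory_fit`.
#' @return A ggplot object: posterior mean of `w(t)` with 90% band, park
#'   trajectories in grey.
#' @export
plot_trajectory_fit <- function(fit) {
  dfw <- tibble::tibble(lag = fit$lag, mean = fit$post$w_mean,
                        q05 = fit$post$w_q05, q95 = fit$post$w_q95)
  dfu <- dplyr::bind_rows(lapply(seq_along(fit$park_id), function(i)
    tibble::tibble(lag = fit$lag, park = fit$park_id[i],
                   u = fit$post$u_mean[i, ])))
  ggplot2::ggplot(dfw, ggplot2::aes(x = .data$lag)) +
    ggplot2::geom_line(data = dfu,
                       ggplot2::aes(y = .data$u, group = .data$park),
                       colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q05, ymax = .data$q95),
                         fill = "red", alpha = 0.15) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "red") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "days from event", y = "temperature (degC)") +
    ggplot2::theme_minimal()
}

#' Plot the global coefficient curves with pointwise 90% bands
#' @param fit An `event_model_fit`.
#' @export
plot_coefficient_curves <- function(fit) {
  df <- dplyr::bind_rows(
    tibble::tibble(day = fit$grid, coef = "alpha (days/degC)",
                   mean = fit$post$alpha_mean, q05 = fit$post$alpha_q05,
                   q95 = fit$post$alpha_q95),
    tibble::tibble(day = fit$grid, coef = "beta (days/cm)",
                   mean = fit$post$beta_mean, q05 = fit$post$beta_q05,
                   q95 = fit$post$beta_q95))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q05, ymax = .data$q95),
                         alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::facet_wrap(~coef, scales = "free_y") +
    ggplot2::labs(x = "day of year", y = "effect on event day") +
    ggplot2::theme_minimal()
}

#' Heatmap of a window-sum credibility surface
#' @param surface A `credibility_surface` from [window_sum_credibility()].
#' @export
plot_credibility_surface <- function(surface) {
  grid <- attr(surface, "grid")
  df <- expand.grid(t1 = grid, t2 = grid)
  df$p <- as.vector(unclass(surface))
  df <- df[!is.na(df$p), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t2, y = .data$t1,
                                   fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 0.5, low = "blue",
                                  high = "red", limits = c(0, 1),
                                  name = "P(sum >= 0)") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "t2", y = "t1") +
    ggplot2::theme_minimal()
}
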