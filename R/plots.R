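#' Spike raster plot
#'
#' @param raster a `spike_raster` tibble.
#' @param populations optional subset of populations to show.
#' @return A ggplot object.
#' @export
plot_raster <- function(raster, populations = NULL) {
  if (!is.null(populations)) {
    raster <- filter(raster, .data$population %in% populations)
  }
  ggplot2::ggplot(raster, ggplot2::aes(x = .data$t, y = .data$neuron)) +
    ggplot2::geom_point(shape = ".", alpha = 0.6) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$population),
                        scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "neuron") +
    ggplot2::theme_minimal()
}

#' Population rate plot with optional burst shading
#'
#' @param rate a `rate_series` from [population_rate()].
#' @param bursts optional `burst_stats` from [detect_bursts()].
#' @return A ggplot object.
#' @export
plot_rate <- function(rate, bursts = NULL) {
  p <- ggplot2::ggplot(rate, ggplot2::aes(x = .data$t, y = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "population rate (Hz)") +
    ggplot2::theme_minimal()
  if (!is.null(bursts) && nrow(bursts$bursts)) {
    p <- p + ggplot2::geom_rect(
      data = bursts$bursts,
      ggplot2::aes(xmin = .data$onset, xmax = .data$offset,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.2
    )
  }
  p
}

#' @describeIn plot_rate autoplot method for rate series
#' @param object a `rate_series`.
#' @param ... passed on.
#' @method autoplot rate_series
#' @export
autoplot.rate_series <- function(object, ...) plot_rate(object, ...)

#' @describeIn plot_raster autoplot method for spike rasters
#' @param object a `spike_raster`.
#' @param ... passed on.
#' @method autoplot spike_raster
#' @export
autoplot.spike_raster <- function(object, ...) plot_raster(object, ...)

#' Gait profile plot (stretch, velocity, EMG envelope)
#'
#' @param profile a `gait_profile`.
#' @return A ggplot object.
#' @export
plot_gait <- function(profile) {
  long <- tidyr::pivot_longer(as_tibble(profile), -"t")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$name), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = paste("synthetic gait:", attr(profile, "muscle"))) +
    ggplot2::theme_minimal()
}

#' Posterior seed trajectories from an equivalence fit
#'
#' @param fit a `seed_equiv_fit`.
#' @return A ggplot of observed per-seed step rates with the fitted
#'   condition trajectory.
#' @export
plot_equivalence <- function(fit) {
  bd <- fit$design
  idx <- fit$index
  a_mean <- colMeans(fit$draws[, idx$a, drop = FALSE])
  beta_mean <- matrix(colMeans(fit$draws[, idx$beta, drop = FALSE]),
                      bd$Kq, bd$n_cond)
  grid <- seq(0, 1, length.out = 101)
  Bg <- splines::splineDesign(bd$knots, grid, ord = bd$degree + 1) %*% bd$Q
  traj <- purrr::map_dfr(seq_len(bd$n_cond), function(c) {
    tibble(condition = bd$conditions[c], t = grid,
           y = as.numeric(a_mean[c] + Bg %*% beta_mean[, c]))
  })
  obs <- bd$data
  obs$t <- bd$t
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$t, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$seed)),
                        alpha = 0.6, show.legend = FALSE) +
    ggplot2::geom_line(data = traj, linewidth = 1) +
    ggplot2::facet_wrap(~condition, scales = "free_y") +
    ggplot2::labs(x = "rescaled step time", y = "mean firing rate (Hz)") +
    ggplot2::theme_minimal()
}
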