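# ggplot2 visualisations of the main result types.

#' Plot a fitted partition distribution
#'
#' ECDF of the folded fractions with the fitted exponential-suppression
#' cumulative model and the linear random-splitting null.
#'
#' @param object a `partition_fit` from [fit_partition_cdf()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.partition_fit <- function(object, ...) {
  x <- attr(object, "x")
  h <- attr(object, "h")
  grid <- tibble(x = seq(0.5, 1, length.out = 200))
  grid$model <- if (object$lambda > 0) 1 - exp(-(grid$x - 0.5) / object$lambda) else as.numeric(grid$x >= 0.5)
  grid$null <- 2 * (grid$x - 0.5)
  ggplot2::ggplot() +
    ggplot2::geom_step(data = tibble(x = x, F = cumsum(rep(1 / length(x), length(x)))),
                       ggplot2::aes(.data$x, .data$F), colour = "grey30") +
    ggplot2::geom_line(data = grid, ggplot2::aes(.data$x, .data$model),
                       colour = "#d53e9c", linetype = "dashed") +
    ggplot2::geom_line(data = grid, ggplot2::aes(.data$x, .data$null),
                       colour = "#c0392b") +
    ggplot2::labs(
      x = "fraction of mother chain in larger daughter",
      y = "cumulative probability",
      title = sprintf("Partition accuracy: lambda = %.3f, median = %.3f",
                      object$lambda, object$median),
      subtitle = "dashed: exponential-suppression fit; solid red: random-splitting null") +
    ggplot2::theme_minimal()
}

#' Plot a fluorescence recovery fit
#'
#' @param object a `recovery_fit` from [fit_recovery()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.recovery_fit <- function(object, ...) {
  df <- attr(object, "data")
  grid <- tibble(t = seq(0, max(df$t), length.out = 200))
  grid$fit <- object$A * (1 - exp(-object$k * grid$t)) + object$F0
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$y)) +
    ggplot2::geom_point(size = 1, colour = "grey30") +
    ggplot2::geom_line(data = grid, ggplot2::aes(.data$t, .data$fit),
                       colour = "#2980b9") +
    ggplot2::labs(x = "time post-bleach (s)", y = "normalized intensity",
                  title = sprintf("Recovery: t1/2 = %.1f s, mobile fraction = %.2f",
                                  object$t_half, object$mobile_fraction)) +
    ggplot2::theme_minimal()
}

#' Plot a simulated chain trajectory
#'
#' Particle positions along the cell axis over time, with midcell marked.
#'
#' @param object an `mc_trajectory` from [simulate_chain()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.mc_trajectory <- function(object, ...) {
  cfg <- attr(object, "config")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$t_s, .data$x_nm,
                               group = .data$particle_id)) +
    ggplot2::geom_line(alpha = 0.6, linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = cfg$L / 2, linetype = "dotted") +
    ggplot2::labs(x = "time (s)", y = "position along cell axis (nm)",
                  title = sprintf("%d magnetosomes, F_s = %g pN, D = %g nm²/s",
                                  cfg$n_particles, cfg$F_s, cfg$D)) +
    ggplot2::theme_minimal()
}

#' Plot ensemble track statistics
#'
#' Mean with standard-error ribbon against time, for the output of
#' [cumulative_displacement()], [track_msd()] or [apparent_diffusion()].
#'
#' @param stat a tibble with `t_min` and one of `mean_nm`, `msd_nm2`,
#'   `dstar_nm2_min`, plus a matching `sem_*` column where available.
#' @return A ggplot.
#' @export
plot_track_stat <- function(stat) {
  ycol <- intersect(c("mean_nm", "msd_nm2", "dstar_nm2_min"), names(stat))[1]
  if (is.na(ycol)) abort("no recognised statistic column in `stat`.")
  semcol <- c(mean_nm = "sem_nm", msd_nm2 = "sem_nm2", dstar_nm2_min = "")[[ycol]]
  lab <- c(mean_nm = "cumulative displacement (nm)",
           msd_nm2 = "MSD (nm²)",
           dstar_nm2_min = "apparent diffusion D* (nm²/min)")[[ycol]]
  p <- ggplot2::ggplot(stat, ggplot2::aes(.data$t_min, .data[[ycol]]))
  if (nzchar(semcol) && semcol %in% names(stat)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data[[ycol]] - .data[[semcol]],
                   ymax = .data[[ycol]] + .data[[semcol]]),
      fill = "grey80")
  }
  p + ggplot2::geom_line(colour = "#27ae60") +
    ggplot2::labs(x = "time (min)", y = lab) +
    ggplot2::theme_minimal()
}
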