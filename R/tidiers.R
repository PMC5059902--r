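# broom-style tidiers for the fitted objects.

#' @describeIn fit_partition_cdf tidy(): one row per parameter.
#' @param x a `partition_fit`.
#' @param ... unused.
#' @export
tidy.partition_fit <- function(x, ...) {
  tibble(term = "lambda", estimate = x$lambda, std.error = x$lambda_se)
}

#' @describeIn fit_partition_cdf glance(): one-row model summary.
#' @export
glance.partition_fit <- function(x, ...) {
  tibble(lambda = x$lambda, lambda_mle = x$lambda_mle, median = x$median,
         fit_R = x$fit_R, r_squared = x$r_squared, n = x$n,
         degenerate = x$degenerate)
}

#' @describeIn fit_recovery tidy(): one row per parameter.
#' @param x a `recovery_fit`.
#' @param ... unused.
#' @export
tidy.recovery_fit <- function(x, ...) {
  tibble(term = c("A", "k", "F0"),
         estimate = c(x$A, x$k, x$F0),
         std.error = c(x$A_se, x$k_se, x$F0_se))
}

#' @describeIn fit_recovery glance(): one-row fit summary.
#' @export
glance.recovery_fit <- function(x, ...) {
  tibble(t_half = x$t_half, t_half_se = x$t_half_se,
         mobile_fraction = x$mobile_fraction,
         no_recovery = x$no_recovery, converged = x$converged, n = x$n)
}

#' @describeIn fit_zone_kinetics tidy(): one row per parameter.
#' @param x a `zone_fit`.
#' @param ... unused.
#' @export
tidy.zone_fit <- function(x, ...) {
  tibble(term = c("amplitude", "rate", "offset"),
         estimate = c(x$amplitude, x$rate, x$offset),
         std.error = c(x$amplitude_se, x$rate_se, NA_real_))
}

#' @describeIn fit_zone_kinetics glance(): one-row fit summary.
#' @export
glance.zone_fit <- function(x, ...) {
  tibble(half_time = x$half_time, rate = x$rate, direction = x$direction,
         flat = x$flat, n = x$n)
}
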