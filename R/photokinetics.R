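# FRAP / photoconversion quantification. Intensity traces arrive as tidy
# tables with one row per frame: cell_id, zone, t_s, roi, cell, bg,
# event_frame (1-based frame index of the laser pulse, constant per trace).

check_trace <- function(trace, min_pre = 3) {
  need <- c("t_s", "roi", "cell", "bg", "event_frame")
  miss <- setdiff(need, names(trace))
  if (length(miss) > 0)
    abort(paste0("trace lacks column(s): ", paste(miss, collapse = ", ")))
  ev <- unique(trace$event_frame)
  if (length(ev) != 1 || ev < 1 || ev > nrow(trace))
    abort("`event_frame` must be a single in-range frame index.")
  denom <- trace$cell - trace$bg
  if (any(denom <= 0)) {
    abort(sprintf("whole-cell intensity must exceed background (first offending frame: %d)",
                  which(denom <= 0)[1]))
  }
  if (ev - 1 < min_pre)
    abort(sprintf("need at least %d pre-event frames, got %d", min_pre, ev - 1))
  ev
}

#' Normalize a FRAP trace against whole-cell fluorescence
#'
#' Double normalization: per frame, the background-subtracted ROI intensity is
#' divided by the background-subtracted whole-cell intensity (so acquisition
#' bleaching, which scales both, cancels), and the resulting ratio is divided
#' by its own pre-event mean. A value of 1 is the pre-bleach level of the ROI
#' corrected for whole-cell fluorescence; the pre-event mean of the output is
#' exactly 1. Scaling all raw intensities by a common constant leaves the
#' output unchanged.
#'
#' @param trace one trace: a tibble with `t_s`, `roi`, `cell`, `bg`,
#'   `event_frame` (1-based pulse frame, constant within the trace).
#' @param double if `FALSE`, skip the division by the pre-event mean
#'   (single normalization).
#' @return The trace with columns `norm` (normalized relative intensity),
#'   `post` (logical) and `t_post_s` (time since the event; `NA` pre-event).
#' @export
normalize_frap <- function(trace, double = TRUE) {
  ev <- check_trace(trace)
  out <- as_tibble(trace)
  ratio <- (out$roi - out$bg) / (out$cell - out$bg)
  pre_mean <- mean(ratio[seq_len(ev - 1)])
  out$norm <- if (double) ratio / pre_mean else ratio
  out$post <- seq_len(nrow(out)) >= ev
  out$t_post_s <- ifelse(out$post, out$t_s - out$t_s[ev], NA_real_)
  out
}

#' Fit single-exponential fluorescence recovery
#'
#' Nonlinear least squares of `F(t) = A (1 - exp(-k t)) + F0` to post-event
#' normalized intensities, `t` measured from immediately after the laser
#' pulse. Returns the recovery half-time `t_half = ln 2 / k` with a
#' first-order propagated standard error, and the mobile fraction
#' `A / (1 - F0)`: the fitted plateau recovery relative to the pre-bleach
#' level above the post-bleach floor (full recovery to 1 gives mobile
#' fraction 1). The fit is flagged `no_recovery` when the 95 % confidence
#' interval of `A` includes 0, the behaviour expected of fixed-cell
#' (dark-state) controls.
#'
#' Initial values: `F0` = first post-event value, `A` = last - first,
#' `k` = ln 2 / (time to half range); bounded restarts on failure.
#'
#' @param times_post_event times since the pulse, s.
#' @param values normalized intensities (from [normalize_frap()]).
#' @return A `recovery_fit` object with elements `A`, `k`, `F0`, their
#'   standard errors, `t_half`, `t_half_se`, `mobile_fraction`,
#'   `no_recovery`, `converged`, `n`. Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
fit_recovery <- function(times_post_event, values) {
  if (length(times_post_event) < 5) abort("need at least 5 post-event points.")
  if (length(times_post_event) != length(values)) abort("times and values differ in length.")
  df <- tibble(t = times_post_event - min(times_post_event), y = values)

  F0_init <- df$y[1]
  A_init <- df$y[nrow(df)] - df$y[1]
  halfway <- F0_init + A_init / 2
  t_half_guess <- df$t[which(df$y >= halfway)[1]]
  if (is.na(t_half_guess) || t_half_guess <= 0) t_half_guess <- max(df$t) / 4
  starts <- list(
    list(A = max(A_init, 1e-3), k = log(2) / t_half_guess, F0 = F0_init),
    list(A = 0.5, k = 1 / max(df$t), F0 = F0_init),
    list(A = 0.1, k = 10 / max(df$t), F0 = mean(df$y)))

  mod <- NULL
  for (st in starts) {
    mod <- tryCatch(
      minpack.lm::nlsLM(y ~ A * (1 - exp(-k * t)) + F0, data = df, start = st,
                        lower = c(A = 0, k = 1e-10, F0 = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(mod)) break
  }
  if (is.null(mod)) {
    res <- df$y - mean(df$y)
    abort(sprintf(
      "recovery fit did not converge after %d restarts (residual sd of a flat model: %.3g)",
      length(starts), sd(res)))
  }
  co <- coef(mod)
  se <- sqrt(diag(vcov(mod)))
  k <- unname(co[["k"]])
  A <- unname(co[["A"]])
  F0 <- unname(co[["F0"]])
  no_recovery <- (A - qnorm(0.975) * se[["A"]]) <= 0
  structure(list(
    A = A, k = k, F0 = F0,
    A_se = unname(se[["A"]]), k_se = unname(se[["k"]]), F0_se = unname(se[["F0"]]),
    t_half = log(2) / k,
    t_half_se = log(2) * se[["k"]] / k^2,
    mobile_fraction = A / (1 - F0),
    no_recovery = no_recovery,
    converged = TRUE,
    n = nrow(df)
  ), class = "recovery_fit", data = df)
}

#' Normalize photoconversion zone traces
#'
#' Applies the whole-cell correction of [normalize_frap()] to the three zone
#' traces of a photoconversion experiment (photoconverted pole, non-polar
#' area, opposite pole) and scales all three by the photoconverted zone's
#' corrected intensity at t = 0 post-pulse, the maximum signal obtainable, so
#' the converted zone starts at exactly 1.
#'
#' @param zone_traces tibble with columns `zone` (values
#'   `photoconverted_pole`, `non_polar`, `opposite_pole`), `t_s`, `roi`,
#'   `cell`, `bg`, `event_frame`.
#' @return The input with `norm`, `post`, `t_post_s` appended.
#' @export
normalize_photoconversion <- function(zone_traces) {
  zones <- c("photoconverted_pole", "non_polar", "opposite_pole")
  if (!"zone" %in% names(zone_traces)) abort("zone_traces must have a `zone` column.")
  miss <- setdiff(zones, unique(zone_traces$zone))
  if (length(miss) > 0)
    abort(paste0("missing zone trace(s): ", paste(miss, collapse = ", ")))
  per <- zone_traces |>
    dplyr::group_by(.data$zone) |>
    dplyr::group_modify(function(.x, ...) {
      ev <- check_trace(.x, min_pre = 1)
      out <- .x
      out$ratio <- (out$roi - out$bg) / (out$cell - out$bg)
      out$post <- seq_len(nrow(out)) >= ev
      out$t_post_s <- ifelse(out$post, out$t_s - out$t_s[ev], NA_real_)
      out
    }) |>
    dplyr::ungroup()
  conv0 <- per |>
    dplyr::filter(.data$zone == "photoconverted_pole", .data$post) |>
    dplyr::slice_min(.data$t_post_s, n = 1, with_ties = FALSE)
  if (conv0$ratio <= 0)
    abort("photoconverted-zone intensity at t = 0 must exceed background.")
  per |>
    dplyr::mutate(norm = .data$ratio / conv0$ratio) |>
    dplyr::select(-"ratio")
}

#' Fit single-exponential zone kinetics (rise or decay)
#'
#' Rise: `A (1 - exp(-k t)) + F0`; decay: `A exp(-k t) + C`. Returns the
#' half-time `ln 2 / k`. A fitted amplitude at (or below) zero triggers a
#' direction-mismatch warning; an essentially constant series yields rate 0
#' and an infinite half-time with the `flat` flag set.
#'
#' @param times times since the pulse, s.
#' @param values normalized zone intensities.
#' @param direction `"rise"` or `"decay"`.
#' @return A `zone_fit` object: `half_time`, `rate`, `amplitude`, `offset`,
#'   standard errors, `flat`, `direction`.
#' @export
fit_zone_kinetics <- function(times, values, direction = c("rise", "decay")) {
  direction <- match.arg(direction)
  if (length(times) < 5) abort("need at least 5 points.")
  df <- tibble(t = times - min(times), y = values)
  rng <- diff(range(df$y))
  if (rng < 1e-10 * max(abs(df$y), 1)) {
    return(structure(list(half_time = Inf, rate = 0, amplitude = 0,
                          offset = mean(df$y), rate_se = NA_real_,
                          amplitude_se = NA_real_, flat = TRUE,
                          direction = direction, n = nrow(df)),
                     class = "zone_fit", data = df))
  }
  form <- if (direction == "rise") y ~ A * (1 - exp(-k * t)) + C else y ~ A * exp(-k * t) + C
  A0 <- if (direction == "rise") df$y[nrow(df)] - df$y[1] else df$y[1] - df$y[nrow(df)]
  st <- list(A = A0, k = log(2) / (max(df$t) / 4),
             C = if (direction == "rise") df$y[1] else df$y[nrow(df)])
  mod <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = st,
                      lower = c(A = -Inf, k = 1e-10, C = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) abort(paste0("zone kinetics fit failed: ", conditionMessage(e))))
  co <- coef(mod)
  se <- sqrt(diag(vcov(mod)))
  if (co[["A"]] <= 0)
    warn(sprintf("fitted amplitude is not positive (%.3g): data trend does not match direction '%s'",
                 co[["A"]], direction))
  structure(list(
    half_time = log(2) / co[["k"]],
    rate = unname(co[["k"]]),
    amplitude = unname(co[["A"]]),
    offset = unname(co[["C"]]),
    rate_se = unname(se[["k"]]),
    amplitude_se = unname(se[["A"]]),
    flat = FALSE,
    direction = direction,
    n = nrow(df)
  ), class = "zone_fit", data = df)
}

#' Treadmilling speed from a kymograph front line
#'
#' Ordinary least-squares slope of the filament growth-front position versus
#' time, in nm/min. Needs at least `min_frames` consecutive frames (four
#' 30-s frames, a 90-s interval, by default), starting once the front is
#' distinguishable (typically 60 s post-bleach). Invariant under shifts of
#' the time origin and position offset.
#'
#' @param times_s frame times, s.
#' @param front_nm front-line positions, nm.
#' @param min_frames minimal number of frames.
#' @param noise_tol tolerance (nm) beyond which a net backwards front motion
#'   triggers a warning.
#' @return A list: `speed_nm_min`, `se_nm_min`, `n`.
#' @export
#' @examples
#' treadmilling_speed(c(60, 90, 120, 150), c(0, 157, 313, 470))
treadmilling_speed <- function(times_s, front_nm, min_frames = 4, noise_tol = 60) {
  if (length(times_s) < min_frames)
    abort(sprintf("need at least %d frames, got %d", min_frames, length(times_s)))
  if (length(times_s) != length(front_nm)) abort("times and positions differ in length.")
  ord <- order(times_s)
  t <- times_s[ord]; p <- front_nm[ord]
  drops <- diff(p)
  if (any(drops < -noise_tol))
    warn("front line moves backwards beyond noise tolerance; speed may be unreliable")
  fit <- lm(p ~ t)
  # summary.lm warns on zero-residual fits; noiseless fronts are legitimate
  sm <- suppressWarnings(summary(fit)$coefficients)
  list(speed_nm_min = unname(coef(fit)[["t"]]) * 60,
       se_nm_min = unname(sm["t", "Std. Error"]) * 60,
       n = length(t))
}

#' Treadmilling speeds for a table of fronts
#'
#' @param fronts tibble with columns `filament_id`, `t_s`, `front_nm`.
#' @param ... passed to [treadmilling_speed()].
#' @return A tibble `filament_id`, `speed_nm_min`, `se_nm_min`, `n`.
#' @export
treadmill_speeds <- function(fronts, ...) {
  need <- c("filament_id", "t_s", "front_nm")
  miss <- setdiff(need, names(fronts))
  if (length(miss) > 0)
    abort(paste0("fronts table lacks column(s): ", paste(miss, collapse = ", ")))
  dots <- list(...)
  fronts |>
    dplyr::group_by(.data$filament_id) |>
    dplyr::group_modify(function(.x, .y) {
      as_tibble(do.call(treadmilling_speed, c(list(.x$t_s, .x$front_nm), dots)))
    }) |>
    dplyr::ungroup()
}

#' Correlation of treadmilling speed with FRAP recovery half-time
#'
#' Pearson correlation (with the two-sided t-test on r, df = n - 2) and OLS
#' line across strain means of filament treadmilling speed and fluorescence
#' recovery half-time.
#'
#' @param pairs tibble with columns `speed_nm_min` and `t_half_s` (one row
#'   per strain), optionally `strain`.
#' @return A list: `pearson_r`, `p_value`, `slope`, `intercept`, `n`.
#' @export
speed_t12_correlation <- function(pairs) {
  need <- c("speed_nm_min", "t_half_s")
  miss <- setdiff(need, names(pairs))
  if (length(miss) > 0)
    abort(paste0("pairs table lacks column(s): ", paste(miss, collapse = ", ")))
  if (nrow(pairs) < 3) abort("need at least 3 strain pairs.")
  if (sd(pairs$speed_nm_min) == 0 || sd(pairs$t_half_s) == 0)
    abort("correlation undefined: zero variance in speed or half-time.")
  ct <- stats::cor.test(pairs$speed_nm_min, pairs$t_half_s, method = "pearson")
  fit <- lm(t_half_s ~ speed_nm_min, data = pairs)
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = nrow(pairs))
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf(
    "<recovery_fit> F(t) = A(1 - exp(-k t)) + F0, n = %d\n  A = %.4f (SE %.4f), k = %.5g /s, F0 = %.4f\n  t_half = %.2f s (SE %.2f), mobile fraction = %.3f%s\n",
    x$n, x$A, x$A_se, x$k, x$F0, x$t_half, x$t_half_se, x$mobile_fraction,
    if (x$no_recovery) " [no recovery]" else ""))
  invisible(x)
}

#' @export
print.zone_fit <- function(x, ...) {
  cat(sprintf("<zone_fit> %s, half-time = %.2f s, rate = %.5g /s%s\n",
              x$direction, x$half_time, x$rate,
              if (x$flat) " [flat series]" else ""))
  invisible(x)
}
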