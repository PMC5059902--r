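# FRAP / photoconversion normalization and kinetics, treadmilling, correlation.

frap_trace <- function(pre, post, pre_n = 3, post_n = 3, bg = 10) {
  nf <- pre_n + post_n
  tibble::tibble(
    t_s = seq(0, by = 10, length.out = nf),
    roi = c(rep(pre[1], pre_n), rep(post[1], post_n)),
    cell = c(rep(pre[2], pre_n), rep(post[2], post_n)),
    bg = bg, event_frame = pre_n + 1)
}

test_that("FRAP double normalization matches the hand-computed ratio", {
  tr <- frap_trace(pre = c(60, 110), post = c(20, 100))
  nr <- normalize_frap(tr)
  expect_equal(mean(nr$norm[!nr$post]), 1, tolerance = 1e-12)
  # post value: ((20-10)/(100-10)) / ((60-10)/(110-10)) = (10/90)/(50/100)
  expect_equal(unique(nr$norm[nr$post]), (10 / 90) / (50 / 100), tolerance = 1e-12)
})

test_that("whole-cell correction cancels acquisition bleaching and scale", {
  # ROI proportional to whole cell at every frame -> constant 1
  cell <- 10 + 1000 * exp(-0.01 * (0:9))
  tr <- tibble::tibble(t_s = (0:9) * 10, roi = 10 + 0.25 * (cell - 10),
                       cell = cell, bg = 10, event_frame = 4)
  expect_equal(normalize_frap(tr)$norm, rep(1, 10), tolerance = 1e-12)
  # global intensity scaling leaves the output unchanged
  tr2 <- frap_trace(pre = c(60, 110), post = c(20, 100))
  tr3 <- dplyr::mutate(tr2, roi = roi * 7.5, cell = cell * 7.5, bg = bg * 7.5)
  expect_equal(normalize_frap(tr3)$norm, normalize_frap(tr2)$norm, tolerance = 1e-12)
  bad <- dplyr::mutate(tr2, cell = ifelse(dplyr::row_number() == 5, 5, cell))
  expect_error(normalize_frap(bad), "frame")
})

test_that("recovery fitting is exact on noiseless data and flags flat traces", {
  A <- 0.8; k <- 0.01; F0 <- 0.2
  t <- seq(0, 400, by = 10)
  fit <- fit_recovery(t, A * (1 - exp(-k * t)) + F0)
  expect_lt(abs(fit$A - A) / A, 1e-6)
  expect_lt(abs(fit$k - k) / k, 1e-6)
  expect_lt(abs(fit$F0 - F0) / F0, 1e-6)
  expect_equal(fit$t_half, log(2) / 0.01, tolerance = 1e-6) # 69.31 s
  expect_equal(fit$t_half * fit$k, log(2), tolerance = 1e-12) # exact identity
  expect_equal(fit$mobile_fraction, 1, tolerance = 1e-6) # A = 1 - F0 here
  expect_false(fit$no_recovery)
  # fixed-cell control: flat post-event trace
  set.seed(5)
  flat <- fit_recovery(t, 0.2 + rnorm(length(t), 0, 0.01))
  expect_true(flat$no_recovery)
  expect_error(fit_recovery(1:3, 1:3), "5 post-event")
})

test_that("noisy recovery replicates recover the generating half-time", {
  k <- log(2) / 68.3
  t <- seq(0, 300, by = 10)
  set.seed(21)
  t_halves <- replicate(30, {
    y <- 0.8 * (1 - exp(-k * t)) + 0.2 + rnorm(length(t), 0, 0.05)
    fit_recovery(t, y)$t_half
  })
  expect_lt(abs(mean(t_halves) - 68.3) / 68.3, 0.05)
})

test_that("zone kinetics fit rise and decay with matching half-times", {
  t <- seq(0, 900, by = 15)
  k <- log(2) / 187.8
  dec <- fit_zone_kinetics(t, exp(-k * t), direction = "decay")
  expect_equal(dec$half_time, 187.8, tolerance = 1e-6)
  # constant series: rate ~ 0, infinite half-time flag
  flat <- fit_zone_kinetics(t, rep(0.4, length(t)), direction = "rise")
  expect_true(flat$flat)
  expect_equal(flat$rate, 0)
  expect_equal(flat$half_time, Inf)
  # paired decay/rise sharing one true rate agree within 2 SE
  set.seed(9)
  y_dec <- exp(-k * t) + rnorm(length(t), 0, 0.02)
  y_ris <- 1 - exp(-k * t) + rnorm(length(t), 0, 0.02)
  f1 <- fit_zone_kinetics(t, y_dec, "decay")
  f2 <- fit_zone_kinetics(t, y_ris, "rise")
  se12 <- log(2) * sqrt((f1$rate_se / f1$rate^2)^2 + (f2$rate_se / f2$rate^2)^2)
  expect_lt(abs(f1$half_time - f2$half_time), 2 * se12)
  expect_warning(fit_zone_kinetics(t, exp(-k * t), direction = "rise"), "direction")
})

test_that("photoconversion normalization anchors the converted pole at 1", {
  zt <- gen_photoconversion(k1 = log(2) / 187.8, k2 = log(2) / 400,
                            noise_sd = 0, seed = 2)
  nz <- normalize_photoconversion(zt)
  conv <- nz |> dplyr::filter(zone == "photoconverted_pole", post)
  expect_equal(conv$norm[1], 1, tolerance = 1e-12)
  # conserved total: the three zones sum to a constant over post-pulse time
  sums <- nz |> dplyr::filter(post) |>
    dplyr::group_by(t_post_s) |> dplyr::summarise(s = sum(norm))
  expect_equal(sums$s, rep(sums$s[1], nrow(sums)), tolerance = 1e-9)
  # static filaments: all zones flat
  zt0 <- gen_photoconversion(k1 = 0, k2 = 0, noise_sd = 0, seed = 2)
  nz0 <- normalize_photoconversion(zt0) |> dplyr::filter(post)
  spread <- nz0 |> dplyr::group_by(zone) |>
    dplyr::summarise(rng = diff(range(norm)))
  expect_true(all(spread$rng < 1e-9))
  expect_error(normalize_photoconversion(dplyr::filter(zt, zone != "non_polar")),
               "non_polar")
})

test_that("treadmilling speed is the OLS front slope in nm/min", {
  # near-perfect line traced at 30-s frames: slope 5.22 nm/s = 313.2 nm/min
  res <- treadmilling_speed(c(60, 90, 120, 150), c(0, 157, 313, 470))
  expect_equal(res$speed_nm_min, 313.2, tolerance = 1e-10)
  expect_equal(treadmilling_speed(c(60, 90, 120, 150), rep(5, 4))$speed_nm_min, 0)
  expect_error(treadmilling_speed(c(60, 90, 120), c(0, 1, 2)), "4 frames")
  expect_warning(treadmilling_speed(c(60, 90, 120, 150), c(400, 300, 150, 0)),
                 "backwards")
  # invariance under time-origin shift and position offset
  a <- treadmilling_speed(c(60, 90, 120, 150), c(0, 157, 313, 470))
  b <- treadmilling_speed(c(60, 90, 120, 150) + 300, c(0, 157, 313, 470) + 1000)
  expect_equal(a$speed_nm_min, b$speed_nm_min, tolerance = 1e-10)
})

test_that("speed vs recovery half-time correlation reproduces the strain-mean r", {
  strains <- tibble::tibble(
    strain = c("chromosomal", "plasmid WT", "plasmid dmamK",
               "plasmid dmamJK", "plasmid MSR-1B"),
    speed_nm_min = c(313, 337, 313, 200, 261),
    t_half_s = c(68.3, 71.8, 62.2, 98.4, 89.3))
  res <- speed_t12_correlation(strains)
  expect_equal(res$pearson_r, -0.9097, tolerance = 0.002)
  expect_gt(res$p_value, 0.01)
  expect_lt(res$p_value, 0.05)
  # perfectly collinear pairs
  col <- tibble::tibble(speed_nm_min = c(1, 2, 3, 4), t_half_s = c(8, 6, 4, 2))
  expect_equal(speed_t12_correlation(col)$pearson_r, -1)
  # three points against the direct covariance formula
  p3 <- tibble::tibble(speed_nm_min = c(300, 250, 210), t_half_s = c(60, 95, 80))
  hand <- sum((p3$speed_nm_min - mean(p3$speed_nm_min)) *
              (p3$t_half_s - mean(p3$t_half_s))) /
    sqrt(sum((p3$speed_nm_min - mean(p3$speed_nm_min))^2) *
         sum((p3$t_half_s - mean(p3$t_half_s))^2))
  expect_equal(speed_t12_correlation(p3)$pearson_r, hand, tolerance = 1e-12)
  expect_error(speed_t12_correlation(
    tibble::tibble(speed_nm_min = c(1, 1, 1), t_half_s = c(1, 2, 3))), "variance")
})
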