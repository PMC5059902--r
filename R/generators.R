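# Seeded synthetic-data generators. Each generator emits the exact tidy
# schema its consuming estimator expects and records its parameters and seed
# as attributes, so every pipeline stage can be exercised end to end without
# raw imaging data. Defaults are anchored to the measured scales of
# magnetosome-chain biology: partition accuracy lambda ~ 0.061, chain speed
# ~ 18.4 nm/min, MamK recovery t1/2 ~ 68 s, treadmilling ~ 313 nm/min.

gen_attrs <- function(x, kind, params, seed) {
  attr(x, "generator") <- list(kind = kind, params = params, seed = seed)
  x
}

#' Generate chain-partition events
#'
#' Folded fractions are drawn from the exponential-suppression model by
#' inverse CDF, `x = 0.5 - lambda * log(1 - u)`, resampling any draw above 1
#' (which keeps the exponential shape; the mass beyond 1 is negligible for
#' lambda near 0.06), or from the uniform random-splitting null
#' `x ~ U(0.5, 1)`. Each event is emitted as the daughter pair
#' `(x * total, (1 - x) * total)`; counts are rounded to integers.
#'
#' @param n number of division events.
#' @param lambda accuracy parameter (ignored in `"uniform"` mode).
#' @param mode `"exponential"` or `"uniform"` (the random-splitting null).
#' @param measure `"length_nm"` or `"magnetosome_count"`.
#' @param total mother-chain total (nm or count); scalar or length `n`.
#' @param seed integer seed.
#' @return A tibble `event_id`, `measure_kind`, `daughter_a`, `daughter_b`.
#' @export
gen_partition_events <- function(n, lambda = 0.061,
                                 mode = c("exponential", "uniform"),
                                 measure = c("length_nm", "magnetosome_count"),
                                 total = 2000, seed = 1L) {
  mode <- match.arg(mode)
  measure <- match.arg(measure)
  if (mode == "exponential" && (!is.numeric(lambda) || lambda < 0))
    abort("`lambda` must be >= 0.")
  set.seed(seed)
  x <- if (mode == "uniform") {
    runif(n, 0.5, 1)
  } else if (lambda == 0) {
    rep(0.5, n)
  } else {
    draw <- function(m) 0.5 - lambda * log(1 - runif(m))
    x <- draw(n)
    while (any(x > 1)) x[x > 1] <- draw(sum(x > 1))
    x
  }
  total <- rep_len(total, n)
  a <- x * total
  b <- (1 - x) * total
  if (measure == "magnetosome_count") {
    a <- round(a); b <- total - a
  }
  out <- tibble(event_id = seq_len(n), measure_kind = measure,
                daughter_a = a, daughter_b = b)
  gen_attrs(out, "partition", list(lambda = lambda, mode = mode, total = total[1]), seed)
}

#' Generate drift-and-arrest centroid tracks
#'
#' Emulates post-division chain motion: directed drift at speed `v` toward an
#' arrest position, Brownian increments of variance `2 D dt` while moving,
#' position frozen after arrival, plus i.i.d. Gaussian localization noise on
#' every observed frame.
#'
#' @param n number of tracks (cells).
#' @param v drift speed, nm/min.
#' @param D diffusion coefficient, nm^2/min.
#' @param sigma localization noise sd, nm (a typical centroid precision is
#'   ~20 nm).
#' @param arrest_at arrest (target) position, nm from the start.
#' @param frame_interval frame interval, min.
#' @param duration track duration, min.
#' @param dim 1 (axial) or 2 (xy; drift along x).
#' @param seed integer seed.
#' @return A tibble `cell_id`, `t_min`, `x_nm` (and `y_nm` if `dim = 2`).
#' @export
gen_tracks <- function(n = 87, v = 18.4, D = 0, sigma = 20, arrest_at = 1104,
                       frame_interval = 5, duration = 60, dim = 1, seed = 1L) {
  if (v < 0 || D < 0 || sigma < 0) abort("`v`, `D` and `sigma` must be >= 0.")
  if (!dim %in% c(1, 2)) abort("`dim` must be 1 or 2.")
  set.seed(seed)
  nf <- floor(duration / frame_interval) + 1L
  times <- seq(0, by = frame_interval, length.out = nf)
  sig_b <- sqrt(2 * D * frame_interval)
  out <- purrr::map(seq_len(n), function(cell) {
    x <- numeric(nf)
    y <- numeric(nf)
    arrested <- FALSE
    for (j in 2:nf) {
      if (!arrested) {
        step <- min(v * frame_interval, arrest_at - x[j - 1])
        x[j] <- x[j - 1] + step + rnorm(1, 0, sig_b)
        if (dim == 2) y[j] <- y[j - 1] + rnorm(1, 0, sig_b)
        if (x[j] >= arrest_at) { x[j] <- arrest_at; arrested <- TRUE }
      } else {
        x[j] <- x[j - 1]
        y[j] <- y[j - 1]
      }
    }
    res <- tibble(cell_id = cell, t_min = times,
                  x_nm = x + rnorm(nf, 0, sigma))
    if (dim == 2) res$y_nm <- y + rnorm(nf, 0, sigma)
    res
  }) |> dplyr::bind_rows()
  gen_attrs(out, "tracks",
            list(v = v, D = D, sigma = sigma, arrest_at = arrest_at,
                 frame_interval = frame_interval, duration = duration, dim = dim),
            seed)
}

#' Generate FRAP intensity traces
#'
#' The underlying relative ROI signal sits at 1 before the pulse, drops to
#' `F0` at the event and recovers as `F0 + A (1 - exp(-k t))`. The raw
#' channels are built so that the double normalization of [normalize_frap()]
#' is exact on noiseless data: the whole-cell channel decays at the
#' acquisition-bleach rate, the ROI holds a fixed share of it scaled by the
#' relative signal, and the background channel is constant. In `flat` mode
#' the post-event signal stays at `F0` (a fixed-cell, dark-state control).
#'
#' @param n number of traces (cells).
#' @param k recovery rate, 1/s.
#' @param A recovery amplitude.
#' @param F0 relative intensity immediately after the pulse.
#' @param noise_sd Gaussian noise sd on the relative ROI signal.
#' @param bleach_rate acquisition photobleaching rate of the whole-cell
#'   channel, 1/s.
#' @param frame_interval frame interval, s.
#' @param pre_frames number of pre-event frames.
#' @param duration post-event duration, s.
#' @param flat if `TRUE`, generate fixed-cell control traces (no recovery).
#' @param seed integer seed.
#' @return A tibble `cell_id`, `t_s`, `roi`, `cell`, `bg`, `event_frame`.
#' @export
gen_frap_traces <- function(n = 1, k = log(2) / 68.3, A = 0.8, F0 = 0.2,
                            noise_sd = 0, bleach_rate = 0,
                            frame_interval = 10, pre_frames = 5,
                            duration = 600, flat = FALSE, seed = 1L) {
  if (!flat && k <= 0) abort("`k` must be > 0 for recovering traces.")
  if (noise_sd < 0 || bleach_rate < 0) abort("rates and noise sd must be >= 0.")
  set.seed(seed)
  n_post <- floor(duration / frame_interval) + 1L
  nf <- pre_frames + n_post
  t_s <- seq(0, by = frame_interval, length.out = nf)
  ev <- pre_frames + 1L
  t_post <- t_s[ev:nf] - t_s[ev]
  bg <- 10
  cell0 <- 1000
  roi_share <- 0.3
  out <- purrr::map(seq_len(n), function(cellid) {
    rel <- c(rep(1, pre_frames),
             if (flat) rep(F0, n_post) else F0 + A * (1 - exp(-k * t_post)))
    rel <- rel + rnorm(nf, 0, noise_sd)
    cellch <- bg + cell0 * exp(-bleach_rate * t_s)
    tibble(cell_id = cellid, t_s = t_s,
           roi = bg + rel * roi_share * (cellch - bg),
           cell = cellch, bg = bg, event_frame = ev)
  }) |> dplyr::bind_rows()
  gen_attrs(out, "frap",
            list(k = k, A = A, F0 = F0, noise_sd = noise_sd,
                 bleach_rate = bleach_rate, flat = flat), seed)
}

#' Generate photoconversion zone traces
#'
#' Three-compartment first-order transfer with conserved total signal:
#' the photoconverted pole decays at rate `k1` into the opposite pole, which
#' passes signal on to the non-polar area at rate `k2` (set `k2 = 0` for a
#' pure two-compartment chase). This compartment chain is a test harness
#' reproducing the observed ordering of half-times (pole decay roughly equal
#' to the opposite-pole rise, with the non-polar rise lagging), not a
#' mechanistic model. With all rates 0 the zones are flat, mimicking a
#' static, non-dynamic filament.
#'
#' @param k1 pole decay / transfer rate, 1/s.
#' @param k2 opposite-pole to non-polar transfer rate, 1/s.
#' @param noise_sd Gaussian noise sd on relative zone signals.
#' @param frame_interval frame interval, s.
#' @param pre_frames pre-pulse frames (red channel near zero).
#' @param duration post-pulse duration, s.
#' @param seed integer seed.
#' @return A tibble `cell_id`, `zone`, `t_s`, `roi`, `cell`, `bg`,
#'   `event_frame` with the three zones of one cell.
#' @export
gen_photoconversion <- function(k1 = log(2) / 187.8, k2 = 0, noise_sd = 0,
                                frame_interval = 15, pre_frames = 2,
                                duration = 900, seed = 1L) {
  if (k1 < 0 || k2 < 0) abort("transfer rates must be >= 0.")
  set.seed(seed)
  n_post <- floor(duration / frame_interval) + 1L
  nf <- pre_frames + n_post
  t_s <- seq(0, by = frame_interval, length.out = nf)
  ev <- pre_frames + 1L
  tp <- t_s[ev:nf] - t_s[ev]
  P <- if (k1 == 0) rep(1, length(tp)) else exp(-k1 * tp)
  O <- if (k1 == 0) rep(0, length(tp))
       else if (k2 == 0) 1 - P
       else if (abs(k2 - k1) < 1e-12) k1 * tp * exp(-k1 * tp)
       else k1 / (k2 - k1) * (exp(-k1 * tp) - exp(-k2 * tp))
  N <- 1 - P - O
  bg <- 10
  cell0 <- 1000
  roi_share <- 0.3
  pre <- rep(0.01, pre_frames) # residual pre-pulse red signal
  zones <- list(photoconverted_pole = c(pre, P),
                non_polar = c(pre, N),
                opposite_pole = c(pre, O))
  out <- purrr::imap(zones, function(rel, zname) {
    rel <- rel + rnorm(nf, 0, noise_sd)
    tibble(cell_id = 1L, zone = zname, t_s = t_s,
           roi = bg + rel * roi_share * cell0,
           cell = bg + cell0, bg = bg, event_frame = ev)
  }) |> dplyr::bind_rows()
  gen_attrs(out, "photoconversion",
            list(k1 = k1, k2 = k2, noise_sd = noise_sd), seed)
}

#' Generate kymograph front lines
#'
#' Constant-velocity growth fronts sampled every `frame_interval` seconds
#' from `t_start` (the first frame at which a front is usually
#' distinguishable, 60 s post-bleach) with Gaussian localization jitter.
#'
#' @param n number of filaments.
#' @param speed front speed, nm/min.
#' @param jitter localization jitter sd, nm.
#' @param frame_interval frame interval, s.
#' @param n_frames frames per front (at least 4, a 90-s interval).
#' @param t_start first usable frame time, s post-bleach.
#' @param seed integer seed.
#' @return A tibble `filament_id`, `t_s`, `front_nm`.
#' @export
gen_fronts <- function(n = 36, speed = 313, jitter = 0, frame_interval = 30,
                       n_frames = 8, t_start = 60, seed = 1L) {
  if (speed < 0 || jitter < 0) abort("`speed` and `jitter` must be >= 0.")
  set.seed(seed)
  t_s <- seq(t_start, by = frame_interval, length.out = n_frames)
  out <- purrr::map(seq_len(n), function(fid) {
    tibble(filament_id = fid, t_s = t_s,
           front_nm = speed / 60 * (t_s - t_start) + rnorm(n_frames, 0, jitter))
  }) |> dplyr::bind_rows()
  gen_attrs(out, "fronts",
            list(speed = speed, jitter = jitter,
                 frame_interval = frame_interval, n_frames = n_frames), seed)
}
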