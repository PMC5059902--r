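# Chain-centroid track statistics. Tracks arrive as tidy tables:
# cell_id, t_min, x_nm and optionally y_nm, one row per frame, uniform frame
# spacing per cell. All ensemble statistics are computed from each track's
# own origin (non-stationary convention) because post-division chain motion
# is directed then arrested, not stationary.

track_coords <- function(tracks) {
  need <- c("cell_id", "t_min", "x_nm")
  miss <- setdiff(need, names(tracks))
  if (length(miss) > 0)
    abort(paste0("tracks table lacks column(s): ", paste(miss, collapse = ", ")))
  bad <- !is.finite(tracks$x_nm)
  if ("y_nm" %in% names(tracks)) bad <- bad | !is.finite(tracks[["y_nm"]])
  if (any(bad)) abort("track coordinates must be finite.")
  dplyr::arrange(as_tibble(tracks), .data$cell_id, .data$t_min)
}

step_lengths <- function(df, has_y) {
  dx <- diff(df$x_nm)
  if (has_y) sqrt(dx^2 + diff(df$y_nm)^2) else abs(dx)
}

#' Mean cumulative displacement of an ensemble of tracks
#'
#' Per track, the running sum of frame-to-frame Euclidean step lengths
#' (non-decreasing by construction); across tracks, the ensemble mean and
#' standard error per time point. All tracks must share a frame grid.
#'
#' @param tracks tidy track table (`cell_id`, `t_min`, `x_nm`, optionally
#'   `y_nm`).
#' @param each if `TRUE`, return per-track cumulative displacement instead of
#'   the ensemble summary.
#' @return A tibble `t_min`, `mean_nm`, `sem_nm`, `n` (or `cell_id`, `t_min`,
#'   `cumdisp_nm` when `each = TRUE`).
#' @export
cumulative_displacement <- function(tracks, each = FALSE) {
  df <- track_coords(tracks)
  has_y <- "y_nm" %in% names(df)
  per <- df |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(~ tibble(
      t_min = .x$t_min,
      cumdisp_nm = c(0, cumsum(step_lengths(.x, has_y)))
    )) |>
    dplyr::ungroup()
  if (each) return(per)
  grids <- per |> dplyr::count(.data$cell_id)
  if (length(unique(grids$n)) > 1)
    abort("tracks have unequal frame grids; resample before summarising.")
  per |>
    dplyr::group_by(.data$t_min) |>
    dplyr::summarise(mean_nm = mean(.data$cumdisp_nm),
                     sem_nm = sd(.data$cumdisp_nm) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
}

#' Ensemble mean-square displacement
#'
#' `MSD(t) = <|r(t) - r(0)|^2>` averaged over tracks, each measured from its
#' own first frame. For pure drift at speed v, `MSD(t) = (v t)^2`; for pure
#' diffusion, `MSD(t) = 2 dim D t`. `MSD(0) = 0` by construction.
#'
#' @inheritParams cumulative_displacement
#' @return A tibble `t_min`, `msd_nm2`, `sem_nm2`, `n`.
#' @export
track_msd <- function(tracks) {
  df <- track_coords(tracks)
  has_y <- "y_nm" %in% names(df)
  per <- df |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(.x, ...) {
      if (nrow(.x) < 2) abort("every track needs at least 2 frames.")
      sq <- (.x$x_nm - .x$x_nm[1])^2
      if (has_y) sq <- sq + (.x$y_nm - .x$y_nm[1])^2
      tibble(t_min = .x$t_min - .x$t_min[1], sq_nm2 = sq)
    }) |>
    dplyr::ungroup()
  per |>
    dplyr::group_by(.data$t_min) |>
    dplyr::summarise(msd_nm2 = mean(.data$sq_nm2),
                     sem_nm2 = sd(.data$sq_nm2) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
}

#' Apparent diffusion coefficient from an MSD curve
#'
#' `D*(t) = MSD(t) / (2 dim t)`. Constant in `t` for pure diffusion,
#' linearly increasing (`v^2 t / (2 dim)`) for directed motion, so a rise
#' followed by decay is the signature of transport that arrests.
#'
#' @param msd a tibble from [track_msd()] (columns `t_min`, `msd_nm2`).
#' @param dim spatial dimensionality of the coordinates (1, 2 or 3).
#' @return The input restricted to `t_min > 0` with `dstar_nm2_min` appended.
#' @export
apparent_diffusion <- function(msd, dim = 2) {
  if (!dim %in% c(1, 2, 3)) abort("`dim` must be 1, 2 or 3.")
  msd |>
    dplyr::filter(.data$t_min > 0) |>
    dplyr::mutate(dstar_nm2_min = .data$msd_nm2 / (2 * dim * .data$t_min))
}

#' Windowed velocity of tracks
#'
#' Net displacement magnitude per non-overlapping, left-aligned time window,
#' divided by the window duration. Partial trailing windows are dropped.
#'
#' @inheritParams cumulative_displacement
#' @param window window length, min; must span at least 2 frames.
#' @return A tibble `cell_id`, `window_start_min`, `v_nm_min`.
#' @export
windowed_velocity <- function(tracks, window = 10) {
  df <- track_coords(tracks)
  has_y <- "y_nm" %in% names(df)
  df |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(.x, ...) {
      if (window < min(diff(.x$t_min)))
        abort("`window` must be at least one frame interval long.")
      t0 <- .x$t_min[1]
      # window k runs from t0 + k*window to t0 + (k+1)*window; a window is
      # kept only if a frame exists at (or past) its right edge
      nwin <- floor((.x$t_min[nrow(.x)] - t0) / window)
      if (nwin < 1) return(tibble(window_start_min = double(), v_nm_min = double()))
      res <- purrr::map(seq_len(nwin) - 1L, function(k) {
        i0 <- which(.x$t_min >= t0 + k * window)[1]
        i1 <- which(.x$t_min >= t0 + (k + 1) * window)[1]
        if (is.na(i0) || is.na(i1) || i1 <= i0) return(NULL)
        dx <- .x$x_nm[i1] - .x$x_nm[i0]
        disp <- if (has_y) sqrt(dx^2 + (.x$y_nm[i1] - .x$y_nm[i0])^2) else abs(dx)
        tibble(window_start_min = .x$t_min[i0],
               v_nm_min = disp / (.x$t_min[i1] - .x$t_min[i0]))
      })
      dplyr::bind_rows(res)
    }) |>
    dplyr::ungroup()
}

#' Mean speed of each track
#'
#' Total path length divided by elapsed time. Optionally restricted to the
#' pre-arrest segment, with arrest detected as the first window whose
#' [windowed_velocity()] falls below `arrest_floor`.
#'
#' @inheritParams cumulative_displacement
#' @param arrest_floor optional speed floor, nm/min; if given, frames from
#'   the first window slower than the floor onward are dropped.
#' @param window window (min) used for arrest detection.
#' @return A tibble `cell_id`, `speed_nm_min`, `elapsed_min`, `path_nm`.
#' @export
mean_speed <- function(tracks, arrest_floor = NULL, window = 10) {
  df <- track_coords(tracks)
  has_y <- "y_nm" %in% names(df)
  if (!is.null(arrest_floor)) {
    wv <- windowed_velocity(df, window)
    arrest <- wv |>
      dplyr::filter(.data$v_nm_min < arrest_floor) |>
      dplyr::group_by(.data$cell_id) |>
      dplyr::summarise(arrest_min = min(.data$window_start_min), .groups = "drop")
    df <- df |>
      dplyr::left_join(arrest, by = "cell_id") |>
      dplyr::filter(is.na(.data$arrest_min) | .data$t_min <= .data$arrest_min) |>
      dplyr::select(-"arrest_min")
  }
  df |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(.x, ...) {
      if (nrow(.x) < 2) abort("every track needs at least 2 frames.")
      el <- .x$t_min[nrow(.x)] - .x$t_min[1]
      if (el <= 0) abort("zero elapsed time in track.")
      path <- sum(step_lengths(.x, has_y))
      tibble(speed_nm_min = path / el, elapsed_min = el, path_nm = path)
    }) |>
    dplyr::ungroup()
}
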