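#' Simulate magnetosome chain dynamics
#'
#' Integrates the overdamped 1-D Langevin dynamics described in [sim_config()]
#' with the Euler-Maruyama scheme: for each particle,
#' `dx = (F_active + F_dipole + F_steric)/gamma * dt + sqrt(2 D dt) * xi`,
#' with `xi` standard normal. The active force has magnitude `F_s` directed
#' toward midcell and vanishes inside a dead-band of one force-free step
#' (`v0 * dt`) around `L/2`, which realizes the linear force-velocity relation
#' `v = v0 (1 - F_load/F_s)` under an opposing load and prevents limit-cycle
#' chatter at the target. Boundaries reflect; overlapping neighbours are
#' projected back to contact symmetrically after every step.
#'
#' The run is bit-reproducible: all noise is drawn up front from R's RNG
#' seeded with `config$seed` (or `seed`, if given).
#'
#' @param config a [sim_config()] object.
#' @param seed optional seed overriding `config$seed`.
#' @param .noise optional pre-drawn standard-normal matrix
#'   (`n_particles` x steps), used by reflection-symmetry tests; normally
#'   leave `NULL`.
#' @return An `mc_trajectory`: a tibble with columns `t_s`, `particle_id`,
#'   `x_nm`, carrying the config, the seed used and the raw position matrix
#'   as attributes.
#' @seealso [repositioning_metrics()], [detect_chains()]
#' @export
#' @examples
#' cfg <- sim_config(n_particles = 1, D = 0, dipole_moments = 0, t_max = 100,
#'                   initial_layout = "explicit", positions = 500)
#' traj <- simulate_chain(cfg)
simulate_chain <- function(config, seed = NULL, .noise = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- as.integer(seed %||% config$seed)
  nsteps <- as.integer(round(config$t_max / config$dt))
  save_every <- max(1L, as.integer(round(config$save_interval / config$dt)))
  n <- config$n_particles

  set.seed(seed)
  x0 <- config$positions
  if (is.null(x0)) { # random_scatter, drawn from the same seeded stream
    r <- config$diameters / 2
    x0 <- sort(runif(n, min = max(r), max = config$L - max(r)))
  }
  if (is.null(.noise)) {
    .noise <- if (config$D > 0) {
      matrix(rnorm(n * nsteps), nrow = n)
    } else {
      matrix(0, nrow = n, ncol = nsteps)
    }
  }
  stopifnot(nrow(.noise) == n, ncol(.noise) == nsteps)

  pos <- .sim_core(x0, config$diameters, config$dipole_moments,
                   config$L, config$D, config$gamma, config$F_s,
                   config$dt, nsteps, save_every,
                   config$interaction_gap_threshold, .noise)
  times <- seq(0, by = save_every * config$dt, length.out = ncol(pos))

  out <- tibble(
    t_s = rep(times, each = n),
    particle_id = rep(seq_len(n), times = length(times)),
    x_nm = as.vector(pos)
  )
  structure(out,
            class = c("mc_trajectory", class(out)),
            config = config, seed = seed,
            positions = pos, times = times)
}

#' Collinear point-dipole force between two magnetosomes
#'
#' Head-to-tail attraction of two collinear magnetic point dipoles,
#' `F = 3 mu0 m1 m2 / (2 pi r^4)`, returned in pN with the attractive sign
#' convention (negative). Strictly decreasing in magnitude with distance
#' (`r^-4`).
#'
#' @param m1,m2 dipole moments, A m^2.
#' @param r centre-to-centre distance, nm; must be > 0.
#' @return Signed force in pN (attraction negative). Vectorized.
#' @export
#' @examples
#' dipole_force(1.6e-17, 1.6e-17, 50) # about -24.6 pN at contact of 50-nm crystals
dipole_force <- function(m1, m2, r) {
  if (any(r <= 0)) abort("`r` must be > 0.")
  -DIPOLE_K * m1 * m2 / r^4
}

#' Group magnetosomes into chains by gap threshold
#'
#' Adjacent particles belong to the same chain when their surface-to-surface
#' gap is at most `gap_threshold` (boundary inclusive), the distance scale
#' below which magnetostatic interaction between magnetite crystals is
#' appreciable.
#'
#' @param positions particle centre positions, nm.
#' @param diameters particle diameters, nm (scalar recycled).
#' @param gap_threshold maximal within-chain surface gap, nm.
#' @return A list of integer vectors: indices into `positions` (original
#'   order), one per chain, ordered along the axis; their union is all
#'   particles.
#' @export
#' @examples
#' detect_chains(c(0, 80, 175, 285), 50) # gaps 30, 45, 60 -> two chains
detect_chains <- function(positions, diameters, gap_threshold = 50) {
  n <- length(positions)
  if (!length(diameters) %in% c(1L, n))
    abort("`diameters` must be a scalar or match `positions` in length.")
  diameters <- rep_len(diameters, n)
  if (gap_threshold <= 0) abort("`gap_threshold` must be > 0.")
  if (n == 0) return(list())
  ord <- order(positions)
  x <- positions[ord]
  d <- diameters[ord]
  if (n == 1) return(list(ord))
  gaps <- diff(x) - (d[-n] / 2 + d[-1] / 2)
  grp <- cumsum(c(0, gaps > gap_threshold))
  unname(split(ord, grp))
}

#' Chain-formation and repositioning metrics of a trajectory
#'
#' Per saved frame: the number of chains ([detect_chains()]) and the offset of
#' the largest chain's centre from midcell (ties between equally large chains
#' resolve to the one nearest midcell). The half-repositioning time is the
#' first time at which the offset falls below half its initial value.
#'
#' @param traj an `mc_trajectory` from [simulate_chain()].
#' @param gap_threshold chain-membership gap, nm; defaults to the config's
#'   interaction threshold.
#' @return A list with `by_frame` (tibble: `t_s`, `chain_count`, `offset_nm`),
#'   `half_repositioning_time` (s; `NA` with `reached_half = FALSE` if the
#'   offset never halves), `final_chain_count` and `final_offset_nm`.
#' @export
repositioning_metrics <- function(traj, gap_threshold = NULL) {
  stopifnot(inherits(traj, "mc_trajectory"))
  pos <- attr(traj, "positions")
  times <- attr(traj, "times")
  cfg <- attr(traj, "config")
  if (is.null(pos) || length(times) < 2) abort("trajectory must have at least 2 frames.")
  gap_threshold <- gap_threshold %||% cfg$interaction_gap_threshold
  half <- cfg$L / 2

  frame_stats <- purrr::map(seq_along(times), function(j) {
    chains <- detect_chains(pos[, j], cfg$diameters, gap_threshold)
    sizes <- lengths(chains)
    biggest <- which(sizes == max(sizes))
    centers <- purrr::map_dbl(chains[biggest], ~ mean(pos[.x, j]))
    offset <- min(abs(centers - half))
    c(chain_count = length(chains), offset_nm = offset)
  })
  by_frame <- tibble(
    t_s = times,
    chain_count = purrr::map_dbl(frame_stats, "chain_count"),
    offset_nm = purrr::map_dbl(frame_stats, "offset_nm")
  )
  target <- by_frame$offset_nm[1] / 2
  hit <- which(by_frame$offset_nm <= target)
  reached <- length(hit) > 0
  list(
    by_frame = by_frame,
    half_repositioning_time = if (reached) by_frame$t_s[hit[1]] else NA_real_,
    reached_half = reached,
    final_chain_count = by_frame$chain_count[length(times)],
    final_offset_nm = by_frame$offset_nm[length(times)]
  )
}

#' Write a trajectory and its metrics to disk
#'
#' The trajectory goes to TSV (`t_s`, `particle_id`, `x_nm`); the metrics
#' sidecar (chain-count series, half-repositioning time, final offset) to
#' JSON next to it. Writes are atomic (temp file + rename).
#'
#' @param traj an `mc_trajectory`.
#' @param path output TSV path; the sidecar gets extension `.metrics.json`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  m <- repositioning_metrics(traj)
  tmp <- paste0(path, ".tmp")
  readr::write_tsv(as_tibble(traj), tmp)
  file.rename(tmp, path)
  side <- sub("\\.tsv$", "", path)
  side <- paste0(side, ".metrics.json")
  tmp2 <- paste0(side, ".tmp")
  jsonlite::write_json(list(
    seed = attr(traj, "seed"),
    chain_count = m$by_frame$chain_count,
    t_s = m$by_frame$t_s,
    half_repositioning_time = m$half_repositioning_time,
    final_chain_count = m$final_chain_count,
    final_offset_nm = m$final_offset_nm
  ), tmp2, auto_unbox = TRUE, digits = NA)
  file.rename(tmp2, side)
  invisible(path)
}

#' @export
print.mc_trajectory <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<mc_trajectory> %d particles, %d frames, seed %d\n",
              cfg$n_particles, length(attr(x, "times")), attr(x, "seed")))
  NextMethod()
}
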