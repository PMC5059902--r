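#' Configuration for the magnetosome chain simulator
#'
#' Builds and validates the parameter set for [simulate_chain()]. The model is
#' one-dimensional along the cell axis: magnetosomes experience midcell-directed
#' active transport with a linear force-velocity relation (zero-force velocity
#' `v0 = F_s / gamma`), free diffusion, nearest-neighbour magnetic dipole
#' attraction while the surface-to-surface gap is at most
#' `interaction_gap_threshold`, hard-sphere exclusion, and reflecting cell
#' boundaries. The friction coefficient `gamma` is an independent parameter,
#' not tied to `D` by a fluctuation-dissipation relation, which is what lets
#' the active term be read as a linear force-velocity law with stall force
#' `F_s`.
#'
#' Defaults describe a newborn *Magnetospirillum gryphiswaldense* daughter
#' cell: length 4000 nm, 50-nm magnetosomes with the dipole moment of a 40-nm
#' magnetite crystal (~1.6e-17 A m^2), a ~1 pN stall force and a 1 nm/s
#' zero-force velocity. These are tunable model parameters, not measured
#' constants.
#'
#' @param L cell length, nm.
#' @param n_particles number of magnetosomes.
#' @param diameters particle diameters in nm; scalar recycled to `n_particles`.
#' @param dipole_moments magnetic dipole moments in A m^2; scalar recycled.
#' @param D diffusion coefficient, nm^2/s.
#' @param gamma friction coefficient, pN s/nm.
#' @param F_s stall force of the active transport, pN.
#' @param dt integration time step, s.
#' @param t_max simulated time, s.
#' @param save_interval interval between saved frames, s (rounded to a whole
#'   number of steps).
#' @param interaction_gap_threshold maximal surface-to-surface gap (nm) at
#'   which magnetostatic attraction acts; beyond it crystals are treated as
#'   magnetically independent.
#' @param initial_layout `"pole_chain"` (particles regularly spaced flush
#'   against the left cell boundary, gaps of `pole_gap` nm), `"regular_spacing"`
#'   (even spread over the cell), `"random_scatter"`, or `"explicit"` (use
#'   `positions`).
#' @param pole_gap surface gap (nm) between neighbours in the `pole_chain`
#'   layout; the default 60 nm puts newborn neighbours just beyond the
#'   magnetostatic interaction range so that chain formation is an outcome of
#'   the dynamics rather than of the initial condition.
#' @param positions explicit initial positions (nm, sorted), for
#'   `initial_layout = "explicit"`.
#' @param seed integer seed for the simulation noise.
#' @param step_budget refusal threshold on `n_particles * t_max / dt`.
#'
#' @return An object of class `sim_config` (a validated list). The vacuum
#'   permeability `mu0 = 4e-7 * pi` is a fixed physical constant carried in the
#'   object for reference; it is not tunable.
#' @seealso [simulate_chain()], [dipole_force()]
#' @export
#' @examples
#' cfg <- sim_config(n_particles = 2, D = 0, F_s = 0,
#'                   initial_layout = "explicit", positions = c(900, 1000))
sim_config <- function(L = 4000,
                       n_particles = 15,
                       diameters = 50,
                       dipole_moments = 1.6e-17,
                       D = 10,
                       gamma = 1,
                       F_s = 1,
                       dt = 0.01,
                       t_max = 2500,
                       save_interval = 1,
                       interaction_gap_threshold = 50,
                       initial_layout = c("pole_chain", "regular_spacing",
                                          "random_scatter", "explicit"),
                       pole_gap = 60,
                       positions = NULL,
                       seed = 1L,
                       step_budget = 2e9) {
  initial_layout <- match.arg(initial_layout)
  if (!is.numeric(L) || L <= 0) abort("`L` must be a positive cell length in nm.")
  if (n_particles < 1) abort("`n_particles` must be at least 1.")
  n <- as.integer(n_particles)
  diameters <- rep_len(as.numeric(diameters), n)
  dipole_moments <- rep_len(as.numeric(dipole_moments), n)
  if (any(diameters <= 0)) abort("all `diameters` must be > 0.")
  if (gamma <= 0) abort("`gamma` must be > 0.")
  if (D < 0) abort("`D` must be >= 0.")
  if (F_s < 0) abort("`F_s` must be >= 0 (v0 = F_s/gamma must be nonnegative).")
  if (!is.finite(F_s / gamma)) abort("v0 = F_s/gamma must be finite.")
  if (dt <= 0) abort("`dt` must be > 0.")
  if (t_max < dt) abort("`t_max` must be at least `dt`.")
  if (interaction_gap_threshold <= 0) abort("`interaction_gap_threshold` must be > 0.")
  if (n * (t_max / dt) > step_budget) {
    abort(sprintf(
      "refusing to run: n_particles * t_max / dt = %.3g exceeds the step budget %.3g",
      n * (t_max / dt), step_budget))
  }

  radius <- diameters / 2
  x0 <- switch(initial_layout,
    pole_chain = {
      spacing <- diameters[-n] / 2 + diameters[-1] / 2 + pole_gap
      radius[1] + c(0, cumsum(spacing))
    },
    regular_spacing = seq(radius[1], L - radius[n], length.out = n),
    random_scatter = NULL, # drawn at simulation time from the seeded RNG
    explicit = {
      if (is.null(positions)) abort("`positions` must be supplied for initial_layout = 'explicit'.")
      if (length(positions) != n) abort("`positions` must have length `n_particles`.")
      sort(as.numeric(positions))
    })
  if (!is.null(x0) && (any(x0 < 0) || any(x0 > L)))
    abort("all initial positions must lie in [0, L].")

  structure(list(
    L = L, n_particles = n, diameters = diameters,
    dipole_moments = dipole_moments, D = D, gamma = gamma, F_s = F_s,
    v0 = F_s / gamma, dt = dt, t_max = t_max, save_interval = save_interval,
    interaction_gap_threshold = interaction_gap_threshold,
    initial_layout = initial_layout, pole_gap = pole_gap,
    positions = x0, seed = as.integer(seed), mu0 = MU0
  ), class = "sim_config")
}

#' Read a simulator configuration from JSON
#'
#' Keys must match the arguments of [sim_config()]; unknown keys are rejected
#' so that typos cannot silently fall back to defaults.
#'
#' @param path path to a JSON file.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- setdiff(names(formals(sim_config)), "")
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    abort(paste0("unknown configuration key(s): ", paste(bad, collapse = ", ")))
  do.call(sim_config, vals)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d particles in a %g nm cell\n  F_s = %g pN, v0 = %g nm/s, D = %g nm^2/s, dt = %g s, t_max = %g s\n  layout = %s, dipole gap cutoff = %g nm, seed = %d\n",
    x$n_particles, x$L, x$F_s, x$v0, x$D, x$dt, x$t_max,
    x$initial_layout, x$interaction_gap_threshold, x$seed))
  invisible(x)
}
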