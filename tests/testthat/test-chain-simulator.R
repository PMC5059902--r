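# Overdamped 1-D chain simulator: force laws, chain detection, dynamics.

test_that("dipole force follows the collinear point-dipole law", {
  expect_equal(dipole_force(0, 0, 50), 0)
  expect_equal(dipole_force(0, 1.6e-17, 50), 0)
  # r^-4: doubling the distance divides the magnitude by 16
  expect_equal(dipole_force(1e-17, 1e-17, 100) * 16, dipole_force(1e-17, 1e-17, 50))
  # hand evaluation of 3 mu0 m^2 / (2 pi r^4) in SI, converted to pN:
  # 6e-7 * (1.6e-17)^2 / (50e-9)^4 * 1e12 = 24.576 pN, attractive
  expect_equal(dipole_force(1.6e-17, 1.6e-17, 50), -24.576, tolerance = 1e-12)
  expect_true(abs(dipole_force(1e-17, 1e-17, 60)) < abs(dipole_force(1e-17, 1e-17, 59)))
  expect_error(dipole_force(1e-17, 1e-17, 0), "r")
})

test_that("chain detection groups by surface gap, boundary inclusive", {
  # diameters 50, surface gaps 30, 45, 60 -> split only at the 60 nm gap
  expect_equal(detect_chains(c(0, 80, 175, 285), 50), list(1:3, 4L))
  expect_equal(detect_chains(500, 50), list(1L))
  # gaps exactly at the 50 nm threshold stay joined
  expect_equal(detect_chains(c(0, 100, 200), 50), list(1:3))
  expect_error(detect_chains(c(0, 100), c(50, 50, 50)), "length")
})

test_that("chain detection matches brute-force grouping on random layouts", {
  brute <- function(x, d, thr) {
    ord <- order(x); xs <- x[ord]; ds <- d[ord]
    groups <- list(ord[1])
    for (i in 2:length(x)) {
      gap <- xs[i] - xs[i - 1] - (ds[i] + ds[i - 1]) / 2
      if (gap <= thr) {
        groups[[length(groups)]] <- c(groups[[length(groups)]], ord[i])
      } else {
        groups[[length(groups) + 1]] <- ord[i]
      }
    }
    groups
  }
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(2:12, 1)
    x <- sort(runif(n, 0, 3000))
    d <- runif(n, 30, 60)
    got <- detect_chains(x, d, 50)
    expect_equal(got, brute(x, d, 50))
    expect_setequal(unlist(got), seq_len(n))
  }
})

test_that("a lone particle drifts to midcell at v0 and then stays", {
  cfg <- sim_config(n_particles = 1, D = 0, dipole_moments = 0, t_max = 2000,
                    initial_layout = "explicit", positions = 500, seed = 1)
  traj <- simulate_chain(cfg)
  pos <- attr(traj, "positions")[1, ]
  times <- attr(traj, "times")
  # v0 = 1 nm/s over 1500 nm: arrival at t = 1500 s within one saved frame
  expect_equal(pos[which(times == 1500)], 2000, tolerance = 1e-6)
  expect_true(all(abs(pos[times >= 1501] - 2000) <= cfg$v0 * cfg$dt + 1e-9))
  expect_true(all(diff(abs(pos - 2000)) <= 1e-9)) # monotone approach
})

test_that("two-particle dipole coalescence matches an independent ODE oracle", {
  skip_if_not_installed("deSolve")
  m <- 1.6e-17; gam <- 1; contact <- 50
  cfg <- sim_config(n_particles = 2, D = 0, F_s = 0, t_max = 10, dt = 0.002,
                    save_interval = 0.01, initial_layout = "explicit",
                    positions = c(900, 1000), seed = 1)
  traj <- simulate_chain(cfg)
  p <- attr(traj, "positions"); tt <- attr(traj, "times")
  sep <- p[2, ] - p[1, ]
  t_sim <- tt[which(sep <= contact + 1e-6)[1]]
  # adaptive integration of dr/dt = -2 F(r)/gamma, stop at contact
  ode <- deSolve::lsoda(
    y = c(r = 100),
    times = seq(0, 10, by = 0.001),
    func = function(t, y, p) list(-2 * abs(dipole_force(m, m, max(y[1], 1))) / gam),
    rtol = 1e-10, atol = 1e-10)
  t_ode <- ode[which(ode[, "r"] <= contact)[1], "time"]
  expect_lt(abs(t_sim - t_ode) / t_ode, 0.01)
  expect_equal(sep[length(sep)], contact, tolerance = 1e-6)
})

test_that("trajectories respect domain, exclusion and particle-count invariants", {
  cfg <- sim_config(t_max = 300, seed = 11)
  traj <- simulate_chain(cfg)
  pos <- attr(traj, "positions")
  expect_equal(nrow(pos), 15)
  expect_true(all(pos >= 0 & pos <= cfg$L))
  contact <- outer(cfg$diameters / 2, cfg$diameters / 2, "+")
  for (j in seq(1, ncol(pos), by = 25)) {
    d <- abs(outer(pos[, j], pos[, j], "-"))
    overlap <- contact - d - 1e-6
    diag(overlap) <- 0
    expect_true(all(overlap <= 0))
  }
})

test_that("free diffusion reproduces MSD = 2 D t (no drift, no magnetics)", {
  D <- 1000; nrep <- 500; nsteps <- 1000; dt <- 0.01
  msd_at <- c(10, 100, 1000)
  disp <- matrix(NA_real_, nrep, length(msd_at))
  for (r in seq_len(nrep)) {
    cfg <- sim_config(n_particles = 1, D = D, F_s = 0, dipole_moments = 0,
                      L = 40000, t_max = nsteps * dt, dt = dt,
                      save_interval = dt, initial_layout = "explicit",
                      positions = 20000, seed = 5000 + r)
    p <- attr(simulate_chain(cfg), "positions")[1, ]
    disp[r, ] <- (p[msd_at + 1] - p[1])^2
  }
  for (k in seq_along(msd_at)) {
    t <- msd_at[k] * dt
    se <- sd(disp[, k]) / sqrt(nrep)
    expect_lt(abs(mean(disp[, k]) - 2 * D * t), 3 * se)
  }
})

test_that("dynamics are invariant under mirror reflection of the cell", {
  x0 <- c(500, 1500, 3000)
  cfg <- sim_config(n_particles = 3, D = 50, t_max = 50, seed = 9,
                    initial_layout = "explicit", positions = x0)
  nsteps <- round(cfg$t_max / cfg$dt)
  set.seed(9)
  noise <- matrix(rnorm(3 * nsteps), nrow = 3)
  traj <- simulate_chain(cfg, .noise = noise)
  cfg_m <- sim_config(n_particles = 3, D = 50, t_max = 50, seed = 9,
                      initial_layout = "explicit", positions = sort(cfg$L - x0))
  traj_m <- simulate_chain(cfg_m, .noise = -noise[3:1, ])
  p <- attr(traj, "positions"); pm <- attr(traj_m, "positions")
  expect_equal(pm, cfg$L - p[3:1, ], tolerance = 1e-6)
})

test_that("simulation is bit-reproducible for a fixed seed", {
  cfg <- sim_config(t_max = 60, seed = 123)
  a <- attr(simulate_chain(cfg), "positions")
  b <- attr(simulate_chain(cfg), "positions")
  expect_identical(a, b)
})

test_that("repositioning metrics report offsets and half-times", {
  # all particles parked at midcell: offset 0 at all times, half-time 0
  cfg0 <- sim_config(n_particles = 3, D = 0, F_s = 1, dipole_moments = 0,
                     t_max = 10, initial_layout = "explicit",
                     positions = c(1950, 2000, 2050), seed = 1)
  m0 <- repositioning_metrics(simulate_chain(cfg0))
  expect_true(all(m0$by_frame$offset_nm < 1))
  expect_equal(m0$half_repositioning_time, 0)
  # pure drift from offset X0: half-time = X0 / (2 v0) within one frame
  x0 <- 800
  cfg1 <- sim_config(n_particles = 1, D = 0, dipole_moments = 0, t_max = 1500,
                     initial_layout = "explicit", positions = 2000 - x0, seed = 1)
  m1 <- repositioning_metrics(simulate_chain(cfg1))
  expect_equal(m1$half_repositioning_time, x0 / (2 * cfg1$v0),
               tolerance = 2 * cfg1$save_interval / (x0 / (2 * cfg1$v0)))
})

test_that("configuration validation rejects bad inputs and oversize runs", {
  expect_error(sim_config(dt = 0), "dt")
  expect_error(sim_config(gamma = 0), "gamma")
  expect_error(sim_config(D = -1), "D")
  expect_error(sim_config(initial_layout = "explicit", positions = c(1, 2)), "length")
  expect_error(sim_config(initial_layout = "explicit",
                          positions = c(rep(100, 14), 4500)), "\\[0, L\\]")
  expect_error(sim_config(t_max = 1e9), "budget")
})

test_that("JSON configs round-trip and unknown keys are rejected", {
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  jsonlite::write_json(list(n_particles = 3, D = 5, seed = 2), path, auto_unbox = TRUE)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_particles, 3L)
  jsonlite::write_json(list(n_particles = 3, diffusion = 5), path, auto_unbox = TRUE)
  expect_error(read_sim_config(path), "diffusion")
})
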