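test_that("velocity-Verlet is exact for zero force and uniform acceleration", {
  sys <- single_bead_system()
  st <- velocity_verlet_step(sys, matrix(0, 1, 3), 0.01)
  expect_identical(st$system$positions, sys$positions)
  # constant force f, v0 = 0: x(n dt) = f (n dt)^2 / 2 exactly for VV
  f <- matrix(c(0.3, 0, 0), 1, 3)
  s <- sys
  fo <- f
  for (n in 1:200) {
    st <- velocity_verlet_step(s, fo, 0.01)
    s <- st$system; fo <- st$forces
  }
  expect_equal(s$unwrapped[1, 1] - sys$unwrapped[1, 1],
               0.5 * 0.3 * (200 * 0.01)^2, tolerance = 1e-10)
})

test_that("a harmonic oscillator integrated at dt = 0.01 keeps its period", {
  sys <- single_bead_system(box = 50)
  sys$unwrapped[1, 1] <- sys$unwrapped[1, 1] + 1   # displace by 1
  sys$positions <- gelperm:::wrap_coords(sys$unwrapped, 50)
  center <- 25
  ffun <- function(s) cbind(-(s$unwrapped[, 1] - center), 0, 0)  # k = 1
  s <- sys; fo <- ffun(sys)
  x <- numeric(3000)
  for (n in 1:3000) {
    st <- velocity_verlet_step(s, fo, 0.01, forces_fn = ffun)
    s <- st$system; fo <- st$forces
    x[n] <- s$unwrapped[1, 1] - center
  }
  crossings <- which(diff(sign(x)) > 0)       # upward zero crossings
  period <- mean(diff(crossings)) * 0.01
  expect_equal(period, 2 * pi, tolerance = 0.01 * 2 * pi)
})

test_that("the Langevin kick damps exactly at zero temperature", {
  sys <- single_bead_system(vel = c(1, -2, 0.5))
  out <- langevin_kick(sys, gamma = 0.5, temperature = 0, dt = 0.01)
  expect_equal(out$velocities, sys$velocities * (1 - 0.5 * 0.01),
               tolerance = 1e-12)
})

test_that("the thermostat reproduces equipartition and free diffusion", {
  # kinetic energy per dof = kT/2 within 3%
  sys <- ideal_gas_system(50, box = 30, seed = 2)
  cfg <- run_config(total_time = 2e3, langevin_gamma = 1, temperature = 0.23,
                    seed = 17, output_interval = 200)
  traj <- run_simulation(sys, force_field(eps_polymer_polymer = 0,
                                          eps_polymer_np = 0), cfg)
  Tbar <- mean(traj$energies$temperature[-(1:10)])
  expect_equal(Tbar, 0.23, tolerance = 0.03)

  # Einstein relation D = kT / gamma within 5% (short lags: many origins)
  gas2 <- ideal_gas_system(150, box = 30, seed = 12)
  tr <- run_simulation(gas2, force_field(eps_polymer_polymer = 0,
                                         eps_polymer_np = 0),
                       run_config(2e3, langevin_gamma = 1, seed = 19,
                                  output_interval = 200))
  msd <- msd_3d(tr$unwrapped, times = tr$times)
  fit <- fit_diffusivity(msd, window = c(20, 300))
  expect_equal(fit$diffusivity, 0.23 / 1, tolerance = 0.05)
})

test_that("orientation updates renormalize and relax to the pair minimum", {
  ff <- force_field(np_eps = 4, np_rmin = 2, np_rcut = 3.6, np_mu = 3,
                    np_theta0 = 0)
  sys <- empty_system(30)
  pos <- rbind(c(14, 15, 15), c(16, 15, 15))
  n1 <- c(0.3, 0.2, 1); n1 <- n1 / sqrt(sum(n1^2))
  n2 <- c(-0.2, 0.4, 1); n2 <- n2 / sqrt(sum(n2^2))
  sys$positions <- pos; sys$unwrapped <- pos
  sys$velocities <- matrix(0, 2, 3)
  sys$normals <- rbind(n1, n2)
  sys$bead_type <- rep("np_bead", 2)
  sys$np_id <- c(1L, 1L)
  sys$masses <- c(1, 1)
  sys$rigid <- FALSE

  fr <- compute_forces(sys, ff)
  up <- update_normals(sys, fr, dt = 0.01)
  expect_equal(unname(sqrt(rowSums(up$normals^2))), c(1, 1), tolerance = 1e-9)
  zero <- update_normals(sys, matrix(0, 2, 3), dt = 0.01)
  expect_equal(zero$normals, sys$normals, tolerance = 1e-12)

  # gradient flow at T = 0 (positions fixed) reaches the energy minimum
  s <- sys
  for (i in 1:4000) {
    g <- compute_forces(s, ff)
    s <- update_normals(s, g, dt = 0.02)
  }
  e_relaxed <- compute_forces(s, ff)$potential_energy
  # oracle: direct numerical minimization over the two orientations
  obj <- function(th) {
    a <- c(sin(th[1]) * cos(th[2]), sin(th[1]) * sin(th[2]), cos(th[1]))
    b <- c(sin(th[3]) * cos(th[4]), sin(th[3]) * sin(th[4]), cos(th[3]))
    np_pair(pos[2, ] - pos[1, ], a, b, ff)$energy
  }
  best <- Inf
  withr::with_seed(3, {
    for (k in 1:20) {
      o <- optim(runif(4, 0, pi), obj)
      best <- min(best, o$value)
    }
  })
  expect_equal(e_relaxed, best, tolerance = 1e-4)
})

test_that("rigid bodies preserve geometry and follow the rigid-rotor law", {
  m <- build_rigid_ellipsoid(6, 2, 1.5)
  st <- rigid_state(m)
  p0 <- rigid_bead_positions(st)$positions
  s <- st
  for (i in 1:500) s <- propagate_rigid(s, c(0, 0, 0), c(0, 0, 0), 0.01)
  expect_equal(rigid_bead_positions(s)$positions, p0, tolerance = 1e-9)

  # constant torque about the long (x) principal axis: omega = tau t / I
  s <- st
  tq <- c(0.5, 0, 0)
  for (i in 1:1000) s <- propagate_rigid(s, c(0, 0, 0), tq, 0.01)
  Ix <- s$inertia_body[1, 1]
  om <- solve(gelperm:::quat_matrix(s$q) %*% s$inertia_body %*%
                t(gelperm:::quat_matrix(s$q)), s$L)
  expect_equal(om[1], 0.5 * 10 / Ix, tolerance = 1e-3)
})

test_that("a thermostatted rigid ellipsoid keeps its aspect ratio exactly", {
  net <- build_network(network_spec(30, 9.5, bead_spacing = 1.9))
  sys <- place_nps(net, build_rigid_ellipsoid(6, 2, 1.6), 1,
                   min_clearance = 1.5, seed = 4)
  traj <- run_simulation(sys, force_field(np_rmin = 1.5, np_rcut = 3),
                         run_config(50, seed = 5, output_interval = 50))
  sh <- shape_metrics(traj)
  expect_equal(sd(sh$ar), 0, tolerance = 1e-9)
  expect_equal(mean(sh$ar), 2, tolerance = 0.04)
})

test_that("NVE runs conserve energy and the drift shrinks as dt^2", {
  # bond stiffness chosen so dt = 0.01 resolves the stiffest mode well
  # (omega dt ~ 0.1); the dt^2 scaling below verifies the symplectic order
  net <- build_network(network_spec(12, 4.1, bead_spacing = 1.35,
                                    bond_k = 25))
  ff <- force_field(sigma_lj = 1.2, lj_cutoff = 2.5, np_rcut = 2.6,
                    np_rmin = 1.4)
  # short thermostatted pre-roll to a typical state, then NVE
  eq <- run_simulation(net, ff, run_config(10, langevin_gamma = 1,
                                           temperature = 0.23, seed = 8,
                                           output_interval = 1000))
  start <- eq$final_system
  drift <- vapply(c(0.01, 0.005), function(dt) {
    cfg <- run_config(total_time = 1e4 * 0.01, dt = dt, langevin_gamma = 0,
                      seed = 1, output_interval = round(1 / dt))
    traj <- run_simulation(start, ff, cfg)
    etot <- traj$energies$potential + traj$energies$kinetic
    max(abs(etot - etot[1])) / abs(traj$energies$potential[1])
  }, numeric(1))
  expect_lt(drift[1], 0.001)
  expect_lt(drift[2], drift[1] / 2)
})

test_that("trajectories are bit-reproducible for a seed and guard blow-ups", {
  net <- build_network(network_spec(12, 4.1, bead_spacing = 1.35))
  ff <- force_field(sigma_lj = 1.2, lj_cutoff = 2.5, np_rcut = 2.6,
                    np_rmin = 1.4)
  cfg <- run_config(20, seed = 99, output_interval = 100)
  t1 <- run_simulation(net, ff, cfg)
  t2 <- run_simulation(net, ff, cfg)
  expect_identical(t1$unwrapped, t2$unwrapped)
  expect_identical(t1$energies, t2$energies)

  bad <- net
  bad$velocities[1, ] <- c(500, 0, 0)
  expect_error(run_simulation(bad, ff, cfg), "blow-up")
})

test_that("unwrapped coordinates equal wrapped modulo the box on every frame", {
  net <- build_network(network_spec(12, 4.1, bead_spacing = 1.35))
  ff <- force_field(sigma_lj = 1.2, lj_cutoff = 2.5, np_rcut = 2.6,
                    np_rmin = 1.4)
  traj <- run_simulation(net, ff, run_config(20, seed = 3,
                                             output_interval = 200))
  ratio <- (traj$unwrapped - traj$wrapped) / traj$box_length
  expect_lt(max(abs(ratio - round(ratio))), 1e-9)
})
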