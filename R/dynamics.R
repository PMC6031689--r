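#' Integration and thermostat settings for a simulation run
#'
#' Velocity-Verlet integration with a per-bead Langevin thermostat
#' (friction + fluctuation applied after the second half-kick each step).
#' Shell-bead orientation vectors follow a first-order overdamped rotational
#' Langevin update sharing the thermostat temperature, with their own
#' friction `gamma_r`.
#'
#' @param total_time Total simulated time (tau).
#' @param dt Integration time step (tau); default 0.01.
#' @param temperature Target thermal energy kT (eps); default 0.23.
#' @param langevin_gamma Translational friction per bead (m/tau). 0 gives
#'   NVE dynamics.
#' @param gamma_r Rotational friction for orientation vectors.
#' @param seed Integer seed; the run is bit-reproducible for a given seed.
#' @param output_interval Steps between stored frames.
#' @param thermostat_interval Apply the Langevin kick (and the orientation
#'   update) every this many steps, with the friction and noise scaled to
#'   the kick interval (an exact splitting of the same
#'   Ornstein-Uhlenbeck process; identical statistics on timescales beyond
#'   `thermostat_interval * dt`). Default 1.
#' @param msd_fit_window Time-lag window (tau) for the diffusivity fit;
#'   defaults to `c(0.65, 0.9) * total_time`, the proportional analogue of
#'   fitting lags 1.3e6-1.8e6 tau in a 2e6 tau run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(total_time, dt = 0.01, temperature = 0.23,
                       langevin_gamma = 0.1, gamma_r = 10, seed = 1,
                       output_interval = max(1L, round(total_time / dt / 500)),
                       thermostat_interval = 1, msd_fit_window = NULL) {
  if (dt <= 0) stop("dt must be positive")
  if (total_time < dt) stop("total_time must be at least dt")
  if (is.null(msd_fit_window)) msd_fit_window <- c(0.65, 0.9) * total_time
  if (msd_fit_window[1] < 0 || msd_fit_window[2] > total_time ||
      msd_fit_window[1] >= msd_fit_window[2])
    stop("msd_fit_window must lie within [0, total_time]")
  structure(
    list(total_time = total_time, dt = dt, temperature = temperature,
         langevin_gamma = langevin_gamma, gamma_r = gamma_r,
         seed = as.integer(seed),
         output_interval = as.integer(output_interval),
         thermostat_interval = as.integer(thermostat_interval),
         msd_fit_window = msd_fit_window),
    class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> %.4g tau at dt %.3g (%.3g steps), kT %.3g, gamma %.3g, seed %d\n",
              x$total_time, x$dt, x$total_time / x$dt, x$temperature,
              x$langevin_gamma, x$seed))
  invisible(x)
}

#' Run a molecular-dynamics trajectory
#'
#' Propagates the system with Velocity-Verlet + Langevin dynamics
#' (see [run_config()]). Nanoparticles flagged rigid are propagated as rigid
#' bodies (center-of-mass Verlet plus quaternion rotation driven by the net
#' torque, with the bead-level thermostat projected onto the rigid degrees
#' of freedom). Positions are stored wrapped; a parallel unwrapped record is
#' maintained for diffusion analysis. A per-step displacement guard aborts
#' with a diagnostic if any bead moves more than 0.5 sigma in one step.
#'
#' @param system A `bead_system`.
#' @param params A [force_field()].
#' @param config A [run_config()].
#' @return An `md_trajectory`: frame times, wrapped and unwrapped bead
#'   coordinates, shell-bead orientations, per-NP unwrapped centroids and
#'   per-frame energies.
#' @export
run_simulation <- function(system, params, config) {
  stopifnot(inherits(system, "bead_system"), inherits(params, "force_field"),
            inherits(config, "run_config"))
  validate_bead_system(system)
  if (system$box_length < 2 * max_cutoff(params))
    stop("box smaller than twice the maximum interaction cutoff")
  nsteps <- round(config$total_time / config$dt)
  out_every <- min(config$output_interval, max(nsteps, 1L))
  res <- run_simulation_cpp(
    as_cpp_system(system), as_cpp_params(params, system),
    list(dt = config$dt, nsteps = as.double(nsteps),
         gamma = config$langevin_gamma, gamma_r = config$gamma_r,
         temperature = config$temperature, output_interval = out_every,
         thermostat_interval = config$thermostat_interval %||% 1L,
         seed = as.double(config$seed)))

  final <- system
  final$positions <- res$final_positions
  final$velocities <- res$final_velocities
  final$normals <- res$final_normals
  final$unwrapped <- res$final_unwrapped

  structure(
    list(times = res$times,
         wrapped = res$wrapped,
         unwrapped = res$unwrapped,
         normals = res$normals,
         np_bead_index = res$np_bead_index + 1L,
         np_centroids = res$centroids,
         energies = tibble::tibble(
           time = res$times, potential = res$potential,
           kinetic = res$kinetic,
           temperature = res$kinetic_temperature),
         bead_type = system$bead_type,
         np_id = system$np_id,
         rigid = system$rigid,
         box_length = system$box_length,
         config = config, params = params,
         final_system = final),
    class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d frames x %d beads, %d NPs, t = 0..%.4g tau\n",
              length(x$times), dim(x$wrapped)[2], length(x$rigid),
              max(x$times)))
  invisible(x)
}

#' One Velocity-Verlet step
#'
#' Standard half-kick / drift / half-kick update. Forces for the second
#' half-kick are recomputed from `params` when given, from `forces_fn`
#' (a function of the updated system returning an N x 3 matrix) when given,
#' and otherwise the input forces are reused (appropriate for constant
#' external forces). Positions are wrapped and the unwrapped record advanced
#' by the raw displacement.
#'
#' @param system A `bead_system`.
#' @param forces N x 3 force matrix consistent with the current positions
#'   (or a `force_result`).
#' @param dt Time step (tau).
#' @param params Optional [force_field()] used to recompute forces.
#' @param forces_fn Optional `function(system) -> N x 3 matrix`.
#' @return List with the updated `system` and the `forces` used for the
#'   second half-kick.
#' @export
velocity_verlet_step <- function(system, forces, dt, params = NULL,
                                 forces_fn = NULL) {
  if (inherits(forces, "force_result")) forces <- forces$forces
  m <- system$masses
  v <- system$velocities + 0.5 * dt * forces / m
  disp <- dt * v
  if (max(abs(disp)) > 0.5)
    stop("integration blow-up: a bead moved more than 0.5 sigma in one step")
  system$unwrapped <- system$unwrapped + disp
  system$positions <- wrap_coords(system$positions + disp, system$box_length)
  if (!is.null(params)) {
    forces <- compute_forces(system, params)$forces
  } else if (!is.null(forces_fn)) {
    forces <- forces_fn(system)
  }
  system$velocities <- v + 0.5 * dt * forces / m
  list(system = system, forces = forces)
}

#' One Langevin thermostat kick
#'
#' Applies per-bead friction `-gamma v dt / m` and Gaussian noise with
#' per-component variance `2 gamma kT dt / m^2` (fluctuation-dissipation
#' balanced). Total momentum is not re-zeroed; the thermostat acts per bead.
#'
#' @param system A `bead_system`.
#' @param gamma Friction (m/tau), `> 0`.
#' @param temperature Thermal energy kT (eps); 0 gives pure damping.
#' @param dt Time step (tau).
#' @return The system with updated velocities.
#' @export
langevin_kick <- function(system, gamma, temperature, dt) {
  stopifnot(gamma > 0)
  m <- system$masses
  n <- nrow(system$velocities)
  noise <- matrix(rnorm(3 * n), n, 3) * sqrt(2 * gamma * temperature * dt) / m
  system$velocities <- system$velocities -
    (gamma * dt / m) * system$velocities + noise
  system
}

#' Overdamped rotational update of shell-bead orientations
#'
#' Rotates each orientation vector by a first-order overdamped Langevin
#' step: the component of the generalized force perpendicular to the vector
#' drives the rotation (`dt / gamma_r`), thermal noise with variance
#' `2 kT dt / gamma_r` per perpendicular component is added when
#' `temperature > 0`, and the vector is renormalized to unit length.
#'
#' @param system A `bead_system`.
#' @param torques N x 3 matrix of generalized orientation forces (`-dU/dn`,
#'   e.g. `compute_forces(...)$normal_torques`).
#' @param dt Time step (tau).
#' @param gamma_r Rotational friction.
#' @param temperature Thermal energy kT (eps); default 0 (deterministic
#'   relaxation).
#' @return The system with updated normals.
#' @export
update_normals <- function(system, torques, dt, gamma_r = 1,
                           temperature = 0) {
  if (inherits(torques, "force_result")) torques <- torques$normal_torques
  idx <- which(system$bead_type == "np_bead")
  if (length(idx) == 0) return(system)
  n <- system$normals[idx, , drop = FALSE]
  g <- torques[idx, , drop = FALSE]
  gperp <- g - rowSums(g * n) * n
  upd <- (dt / gamma_r) * gperp
  if (temperature > 0) {
    xi <- matrix(rnorm(3 * length(idx)), length(idx), 3)
    xi <- xi - rowSums(xi * n) * n
    upd <- upd + sqrt(2 * temperature * dt / gamma_r) * xi
  }
  n <- n + upd
  system$normals[idx, ] <- n / sqrt(rowSums(n^2))
  system
}

#' Rigid-body state for a nanoparticle model
#'
#' Builds the rigid-body representation (center of mass, orientation
#' quaternion, body-frame bead coordinates and inertia tensor) used by
#' [propagate_rigid()].
#'
#' @param model An `np_model` (unit bead masses).
#' @param com Initial center of mass.
#' @return An object of class `rigid_state`.
#' @export
rigid_state <- function(model, com = c(0, 0, 0)) {
  b <- sweep(model$bead_positions, 2, colMeans(model$bead_positions))
  nb <- nrow(b)
  I <- matrix(0, 3, 3)
  for (t in seq_len(nb)) {
    d <- b[t, ]
    I <- I + (sum(d^2) * diag(3) - outer(d, d))
  }
  structure(
    list(body_coords = b, body_normals = model$bead_normals,
         inertia_body = I, mass = nb, com = com, vcom = c(0, 0, 0),
         q = c(1, 0, 0, 0), L = c(0, 0, 0)),
    class = "rigid_state")
}

quat_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Current bead positions and normals of a rigid body
#'
#' @param state A [rigid_state()].
#' @return List with `positions` and `normals` in the space frame.
#' @export
rigid_bead_positions <- function(state) {
  R <- quat_matrix(state$q)
  list(positions = sweep(state$body_coords %*% t(R), 2, state$com, "+"),
       normals = state$body_normals %*% t(R))
}

#' One Velocity-Verlet step of a rigid body
#'
#' Translates the center of mass by Velocity-Verlet under the given net
#' force and advances the orientation quaternion with the space-frame
#' angular velocity obtained from the angular momentum (half-kicked by the
#' net torque before and after the rotation). Internal geometry is exactly
#' preserved.
#'
#' @param state A [rigid_state()].
#' @param force Net force 3-vector (constant over the step).
#' @param torque Net torque 3-vector about the center of mass.
#' @param dt Time step (tau).
#' @return The advanced `rigid_state`.
#' @export
propagate_rigid <- function(state, force, torque, dt) {
  M <- state$mass
  state$vcom <- state$vcom + 0.5 * dt * force / M
  state$com <- state$com + dt * state$vcom
  state$L <- state$L + 0.5 * dt * torque
  R <- quat_matrix(state$q)
  Ispace <- R %*% state$inertia_body %*% t(R)
  om <- solve(Ispace, state$L)
  q <- state$q
  dq <- 0.5 * c(-sum(om * q[2:4]),
                om[1] * q[1] + om[2] * q[4] - om[3] * q[3],
                om[2] * q[1] + om[3] * q[2] - om[1] * q[4],
                om[3] * q[1] + om[1] * q[3] - om[2] * q[2])
  q <- q + dt * dq
  state$q <- q / sqrt(sum(q^2))
  state$L <- state$L + 0.5 * dt * torque
  state$vcom <- state$vcom + 0.5 * dt * force / M
  state
}
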