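#' Dynamics settings
#'
#' Langevin particle dynamics in the BAOAB splitting: with zero friction
#' the integrator reduces to plain velocity Verlet (microcanonical), with
#' zero temperature and positive friction it performs damped relaxation.
#'
#' @param time_step integration time step in fs; default 350 fs, stable
#'   for the default spring constants and block mass (the bond vibration
#'   period is about 10.6 ps, about 30 steps).
#' @param n_steps number of steps to integrate.
#' @param temperature thermostat temperature, K.
#' @param friction Langevin friction, 1/ps.
#' @param random_seed seed used by [run_constant_strain()] for the
#'   thermostat noise; all randomness flows from it.
#' @param snapshot_every keep a full system snapshot every this many steps
#'   (0 = never).
#' @param series_every record stress/energy observables every this many
#'   steps (0 = never).
#' @return an object of class `dynamics_config`.
#' @export
dynamics_config <- function(time_step = 350, n_steps = 1000L,
                            temperature = 300, friction = 0.1,
                            random_seed = 1L,
                            snapshot_every = 0L, series_every = 100L) {
  if (time_step <= 0) stop("time_step must be positive", call. = FALSE)
  if (n_steps < 0) stop("n_steps must be >= 0", call. = FALSE)
  if (temperature < 0) stop("temperature must be >= 0", call. = FALSE)
  if (friction < 0) stop("friction must be >= 0", call. = FALSE)
  structure(list(time_step = as.numeric(time_step), n_steps = as.integer(n_steps),
                 temperature = as.numeric(temperature), friction = as.numeric(friction),
                 random_seed = as.integer(random_seed),
                 snapshot_every = as.integer(snapshot_every),
                 series_every = as.integer(series_every)),
            class = "dynamics_config")
}

# Shared driver around the compiled core. broken_state carries the
# monotone first-broken-step bookkeeping across calls.
.run_core <- function(system, potentials, config, n_steps,
                      force_tol = 0, broken_state = NULL) {
  stopifnot(inherits(system, "lattice_system"),
            inherits(potentials, "potential_table"),
            inherits(config, "dynamics_config"))
  m <- nrow(system$bonds)
  if (is.null(broken_state))
    broken_state <- list(first_step = rep(NA_integer_, m),
                         length = rep(NA_real_, m))
  as_vec <- function(p) c(p$k, p$r0, p$rc)
  res <- cg_run(system$positions, system$velocities, system$species,
                system$mass, system$bonds, system$clamped,
                as_vec(potentials$PP), as_vec(potentials$PD), as_vec(potentials$DD),
                dt = config$time_step * 1e-3,  # fs -> ps
                n_steps = as.integer(n_steps),
                temperature = config$temperature, friction = config$friction,
                series_every = config$series_every,
                snapshot_every = config$snapshot_every,
                force_tol = force_tol,
                periodic_x = identical(system$boundary$mode, "periodic_x"),
                box_lx = if (is.na(system$boundary$box_lx)) 0 else system$boundary$box_lx,
                broken_first0 = broken_state$first_step,
                broken_len0 = broken_state$length,
                time0 = system$time)
  system$positions[] <- res$positions
  system$velocities[] <- res$velocities
  system$species <- res$species
  system$time <- res$time_ps
  series <- as.data.frame(res$series)
  list(system = system,
       series = series,
       switching_log = data.frame(step = res$switch_step, block_id = res$switch_id),
       broken_state = list(first_step = res$broken_first_step,
                           length = res$broken_length),
       snapshots = res$snapshots,
       steps_done = res$steps_done,
       converged = res$converged,
       max_force = res$max_force,
       potential_energy = res$potential_energy)
}

#' Advance the system by one or more dynamics steps
#'
#' One step = one BAOAB Langevin velocity-Verlet update with the species
#' switching rule applied after the position update (all switches implied
#' by the new positions take effect simultaneously, then forces are
#' refreshed). Grip (clamped) blocks keep their loading-axis coordinate
#' fixed to machine precision; their transverse coordinate is free. A
#' per-step displacement larger than the pristine equilibrium distance
#' raises an instability error naming the offending block.
#'
#' Uses the current R random-number stream for the thermostat noise; seed
#' it (or use [run_constant_strain()], which seeds from its config) for
#' reproducible trajectories.
#'
#' @param system a [lattice_system].
#' @param potentials a [potential_table()].
#' @param config a [dynamics_config()].
#' @param n_steps number of steps; defaults to `config$n_steps`.
#' @return a list: `system` (advanced), `series` (data frame of recorded
#'   observables), `switching_log` (data frame step/block_id),
#'   `broken_state`, `snapshots`, `steps_done`, `potential_energy`,
#'   `max_force`.
#' @export
step_dynamics <- function(system, potentials, config, n_steps = config$n_steps) {
  .run_core(system, potentials, config, n_steps)
}

#' Damped zero-temperature relaxation
#'
#' Runs dissipative dynamics (temperature forced to 0 K) until the
#' maximum per-block force magnitude drops below `force_tolerance` or
#' `config$n_steps` is exhausted, and reports which criterion stopped it.
#' Used to prepare unstrained reference states and to find equilibrium
#' geometries.
#'
#' @inheritParams step_dynamics
#' @param force_tolerance convergence threshold on the maximum force
#'   magnitude over non-clamped blocks, kJ mol^-1 nm^-1.
#' @return a list: `system`, `converged` (TRUE if the force criterion
#'   stopped the run), `stopped_by` (`"force_tolerance"` or `"n_steps"`),
#'   `steps_done`, `max_force`.
#' @export
relax <- function(system, potentials, config = dynamics_config(temperature = 0,
                                                               friction = 0.5,
                                                               n_steps = 200000L,
                                                               series_every = 0L),
                  force_tolerance = 1e-6) {
  if (force_tolerance <= 0) stop("force_tolerance must be positive", call. = FALSE)
  config$temperature <- 0
  if (config$friction <= 0) config$friction <- 0.5
  out <- .run_core(system, potentials, config, config$n_steps,
                   force_tol = force_tolerance)
  list(system = out$system,
       converged = out$converged,
       stopped_by = if (out$converged) "force_tolerance" else "n_steps",
       steps_done = out$steps_done,
       max_force = out$max_force)
}

#' Strain-and-hold relaxation experiment
#'
#' The loading protocol used throughout: the sample is deformed
#' instantaneously by an affine strain (see [apply_affine_strain()]),
#' then relaxed for `protocol$hold_steps` dynamics steps with the grip
#' columns held fixed at their strained positions. Stress and energy are
#' recorded every `config$series_every` steps (including the strained
#' initial state at step 0), snapshots every `config$snapshot_every`
#' steps, and every pristine-to-damaged switching event with its step.
#' The run is deterministic given `config$random_seed`.
#'
#' @param system a [lattice_system] (typically unstrained and relaxed).
#' @param potentials a [potential_table()].
#' @param protocol a [strain_protocol()].
#' @param config a [dynamics_config()].
#' @param out_dir optional directory; when given, the stress series,
#'   switching log, broken-bond record (CSV) and snapshots (extended XYZ)
#'   are written there.
#' @return a list: `system` (final state), `stress` (data frame: step,
#'   time_ps, sigma_xx, sigma_yy, sigma_xy, potential_energy, n_damaged,
#'   n_broken_bonds), `switching_log`, `broken` (data frame: bond, i, j,
#'   first_step, length_at_detection for every ruptured bond),
#'   `snapshots`, `steps_done`.
#' @export
run_constant_strain <- function(system, potentials, protocol, config,
                                out_dir = NULL) {
  stopifnot(inherits(protocol, "strain_protocol"))
  if (!identical(protocol$mode, "instantaneous"))
    stop("only the instantaneous strain mode is implemented", call. = FALSE)
  system <- apply_affine_strain(system, protocol)
  set.seed(config$random_seed)
  out <- .run_core(system, potentials, config, protocol$hold_steps)
  b <- out$broken_state
  ruptured <- which(!is.na(b$first_step))
  broken <- data.frame(bond = ruptured,
                       i = system$bonds[ruptured, 1],
                       j = system$bonds[ruptured, 2],
                       first_step = b$first_step[ruptured],
                       length_at_detection = b$length[ruptured])
  result <- list(system = out$system, stress = out$series,
                 switching_log = out$switching_log, broken = broken,
                 broken_state = b,
                 snapshots = out$snapshots, steps_done = out$steps_done)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(result$stress, file.path(out_dir, "stress_series.csv"),
                     row.names = FALSE)
    utils::write.csv(result$switching_log, file.path(out_dir, "switching_log.csv"),
                     row.names = FALSE)
    utils::write.csv(result$broken, file.path(out_dir, "broken_bonds.csv"),
                     row.names = FALSE)
    write_bond_list(out$system, file.path(out_dir, "bonds.tsv"))
    for (snap in result$snapshots) {
      s2 <- out$system
      s2$positions[] <- snap$positions
      s2$velocities[] <- snap$velocities
      s2$species <- snap$species
      s2$time <- snap$time_ps
      write_snapshot(s2, file.path(out_dir, sprintf("snapshot_%08d.xyz", snap$step)))
    }
  }
  result
}
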