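#' Integrator parameters
#'
#' Parameters of the NVT Langevin dynamics: velocity-Verlet with an
#' Ornstein-Uhlenbeck velocity refresh mid-step (BAOAB splitting; with
#' \code{gamma = 0} it reduces exactly to plain velocity-Verlet, i.e. NVE).
#' Defaults are the full-scale protocol: \code{dt = 0.005} tau, damping
#' \code{gamma = 1} per tau, 4e6 equilibration and 1e6 production steps.
#'
#' @param temperature reduced temperature (epsilon / kB).
#' @param dt time step in tau.
#' @param gamma Langevin damping constant (1/tau); 0 switches the thermostat
#'   off.
#' @param n_steps_equil,n_steps_prod equilibration / production step counts.
#'   Snapshots are recorded during production only.
#' @param snapshot_stride steps between recorded snapshots.
#' @param log_stride steps between thermodynamic log rows.
#' @param seed integer seed for the thermostat noise (and metadata).
#' @param skin neighbor-list skin distance.
#' @export
md_params <- function(temperature = 1, dt = 0.005, gamma = 1,
                      n_steps_equil = 4e6, n_steps_prod = 1e6,
                      snapshot_stride = 1000, log_stride = 1000,
                      seed = 1, skin = 0.4) {
  stopifnot(dt > 0, gamma >= 0, temperature > 0, skin > 0)
  structure(list(temperature = temperature, dt = dt, gamma = gamma,
                 n_steps_equil = as.integer(n_steps_equil),
                 n_steps_prod = as.integer(n_steps_prod),
                 snapshot_stride = as.integer(snapshot_stride),
                 log_stride = as.integer(log_stride),
                 seed = as.integer(seed), skin = skin),
            class = "md_params")
}

sys_ff <- function(sys, ff) {
  if (is.null(ff)) force_field(sigma_n = sys$sigma_n) else ff
}

#' Advance a system by a number of integration steps
#'
#' Runs the Langevin velocity-Verlet integrator for \code{n_steps} and
#' returns the updated system (positions and velocities; graft beads stay
#' frozen at their anchors).  Aborts with an informative error on bond
#' overstretch, wall escape or non-finite coordinates.
#'
#' @param sys a \code{particle_system}.
#' @param ff a \code{\link{force_field}}; defaults to one matching
#'   \code{sys$sigma_n}.
#' @param params an \code{\link{md_params}}.
#' @param n_steps number of steps (default 1).
#' @return the updated \code{particle_system}, with the thermodynamic log of
#'   the stretch attached as attribute \code{"log"}.
#' @export
step_md <- function(sys, ff = NULL, params = md_params(), n_steps = 1L) {
  ff <- sys_ff(sys, ff)
  out <- cpp_run_md(sys$positions, sys$velocities, sys$species, sys$bonds,
                    sys$frozen, ff_to_cpp(ff), geom_to_cpp(sys$geometry),
                    params$dt, params$gamma, params$temperature,
                    as.integer(n_steps), 0L, params$log_stride, params$seed,
                    FALSE, params$skin)
  sys$positions <- out$positions
  sys$velocities <- out$velocities
  attr(sys, "log") <- out$log
  sys
}

#' Run an NVT simulation: equilibration then production
#'
#' Executes \code{n_steps_equil} equilibration steps followed by
#' \code{n_steps_prod} production steps, recording position snapshots every
#' \code{snapshot_stride} production steps.  Deterministic given the seed
#' (on a fixed platform).
#'
#' @inheritParams step_md
#' @return an object of class \code{md_trajectory}: snapshot coordinates
#'   (array \code{n_atoms x 3 x n_frames}), frame step indices, species,
#'   chain topology and graft anchors, geometry, the thermodynamic logs of
#'   both stages, and the final \code{particle_system}.
#' @export
run_md <- function(sys, ff = NULL, params = md_params()) {
  ff <- sys_ff(sys, ff)
  ffl <- ff_to_cpp(ff)
  gml <- geom_to_cpp(sys$geometry)
  eq <- cpp_run_md(sys$positions, sys$velocities, sys$species, sys$bonds,
                   sys$frozen, ffl, gml, params$dt, params$gamma,
                   params$temperature, params$n_steps_equil, 0L,
                   params$log_stride, params$seed, FALSE, params$skin)
  pr <- cpp_run_md(eq$positions, eq$velocities, sys$species, sys$bonds,
                   sys$frozen, ffl, gml, params$dt, params$gamma,
                   params$temperature, params$n_steps_prod,
                   params$snapshot_stride, params$log_stride,
                   params$seed + 1000003L, TRUE, params$skin)
  final <- sys
  final$positions <- pr$positions
  final$velocities <- pr$velocities
  structure(list(
    coords = pr$frames, frame_steps = pr$frame_steps,
    species = sys$species, chains = sys$chains, bonds = sys$bonds,
    anchors = sys$anchors, anchor_normals = sys$anchor_normals,
    geometry = sys$geometry, sigma_n = sys$sigma_n,
    log_equil = eq$log, log_prod = pr$log,
    params = params, final_system = final
  ), class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frames of %d particles (%s), T = %g\n",
              n_frames(x), length(x$species), x$geometry$kind,
              x$params$temperature))
  invisible(x)
}

#' Number of snapshots in a trajectory
#' @param traj an \code{md_trajectory}.
#' @export
n_frames <- function(traj) {
  d <- dim(traj$coords)
  if (is.null(d)) 0L else d[3]
}

#' Potential, wall and kinetic energies of a configuration
#'
#' Single force/energy evaluation through the engine's neighbor-list path.
#'
#' @inheritParams step_md
#' @return list with \code{E_pair}, \code{E_bond}, \code{E_wall},
#'   \code{E_kin} and the force matrix.
#' @export
system_energies <- function(sys, ff = NULL, skin = 0.4) {
  ff <- sys_ff(sys, ff)
  cpp_energies(sys$positions, sys$velocities, sys$species, sys$bonds,
               sys$frozen, ff_to_cpp(ff), geom_to_cpp(sys$geometry), skin)
}
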