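#' Default Monte Carlo move mixture
#'
#' One half of the attempted moves is distributed equally over the five
#' canonical moves (vertex displacement, link flip, carrier translation,
#' carrier rotation, receptor diffusion); the other half is split between
#' the rare-event flexure and bond moves in the ratio 2 : 5.
#'
#' @return named numeric vector of seven weights summing to 1.
#' @export
move_mix <- function() {
  c(vertex = 0.1, flip = 0.1, nc_translate = 0.1, nc_rotate = 0.1,
    rec_diffusion = 0.1, flexure = 0.5 * 2 / 7, bond = 0.5 * 5 / 7)
}

#' Simulation configuration
#'
#' @param steps total attempted elementary moves ("one MC step" = one
#'   attempted move).
#' @param burnin steps treated as equilibration: step-size auto-tuning (when
#'   `tune = TRUE`) runs only during burn-in, and burn-in records are dropped
#'   from the returned trajectory.
#' @param record_every cadence (steps) for recording the order parameter and
#'   energies; 10 by default.
#' @param bound_every cadence for recording bound-receptor positions
#'   (0 = off).
#' @param snapshot_every cadence for full mesh snapshots (0 = off).
#' @param seed integer RNG seed (mandatory; recorded in all outputs).
#' @param move_weights seven move weights; see [move_mix()].  Weights of
#'   carrier/receptor moves are zeroed automatically when the system lacks
#'   the corresponding degrees of freedom.
#' @param step_sizes numeric length 4: vertex 3-D cube side, vertex
#'   height-only amplitude, carrier translation cube side (nm), carrier
#'   rotation amplitude (rad).
#' @param k_trials Rosenbluth trial count for flexure/bond moves.
#' @param tune auto-tune step sizes to 30-50% acceptance during burn-in,
#'   then freeze.
#' @param bias optional harmonic bias: list with `dR0` (nm) and `k_bias`
#'   (kBT/nm^2), as produced by umbrella drivers.
#' @param debug run extra invariant checks after accepted link flips.
#' @return list of class `ncav_sim_config`.
#' @export
sim_config <- function(steps, burnin = 0, record_every = 10,
                       bound_every = 0, snapshot_every = 0, seed = 1,
                       move_weights = move_mix(),
                       step_sizes = c(1, 1, 2, 0.2), k_trials = 8,
                       tune = TRUE, bias = NULL, debug = FALSE) {
  stopifnot(record_every >= 1, steps >= 1, burnin >= 0,
            length(move_weights) == 7, all(move_weights >= 0),
            length(step_sizes) == 4)
  structure(list(steps = steps, burnin = burnin,
                 record_every = record_every, bound_every = bound_every,
                 snapshot_every = snapshot_every, seed = seed,
                 move_weights = move_weights, step_sizes = step_sizes,
                 k_trials = k_trials, tune = tune, bias = bias,
                 debug = debug),
            class = "ncav_sim_config")
}

#' Metropolis acceptance rule
#'
#' Accepts a proposed move with probability `min(1, exp(-dE))` for energy
#' changes in kBT.  Infinite `dE` (constraint violation) is always rejected;
#' `NaN` is an error.
#'
#' @param delta_E energy change(s) in kBT; vectorized.
#' @return logical vector of acceptances (consumes one uniform draw per
#'   element from R's RNG).
#' @export
metropolis_accept <- function(delta_E) {
  if (any(is.nan(delta_E))) stop("NaN energy change in Metropolis rule")
  runif(length(delta_E)) < exp(pmin(-delta_E, 0))
}

#' Run the Monte Carlo engine
#'
#' Schedules the seven elementary moves according to the configured mixture,
#' records observables at the configured cadence, and returns the updated
#' system together with the production trajectory.  Re-running with the same
#' seed and configuration reproduces the trajectory exactly; a run can be
#' continued from the returned system (which carries the engine RNG state
#' and frozen step sizes), and the continuation is bit-identical to an
#' uninterrupted longer run with tuning disabled.
#'
#' @param system an `ncav_system`.
#' @param config an `ncav_sim_config`.
#' @return list of class `ncav_sim_result`:
#'   `system` (final state), `trajectory` (data.frame of records after
#'   burn-in: step, dR, n_b, energies, area, carrier position and
#'   orientation quaternion), `bound` (long data.frame of bound-receptor
#'   base positions), `snapshots` (list of vertex matrices),
#'   `counters` (per-move attempted/accepted), `diagnostics` (energy drift,
#'   flip-invariant violations, final energies).
#' @export
run_simulation <- function(system, config) {
  stopifnot(inherits(system, "ncav_system"),
            inherits(config, "ncav_sim_config"))
  w <- as.numeric(config$move_weights)
  if (is.null(system$carrier)) w[c(3, 4, 7)] <- 0
  if (length(system$receptors$vertex) == 0) w[5:7] <- 0
  if (sum(w) <= 0) stop("no admissible moves for this system")
  w <- w / sum(w)
  step_sizes <- if (!is.null(system$step_sizes)) system$step_sizes
                else config$step_sizes
  cfg <- list(steps = config$steps, burnin = config$burnin,
              record_every = config$record_every,
              bound_every = config$bound_every,
              snapshot_every = config$snapshot_every,
              seed = config$seed, k_trials = config$k_trials,
              deltas = as.numeric(step_sizes),
              bias_on = !is.null(config$bias),
              k_bias = if (!is.null(config$bias)) config$bias$k_bias else 0,
              dR0 = if (!is.null(config$bias)) config$bias$dR0 else 0,
              move_weights = w, tune = config$tune, debug = config$debug,
              rng_state = system$rng_state)
  out <- cpp_run_mc(as_engine_state(system), cfg)
  rec <- out$records
  traj <- data.frame(step = rec$step, dR = rec$dR, n_b = rec$n_b,
                     H_m = rec$H_m, H_f = rec$H_f, H_b = rec$H_b,
                     E_total = rec$E_total, area = rec$area,
                     theta1 = rec$theta1, phi1 = rec$phi1)
  if (!is.null(system$carrier) && nrow(rec$nc) == nrow(traj)) {
    traj$nc_x <- rec$nc[, 1]; traj$nc_y <- rec$nc[, 2]
    traj$nc_z <- rec$nc[, 3]
    traj$q_w <- rec$nc[, 4]; traj$q_x <- rec$nc[, 5]
    traj$q_y <- rec$nc[, 6]; traj$q_z <- rec$nc[, 7]
  }
  bound <- as.data.frame(out$bound)
  names(bound) <- c("record", "receptor", "x", "y", "z")
  keep <- traj$step > config$burnin
  bound <- bound[bound$record %in% which(keep), , drop = FALSE]
  traj <- traj[keep, , drop = FALSE]
  counters <- data.frame(
    move = names(move_mix()),
    attempted = out$counters$attempted, accepted = out$counters$accepted)
  sys2 <- update_system_from_state(system, out$state, out$state$rng_state)
  structure(
    list(system = sys2, trajectory = traj, bound = bound,
         snapshots = out$snapshots, counters = counters,
         diagnostics = list(max_drift = out$max_drift,
                            flip_violations = out$flip_violations,
                            energy = out$energy,
                            seed = config$seed,
                            step_sizes = out$state$deltas)),
    class = "ncav_sim_result")
}

#' @export
print.ncav_sim_result <- function(x, ...) {
  cat(sprintf("ncav_sim_result: %d records, %d bound-receptor rows\n",
              nrow(x$trajectory), nrow(x$bound)))
  acc <- with(x$counters, ifelse(attempted > 0, accepted / attempted, NA))
  cat("  acceptance:", paste(sprintf("%s %.2f", x$counters$move, acc),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Save / restore a simulation checkpoint
#'
#' A checkpoint is a single-file state container holding the complete
#' system (positions, connectivity, receptor and bond bookkeeping, pinned
#' set, engine RNG state and frozen step sizes).  Restoring and continuing
#' reproduces the uninterrupted trajectory bit-for-bit.
#'
#' @param system an `ncav_system`.
#' @param path file path.
#' @export
save_checkpoint <- function(system, path) {
  stopifnot(inherits(system, "ncav_system"))
  saveRDS(system, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
restore_checkpoint <- function(path) {
  system <- readRDS(path)
  if (!inherits(system, "ncav_system")) stop("not an ncav_system checkpoint")
  system
}

#' Euler angles of orientation quaternions
#'
#' Converts unit quaternions (w, x, y, z) to Tait-Bryan ZYX angles
#' (phi = yaw, theta = pitch, psi = roll).  This convention is regular at
#' the identity - for small rotations the three angles reduce to the
#' rotation-vector components - which makes it the appropriate
#' parametrization for measuring the orientational fluctuations of a bound
#' carrier about its mean pose.
#'
#' @param q numeric length-4 vector or 4-column matrix.
#' @return matrix with columns `phi`, `theta`, `psi` (rad).
#' @export
quat_to_euler <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  phi <- atan2(2 * (w * z + x * y), 1 - 2 * (y^2 + z^2))
  theta <- asin(pmin(pmax(2 * (w * y - x * z), -1), 1))
  psi <- atan2(2 * (w * x + y * z), 1 - 2 * (x^2 + y^2))
  cbind(phi = phi, theta = theta, psi = psi)
}
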