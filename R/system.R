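#' Receptor flexural energy
#'
#' Harmonic flexure about the local membrane normal:
#' \deqn{H_f = \kappa_f \theta^2 / 2} (kBT), independent of the azimuth.
#'
#' @param theta flexural angle(s) in radians, in `[0, pi]`.
#' @param kappa_f flexural rigidity (kBT per rad^2).
#' @return energy in kBT (vectorized over `theta`).
#' @export
flexural_energy <- function(theta, kappa_f) {
  if (any(theta < 0 | theta > pi))
    stop("flexural angle must lie in [0, pi]")
  0.5 * kappa_f * theta^2
}

#' Bell bond potential
#'
#' Piecewise receptor-ligand interaction as a function of the tip-tip
#' distance `d`:
#' \deqn{H_b(d) = H_0 + \kappa_b (d - d^*)^2 / 2 \quad (d \le d^*), \qquad
#'       H_b = 0 \quad (d > d^*).}
#'
#' @param d tip-tip distance(s), nm (non-negative).
#' @param H0 bond depth (kBT, negative).
#' @param kappa_b bond spring constant (kBT/nm^2).
#' @param d_star reaction range (nm).
#' @return energy in kBT (vectorized over `d`).
#' @export
bond_energy <- function(d, H0, kappa_b, d_star) {
  if (any(d < 0)) stop("bond distance must be non-negative")
  ifelse(d <= d_star, H0 + 0.5 * kappa_b * (d - d_star)^2, 0)
}

#' Receptor tip position
#'
#' Tip of a rigid receptor rod of length `L_an` based at a mesh vertex, with
#' flexural angles (`theta`, `phi`) relative to the local vertex normal:
#' `theta = phi = 0` reproduces the normal direction, and the tip-base
#' distance is exactly `L_an` for any angles.
#'
#' @param mesh an `ncav_mesh`.
#' @param vertex 1-based vertex id.
#' @param theta,phi flexural angles (rad).
#' @param L_an receptor length (nm).
#' @return length-3 numeric tip position (nm).
#' @export
receptor_tip <- function(mesh, vertex, theta, phi, L_an = 19) {
  if (theta < 0 || theta > pi) stop("flexural angle must lie in [0, pi]")
  cpp_receptor_tip(mesh$vertices, mesh$triangles, mesh$L, mesh$a0,
                   mesh$link_max_factor, vertex, theta, phi, L_an)
}

#' Deterministic ligand directions on a sphere
#'
#' Fibonacci-lattice points on the unit sphere: a seedless, reproducible
#' quasi-uniform arrangement of the `n` ligand (antibody) directions in the
#' carrier body frame.
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  th <- golden * (i - 0.5)
  cbind(x = r * cos(th), y = r * sin(th), z = z)
}

#' Assemble a nanocarrier-membrane system
#'
#' Places receptors on randomly chosen distinct mesh vertices (unflexed,
#' unbonded) and, optionally, a rigid spherical carrier with radially
#' oriented ligands above the membrane.  The receptor count follows the
#' surface density interpreted per projected area:
#' `round(density_um2 * Ap / 1e6)`.
#'
#' @param mesh a periodic `ncav_mesh`.
#' @param params parameter tree from [load_config()].
#' @param nc logical: include the carrier?
#' @param seed integer seed for receptor placement.
#' @param n_receptors receptor count override (default from
#'   `params$receptor$density_um2`).
#' @param nc_center optional length-3 carrier centre (nm); default is the
#'   box centre laterally, resting height `max(z) + r_nc + 1` vertically.
#' @param ligand_dirs optional `N_ab x 3` matrix of body-frame ligand
#'   directions; default is the Fibonacci lattice.
#' @return an object of class `ncav_system`.
#' @export
build_system <- function(mesh, params = load_config(), nc = TRUE, seed = 1,
                         n_receptors = NULL, nc_center = NULL,
                         ligand_dirs = NULL) {
  if (mesh$L <= 0) stop("systems require a periodic membrane patch")
  nv <- nrow(mesh$vertices)
  if (is.null(n_receptors))
    n_receptors <- round(params$receptor$density_um2 * mesh$L^2 / 1e6)
  if (n_receptors > nv)
    stop("more receptors (", n_receptors, ") than vertices (", nv, ")")
  set.seed(seed)
  base <- sort(sample.int(nv, n_receptors))
  carrier <- NULL
  if (nc) {
    if (is.null(ligand_dirs))
      ligand_dirs <- fibonacci_sphere(params$carrier$N_ab)
    if (is.null(nc_center))
      nc_center <- c(mesh$L / 2, mesh$L / 2,
                     max(mesh$vertices[, 3]) + params$carrier$r_nc + 1)
    carrier <- list(center = as.numeric(nc_center), quat = c(1, 0, 0, 0),
                    r_nc = params$carrier$r_nc, L_ab = params$carrier$L_ab,
                    ligand_dirs = unname(as.matrix(ligand_dirs)),
                    lig_bond = integer(nrow(ligand_dirs)))
  }
  structure(
    list(mesh = mesh, params = params,
         receptors = list(vertex = base,
                          theta = numeric(n_receptors),
                          phi = numeric(n_receptors),
                          bond = integer(n_receptors)),
         carrier = carrier, rng_state = "", step_sizes = NULL),
    class = "ncav_system")
}

#' @export
print.ncav_system <- function(x, ...) {
  cat(sprintf("ncav_system: %d-vertex membrane, %d receptors%s\n",
              nrow(x$mesh$vertices), length(x$receptors$vertex),
              if (is.null(x$carrier)) ", no carrier"
              else sprintf(", carrier with %d ligands at z = %.1f nm",
                           nrow(x$carrier$ligand_dirs), x$carrier$center[3])))
  invisible(x)
}

as_engine_state <- function(system) {
  p <- system$params
  st <- list(
    vertices = system$mesh$vertices,
    triangles = system$mesh$triangles,
    L = system$mesh$L, a0 = system$mesh$a0,
    link_max_factor = system$mesh$link_max_factor,
    kappa = p$membrane$kappa, sigma = p$membrane$sigma,
    pinned = as.integer(system$mesh$pinned),
    rec_vertex = as.integer(system$receptors$vertex),
    rec_theta = as.numeric(system$receptors$theta),
    rec_phi = as.numeric(system$receptors$phi),
    rec_bond = as.integer(system$receptors$bond),
    L_an = p$receptor$L_an, kappa_f = p$receptor$kappa_f,
    adjacency = system$adjacency,
    has_nc = !is.null(system$carrier))
  if (st$has_nc) {
    st$R_nc <- system$carrier$center
    st$quat <- system$carrier$quat
    st$r_nc <- system$carrier$r_nc
    st$L_ab <- system$carrier$L_ab
    st$ligand_dirs <- system$carrier$ligand_dirs
    st$lig_bond <- as.integer(system$carrier$lig_bond)
    st$H0 <- p$bond$H0
    st$kappa_b <- p$bond$kappa_b
    st$d_star <- p$bond$d_star
    st$L_z <- p$membrane$L_z
  }
  st
}

update_system_from_state <- function(system, state, rng_state) {
  system$mesh$vertices <- state$vertices
  system$mesh$triangles <- state$triangles
  system$receptors$vertex <- state$rec_vertex
  system$receptors$theta <- state$rec_theta
  system$receptors$phi <- state$rec_phi
  system$receptors$bond <- state$rec_bond
  if (!is.null(system$carrier)) {
    system$carrier$center <- state$R_nc
    system$carrier$quat <- state$quat
    system$carrier$lig_bond <- state$lig_bond
  }
  system$rng_state <- rng_state
  system$step_sizes <- state$deltas
  system$adjacency <- state$adjacency
  system
}

#' Total system energy
#'
#' Full recomputation of the Hamiltonian
#' \deqn{H_t = H_m + \sum_i H_f(\theta_i) + \sum_{bonds} H_b(d_{ij})}
#' from the current state; used for consistency checks against the engine's
#' incrementally maintained energies.
#'
#' @param system an `ncav_system`.
#' @return list with `H_m`, `H_f`, `H_b`, `total` (kBT), `area` (nm^2),
#'   `n_bonds`, and the order parameter `dR` (nm, `NA` without a carrier).
#' @export
total_energy <- function(system) {
  cpp_system_energy(as_engine_state(system))
}
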