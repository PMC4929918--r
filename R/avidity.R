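#' Multivalency statistics from a trajectory
#'
#' Normalized distribution P(n_b) of the number of simultaneous
#' receptor-ligand bonds over the bound segment of a trajectory (records
#' with order parameter below `r_star`), with block-bootstrap error bars,
#' the modal and the mean multivalency.
#'
#' @param traj trajectory data.frame from [run_simulation()].
#' @param r_star unbound cutoff (nm); records with `dR < r_star` are bound.
#' @param n_boot bootstrap replicates (block bootstrap, 20 blocks).
#' @return list of class `ncav_multivalency`: `table` (data.frame `n_b`,
#'   `P`, `P_se`), `mode`, `mean`, `n_samples`.
#' @export
multivalency_histogram <- function(traj, r_star = 100, n_boot = 200) {
  bound <- traj$n_b[is.finite(traj$dR) & traj$dR < r_star]
  if (length(bound) == 0)
    stop("insufficient sampling: no bound-state records (dR < ",
         r_star, " nm)")
  nmax <- max(bound)
  P <- tabulate(bound + 1, nbins = nmax + 1) / length(bound)
  nb <- 0:nmax
  P_se <- rep(NA_real_, length(P))
  if (n_boot > 0 && length(bound) >= 40) {
    blocks <- split(bound, cut(seq_along(bound), 20, labels = FALSE))
    reps <- replicate(n_boot, {
      s <- unlist(blocks[sample.int(20, replace = TRUE)])
      tabulate(s + 1, nbins = nmax + 1) / length(s)
    })
    P_se <- apply(reps, 1, sd)
  }
  structure(list(table = data.frame(n_b = nb, P = P, P_se = P_se),
                 mode = nb[which.max(P)], mean = mean(bound),
                 n_samples = length(bound)),
            class = "ncav_multivalency")
}

#' @export
print.ncav_multivalency <- function(x, ...) {
  cat(sprintf("P(n_b) over %d bound records: mode %d, mean %.2f\n",
              x$n_samples, x$mode, x$mean))
  invisible(x)
}

unwrap_path <- function(x, L) {
  if (length(x) < 2 || L <= 0) return(x)
  d <- diff(x)
  d <- d - L * round(d / L)
  x[1] + c(0, cumsum(d))
}

cov_ellipse_area <- function(xy, coverage = 1, floor_area = 1e-6) {
  if (nrow(xy) < 3) return(structure(floor_area, floored = TRUE))
  S <- cov(xy)
  dt <- det(S)
  if (!is.finite(dt) || dt < 1e-24) {
    warning("rank-deficient position covariance; returning the area floor")
    return(structure(floor_area, floored = TRUE))
  }
  pi * coverage^2 * sqrt(dt)
}

#' Entropy estimators for the bound carrier-membrane state
#'
#' From the bound-state segment of a simulation, estimates
#' \itemize{
#'   \item `A_R_b`: average area traversed by a bound receptor, as the
#'     covariance-ellipse area (`pi * coverage^2 * sqrt(det Sigma)`) of the
#'     pooled bound-receptor positions in the tangent plane defined by the
#'     mean orientation of the bound receptors, with the carrier-centre
#'     projection as origin;
#'   \item `A_N_b`: the same ellipse area for the carrier centre's lateral
#'     (unwrapped) coordinates;
#'   \item `rot_volume`: the product of the standard deviations of the
#'     three ZYZ Euler angles of the carrier orientation, measured relative
#'     to the mean orientation;
#'   \item `A_R_u = <A> / N_ant`: the area available per unbound receptor.
#' }
#'
#' @param result an `ncav_sim_result` (needs `bound_every > 0` recording).
#' @param r_star unbound cutoff (nm).
#' @param coverage ellipse coverage factor (1 = the 1-sigma ellipse).
#' @param min_samples minimum number of bound records required.
#' @return list of class `ncav_entropy` with fields `A_R_b`, `A_R_u`,
#'   `A_N_b` (nm^2), `rot_volume` (rad^3), `n_samples`, `tangent_normal`.
#' @export
entropy_estimators <- function(result, r_star = 100, coverage = 1,
                               min_samples = 100) {
  traj <- result$trajectory
  if (is.null(traj$nc_x)) stop("entropy estimators require a carrier run")
  L <- result$system$mesh$L
  bound <- is.finite(traj$dR) & traj$dR < r_star
  if (sum(bound) < min_samples)
    stop("insufficient sampling: ", sum(bound), " bound records < ",
         min_samples)
  # carrier translational area (unwrapped lateral path)
  xy <- cbind(unwrap_path(traj$nc_x[bound], L),
              unwrap_path(traj$nc_y[bound], L))
  A_N_b <- cov_ellipse_area(xy, coverage)
  # rotational volume relative to the mean orientation
  Q <- as.matrix(traj[bound, c("q_w", "q_x", "q_y", "q_z")])
  sgn <- ifelse(as.vector(Q %*% Q[1, ]) < 0, -1, 1)  # double-cover sign fix
  Q <- Q * sgn
  qm <- colMeans(Q)
  qm <- qm / sqrt(sum(qm^2))
  qconj <- c(qm[1], -qm[2:4])
  rel <- t(apply(Q, 1, function(q) quat_mul(qconj, q)))
  eul <- quat_to_euler(rel)
  rot_volume <- prod(apply(eul, 2, sd))
  # bound-receptor traversal area in the mean-orientation tangent plane
  b <- result$bound
  rec_idx <- match(b$record, which(bound))
  b <- b[!is.na(rec_idx), , drop = FALSE]
  rec_idx <- rec_idx[!is.na(rec_idx)]
  A_R_b <- structure(NA_real_, floored = FALSE)
  normal <- c(0, 0, 1)
  if (nrow(b) >= 3) {
    bt <- traj[bound, ][rec_idx, ]
    rel3 <- cbind(wrap_diff(b$x - bt$nc_x, L), wrap_diff(b$y - bt$nc_y, L),
                  b$z - bt$nc_z)
    u <- -rel3 / sqrt(rowSums(rel3^2))      # receptor base -> carrier centre
    normal <- colMeans(u)
    normal <- normal / sqrt(sum(normal^2))
    t1 <- c(1, 0, 0) - normal[1] * normal
    if (sqrt(sum(t1^2)) < 1e-6) t1 <- c(0, 1, 0) - normal[2] * normal
    t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(normal[2] * t1[3] - normal[3] * t1[2],
            normal[3] * t1[1] - normal[1] * t1[3],
            normal[1] * t1[2] - normal[2] * t1[1])
    tcoords <- cbind(rel3 %*% t1, rel3 %*% t2)
    A_R_b <- cov_ellipse_area(tcoords, coverage)
  }
  A_R_u <- mean(traj$area[bound]) / length(result$system$receptors$vertex)
  structure(list(A_R_b = A_R_b, A_R_u = A_R_u, A_N_b = A_N_b,
                 rot_volume = rot_volume, n_samples = sum(bound),
                 tangent_normal = normal, coverage = coverage),
            class = "ncav_entropy")
}

wrap_diff <- function(d, L) if (L > 0) d - L * round(d / L) else d

quat_mul <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Absolute association constant of multivalent carrier binding
#'
#' Assembles the association constant
#' \deqn{K_a = \binom{N_{ant}}{n_b} \binom{N_{ab}}{n_b}
#'   \frac{\Delta\phi\,\Delta\theta\,\Delta\psi}{8\pi^2}
#'   \left(\frac{A_R^b}{A_R^u}\right)^{n_b}
#'   \frac{A_N^b}{L_z (L_z - r^*)} \int_0^{r^*} e^{-W(r)} dr}
#' from the multivalency estimate, the entropy estimators and the anchored
#' PMF.  All factors are computed in log space (log-Gamma for the
#' combinatorial factors); the enthalpic integral is a trapezoid on the PMF
#' grid restricted to `[min(dR), r_star]` (the unsampled hard-core region
#' below the grid contributes negligibly).
#'
#' @param pmf anchored `ncav_pmf` in kBT.
#' @param n_b number of bonds to plug in (modal multivalency by default
#'   convention; pass `stats$mode` or `round(stats$mean)`).
#' @param ent entropy estimates from [entropy_estimators()] (or a compatible
#'   list with `A_R_b`, `A_R_u`, `A_N_b`, `rot_volume`).
#' @param N_ant receptor count on the patch.
#' @param N_ab ligand count on the carrier.
#' @param L_z box height (nm).
#' @param r_star unbound cutoff (nm).
#' @return object of class `ncav_avidity`: `log_Ka`, `Ka`, `Kd` (internal
#'   nm-based units), and the additive `components` of `log_Ka`
#'   (combinatorial, rotational, receptor-translational,
#'   carrier-translational, enthalpic).
#' @export
association_constant <- function(pmf, n_b, ent, N_ant, N_ab, L_z = 500,
                                 r_star = 100) {
  if (!isTRUE(attr(pmf, "anchored")))
    stop("association constant requires an anchored PMF")
  if (n_b > N_ant || n_b > N_ab)
    stop("n_b = ", n_b, " exceeds the receptor or ligand count")
  if (n_b < 0) stop("n_b must be non-negative")
  log_comb <- lchoose(N_ant, n_b) + lchoose(N_ab, n_b)
  log_rot <- log(ent$rot_volume / (8 * pi^2))
  log_trans_rec <- n_b * log(ent$A_R_b / ent$A_R_u)
  log_trans_nc <- log(ent$A_N_b) - log(L_z * (L_z - r_star))
  grid <- pmf$dR <= r_star
  if (sum(grid) < 2) stop("PMF grid does not reach below r* = ", r_star)
  x <- pmf$dR[grid]; y <- exp(-pmf$W[grid])
  integral <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  log_enth <- log(integral)
  comps <- c(combinatorial = log_comb, rotational = log_rot,
             receptor_translational = log_trans_rec,
             carrier_translational = log_trans_nc,
             enthalpic = log_enth)
  log_Ka <- sum(comps)
  structure(list(log_Ka = log_Ka, Ka = exp(log_Ka), Kd = exp(-log_Ka),
                 components = comps, n_b = n_b,
                 inputs = list(N_ant = N_ant, N_ab = N_ab, L_z = L_z,
                               r_star = r_star)),
            class = "ncav_avidity")
}

#' @export
print.ncav_avidity <- function(x, ...) {
  cat(sprintf("K_a (internal nm units): exp(%.3f); n_b = %d\n",
              x$log_Ka, x$n_b))
  print(round(x$components, 3))
  invisible(x)
}

#' Interpolate the association constant between receptor densities
#'
#' Linear interpolation of the binding free energy F = -ln K_a between two
#' simulated receptor densities, equivalent to geometric interpolation of
#' K_a itself:
#' \deqn{K_a^* = K_{a1}^{(n_2-n^*)/(n_2-n_1)} K_{a2}^{(n^*-n_1)/(n_2-n_1)}.}
#'
#' @param Ka1,Ka2 association constants at densities `n1 < n2` (may be
#'   `ncav_avidity` objects or positive numbers).
#' @param n1,n2 bracketing receptor densities.
#' @param n_star target density; must lie in `[n1, n2]` unless
#'   `extrapolate = TRUE`.
#' @param extrapolate allow extrapolation outside the bracket.
#' @return interpolated K_a (list with `log_Ka`, `Ka`, `Kd`).
#' @export
interpolate_Ka <- function(Ka1, Ka2, n1, n2, n_star, extrapolate = FALSE) {
  if (n2 <= n1) stop("need n2 > n1")
  lk1 <- if (inherits(Ka1, "ncav_avidity")) Ka1$log_Ka else log(Ka1)
  lk2 <- if (inherits(Ka2, "ncav_avidity")) Ka2$log_Ka else log(Ka2)
  if (!extrapolate && (n_star < n1 || n_star > n2))
    stop("n_star = ", n_star, " outside [", n1, ", ", n2,
         "]; set extrapolate = TRUE to allow")
  t <- (n_star - n1) / (n2 - n1)
  lk <- (1 - t) * lk1 + t * lk2
  list(log_Ka = lk, Ka = exp(lk), Kd = exp(-lk))
}

#' Dissociation constant ratio against a reference system
#'
#' @param result,reference `ncav_avidity` objects (or lists with `log_Ka`).
#' @return list with `ratio` (K_d / K_d_ref) and `log_ratio`.
#' @export
normalize_kd <- function(result, reference) {
  lr <- reference$log_Ka - result$log_Ka
  list(ratio = exp(lr), log_ratio = lr)
}
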