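#' Closed icosphere fixture
#'
#' Subdivided icosahedron projected onto a sphere of radius `R`; a closed,
#' consistently outward-oriented mesh used as an analytic oracle for the
#' curvature and bending-energy estimators (c1 = c2 = 1/R; bending energy
#' 8 pi kappa independent of R).
#'
#' @param R sphere radius (nm).
#' @param subdiv number of 4-to-1 subdivision rounds (0 gives the raw
#'   icosahedron).
#' @return an `ncav_mesh` with `L = -1` (non-periodic).
#' @export
icosphere <- function(R = 100, subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    cache <- new.env(parent = emptyenv())
    midpoint <- function(a, b) {
      key <- paste(sort(c(a, b)), collapse = "-")
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      p <- V[a, ] + V[b, ]
      V <<- rbind(V, p / sqrt(sum(p^2)))
      cache[[key]] <- nrow(V)
      nrow(V)
    }
    newF <- matrix(0L, 4 * nrow(F), 3)
    for (f in seq_len(nrow(F))) {
      a <- F[f, 1]; b <- F[f, 2]; cc <- F[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newF[4 * f - 3, ] <- c(a, ab, ca)
      newF[4 * f - 2, ] <- c(b, bc, ab)
      newF[4 * f - 1, ] <- c(cc, ca, bc)
      newF[4 * f, ] <- c(ab, bc, ca)
    }
    F <- newF
  }
  new_mesh(V * R, F, L = -1, a0 = 1, link_max_factor = 1e9)
}

#' Open cylinder fixture
#'
#' Triangulated cylinder of radius `R` along z, used as an analytic oracle
#' for the principal-curvature split (max principal curvature 1/R, min 0).
#' The two open rims are boundary vertices; curvature is asserted on interior
#' vertices only.
#'
#' @param R cylinder radius (nm).
#' @param length cylinder length (nm).
#' @param n_circ,n_axial discretization counts around and along the axis.
#' @return an `ncav_mesh` with `L = -1`.
#' @export
cylinder_mesh <- function(R = 50, length = 300, n_circ = 40, n_axial = 30) {
  zstep <- length / (n_axial - 1)
  g <- expand.grid(i = 0:(n_circ - 1), k = 0:(n_axial - 1))
  th <- 2 * pi * g$i / n_circ
  V <- cbind(R * cos(th), R * sin(th), g$k * zstep)
  idx <- function(i, k) (i %% n_circ) + n_circ * k + 1L
  F <- NULL
  for (k in 0:(n_axial - 2)) {
    i <- 0:(n_circ - 1)
    F <- rbind(F,
               cbind(idx(i, k), idx(i + 1, k), idx(i + 1, k + 1)),
               cbind(idx(i, k), idx(i + 1, k + 1), idx(i, k + 1)))
  }
  new_mesh(V, F, L = -1, a0 = 1, link_max_factor = 1e9)
}

#' Sinusoidal displacement of a flat patch
#'
#' Flat periodic patch with heights h(x, y) = h0 sin(2 pi periods x / L),
#' an analytic fixture for the excess-area and height-field oracles.
#'
#' @param L,a0 as in [flat_patch()].
#' @param h0 amplitude (nm).
#' @param periods number of full periods across the box.
#' @return an `ncav_mesh`.
#' @export
sinusoid_patch <- function(L, a0 = 10, h0 = 25, periods = 1) {
  m <- flat_patch(L, a0)
  m$vertices[, 3] <- h0 * sin(2 * pi * periods * m$vertices[, 1] / L)
  m
}

#' Deterministic fixture generator
#'
#' Single entry point producing the synthetic fixtures used by the test
#' oracles; generation is deterministic given the spec (seeded where
#' randomness is involved).
#'
#' @param kind one of `"icosphere"`, `"cylinder"`, `"sinusoid-patch"`,
#'   `"gaussian-field"`, `"toy-1d-umbrella"`, `"toy-binding"`.
#' @param ... parameters forwarded to the specific generator.
#' @return the fixture: a mesh, a height-field matrix, or a toy-system list
#'   with its embedded analytic reference values.
#' @export
generate_fixture <- function(kind = c("icosphere", "cylinder",
                                      "sinusoid-patch", "gaussian-field",
                                      "toy-1d-umbrella", "toy-binding"),
                             ...) {
  kind <- match.arg(kind)
  switch(kind,
    "icosphere" = icosphere(...),
    "cylinder" = cylinder_mesh(...),
    "sinusoid-patch" = sinusoid_patch(...),
    "gaussian-field" = gaussian_membrane_field(...),
    "toy-1d-umbrella" = toy_umbrella_system(...),
    "toy-binding" = toy_binding_system(...))
}

#' One-dimensional umbrella-sampling toy system
#'
#' A particle in a potential with a parabolic well of known depth centred at
#' `x0` (spanning `x0 - w` to `x0 + w`, where it joins an exactly flat
#' plateau), plus a steep repulsive inner wall.  Window samples are drawn by
#' inverse-CDF sampling of the exact biased density on a fine grid, so the
#' fixture tests WHAM/TI reconstruction independently of any Monte Carlo
#' engine.
#'
#' @param depth well depth (kBT); the anchored PMF minimum is `-depth`.
#' @param x0 well centre.
#' @param w half-width of the well; the plateau starts at `x0 + w`.
#' @param xmax plateau end.
#' @return list with `V` (vectorized potential), `depth`, `x0`, `w`, `xmax`.
#' @export
toy_umbrella_system <- function(depth = 5, x0 = 20, w = 8, xmax = 60) {
  force(depth); force(x0); force(w)
  V <- function(x) {
    out <- numeric(length(x))
    well <- x >= x0 - w & x <= x0 + w
    out[well] <- depth * (((x[well] - x0) / w)^2 - 1)
    left <- x < x0 - w
    out[left] <- 2 * (x[left] - (x0 - w))^2   # steep inner wall
    out
  }
  list(V = V, depth = depth, x0 = x0, w = w, xmax = xmax)
}

#' Two-state receptor-ligand binding toy system
#'
#' A single receptor on a rigid flat patch below a single fixed ligand tip,
#' with only flexure and bond moves active.  The embedded reference is the
#' exact bound-state probability from two-dimensional quadrature of the
#' configurational integral over the receptor orientation hemisphere:
#' \deqn{p_b = Z_b / (Z_b + Z_u)} with
#' `Z_u = int sin(th) exp(-H_f) dth dphi` over the hemisphere and
#' `Z_b` the same integral restricted to orientations with tip-tip distance
#' `d <= d*`, weighted additionally by `exp(-H_b(d))`.
#'
#' @param params model parameters ([load_config()] tree); the bond depth can
#'   be overridden to keep the two-state occupancy away from 0/1.
#' @param tip_height height of the ligand tip above the receptor base (nm).
#' @param n_grid quadrature resolution.
#' @return list with the system geometry, parameters, and `p_bound_exact`.
#' @export
toy_binding_system <- function(params = load_config(), tip_height = 19.5,
                               n_grid = 200001) {
  kf <- params$receptor$kappa_f
  L_an <- params$receptor$L_an
  H0 <- params$bond$H0
  kb <- params$bond$kappa_b
  ds <- params$bond$d_star
  # ligand tip straight above the base: d depends on theta only
  th <- seq(0, pi / 2, length.out = n_grid)
  tipx <- L_an * sin(th)
  tipz <- L_an * cos(th)
  d <- sqrt(tipx^2 + (tip_height - tipz)^2)
  wf <- sin(th) * exp(-kf * th^2 / 2)
  bonded <- d <= ds
  wb <- ifelse(bonded, wf * exp(-(H0 + 0.5 * kb * (d - ds)^2)), 0)
  dth <- th[2] - th[1]
  Zu <- sum(wf) * dth          # phi integral cancels in the ratio
  Zb <- sum(wb) * dth
  list(tip_height = tip_height, params = params,
       p_bound_exact = Zb / (Zu + Zb))
}

#' Ruffled membrane patch with a target excess area
#'
#' Flat periodic patch folded into a triangular-wave corrugation running
#' along the lattice anti-diagonal, with the amplitude chosen by bisection
#' so the stored (excess) membrane area matches `target_aex` while every
#' link stays below 98% of the upper tether bound.  The anti-diagonal
#' orientation is what makes large stored areas reachable on this lattice:
#' the split diagonals of the grid are level lines of the corrugation, so
#' only the short links carry the slope.  Membranes storing large excess
#' areas equilibrate extremely slowly under local moves, so high-excess-area
#' simulations are prepared in such a folded state (the fold pattern then
#' roughens thermally) rather than grown from a flat sheet; the realized
#' excess area is returned as an attribute and its stationarity over the
#' production window should be checked from the trajectory.
#'
#' @param L,a0,link_max_factor,spacing as in [flat_patch()]; the default
#'   spacing is `a0` (the dense lattice): a compressed network is exactly
#'   what a membrane storing a large excess area is.
#' @param target_aex target excess area (percent).
#' @param n_folds number of corrugation periods across the box diagonal.
#' @return an `ncav_mesh` with attribute `Aex`.
#' @export
ruffled_patch <- function(L, a0 = 10, link_max_factor = sqrt(3),
                          spacing = a0, target_aex = 40, n_folds = 4) {
  m <- flat_patch(L, a0, link_max_factor, spacing)
  u <- (m$vertices[, 1] - m$vertices[, 2]) / sqrt(2)   # anti-diagonal coord
  lambda <- (L / sqrt(2)) / n_folds
  tri_wave <- function(t) 2 * abs(t / lambda - floor(t / lambda + 0.5))
  hv <- tri_wave(u)                                    # unit amplitude
  lmax_allow <- 0.98 * a0 * link_max_factor
  set_height <- function(amp) {
    mm <- m
    mm$vertices[, 3] <- amp * hv
    mm
  }
  max_link <- function(amp) max(mesh_links(set_height(amp))$length)
  lo <- 0; hi <- lambda
  while (max_link(hi) < lmax_allow && hi < 64 * lambda) hi <- hi * 2
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (max_link(mid) < lmax_allow) lo <- mid else hi <- mid
  }
  amp_cap <- lo
  aex_of <- function(amp) excess_area(set_height(amp))
  amp <- amp_cap
  if (aex_of(amp_cap) > target_aex) {
    lo <- 0; hi <- amp_cap
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if (aex_of(mid) < target_aex) lo <- mid else hi <- mid
    }
    amp <- hi
  }
  out <- set_height(amp)
  attr(out, "Aex") <- aex_of(amp)
  out
}
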