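#' Build a flat periodic membrane patch
#'
#' Constructs a regular n x n square grid over an L x L periodic box (torus
#' topology), each square split into two triangles with a common diagonal
#' direction, and all heights zero.  The counts obey N_m = n^2, T_m = 2 n^2,
#' L_m = 3 n^2, so the torus Euler relation N_m + T_m - L_m = 0 holds by
#' construction.  Straight links have length `a0` (the lower tether bound)
#' and diagonal links a0*sqrt(2), inside the admissible range
#' [a0, a0*link_max_factor] for the default factor sqrt(3).
#'
#' For fluctuation production runs, `spacing` can be set above `a0` (up to
#' `a0 * link_max_factor / sqrt(2)` so the grid diagonals stay admissible):
#' a hard-tether network has an entropically preferred link length of about
#' 1.2 `a0`, and initializing the lattice near its rest spacing keeps the
#' framed sheet stress-free, avoiding the long-wavelength buckling that an
#' over-dense lattice develops under a fixed projected area.
#'
#' @param L projected box side (nm); must be an integer multiple of
#'   `spacing`.
#' @param a0 discretization length (nm); also the lower link-length bound.
#' @param link_max_factor upper link-length bound in units of `a0`.
#' @param spacing initial lattice constant (nm); defaults to `a0`.
#' @return an object of class `ncav_mesh`: a list with `vertices` (N x 3
#'   matrix, nm), `triangles` (T x 3 integer matrix, 1-based, consistently
#'   oriented with upward normals), `L`, `a0`, `link_max_factor`, and
#'   `pinned` (integer vector of immobile vertex ids, initially empty).
#' @examples
#' m <- flat_patch(40, 10)
#' mesh_counts(m)       # N_m = 16, T_m = 32, L_m = 48, Euler defect 0
#' excess_area(m)       # 0: flat sheet
#' @export
flat_patch <- function(L, a0 = 10, link_max_factor = sqrt(3),
                       spacing = a0) {
  if (spacing < a0 || spacing * sqrt(2) > a0 * link_max_factor)
    stop("spacing must lie in [a0, a0*link_max_factor/sqrt(2)] so that all ",
         "initial links are admissible")
  n <- L / spacing
  if (abs(n - round(n)) > 1e-9)
    stop("L/spacing must be an integer (got L = ", L, ", spacing = ",
         spacing, ")")
  n <- round(n)
  if (n < 4) stop("degenerate mesh: L/spacing must be at least 4, got ", n)
  g <- expand.grid(i = 0:(n - 1), j = 0:(n - 1))
  vertices <- cbind(x = g$i * spacing, y = g$j * spacing, z = 0)
  idx <- function(i, j) (i %% n) + n * (j %% n) + 1L
  i <- g$i; j <- g$j
  v00 <- idx(i, j); v10 <- idx(i + 1, j)
  v01 <- idx(i, j + 1); v11 <- idx(i + 1, j + 1)
  triangles <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  new_mesh(vertices, triangles, L = L, a0 = a0,
           link_max_factor = link_max_factor)
}

new_mesh <- function(vertices, triangles, L, a0, link_max_factor,
                     pinned = integer(0)) {
  vertices <- unname(as.matrix(vertices))
  storage.mode(vertices) <- "double"
  triangles <- unname(as.matrix(triangles))
  storage.mode(triangles) <- "integer"
  structure(
    list(vertices = vertices, triangles = triangles, L = L, a0 = a0,
         link_max_factor = link_max_factor, pinned = as.integer(pinned)),
    class = "ncav_mesh")
}

#' @export
print.ncav_mesh <- function(x, ...) {
  cnt <- mesh_counts(x)
  cat(sprintf(
    "ncav_mesh: %d vertices, %d triangles, %d links (Euler defect %d)\n",
    cnt["N_m"], cnt["T_m"], cnt["L_m"], cnt["euler"]))
  if (x$L > 0) cat(sprintf("  periodic box %g x %g nm, a0 = %g nm\n",
                           x$L, x$L, x$a0))
  else cat("  non-periodic (closed or open fixture mesh)\n")
  if (length(x$pinned)) cat(sprintf("  %d pinned vertices\n", length(x$pinned)))
  invisible(x)
}

mesh_core_info <- function(mesh) {
  cpp_mesh_info(mesh$vertices, mesh$triangles, mesh$L, mesh$a0,
                mesh$link_max_factor)
}

#' Mesh element counts and topology check
#'
#' @param mesh an `ncav_mesh`.
#' @return named integer vector with `N_m` (vertices), `T_m` (triangles),
#'   `L_m` (links) and `euler` = N_m + T_m - L_m (0 on a torus).
#' @export
mesh_counts <- function(mesh) {
  info <- mesh_core_info(mesh)
  c(N_m = info$n_vertices, T_m = info$n_triangles, L_m = info$n_links,
    euler = info$euler_defect)
}

#' Link (edge) table of a mesh
#'
#' @param mesh an `ncav_mesh`.
#' @return data.frame with 1-based vertex ids `a`, `b` and the minimum-image
#'   link length (nm).
#' @export
mesh_links <- function(mesh) {
  info <- mesh_core_info(mesh)
  data.frame(a = info$links[, 1], b = info$links[, 2],
             length = info$link_lengths)
}

#' Per-vertex discrete curvature
#'
#' Estimates principal curvatures at every vertex from the cotangent
#' mean-curvature vector and the angle-deficit Gaussian curvature, both
#' normalized by the obtuse-safe mixed Voronoi area.  The vertex-associated
#' area `A_v` is one third of the incident triangle area, so that
#' `sum(A_v)` equals the total curvilinear area exactly.  Sign convention:
#' curvature is positive where the surface bulges along the vertex normal
#' (an outward-oriented sphere of radius R has c1 = c2 = +1/R).
#'
#' Boundary vertices of open fixture meshes get `NA` curvatures.
#'
#' @param mesh an `ncav_mesh`.
#' @return data.frame with columns `c1`, `c2` (principal curvatures, 1/nm),
#'   `H` (mean curvature), `K` (Gaussian curvature), `A_v` (nm^2) and
#'   `boundary` (logical).
#' @export
vertex_curvature <- function(mesh) {
  r <- cpp_vertex_curvature(mesh$vertices, mesh$triangles, mesh$L, mesh$a0,
                            mesh$link_max_factor)
  data.frame(c1 = r$c1, c2 = r$c2, H = r$H, K = r$K, A_v = r$A_v,
             boundary = r$boundary)
}

#' Helfrich elastic energy of a membrane mesh
#'
#' Discretized curvature energy
#' \deqn{H_m = \sum_v [\kappa/2\,(c_{1,v}+c_{2,v})^2 A_v + \sigma A_v]}
#' in kBT, with per-vertex principal curvatures from [vertex_curvature()].
#' The bending part is linear in `kappa` and the tension part linear in
#' `sigma` at fixed geometry.
#'
#' @param mesh an `ncav_mesh` (periodic patch or closed fixture).
#' @param kappa bending rigidity (kBT).
#' @param sigma surface tension (kBT/nm^2).
#' @return list with `bending`, `tension`, `total` (kBT) and `area` (nm^2).
#' @examples
#' m <- flat_patch(80, 10)
#' helfrich_energy(m, kappa = 20, sigma = 0)$total  # 0 for a flat sheet
#' @export
helfrich_energy <- function(mesh, kappa, sigma = 0) {
  cpp_helfrich(mesh$vertices, mesh$triangles, mesh$L, mesh$a0,
               mesh$link_max_factor, kappa, sigma)
}

#' Membrane excess area
#'
#' Percentage by which the curvilinear area exceeds the projected area:
#' `100 * (A - Ap) / A` with `Ap = L^2`.
#'
#' @param mesh a periodic `ncav_mesh`.
#' @return excess area in percent.
#' @export
excess_area <- function(mesh) {
  if (mesh$L <= 0) stop("excess area requires a periodic patch (L > 0)")
  A <- mesh_core_info(mesh)$area
  100 * (A - mesh$L^2) / A
}

#' Pin a random fraction of vertices (mean-field cytoskeleton)
#'
#' Marks a uniformly random subset of vertices as immobile under Monte Carlo
#' vertex moves; pinned vertices still contribute to all energies.  Pinning
#' mimics attachment of the cortical cytoskeleton: fractions of 0-12%
#' correspond to cytoskeletal mesh sizes of roughly >500 nm down to ~150 nm.
#'
#' @param mesh an `ncav_mesh`.
#' @param fraction fraction of vertices to pin, in [0, 0.12] by default
#'   validation (`max_fraction` relaxes this).
#' @param seed integer seed making the pinned set reproducible.
#' @param max_fraction upper validation bound.
#' @return the mesh with its `pinned` set replaced.
#' @export
pin_vertices <- function(mesh, fraction, seed, max_fraction = 0.12) {
  if (fraction < 0 || fraction > max_fraction)
    stop("pinning fraction must lie in [0, ", max_fraction, "]")
  n <- nrow(mesh$vertices)
  k <- round(fraction * n)
  set.seed(seed)
  mesh$pinned <- if (k > 0) sort(sample.int(n, k)) else integer(0)
  attr(mesh$pinned, "seed") <- seed
  mesh
}

fmt9 <- function(x) sprintf("%.9g", x)

#' Write / read meshes in OFF format
#'
#' Plain-text Object File Format; coordinates are written with 9 significant
#' digits so that a write/read round trip reproduces them bit-for-bit at that
#' precision.  Periodic-box metadata is preserved in a comment line.
#'
#' @param mesh an `ncav_mesh`.
#' @param path file path.
#' @return `read_off` returns an `ncav_mesh`; `write_off` returns `path`
#'   invisibly.
#' @export
write_off <- function(mesh, path) {
  cnt <- mesh_counts(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("# ncavidity L=%s a0=%s link_max_factor=%s",
                     fmt9(mesh$L), fmt9(mesh$a0),
                     fmt9(mesh$link_max_factor)), con)
  writeLines(sprintf("%d %d %d", cnt["N_m"], cnt["T_m"], cnt["L_m"]), con)
  writeLines(apply(mesh$vertices, 1, function(v)
    paste(fmt9(v), collapse = " ")), con)
  writeLines(apply(mesh$triangles, 1, function(t)
    paste(c(3, t - 1L), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_off
#' @export
read_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (trimws(lines[1]) != "OFF") stop("not an OFF file: ", path)
  meta <- c(L = -1, a0 = 1, link_max_factor = 1e9)
  body <- lines[-1]
  comments <- body[startsWith(trimws(body), "#")]
  body <- body[!startsWith(trimws(body), "#")]
  for (cm in comments) {
    for (key in names(meta)) {
      mm <- regmatches(cm, regexec(paste0(key, "=([-0-9.eE+]+)"), cm))[[1]]
      if (length(mm) == 2) meta[key] <- as.numeric(mm[2])
    }
  }
  hdr <- as.integer(strsplit(trimws(body[1]), "\\s+")[[1]])
  nv <- hdr[1]; nf <- hdr[2]
  vl <- body[2:(1 + nv)]
  fl <- body[(2 + nv):(1 + nv + nf)]
  vertices <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), as.numeric))
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), as.integer))
  if (any(faces[, 1] != 3)) stop("non-triangular face in OFF file")
  new_mesh(vertices, faces[, 2:4] + 1L, L = meta[["L"]], a0 = meta[["a0"]],
           link_max_factor = meta[["link_max_factor"]])
}

#' Write / read meshes as legacy ASCII VTK polydata
#'
#' @inheritParams write_off
#' @export
write_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("ncavidity mesh L=%s a0=%s link_max_factor=%s",
                       fmt9(mesh$L), fmt9(mesh$a0),
                       fmt9(mesh$link_max_factor)),
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(mesh$vertices))), con)
  writeLines(apply(mesh$vertices, 1, function(v)
    paste(fmt9(v), collapse = " ")), con)
  nt <- nrow(mesh$triangles)
  writeLines(sprintf("POLYGONS %d %d", nt, 4L * nt), con)
  writeLines(apply(mesh$triangles, 1, function(t)
    paste(c(3, t - 1L), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_vtk
#' @export
read_vtk <- function(path) {
  lines <- readLines(path)
  meta <- c(L = -1, a0 = 1, link_max_factor = 1e9)
  for (key in names(meta)) {
    mm <- regmatches(lines[2], regexec(paste0(key, "=([-0-9.eE+]+)"),
                                       lines[2]))[[1]]
    if (length(mm) == 2) meta[key] <- as.numeric(mm[2])
  }
  ip <- grep("^POINTS", lines)
  np <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  vertices <- do.call(rbind, lapply(
    strsplit(trimws(lines[(ip + 1):(ip + np)]), "\\s+"), as.numeric))
  it <- grep("^POLYGONS", lines)
  nt <- as.integer(strsplit(lines[it], "\\s+")[[1]][2])
  faces <- do.call(rbind, lapply(
    strsplit(trimws(lines[(it + 1):(it + nt)]), "\\s+"), as.integer))
  if (any(faces[, 1] != 3)) stop("non-triangular polygon in VTK file")
  new_mesh(vertices, faces[, 2:4] + 1L, L = meta[["L"]], a0 = meta[["a0"]],
           link_max_factor = meta[["link_max_factor"]])
}
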