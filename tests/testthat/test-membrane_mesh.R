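test_that("flat patch has torus topology and exact grid counts", {
  for (L in c(40, 510)) {
    m <- flat_patch(L, 10)
    n <- L / 10
    cnt <- mesh_counts(m)
    expect_equal(unname(cnt["N_m"]), n^2)
    expect_equal(unname(cnt["T_m"]), 2 * n^2)
    expect_equal(unname(cnt["L_m"]), 3 * n^2)
    expect_equal(unname(cnt["euler"]), 0)
    expect_equal(excess_area(m), 0, tolerance = 1e-12)
  }
  # all initial link lengths admissible: a0 and a0*sqrt(2) within bounds
  li <- mesh_links(flat_patch(80, 10))
  expect_true(all(li$length >= 10 - 1e-9))
  expect_true(all(li$length <= 10 * sqrt(3) + 1e-9))
  expect_setequal(round(unique(li$length), 6), round(c(10, 10 * sqrt(2)), 6))
})

test_that("flat patch rejects bad geometry requests", {
  expect_error(flat_patch(45, 10), "integer")
  expect_error(flat_patch(30, 10), "at least 4")
  expect_error(flat_patch(120, 10, spacing = 15), "admissible")
})

test_that("curvature estimator matches sphere and cylinder analytics", {
  ic <- icosphere(R = 100, subdiv = 3)
  cur <- vertex_curvature(ic)
  expect_false(any(cur$boundary))
  expect_true(all(abs(cur$c1 * 100 - 1) < 0.05))
  expect_true(all(abs(cur$c2 * 100 - 1) < 0.05))
  cy <- cylinder_mesh(R = 50, length = 300, n_circ = 40, n_axial = 30)
  cc <- vertex_curvature(cy)
  interior <- !cc$boundary & cy$vertices[, 3] > 50 & cy$vertices[, 3] < 250
  cmax <- pmax(cc$c1, cc$c2)[interior]
  cmin <- pmin(cc$c1, cc$c2)[interior]
  expect_true(all(abs(cmax - 0.02) < 0.001))
  expect_true(all(abs(cmin) < 0.001))
})

test_that("flat patch is exactly curvature-free", {
  cur <- vertex_curvature(flat_patch(80, 10))
  expect_equal(max(abs(cur$c1)), 0, tolerance = 1e-12)
  expect_equal(max(abs(cur$c2)), 0, tolerance = 1e-12)
})

test_that("vertex areas tile the curvilinear area exactly", {
  m <- sinusoid_patch(200, 10, h0 = 15)
  cur <- vertex_curvature(m)
  info <- helfrich_energy(m, kappa = 1, sigma = 0)
  expect_equal(sum(cur$A_v), info$area, tolerance = 1e-9)
})

test_that("Helfrich energy: flat sheet, sphere oracle, linearity", {
  m <- flat_patch(80, 10)
  e <- helfrich_energy(m, kappa = 20, sigma = 0)
  expect_equal(e$total, 0, tolerance = 1e-10)
  # flat patch with tension: exactly sigma * A
  e2 <- helfrich_energy(m, kappa = 20, sigma = 0.5)
  expect_equal(e2$total, 0.5 * 80^2, tolerance = 1e-9)
  # closed sphere: bending energy 8 pi kappa for any radius
  for (R in c(60, 150)) {
    ic <- icosphere(R = R, subdiv = 3)
    eb <- helfrich_energy(ic, kappa = 20, sigma = 0)$bending
    expect_within(eb, 8 * pi * 20, 0.10)
  }
  # doubling kappa doubles the bending part exactly
  ic <- icosphere(R = 100, subdiv = 2)
  expect_equal(helfrich_energy(ic, kappa = 40)$bending,
               2 * helfrich_energy(ic, kappa = 20)$bending,
               tolerance = 1e-12)
})

test_that("Helfrich energy is invariant under rigid motions", {
  m <- sinusoid_patch(120, 10, h0 = 10)
  m$L <- -1  # treat as a free-floating sheet for the rigid-motion check
  e0 <- helfrich_energy(m, kappa = 20, sigma = 0.3)$total
  mt <- m
  mt$vertices <- mt$vertices + matrix(c(5, -3, 11), nrow(mt$vertices), 3,
                                      byrow = TRUE)
  expect_equal(helfrich_energy(mt, 20, 0.3)$total, e0, tolerance = 1e-9)
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  mr <- m
  mr$vertices <- m$vertices %*% Rz
  expect_equal(helfrich_energy(mr, 20, 0.3)$total, e0, tolerance = 1e-9)
})

test_that("excess area matches the arc-length quadrature oracle", {
  h0 <- 25; L <- 500
  m <- sinusoid_patch(L, a0 = 5, h0 = h0)
  f <- function(x) sqrt(1 + (h0 * 2 * pi / L * cos(2 * pi * x / L))^2)
  A <- integrate(f, 0, L, rel.tol = 1e-10)$value * L
  expect_within(excess_area(m), 100 * (A - L^2) / A, 0.01)
  # monotone in the amplitude
  aex <- vapply(c(5, 10, 20, 30), function(h)
    excess_area(sinusoid_patch(L, a0 = 10, h0 = h)), numeric(1))
  expect_true(all(diff(aex) > 0))
})

test_that("link flips preserve topology and length bounds", {
  sys <- tiny_membrane_system(L = 80)
  cfg <- sim_config(steps = 2e5, seed = 9, move_weights = only_moves("flip"),
                    tune = FALSE, debug = TRUE)
  run <- run_simulation(sys, cfg)
  expect_gt(run$counters$accepted[2], 1000)
  expect_equal(run$diagnostics$flip_violations, 0)
  cnt <- mesh_counts(run$system$mesh)
  expect_equal(unname(cnt["euler"]), 0)
  li <- mesh_links(run$system$mesh)
  expect_true(all(li$length >= 10 - 1e-9 & li$length <= 10 * sqrt(3) + 1e-9))
})

test_that("accepted moves never violate link bounds or topology", {
  sys <- tiny_membrane_system(L = 96, spacing = 12, kappa = 20)
  run <- run_simulation(sys, sim_config(
    steps = 3e5, seed = 4, move_weights = only_moves("vertex", "flip"),
    debug = TRUE))
  li <- mesh_links(run$system$mesh)
  expect_true(all(li$length >= 10 - 1e-9 & li$length <= 10 * sqrt(3) + 1e-9))
  expect_equal(unname(mesh_counts(run$system$mesh)["euler"]), 0)
  expect_equal(run$diagnostics$flip_violations, 0)
})

test_that("degenerate triangles are reported by name", {
  m <- flat_patch(40, 10)
  m$vertices[2, ] <- m$vertices[1, ]   # collapse an edge
  expect_error(vertex_curvature(m), "triangle")
})

test_that("pinning validates its fraction and is reproducible", {
  m <- flat_patch(80, 10)
  expect_error(pin_vertices(m, 0.5, seed = 1), "0.12")
  m1 <- pin_vertices(m, 0.1, seed = 7)
  m2 <- pin_vertices(m, 0.1, seed = 7)
  expect_identical(m1$pinned, m2$pinned)
  expect_equal(length(m1$pinned), round(0.1 * 64))
  # pinned vertices do not move under vertex moves
  p <- load_config(overrides = list(membrane = list(L = 80, kappa = 20)))
  sys <- build_system(m1, p, nc = FALSE, n_receptors = 0, seed = 1)
  run <- run_simulation(sys, sim_config(steps = 1e5, seed = 2,
    move_weights = only_moves("vertex")))
  expect_equal(run$system$mesh$vertices[m1$pinned, ],
               m$vertices[m1$pinned, ])
  moved <- setdiff(seq_len(64), m1$pinned)
  expect_gt(max(abs(run$system$mesh$vertices[moved, 3])), 0)
})

test_that("mesh files round-trip at 9 significant digits", {
  m <- sinusoid_patch(80, 10, h0 = 7.123456789)
  m$vertices <- m$vertices + 1e-4 * sin(seq_len(length(m$vertices)))
  for (io in list(c(write_off, read_off), c(write_vtk, read_vtk))) {
    path <- tempfile(fileext = ".mesh")
    io[[1]](m, path)
    m2 <- io[[2]](path)
    expect_identical(m2$triangles, m$triangles)
    expect_equal(m2$vertices, m$vertices, tolerance = 1e-8)
    expect_identical(sprintf("%.9g", m2$vertices), sprintf("%.9g", m$vertices))
    expect_equal(m2$L, m$L)
  }
})
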