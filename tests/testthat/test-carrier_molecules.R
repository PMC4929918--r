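test_that("unit conversions round-trip to double precision", {
  for (x in c(1, -7.98e-20, 7000)) {
    expect_equal(kBT_to_joule(joule_to_kBT(x)), x, tolerance = 1e-12)
    expect_equal(kBT_nm2_to_Npm(Npm_to_kBT_nm2(x)), x, tolerance = 1e-12)
    expect_equal(kBT_to_pNnm(pNnm_to_kBT(x)), x, tolerance = 1e-12)
  }
})

test_that("literature defaults convert to the expected internal values", {
  p <- load_config()
  # hand conversion: -7.98e-20 J / (1.380649e-23 J/K * 300 K)
  expect_equal(p$bond$H0, -7.98e-20 / (1.380649e-23 * 300),
               tolerance = 1e-12)
  expect_lt(abs(p$bond$H0 - (-19.27)), 0.01)
  # 7000 pN nm at 300 K is about 1690 kBT per rad^2
  expect_equal(p$receptor$kappa_f, 7000e-21 / (1.380649e-23 * 300),
               tolerance = 1e-12)
  expect_lt(abs(p$receptor$kappa_f - 1690), 1)
  # 1 N/m in kBT/nm^2
  expect_equal(p$bond$kappa_b, 1e-18 / (1.380649e-23 * 300),
               tolerance = 1e-12)
})

test_that("flexural energy follows the harmonic form and its domain", {
  expect_equal(flexural_energy(0, 200), 0)
  expect_equal(flexural_energy(0.1, 200), 1.0)
  expect_error(flexural_energy(-0.1, 200), "0, pi")
  expect_error(flexural_energy(3.5, 200), "0, pi")
  # beta H_f at 0.05 rad under the adopted unit reading of the default
  p <- load_config()
  expect_equal(flexural_energy(0.05, p$receptor$kappa_f),
               0.5 * 7000e-21 / (1.380649e-23 * 300) * 0.05^2,
               tolerance = 1e-12)
})

test_that("Bell bond potential is piecewise with the printed depth", {
  p <- load_config()
  H0 <- p$bond$H0; kb <- p$bond$kappa_b; ds <- p$bond$d_star
  expect_equal(bond_energy(ds, H0, kb, ds), H0)
  expect_equal(bond_energy(ds + 0.01, H0, kb, ds), 0)
  expect_equal(bond_energy(2 * ds, H0, kb, ds), 0)
  expect_equal(bond_energy(0.5, H0, kb, ds), H0 + 0.5 * kb * 0.25)
  expect_error(bond_energy(-1, H0, kb, ds), "non-negative")
})

test_that("receptor tip geometry is a rigid rod in the local frame", {
  m <- flat_patch(80, 10)
  tip <- receptor_tip(m, vertex = 1, theta = 0, phi = 0, L_an = 19)
  expect_equal(tip, m$vertices[1, ] + c(0, 0, 19), tolerance = 1e-12,
               ignore_attr = TRUE)
  tip90 <- receptor_tip(m, 1, pi / 2, 0.3, L_an = 19)
  expect_equal(tip90[3], 0, tolerance = 1e-12)
  set.seed(1)
  for (i in 1:20) {
    th <- runif(1, 0, pi / 2); ph <- runif(1, 0, 2 * pi)
    v <- sample(64, 1)
    tip <- receptor_tip(m, v, th, ph, L_an = 19)
    expect_equal(sqrt(sum((tip - m$vertices[v, ])^2)), 19,
                 tolerance = 1e-12)
  }
})

test_that("ligand directions are deterministic unit vectors", {
  d1 <- fibonacci_sphere(162)
  d2 <- fibonacci_sphere(162)
  expect_identical(d1, d2)
  expect_equal(sqrt(rowSums(d1^2)), rep(1, 162), tolerance = 1e-12)
  # quasi-uniform: centroid near the origin
  expect_lt(max(abs(colMeans(d1))), 0.02)
})

test_that("receptor count follows the projected-area density", {
  p <- load_config(overrides = list(
    membrane = list(L = 300),
    receptor = list(density_um2 = 2000)))
  sys <- build_system(flat_patch(300, 10), p, nc = FALSE, seed = 1)
  expect_equal(length(sys$receptors$vertex), round(2000 * 300^2 / 1e6))
  expect_false(any(duplicated(sys$receptors$vertex)))
})

test_that("total energy decomposes and matches the engine cache", {
  sys <- tiny_membrane_system(L = 80, kappa = 20, sigma = 0)
  e <- total_energy(sys)
  expect_equal(e$total, 0, tolerance = 1e-9)
  # after a short run, the incrementally maintained energy matches a full
  # recomputation of the final state
  sys2 <- tiny_membrane_system(L = 96, spacing = 12, n_receptors = 5,
                               seed = 2)
  run <- run_simulation(sys2, sim_config(steps = 2e5, seed = 3))
  e_cache <- run$diagnostics$energy
  e_full <- total_energy(run$system)
  expect_lt(abs(e_cache[["H_m"]] - e_full$H_m), 1e-6)
  expect_lt(abs(run$diagnostics$max_drift), 1e-2)
})

test_that("a single bond at d = d* contributes exactly H0", {
  sys <- one_bond_system(H0_kBT = -2, tip_height = 19 + 1)  # tip at L_an + d*
  sys$receptors$bond <- 1L
  sys$carrier$lig_bond <- 1L
  e <- total_energy(sys)
  expect_equal(e$n_bonds, 1)
  expect_equal(e$H_b, -2, tolerance = 1e-9)
  expect_equal(e$total - e$H_m - e$H_f, -2, tolerance = 1e-9)
})

test_that("bond bookkeeping stays a partial matching under sampling", {
  sys <- one_bond_system(H0_kBT = -5)
  run <- run_simulation(sys, sim_config(
    steps = 2e5, seed = 11, move_weights = only_moves("flexure", "bond"),
    tune = FALSE))
  rb <- run$system$receptors$bond
  lb <- run$system$carrier$lig_bond
  if (rb[1] > 0) expect_equal(lb[rb[1]], 1L)
  bonded_l <- which(lb > 0)
  expect_true(all(rb[lb[bonded_l]] == bonded_l))
})

test_that("configuration loading applies defaults and rejects unknown keys", {
  empty <- tempfile(fileext = ".yml")
  writeLines("", empty)
  p <- load_config(empty)
  expect_equal(p$carrier$r_nc, 50)   # 100 nm diameter
  expect_equal(p$temperature_K, 300)
  expect_equal(p$receptor$L_an, 19)
  expect_equal(p$carrier$L_ab, 15)
  expect_equal(p$membrane$L_z, 500)
  f <- tempfile(fileext = ".yml")
  writeLines(c("bond:", "  H0_J: -4.0e-20"), f)
  p2 <- load_config(f)
  expect_equal(p2$bond$H0, -4e-20 / (1.380649e-23 * 300), tolerance = 1e-12)
  bad <- tempfile(fileext = ".yml")
  writeLines(c("bond:", "  spring: 2"), bad)
  expect_error(load_config(bad), "bond.spring")
  bad2 <- tempfile(fileext = ".yml")
  writeLines("glycocalyx: 1", bad2)
  expect_error(load_config(bad2), "unknown configuration key")
})
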