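test_that("Metropolis rule accepts downhill always and uphill at e^-dE", {
  expect_true(all(metropolis_accept(rep(-5, 100))))
  expect_false(any(metropolis_accept(rep(Inf, 100))))
  expect_error(metropolis_accept(NaN), "NaN")
  set.seed(1)
  n <- 1e5
  rate <- mean(metropolis_accept(rep(1, n)))
  se <- sqrt(exp(-1) * (1 - exp(-1)) / n)
  expect_lt(abs(rate - exp(-1)), 3 * se)
})

test_that("identical seeds give identical trajectories", {
  sys <- tiny_membrane_system(L = 96, spacing = 12, n_receptors = 4, seed = 5)
  cfg <- sim_config(steps = 5e4, seed = 123)
  r1 <- run_simulation(sys, cfg)
  r2 <- run_simulation(sys, cfg)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$system$mesh$vertices, r2$system$mesh$vertices)
})

test_that("checkpoint restore continues the trajectory bit-identically", {
  sys <- tiny_membrane_system(L = 96, spacing = 12, n_receptors = 4, seed = 5)
  cfg_full <- sim_config(steps = 6e4, seed = 42, tune = FALSE)
  full <- run_simulation(sys, cfg_full)
  cfg_half <- sim_config(steps = 3e4, seed = 42, tune = FALSE)
  half <- run_simulation(sys, cfg_half)
  ckpt <- tempfile(fileext = ".rds")
  save_checkpoint(half$system, ckpt)
  resumed <- run_simulation(restore_checkpoint(ckpt),
                            sim_config(steps = 3e4, seed = 0, tune = FALSE))
  expect_identical(resumed$system$mesh$vertices, full$system$mesh$vertices)
  expect_equal(resumed$trajectory$E_total,
               full$trajectory$E_total[full$trajectory$step > 3e4],
               tolerance = 1e-12)
})

test_that("move scheduling follows the configured mixture", {
  sys <- one_bond_system()
  cfg <- sim_config(steps = 2e5, seed = 7)
  run <- run_simulation(sys, cfg)
  att <- run$counters$attempted
  frac <- att / sum(att)
  w <- move_mix()
  for (k in seq_len(7)) {
    se <- sqrt(w[k] * (1 - w[k]) / sum(att))
    expect_lt(abs(frac[k] - w[k]), 4 * se + 1e-6,
              label = paste("move", k, "fraction"))
  }
  # the rare-move split: moves 6 and 7 carry half the weight in ratio 2:5
  expect_lt(abs(frac[6] - 0.5 * 2 / 7), 4 * sqrt(frac[6] / sum(att)) + 0.003)
  expect_lt(abs(frac[7] - 0.5 * 5 / 7), 4 * sqrt(frac[7] / sum(att)) + 0.003)
})

test_that("carrier excluded volume holds in every sampled state", {
  p <- load_config(overrides = list(
    membrane = list(L = 120, kappa = 20, L_z = 150)))
  mesh <- flat_patch(120, 10, spacing = 12)
  sys <- build_system(mesh, p, nc = TRUE, n_receptors = 10, seed = 2)
  run <- run_simulation(sys, sim_config(steps = 2e5, seed = 3, debug = TRUE))
  V <- run$system$mesh$vertices
  ctr <- run$system$carrier$center
  d <- sqrt((V[, 1] - ctr[1])^2 + (V[, 2] - ctr[2])^2 + (V[, 3] - ctr[3])^2)
  expect_true(all(d >= 50 - 1e-9))
  # receptor occupancy: one receptor per vertex
  expect_false(any(duplicated(run$system$receptors$vertex)))
})

test_that("receptor flexure samples the Boltzmann angular density", {
  kf <- 20
  p <- load_config(overrides = list(
    receptor = list(kappa_f_pNnm = kBT_to_pNnm(kf))))
  sys <- build_system(flat_patch(80, 10), p, nc = FALSE, n_receptors = 1,
                      seed = 2)
  run <- run_simulation(sys, sim_config(
    steps = 6e5, burnin = 2e4, record_every = 2, seed = 5,
    move_weights = only_moves("flexure"), tune = FALSE))
  th <- run$trajectory$theta1
  Z <- integrate(function(t) sin(t) * exp(-kf * t^2 / 2), 0, pi / 2)$value
  bw <- 0.05
  edges <- seq(0, pi / 2 + bw, by = bw)
  dens <- hist(th, breaks = edges, plot = FALSE)$density
  mids <- edges[-1] - bw / 2
  expect_lt(max(abs(dens - sin(mids) * exp(-kf * mids^2 / 2) / Z)), 0.03)
  # stiff limit: small-angle equipartition <theta^2> = 2 / kappa_f
  kfl <- 800
  pl <- load_config(overrides = list(
    receptor = list(kappa_f_pNnm = kBT_to_pNnm(kfl))))
  sysl <- build_system(flat_patch(80, 10), pl, nc = FALSE, n_receptors = 1,
                       seed = 2)
  runl <- run_simulation(sysl, sim_config(
    steps = 4e5, burnin = 2e4, record_every = 5, seed = 7,
    move_weights = only_moves("flexure"), tune = FALSE))
  expect_within(mean(runl$trajectory$theta1^2), 2 / kfl, 0.05)
  # floppy limit: uniform in cos(theta) on the upper hemisphere
  p0 <- load_config(overrides = list(receptor = list(kappa_f_pNnm = 0)))
  sys0 <- build_system(flat_patch(80, 10), p0, nc = FALSE, n_receptors = 1,
                       seed = 2)
  run0 <- run_simulation(sys0, sim_config(
    steps = 3e5, burnin = 2e4, record_every = 5, seed = 6,
    move_weights = only_moves("flexure"), tune = FALSE))
  ct <- cos(run0$trajectory$theta1)
  expect_lt(abs(mean(ct) - 0.5), 0.01)
  expect_lt(max(abs(quantile(ct, c(0.25, 0.5, 0.75)) - c(0.25, 0.5, 0.75))),
            0.02)
})

test_that("bond occupancy matches the two-state partition oracle", {
  sys <- one_bond_system(H0_kBT = -2, tip_height = 19.5)
  toy <- toy_binding_system(sys$params, tip_height = 19.5)
  run <- run_simulation(sys, sim_config(
    steps = 1.5e6, burnin = 5e4, record_every = 5, seed = 8,
    move_weights = only_moves("flexure", "bond"), tune = FALSE))
  nb <- run$trajectory$n_b
  blocks <- tapply(nb, cut(seq_along(nb), 40), mean)
  se <- sd(blocks) / sqrt(length(blocks))
  expect_lt(abs(mean(nb) - toy$p_bound_exact), max(2 * se, 0.01))
  # tips always out of range: never bound
  far <- one_bond_system(H0_kBT = -10, tip_height = 25)
  run_far <- run_simulation(far, sim_config(
    steps = 1e5, seed = 9, move_weights = only_moves("flexure", "bond"),
    tune = FALSE))
  expect_equal(max(run_far$trajectory$n_b), 0)
  # very deep bond: always bound once formed
  deep <- one_bond_system(H0_kBT = -25, tip_height = 19.5)
  run_deep <- run_simulation(deep, sim_config(
    steps = 2e5, burnin = 5e4, record_every = 10, seed = 10,
    move_weights = only_moves("flexure", "bond"), tune = FALSE))
  expect_gt(mean(run_deep$trajectory$n_b), 0.999)
})

test_that("distinct seeds and starts agree on the mean occupancy", {
  p_mean <- vapply(c(21, 22), function(s) {
    sys <- one_bond_system(H0_kBT = -1.5, tip_height = 19.4, seed = s)
    run <- run_simulation(sys, sim_config(
      steps = 6e5, burnin = 5e4, record_every = 5, seed = s * 13,
      move_weights = only_moves("flexure", "bond"), tune = FALSE))
    mean(run$trajectory$n_b)
  }, numeric(1))
  expect_lt(abs(p_mean[1] - p_mean[2]), 0.03)
})

test_that("bias energy enters the sampled distribution", {
  # with a strong bias on dR the carrier stays near the window centre
  p <- load_config(overrides = list(
    membrane = list(L = 120, kappa = 40, L_z = 300)))
  sys <- build_system(flat_patch(120, 10, spacing = 12), p, nc = TRUE,
                      n_receptors = 0, seed = 2)
  run <- run_simulation(sys, sim_config(
    steps = 3e5, burnin = 1e5, seed = 4,
    bias = list(dR0 = 80, k_bias = 2)))
  dR <- run$trajectory$dR
  expect_lt(abs(mean(dR) - 80), 2)
  expect_lt(sd(dR), 2)
})
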