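# synthetic simulation result with prescribed carrier/receptor statistics
fake_result <- function(n = 2000, L = 300, nc_sd = 4, rec_sd = 5,
                        euler_amp = 0.1, seed = 1, frozen_rotation = FALSE,
                        pinned_receptor = FALSE) {
  set.seed(seed)
  ang <- function() if (frozen_rotation) rep(0, n) else
    runif(n, -euler_amp, euler_amp)
  # small rotations about x then y then z (angles are tiny, order immaterial)
  ax <- ang() / 2; ay <- ang() / 2; az <- ang() / 2
  q <- cbind(q_w = 1 - (ax^2 + ay^2 + az^2) / 2, q_x = ax, q_y = ay,
             q_z = az)
  q <- q / sqrt(rowSums(q^2))
  traj <- data.frame(
    step = seq_len(n) * 10, dR = 60, n_b = 1, H_m = 0, H_f = 0, H_b = -19,
    E_total = -19, area = L^2, theta1 = 0, phi1 = 0,
    nc_x = L / 2 + rnorm(n, 0, nc_sd), nc_y = L / 2 + rnorm(n, 0, nc_sd),
    nc_z = 60)
  traj <- cbind(traj, q)
  rx <- if (pinned_receptor) rep(0, n) else rnorm(n, 0, rec_sd)
  ry <- if (pinned_receptor) rep(0, n) else rnorm(n, 0, rec_sd)
  bound <- data.frame(record = seq_len(n), receptor = 1,
                      x = traj$nc_x + rx, y = traj$nc_y + ry, z = 0)
  list(trajectory = traj, bound = bound,
       system = list(mesh = list(L = L),
                     receptors = list(vertex = seq_len(50))))
}

test_that("multivalency histogram handles constant and binomial series", {
  traj <- data.frame(dR = rep(60, 500), n_b = 3)
  mh <- multivalency_histogram(traj, r_star = 100)
  expect_equal(mh$mode, 3)
  expect_equal(mh$table$P[mh$table$n_b == 3], 1)
  set.seed(2)
  nb <- rbinom(4000, 20, 0.3)
  mh2 <- multivalency_histogram(data.frame(dR = 60, n_b = nb), r_star = 100)
  se <- sd(nb) / sqrt(length(nb))
  expect_lt(abs(mh2$mean - 6), 2 * se + 2 * se)  # generator mean 20 * 0.3
  expect_equal(sum(mh2$table$P), 1, tolerance = 1e-12)
  # unbound-only trajectory is an error
  expect_error(multivalency_histogram(data.frame(dR = 150, n_b = 1)),
               "insufficient")
})

test_that("entropy estimators recover prescribed Gaussian statistics", {
  r <- fake_result(n = 4000, nc_sd = 4, rec_sd = 5, euler_amp = 0.1)
  ent <- entropy_estimators(r, r_star = 100)
  expect_within(ent$A_N_b, pi * 16, 0.10)
  expect_within(ent$A_R_b, pi * 25, 0.10)
  # uniform angles on [-a, a] have sd a/sqrt(3)
  expect_within(ent$rot_volume, (0.1 / sqrt(3))^3, 0.15)
  expect_equal(ent$A_R_u, 300^2 / 50)
  # tangent frame points from the bound bases towards the carrier
  expect_gt(ent$tangent_normal[3], 0.99)
})

test_that("degenerate bound states hit documented floors", {
  r <- fake_result(pinned_receptor = TRUE)
  expect_warning(ent <- entropy_estimators(r, r_star = 100),
                 "rank-deficient")
  expect_lt(ent$A_R_b, 1e-5)
  rf <- fake_result(frozen_rotation = TRUE)
  entf <- entropy_estimators(rf, r_star = 100)
  expect_equal(entf$rot_volume, 0)
  expect_error(entropy_estimators(fake_result(n = 50), min_samples = 100),
               "insufficient")
})

test_that("combinatorial factor and formula limits are exact", {
  grid <- seq(0, 100, by = 0.5)
  pmf0 <- structure(data.frame(dR = grid, W = 0, counts = 1),
                    anchored = TRUE, bin_width = 0.5,
                    class = c("ncav_pmf", "data.frame"))
  ent <- list(A_R_b = 30, A_R_u = 450, A_N_b = 200,
              rot_volume = 8 * pi^2)
  # N_ant = 3, n_b = 2, N_ab = 2: combinatorial factor is 3 * 1 = 3
  a <- association_constant(pmf0, 2, ent, N_ant = 3, N_ab = 2,
                            L_z = 500, r_star = 100)
  expect_equal(exp(a$components[["combinatorial"]]), 3, tolerance = 1e-12)
  # W = 0, n_b = 0, full rotational freedom: exact closed form
  a0 <- association_constant(pmf0, 0, ent, N_ant = 3, N_ab = 2,
                             L_z = 500, r_star = 100)
  expect_equal(a0$Ka, 200 * 100 / (500 * (500 - 100)), tolerance = 1e-9)
  # log K_a is the sum of its component logs
  expect_equal(a$log_Ka, sum(a$components), tolerance = 1e-12)
  expect_equal(a$Ka * a$Kd, 1, tolerance = 1e-12)
  # domain errors
  expect_error(association_constant(pmf0, 5, ent, N_ant = 3, N_ab = 2),
               "exceeds")
  unanch <- pmf0; attr(unanch, "anchored") <- FALSE
  expect_error(association_constant(unanch, 1, ent, 3, 2), "anchored")
})

test_that("assembled K_a matches a configurational-integral oracle", {
  # one receptor, one ligand toy with a harmonic PMF; the oracle evaluates
  # the same configurational integral with exact areas and adaptive
  # quadrature, while the implementation goes through sampled covariance
  # estimators and a trapezoid on a coarse grid
  r_star <- 80; L_z <- 500; D <- 6; r0 <- 55; kw <- 0.15
  Wfun <- function(r) pmin(0.5 * kw * (r - r0)^2 - D, 0)
  grid <- seq(40, 100, by = 1)
  pmf <- structure(data.frame(dR = grid, W = Wfun(grid), counts = 1),
                   anchored = TRUE, bin_width = 1,
                   class = c("ncav_pmf", "data.frame"))
  set.seed(9)
  n <- 6000
  R_N <- 9; R_R <- 12; a_eul <- 0.2
  disc <- function(R) {
    th <- runif(n, 0, 2 * pi); rr <- R * sqrt(runif(n))
    cbind(rr * cos(th), rr * sin(th))
  }
  xyN <- disc(R_N); xyR <- disc(R_R)
  eul <- matrix(runif(3 * n, -a_eul, a_eul), ncol = 3)
  est_area <- function(xy) pi * 2^2 * sqrt(det(cov(xy)))  # coverage 2
  ent_est <- list(A_R_b = est_area(xyR), A_R_u = 450,
                  A_N_b = est_area(xyN),
                  rot_volume = prod(apply(eul, 2, sd)))
  impl <- association_constant(pmf, 1, ent_est, N_ant = 1, N_ab = 1,
                               L_z = L_z, r_star = r_star)
  oracle <- (a_eul / sqrt(3))^3 / (8 * pi^2) *
    (pi * R_R^2 / 450) *
    (pi * R_N^2 / (L_z * (L_z - r_star))) *
    integrate(function(r) exp(-Wfun(r)), 40, r_star, rel.tol = 1e-10)$value
  expect_within(impl$Ka, oracle, 0.10)
})

test_that("K_a grows monotonically with the bond depth", {
  grid <- seq(40, 100, by = 0.5)
  ent <- list(A_R_b = 30, A_R_u = 450, A_N_b = 200, rot_volume = 0.001)
  Ka <- vapply(c(2, 5, 8, 12), function(D) {
    W <- pmin(0.1 * (grid - 55)^2 - D, 0)
    pmf <- structure(data.frame(dR = grid, W = W, counts = 1),
                     anchored = TRUE, bin_width = 0.5,
                     class = c("ncav_pmf", "data.frame"))
    association_constant(pmf, 3, ent, N_ant = 80, N_ab = 162,
                         r_star = 90)$log_Ka
  }, numeric(1))
  expect_true(all(diff(Ka) > 0))
})

test_that("component logs stay finite at full experimental scale", {
  grid <- seq(40, 100, by = 0.5)
  W <- pmin(0.1 * (grid - 55)^2 - 40, 0)
  pmf <- structure(data.frame(dR = grid, W = W, counts = 1),
                   anchored = TRUE, bin_width = 0.5,
                   class = c("ncav_pmf", "data.frame"))
  ent <- list(A_R_b = 30, A_R_u = 260100 / 1040, A_N_b = 200,
              rot_volume = 1e-4)
  # 4000 um^-2 on a 510 nm patch, the full 162-ligand carrier, n_b = 12
  a <- association_constant(pmf, 12, ent, N_ant = 1040, N_ab = 162,
                            r_star = 100)
  expect_true(all(is.finite(a$components)))
  expect_true(is.finite(a$log_Ka))
})

test_that("density interpolation is geometric with exact endpoints", {
  ip <- interpolate_Ka(10, 1000, n1 = 200, n2 = 400, n_star = 300)
  expect_equal(ip$Ka, 100, tolerance = 1e-12)
  expect_equal(interpolate_Ka(10, 1000, 200, 400, 200)$Ka, 10,
               tolerance = 1e-12)
  expect_equal(interpolate_Ka(10, 1000, 200, 400, 400)$Ka, 1000,
               tolerance = 1e-12)
  # log K_a* is linear in n*: three-point collinearity
  l <- vapply(c(250, 300, 350), function(ns)
    interpolate_Ka(10, 1000, 200, 400, ns)$log_Ka, numeric(1))
  expect_equal(l[2] - l[1], l[3] - l[2], tolerance = 1e-12)
  expect_error(interpolate_Ka(10, 1000, 200, 400, 500), "outside")
  expect_equal(interpolate_Ka(10, 1000, 200, 400, 500,
                              extrapolate = TRUE)$Ka, 1e4, tolerance = 1e-9)
})

test_that("K_d normalization is a consistent ratio", {
  a <- list(log_Ka = 5); ref <- list(log_Ka = 5)
  expect_equal(normalize_kd(a, ref)$ratio, 1, tolerance = 1e-12)
  half <- list(log_Ka = 5 - log(2))   # K_d doubled
  expect_equal(normalize_kd(half, ref)$ratio, 2, tolerance = 1e-12)
  b <- list(log_Ka = 3); c3 <- list(log_Ka = 8)
  lhs <- normalize_kd(a, b)$ratio * normalize_kd(b, c3)$ratio
  expect_equal(lhs, normalize_kd(a, c3)$ratio, tolerance = 1e-12)
})
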