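test_that("harmonic bias energy and its default strength", {
  expect_equal(bias_energy(70, 70, 0.5), 0)
  expect_equal(default_k_bias(2), 0.5)
  # one window spacing away costs exactly 1 kBT at the default strength
  expect_equal(bias_energy(72, 70, default_k_bias(2)), 1)
  expect_equal(bias_energy(68, 70, default_k_bias(2)), 1)
})

test_that("WHAM recovers a quadratic toy potential within 0.2 kBT", {
  # particle in V(x) = k x^2 / 2 sampled by exact Gaussian draws per window
  k <- 0.1
  set.seed(4)
  kb <- 0.5
  dR0s <- seq(-12, 12, by = 2)
  windows <- lapply(dR0s, function(d0) {
    vtot <- k + kb                      # biased state is Gaussian
    mu <- kb * d0 / vtot
    new_window(d0, kb, rnorm(4000, mu, sqrt(1 / vtot)))
  })
  pmf <- wham(windows)
  covered <- abs(pmf$dR) < 9
  err <- pmf$W[covered] - k * pmf$dR[covered]^2 / 2
  err <- err - mean(err)                # unanchored: compare shapes
  expect_lt(max(abs(err)), 0.2)
})

test_that("WHAM handles flat landscapes and detects coverage gaps", {
  set.seed(5)
  flat <- lapply(c(0, 4, 8), function(d0)
    new_window(d0, 0.5, rnorm(3000, d0, sqrt(2))))
  pmf <- wham(flat)
  mid <- pmf$dR > -2 & pmf$dR < 10
  expect_lt(diff(range(pmf$W[mid])), 0.35)
  gap <- lapply(c(0, 40), function(d0)
    new_window(d0, 0.5, rnorm(2000, d0, sqrt(2))))
  expect_error(wham(gap), "coverage gap")
})

test_that("TI anchoring fixes the unbound level and matches the plateau", {
  toy <- toy_umbrella_system(depth = 5, x0 = 20, w = 8, xmax = 60)
  wins <- sample_toy_windows(toy, seq(10, 58, by = 2), n_samples = 6000,
                             seed = 3)
  pmf <- ti_anchor(wham(wins), wins)
  expect_true(attr(pmf, "anchored"))
  # known well depth
  expect_lt(abs(min(pmf$W) + 5), 0.3)
  # plateau is zero and the two anchoring routes agree
  plateau <- pmf$dR > 40 & pmf$dR < 56
  expect_lt(abs(mean(pmf$W[plateau])), 0.2)
  expect_lt(abs(attr(pmf, "consistency")), 0.3)
  # full profile against the analytic potential over the covered range
  covered <- pmf$dR > 13 & pmf$dR < 55
  expect_lt(max(abs(pmf$W[covered] - toy$V(pmf$dR[covered]))), 0.35)
})

test_that("anchored PMF is invariant to window doubling", {
  toy <- toy_umbrella_system(depth = 4)
  w1 <- sample_toy_windows(toy, seq(12, 56, by = 4), n_samples = 6000,
                           seed = 7)
  w2 <- sample_toy_windows(toy, seq(12, 56, by = 2), n_samples = 6000,
                           seed = 8)
  p1 <- ti_anchor(wham(w1), w1)
  p2 <- ti_anchor(wham(w2), w2)
  grid <- seq(16, 50, by = 1)
  i1 <- approx(p1$dR, p1$W, grid)$y
  i2 <- approx(p2$dR, p2$W, grid)$y
  expect_lt(max(abs(i1 - i2)), 0.35)
})

test_that("anchoring refuses profiles without an unbound plateau", {
  toy <- toy_umbrella_system(depth = 5, x0 = 20, w = 8)
  wins <- sample_toy_windows(toy, seq(10, 18, by = 2), n_samples = 3000,
                             seed = 9)
  expect_error(ti_anchor(wham(wins), wins), "plateau")
})

test_that("WHAM agrees with direct Boltzmann inversion on a toy system", {
  toy <- toy_umbrella_system(depth = 3, x0 = 20, w = 8, xmax = 40)
  wins <- sample_toy_windows(toy, seq(12, 38, by = 2), n_samples = 6000,
                             seed = 11)
  pmf <- ti_anchor(wham(wins), wins)
  # unbiased draws from the same density via the inverse CDF
  set.seed(12)
  x <- seq(9, 40, length.out = 20000)
  w <- exp(-toy$V(x))
  cdf <- cumsum(w) / sum(w)
  samples <- x[findInterval(runif(40000, min(cdf), 1), cdf) + 1]
  inv <- boltzmann_inversion(samples, bin_width = 0.5)
  grid <- inv$dR[inv$dR > 14 & inv$dR < 36]
  werr <- approx(pmf$dR, pmf$W, grid)$y - min(pmf$W) -
    (approx(inv$dR, inv$W, grid)$y - min(inv$W))
  expect_lt(max(abs(werr)), 0.3)
})

test_that("r* detection finds the persistent flat tail", {
  grid <- seq(50, 120, by = 0.5)
  W <- ifelse(grid < 60, -8 * exp(-(grid - 50) / 4), 0)
  pmf <- structure(data.frame(dR = grid, W = W, counts = 100),
                   anchored = TRUE, bin_width = 0.5,
                   class = c("ncav_pmf", "data.frame"))
  rs <- detect_r_star(pmf, tol = 0.5)
  expect_lt(abs(rs - 60), 3)
  # identically zero profile: first grid point
  pmf0 <- pmf; pmf0$W <- 0
  expect_equal(detect_r_star(pmf0, tol = 0.5), grid[1])
  expect_error(detect_r_star(pmf, tol = 0), "positive")
  deep <- pmf; deep$W <- -5
  expect_error(detect_r_star(deep, tol = 0.5), "never flattens")
  unanch <- pmf; attr(unanch, "anchored") <- FALSE
  expect_error(detect_r_star(unanch, tol = 0.5), "anchored")
})
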