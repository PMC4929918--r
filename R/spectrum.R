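#' Monge-gauge height field of a membrane patch
#'
#' Interpolates vertex heights onto a regular `grid_n` x `grid_n` periodic
#' grid by barycentric interpolation over the projected triangulation.  The
#' patch must be a graph over the reference plane: projected triangles that
#' are inverted (overhangs/folds) raise an error naming their count, unless
#' `on_fold = "fill"`, which skips them and fills any uncovered grid point
#' from the nearest projected vertex.
#'
#' @param mesh a periodic `ncav_mesh`.
#' @param grid_n grid resolution per side.
#' @param on_fold `"error"` (default) or `"fill"`.
#' @return `grid_n` x `grid_n` matrix of heights (nm) with attributes `L`
#'   and `n_inverted`.
#' @export
height_field <- function(mesh, grid_n, on_fold = c("error", "fill")) {
  on_fold <- match.arg(on_fold)
  r <- cpp_height_field(mesh$vertices, mesh$triangles, mesh$L, grid_n,
                        if (on_fold == "error") 0L else 1L)
  structure(r$h, L = mesh$L, n_inverted = r$n_inverted)
}

#' Height-fluctuation power spectrum
#'
#' Radially averaged spectrum of a periodic height field.  The Fourier
#' convention is \eqn{h_q = N^{-2} \sum_x h(x) e^{-i q x}} so that Parseval's
#' identity reads `sum_q |h_q|^2 = mean(h^2)` and the thermal expectation of
#' a Helfrich membrane is
#' \deqn{\langle |h_q|^2 \rangle = k_B T / [A_p (\kappa q^4 + \sigma q^2)].}
#'
#' Shells are formed from the distinct wavenumber magnitudes of the grid
#' (rounded to 1e-9 relative): each shell averages all modes with the same
#' |q|.
#'
#' @param h height matrix (or a list of matrices to average), with box side
#'   `L` taken from its attribute or given explicitly.
#' @param L box side (nm).
#' @return data.frame with `q` (1/nm), `S` (= mean |h_q|^2, nm^2),
#'   `n_modes` (modes per shell) and `n_fields` (averaged realizations).
#' @export
power_spectrum <- function(h, L = NULL) {
  hs <- if (is.list(h)) h else list(h)
  if (is.null(L)) L <- attr(hs[[1]], "L")
  if (is.null(L)) stop("box side L is required")
  n <- nrow(hs[[1]])
  S <- Reduce(`+`, lapply(hs, function(x) Mod(fft(x) / n^2)^2)) / length(hs)
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  qx <- 2 * pi * k / L
  qmag <- sqrt(outer(qx^2, qx^2, `+`))
  key <- round(qmag * 1e9) / 1e9
  keep <- key > 0
  agg <- tapply(S[keep], key[keep], mean)
  cnt <- tapply(S[keep], key[keep], length)
  data.frame(q = as.numeric(names(agg)), S = as.numeric(agg),
             n_modes = as.integer(cnt), n_fields = length(hs),
             row.names = NULL)
}

#' Synthesize a Gaussian membrane height field
#'
#' Draws a random periodic height field whose modes follow the Helfrich
#' spectrum with the given `kappa` and `sigma` exactly (in kBT units), by
#' filtering white noise in Fourier space.  Used as the generator half of
#' the generator-estimator closure tests and as the `gaussian-field`
#' fixture.
#'
#' @param grid_n grid resolution.
#' @param L box side (nm).
#' @param kappa bending rigidity (kBT).
#' @param sigma tension (kBT/nm^2).
#' @param seed integer seed.
#' @return height matrix with attribute `L`.
#' @export
gaussian_membrane_field <- function(grid_n, L, kappa, sigma = 0, seed = 1) {
  set.seed(seed)
  n <- grid_n
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  qx <- 2 * pi * k / L
  q2 <- outer(qx^2, qx^2, `+`)
  Sq <- 1 / (L^2 * (kappa * q2^2 + sigma * q2))
  Sq[1, 1] <- 0
  w <- matrix(rnorm(n * n), n, n)
  hq <- (fft(w) / n) * sqrt(Sq)
  h <- Re(fft(hq, inverse = TRUE))
  structure(h, L = L)
}

#' Fit the Helfrich fluctuation spectrum
#'
#' Weighted least squares of `1/S` against `Ap (kappa q^4 + sigma q^2)`
#' (kBT units) over a fit range that excludes the lowest (frame-constrained)
#' shell and discretization-dominated shells with `q > pi / (2 a0)`.
#' Weights are `n_modes * n_fields * S^2`, i.e. inverse-variance weights for
#' the reciprocal of a shell-averaged exponential spectrum estimate.
#'
#' @param spec spectrum data.frame from [power_spectrum()].
#' @param Ap projected area (nm^2).
#' @param a0 discretization length (nm) setting the default upper fit bound.
#' @param q_range optional explicit fit range `c(qmin, qmax)`.
#' @return list with `kappa`, `sigma`, their standard errors, the covariance
#'   matrix, the fit range, shell count, and `physical` (FALSE when the
#'   fitted `kappa` is non-positive, flagging a non-physical fit).
#' @export
fit_helfrich <- function(spec, Ap, a0 = 10, q_range = NULL) {
  if (is.null(q_range)) {
    q1 <- min(spec$q)
    q_range <- c(1.5 * q1, pi / (2 * a0))
  }
  use <- spec$q >= q_range[1] & spec$q <= q_range[2]
  if (sum(use) < 6)
    stop("fewer than 6 usable q shells in the fit range [",
         signif(q_range[1], 3), ", ", signif(q_range[2], 3), "]")
  d <- spec[use, ]
  y <- 1 / d$S
  wts <- d$n_modes * d$n_fields * d$S^2
  fit <- lm(y ~ 0 + I(Ap * d$q^4) + I(Ap * d$q^2), weights = wts)
  cf <- coef(fit)
  vc <- vcov(fit)
  kappa <- unname(cf[1]); sigma <- unname(cf[2])
  list(kappa = kappa, sigma = sigma,
       kappa_se = sqrt(vc[1, 1]), sigma_se = sqrt(vc[2, 2]),
       cov = unname(vc), q_range = q_range, n_shells = nrow(d),
       residual_rms = sqrt(mean(residuals(fit)^2 * wts) / mean(wts)),
       physical = kappa > 0)
}

#' Membrane-only simulation with spectrum analysis
#'
#' Convenience driver: runs the Monte Carlo engine on a membrane-only system
#' (optionally pinned), converts snapshots to height fields, and fits the
#' fluctuation spectrum.
#'
#' @param L,a0 patch geometry (nm).
#' @param kappa,sigma input elastic parameters (kBT, kBT/nm^2).
#' @param steps,burnin step counts.
#' @param seed integer seed.
#' @param pinning_fraction fraction of pinned vertices (0 = none).
#' @param grid_n height-field resolution (default: vertices per side).
#' @param snapshot_every snapshot cadence (default: every 20 sweeps).
#' @param spacing initial lattice constant (nm); defaults to 1.2 a0, the
#'   approximate rest spacing of the hard-tether network, so the framed
#'   sheet starts stress-free (see [flat_patch()]).
#' @return list with the spectrum (`spec`), fit (`fit`), mean excess area
#'   (`Aex`), acceptance counters and the final system.
#' @export
membrane_spectrum_run <- function(L, a0 = 10, kappa = 20, sigma = 0,
                                  steps = 2e6, burnin = 5e5, seed = 1,
                                  pinning_fraction = 0, grid_n = NULL,
                                  snapshot_every = NULL, spacing = 1.2 * a0) {
  mesh <- flat_patch(L, a0, spacing = spacing)
  if (pinning_fraction > 0)
    mesh <- pin_vertices(mesh, pinning_fraction, seed = seed + 1)
  params <- load_config(overrides = list(
    membrane = list(L = L, a0 = a0, kappa = kappa, sigma = sigma)))
  system <- build_system(mesh, params, nc = FALSE, n_receptors = 0,
                         seed = seed)
  n <- round(L / spacing)
  if (is.null(grid_n)) grid_n <- n
  if (is.null(snapshot_every)) snapshot_every <- 20 * n^2
  cfg <- sim_config(steps = steps, burnin = burnin, record_every = 1000,
                    snapshot_every = snapshot_every, seed = seed,
                    move_weights = c(0.7, 0.3, 0, 0, 0, 0, 0))
  run <- run_simulation(system, cfg)
  nsnap_burn <- floor(burnin / snapshot_every)
  snaps <- run$snapshots[-seq_len(nsnap_burn)]
  fields <- lapply(snaps, function(V) {
    m <- run$system$mesh
    m$vertices <- V
    height_field(m, grid_n, on_fold = "fill")
  })
  spec <- power_spectrum(fields, L = L)
  fit <- fit_helfrich(spec, Ap = L^2, a0 = a0)
  list(spec = spec, fit = fit,
       Aex = mean(100 * (run$trajectory$area - L^2) / run$trajectory$area),
       counters = run$counters, system = run$system,
       diagnostics = run$diagnostics)
}

#' Cytoskeletal pinning renormalization study
#'
#' Runs the membrane-only pipeline for a ladder of pinning fractions and
#' tabulates the apparent (renormalized) elastic parameters obtained from
#' the fluctuation spectrum, together with the realized excess area.
#' Pinning immobilizes vertices without removing them from the energetics,
#' which suppresses long-wavelength undulations and appears in the fitted
#' spectrum mainly as an increased effective tension.
#'
#' @param fractions pinning fractions in [0, 0.12].
#' @param L,a0,kappa,sigma,steps,burnin,seed forwarded to
#'   [membrane_spectrum_run()].
#' @return data.frame with columns `pinning_fraction`, `Aex`, `kappa_eff`,
#'   `kappa_se`, `sigma_eff`, `sigma_se`.
#' @export
pinning_renormalization_study <- function(fractions = c(0, 0.03, 0.06, 0.12),
                                          L = 160, a0 = 10, kappa = 20,
                                          sigma = 0, steps = 2e6,
                                          burnin = 5e5, seed = 1) {
  if (any(fractions < 0 | fractions > 0.12))
    stop("pinning fractions must lie in [0, 0.12]")
  rows <- lapply(seq_along(fractions), function(i) {
    r <- membrane_spectrum_run(L, a0, kappa, sigma, steps = steps,
                               burnin = burnin, seed = seed + 100 * i,
                               pinning_fraction = fractions[i])
    data.frame(pinning_fraction = fractions[i], Aex = r$Aex,
               kappa_eff = r$fit$kappa, kappa_se = r$fit$kappa_se,
               sigma_eff = r$fit$sigma, sigma_se = r$fit$sigma_se)
  })
  do.call(rbind, rows)
}

#' Write / read the pinning-study table
#'
#' Tab-separated round trip for the table produced by
#' [pinning_renormalization_study()], with a unit-bearing header comment.
#'
#' @param tab study table.
#' @param path file path.
#' @export
write_pinning_table <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# pinning renormalization table; Aex in percent, ",
                    "kappa in kBT, sigma in kBT/nm^2"), con)
  write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pinning_table
#' @export
read_pinning_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#")
}
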