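#' Harmonic umbrella bias
#'
#' \deqn{U_{bias} = k_{bias} (\Delta R - \Delta R_0)^2 / 2.}
#' The default spring constant is chosen so that the carrier samples a whole
#' window of width `delta_R` when it acquires 1 kBT of thermal energy:
#' `k_bias = 2 kBT / delta_R^2`, i.e. 0.5 kBT/nm^2 for the default 2 nm
#' window spacing.
#'
#' @param dR order parameter value(s) (nm).
#' @param dR0 window centre (nm).
#' @param k_bias spring constant (kBT/nm^2).
#' @return bias energy in kBT (vectorized).
#' @export
bias_energy <- function(dR, dR0, k_bias = default_k_bias()) {
  0.5 * k_bias * (dR - dR0)^2
}

#' @rdname bias_energy
#' @param delta_R window spacing (nm).
#' @export
default_k_bias <- function(delta_R = 2) 2 / delta_R^2

new_window <- function(dR0, k_bias, samples, seed = NA_integer_) {
  list(dR0 = dR0, k_bias = k_bias, samples = as.numeric(samples),
       seed = seed)
}

#' Exact window samples for a one-dimensional toy potential
#'
#' Draws independent samples from the biased density
#' `exp(-V(x) - k_bias (x - dR0)^2 / 2)` by inverse-CDF sampling on a fine
#' grid; an engine-free oracle source for the WHAM and TI tests.
#'
#' @param toy a toy system from [toy_umbrella_system()].
#' @param dR0_values window centres.
#' @param n_samples draws per window.
#' @param k_bias bias spring constant (kBT/nm^2).
#' @param seed integer seed.
#' @param grid_n grid resolution for the inverse CDF.
#' @return list of umbrella windows.
#' @export
sample_toy_windows <- function(toy, dR0_values, n_samples = 4000,
                               k_bias = default_k_bias(), seed = 1,
                               grid_n = 20000) {
  set.seed(seed)
  xhi <- max(toy$xmax, max(dR0_values) + 5 / sqrt(k_bias))
  x <- seq(toy$x0 - toy$w - 3, xhi, length.out = grid_n)
  Vx <- toy$V(x)
  lapply(dR0_values, function(d0) {
    logw <- -Vx - 0.5 * k_bias * (x - d0)^2
    w <- exp(logw - max(logw))
    cdf <- cumsum(w)
    cdf <- cdf / cdf[length(cdf)]
    u <- runif(n_samples)
    new_window(d0, k_bias, x[findInterval(u, cdf) + 1], seed = seed)
  })
}

#' Run umbrella-sampling windows with the Monte Carlo engine
#'
#' Processes the window ladder in the given order, warm-starting each window
#' from the final state of the previous one.  Before each window the carrier
#' is translated vertically so that the order parameter starts near the
#' window centre.
#'
#' @param system an `ncav_system` with a carrier.
#' @param dR0_values window centres (nm); default spacing 2 nm.
#' @param k_bias bias spring constant (kBT/nm^2).
#' @param steps,burnin steps per window.
#' @param seed base seed; window i uses `seed + i`.
#' @param record_every order-parameter recording cadence (steps).
#' @return list with `windows` (umbrella windows) and `system` (final state).
#' @export
run_umbrella <- function(system, dR0_values, k_bias = default_k_bias(),
                         steps = 2e5, burnin = 5e4, seed = 1,
                         record_every = 10) {
  if (is.null(system$carrier)) stop("umbrella sampling requires a carrier")
  windows <- vector("list", length(dR0_values))
  for (i in seq_along(dR0_values)) {
    d0 <- dR0_values[i]
    # move the carrier vertically toward the window centre
    for (rep in 1:3) {
      dR_now <- total_energy(system)$dR
      if (!is.finite(dR_now)) break
      system$carrier$center[3] <- system$carrier$center[3] + (d0 - dR_now)
    }
    cfg <- sim_config(steps = steps, burnin = burnin,
                      record_every = record_every, seed = seed + i,
                      bias = list(dR0 = d0, k_bias = k_bias),
                      tune = (i == 1))
    run <- run_simulation(system, cfg)
    system <- run$system
    windows[[i]] <- new_window(d0, k_bias, run$trajectory$dR,
                               seed = seed + i)
  }
  list(windows = windows, system = system)
}

#' Weighted histogram analysis of umbrella windows
#'
#' Self-consistent WHAM reconstruction of the unbiased free-energy profile
#' from overlapping biased histograms.  The returned profile is defined up
#' to an additive constant (anchor it with [ti_anchor()]).
#'
#' @param windows list of umbrella windows (each with `dR0`, `k_bias`,
#'   `samples`).
#' @param bin_width histogram bin width (nm); default one tenth of the
#'   window spacing.
#' @param tol convergence tolerance on the window free energies (kBT).
#' @param maxit iteration cap.
#' @return object of class `ncav_pmf`: data.frame fields `dR`, `W` (kBT),
#'   `counts`, plus attributes `f` (window offsets), `windows` (metadata),
#'   `bin_width`, `anchored = FALSE`.
#' @export
wham <- function(windows, bin_width = NULL, tol = 1e-8, maxit = 1e5) {
  if (length(windows) < 2) stop("WHAM needs at least 2 windows")
  dR0 <- vapply(windows, `[[`, numeric(1), "dR0")
  ord <- order(dR0)
  windows <- windows[ord]
  dR0 <- dR0[ord]
  if (is.null(bin_width)) {
    spacing <- if (length(dR0) > 1) min(diff(dR0)) else 2
    bin_width <- spacing / 10
  }
  all_s <- unlist(lapply(windows, `[[`, "samples"))
  edges <- seq(floor(min(all_s) / bin_width) * bin_width,
               max(all_s) + bin_width, by = bin_width)
  mids <- edges[-1] - bin_width / 2
  nw <- length(windows); nb <- length(mids)
  n_ik <- t(vapply(windows, function(w) {
    tabulate(findInterval(w$samples, edges, rightmost.closed = TRUE),
             nbins = nb)
  }, numeric(nb)))
  # overlap diagnostic on consecutive windows
  occ <- n_ik > 0
  for (i in seq_len(nw - 1)) {
    if (!any(occ[i, ] & occ[i + 1, ]))
      stop("umbrella coverage gap between windows at dR0 = ", dR0[i],
           " and ", dR0[i + 1], " nm (no shared occupied bin)")
  }
  N_i <- rowSums(n_ik)
  kb <- vapply(windows, `[[`, numeric(1), "k_bias")
  c_ib <- 0.5 * kb * (outer(dR0, mids, `-`))^2    # nw x nb bias energies
  e_ib <- exp(-c_ib)
  n_b <- colSums(n_ik)
  f <- numeric(nw)
  for (it in seq_len(maxit)) {
    denom <- colSums(N_i * exp(f) * e_ib)
    P <- ifelse(denom > 0, n_b / denom, 0)
    f_new <- -log(pmax(e_ib %*% P, 1e-300))[, 1]
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
  }
  P <- P / sum(P)
  W <- ifelse(P > 0, -log(P), NA)
  keep <- is.finite(W)
  structure(
    data.frame(dR = mids[keep], W = W[keep] - min(W[keep]),
               counts = n_b[keep]),
    f = f, windows = data.frame(dR0 = dR0, k_bias = kb, n = N_i),
    bin_width = bin_width, iterations = it, anchored = FALSE,
    class = c("ncav_pmf", "data.frame"))
}

#' Anchor a PMF so the unbound state has zero free energy
#'
#' Fixes the additive constant of a WHAM profile by thermodynamic
#' integration along the window ladder: the mean restraint force
#' `-k_bias (<dR>_i - dR0_i)` is integrated over the window centres to give
#' the biased-system free energies up to one constant, which is determined
#' by the free-particle reference at the outermost (unbound) window where
#' the PMF is flat.  A plateau-zero offset is computed as an independent
#' cross-check and reported as `consistency` (the difference between the
#' two anchors).
#'
#' @param pmf unanchored `ncav_pmf` from [wham()].
#' @param windows the umbrella windows used to build it.
#' @param plateau_from start of the plateau region for the cross-check
#'   offset; default: the outermost window centre.
#' @return the PMF with `W` anchored (unbound level 0), attributes
#'   `offset_ti`, `offset_plateau`, `consistency`, `anchored = TRUE`.
#' @export
ti_anchor <- function(pmf, windows, plateau_from = NULL) {
  dR0 <- vapply(windows, `[[`, numeric(1), "dR0")
  ord <- order(dR0)
  windows <- windows[ord]
  dR0 <- dR0[ord]
  kb <- vapply(windows, `[[`, numeric(1), "k_bias")
  mf <- vapply(seq_along(windows), function(i)
    -kb[i] * (mean(windows[[i]]$samples) - dR0[i]), numeric(1))
  # unbound plateau check on the outermost window: near-zero mean force
  se_last <- kb[length(kb)] *
    sd(windows[[length(windows)]]$samples) /
    sqrt(length(windows[[length(windows)]]$samples) / 10)
  if (abs(mf[length(mf)]) > max(4 * se_last, 0.05 * kb[length(kb)]))
    stop("no unbound plateau detected: outermost window still feels a mean ",
         "force of ", signif(mf[length(mf)], 3), " kBT/nm")
  # TI free energy of the biased systems along the ladder
  F_ti <- c(0, cumsum(0.5 * (mf[-1] + mf[-length(mf)]) * diff(dR0)))
  # absolute reference: free particle in the outermost bias (W = 0 there)
  F_ti <- F_ti - F_ti[length(F_ti)] - log(sqrt(2 * pi / kb[length(kb)]))
  # biased free energies implied by the candidate profile
  bw <- attr(pmf, "bin_width")
  F_hat <- vapply(seq_along(windows), function(i) {
    -log(sum(exp(-(pmf$W + 0.5 * kb[i] * (pmf$dR - dR0[i])^2))) * bw)
  }, numeric(1))
  offset_ti <- mean(F_ti - F_hat)
  if (is.null(plateau_from)) plateau_from <- max(dR0)
  plateau <- pmf$dR >= plateau_from
  if (!any(plateau)) plateau <- pmf$dR >= sort(pmf$dR, TRUE)[
    min(10, nrow(pmf))]
  offset_plateau <- -mean(pmf$W[plateau])
  out <- pmf
  out$W <- pmf$W + offset_ti
  attr(out, "offset_ti") <- offset_ti
  attr(out, "offset_plateau") <- offset_plateau
  attr(out, "consistency") <- offset_ti - offset_plateau
  attr(out, "anchored") <- TRUE
  out
}

#' Detect the unbound cutoff r*
#'
#' Smallest order-parameter value beyond which the anchored PMF stays within
#' `tol` of zero for the rest of the profile: past this separation the
#' carrier conformations no longer overlap those of the membrane-receptor
#' system and the carrier is unbound.
#'
#' @param pmf anchored `ncav_pmf`.
#' @param tol flatness tolerance (kBT), > 0.
#' @return r* (nm).
#' @export
detect_r_star <- function(pmf, tol = 0.5) {
  if (tol <= 0) stop("tolerance must be positive (a zero tolerance can ",
                     "never be met by a stochastic profile)")
  if (!isTRUE(attr(pmf, "anchored")))
    stop("r* detection requires an anchored PMF (run ti_anchor first)")
  flat <- rev(cumprod(rev(abs(pmf$W) < tol))) > 0
  if (!flat[length(flat)] || !any(flat))
    stop("PMF never flattens within the sampled range: r* undefined")
  pmf$dR[which(flat)[1]]
}

#' Direct Boltzmann inversion of unbiased samples
#'
#' Reference estimator used to validate WHAM: `W = -log(hist density)` from
#' a long unbiased run, shifted to zero minimum.
#'
#' @param samples unbiased order-parameter samples.
#' @param bin_width histogram bin width.
#' @return data.frame with `dR`, `W`.
#' @export
boltzmann_inversion <- function(samples, bin_width = 0.2) {
  edges <- seq(floor(min(samples) / bin_width) * bin_width,
               max(samples) + bin_width, by = bin_width)
  cnt <- tabulate(findInterval(samples, edges, rightmost.closed = TRUE),
                  nbins = length(edges) - 1)
  mids <- edges[-1] - bin_width / 2
  keep <- cnt > 0
  data.frame(dR = mids[keep], W = -log(cnt[keep]) + log(max(cnt)))
}
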