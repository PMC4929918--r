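#' Default per-organ context table (mouse)
#'
#' Shipped defaults for the five organs of the steady-state tissue-targeting
#' model.  Receptor densities quoted in the text (lung about 2000, heart
#' about 50 ICAM1 per um^2) are filled in; quantities that are only
#' available as figure data in the sources (remaining densities, the
#' non-targeted partitioning coefficients Kp measured with IgG-coated
#' control carriers) are left `NA` with provenance
#' `"user-must-supply"` so that figure-read numbers are never silently
#' treated as ground truth.  Cell volume fractions follow the standard
#' choices: endothelial fraction 0.30 everywhere, macrophage fraction 0.03
#' in the clearance organs (liver, spleen) and 0 elsewhere.
#'
#' @return data.frame with one row per organ and a `provenance` column.
#' @export
default_organ_table <- function() {
  organs <- c("lung", "liver", "kidney", "heart", "spleen")
  data.frame(
    organ = organs,
    species = "mouse",
    N_ant_um2 = c(2000, NA, NA, 50, NA),
    kappa = 40, Aex = 10,
    Kp = NA_real_,
    phi_EC = 0.30,
    phi_M = ifelse(organs %in% c("liver", "spleen"), 0.03, 0),
    D_EC_um = 5, D_M_um = 5,
    L_EC_b_nm = 100, L_M_b_nm = 100,
    provenance = ifelse(organs %in% c("lung", "heart"),
                        "density: text estimate; Kp: user-must-supply",
                        "density and Kp: user-must-supply (figure data)"),
    stringsAsFactors = FALSE)
}

#' Standardized tissue uptake (%idg scale)
#'
#' Steady-state uptake score for a carrier with injected concentration
#' `C_out` perfused through a capillary with cell-free layer `L_cap`:
#' \deqn{\%idg \sim \{K_p K_{EC} C_{out} + \phi_{EC} K_{EC} L_{EC,b} D_{EC}
#'   C_{out}\} \frac{L_{cap}}{L_{EC,b}} + \phi_M K_M L_{M,b} D_M C_{out}
#'   \frac{L_{cap}}{L_{M,b}}.}
#' The absolute scale is arbitrary (it carries `L_cap` and `C_out`); only
#' ratios between organs are meaningful, and those are independent of
#' `L_cap` and `C_out`.
#'
#' Scenario switches: a flat-substrate prediction uses the flat-substrate
#' `K_EC`; endothelium-only sets `K_M = 0`; the macrophage scenarios supply
#' the resting- or activated-macrophage `K_M`.
#'
#' @param Kp non-targeted partitioning coefficient.
#' @param K_EC endothelial association constant.
#' @param phi_EC,phi_M cell volume fractions.
#' @param D_EC,D_M cell diameters (um).
#' @param L_EC_b,L_M_b bound-layer thicknesses r* per cell type (nm).
#' @param K_M macrophage association constant (0 disables the term).
#' @param L_cap capillary cell-free layer (arbitrary units).
#' @param C_out injected concentration (arbitrary units).
#' @return uptake score (arbitrary common scale); vectorized over organs.
#' @export
percent_idg <- function(Kp, K_EC, phi_EC = 0.30, D_EC = 5, L_EC_b = 100,
                        K_M = 0, phi_M = 0, D_M = 5, L_M_b = 100,
                        L_cap = 1, C_out = 1) {
  if (any(is.na(Kp)) || any(is.na(K_EC)))
    stop("missing Kp or K_EC for an enabled scenario; supply per-organ ",
         "values (shipped defaults are placeholders)")
  (Kp * K_EC * C_out + phi_EC * K_EC * L_EC_b * D_EC * C_out) *
    (L_cap / L_EC_b) +
    phi_M * K_M * L_M_b * D_M * C_out * (L_cap / L_M_b)
}

#' Normalized tissue targeting with avidity uncertainty
#'
#' Computes per-organ uptake scores and expresses them in scaled units
#' `eta = %idg_organ / %idg_lung`.  The uncertainty band evaluates the
#' scores at `K_EC - dK_EC`, `K_EC`, `K_EC + dK_EC` (and likewise for
#' `K_M`), normalized by the lung score at the central value, so
#' `eta_lung = 1` exactly at the centre.
#'
#' @param organs data.frame with columns `organ`, `Kp`, `K_EC` and
#'   optionally `dK_EC`, `K_M`, `dK_M`, `phi_EC`, `phi_M`, `D_EC_um`,
#'   `D_M_um`, `L_EC_b_nm`, `L_M_b_nm` (defaults as in
#'   [default_organ_table()]).
#' @param L_cap,C_out common scale factors (cancel in eta).
#' @return data.frame `organ`, `idg`, `eta`, `eta_lo`, `eta_hi`.
#' @export
eta_with_uncertainty <- function(organs, L_cap = 1, C_out = 1) {
  need <- function(col, default) {
    if (col %in% names(organs)) organs[[col]] else default
  }
  if (!"lung" %in% organs$organ)
    stop("normalization requires a 'lung' row in the organ table")
  dK <- need("dK_EC", 0)
  K_M <- need("K_M", 0)
  dK_M <- need("dK_M", 0)
  score <- function(kshift) {
    percent_idg(Kp = organs$Kp,
                K_EC = pmax(organs$K_EC + kshift * dK, 0),
                phi_EC = need("phi_EC", 0.30),
                D_EC = need("D_EC_um", 5),
                L_EC_b = need("L_EC_b_nm", 100),
                K_M = pmax(K_M + kshift * dK_M, 0),
                phi_M = need("phi_M", 0),
                D_M = need("D_M_um", 5),
                L_M_b = need("L_M_b_nm", 100),
                L_cap = L_cap, C_out = C_out)
  }
  idg <- score(0)
  lung <- idg[organs$organ == "lung"][1]
  band <- cbind(score(-1), idg, score(1)) / lung
  data.frame(organ = organs$organ, idg = idg, eta = idg / lung,
             eta_lo = apply(band, 1, min), eta_hi = apply(band, 1, max))
}

#' Bootstrap Pearson correlation between model and experiment
#'
#' Generates `n_sets` sets of `n_draws` Gaussian replicates of each paired
#' (model, experiment) value from its mean and standard deviation, computes
#' the Pearson r^2 between the model and experiment draws within each set,
#' and reports the mean r^2 over all draws together with the standard
#' deviation across sets.  Zero standard deviations are point masses.
#'
#' @param model,model_sd model means and standard deviations.
#' @param expt,expt_sd experimental means and standard deviations.
#' @param seed integer seed (same seed, same result).
#' @param n_sets,n_draws bootstrap layout (default five sets of 2000).
#' @return list of class `ncav_r2`: `r2_mean`, `r2_sd`, `r2_sets`, `seed`.
#' @export
bootstrap_r2 <- function(model, model_sd, expt, expt_sd, seed = 1,
                         n_sets = 5, n_draws = 2000) {
  n <- length(model)
  stopifnot(n >= 3, length(expt) == n,
            length(model_sd) %in% c(1, n), length(expt_sd) %in% c(1, n))
  model_sd <- rep(model_sd, length.out = n)
  expt_sd <- rep(expt_sd, length.out = n)
  set.seed(seed)
  r2 <- vapply(seq_len(n_sets), function(s) {
    md <- rnorm(n_draws * n, mean = rep(model, each = n_draws),
                sd = rep(model_sd, each = n_draws))
    ed <- rnorm(n_draws * n, mean = rep(expt, each = n_draws),
                sd = rep(expt_sd, each = n_draws))
    suppressWarnings(cor(md, ed))^2
  }, numeric(1))
  structure(list(r2_mean = mean(r2), r2_sd = sd(r2), r2_sets = r2,
                 seed = seed, n_sets = n_sets, n_draws = n_draws),
            class = "ncav_r2")
}

#' @export
print.ncav_r2 <- function(x, ...) {
  cat(sprintf("bootstrap r^2 = %.3f +/- %.3f (%d sets x %d draws, seed %d)\n",
              x$r2_mean, x$r2_sd, x$n_sets, x$n_draws, x$seed))
  invisible(x)
}

#' Compare a targeting model against the no-targeting null model
#'
#' Two-sided unpaired t-test on the per-set bootstrap r^2 values of the
#' targeting model versus the null model (uptake given by Kp alone,
#' independent of the ligand density).  Identical degenerate groups return
#' p = 1.
#'
#' @param model_stats,null_stats `ncav_r2` objects.
#' @return list with `p_value`, `t`, and the two group means.
#' @export
null_model_test <- function(model_stats, null_stats) {
  a <- model_stats$r2_sets
  b <- null_stats$r2_sets
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 bootstrap sets per group")
  if (sd(a) == 0 && sd(b) == 0 && isTRUE(all.equal(mean(a), mean(b))))
    return(list(p_value = 1, t = 0, mean_model = mean(a),
                mean_null = mean(b)))
  tt <- t.test(a, b)
  list(p_value = tt$p.value, t = unname(tt$statistic),
       mean_model = mean(a), mean_null = mean(b))
}
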