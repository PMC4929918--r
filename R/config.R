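#' Model parameter defaults
#'
#' Returns the full parameter tree of the model with literature defaults.
#' SI-quoted quantities (`H0_J`, `kappa_b_Npm`, `kappa_f_pNnm`) are converted
#' to internal units (nm, kBT at `temperature_K`) by [load_config()]; the
#' converted values are stored alongside under `H0`, `kappa_b`, `kappa_f`.
#'
#' Units per key:
#' \describe{
#'   \item{temperature_K}{system temperature (K); default 300}
#'   \item{membrane}{`L` projected patch side (nm, default 510, i.e. a
#'     ~0.26 um^2 patch), `a0` discretization length (nm, 10),
#'     `link_max_factor` upper tether bound in units of `a0` (sqrt(3)),
#'     `kappa` bending rigidity (kBT, 20), `sigma` frame tension
#'     (kBT/nm^2, 0), `L_z` box height along the reaction coordinate
#'     (nm, 500)}
#'   \item{receptor}{`L_an` length (nm, 19), `kappa_f_pNnm` flexural
#'     rigidity (pN nm per rad^2, 7000), `density_um2` surface density per
#'     projected area (um^-2, 2000)}
#'   \item{carrier}{`r_nc` NC radius (nm, 50), `N_ab` ligands per NC (162),
#'     `L_ab` ligand (antibody) length (nm, 15)}
#'   \item{bond}{`H0_J` equilibrium free-energy change per bond (J,
#'     -7.98e-20), `kappa_b_Npm` bond spring constant (N/m, 1), `d_star`
#'     reaction range (nm, 1)}
#' }
#'
#' @return nested list of parameters.
#' @export
default_params <- function() {
  list(
    temperature_K = 300,
    membrane = list(
      L = 510, a0 = 10, link_max_factor = sqrt(3),
      kappa = 20, sigma = 0, L_z = 500
    ),
    receptor = list(
      L_an = 19, kappa_f_pNnm = 7000, density_um2 = 2000
    ),
    carrier = list(
      r_nc = 50, N_ab = 162, L_ab = 15
    ),
    bond = list(
      H0_J = -7.98e-20, kappa_b_Npm = 1, d_star = 1
    )
  )
}

convert_params <- function(p) {
  T <- p$temperature_K
  p$receptor$kappa_f <- pNnm_to_kBT(p$receptor$kappa_f_pNnm, T)
  p$bond$H0 <- joule_to_kBT(p$bond$H0_J, T)
  p$bond$kappa_b <- Npm_to_kBT_nm2(p$bond$kappa_b_Npm, T)
  p
}

check_unknown <- function(user, template, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(template))
      stop("unknown configuration key: '", full, "'", call. = FALSE)
    if (is.list(template[[key]]) && !is.null(user[[key]])) {
      if (!is.list(user[[key]]))
        stop("configuration key '", full, "' must be a mapping", call. = FALSE)
      check_unknown(user[[key]], template[[key]], full)
    }
  }
  invisible(TRUE)
}

#' Load and validate a model configuration
#'
#' Reads a YAML configuration file, validates every key against the parameter
#' template of [default_params()] (unknown keys are rejected with the full key
#' path), fills absent keys with defaults, and converts SI-quoted quantities
#' to internal units (nm, kBT).
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @param overrides optional named list merged over the file contents.
#' @return validated parameter list with internal-unit fields
#'   `receptor$kappa_f` (kBT/rad^2), `bond$H0` (kBT), `bond$kappa_b`
#'   (kBT/nm^2) populated.
#' @examples
#' p <- load_config()
#' round(p$bond$H0, 2)   # about -19.27 kBT at 300 K
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  defaults <- default_params()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  if (!is.null(overrides)) user <- modifyList(user, overrides)
  check_unknown(user, defaults)
  p <- modifyList(defaults, user)
  convert_params(p)
}
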