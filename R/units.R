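#' Physical constants and unit conversions
#'
#' The package works internally in nanometres and units of the thermal energy
#' kBT at the system temperature.  These helpers convert the SI values in
#' which biophysical parameters are usually quoted (J, N/m, pN nm) to and
#' from internal units.  Round-trip conversions are exact to double precision.
#'
#' @param T temperature in kelvin.
#' @param x value to convert.
#' @name units
NULL

#' @rdname units
#' @export
kB_SI <- 1.380649e-23  # J/K (exact, 2019 SI)

#' @rdname units
#' @return `kBT_joule`: the thermal energy in joules at temperature `T`.
#' @export
kBT_joule <- function(T = 300) kB_SI * T

#' @rdname units
#' @return `joule_to_kBT`: energy in kBT units.
#' @export
joule_to_kBT <- function(x, T = 300) x / kBT_joule(T)

#' @rdname units
#' @export
kBT_to_joule <- function(x, T = 300) x * kBT_joule(T)

#' @rdname units
#' @return `Npm_to_kBT_nm2`: a spring constant in N/m expressed in kBT/nm^2.
#' @export
Npm_to_kBT_nm2 <- function(x, T = 300) x * 1e-18 / kBT_joule(T)

#' @rdname units
#' @export
kBT_nm2_to_Npm <- function(x, T = 300) x * kBT_joule(T) / 1e-18

#' @rdname units
#' @return `pNnm_to_kBT`: an energy (or torsional rigidity per rad^2) in
#'   pN nm expressed in kBT.
#' @export
pNnm_to_kBT <- function(x, T = 300) x * 1e-21 / kBT_joule(T)

#' @rdname units
#' @export
kBT_to_pNnm <- function(x, T = 300) x * kBT_joule(T) / 1e-21
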