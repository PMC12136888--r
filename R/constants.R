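#' Physical constants and solvent defaults
#'
#' All thermodynamics in this package uses calorie-based units so fitted
#' enthalpies and entropies are directly comparable with the classical
#' calorimetric literature on globular proteins. Hydrodynamics uses CGS
#' units internally (g, cm, s, poise), with sedimentation coefficients
#' expressed in svedbergs (1 S = 1e-13 s) at the interface.
#'
#' @format `aav_constants` is a list with elements:
#' \describe{
#'   \item{R_cal}{Gas constant, 1.987 cal/(K·mol).}
#'   \item{N_A}{Avogadro constant, 6.022e23 /mol.}
#'   \item{kelvin_offset}{273.15, for °C <-> K conversion.}
#'   \item{svedberg}{1e-13 s, one svedberg.}
#'   \item{rho_pbs}{Density of PBS at 20 °C, 1.005 g/mL.}
#'   \item{eta_pbs}{Viscosity of PBS at 20 °C, 0.01002 poise (1.002 cP).}
#'   \item{vbar_protein}{Partial specific volume of protein, 0.730 mL/g.}
#'   \item{vbar_ssdna}{Partial specific volume of ssDNA, 0.550 mL/g.}
#' }
#' @export
aav_constants <- list(
  R_cal         = 1.987,
  N_A           = 6.022e23,
  kelvin_offset = 273.15,
  svedberg      = 1e-13,
  rho_pbs       = 1.005,
  eta_pbs       = 0.01002,
  vbar_protein  = 0.730,
  vbar_ssdna    = 0.550
)

# Internal shorthands
.RGAS <- aav_constants$R_cal
.KELVIN <- aav_constants$kelvin_offset
.NAVO <- aav_constants$N_A
.SVED <- aav_constants$svedberg

#' Default solvent conditions (PBS at 20 degrees Celsius)
#'
#' @param rho solvent density in g/mL
#' @param eta solvent viscosity in poise
#' @param temperature_C solvent temperature in °C (metadata only; the
#'   density and viscosity must already correspond to it)
#' @return an object of class `hydro_conditions`
#' @export
hydro_conditions <- function(rho = aav_constants$rho_pbs,
                             eta = aav_constants$eta_pbs,
                             temperature_C = 20) {
  stopifnot(is.numeric(rho), length(rho) == 1L, rho > 0,
            is.numeric(eta), length(eta) == 1L, eta > 0)
  structure(list(rho = rho, eta = eta, temperature_C = temperature_C),
            class = "hydro_conditions")
}

#' @export
print.hydro_conditions <- function(x, ...) {
  cat(sprintf("Solvent: rho = %.4g g/mL, eta = %.4g P (%.4g cP), T = %g degC\n",
              x$rho, x$eta, x$eta * 100, x$temperature_C))
  invisible(x)
}
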