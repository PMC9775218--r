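#' Physical constants and unit conversions
#'
#' Estimator internals work in units of kT; conversion to kJ/mol happens
#' only at input/output boundaries. The gas constant is
#' R = 0.0083144621 kJ mol^-1 K^-1 and the default temperature is 298 K.
#'
#' @name units
NULL

#' Gas constant in kJ mol^-1 K^-1
#' @export
GAS_CONSTANT_KJ <- 0.0083144621

#' Coulomb prefactor in kJ nm mol^-1 e^-2
#' @export
COULOMB_KJ_NM <- 138.935

#' kcal/mol per kJ/mol conversion factor
#' @export
KCAL_PER_KJ <- 1 / 4.184

#' Thermal energy kT in kJ/mol
#'
#' @param temperature temperature in kelvin (default 298 K)
#' @return kT in kJ/mol
#' @examples
#' kT_kJmol(298)  # 2.4777...
#' @export
kT_kJmol <- function(temperature = 298) {
  stopifnot(is.numeric(temperature), temperature > 0)
  GAS_CONSTANT_KJ * temperature
}

#' Convert energies between kT and kJ/mol
#'
#' @param x numeric energies
#' @param temperature kelvin
#' @return converted energies
#' @export
kt_to_kjmol <- function(x, temperature = 298) x * kT_kJmol(temperature)

#' @rdname kt_to_kjmol
#' @export
kjmol_to_kt <- function(x, temperature = 298) x / kT_kJmol(temperature)

#' Convert kcal/mol to kJ/mol
#' @param x energies in kcal/mol
#' @return energies in kJ/mol
#' @export
kcal_to_kjmol <- function(x) x * 4.184
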