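#' Physical constants and unit conventions
#'
#' Internal units are nm, fs, u (g/mol), kJ/mol, elementary charge, K and
#' cm^-1. All conversions go through this single constant set.
#'
#' @format A list with components:
#' \describe{
#'   \item{kB}{Boltzmann constant, kJ/(mol K).}
#'   \item{c_cm_fs}{Speed of light in cm/fs (for wavenumber/angular-frequency
#'     conversion, omega = 2 pi c nu-tilde).}
#'   \item{f_coulomb}{Coulomb prefactor, kJ nm/(mol e^2).}
#'   \item{N_A}{Avogadro constant, 1/mol.}
#'   \item{M_water}{Molar mass of H2O, g/mol.}
#'   \item{mass_O, mass_H}{Site masses, u.}
#'   \item{kJ_per_internal}{Energy conversion: 1 kJ/mol in u nm^2/fs^2.}
#' }
#' @export
water_constants <- list(
  kB = 0.0083144621,
  c_cm_fs = 2.99792458e-5,
  f_coulomb = 138.935458,
  N_A = 6.02214076e23,
  M_water = 18.0153,
  mass_O = 15.9994,
  mass_H = 1.00794,
  kJ_per_internal = 1e-6
)

#' Convert wavenumber (cm^-1) to angular frequency (rad/fs)
#' @param nu_tilde wavenumber in cm^-1
#' @return angular frequency in rad/fs
#' @export
wavenumber_to_angular <- function(nu_tilde) {
  2 * pi * water_constants$c_cm_fs * nu_tilde
}

#' Convert angular frequency (rad/fs) to wavenumber (cm^-1)
#' @param omega angular frequency in rad/fs
#' @return wavenumber in cm^-1
#' @export
angular_to_wavenumber <- function(omega) {
  omega / (2 * pi * water_constants$c_cm_fs)
}
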