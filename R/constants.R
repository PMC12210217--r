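#' Physical constants used throughout the package
#'
#' Molecular weights and liquid densities of the two solvent species at
#' 25 degrees C, the Boltzmann constant in MD units, and the conversion from
#' amu/Angstrom^3 to g/cm^3. Kept in one place so every module agrees.
#'
#' @format A named list:
#' \describe{
#'   \item{mw_thf}{molar mass of tetrahydrofuran, g/mol}
#'   \item{mw_water}{molar mass of water, g/mol}
#'   \item{rho_thf}{density of liquid THF, g/mL}
#'   \item{rho_water}{density of liquid water, g/mL}
#'   \item{water_molarity}{mol of water per litre of water (the convention
#'     behind "N molar THF" compositions), mol/L}
#'   \item{kB}{Boltzmann constant, kJ/mol/K}
#'   \item{amu_A3_to_g_cm3}{1 amu/A^3 expressed in g/cm^3}
#' }
#' @export
solvent_constants <- list(
  mw_thf = 72.11,
  mw_water = 18.015,
  rho_thf = 0.889,
  rho_water = 0.997,
  water_molarity = 55.5,
  kB = 0.0083144621,
  amu_A3_to_g_cm3 = 1.6605
)

# thermal energy in kJ/mol at temperature T (K)
kT <- function(temperature) solvent_constants$kB * temperature
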