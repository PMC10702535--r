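# Physical constants and unit conversions.
# Internal unit system: lengths in Angstrom, energies in kJ/mol,
# temperatures in K, concentrations in mol/L unless stated otherwise.

#' Physical constants used throughout the package
#'
#' A named list of physical constants in the package's internal unit
#' system (Angstrom, kJ/mol, K, mol/L):
#' \describe{
#'   \item{R_gas}{molar gas constant, kJ/mol/K}
#'   \item{N_av}{Avogadro constant, 1/mol}
#'   \item{molar_to_num}{number density (molecules/A^3) of a 1 mol/L solution}
#'   \item{M1_water}{molar mass of water, kg/mol}
#'   \item{M2_caffeine}{molar mass of caffeine, kg/mol}
#' }
#'
#' @export
sasa_constants <- list(
  R_gas        = 8.31446261815324e-3,
  N_av         = 6.02214076e23,
  molar_to_num = 6.02214076e-4,
  M1_water     = 0.0180153,
  M2_caffeine  = 0.19419
)

#' Thermal energy kT in kJ/mol
#'
#' @param temperature temperature in K
#' @return kT expressed per mole (i.e. RT) in kJ/mol
#' @export
kT <- function(temperature) sasa_constants$R_gas * temperature

# inverse thermal energy, mol/kJ
beta_of <- function(temperature) 1 / kT(temperature)
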