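# Physical constants used throughout. Energies are kJ/mol, lengths Angstrom,
# charges elementary charge units, concentrations mol/L.

# Gas constant, kJ/(mol K)
.RGAS <- 8.31446261815324e-3

# Coulomb constant, kJ * Angstrom / (mol e^2)
.KCOUL <- 1389.35

#' Thermal energy scale of titration, ln(10) * R * T
#'
#' The free-energy cost of one pH unit of driving force; 5.708 kJ/mol at
#' 298.15 K. Used to convert between pKa shifts and electrostatic energies.
#'
#' @param temperature Temperature in Kelvin.
#' @return Numeric scalar, kJ/mol.
#' @examples
#' ln10RT()          # 5.708 at 25 C
#' @export
ln10RT <- function(temperature = 298.15) {
  log(10) * .RGAS * temperature
}

# Debye screening parameter kappa^2 (1/A^2) for a 1:1 electrolyte of ionic
# strength I (mol/L) in a medium of dielectric constant eps at temperature T.
# kappa^2 = 4 pi * lambda_Bjerrum * sum_i n_i z_i^2, number densities in 1/A^3.
.kappa2 <- function(ionic_strength, eps, temperature = 298.15) {
  if (ionic_strength <= 0) return(0)
  lambda_b <- .KCOUL / (eps * .RGAS * temperature)
  n_tot <- 2 * ionic_strength * 6.02214076e-4  # ions / A^3, z = +-1
  4 * pi * lambda_b * n_tot
}

# Round half-up to a number of decimals (R's round() is half-even); used for
# table-style reporting of proton-uptake values at two decimals.
.round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
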