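#' Physical constants in the package unit system
#'
#' The package works in a single molar unit system: lengths in Angstrom,
#' energies in kJ/mol, forces in kJ/mol/Angstrom, masses in amu (g/mol),
#' entropies in J/K/mol and frequencies in 1/s. Conversions happen only at
#' the I/O boundary.
#'
#' @param T temperature in Kelvin (default 298).
#' @return An object of class \code{eemcc_constants} with elements:
#'   \describe{
#'     \item{kB}{Boltzmann constant in molar form (the gas constant),
#'       kJ/mol/K.}
#'     \item{kB_entropy}{Same constant in J/K/mol, the unit entropies are
#'       reported in.}
#'     \item{h}{Planck constant in molar form, kJ s/mol.}
#'     \item{T}{temperature, K.}
#'     \item{sigma_water}{rotational symmetry number of water, fixed at 2.}
#'     \item{freq2}{conversion factor from (kJ/mol)/(amu Angstrom^2) to
#'       1/s^2, used when turning covariance eigenvalues into frequencies.}
#'   }
#' @export
#' @examples
#' const <- eemcc_constants()
#' const$kB * const$T  # thermal energy at 298 K, kJ/mol
eemcc_constants <- function(T = 298) {
  stopifnot(is.numeric(T), length(T) == 1L, T > 0)
  structure(
    list(
      kB = 8.314462618e-3,          # kJ/mol/K
      kB_entropy = 8.314462618,     # J/K/mol
      h = 3.990312712893e-13,       # kJ s/mol  (6.62607015e-34 J s * N_A)
      T = T,
      sigma_water = 2,
      # 1 (kJ/mol) / (amu Angstrom^2) = 1e3 J/mol / (1e-3 kg/mol * 1e-20 m^2)
      freq2 = 1e26
    ),
    class = "eemcc_constants"
  )
}

#' @export
print.eemcc_constants <- function(x, ...) {
  cat("eemcc physical constants: T =", x$T, "K, kB =", x$kB,
      "kJ/mol/K, sigma(water) =", x$sigma_water, "\n")
  invisible(x)
}
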