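#' Thermodynamic parameters
#'
#' Bundles the temperature with the Boltzmann constant (in kcal/(mol K)) and
#' the derived quantities `kT` and `kT * ln(10)` used throughout the
#' protonation Hamiltonian: a unit change in `pH - pKa` costs `kT * ln(10)`
#' (about 1.3727 kcal/mol at 300 K).
#'
#' @param temperature Simulation temperature in kelvin. Default 300.
#' @return An object of class `thermo_params` with fields `temperature`,
#'   `boltzmann_constant`, `kT` and `kT_ln10` (all energies in kcal/mol).
#' @export
#' @examples
#' th <- thermo_params()
#' th$kT_ln10  # ~1.3727 kcal/mol
thermo_params <- function(temperature = 300) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("temperature must be a single finite value > 0 (kelvin)")
  }
  kB <- 1.9872041e-3  # kcal/(mol K)
  structure(
    list(
      temperature = as.numeric(temperature),
      boltzmann_constant = kB,
      kT = kB * temperature,
      kT_ln10 = kB * temperature * log(10)
    ),
    class = "thermo_params"
  )
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf("<thermo_params> T = %g K, kT = %.6f kcal/mol, kT*ln10 = %.6f kcal/mol\n",
              x$temperature, x$kT, x$kT_ln10))
  invisible(x)
}
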