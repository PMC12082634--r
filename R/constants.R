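#' Physical constants (package-wide unit convention: nm, ns, K, kJ/mol,
#' rates in 1/us unless stated otherwise)
#'
#' `RGAS` is the molar gas constant in kJ/(mol K), `KBOLTZ` the Boltzmann
#' constant in J/K and `PLANCK` the Planck constant in J s.
#'
#' @keywords internal
#' @name constants
NULL

RGAS <- 8.314462618e-3   # kJ/(mol K)
KBOLTZ <- 1.380649e-23   # J/K
PLANCK <- 6.62607015e-34 # J s

#' Thermal energy RT
#'
#' Kept internal (unexported) so it does not mask `stats::rt`.
#'
#' @param temperature temperature in K
#' @return RT in kJ/mol
#' @noRd
rt <- function(temperature) {
  stopifnot(is.numeric(temperature), all(temperature > 0))
  RGAS * temperature
}
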