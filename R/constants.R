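# Physical constants (CODATA 2018, SI) used throughout. Internal units are
# nm for length and kT at the working temperature for energy; conversions to
# kJ/mol happen only at I/O boundaries.

.const <- list(
  e       = 1.602176634e-19,   # elementary charge, C
  kB      = 1.380649e-23,      # Boltzmann, J/K
  eps0    = 8.8541878128e-12,  # vacuum permittivity, F/m
  Navo    = 6.02214076e23,     # Avogadro, 1/mol
  hplanck = 6.62607015e-34,    # Planck, J s
  Rgas    = 8.314462618        # gas constant, J/(mol K)
)

#' Thermal energy
#'
#' `kT_joule()` returns the thermal energy k_B T in joules; `kT_kjmol()` in
#' kJ/mol (2.494 kJ/mol at 300 K, the constant used when converting tabulated
#' surface potentials between kJ/mol and kT).
#'
#' @param temperature Absolute temperature in kelvin.
#' @return A numeric scalar.
#' @examples
#' kT_kjmol(300)
#' @export
kT_joule <- function(temperature = 300) .const$kB * temperature

#' @rdname kT_joule
#' @export
kT_kjmol <- function(temperature = 300) .const$Rgas * temperature / 1000
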