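# CODATA 2018 exact values (SI redefinition)
.const <- list(
  e    = 1.602176634e-19,   # elementary charge, C
  kB   = 1.380649e-23,      # Boltzmann constant, J/K
  N_A  = 6.02214076e23,     # Avogadro number, 1/mol
  eps0 = 8.8541878128e-12   # vacuum permittivity, F/m
)

#' Thermal voltage kT/e
#' @param temperature temperature in K
#' @return thermal voltage in volts (~25.7 mV at 298.15 K)
#' @export
thermal_voltage <- function(temperature = 298.15) {
  .const$kB * temperature / .const$e
}
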