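# Shared physical constants and closed-form double-layer oracles used as
# independent references for the numerical solver.
CONST <- list(
  e = 1.602176634e-19, kB = 1.380649e-23,
  N_A = 6.02214076e23, eps0 = 8.8541878128e-12
)

# symmetric 1:1 salt composition at a given molarity (plus water ions)
salt_composition <- function(c_molar, pH = 7) {
  sp <- rbind(ion_species("Na+", 1, c_molar),
              ion_species("Cl-", -1, c_molar),
              ion_species("H+", 1, 10^(-pH)),
              ion_species("OH-", -1, 1e-14 / 10^(-pH)))
  electrolyte(sp, pH = pH)
}

# Grahame equation: sigma(psi0) for a 1:1 electrolyte, planar surface
grahame_sigma <- function(psi0, c_molar, temperature = 298.15,
                          eps_r = 78.36) {
  kT <- CONST$kB * temperature
  eps <- eps_r * CONST$eps0
  sqrt(8 * c_molar * 1e3 * CONST$N_A * eps * kT) *
    sinh(CONST$e * psi0 / (2 * kT))
}

# Debye-Hueckel profile
dh_profile <- function(psi0, x, lD) psi0 * exp(-x / lD)

# small default solver grid for speed in unit tests; accuracy-critical
# tests use the full default config
fast_config <- function(...) solver_config(n_grid = 400, ...)
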