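#' Define a single ionic (or neutral) solution species
#'
#' @param name species label, e.g. `"H+"`, `"TrisH+"`.
#' @param valence integer charge number \eqn{z_i}. Zero is allowed for
#'   neutral species (e.g. free Tris base); such species carry no Poisson
#'   source charge.
#' @param concentration bulk molar concentration, mol/L, non-negative.
#' @param dispersion_B Mahanty--Ninham ionic dispersion coefficient
#'   \eqn{B_i} in J m^3 (default 0, i.e. purely electrostatic).
#' @return a one-row data frame of class `ion_species`.
#' @export
ion_species <- function(name, valence, concentration, dispersion_B = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(valence) || length(valence) != 1L ||
      abs(valence - round(valence)) > 1e-9) {
    stop("valence must be a single integer", call. = FALSE)
  }
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      is.na(concentration) || concentration < 0) {
    stop("concentration must be a single non-negative number (mol/L)",
         call. = FALSE)
  }
  out <- data.frame(
    name = name,
    valence = as.integer(round(valence)),
    concentration = as.numeric(concentration),
    dispersion_B = as.numeric(dispersion_B),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ion_species", class(out))
  out
}

#' Assemble an electrolyte composition
#'
#' Low-level constructor; most users will call [tris_composition()].
#' Electroneutrality of the charged species is enforced at construction.
#'
#' @param species a data frame of species rows as produced by
#'   [ion_species()] (rbind-ed).
#' @param pH bulk pH; must be consistent with the H+ entry.
#' @param temperature absolute temperature, K.
#' @param rel_permittivity relative permittivity of the solvent
#'   (78.36 for water at 298.15 K).
#' @return an object of class `electrolyte_composition`.
#' @export
electrolyte <- function(species, pH, temperature = 298.15,
                        rel_permittivity = 78.36) {
  stopifnot(is.data.frame(species),
            all(c("name", "valence", "concentration") %in% names(species)))
  if (is.null(species$dispersion_B)) species$dispersion_B <- 0
  if (any(species$concentration < 0)) {
    stop("invalid composition: negative concentration", call. = FALSE)
  }
  net <- sum(species$valence * species$concentration)
  if (abs(net) > 1e-12) {
    stop(sprintf(
      "composition is not electroneutral (sum z*c = %.3e mol/L)", net),
      call. = FALSE)
  }
  out <- list(species = as.data.frame(species), pH = pH,
              temperature = temperature,
              rel_permittivity = rel_permittivity)
  class(out) <- "electrolyte_composition"
  out
}

#' @export
print.electrolyte_composition <- function(x, ...) {
  cat(sprintf("Electrolyte composition at pH %.2f, %.2f K (eps_r = %.2f)\n",
              x$pH, x$temperature, x$rel_permittivity))
  sp <- x$species
  for (i in seq_len(nrow(sp))) {
    cat(sprintf("  %-8s z = %+d  c = %.4g mM%s\n", sp$name[i], sp$valence[i],
                1e3 * sp$concentration[i],
                if (sp$dispersion_B[i] != 0)
                  sprintf("  B = %.3g J m^3", sp$dispersion_B[i]) else ""))
  }
  cat(sprintf("  I = %.4g mM, Debye length = %.3g nm\n",
              1e3 * ionic_strength(x), 1e9 * debye_length(x)))
  invisible(x)
}

#' Tris buffer composition at a given pH
#'
#' Speciates a Tris/TrisH+ buffer by Henderson--Hasselbalch at the given
#' pH, adds H+ and OH- from water autoionization (Kw = 1e-14), an optional
#' 1:1 background salt, and closes electroneutrality exactly with Cl-
#' (net positive charge) or Na+ (net negative charge) -- the counterions
#' introduced by an HCl/NaOH titration.
#'
#' @param total_tris total buffer concentration (Tris + TrisH+), mol/L.
#' @param pH bulk pH, in (0, 14).
#' @param temperature absolute temperature, K.
#' @param background_salt additional 1:1 salt (NaCl), mol/L, added
#'   symmetrically.
#' @param tris_pK acid dissociation pK of TrisH+ (8.07 at 25 C).
#' @param rel_permittivity relative permittivity of the solvent.
#' @param dispersion_B optional named numeric vector of Mahanty--Ninham
#'   coefficients (J m^3) keyed by species name (`"H+"`, `"OH-"`,
#'   `"TrisH+"`, `"Na+"`, `"Cl-"`); unnamed species default to 0.
#' @return an `electrolyte_composition`.
#' @examples
#' comp <- tris_composition(0.010, pH = 7.5)
#' ionic_strength(comp)
#' debye_length(comp) * 1e9  # nm
#' @export
tris_composition <- function(total_tris, pH, temperature = 298.15,
                             background_salt = 0, tris_pK = 8.07,
                             rel_permittivity = 78.36,
                             dispersion_B = NULL) {
  stopifnot(total_tris >= 0, background_salt >= 0)
  if (!(pH > 0 && pH < 14)) stop("pH must lie in (0, 14)", call. = FALSE)
  Kw <- 1e-14
  H  <- 10^(-pH)
  OH <- Kw / H
  # Henderson-Hasselbalch: protonated fraction of the Tris couple
  f_TrisH <- 1 / (1 + 10^(pH - tris_pK))
  TrisH <- total_tris * f_TrisH
  Tris0 <- total_tris * (1 - f_TrisH)

  B <- function(nm) {
    if (is.null(dispersion_B) || !nm %in% names(dispersion_B)) return(0)
    unname(dispersion_B[nm])
  }
  rows <- list(
    ion_species("H+",  +1L, H,  B("H+")),
    ion_species("OH-", -1L, OH, B("OH-"))
  )
  if (total_tris > 0) {
    rows <- c(rows, list(ion_species("TrisH+", +1L, TrisH, B("TrisH+")),
                         ion_species("Tris",    0L, Tris0, 0)))
  }
  na_cl <- c(Na = background_salt, Cl = background_salt)
  net <- H - OH + TrisH           # charge to be closed by counterion
  if (abs(net) < 1e-15) net <- 0  # drop floating-point residue

  if (net > 0) na_cl["Cl"] <- na_cl["Cl"] + net
  if (net < 0) na_cl["Na"] <- na_cl["Na"] - net
  if (na_cl["Na"] > 0) {
    rows <- c(rows, list(ion_species("Na+", +1L, unname(na_cl["Na"]), B("Na+"))))
  }
  if (na_cl["Cl"] > 0) {
    rows <- c(rows, list(ion_species("Cl-", -1L, unname(na_cl["Cl"]), B("Cl-"))))
  }
  species <- do.call(rbind, lapply(rows, as.data.frame))
  electrolyte(species, pH = pH, temperature = temperature,
              rel_permittivity = rel_permittivity)
}

#' Ionic strength of a composition
#'
#' \eqn{I = \tfrac12 \sum_i c_i z_i^2} over all species (neutral species
#' contribute nothing).
#'
#' @param comp an `electrolyte_composition`.
#' @return ionic strength in mol/L.
#' @export
ionic_strength <- function(comp) {
  stopifnot(inherits(comp, "electrolyte_composition"))
  sp <- comp$species
  0.5 * sum(sp$concentration * sp$valence^2)
}

#' Debye screening length
#'
#' \eqn{\kappa^{-1} = \sqrt{\varepsilon_r \varepsilon_0 k_B T /
#' (2 N_A e^2 \cdot 10^3 I)}}; about 3.04 nm in 10 mM 1:1 electrolyte at
#' 25 C.
#'
#' @param comp an `electrolyte_composition`.
#' @return Debye length in metres.
#' @export
debye_length <- function(comp) {
  I <- ionic_strength(comp)
  if (I <= 0) {
    stop("infinite screening length: ionic strength is zero", call. = FALSE)
  }
  eps <- comp$rel_permittivity * .const$eps0
  sqrt(eps * .const$kB * comp$temperature /
         (2 * .const$N_A * .const$e^2 * I * 1e3))
}
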