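#' Define a charge-regulated surface site class
#'
#' Three site chemistries are supported:
#' \describe{
#'   \item{`acid_silanol`}{SiOH = SiO- + H+ (pK_O,a); carries -1 when
#'     deprotonated.}
#'   \item{`base_silanol`}{SiOH+ = SiO + H+ (pK_O,b); the "-SiO" label is
#'     shorthand for a basic surface site, +1 when protonated, neutral
#'     otherwise -- not a literal chemical structure.}
#'   \item{`amine`}{RNH3+ = RNH2 + H+ (pK_N); +1 when protonated.}
#' }
#'
#' @param kind one of `"acid_silanol"`, `"base_silanol"`, `"amine"`.
#' @param pK negative log of the site dissociation constant.
#' @param density surface site density, sites/nm^2, non-negative.
#' @return an object of class `surface_site`.
#' @export
surface_site <- function(kind = c("acid_silanol", "base_silanol", "amine"),
                         pK, density) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(pK), length(pK) == 1L, is.finite(pK))
  if (!is.numeric(density) || density < 0) {
    stop("site density must be non-negative (sites/nm^2)", call. = FALSE)
  }
  structure(list(kind = kind, pK = pK, density = density),
            class = "surface_site")
}

#' Assemble a charge-regulated surface model
#'
#' @param ... `surface_site` objects, at most one per kind.
#' @param label free-text label, e.g. `"MSN"` or `"MSN-NH2"`.
#' @return an object of class `surface_model`.
#' @examples
#' surface_model(
#'   surface_site("acid_silanol", pK = 7.6, density = 0.5),
#'   surface_site("base_silanol", pK = 2.2, density = 0.5),
#'   label = "amphoteric silica"
#' )
#' @export
surface_model <- function(..., label = "surface") {
  sites <- list(...)
  if (length(sites) == 1L && is.list(sites[[1]]) &&
      !inherits(sites[[1]], "surface_site")) {
    sites <- sites[[1]]
  }
  stopifnot(all(vapply(sites, inherits, logical(1), "surface_site")))
  kinds <- vapply(sites, `[[`, character(1), "kind")
  if (anyDuplicated(kinds)) {
    stop("at most one site class per kind", call. = FALSE)
  }
  names(sites) <- kinds
  structure(list(sites = sites, label = label), class = "surface_model")
}

#' @export
print.surface_model <- function(x, ...) {
  cat(sprintf("Surface model '%s':\n", x$label))
  for (s in x$sites) {
    cat(sprintf("  %-13s pK = %5.2f  N = %.4g /nm^2\n",
                s$kind, s$pK, s$density))
  }
  invisible(x)
}

#' Ionized fraction of a site class at a given surface proton activity
#'
#' Langmuir (single-site mass-action) isotherms:
#' acid silanol returns the deprotonated (-1 charged) fraction
#' \eqn{K_a/(H_s + K_a)}; basic silanol and amine return the protonated
#' (+1 charged) fraction \eqn{H_s/(H_s + K)}.
#'
#' @param kind site kind (see [surface_site()]).
#' @param pK site pK.
#' @param surface_proton_conc proton concentration at the surface, mol/L,
#'   strictly positive (Boltzmann-weighted bulk value).
#' @return charged fraction in \[0, 1\].
#' @export
ionized_fraction <- function(kind = c("acid_silanol", "base_silanol", "amine"),
                             pK, surface_proton_conc) {
  kind <- match.arg(kind)
  if (any(surface_proton_conc <= 0)) {
    stop("surface proton concentration must be positive", call. = FALSE)
  }
  K <- 10^(-pK)
  Hs <- surface_proton_conc
  if (kind == "acid_silanol") K / (Hs + K) else Hs / (Hs + K)
}

#' Surface charge density under charge regulation
#'
#' The surface proton concentration is Boltzmann-weighted by the surface
#' potential, \eqn{H_s = [H^+]_{bulk} \exp(-e\psi_0/k_BT)}, and the net
#' charge density is
#' \eqn{\sigma = e \cdot 10^{18} (N_b \theta_b^+ + N_N \theta_N^+ -
#' N_a \theta_a^-)} with densities in sites/nm^2. Strictly decreasing in
#' `psi0`, which guarantees a unique self-consistent coupling with the
#' Poisson--Boltzmann field.
#'
#' @param model a `surface_model`.
#' @param psi0 surface potential, volts (vectorized).
#' @param comp an `electrolyte_composition` supplying bulk \[H+\] and
#'   temperature.
#' @return surface charge density in C/m^2.
#' @export
surface_charge_density <- function(model, psi0, comp) {
  stopifnot(inherits(model, "surface_model"),
            inherits(comp, "electrolyte_composition"))
  kT_e <- thermal_voltage(comp$temperature)
  H_bulk <- 10^(-comp$pH)
  Hs <- H_bulk * exp(-psi0 / kT_e)
  sigma <- 0
  for (s in model$sites) {
    if (s$density == 0) next
    theta <- ionized_fraction(s$kind, s$pK, Hs)
    sgn <- if (s$kind == "acid_silanol") -1 else +1
    sigma <- sigma + sgn * s$density * theta
  }
  .const$e * 1e18 * sigma
}
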