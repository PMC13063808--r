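#' Solver configuration for the 1D Poisson--Boltzmann problem
#'
#' @param geometry `"planar"` half-space (default; curvature is negligible
#'   when the particle radius far exceeds the Debye length, as for ~75 nm
#'   particles in ~3 nm-screening electrolyte) or `"spherical"`.
#' @param radius particle radius in metres; required for spherical
#'   geometry.
#' @param domain_length extent of the computational domain in Debye
#'   lengths (far Dirichlet boundary psi = 0).
#' @param n_grid number of grid nodes, log-clustered towards the surface.
#' @param tol relative tolerance on psi for the Newton iteration and the
#'   outer self-consistency root.
#' @param slip_distance hydrodynamic slipping plane distance from the
#'   surface, metres; default 7 Angstrom (about three water diameters),
#'   where the zeta potential is read off.
#' @param dispersion_enabled include Mahanty--Ninham ionic dispersion
#'   potentials (coefficients come from the species' `dispersion_B`).
#' @param dispersion_cutoff saturation distance for the \eqn{B/x^3}
#'   dispersion potential, metres.
#' @param max_iter Newton iteration cap.
#' @return an object of class `solver_config`.
#' @export
solver_config <- function(geometry = c("planar", "spherical"), radius = NULL,
                          domain_length = 15, n_grid = 2000, tol = 1e-10,
                          slip_distance = 7e-10, dispersion_enabled = FALSE,
                          dispersion_cutoff = 2e-10, max_iter = 100L) {
  geometry <- match.arg(geometry)
  if (geometry == "spherical" &&
      (is.null(radius) || !is.numeric(radius) || radius <= 0)) {
    stop("spherical geometry requires a positive radius (m)", call. = FALSE)
  }
  if (n_grid < 50) stop("n_grid must be >= 50", call. = FALSE)
  if (domain_length < 5) stop("domain_length must be >= 5 Debye lengths",
                              call. = FALSE)
  if (dispersion_cutoff <= 0) stop("dispersion_cutoff must be positive",
                                   call. = FALSE)
  structure(list(geometry = geometry, radius = radius,
                 domain_length = domain_length, n_grid = as.integer(n_grid),
                 tol = tol, slip_distance = slip_distance,
                 dispersion_enabled = isTRUE(dispersion_enabled),
                 dispersion_cutoff = dispersion_cutoff,
                 max_iter = as.integer(max_iter)),
            class = "solver_config")
}

#' Mahanty--Ninham ionic dispersion potential
#'
#' \eqn{U(x) = B/x^3}, saturated to \eqn{B/x_c^3} below the cutoff
#' \eqn{x_c} to avoid the contact divergence. Identically zero when
#' `B = 0` (the classical, purely electrostatic model).
#'
#' @param B dispersion coefficient, J m^3 (sign sets attraction/repulsion).
#' @param x distance from the surface, metres (vectorized, `x >= 0`).
#' @param cutoff saturation distance, metres, strictly positive.
#' @return potential energy in joules, same length as `x`.
#' @export
dispersion_potential <- function(B, x, cutoff = 2e-10) {
  if (cutoff <= 0) stop("dispersion cutoff must be positive", call. = FALSE)
  if (any(x < 0)) stop("x must be non-negative", call. = FALSE)
  if (B == 0) return(rep(0, length(x)))
  B / pmax(x, cutoff)^3
}

# log-clustered grid on [0, L]: geometric stretching, first spacing
# ~ L*beta/(n*(e^beta - 1)) so the slip plane and dispersion cutoff are
# well resolved
.pb_grid <- function(L, n, beta = 6) {
  t <- seq(0, 1, length.out = n)
  L * (exp(beta * t) - 1) / (exp(beta) - 1)
}

# shared problem setup: grid, charged-species arrays, dispersion matrix
.pb_setup <- function(comp, config) {
  sp <- comp$species[comp$species$valence != 0L, , drop = FALSE]
  if (nrow(sp) == 0L) stop("composition has no ionic species", call. = FALSE)
  net <- sum(sp$valence * sp$concentration)
  if (abs(net) > 1e-12) {
    stop("composition is not electroneutral", call. = FALSE)
  }
  lD <- debye_length(comp)
  x <- .pb_grid(config$domain_length * lD, config$n_grid)
  U <- matrix(0, nrow = length(x), ncol = nrow(sp))
  if (config$dispersion_enabled) {
    for (k in seq_len(nrow(sp))) {
      U[, k] <- dispersion_potential(sp$dispersion_B[k], x,
                                     config$dispersion_cutoff)
    }
  }
  list(x = x, z = as.numeric(sp$valence),
       n_m3 = sp$concentration * 1e3 * .const$N_A, U = U,
       eps = comp$rel_permittivity * .const$eps0,
       kT = .const$kB * comp$temperature, lD = lD,
       radius = if (config$geometry == "spherical") config$radius else -1)
}

# Dirichlet solve at given psi0; returns psi and the surface field.
# `warm` is an environment caching the last converged solution: outer
# root iterations probe nearby psi0 values, and rescaling the previous
# profile cuts the Newton iteration count substantially.
.pb_dirichlet <- function(setup, psi0, config, init = NULL, warm = NULL) {
  if (is.null(init) && !is.null(warm) && !is.null(warm$psi0) &&
      warm$psi0 * psi0 > 0 && abs(psi0 / warm$psi0 - 1) < 0.5) {
    init <- warm$psi * (psi0 / warm$psi0)
  }
  if (is.null(init)) init <- psi0 * exp(-setup$x / setup$lD)
  res <- .pb_dirichlet_cpp(setup$x, psi0, setup$z, setup$n_m3, setup$U,
                           setup$eps, setup$kT, setup$radius, init,
                           config$tol, config$max_iter)
  if (!res$converged) {
    stop(sprintf(paste0("PB solver did not converge at psi0 = %.4g V ",
                        "(%d iterations, residual %.3g)"),
                 psi0, res$iterations, res$residual_norm), call. = FALSE)
  }
  if (!is.null(warm)) {
    warm$psi0 <- psi0
    warm$psi <- res$psi
  }
  res
}

# with all dispersion coefficients zero the PB source vanishes at psi = 0,
# so psi0 = 0 implies psi identically 0; not so with dispersion active
.trivial_at_zero <- function(setup) all(setup$U == 0)

# sigma implied by the field at the surface: sigma = -eps * dpsi/dx(0)
.sigma_field <- function(setup, psi0, config, warm = NULL) {
  if (psi0 == 0 && .trivial_at_zero(setup)) return(0)
  res <- .pb_dirichlet(setup, psi0, config, warm = warm)
  -setup$eps * res$dpsi0
}

.make_profile <- function(setup, psi0, sigma, config, warm = NULL) {
  res <- if (psi0 == 0 && .trivial_at_zero(setup)) {
    list(psi = rep(0, length(setup$x)), dpsi0 = 0, iterations = 0L,
         converged = TRUE)
  } else {
    .pb_dirichlet(setup, psi0, config, warm = warm)
  }
  structure(list(x = setup$x, psi = res$psi, psi0 = psi0, sigma = sigma,
                 iterations = res$iterations,
                 debye_length = setup$lD),
            class = "potential_profile")
}

#' @export
print.potential_profile <- function(x, ...) {
  cat(sprintf(paste0("Potential profile: psi0 = %.3f mV, sigma = %.4g ",
                     "C/m^2, %d nodes over %.3g nm\n"),
              1e3 * x$psi0, x$sigma, length(x$x), 1e9 * max(x$x)))
  invisible(x)
}

# Grahame-style surface-potential estimate for an equivalent symmetric
# electrolyte at the same ionic strength: psi0 ~ (2kT/e) asinh(sigma /
# sqrt(8 I N_A 1e3 eps kT)). Only used to scale root brackets.
.psi0_estimate <- function(sigma, setup) {
  I_m3 <- 0.5 * sum(setup$n_m3 * setup$z^2)
  2 * setup$kT / .const$e *
    asinh(sigma / sqrt(8 * I_m3 * setup$eps * setup$kT))
}

# bracket a monotone scalar root: keep the near-zero end fixed, double
# the far end away from zero until the sign changes
.expand_bracket <- function(f, lo, hi, max_expand = 40, f_lo = NULL) {
  flo <- if (is.null(f_lo)) f(lo) else f_lo
  for (n in seq_len(max_expand)) {
    fhi <- f(hi)
    if (flo * fhi <= 0) return(sort(c(lo, hi)))
    hi <- 2 * hi
  }
  stop("failed to bracket the surface potential", call. = FALSE)
}

#' Solve the Poisson--Boltzmann problem at fixed surface charge
#'
#' Solves the 1D (modified) PB boundary-value problem with a prescribed
#' Neumann surface charge density, bypassing charge regulation. Mainly a
#' testing/oracle mode: in a 1:1 electrolyte without dispersion the
#' surface potential must satisfy the Grahame equation.
#'
#' @param sigma surface charge density, C/m^2.
#' @param comp an `electrolyte_composition`.
#' @param config a [solver_config()].
#' @return a `potential_profile` with fields `x` (m), `psi` (V), `psi0`,
#'   `sigma`.
#' @export
pb_solve_fixed_charge <- function(sigma, comp, config = solver_config()) {
  setup <- .pb_setup(comp, config)
  if (sigma == 0) return(.make_profile(setup, 0, 0, config))
  # linear (Debye-Huckel capacitor) first guess for psi0, then Brent on
  # the monotone map psi0 -> sigma_field(psi0)
  guess <- .psi0_estimate(sigma, setup)
  warm <- new.env(parent = emptyenv())
  g <- function(p) .sigma_field(setup, p, config, warm) - sigma
  br <- .expand_bracket(g, 0, guess)
  kT_e <- setup$kT / .const$e
  root <- stats::uniroot(g, br, tol = max(config$tol * kT_e, 1e-9))
  .make_profile(setup, root$root, sigma, config, warm = warm)
}

#' Solve the charge-regulated Poisson--Boltzmann problem
#'
#' Couples the charge-regulation boundary condition to the PB field: the
#' returned surface potential satisfies
#' \eqn{\sigma_{chem}(\psi_0) = -\varepsilon\varepsilon_0 \psi'(0)},
#' found by strictly-bracketed root finding (sigma_chem is strictly
#' decreasing and the field charge strictly increasing in psi0, so the
#' root is unique).
#'
#' @param model a `surface_model` (charge-regulated site classes).
#' @param comp an `electrolyte_composition`.
#' @param config a [solver_config()].
#' @return a `potential_profile`.
#' @examples
#' comp <- tris_composition(0.010, pH = 7.5)
#' surf <- surface_model(
#'   surface_site("acid_silanol", pK = 7.6, density = 0.2),
#'   surface_site("base_silanol", pK = 2.2, density = 0.2),
#'   label = "silica")
#' prof <- pb_solve(surf, comp, solver_config(n_grid = 400))
#' @export
pb_solve <- function(model, comp, config = solver_config()) {
  stopifnot(inherits(model, "surface_model"))
  setup <- .pb_setup(comp, config)
  kT_e <- setup$kT / .const$e
  sig0 <- surface_charge_density(model, 0, comp)
  trivial <- .trivial_at_zero(setup)
  if (sig0 == 0 && trivial) return(.make_profile(setup, 0, 0, config))
  warm <- new.env(parent = emptyenv())
  h <- function(p) {
    surface_charge_density(model, p, comp) -
      .sigma_field(setup, p, config, warm)
  }
  # h is strictly decreasing (sigma_chem falls, the field charge rises
  # with psi0); bracket from near zero outward on the side h(0) points to
  h0 <- h(0)
  if (h0 == 0) return(.make_profile(setup, 0, sig0, config))
  s <- if (h0 > 0) 1 else -1
  guess <- s * max(abs(.psi0_estimate(sig0, setup)), 1e-4)
  br <- .expand_bracket(h, 0, guess, f_lo = h0)
  root <- stats::uniroot(h, br, tol = max(config$tol * kT_e, 1e-9))
  psi0 <- root$root
  .make_profile(setup, psi0, surface_charge_density(model, psi0, comp),
                config, warm = warm)
}
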