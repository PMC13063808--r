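#' Construct a zeta--pH titration curve
#'
#' @param pH numeric vector in \[0, 14\], strictly increasing.
#' @param zeta zeta potential, mV, finite, same length.
#' @param zeta_sd optional per-point uncertainty, mV.
#' @return an object of class `titration_curve` (a data frame).
#' @export
titration_curve <- function(pH, zeta, zeta_sd = NULL) {
  stopifnot(length(pH) == length(zeta))
  if (any(pH < 0 | pH > 14)) stop("pH values must lie in [0, 14]",
                                  call. = FALSE)
  if (is.unsorted(pH, strictly = TRUE)) {
    stop("pH must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(zeta))) stop("zeta must be finite", call. = FALSE)
  out <- data.frame(pH = pH, zeta = zeta)
  if (!is.null(zeta_sd)) {
    stopifnot(length(zeta_sd) == length(pH), all(zeta_sd >= 0))
    out$zeta_sd <- zeta_sd
  }
  class(out) <- c("titration_curve", class(out))
  out
}

#' Buffer specification for titration forward models
#'
#' Bundles everything needed to build an [tris_composition()] at each pH.
#'
#' @param total total buffer concentration, mol/L (default 10 mM Tris).
#' @param pK buffer pK (TrisH+ 8.07 at 25 C).
#' @param background_salt additional 1:1 salt, mol/L.
#' @param temperature K.
#' @param rel_permittivity solvent relative permittivity.
#' @param dispersion_B optional named vector of ion dispersion
#'   coefficients, J m^3 (see [tris_composition()]).
#' @return a `buffer_spec` list.
#' @export
tris_buffer <- function(total = 0.010, pK = 8.07, background_salt = 0,
                        temperature = 298.15, rel_permittivity = 78.36,
                        dispersion_B = NULL) {
  structure(list(total = total, pK = pK, background_salt = background_salt,
                 temperature = temperature,
                 rel_permittivity = rel_permittivity,
                 dispersion_B = dispersion_B),
            class = "buffer_spec")
}

.composition_at <- function(buffer_spec, pH) {
  tris_composition(buffer_spec$total, pH,
                   temperature = buffer_spec$temperature,
                   background_salt = buffer_spec$background_salt,
                   tris_pK = buffer_spec$pK,
                   rel_permittivity = buffer_spec$rel_permittivity,
                   dispersion_B = buffer_spec$dispersion_B)
}

#' Zeta potential from a solved potential profile
#'
#' The zeta potential is identified with the electrostatic potential at
#' the hydrodynamic slipping plane, obtained by linear interpolation of
#' psi(x) at `slip_distance` and converted to mV.
#'
#' @param profile a `potential_profile` from [pb_solve()].
#' @param slip_distance distance of the slipping plane from the surface,
#'   m; must lie within the solved domain. Zero returns the surface
#'   potential itself.
#' @return zeta potential in mV.
#' @export
zeta_from_profile <- function(profile, slip_distance = 7e-10) {
  stopifnot(inherits(profile, "potential_profile"))
  if (slip_distance < min(profile$x) || slip_distance > max(profile$x)) {
    stop("slip distance lies outside the solved domain", call. = FALSE)
  }
  1e3 * stats::approx(profile$x, profile$psi, xout = slip_distance)$y
}

#' Predict a zeta--pH titration curve
#'
#' For each pH, builds the buffer composition, solves the
#' charge-regulated PB problem and reads the zeta potential at the
#' slipping plane.
#'
#' @param model a `surface_model`.
#' @param buffer_spec a [tris_buffer()] specification.
#' @param pH_grid pH values, each in (0, 14).
#' @param config a [solver_config()].
#' @return a `titration_curve`.
#' @export
predict_titration <- function(model, buffer_spec = tris_buffer(),
                              pH_grid = seq(3, 10, by = 0.25),
                              config = solver_config()) {
  stopifnot(all(pH_grid > 0 & pH_grid < 14))
  o <- order(pH_grid)
  zeta <- vapply(pH_grid[o], function(p) {
    prof <- tryCatch(
      pb_solve(model, .composition_at(buffer_spec, p), config),
      error = function(e) stop(sprintf("pH %.3g: %s", p, conditionMessage(e)),
                               call. = FALSE))
    zeta_from_profile(prof, config$slip_distance)
  }, numeric(1))
  titration_curve(pH_grid[o], zeta)
}

#' Isoelectric point of a charge-regulated surface
#'
#' Bisects the predicted zeta potential in pH to |zeta| < 0.01 mV.
#' If the predicted zeta does not change sign over the bracket, returns
#' `NA` with attribute `reason = "no sign change"` rather than an error
#' (a surface can be monotone-charged over the whole range).
#'
#' @param model a `surface_model`.
#' @param buffer_spec a [tris_buffer()].
#' @param config a [solver_config()].
#' @param pH_bracket length-2 numeric search interval.
#' @return the IEP (pH units, reported to 0.01), or `NA` if zeta does not
#'   cross zero in the bracket.
#' @export
isoelectric_point <- function(model, buffer_spec = tris_buffer(),
                              config = solver_config(),
                              pH_bracket = c(3, 10)) {
  f <- function(p) {
    prof <- pb_solve(model, .composition_at(buffer_spec, p), config)
    zeta_from_profile(prof, config$slip_distance)
  }
  zlo <- f(pH_bracket[1]); zhi <- f(pH_bracket[2])
  if (zlo * zhi > 0) {
    return(structure(NA_real_, reason = "no sign change"))
  }
  lo <- pH_bracket[1]; hi <- pH_bracket[2]
  mid <- (lo + hi) / 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    zm <- f(mid)
    if (abs(zm) < 0.01) break
    if (zm * zlo > 0) { lo <- mid; zlo <- zm } else hi <- mid
  }
  round(mid, 2)
}

# flatten free parameters of a surface model to a named vector and back.
# names: pK_<kind> / N_<kind> with kind in acid, base, amine
.par_names <- c(pK_acid = "acid_silanol", N_acid = "acid_silanol",
                pK_base = "base_silanol", N_base = "base_silanol",
                pK_amine = "amine",       N_amine = "amine")

.apply_params <- function(template, par) {
  sites <- template$sites
  for (nm in names(par)) {
    kind <- .par_names[[nm]]
    if (is.null(kind)) stop(sprintf("unknown parameter '%s'", nm),
                            call. = FALSE)
    if (is.null(sites[[kind]])) {
      stop(sprintf("template has no %s site for parameter '%s'", kind, nm),
           call. = FALSE)
    }
    field <- if (startsWith(nm, "pK")) "pK" else "density"
    sites[[kind]][[field]] <- unname(par[[nm]])
  }
  surface_model(sites, label = template$label)
}

.extract_params <- function(model, free_parameters) {
  vapply(free_parameters, function(nm) {
    kind <- .par_names[[nm]]
    field <- if (startsWith(nm, "pK")) "pK" else "density"
    model$sites[[kind]][[field]]
  }, numeric(1))
}

#' Fit charge-regulation parameters to a measured titration
#'
#' Minimizes the sum of squared residuals between predicted and observed
#' zeta potentials (mV) by bounded Levenberg--Marquardt least squares
#' ([minpack.lm::nls.lm]) from multiple seeded Latin-hypercube starting
#' points. Deterministic given `seed`.
#'
#' Parameter names combine the quantity and the site kind:
#' `pK_acid`, `N_acid`, `pK_base`, `N_base`, `pK_amine`, `N_amine`
#' (densities in sites/nm^2).
#'
#' @param data a [titration_curve()] of observations.
#' @param model_template a `surface_model` supplying site structure and
#'   values of the fixed parameters.
#' @param free_parameters character vector of parameter names to fit.
#' @param bounds named list of length-2 numeric ranges per free parameter;
#'   defaults to pK in \[1, 13\] and densities in \[0, 10\] /nm^2.
#' @param buffer_spec a [tris_buffer()].
#' @param config a [solver_config()].
#' @param n_starts number of Latin-hypercube multi-starts.
#' @param seed integer seed for the start draws.
#' @param weighted if `TRUE` and the data carry `zeta_sd`, weight the
#'   residuals by 1/sd.
#' @return a `fit_result` list: `parameters`, `uncertainty` (Gauss--Newton
#'   approximation from the Jacobian at the optimum), `residual_norm`
#'   (mV^2), `converged`, `n_evaluations`, `seed`, per-start diagnostics.
#' @export
fit_charge_regulation <- function(data, model_template, free_parameters,
                                  bounds = NULL,
                                  buffer_spec = tris_buffer(),
                                  config = solver_config(),
                                  n_starts = 5, seed = 1,
                                  weighted = FALSE) {
  stopifnot(inherits(data, "titration_curve"),
            inherits(model_template, "surface_model"),
            length(free_parameters) >= 1)
  if (nrow(data) < length(free_parameters)) {
    stop("need at least as many data points as free parameters",
         call. = FALSE)
  }
  default_bound <- function(nm) {
    if (startsWith(nm, "pK")) c(1, 13) else c(0, 10)
  }
  lower <- vapply(free_parameters, function(nm) {
    b <- if (!is.null(bounds[[nm]])) bounds[[nm]] else default_bound(nm)
    b[1]
  }, numeric(1))
  upper <- vapply(free_parameters, function(nm) {
    b <- if (!is.null(bounds[[nm]])) bounds[[nm]] else default_bound(nm)
    b[2]
  }, numeric(1))
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("bounds must be finite", call. = FALSE)
  }

  w <- if (weighted && !is.null(data$zeta_sd)) 1 / data$zeta_sd else
    rep(1, nrow(data))
  n_eval <- 0L
  cache <- new.env(parent = emptyenv())
  resid_fn <- function(par) {
    names(par) <- free_parameters
    key <- paste(format(par, digits = 17), collapse = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    n_eval <<- n_eval + 1L
    m <- .apply_params(model_template, par)
    pred <- predict_titration(m, buffer_spec, data$pH, config)
    r <- w * (pred$zeta - data$zeta)
    cache[[key]] <- r
    r
  }

  # seeded Latin-hypercube starts within bounds (global RNG state restored)
  p <- length(free_parameters)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  lh <- lhs::randomLHS(max(n_starts, 1), p)
  if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
  start_mat <- sweep(sweep(lh, 2, upper - lower, `*`), 2, lower, `+`)
  colnames(start_mat) <- free_parameters

  fits <- vector("list", nrow(start_mat))
  for (i in seq_len(nrow(start_mat))) {
    fits[[i]] <- tryCatch(
      minpack.lm::nls.lm(par = start_mat[i, ], lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
  }
  ok <- vapply(fits, inherits, logical(1), "nls.lm")
  if (!any(ok)) {
    msgs <- vapply(fits, conditionMessage, character(1))
    stop(paste0("all fit starts failed:\n",
                paste(sprintf("  start %d: %s", seq_along(msgs), msgs),
                      collapse = "\n")), call. = FALSE)
  }
  dev <- vapply(fits, function(f) {
    if (inherits(f, "nls.lm")) f$deviance else Inf
  }, numeric(1))
  pnorm2 <- vapply(fits, function(f) {
    if (inherits(f, "nls.lm")) sum(f$par^2) else Inf
  }, numeric(1))
  # best residual wins; ties broken by smaller parameter norm
  best_i <- order(dev, pnorm2)[1]
  best <- fits[[best_i]]
  par <- stats::setNames(as.numeric(best$par), free_parameters)

  # Gauss-Newton covariance from the Jacobian at the optimum (approximate)
  unc <- rep(NA_real_, p)
  names(unc) <- free_parameters
  JtJ <- best$hessian
  dof <- nrow(data) - p
  if (dof > 0 && !is.null(JtJ)) {
    cv <- tryCatch(solve(JtJ) * best$deviance / dof,
                   error = function(e) NULL)
    if (!is.null(cv)) unc <- sqrt(pmax(diag(cv), 0))
  }

  structure(list(
    parameters = par,
    uncertainty = unc,
    residual_norm = best$deviance,
    converged = best$info %in% 1:4,
    n_evaluations = n_eval,
    seed = seed,
    model = .apply_params(model_template, par),
    starts = start_mat,
    start_deviances = dev
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Charge-regulation fit\n")
  tab <- data.frame(estimate = x$parameters, se = x$uncertainty)
  print(round(tab, 4))
  cat(sprintf("residual norm: %.4g mV^2, converged: %s, %d evaluations\n",
              x$residual_norm, x$converged, x$n_evaluations))
  invisible(x)
}
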