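#' Scenario for a synthetic zeta--pH titration
#'
#' @param true_model generating `surface_model`.
#' @param buffer_spec a [tris_buffer()].
#' @param pH_points pH sampling points in (0, 14).
#' @param noise_sd iid Gaussian noise on zeta, mV (Table-1-scale zeta
#'   uncertainties are 1--3 mV).
#' @param seed integer seed.
#' @param config a [solver_config()] for the forward model.
#' @return a `titration_scenario`.
#' @export
titration_scenario <- function(true_model, buffer_spec = tris_buffer(),
                               pH_points = seq(3, 10, length.out = 30),
                               noise_sd = 2, seed = 1,
                               config = solver_config()) {
  stopifnot(inherits(true_model, "surface_model"), noise_sd >= 0,
            all(pH_points > 0 & pH_points < 14))
  structure(list(true_model = true_model, buffer_spec = buffer_spec,
                 pH_points = sort(pH_points), noise_sd = noise_sd,
                 seed = as.integer(seed), config = config),
            class = "titration_scenario")
}

#' Generate a synthetic zeta--pH titration
#'
#' Forward-models the scenario's true surface and adds iid Gaussian noise;
#' bitwise reproducible given the scenario seed (global RNG state is left
#' untouched).
#'
#' @param scenario a [titration_scenario()].
#' @return list with `curve` (a `titration_curve` carrying `zeta_sd =
#'   noise_sd`) and `truth` (generating parameters and the noiseless
#'   curve).
#' @export
generate_titration <- function(scenario) {
  stopifnot(inherits(scenario, "titration_scenario"))
  clean <- predict_titration(scenario$true_model, scenario$buffer_spec,
                             scenario$pH_points, scenario$config)
  noise <- .with_seed(scenario$seed,
                      stats::rnorm(nrow(clean), 0, scenario$noise_sd))
  curve <- titration_curve(clean$pH, clean$zeta + noise,
                           zeta_sd = rep(max(scenario$noise_sd, 1e-12),
                                         nrow(clean)))
  list(curve = curve,
       truth = list(model = scenario$true_model,
                    noiseless = clean, noise_sd = scenario$noise_sd,
                    seed = scenario$seed))
}

#' Scenario for a synthetic stepped QCM-D trace
#'
#' Emulates a flow-adsorption protocol: a sequence of non-overlapping
#' plateaus in frequency shift (one target level per overtone), smoothed
#' first-order (exponential) transitions, optional linear drift and iid
#' Gaussian noise.
#'
#' @param plateau_schedule list of plateaus, each a list with `start`,
#'   `end` (s) and `delta_f` (named vector of plateau levels in Hz per
#'   overtone, e.g. `c(f1 = -10, f3 = -31)`).
#' @param duration total trace length, s.
#' @param dt sampling interval, s.
#' @param noise_sd Gaussian noise SD, Hz.
#' @param drift linear baseline drift, Hz per hour.
#' @param tau transition time constant, s (0 for instantaneous steps).
#' @param seed integer seed.
#' @return a `qcm_scenario`.
#' @export
qcm_scenario <- function(plateau_schedule, duration = NULL, dt = 1,
                         noise_sd = 0, drift = 0, tau = 0, seed = 1) {
  stopifnot(length(plateau_schedule) >= 1)
  starts <- vapply(plateau_schedule, `[[`, numeric(1), "start")
  ends <- vapply(plateau_schedule, `[[`, numeric(1), "end")
  if (any(starts >= ends)) stop("plateau start must precede end",
                                call. = FALSE)
  o <- order(starts)
  if (any(ends[o][-length(o)] > starts[o][-1])) {
    stop("plateaus overlap", call. = FALSE)
  }
  if (is.null(duration)) duration <- max(ends)
  structure(list(plateau_schedule = plateau_schedule[o],
                 duration = duration, dt = dt, noise_sd = noise_sd,
                 drift = drift, tau = tau, seed = as.integer(seed)),
            class = "qcm_scenario")
}

#' Generate a synthetic QCM-D trace
#'
#' @param scenario a [qcm_scenario()].
#' @return a [qcm_trace()].
#' @export
generate_qcm_trace <- function(scenario) {
  stopifnot(inherits(scenario, "qcm_scenario"))
  time <- seq(0, scenario$duration, by = scenario$dt)
  overtone_names <- names(scenario$plateau_schedule[[1]]$delta_f)
  f <- matrix(0, nrow = length(time), ncol = length(overtone_names),
              dimnames = list(NULL, overtone_names))
  level <- stats::setNames(rep(0, length(overtone_names)), overtone_names)
  # piecewise-constant target level; first-order relaxation if tau > 0
  target <- matrix(0, nrow = length(time), ncol = length(overtone_names),
                   dimnames = list(NULL, overtone_names))
  for (p in scenario$plateau_schedule) {
    sel <- time >= p$start & time <= p$end
    for (nm in overtone_names) target[sel, nm] <- p$delta_f[[nm]]
    after <- time > p$end
    for (nm in overtone_names) target[after, nm] <- p$delta_f[[nm]]
  }
  if (scenario$tau > 0) {
    a <- exp(-scenario$dt / scenario$tau)
    for (nm in overtone_names) {
      y <- numeric(length(time))
      y[1] <- target[1, nm]
      for (i in 2:length(time)) {
        y[i] <- a * y[i - 1] + (1 - a) * target[i, nm]
      }
      f[, nm] <- y
    }
  } else {
    f[] <- target
  }
  f <- f + scenario$drift * time / 3600
  if (scenario$noise_sd > 0) {
    noise <- .with_seed(scenario$seed,
                        matrix(stats::rnorm(length(f), 0, scenario$noise_sd),
                               nrow = nrow(f)))
    f <- f + noise
  }
  qcm_trace(time, as.data.frame(f))
}

# evaluate expr under a temporary seed, restoring global RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Calibrated bare-silica surface model
#'
#' An amphoteric silanol surface (acid + basic silanol site classes)
#' whose forward model in 10 mM Tris reproduces the headline observables
#' of a bare mesoporous silica nanoparticle: IEP near 4.9 and zeta near
#' -14 mV at pH 7.5. The parameter values are a synthetic calibration of
#' this package's own forward model against those observables -- they are
#' placeholders, not experimentally fitted site chemistries.
#'
#' @return a `surface_model` labelled `"MSN"`.
#' @export
msn_model <- function() {
  surface_model(
    surface_site("acid_silanol", pK = .msn_cal$pK_acid,
                 density = .msn_cal$N_acid),
    surface_site("base_silanol", pK = .msn_cal$pK_base,
                 density = .msn_cal$N_base),
    label = "MSN")
}

#' Calibrated amino-functionalized silica surface model
#'
#' Reduced silanol densities plus a grafted-amine site class, calibrated
#' so the forward model in 10 mM Tris gives IEP near 7.9 and zeta near
#' +10 mV at pH 7.5 (the observables of an aminopropyl-grafted particle).
#' Synthetic calibration, see [msn_model()].
#'
#' @return a `surface_model` labelled `"MSN-NH2"`.
#' @export
msn_nh2_model <- function() {
  surface_model(
    surface_site("acid_silanol", pK = .msn_nh2_cal$pK_acid,
                 density = .msn_nh2_cal$N_acid),
    surface_site("base_silanol", pK = .msn_nh2_cal$pK_base,
                 density = .msn_nh2_cal$N_base),
    surface_site("amine", pK = .msn_nh2_cal$pK_amine,
                 density = .msn_nh2_cal$N_amine),
    label = "MSN-NH2")
}
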