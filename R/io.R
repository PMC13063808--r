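#' Read a zeta--pH titration CSV
#'
#' Expects the header `pH,zeta_mV` with an optional `zeta_sd_mV` column.
#' Rows are sorted by pH; duplicate pH values are averaged with a
#' warning; pH outside \[0, 14\] or non-numeric rows are rejected with
#' line numbers.
#'
#' @param path CSV file path.
#' @return a [titration_curve()].
#' @export
read_titration_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pH", "zeta_mV")
  if (!all(need %in% names(df))) {
    stop(sprintf("expected header pH,zeta_mV[,zeta_sd_mV]; got: %s",
                 paste(names(df), collapse = ",")), call. = FALSE)
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$pH))) |
                 !is.finite(suppressWarnings(as.numeric(df$zeta_mV))))
  if (length(bad)) {
    stop(sprintf("malformed rows (data lines %s)",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  df$pH <- as.numeric(df$pH)
  df$zeta_mV <- as.numeric(df$zeta_mV)
  out_of_range <- which(df$pH < 0 | df$pH > 14)
  if (length(out_of_range)) {
    stop(sprintf("pH outside [0, 14] (data lines %s)",
                 paste(out_of_range, collapse = ", ")), call. = FALSE)
  }
  df <- df[order(df$pH), , drop = FALSE]
  if (anyDuplicated(df$pH)) {
    warning("duplicate pH values averaged", call. = FALSE)
    sd_col <- if ("zeta_sd_mV" %in% names(df)) "zeta_sd_mV" else NULL
    agg <- stats::aggregate(df[c("zeta_mV", sd_col)], by = list(pH = df$pH),
                            FUN = mean)
    df <- agg[order(agg$pH), , drop = FALSE]
  }
  titration_curve(df$pH, df$zeta_mV,
                  zeta_sd = if ("zeta_sd_mV" %in% names(df))
                    df$zeta_sd_mV else NULL)
}

#' Write a titration curve to CSV
#'
#' Inverse of [read_titration_csv()] (header `pH,zeta_mV[,zeta_sd_mV]`).
#'
#' @param curve a [titration_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(curve, path) {
  stopifnot(inherits(curve, "titration_curve"))
  df <- data.frame(pH = curve$pH, zeta_mV = curve$zeta)
  if (!is.null(curve$zeta_sd)) df$zeta_sd_mV <- curve$zeta_sd
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a QCM-D export CSV
#'
#' Expects the header `time_s,f1_Hz,f3_Hz,...[,d1,d3,...]` (a Q-Sense-like
#' export): one frequency-shift column per odd overtone, optional
#' dissipation columns in units of 1e-6.
#'
#' @param path CSV file path.
#' @return a [qcm_trace()].
#' @export
read_qcm_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time_s" %in% names(df)) {
    stop("expected a time_s column", call. = FALSE)
  }
  fcols <- grep("^f[0-9]+_Hz$", names(df), value = TRUE)
  dcols <- grep("^d[0-9]+$", names(df), value = TRUE)
  if (!length(fcols)) stop("no frequency columns (f<n>_Hz) found",
                           call. = FALSE)
  delta_f <- df[fcols]
  names(delta_f) <- sub("_Hz$", "", fcols)
  delta_D <- if (length(dcols)) df[dcols] else NULL
  qcm_trace(df$time_s, delta_f, delta_D)
}

#' Write a potential profile to CSV
#'
#' Two columns, `x_nm,psi_mV`.
#'
#' @param profile a `potential_profile` from [pb_solve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "potential_profile"))
  utils::write.csv(data.frame(x_nm = 1e9 * profile$x,
                              psi_mV = 1e3 * profile$psi),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration (YAML)
#'
#' Parses the configuration blocks used across the package:
#' `buffer` (`name`, `total_mM`, `pK`, `background_salt_mM`,
#' `temperature_K`, `rel_permittivity`), `surface` (`label`, `sites:`
#' list of `{kind, pK, density_per_nm2}`), `solver` (fields of
#' [solver_config()]) and an optional `fit` block (`free_parameters`,
#' `bounds`, `n_starts`, `seed`). Unknown top-level keys are rejected.
#'
#' @param path YAML file path.
#' @return list with `buffer_spec`, `surface`, `config`, `fit` plus a
#'   `config_hash` of the canonicalized content.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  known <- c("buffer", "surface", "solver", "fit")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  b <- cfg$buffer
  buffer_spec <- tris_buffer(
    total = if (!is.null(b$total_mM)) b$total_mM / 1e3 else 0.010,
    pK = if (!is.null(b$pK)) b$pK else 8.07,
    background_salt = if (!is.null(b$background_salt_mM))
      b$background_salt_mM / 1e3 else 0,
    temperature = if (!is.null(b$temperature_K)) b$temperature_K else 298.15,
    rel_permittivity = if (!is.null(b$rel_permittivity))
      b$rel_permittivity else 78.36)
  surface <- NULL
  if (!is.null(cfg$surface)) {
    sites <- lapply(cfg$surface$sites, function(s) {
      surface_site(s$kind, pK = s$pK, density = s$density_per_nm2)
    })
    surface <- surface_model(sites,
                             label = if (!is.null(cfg$surface$label))
                               cfg$surface$label else "surface")
  }
  sargs <- cfg$solver
  config <- if (is.null(sargs)) solver_config() else
    do.call(solver_config, sargs)
  list(buffer_spec = buffer_spec, surface = surface, config = config,
       fit = cfg$fit,
       config_hash = .config_hash(cfg))
}

# order-independent content hash of a config list (no external digest
# dependency: serialize canonically and hash with a small FNV-1a)
.config_hash <- function(x) {
  canon <- function(v) {
    if (is.list(v)) {
      if (!is.null(names(v))) v <- v[order(names(v))]
      lapply(v, canon)
    } else v
  }
  s <- paste(utils::capture.output(utils::str(canon(x), digits.d = 15)),
             collapse = "\n")
  bytes <- utf8ToInt(s)
  # multiplicative accumulator mod 2^32; products stay exact in doubles
  h <- 2166136261
  for (b in bytes) h <- (h * 69069 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Serialize a fit result to JSON
#'
#' Writes parameters, uncertainties, residual norm, convergence flag,
#' seed and an optional config hash -- enough to reproduce the fit.
#'
#' @param fit a `fit_result` from [fit_charge_regulation()].
#' @param path output JSON path.
#' @param config_hash optional hash string from [read_run_config()].
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, config_hash = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  obj <- list(parameters = as.list(fit$parameters),
              uncertainty = as.list(fit$uncertainty),
              residual_norm = fit$residual_norm,
              converged = fit$converged,
              n_evaluations = fit$n_evaluations,
              seed = fit$seed,
              config_hash = config_hash)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
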