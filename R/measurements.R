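#' Construct a QCM-D trace
#'
#' @param time time in seconds, ascending.
#' @param delta_f named list or data frame of frequency-shift series (Hz),
#'   one per overtone; names like `"f1"`, `"f3"`, `"f5"` (odd overtones).
#' @param delta_D optional dissipation series (x 1e-6), named `"d1"`,
#'   `"d3"`, ...
#' @return an object of class `qcm_trace`.
#' @export
qcm_trace <- function(time, delta_f, delta_D = NULL) {
  stopifnot(is.numeric(time), !is.unsorted(time))
  delta_f <- as.data.frame(delta_f)
  ns <- .overtone_numbers(names(delta_f), "f")
  stopifnot(all(vapply(delta_f, length, integer(1)) == length(time)))
  if (!is.null(delta_D)) {
    delta_D <- as.data.frame(delta_D)
    stopifnot(all(vapply(delta_D, length, integer(1)) == length(time)))
  }
  structure(list(time = time, delta_f = delta_f, delta_D = delta_D,
                 overtones = ns), class = "qcm_trace")
}

.overtone_numbers <- function(nms, prefix) {
  ns <- suppressWarnings(as.integer(sub(paste0("^", prefix), "", nms)))
  if (any(is.na(ns)) || any(ns <= 0) || any(ns %% 2 == 0)) {
    stop("overtone series must be named <prefix><n> with n odd positive, ",
         "e.g. f1, f3, f5", call. = FALSE)
  }
  ns
}

#' A labelled time window on a QCM trace
#'
#' @param label window label, e.g. `"MSN on gold"`.
#' @param start,end window bounds in seconds, `start < end`.
#' @return a `step_window`.
#' @export
step_window <- function(label, start, end) {
  if (!(start < end)) stop("window start must precede end", call. = FALSE)
  structure(list(label = label, start = start, end = end),
            class = "step_window")
}

#' Sauerbrey mass from a frequency shift
#'
#' \eqn{\Delta m = -C \, \Delta f / n} for a rigid film, with the mass
#' sensitivity constant C of the quartz sensor (17.7 ng cm^-2 Hz^-1 for a
#' 5 MHz AT-cut crystal).
#'
#' @param delta_f frequency shift, Hz (vectorized).
#' @param overtone odd positive overtone number n.
#' @param C mass sensitivity constant, ng cm^-2 Hz^-1.
#' @return areal mass in ng/cm^2.
#' @export
sauerbrey_mass <- function(delta_f, overtone = 1, C = 17.7) {
  if (length(overtone) != 1 || overtone <= 0 || overtone %% 2 == 0) {
    stop("overtone must be an odd positive integer", call. = FALSE)
  }
  -C * delta_f / overtone
}

# 10%-trimmed mean over a window: robust to spikes at valve switches
.window_stat <- function(time, y, w) {
  sel <- time >= w$start & time <= w$end
  if (!any(sel)) stop(sprintf("window '%s' contains no samples", w$label),
                      call. = FALSE)
  list(mean = mean(y[sel], trim = 0.10), sd = stats::sd(y[sel]),
       n = sum(sel))
}

#' Per-step adsorbed masses from a QCM-D trace
#'
#' For each window the (10%-trimmed) mean frequency shift is referenced
#' either to a fixed baseline window (`mode = "baseline"`, cumulative
#' masses) or to the previous window (`mode = "incremental"`, per-step
#' masses), then converted via [sauerbrey_mass()]. The per-step SD comes
#' from the within-window scatter. A rigidity warning is emitted when the
#' dissipation-to-frequency ratio exceeds 0.4e-6 per Hz, where the
#' Sauerbrey rigid-film assumption degrades (soft hydrated layers).
#'
#' @param trace a [qcm_trace()].
#' @param windows list of [step_window()]s, time-ordered.
#' @param baseline_window a [step_window()] for the reference level.
#' @param overtone overtone to analyse (default 3, falling back to 1 if
#'   absent from the trace).
#' @param C Sauerbrey constant, ng cm^-2 Hz^-1.
#' @param mode `"baseline"` (cumulative) or `"incremental"`.
#' @return data frame: `label`, `delta_f_Hz`, `delta_m_ng_cm2`, `sd`,
#'   `start_s`, `end_s`.
#' @export
step_masses <- function(trace, windows, baseline_window, overtone = 3,
                        C = 17.7, mode = c("baseline", "incremental")) {
  stopifnot(inherits(trace, "qcm_trace"))
  mode <- match.arg(mode)
  if (inherits(windows, "step_window")) windows <- list(windows)
  col <- paste0("f", overtone)
  if (is.null(trace$delta_f[[col]])) {
    overtone <- 1
    col <- "f1"
    if (is.null(trace$delta_f[[col]])) {
      stop("requested overtone not present in trace", call. = FALSE)
    }
  }
  y <- trace$delta_f[[col]]
  base <- .window_stat(trace$time, y, baseline_window)
  ref <- base$mean
  out <- lapply(windows, function(w) {
    st <- .window_stat(trace$time, y, w)
    df <- st$mean - ref
    if (mode == "incremental") ref <<- st$mean
    data.frame(label = w$label, delta_f_Hz = df,
               delta_m_ng_cm2 = sauerbrey_mass(df, overtone, C),
               sd = sauerbrey_mass(st$sd, overtone, C) * -1,
               start_s = w$start, end_s = w$end,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  dcol <- paste0("d", overtone)
  if (!is.null(trace$delta_D) && !is.null(trace$delta_D[[dcol]])) {
    d <- trace$delta_D[[dcol]]
    for (i in seq_along(windows)) {
      w <- windows[[i]]
      dmean <- .window_stat(trace$time, d, w)$mean
      df <- res$delta_f_Hz[i]
      if (df < 0 && dmean * 1e-6 / (-df / overtone) > 0.4e-6) {
        warning(sprintf(
          "window '%s': dissipation/frequency ratio exceeds the rigidity
  heuristic (0.4e-6 per Hz); Sauerbrey mass may underestimate a soft film",
          w$label), call. = FALSE)
      }
    }
  }
  res
}

#' Grafted amount from a thermogravimetric mass-loss step
#'
#' Converts a fractional mass loss attributed to the decomposition of a
#' grafted organic fragment into mmol of fragment per gram of material.
#' Two normalization conventions are offered because reported values
#' rarely state which reference mass is used: per gram of initial sample
#' (`loss / M`) or per gram of residue (`loss / (1 - loss) / M`).
#'
#' @param mass_loss_fraction fractional mass loss in \[0, 1).
#' @param fragment_molar_mass molar mass of the decomposed fragment,
#'   g/mol (e.g. 110.2 for an aminopropylsiloxane fragment C3H8NSiO1.5).
#' @param normalization `"initial_mass"` or `"residual_mass"`.
#' @return grafted amount in mmol/g.
#' @export
tga_grafted_amount <- function(mass_loss_fraction, fragment_molar_mass,
                               normalization = c("initial_mass",
                                                 "residual_mass")) {
  normalization <- match.arg(normalization)
  if (mass_loss_fraction < 0 || mass_loss_fraction >= 1) {
    stop("mass loss fraction must lie in [0, 1)", call. = FALSE)
  }
  if (fragment_molar_mass <= 0) stop("molar mass must be positive",
                                     call. = FALSE)
  frac <- if (normalization == "initial_mass") mass_loss_fraction else
    mass_loss_fraction / (1 - mass_loss_fraction)
  1e3 * frac / fragment_molar_mass
}
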