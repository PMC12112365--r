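#' Right-hand side of the circulation ODE
#'
#' Evaluates the volume derivatives of all compliant compartments at state
#' `state` and time `t`.  Flows are pressure differences over resistances;
#' the four heart valves are ideal diodes (flow only down-gradient).  The
#' derivatives sum to zero: the loop is closed and volume is conserved by
#' construction.
#'
#' @param state named volume vector as produced by [initial_state()].
#' @param t time (s).
#' @param config a [sim_config()].
#' @return named vector `d(state)/dt` (mL/s).
#' @export
cv_derivatives <- function(state, t, config) {
  if (length(state) != 14L)
    abort_invalid_input(
      "state must have 13 compartment volumes plus the aortic flow state")
  if (any(!is.finite(state)) || any(state[1:13] < 0))
    abort_numerical("invalid state (NaN or negative volume) at t = %.4f", t)
  d <- cv_derivs_cpp(build_core_pars(config), as.numeric(state), t)
  stats::setNames(d, state_names())
}

#' Run a closed-loop simulation
#'
#' Integrates the circulation with a fixed-step classical RK4 scheme
#' (step `config$dt`, default 0.1 ms) and returns uniformly sampled
#' signals.  The returned object is a data frame (class `cv_timeseries`)
#' with time, LV pressure and volume, aortic pressure and flow,
#' per-compartment pressures and the instantaneous total volume; the paced
#' heart rate and the configuration travel along as attributes.
#'
#' @param config a [sim_config()].
#' @param y0 optional initial state; defaults to [initial_state()].
#' @return a `cv_timeseries` data frame sampled every `config$dt_output` s.
#' @export
simulate_cv <- function(config, y0 = NULL) {
  if (!inherits(config, "sim_config"))
    abort_invalid_config("`config` must be a sim_config")
  if (is.null(y0)) y0 <- initial_state(config)
  pars <- build_core_pars(config)
  raw <- tryCatch(
    cv_simulate_cpp(pars, as.numeric(y0), config$duration, config$dt,
                    config$dt_output, config$record_from),
    error = function(e) abort_numerical("%s", conditionMessage(e))
  )
  nm <- state_names()[1:13]
  P <- raw$P; V <- raw$V
  colnames(P) <- paste0("P_", nm)
  colnames(V) <- paste0("V_", nm)
  ts <- data.frame(
    t = raw$t,
    P_LV = P[, "P_LV"], V_LV = V[, "V_LV"],
    P_Ao = P[, "P_Ao"], Q_Ao = raw$Q_av,
    P_LA = P[, "P_LA"], P_RA = P[, "P_RA"],
    P_RV = P[, "P_RV"], V_RV = V[, "V_RV"],
    P_ven = P[, "P_ven"], P_PA = P[, "P_PA"], P_PU = P[, "P_PU"],
    P[, paste0("P_s", 1:5)],
    V_total = rowSums(V)
  )
  drift <- max(abs(ts$V_total - config$total_blood_volume)) /
    config$total_blood_volume
  if (drift > 1e-3)
    abort_numerical("volume conservation violated: relative drift %.2e", drift)
  structure(ts, HR = config$HR, dt_output = config$dt_output,
            config = config, class = c("cv_timeseries", "data.frame"))
}

#' Export a time series as delimited text
#'
#' Writes a comma-separated table with a `"name (unit)"` header line,
#' column 1 the time in seconds.
#'
#' @param ts a `cv_timeseries`.
#' @param path output file.
#' @export
write_timeseries <- function(ts, path) {
  if (!inherits(ts, "cv_timeseries"))
    abort_invalid_input("`ts` must be a cv_timeseries")
  units <- vapply(names(ts), function(nm) {
    if (nm == "t") "s"
    else if (startsWith(nm, "P_")) "mmHg"
    else if (startsWith(nm, "Q_")) "mL/s"
    else "mL"
  }, character(1))
  hdr <- paste(sprintf("%s (%s)", names(ts), units), collapse = ",")
  con <- tryCatch(file(path, "w"), error = function(e)
    abort_io("cannot open '%s' for writing", path))
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(ts), con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Import an external pressure/volume trace
#'
#' Accepts a delimited file with columns time, LV pressure and LV volume
#' (in that order, header optional) and returns a minimal `cv_timeseries`
#' suitable for beat segmentation and loop analysis.  If no aortic channel
#' is present, the LV pressure is reused for systolic/diastolic readings.
#'
#' @param path delimited text file with 3 (t, P, V) or more columns.
#' @param HR paced heart rate annotation (beats/min), required for
#'   clock-based segmentation.
#' @param sep field separator.
#' @return a `cv_timeseries`.
#' @export
read_timeseries <- function(path, HR, sep = ",") {
  if (!file.exists(path)) abort_io("file '%s' not found", path)
  check_number(HR, "HR", lower = 30, upper = 200, abort = abort_invalid_input)
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^[0-9.+-]", trimws(strsplit(first, sep)[[1]][1]))
  x <- utils::read.table(path, sep = sep, header = has_header)
  if (ncol(x) < 3L)
    abort_invalid_input("expected at least 3 columns (t, P, V), got %d",
                        ncol(x))
  ts <- data.frame(t = x[[1]], P_LV = x[[2]], V_LV = x[[3]],
                   P_Ao = if (ncol(x) >= 4L) x[[4]] else x[[2]])
  dt <- diff(ts$t)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * stats::median(dt))
    abort_invalid_input("time column must be uniformly increasing")
  structure(ts, HR = HR, dt_output = stats::median(dt),
            class = c("cv_timeseries", "data.frame"))
}
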