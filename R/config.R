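#' Vena-caval occlusion specification
#'
#' The VCO is modelled as a time-based rise of the resistance of the
#' thoracic veins between the venous pool and the right atrium: the
#' resistance ramps linearly from its baseline starting at `t_start`,
#' reaching `max_resistance_factor` times baseline after `ramp_duration`
#' seconds, and stays there.
#'
#' @param t_start occlusion onset (s); should lie beyond the steady-state
#'   settling window.
#' @param ramp_duration duration of the linear ramp (s).
#' @param max_resistance_factor plateau multiplier on the venous
#'   resistance, > 1.
#' @return an object of class `vco_spec`.
#' @export
vco_spec <- function(t_start = 180, ramp_duration = 10,
                     max_resistance_factor = 20) {
  check_number(t_start, "t_start", lower = 0)
  check_number(ramp_duration, "ramp_duration", lower = 1e-9)
  check_number(max_resistance_factor, "max_resistance_factor", lower = 1 + 1e-12)
  structure(list(t_start = t_start, ramp_duration = ramp_duration,
                 max_resistance_factor = max_resistance_factor),
            class = "vco_spec")
}

#' Effective venous resistance under the occlusion ramp
#'
#' @param t time (s), vectorized.
#' @param spec a [vco_spec()].
#' @param base_R baseline venous resistance (mmHg s/mL).
#' @return effective resistance: `base_R` before `t_start`, rising linearly
#'   to `base_R * max_resistance_factor` and plateauing there.
#' @export
apply_vco <- function(t, spec, base_R) {
  if (!inherits(spec, "vco_spec"))
    abort_invalid_input("`spec` must be a vco_spec")
  check_number(base_R, "base_R", lower = 1e-12)
  u <- pmin(pmax((t - spec$t_start) / spec$ramp_duration, 0), 1)
  base_R * (1 + (spec$max_resistance_factor - 1) * u)
}

#' Simulation configuration
#'
#' Assembles the full configuration of a closed-loop run: paced heart rate,
#' vascular and chamber parameter sets, total blood volume, pulmonary and
#' valve constants, run duration and solver settings.
#'
#' @param HR paced heart rate (beats/min), 30-200.
#' @param vascular a [vascular_params()] object.
#' @param chambers named list of [chamber_params()] (LV, LA, RV, RA).
#' @param total_blood_volume total circulating volume (mL); conserved
#'   exactly by the closed loop.
#' @param duration simulated time (s).
#' @param settle_time time allowed to reach periodic steady state (s)
#'   before any intervention; the default 180 s mirrors the three-minute
#'   stabilization of the occlusion protocol.
#' @param dt integrator step (s).
#' @param dt_output output sampling interval (s).
#' @param record_from discard output samples before this time (s) to keep
#'   long settling runs memory-light.
#' @param vco optional [vco_spec()]; `NULL` for an unperturbed run.
#' @param upstream_frac fraction of each systemic branch resistance placed
#'   proximal to the compartment compliance (large arteries); the remainder
#'   is arteriolar.
#' @param pulmonary,valves named lists of the lumped pulmonary and valve
#'   constants; defaults are calibrated alongside [default_chambers()].
#' @param unstressed named list of vessel unstressed volumes (mL).
#' @param seed integer seed carried in the config for any stochastic
#'   fixtures; the ODE core itself is deterministic.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(HR = 80,
                       vascular = nominal_vascular(),
                       chambers = default_chambers(),
                       total_blood_volume = 4700,
                       duration = 20,
                       settle_time = 180,
                       dt = 1e-4,
                       dt_output = 1e-3,
                       record_from = 0,
                       vco = NULL,
                       upstream_frac = 0.20,
                       pulmonary = list(C_PA = 5, R_pul = 0.07,
                                        C_PU = 9, R_pula = 0.01),
                       valves = list(R_mv = 0.055, R_av = 0.010,
                                     R_tv = 0.055, R_pav = 0.006,
                                     L_av = 9e-4),
                       unstressed = list(Ao = 50, s = 30, ven = 2500,
                                         PA = 40, PU = 110),
                       seed = 1L) {
  check_number(HR, "HR", lower = 30, upper = 200)
  if (!inherits(vascular, "vascular_params"))
    abort_invalid_config("`vascular` must be a vascular_params object")
  if (!all(c("LV", "LA", "RV", "RA") %in% names(chambers)))
    abort_invalid_config("`chambers` must name LV, LA, RV and RA")
  for (ch in chambers)
    if (!inherits(ch, "chamber_params"))
      abort_invalid_config("all chambers must be chamber_params objects")
  check_number(total_blood_volume, "total_blood_volume", lower = 100)
  check_number(duration, "duration", lower = 1e-3)
  check_number(dt, "dt", lower = 1e-7, upper = 1e-2)
  check_number(dt_output, "dt_output", lower = dt)
  check_number(upstream_frac, "upstream_frac", lower = 0.01, upper = 0.99)
  if (!is.null(vco) && !inherits(vco, "vco_spec"))
    abort_invalid_config("`vco` must be NULL or a vco_spec")
  structure(
    list(HR = HR, vascular = vascular, chambers = chambers,
         total_blood_volume = total_blood_volume, duration = duration,
         settle_time = settle_time, dt = dt, dt_output = dt_output,
         record_from = record_from, vco = vco,
         upstream_frac = upstream_frac, pulmonary = pulmonary,
         valves = valves, unstressed = unstressed,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Flat parameter list for the C++ core.
build_core_pars <- function(config) {
  period <- 60 / config$HR
  ch <- rbind(chamber_row(config$chambers$LV, period),
              chamber_row(config$chambers$LA, period),
              chamber_row(config$chambers$RV, period),
              chamber_row(config$chambers$RA, period))
  v <- config$vascular
  u <- config$upstream_frac
  list(period = period, chambers = ch,
       C_A = v$C_A, Vun_Ao = config$unstressed$Ao,
       C_s = v$compartment_C, Vun_s = rep(config$unstressed$s, 5),
       R_up = v$compartment_R * u, R_dn = v$compartment_R * (1 - u),
       C_ven = v$venous_C, Vun_ven = config$unstressed$ven,
       R_ven = v$venous_R,
       C_PA = config$pulmonary$C_PA, Vun_PA = config$unstressed$PA,
       R_pul = config$pulmonary$R_pul,
       C_PU = config$pulmonary$C_PU, Vun_PU = config$unstressed$PU,
       R_pula = config$pulmonary$R_pula,
       R_mv = config$valves$R_mv, R_av = config$valves$R_av,
       R_tv = config$valves$R_tv, R_pav = config$valves$R_pav,
       L_av = if (is.null(config$valves$L_av)) 9e-4 else config$valves$L_av,
       vco = !is.null(config$vco),
       vco_t_start = if (is.null(config$vco)) 0 else config$vco$t_start,
       vco_ramp = if (is.null(config$vco)) 1 else config$vco$ramp_duration,
       vco_maxf = if (is.null(config$vco)) 1 else
         config$vco$max_resistance_factor)
}

state_names <- function() {
  c("LV", "LA", "RV", "RA", "Ao", paste0("s", 1:5), "ven", "PA", "PU",
    "Q_av")
}

#' Initial state vector for a configuration
#'
#' Distributes the total blood volume over the compartments at plausible
#' starting pressures (the closed loop then relaxes to its own periodic
#' steady state); the venous pool receives the remainder so the sum equals
#' `total_blood_volume` exactly.
#'
#' @param config a [sim_config()].
#' @return named numeric vector of compartment volumes (mL).
#' @export
initial_state <- function(config) {
  v <- config$vascular
  vol <- c(
    LV = config$chambers$LV$V0 + 100,
    LA = config$chambers$LA$V0 + 50,
    RV = config$chambers$RV$V0 + 100,
    RA = config$chambers$RA$V0 + 50,
    Ao = config$unstressed$Ao + v$C_A * 90,
    stats::setNames(config$unstressed$s + v$compartment_C * 85,
                    paste0("s", 1:5)),
    ven = 0,
    PA = config$unstressed$PA + config$pulmonary$C_PA * 15,
    PU = config$unstressed$PU + config$pulmonary$C_PU * 10
  )
  rest <- config$total_blood_volume - sum(vol)
  if (rest < config$unstressed$ven)
    abort_invalid_config(
      "total_blood_volume %.0f mL too small to fill the venous pool",
      config$total_blood_volume)
  vol["ven"] <- rest
  c(vol, Q_av = 0)  # aortic valve flow state starts at zero
}

#' Write / read a configuration as JSON
#'
#' Serializes the scalar fields of a [sim_config()]; chamber and vascular
#' sets are stored field-by-field so a round trip restores the full
#' configuration.
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @return `read_config()` returns a [sim_config()].
#' @export
write_config <- function(config, path) {
  x <- list(
    HR = config$HR,
    vascular = unclass(config$vascular),
    chambers = lapply(config$chambers, function(ch)
      c(list(E_max = ch$E_max, E_min = ch$E_min, V0 = ch$V0,
             label = ch$label), ch$activation)),
    total_blood_volume = config$total_blood_volume,
    duration = config$duration, settle_time = config$settle_time,
    dt = config$dt, dt_output = config$dt_output,
    record_from = config$record_from,
    vco = if (is.null(config$vco)) NULL else unclass(config$vco),
    upstream_frac = config$upstream_frac,
    pulmonary = config$pulmonary, valves = config$valves,
    unstressed = config$unstressed, seed = config$seed
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_io("config file '%s' not found", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  vas <- do.call(vascular_params, x$vascular[
    c("C_A", "R_T", "compartment_C", "compartment_R", "venous_C",
      "venous_R", "level_label")])
  chambers <- lapply(x$chambers, function(ch)
    chamber_params(ch$E_max, ch$E_min, ch$V0, label = ch$label,
                   m1 = ch$m1, m2 = ch$m2, tau1_frac = ch$tau1_frac,
                   tau2_frac = ch$tau2_frac, av_delay = ch$av_delay,
                   rate_exp = if (is.null(ch$rate_exp)) 1 else ch$rate_exp))
  vco <- if (is.null(x$vco)) NULL else
    vco_spec(x$vco$t_start, x$vco$ramp_duration, x$vco$max_resistance_factor)
  sim_config(HR = x$HR, vascular = vas, chambers = chambers,
             total_blood_volume = x$total_blood_volume,
             duration = x$duration, settle_time = x$settle_time,
             dt = x$dt, dt_output = x$dt_output,
             record_from = x$record_from, vco = vco,
             upstream_frac = x$upstream_frac, pulmonary = x$pulmonary,
             valves = x$valves, unstressed = x$unstressed, seed = x$seed)
}
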