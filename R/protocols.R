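#' Check for periodic steady state
#'
#' True when, over the last `window_beats + 1` complete beats, the maximum
#' relative beat-to-beat change of both stroke volume and end-diastolic
#' volume stays below `tol`.
#'
#' @param ts a `cv_timeseries`.
#' @param window_beats number of beat-to-beat comparisons in the window.
#' @param tol relative tolerance (fraction; default 0.5%).
#' @return logical.
#' @export
steady_state_check <- function(ts, window_beats = 5, tol = 0.005) {
  beats <- segment_beats(ts)
  if (length(beats) < window_beats + 1L)
    abort_insufficient_data("need %d complete beats, series has %d",
                            window_beats + 1L, length(beats))
  tail_beats <- beats[(length(beats) - window_beats):length(beats)]
  m <- beats_metrics(tail_beats)
  rel <- function(x) max(abs(diff(x)) / abs(x[-length(x)]))
  rel(m$SV) < tol && rel(m$EDV) < tol
}

#' Run one vena-caval occlusion experiment
#'
#' Settles the closed loop for `settle_time` seconds (rounded up to a
#' whole number of paced beats so the occlusion starts on a beat
#' boundary), verifies steady state, ramps the thoracic venous resistance,
#' and analyses the run: the first beat of the occlusion is the
#' steady-state beat; occluded beats are collected until the
#' end-diastolic volume has fallen 25% below steady state or the ramp has
#' plateaued (whichever happens first, with a minimum of 6 beats for the
#' fits); the four contractility relations are fit over those beats and
#' the energetics panel is computed on the steady-state beat.
#'
#' @param config a [sim_config()]; its `vco`/`duration` fields are
#'   overridden by the protocol clock.
#' @param consts an [energetics_constants()].
#' @param vco_ramp,vco_factor ramp duration (s) and plateau resistance
#'   multiplier of the occlusion.
#' @return an `experiment_result` list: `condition`,
#'   `steady_state_beat`, `vco_beats`, `fits`, `energetics`,
#'   `steady_state_ok`.
#' @export
run_vco_experiment <- function(config, consts = energetics_constants(),
                               vco_ramp = 10, vco_factor = 20) {
  period <- 60 / config$HR
  n_settle <- ceiling(config$settle_time / period)
  t_vco <- n_settle * period
  n_tail <- ceiling((vco_ramp + 5) / period) + 1L
  cfg <- config
  cfg$vco <- vco_spec(t_start = t_vco, ramp_duration = vco_ramp,
                      max_resistance_factor = vco_factor)
  cfg$duration <- t_vco + (n_tail + 1L) * period
  # keep 8 pre-occlusion beats for the steady-state verdict
  cfg$record_from <- max(0, t_vco - 8 * period)
  ts <- tryCatch(simulate_cv(cfg), error = function(e)
    abort_numerical("simulation failed for level '%s' at %g bpm: %s",
                    config$vascular$level_label, config$HR,
                    conditionMessage(e)))
  pre <- ts[ts$t < t_vco - 1e-9, , drop = FALSE]
  attr(pre, "HR") <- config$HR; attr(pre, "dt_output") <- cfg$dt_output
  class(pre) <- class(ts)
  ss_ok <- steady_state_check(pre, window_beats = 5, tol = 0.005)

  post <- ts[ts$t >= t_vco - 1e-9, , drop = FALSE]
  attr(post, "HR") <- config$HR; attr(post, "dt_output") <- cfg$dt_output
  class(post) <- class(ts)
  beats <- segment_beats(post)
  first_pass <- beats_metrics(beats)
  edv0 <- first_pass$EDV[1]
  cut <- which(first_pass$EDV <= 0.75 * edv0)
  ramp_end_beat <- ceiling(vco_ramp / period) + 1L
  n_use <- if (length(cut)) min(cut[1], length(beats)) else
    min(ramp_end_beat + 2L, length(beats))
  n_use <- max(n_use, min(6L, length(beats)))
  fits <- contractility_fits(beats[seq_len(n_use)])
  ss_beat <- fits$beat_table[1, , drop = FALSE]
  structure(
    list(condition = list(level = config$vascular$level_label,
                          HR = config$HR),
         steady_state_beat = ss_beat,
         vco_beats = fits$beat_table,
         fits = fits[c("espvr", "prsw", "dpdt_edv", "pva_edv", "Vo_used")],
         energetics = energetics_result(ss_beat, config$HR, consts),
         steady_state_ok = ss_ok),
    class = "experiment_result")
}

phase_config <- function(base, level, HR) {
  cfg <- base
  cfg$HR <- HR
  cfg$vascular <- vascular_aging_params(level)
  cfg
}

#' Phase I: vascular-aging sweep at fixed pacing
#'
#' Runs the occlusion experiment at 80 bpm across the five aging levels
#' (normal, 90%, 80%, 60%, stiff aortic compliance).
#'
#' @param base a [sim_config()] template (chambers, volumes, solver).
#' @param consts an [energetics_constants()].
#' @return list of five `experiment_result`, ordered normal to stiff.
#' @export
run_phase1 <- function(base = sim_config(), consts = energetics_constants()) {
  out <- lapply(aging_levels(), function(lv)
    run_vco_experiment(phase_config(base, lv, 80), consts))
  names(out) <- aging_levels()
  out
}

#' Phase II: heart-rate sweep at the normal and stiff levels
#'
#' Runs the occlusion experiment at 60, 100 and 140 bpm for the normal and
#' stiff vascular settings (6 conditions).
#'
#' @inheritParams run_phase1
#' @return named list of six `experiment_result` (`normal_60`, ...,
#'   `stiff_140`).
#' @export
run_phase2 <- function(base = sim_config(), consts = energetics_constants()) {
  grid <- expand.grid(HR = c(60, 100, 140), level = c("normal", "stiff"),
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i)
    run_vco_experiment(phase_config(base, grid$level[i], grid$HR[i]), consts))
  names(out) <- sprintf("%s_%d", grid$level, grid$HR)
  out
}
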