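# Elastance waveform, ODE right-hand side, integrator, simulation contracts.

test_that("elastance waveform hits E_min in late diastole and E_max at peak", {
  period <- 0.75
  for (ch in default_chambers()[c("LV", "RV")]) {
    expect_identical(elastance_waveform(relaxed_phase(period), period, ch),
                     ch$E_min)
    expect_identical(elastance_waveform(0.74, period, ch), ch$E_min)
    t_pk <- activation_peak_time(period, ch)
    expect_equal(elastance_waveform(t_pk, period, ch), ch$E_max)
  }
  # atria are also relaxed mid-cycle despite their shifted onset
  la <- default_chambers()$LA
  expect_identical(elastance_waveform(0.40, period, la), la$E_min)
})

test_that("elastance at half-activation matches direct double-Hill evaluation", {
  # independent hand evaluation of the activation shape at t = 0.15 s for
  # the default LV at 80 bpm: tau scale 0.75^0.35 * 0.75^0.65 = 0.75
  ch <- default_chambers()$LV
  period <- 0.75
  tau1 <- 0.269 * 0.75; tau2 <- 0.452 * 0.75
  x <- seq(0, min(1.5 * tau2, 0.92 * period), length.out = 4096L)
  shape <- function(x) {
    g1 <- (x / tau1)^1.32
    (g1 / (1 + g1)) / (1 + (x / tau2)^27.4)
  }
  expected <- ch$E_min + (ch$E_max - ch$E_min) * shape(0.15) / max(shape(x))
  expect_equal(elastance_waveform(0.15, period, ch), expected,
               tolerance = 1e-12)
})

test_that("elastance waveform rejects bad input", {
  ch <- default_chambers()$LV
  expect_error(elastance_waveform(0.1, -1, ch),
               class = "cardiosim_invalid_config")
  expect_error(elastance_waveform(0.8, 0.75, ch),
               class = "cardiosim_invalid_input")
  expect_error(chamber_params(E_max = 0.5, E_min = 1, V0 = 10),
               class = "cardiosim_invalid_config")
})

test_that("derivatives vanish with equal pressures and closed valves", {
  cfg <- test_config()
  state <- equal_pressure_state(cfg, P0 = 10)
  d <- cv_derivatives(state, relaxed_phase(), cfg)
  expect_equal(max(abs(d)), 0, tolerance = 1e-12)
})

test_that("derivatives conserve volume for arbitrary states", {
  cfg <- test_config()
  set.seed(42)
  for (i in 1:25) {
    state <- equal_pressure_state(cfg, P0 = 10)
    state[1:13] <- state[1:13] * runif(13, 0.6, 1.6)
    state["Q_av"] <- runif(1, 0, 400)
    d <- cv_derivatives(state, runif(1, 0, 0.75), cfg)
    expect_lt(abs(sum(d[1:13])), 1e-9)
  }
})

test_that("derivatives reject invalid states", {
  cfg <- test_config()
  state <- equal_pressure_state(cfg)
  expect_error(cv_derivatives(state[1:10], 0, cfg),
               class = "cardiosim_invalid_input")
  state[3] <- -5
  expect_error(cv_derivatives(state, 0, cfg),
               class = "cardiosim_numerical_failure")
})

test_that("RK4 stepper matches the analytic RC decay within 1e-4", {
  P0 <- 100; R <- 1.28; C <- 0.7
  p <- cardiosim:::rc_decay_cpp(P0, R, C, duration = 2, dt = 1e-4,
                                dt_out = 1e-2)
  t <- seq(0, 2, by = 1e-2)
  expect_equal(length(p), length(t))
  expect_lt(max(abs(p - P0 * exp(-t / (R * C))) / (P0 * exp(-t / (R * C)))),
            1e-4)
})

test_that("unperturbed simulation is periodic, conservative and causal", {
  cfg <- test_config(settle = 30)
  cfg$duration <- 40
  ts <- simulate_cv(cfg)
  # volume conservation at every output sample
  expect_lt(max(abs(ts$V_total - cfg$total_blood_volume)) /
              cfg$total_blood_volume, 1e-3)
  # aortic flow is never negative (diode valve with inertance)
  expect_gte(min(ts$Q_Ao), 0)
  # last 5 beats periodic: beat-to-beat SV and EDV change < 0.5%
  tail_ts <- ts[ts$t >= 40 - 7.5 * 0.75, ]
  attr(tail_ts, "HR") <- cfg$HR; attr(tail_ts, "dt_output") <- cfg$dt_output
  class(tail_ts) <- class(ts)
  m <- beats_metrics(segment_beats(tail_ts))
  expect_gte(nrow(m), 6)
  expect_lt(max(abs(diff(m$SV)) / m$SV[-nrow(m)]), 0.005)
  expect_lt(max(abs(diff(m$EDV)) / m$EDV[-nrow(m)]), 0.005)
})

test_that("simulation rejects unphysiologic configurations", {
  expect_error(vascular_params(C_A = -0.1, R_T = 1.28),
               class = "cardiosim_invalid_config")
  expect_error(sim_config(HR = 300), class = "cardiosim_invalid_config")
  # volume too low to fill the venous pool surfaces at initialisation
  expect_error(initial_state(sim_config(total_blood_volume = 1500)),
               class = "cardiosim_invalid_config")
})

test_that("VCO ramp returns base resistance, linear midpoint and plateau", {
  spec <- vco_spec(t_start = 180, ramp_duration = 10,
                   max_resistance_factor = 20)
  expect_identical(apply_vco(0, spec, 0.025), 0.025)
  expect_identical(apply_vco(180, spec, 0.025), 0.025)
  expect_equal(apply_vco(185, spec, 0.025), 0.025 * (1 + 19 / 2))
  expect_equal(apply_vco(1e6, spec, 0.025), 0.025 * 20)
  t <- seq(170, 210, by = 0.5)
  expect_true(all(diff(apply_vco(t, spec, 0.025)) >= 0))
})
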