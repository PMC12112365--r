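# Vascular aging interpolation, steady-state detection, VCO orchestration.

test_that("aging interpolation endpoints are exact and midpoints linear", {
  nom <- nominal_vascular(); stf <- stiff_vascular()
  expect_identical(vascular_aging_params("normal"), nom)
  expect_identical(vascular_aging_params("stiff"), stf)
  # hand-computed midpoint: C_A = 0.56, R_T along the (C_A, R_T) segment
  v80 <- vascular_aging_params("80%")
  expect_equal(v80$C_A, 0.56)
  expect_equal(v80$R_T, 1.28 + ((0.70 - 0.56) / (0.70 - 0.19)) * (3.66 - 1.28),
               tolerance = 1e-12)
  v90 <- vascular_aging_params("90%")
  expect_equal(v90$C_A, 0.63)
  expect_equal(v90$R_T, 1.28 + ((0.70 - 0.63) / (0.70 - 0.19)) * (3.66 - 1.28),
               tolerance = 1e-12)
})

test_that("every aging level satisfies the parallel-resistance invariant", {
  for (lv in aging_levels()) {
    v <- vascular_aging_params(lv)
    expect_equal(1 / sum(1 / v$compartment_R), v$R_T, tolerance = 1e-9)
    expect_true(all(v$compartment_C > 0))
    f <- aging_level(lv)$fraction
    expect_equal(v$C_A, f * 0.7, tolerance = 1e-12)
  }
})

test_that("aging levels outside the stiff..normal range are rejected", {
  expect_error(vascular_aging_params(0.15), class = "cardiosim_invalid_config")
  expect_error(aging_level("70 percent"), class = "cardiosim_invalid_config")
  expect_error(aging_level(1.2), class = "cardiosim_invalid_config")
})

test_that("steady_state_check accepts periodic series and rejects drift", {
  expect_true(steady_state_check(synthetic_timeseries(n_beats = 8),
                                 window_beats = 5, tol = 0.005))
  expect_false(steady_state_check(synthetic_timeseries(n_beats = 8,
                                                       drift = 0.05),
                                  window_beats = 5, tol = 0.005))
  expect_error(steady_state_check(synthetic_timeseries(n_beats = 3),
                                  window_beats = 5),
               class = "cardiosim_insufficient_data")
})

test_that("the calibrated loop reaches steady state and VCO drops preload", {
  res <- suppressWarnings(run_vco_experiment(test_config(settle = 45)))
  expect_s3_class(res$steady_state_beat, "beat_metrics")
  expect_true(res$steady_state_ok)
  m <- res$vco_beats
  expect_gte(nrow(m), 10)
  # preload falls monotonically beat over beat (one-beat tolerance)
  expect_lte(sum(diff(m$EDV) > 0), 1)
  expect_lt(min(m$EDV), 0.80 * m$EDV[1])
  # fits carry all four relations with high determination
  for (f in res$fits[c("espvr", "prsw", "dpdt_edv", "pva_edv")]) {
    expect_s3_class(f, "contractility_fit")
    expect_gte(f$n, 5)
    expect_gt(f$r_squared, 0.9)
  }
  # the fitted ESPVR recovers the generating elastance constants
  expect_equal(res$fits$espvr$Ees, 2.60, tolerance = 0.10)
  expect_equal(res$fits$espvr$Vo, 10, tolerance = 0.25)
})

test_that("run_phase1 yields five ordered conditions with stiffening effects", {
  res <- run_phase1(test_config(settle = 45))
  expect_named(res, aging_levels())
  expect_length(res, 5)
  pes <- vapply(res, function(r) r$steady_state_beat$Pes, numeric(1))
  sw <- vapply(res, function(r) r$steady_state_beat$SW, numeric(1))
  pe <- vapply(res, function(r) r$steady_state_beat$PE, numeric(1))
  expect_true(all(diff(pes) > 0))
  expect_true(all(diff(sw) > 0))
  expect_true(all(diff(pe) > 0))
  expect_true(all(vapply(res, function(r) r$condition$HR == 80, logical(1))))
})

test_that("run_phase2 yields six conditions with rate effects", {
  res <- run_phase2(test_config(settle = 45))
  expect_length(res, 6)
  expect_named(res, c("normal_60", "normal_100", "normal_140",
                      "stiff_60", "stiff_100", "stiff_140"))
  for (lv in c("normal", "stiff")) {
    sv <- vapply(paste0(lv, "_", c(60, 100, 140)),
                 function(nm) res[[nm]]$steady_state_beat$SV, numeric(1))
    em <- vapply(paste0(lv, "_", c(60, 100, 140)),
                 function(nm) res[[nm]]$energetics$eMVO2, numeric(1))
    expect_true(all(diff(sv) < 0))
    expect_true(all(diff(em) > 0))
  }
})
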