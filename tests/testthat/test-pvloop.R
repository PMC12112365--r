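# Beat segmentation, loop metrics, contractility fits, percent change.

test_that("segmentation cuts whole pacing periods and drops partial beats", {
  ts <- synthetic_timeseries(n_beats = 10, HR = 60)
  expect_length(segment_beats(ts), 10)
  ts2 <- synthetic_timeseries(n_beats = 10.5, HR = 60)
  expect_length(segment_beats(ts2), 10)
  expect_error(segment_beats(synthetic_timeseries(n_beats = 1.5)),
               class = "cardiosim_insufficient_data")
  expect_error(segment_beats(ts, HR = 72), class = "cardiosim_invalid_input")
})

test_that("segmentation aligns end-diastole with activation onset", {
  # synthetic series whose volume peaks exactly on the pacing clock: the
  # first sample of every beat must be the volume maximum even when the
  # series starts mid-beat
  ts <- synthetic_timeseries(n_beats = 6, HR = 60)
  mid <- ts[ts$t >= 1.37, ]
  attr(mid, "HR") <- 60; attr(mid, "dt_output") <- attr(ts, "dt_output")
  class(mid) <- class(ts)
  for (b in segment_beats(mid)) expect_identical(which.max(b$V), 1L)
  # in the full closed loop, end-diastole (first sample) is the volume
  # maximum within half a percent
  cfg <- test_config(settle = 30)
  cfg$duration <- 36
  cfg$record_from <- 30  # mid-beat start: alignment must use the clock
  ts2 <- simulate_cv(cfg)
  for (b in segment_beats(ts2)) expect_gte(b$V[1], 0.995 * max(b$V))
})

test_that("rectangular loop metrics match closed-form areas", {
  b <- rect_beat(V1 = 50, V2 = 120, P1 = 10, P2 = 100)
  m <- beat_metrics(b)
  expect_equal(m$SW, 70 * 90)
  expect_equal(m$ESV, 50)
  expect_equal(m$EDV, 50)  # rectangle starts at the low-volume corner
  m2 <- beat_metrics(b, espvr_Vo = 10)
  expect_equal(m2$Pes, 100)
  expect_equal(m2$PE, 0.5 * 100 * (50 - 10))
  expect_equal(m2$PVA, 6300 + 2000)
})

test_that("shoelace stroke work matches the analytic loop integral", {
  b <- ellipse_beat(a = 35, b = 45)
  m <- suppressWarnings(beat_metrics(b))
  expect_equal(m$SW, pi * 35 * 45, tolerance = 5e-3)
  # shoelace against an independent trapezoidal contour integral
  trapz <- abs(sum((b$P[-1] + b$P[-length(b$P)]) / 2 * diff(b$V)))
  expect_equal(m$SW, trapz, tolerance = 5e-3)
})

test_that("PVA = SW + PE and SV = EDV - ESV hold for every metrics row", {
  beats <- generate_synthetic_vco_beats(fixture_spec(n_beats = 20,
                                                     noise_sd = 0.02,
                                                     seed = 7L))
  expect_equal(beats$PVA, beats$SW + beats$PE, tolerance = 1e-14)
  expect_equal(beats$SV, beats$EDV - beats$ESV, tolerance = 1e-14)
})

test_that("exact linear data are recovered perfectly by all four fits", {
  ESV <- seq(40, 70, length.out = 6)
  tab <- structure(
    data.frame(ESV = ESV, Pes = 2.0 * (ESV - 10),
               EDV = ESV + 40, SW = 71.4 * (ESV + 40 - 20),
               dP_dt_max = 16.9 * (ESV + 40 - 30),
               PVA = 91.7 * (ESV + 40 - 25)),
    class = c("beat_metrics", "data.frame"))
  fe <- fit_espvr(tab)
  expect_equal(fe$Ees, 2.0); expect_equal(fe$Vo, 10); expect_equal(fe$r_squared, 1)
  fp <- fit_prsw(tab)
  expect_equal(fp$Mw, 71.4); expect_equal(fp$Vw, 20)
  fd <- fit_dpdt_edv(tab)
  expect_equal(fd$dEdt_max, 16.9); expect_equal(fd$Vo_dpdt, 30)
  fv <- fit_pva_edv(tab)
  expect_equal(fv$MPVA, 91.7); expect_equal(fv$VPVA, 25)
})

test_that("zero-noise synthetic beats recover generating parameters to 1e-8", {
  spec <- fixture_spec(noise_sd = 0, n_beats = 12)
  beats <- generate_synthetic_vco_beats(spec)
  expect_equal(fit_espvr(beats)$Ees, spec$Ees, tolerance = 1e-8)
  expect_equal(fit_espvr(beats)$Vo, spec$Vo, tolerance = 1e-8)
  expect_equal(fit_prsw(beats)$Mw, spec$Mw, tolerance = 1e-8)
  expect_equal(fit_dpdt_edv(beats)$dEdt_max, spec$dEdt_max, tolerance = 1e-8)
  expect_equal(fit_pva_edv(beats)$MPVA, spec$MPVA, tolerance = 1e-8)
})

test_that("noisy regression recovers slopes within 5% at 12 beats", {
  # ESPVR on points Pes = 1.86 * (Ves - 5) + N(0, 1 mmHg), fixed seed
  set.seed(11)
  ESV <- seq(65, 35, length.out = 12)
  tab <- structure(data.frame(ESV = ESV,
                              Pes = 1.86 * (ESV - 5) + rnorm(12, 0, 1)),
                   class = c("beat_metrics", "data.frame"))
  expect_equal(fit_espvr(tab)$Ees, 1.86, tolerance = 0.05)
  # full stack at 2% multiplicative noise via the generator
  beats <- generate_synthetic_vco_beats(fixture_spec(noise_sd = 0.02,
                                                     n_beats = 12, seed = 3L))
  expect_equal(fit_prsw(beats)$Mw, 71.4, tolerance = 0.05)
  expect_equal(fit_dpdt_edv(beats)$dEdt_max, 16.9, tolerance = 0.05)
  expect_equal(fit_pva_edv(beats)$MPVA, 91.7, tolerance = 0.05)
})

test_that("fit bias shrinks as the beat count grows", {
  err <- function(n) {
    e <- vapply(1:20, function(s) {
      b <- generate_synthetic_vco_beats(fixture_spec(noise_sd = 0.02,
                                                     n_beats = n, seed = s))
      abs(fit_prsw(b)$Mw - 71.4)
    }, numeric(1))
    mean(e)
  }
  expect_lt(err(100), err(12))
})

test_that("degenerate designs raise fit failures", {
  tab <- structure(data.frame(ESV = rep(50, 6), Pes = rnorm(6, 90, 1)),
                   class = c("beat_metrics", "data.frame"))
  expect_error(fit_espvr(tab), class = "cardiosim_fit_failure")
  two <- structure(data.frame(ESV = c(50, 50), Pes = c(90, 91)),
                   class = c("beat_metrics", "data.frame"))
  expect_error(fit_espvr(two), class = "cardiosim_fit_failure")
})

test_that("percent_change matches printed-table arithmetic and round-trips", {
  expect_equal(round(percent_change(22.5, 5.9), 1), -73.8)
  expect_equal(round(percent_change(100.6, 140.1), 1), 39.3)
  expect_equal(percent_change(57.3, 57.3), 0)
  set.seed(5)
  x <- runif(10, 1, 100); y <- runif(10, 1, 100)
  expect_equal(x * (1 + percent_change(x, y) / 100), y, tolerance = 1e-12)
  expect_error(percent_change(0, 5), class = "cardiosim_invalid_input")
})

test_that("open loops are flagged and warned once per beat", {
  b <- rect_beat()
  b$V[length(b$V)] <- b$V[1] * 1.1
  expect_warning(m <- beat_metrics(b), "open PV loop")
  expect_true(m$degenerate)
})
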