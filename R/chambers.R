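#' Time-varying elastance chamber parameters
#'
#' A heart chamber is modelled as a time-varying elastance: chamber pressure
#' is `E(t) * (V - V0)` where `E(t)` cycles once per paced beat between the
#' diastolic elastance `E_min` and the end-systolic elastance `E_max`.  The
#' normalized activation waveform is a double-Hill product
#' `g1(t) * g2(t)` with `g1 = (t/tau1)^m1 / (1 + (t/tau1)^m1)` (contraction)
#' and `g2 = 1 / (1 + (t/tau2)^m2)` (relaxation), rescaled so its maximum is
#' exactly 1 and clipped to zero beyond `1.5 * tau2` so the chamber sits at
#' `E_min` through late diastole.
#'
#' @param E_max end-systolic elastance (mmHg/mL); must exceed `E_min`.
#' @param E_min diastolic elastance (mmHg/mL), > 0.
#' @param V0 unstressed chamber volume (mL), >= 0.
#' @param label chamber id, one of `"LV"`, `"LA"`, `"RV"`, `"RA"`.
#' @param m1,m2 Hill exponents of the contraction and relaxation limbs.
#' @param tau1_frac,tau2_frac time constants of the two limbs as fractions
#'   of the pacing period, so systolic duration scales with heart rate.
#' @param av_delay atrio-ventricular delay (s).  Ventricles use 0 (their
#'   activation starts on the pacing clock); atria are activated `av_delay`
#'   seconds before the next ventricular beat (capped at 21% of the period
#'   at very high rates).
#' @param rate_exp exponent of the systolic-duration/heart-rate relation:
#'   activation time constants scale with
#'   `period^rate_exp * 0.75^(1 - rate_exp)` so that at `rate_exp = 1`
#'   systole is a fixed fraction of the cycle while values < 1 make
#'   systole shorten less than the cycle as rate rises (the classic
#'   square-root-like behaviour of systolic time intervals), squeezing
#'   diastolic filling at high pacing rates.
#' @return an object of class `chamber_params`.
#' @export
chamber_params <- function(E_max, E_min, V0, label = "LV",
                           m1 = 1.32, m2 = 27.4,
                           tau1_frac = 0.269, tau2_frac = 0.452,
                           av_delay = 0, rate_exp = 1) {
  check_number(E_max, "E_max", lower = 1e-6)
  check_number(E_min, "E_min", lower = 1e-6)
  if (E_max <= E_min)
    abort_invalid_config("E_max (%g) must exceed E_min (%g)", E_max, E_min)
  check_number(V0, "V0", lower = 0)
  check_number(av_delay, "av_delay", lower = 0)
  if (!label %in% c("LV", "LA", "RV", "RA"))
    abort_invalid_config("unknown chamber label '%s'", label)
  structure(
    list(E_max = E_max, E_min = E_min, V0 = V0, label = label,
         activation = list(m1 = m1, m2 = m2, tau1_frac = tau1_frac,
                           tau2_frac = tau2_frac, av_delay = av_delay,
                           rate_exp = rate_exp)),
    class = "chamber_params"
  )
}

# 10-column parameter row consumed by the C++ core:
# Emax, Emin, V0, onset, tau1, tau2, m1, m2, cutoff, anorm
chamber_row <- function(chamber, period) {
  a <- chamber$activation
  rexp <- if (is.null(a$rate_exp)) 1 else a$rate_exp
  t_eff <- period^rexp * 0.75^(1 - rexp)  # 0.75 s = 80 bpm reference cycle
  tau1 <- a$tau1_frac * t_eff
  tau2 <- a$tau2_frac * t_eff
  cutoff <- min(1.5 * tau2, 0.92 * period)
  onset <- 0
  if (a$av_delay > 0)
    onset <- period - min(a$av_delay, 0.21 * period)
  # normalisation constant: max of the raw double-Hill shape on a fine grid
  x <- seq(0, cutoff, length.out = 4096L)
  g1 <- (x / tau1)^a$m1
  raw <- (g1 / (1 + g1)) / (1 + (x / tau2)^a$m2)
  c(chamber$E_max, chamber$E_min, chamber$V0, onset, tau1, tau2,
    a$m1, a$m2, cutoff, max(raw))
}

#' Evaluate the chamber elastance waveform
#'
#' @param t_cycle time within the pacing cycle (s), in `[0, period)`;
#'   vectorized.
#' @param period pacing period (s), > 0.
#' @param chamber a [chamber_params()] object.
#' @return elastance in mmHg/mL, between `E_min` and `E_max`.
#' @export
elastance_waveform <- function(t_cycle, period, chamber) {
  check_number(period, "period", lower = 1e-9)
  if (!inherits(chamber, "chamber_params"))
    abort_invalid_input("`chamber` must be a chamber_params object")
  if (any(!is.finite(t_cycle)) || any(t_cycle < 0) || any(t_cycle >= period))
    abort_invalid_input("`t_cycle` must lie in [0, period)")
  cv_elastance_cpp(t_cycle, period, chamber_row(chamber, period))
}

#' Time of peak activation within the cycle
#'
#' Returns the `t_cycle` at which the activation waveform (and hence the
#' elastance) attains its maximum, on the same grid used to normalize the
#' waveform, so `elastance_waveform()` evaluated there returns `E_max`
#' exactly.
#'
#' @inheritParams elastance_waveform
#' @export
activation_peak_time <- function(period, chamber) {
  check_number(period, "period", lower = 1e-9)
  row <- chamber_row(chamber, period)
  tau1 <- row[5]; tau2 <- row[6]; m1 <- row[7]; m2 <- row[8]; cutoff <- row[9]
  x <- seq(0, cutoff, length.out = 4096L)
  g1 <- (x / tau1)^m1
  raw <- (g1 / (1 + g1)) / (1 + (x / tau2)^m2)
  (x[which.max(raw)] + row[4]) %% period
}

#' Default calibrated chamber set
#'
#' Chamber elastances, unstressed volumes and activation timing calibrated
#' so that the nominal vascular load (aortic compliance 0.7 mL/mmHg, total
#' peripheral resistance 1.28 mmHg s/mL) paced at 80 bpm yields aortic
#' pressures of approximately 120/80 mmHg with a stroke volume near
#' 45-60 mL.
#'
#' @return named list of [chamber_params()] for LV, LA, RV, RA.
#' @export
default_chambers <- function() {
  list(
    LV = chamber_params(E_max = 2.60, E_min = 0.10, V0 = 10, label = "LV",
                        rate_exp = 0.35),
    LA = chamber_params(E_max = 0.35, E_min = 0.15, V0 = 3, label = "LA",
                        m1 = 1.9, m2 = 11.9, tau1_frac = 0.11,
                        tau2_frac = 0.18, av_delay = 0.16),
    RV = chamber_params(E_max = 0.60, E_min = 0.09, V0 = 5, label = "RV",
                        rate_exp = 0.35),
    RA = chamber_params(E_max = 0.18, E_min = 0.08, V0 = 3, label = "RA",
                        m1 = 1.9, m2 = 11.9, tau1_frac = 0.11,
                        tau2_frac = 0.18, av_delay = 0.16)
  )
}
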