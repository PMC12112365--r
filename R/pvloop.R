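#' Segment a time series into paced beats
#'
#' Beats are cut on the pacing clock: consecutive non-overlapping windows
#' of exactly `60/HR` seconds starting at the first sample.  A trailing
#' partial beat is dropped.
#'
#' @param ts a `cv_timeseries`.
#' @param HR paced heart rate (beats/min); must agree with the series
#'   annotation when one is present.
#' @return list of `cv_beat` objects, each holding the LV pressure/volume
#'   and aortic pressure samples of one cycle.
#' @export
segment_beats <- function(ts, HR = attr(ts, "HR")) {
  if (is.null(HR)) abort_invalid_input("heart rate not given or annotated")
  ann <- attr(ts, "HR")
  if (!is.null(ann) && abs(ann - HR) > 1e-9)
    abort_invalid_input("HR %.1f inconsistent with series annotation %.1f",
                        HR, ann)
  period <- 60 / HR
  dt <- attr(ts, "dt_output")
  if (is.null(dt)) dt <- stats::median(diff(ts$t))
  # align to the pacing clock: beats start at integer multiples of the
  # period on the absolute time axis (t = 0 is the pacing onset)
  anchor <- ceiling((ts$t[1] - dt / 2) / period) * period
  first <- which(ts$t >= anchor - dt / 2)[1]
  span <- ts$t[nrow(ts)] - ts$t[first]
  if (is.na(first) || span < 2 * period - dt / 2)
    abort_insufficient_data("series spans %.2f s; need at least 2 beats (%.2f s)",
                            span, 2 * period)
  per_beat <- round(period / dt)
  n_beats <- floor((nrow(ts) - first) / per_beat)
  lapply(seq_len(n_beats), function(b) {
    i0 <- first + (b - 1L) * per_beat
    i1 <- i0 + per_beat  # first sample of the next beat closes the loop
    structure(
      list(start = i0, end = i1, beat_index = b,
           t = ts$t[i0:i1], P = ts$P_LV[i0:i1], V = ts$V_LV[i0:i1],
           P_Ao = ts$P_Ao[i0:i1], dt = dt, period = period),
      class = "cv_beat")
  })
}

shoelace_area <- function(P, V) {
  n <- length(P)
  abs(sum(P * (V[c(2:n, 1)] - V[c(n, 1:(n - 1))]))) / 2
}

#' Per-beat pressure-volume loop metrics
#'
#' Computes the standard loop quantities for one paced cycle.  End-diastole
#' is the activation onset (first sample of the beat, pacing-clock
#' aligned); end-systolic volume is the volume minimum; end-systolic
#' pressure is read at the point of maximal elastance `P/(V - Vo)` when a
#' volume-axis intercept `Vo` is supplied, and at the upper-left loop
#' corner (the volume minimum) otherwise.  Stroke work is the shoelace
#' area of the closed loop; potential energy is the ESPVR triangle
#' `0.5 * Pes * (ESV - Vo)`, clipped at zero; `PVA = SW + PE`.
#'
#' @param beat a `cv_beat` from [segment_beats()].
#' @param espvr_Vo ESPVR volume-axis intercept (mL) or `NULL` on a first
#'   pass.
#' @param warn warn on an open (degenerate) loop; tables built over a
#'   preload-reduction run set this to `FALSE` since transient beats are
#'   open by construction and the `degenerate` column carries the flag.
#' @return one-row data frame of class `beat_metrics` with columns
#'   `EDV, ESV, SV, Pes, EDP, SBP, DBP, PP, dP_dt_max, SW, PE, PVA,
#'   beat_index, degenerate`.
#' @export
beat_metrics <- function(beat, espvr_Vo = NULL, warn = TRUE) {
  if (!inherits(beat, "cv_beat"))
    abort_invalid_input("`beat` must be a cv_beat")
  P <- beat$P; V <- beat$V
  EDV <- V[1]; EDP <- P[1]
  ESV <- min(V)
  degenerate <- abs(V[length(V)] - V[1]) > 0.02 * EDV
  if (degenerate && warn)
    warning("open PV loop (start/end volume gap > 2% EDV); beat flagged",
            call. = FALSE)
  Vo <- if (is.null(espvr_Vo)) 0 else espvr_Vo
  if (is.null(espvr_Vo)) {
    Pes <- P[which.min(V)]
  } else {
    ok <- (V - Vo) > 0.05 * (EDV - Vo)
    if (!any(ok)) ok <- rep(TRUE, length(V))
    el <- ifelse(ok, P / (V - Vo), -Inf)
    Pes <- P[which.max(el)]
  }
  SBP <- max(beat$P_Ao); DBP <- min(beat$P_Ao)
  dP_dt_max <- max(diff(P)) / beat$dt
  SW <- shoelace_area(P, V)
  PE <- max(0, 0.5 * Pes * (ESV - Vo))
  structure(
    data.frame(EDV = EDV, ESV = ESV, SV = EDV - ESV, Pes = Pes, EDP = EDP,
               SBP = SBP, DBP = DBP, PP = SBP - DBP,
               dP_dt_max = dP_dt_max, SW = SW, PE = PE, PVA = SW + PE,
               beat_index = beat$beat_index, degenerate = degenerate),
    class = c("beat_metrics", "data.frame"))
}

#' Metrics table for a list of beats
#' @param beats list of `cv_beat`.
#' @inheritParams beat_metrics
#' @return `beat_metrics` data frame, one row per beat; open loops are
#'   flagged in the `degenerate` column rather than warned about.
#' @export
beats_metrics <- function(beats, espvr_Vo = NULL) {
  out <- do.call(rbind, lapply(beats, beat_metrics, espvr_Vo = espvr_Vo,
                               warn = FALSE))
  structure(out, class = c("beat_metrics", "data.frame"))
}

fit_linear <- function(x, y, slope_name, vint_name, relation) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 5L)
    abort_fit_failure("%s fit needs >= 5 beats, got %d", relation, length(x))
  if (stats::sd(x) < 1e-9)
    abort_fit_failure("%s fit is rank-deficient: no volume spread", relation)
  fit <- stats::lm.fit(cbind(1, x), y)
  a <- fit$coefficients[1]; b <- fit$coefficients[2]
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot < 1e-12) 1 else 1 - ss_res / ss_tot
  out <- list(slope = unname(b), intercept = unname(a),
              V_intercept = unname(-a / b), r_squared = r2,
              n = length(x), relation = relation)
  names(out)[1] <- slope_name
  names(out)[3] <- vint_name
  structure(out, class = "contractility_fit")
}

#' Load-varying contractility fits
#'
#' The four linear relations fit by ordinary least squares over the beats
#' of a preload-reduction (VCO) run:
#' \describe{
#'   \item{`fit_espvr`}{end-systolic pressure-volume relation
#'     `Pes = Ees * (ESV - Vo)`; slope `Ees`, volume intercept `Vo`.}
#'   \item{`fit_prsw`}{preload-recruitable stroke work
#'     `SW = Mw * (EDV - Vw)`.}
#'   \item{`fit_dpdt_edv`}{`dP/dtmax = dEdt_max * (EDV - Vo_dpdt)`.}
#'   \item{`fit_pva_edv`}{`PVA = MPVA * (EDV - VPVA)`.}
#' }
#' Each needs at least 5 beats with volume spread; every fit reports its
#' coefficient of determination.
#'
#' @param beats a `beat_metrics` data frame (>= 5 rows).
#' @return a `contractility_fit` list: slope, `intercept`, volume
#'   intercept, `r_squared`, `n`.
#' @export
fit_espvr <- function(beats) {
  fit_linear(beats$ESV, beats$Pes, "Ees", "Vo", "ESPVR")
}

#' @rdname fit_espvr
#' @export
fit_prsw <- function(beats) {
  fit_linear(beats$EDV, beats$SW, "Mw", "Vw", "PRSW")
}

#' @rdname fit_espvr
#' @export
fit_dpdt_edv <- function(beats) {
  fit_linear(beats$EDV, beats$dP_dt_max, "dEdt_max", "Vo_dpdt",
             "dP/dtmax-EDV")
}

#' @rdname fit_espvr
#' @export
fit_pva_edv <- function(beats) {
  fit_linear(beats$EDV, beats$PVA, "MPVA", "VPVA", "EDV-PVA")
}

#' All four contractility relations from raw beats, with a two-pass Vo
#'
#' First pass: metrics with the upper-left-corner end-systole convention
#' and `Vo = 0`; the ESPVR is fit and its volume intercept re-used to
#' relocate end-systole (maximal elastance) and to recompute `PE`/`PVA`;
#' all four relations are then fit on the second-pass table.
#'
#' @param beats list of `cv_beat` objects (a VCO run).
#' @return list with elements `espvr`, `prsw`, `dpdt_edv`, `pva_edv`
#'   (each a `contractility_fit`), `Vo_used` and the second-pass
#'   `beat_table`.
#' @export
contractility_fits <- function(beats) {
  pass1 <- beats_metrics(beats, espvr_Vo = NULL)
  Vo <- fit_espvr(pass1)$Vo
  tab <- beats_metrics(beats, espvr_Vo = Vo)
  list(espvr = fit_espvr(tab), prsw = fit_prsw(tab),
       dpdt_edv = fit_dpdt_edv(tab), pva_edv = fit_pva_edv(tab),
       Vo_used = Vo, beat_table = tab)
}

#' Percent change from a baseline
#'
#' @param baseline reference value (non-zero).
#' @param value new value.
#' @return `100 * (value - baseline) / baseline`.
#' @export
percent_change <- function(baseline, value) {
  if (any(baseline == 0))
    abort_invalid_input("percent change undefined for zero baseline")
  100 * (value - baseline) / baseline
}
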