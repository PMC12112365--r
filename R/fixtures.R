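#' Specification of a synthetic VCO beat table
#'
#' Generating parameters for a synthetic preload-reduction run with known
#' load-varying relations, used to exercise the analysis and energetics
#' stack independently of the ODE core.
#'
#' @param Ees,Vo ESPVR slope (mmHg/mL) and volume intercept (mL).
#' @param Mw,Vw PRSW slope (mmHg) and volume intercept (mL).
#' @param dEdt_max,Vo_dpdt dP/dtmax-EDV slope (mmHg/s/mL) and intercept
#'   (mL).
#' @param MPVA,VPVA EDV-PVA slope (mmHg) and intercept (mL).
#' @param EDV_range descending preload sweep, `c(high, low)` in mL.
#' @param n_beats number of beats (>= 2).
#' @param noise_sd multiplicative Gaussian noise, as a fraction of each
#'   generated value (0 for exact linear data).
#' @param seed integer seed; the generator is the only stochastic code in
#'   the package.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(Ees = 1.86, Vo = 10, Mw = 71.4, Vw = 20,
                         dEdt_max = 16.9, Vo_dpdt = 30,
                         MPVA = 91.7, VPVA = 25,
                         EDV_range = c(100, 70), n_beats = 12,
                         noise_sd = 0, seed = 1L) {
  for (nm in c("Ees", "Mw", "dEdt_max", "MPVA"))
    check_number(get(nm), nm, lower = 1e-9)
  check_number(n_beats, "n_beats", lower = 2)
  check_number(noise_sd, "noise_sd", lower = 0, upper = 0.5)
  if (length(EDV_range) != 2L || EDV_range[1] <= EDV_range[2])
    abort_invalid_config("EDV_range must be c(high, low) with high > low")
  structure(list(Ees = Ees, Vo = Vo, Mw = Mw, Vw = Vw,
                 dEdt_max = dEdt_max, Vo_dpdt = Vo_dpdt,
                 MPVA = MPVA, VPVA = VPVA, EDV_range = EDV_range,
                 n_beats = as.integer(n_beats), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic VCO beat table
#'
#' End-diastolic volumes are evenly spaced, descending over `EDV_range`
#' (mimicking the preload fall of an occlusion).  Stroke work, dP/dtmax
#' and PVA are drawn from the configured linear relations with optional
#' multiplicative Gaussian noise; end-systolic volume and pressure are
#' derived from the ESPVR so that the internal identities
#' `SV = EDV - ESV` and `PVA = SW + PE` hold exactly, with
#' `PE = PVA - SW = 0.5 * Ees * (ESV - Vo)^2`.  Output is deterministic
#' given the seed.
#'
#' @param spec a [fixture_spec()].
#' @return a `beat_metrics` data frame with `n_beats` rows.
#' @export
generate_synthetic_vco_beats <- function(spec = fixture_spec()) {
  if (!inherits(spec, "fixture_spec"))
    abort_invalid_input("`spec` must be a fixture_spec")
  EDV <- seq(spec$EDV_range[1], spec$EDV_range[2],
             length.out = spec$n_beats)
  set.seed(spec$seed)
  jitter <- function(x) x * (1 + stats::rnorm(length(x), 0, spec$noise_sd))
  SW <- jitter(spec$Mw * (EDV - spec$Vw))
  dpdt <- jitter(spec$dEdt_max * (EDV - spec$Vo_dpdt))
  PVA <- jitter(spec$MPVA * (EDV - spec$VPVA))
  PE <- PVA - SW
  if (any(SW <= 0) || any(dpdt <= 0) || any(PE < 0))
    abort_invalid_config(
      "impossible fixture: negative SW, dP/dtmax or PE over the EDV range")
  ESV <- spec$Vo + sqrt(2 * PE / spec$Ees)
  Pes <- spec$Ees * (ESV - spec$Vo)
  if (any(ESV >= EDV))
    abort_invalid_config("impossible fixture: ESV >= EDV over the range")
  SBP <- 1.15 * Pes
  DBP <- 0.80 * Pes
  structure(
    data.frame(EDV = EDV, ESV = ESV, SV = EDV - ESV, Pes = Pes,
               EDP = 0.08 * (EDV - spec$Vo), SBP = SBP, DBP = DBP,
               PP = SBP - DBP, dP_dt_max = dpdt, SW = SW, PE = PE,
               PVA = SW + PE, beat_index = seq_along(EDV),
               degenerate = FALSE),
    class = c("beat_metrics", "data.frame"))
}
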