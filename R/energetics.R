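#' Constants for the myocardial energetics calculations
#'
#' `K1`, `K2` and the intercept parameterize the pressure-work index
#' estimate of myocardial oxygen consumption (mL O2/min, reported per
#' 200 g of left ventricle).  `k_work` converts stroke work from
#' mmHg mL to joules (exact physical constant); `k_O2` is the energy
#' equivalent of oxygen in J per mL O2 (19.6 by default; 20.0 is the
#' common round alternative).
#'
#' @param K1 coefficient of the systolic pressure-rate term
#'   (mL O2/min per mmHg/min).
#' @param K2 coefficient of the flow-work term.
#' @param intercept basal term (mL O2/min).
#' @param BW body weight (kg).
#' @param LV_mass left-ventricular mass (g); reporting basis of the oxygen
#'   consumption estimate.
#' @param k_work J per mmHg mL.
#' @param k_O2 J per mL O2.
#' @return an `energetics_constants` list.
#' @export
energetics_constants <- function(K1 = 4.08e-4, K2 = 3.25e-4,
                                 intercept = 1.43, BW = 75, LV_mass = 200,
                                 k_work = 1.33322e-4, k_O2 = 19.6) {
  for (nm in c("K1", "K2", "intercept", "BW", "LV_mass", "k_work", "k_O2"))
    check_number(get(nm), nm, lower = 1e-12)
  structure(list(K1 = K1, K2 = K2, intercept = intercept, BW = BW,
                 LV_mass = LV_mass, k_work = k_work, k_O2 = k_O2),
            class = "energetics_constants")
}

#' Pressure-work index estimate of myocardial oxygen consumption
#'
#' `eMVO2 = K1 * (SBP * HR) +
#'          K2 * ((0.8 * SBP + 0.2 * DBP) * HR * SV / BW) + intercept`,
#' in mL O2/min on the per-200-g reporting basis.
#'
#' @param SBP,DBP systolic and diastolic arterial pressure (mmHg).
#' @param HR heart rate (beats/min).
#' @param SV stroke volume (mL).
#' @param consts an [energetics_constants()].
#' @return estimated oxygen consumption (mL O2/min).
#' @export
emvo2 <- function(SBP, DBP, HR, SV, consts = energetics_constants()) {
  for (v in list(SBP = SBP, DBP = DBP, HR = HR, SV = SV))
    if (any(!is.finite(v)) || any(v < 0))
      abort_invalid_input("hemodynamic inputs to emvo2 must be >= 0")
  consts$K1 * (SBP * HR) +
    consts$K2 * ((0.8 * SBP + 0.2 * DBP) * HR * SV / consts$BW) +
    consts$intercept
}

#' Mechanical efficiency
#'
#' The work-partition ratio `100 * SW / (SW + PE)` (%): the fraction of the
#' total pressure-volume area delivered as external stroke work.
#'
#' @param SW stroke work (mmHg mL), >= 0.
#' @param PE potential energy (mmHg mL), >= 0.
#' @return efficiency in percent.
#' @export
mechanical_efficiency <- function(SW, PE) {
  if (any(SW < 0) || any(PE < 0))
    abort_invalid_input("SW and PE must be non-negative")
  if (any(SW + PE <= 0))
    abort_invalid_input("mechanical efficiency undefined for SW = PE = 0")
  100 * SW / (SW + PE)
}

myoeff_rate <- function(work, HR, emvo2, consts, what) {
  if (any(!is.finite(emvo2)) || any(emvo2 <= 0))
    abort_invalid_input("emvo2 must be positive")
  if (any(work < 0)) abort_invalid_input("%s must be >= 0", what)
  100 * (work * consts$k_work * HR) / (emvo2 * consts$k_O2)
}

#' Myocardial efficiency
#'
#' External (stroke-work) or total (pressure-volume-area) mechanical power
#' over the energy equivalent of the estimated oxygen consumption:
#' `100 * (SW * k_work * HR) / (eMVO2 * k_O2)` with per-beat work in
#' mmHg mL, `HR` in beats/min and `eMVO2` in mL O2/min, so both rates are
#' in J/min.  `myoeff_pva()` substitutes PVA for SW.
#'
#' @param SW,PVA per-beat stroke work / pressure-volume area (mmHg mL).
#' @param HR heart rate (beats/min).
#' @param emvo2 estimated oxygen consumption (mL O2/min), > 0.
#' @param consts an [energetics_constants()].
#' @return efficiency in percent.
#' @export
myoeff_sw <- function(SW, HR, emvo2, consts = energetics_constants()) {
  myoeff_rate(SW, HR, emvo2, consts, "SW")
}

#' @rdname myoeff_sw
#' @export
myoeff_pva <- function(PVA, HR, emvo2, consts = energetics_constants()) {
  myoeff_rate(PVA, HR, emvo2, consts, "PVA")
}

#' Full energetics panel for one steady-state beat
#'
#' @param beat one-row `beat_metrics` (the steady-state beat of a
#'   condition; its `SBP`/`DBP` are aortic).
#' @param HR heart rate (beats/min).
#' @param consts an [energetics_constants()].
#' @return an `energetics_result` list: `eMVO2`, `ME`, `MyoEff_SW`,
#'   `MyoEff_PVA` (all on their reporting scales) plus the constants used.
#' @export
energetics_result <- function(beat, HR, consts = energetics_constants()) {
  e <- emvo2(beat$SBP, beat$DBP, HR, beat$SV, consts)
  structure(
    list(eMVO2 = e,
         ME = mechanical_efficiency(beat$SW, beat$PE),
         MyoEff_SW = myoeff_sw(beat$SW, HR, e, consts),
         MyoEff_PVA = myoeff_pva(beat$PVA, HR, e, consts),
         constants = consts),
    class = "energetics_result")
}
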