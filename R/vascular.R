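#' Vascular parameter set for one aging level
#'
#' Lumped description of the systemic arterial tree: a proximal aortic
#' Windkessel (compliance `C_A`) feeding five identical parallel systemic
#' compartments, draining into a single venous pool.  Each compartment
#' carries one fifth of the cardiac output, so per-branch resistances are
#' five times the total peripheral resistance `R_T`; the parallel reduction
#' of `compartment_R` therefore equals `R_T` exactly.
#'
#' @param C_A proximal aortic compliance (mL/mmHg).
#' @param R_T total peripheral resistance (mmHg s/mL), aorta-to-vein.
#' @param compartment_C compliances of the 5 systemic compartments
#'   (mL/mmHg).
#' @param compartment_R per-branch total resistances (mmHg s/mL); their
#'   parallel combination must equal `R_T` within 1%.
#' @param venous_C venous pool compliance (mL/mmHg).
#' @param venous_R resistance of the thoracic veins between the pool and
#'   the right atrium (mmHg s/mL); this is the element ramped by the
#'   vena-caval occlusion.
#' @param level_label free-text label of the aging level.
#' @return an object of class `vascular_params`.
#' @export
vascular_params <- function(C_A, R_T,
                            compartment_C = rep(0.10 * C_A / 0.7, 5),
                            compartment_R = rep(5 * R_T, 5),
                            venous_C = 90, venous_R = 0.025,
                            level_label = "custom") {
  check_number(C_A, "C_A", lower = 1e-9)
  check_number(R_T, "R_T", lower = 1e-9)
  if (length(compartment_C) != 5L || any(compartment_C <= 0))
    abort_invalid_config("compartment_C must be 5 positive compliances")
  if (length(compartment_R) != 5L || any(compartment_R <= 0))
    abort_invalid_config("compartment_R must be 5 positive resistances")
  check_number(venous_C, "venous_C", lower = 1e-9)
  check_number(venous_R, "venous_R", lower = 1e-9)
  r_par <- 1 / sum(1 / compartment_R)
  if (abs(r_par - R_T) / R_T > 0.01)
    abort_invalid_config(
      "parallel reduction of compartment_R (%.4f) differs from R_T (%.4f) by more than 1%%",
      r_par, R_T)
  structure(
    list(C_A = C_A, R_T = R_T, compartment_C = compartment_C,
         compartment_R = compartment_R, venous_C = venous_C,
         venous_R = venous_R, level_label = level_label),
    class = "vascular_params"
  )
}

#' Anchor vascular parameter sets
#'
#' `nominal_vascular()` is the normal adult arterial tree
#' (`C_A` = 0.7 mL/mmHg, `R_T` = 1.28 mmHg s/mL); `stiff_vascular()` is the
#' fully aged/stiff condition (`C_A` = 0.19 mL/mmHg,
#' `R_T` = 3.66 mmHg s/mL).  These two pairs anchor the vascular-aging
#' interpolation of [vascular_aging_params()].
#'
#' @return a [vascular_params()] object.
#' @export
nominal_vascular <- function() {
  vascular_params(C_A = 0.7, R_T = 1.28, level_label = "normal")
}

#' @rdname nominal_vascular
#' @export
stiff_vascular <- function() {
  vascular_params(C_A = 0.19, R_T = 3.66, level_label = "stiff")
}

#' Vascular aging level
#'
#' Aging levels are labelled by the aortic compliance as a fraction of
#' nominal: `"normal"` (1.0), `"90%"`, `"80%"`, `"60%"` and `"stiff"`
#' (0.19/0.7, about 0.271).  A bare numeric fraction in
#' `[0.19/0.7, 1]` is also accepted.
#'
#' @param level label or numeric fraction.
#' @return list with `label` and `fraction`.
#' @export
aging_level <- function(level) {
  stiff_frac <- 0.19 / 0.7
  if (is.character(level)) {
    fraction <- switch(level,
      "normal" = 1, "90%" = 0.9, "80%" = 0.8, "60%" = 0.6,
      "stiff" = stiff_frac,
      abort_invalid_config("unknown aging level '%s'", level))
    label <- level
  } else {
    check_number(level, "level", lower = 0, upper = 1)
    fraction <- level
    label <- sprintf("%.0f%%", 100 * level)
  }
  if (fraction > 1 || fraction < stiff_frac - 1e-12)
    abort_invalid_config(
      "aging fraction %.3f outside [%.3f, 1] (stiff .. normal)",
      fraction, stiff_frac)
  list(label = label, fraction = fraction)
}

#' Scale vascular parameters along the aging path
#'
#' Vascular aging is modelled as a proportional loss of arterial compliance
#' together with a rise of peripheral resistance: the aortic compliance is
#' scaled to `fraction * C_A(nominal)` and `R_T` follows by linear
#' interpolation along the segment joining the nominal anchor
#' (0.7, 1.28) to the stiff anchor (0.19, 3.66) in the `(C_A, R_T)` plane.
#' Compartment compliances scale with the compliance fraction and
#' compartment resistances with the `R_T` ratio, so the totals track the
#' interpolated anchors; venous properties are not aged.  At the two
#' endpoints the anchor objects are returned unchanged.
#'
#' @param level an [aging_level()] (or label/fraction accepted by it).
#' @param nominal,stiff anchor [vascular_params()] objects.
#' @return a [vascular_params()] at the requested level.
#' @export
vascular_aging_params <- function(level, nominal = nominal_vascular(),
                                  stiff = stiff_vascular()) {
  lv <- if (is.list(level)) level else aging_level(level)
  f <- lv$fraction
  stiff_frac <- stiff$C_A / nominal$C_A
  if (f > 1 || f < stiff_frac - 1e-12)
    abort_invalid_config("aging fraction %.3f outside [%.3f, 1]",
                         f, stiff_frac)
  if (abs(f - 1) < 1e-12) return(nominal)
  if (abs(f - stiff_frac) < 1e-12) return(stiff)
  C_A <- f * nominal$C_A
  R_T <- nominal$R_T + (nominal$C_A - C_A) / (nominal$C_A - stiff$C_A) *
    (stiff$R_T - nominal$R_T)
  vascular_params(
    C_A = C_A, R_T = R_T,
    compartment_C = nominal$compartment_C * f,
    compartment_R = nominal$compartment_R * (R_T / nominal$R_T),
    venous_C = nominal$venous_C, venous_R = nominal$venous_R,
    level_label = lv$label
  )
}

#' The five standard aging levels, normal to stiff
#' @return character vector of level labels.
#' @export
aging_levels <- function() c("normal", "90%", "80%", "60%", "stiff")
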