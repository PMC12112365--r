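---
title: "Methods: a closed-loop elastance-Windkessel simulator and its PV-loop analysis stack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a closed-loop elastance-Windkessel simulator and its PV-loop analysis stack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiosim)
```

## The model

`cardiosim` implements a lumped-parameter, closed-loop model of the human
circulation for studying how arterial stiffening (vascular aging) and paced
heart rate reshape left-ventricular function and myocardial energetics.

Each heart chamber is a **time-varying elastance**: chamber pressure is

$$P(t) = E(t)\,\bigl(V(t) - V_0\bigr),$$

with $E(t)$ cycling once per paced beat between a diastolic elastance
$E_{min}$ and an end-systolic elastance $E_{max}$.  The normalized
activation waveform is a double-Hill product (a rising Hill limb for
contraction, a falling one for relaxation), rescaled to peak at exactly 1
and clipped to zero in late diastole so a relaxed chamber sits exactly at
$E_{min}$.  Atria use a shorter waveform, advanced by an atrio-ventricular
delay of 0.16 s so the atrial kick lands just before ventricular systole.

The systemic circulation is a **Windkessel network**: a proximal aortic
compliance $C_A$ feeding five identical parallel systemic compartments
(compliance mid-branch, 20% of the branch resistance proximal and 80%
distal to it), draining into a single large venous pool which returns blood
through the thoracic veins to the right atrium.  Per-branch resistances are
five times the total peripheral resistance $R_T$, so the parallel reduction
of the network equals $R_T$ exactly.  A lumped pulmonary arterial/venous
pair closes the loop through the right heart.  The four valves are ideal
diodes with small resistances; the aortic valve additionally carries an
inertance ($L_{av} = 9\times10^{-4}$ mmHg s^2^/mL).  Without that
inertance ejection has no momentum, late-systolic aortic pressure cannot
fall below the pressure peak, and the end-systolic pressure of the loop
would coincide with systolic pressure — contradicting the normal human
loop, where end-systolic pressure (~80-100 mmHg) sits well below a
~120 mmHg systolic peak, and reversing several of the rate effects the
package is meant to reproduce.

The state vector is 13 compartment volumes plus the aortic valve flow.
Volume is conserved by construction: every flow leaves one compartment and
enters another, so the volume derivatives sum to zero identically and the
closed loop holds the configured total blood volume to machine precision.

## Numerical scheme

No ODE integrator package is assumed: the core is a fixed-step classical
Runge-Kutta (RK4) integrator written in C++ (via Rcpp), step 0.1 ms,
output resampled at 1 ms.  The system is non-stiff — all resistances are
linear, elastances are smooth, and the only non-smoothness is the
diode-valve kink — so a small fixed step is simpler and exactly
reproducible across platforms.  The same stepper is exercised against the
analytic discharge of an isolated two-element Windkessel
($P(t) = P_0 e^{-t/RC}$) and agrees to better than one part in $10^4$,
the tolerance enforced in the test suite.  When the aortic valve is shut
and the flow state is negative, the flow is relaxed to zero with a 5 ms
time constant, which keeps the right-hand side Lipschitz.

Beat alignment needs no detection logic: pacing is right-atrial at a fixed
rate, so beats are cut on the pacing clock (period $60/\mathrm{HR}$ s,
anchored at $t = 0$), and end-diastole is the first sample of each beat.

## Calibration and the stated experimental world

All experiments run under autonomic blockade — no reflexes, no
autoregulation — which is why a passive closed loop suffices.  The nominal
arterial anchors are $C_A = 0.7$ mL/mmHg and $R_T = 1.28$ mmHg s/mL; the
fully stiff anchors are $C_A = 0.19$ mL/mmHg and $R_T = 3.66$ mmHg s/mL.
**Vascular aging** scales the aortic compliance to a fraction of nominal
(levels: normal, 90%, 80%, 60%, and stiff $= 0.19/0.7 \approx 27\%$),
with $R_T$ interpolated linearly along the segment between the two anchor
pairs in the $(C_A, R_T)$ plane; compartment compliances scale with the
compliance fraction and compartment resistances with the $R_T$ ratio.
Venous properties are not aged.  The endpoints return the anchor objects
bit-for-bit.

Chamber constants, total blood volume and filling resistances are
calibration choices (the source experiments publish no chamber parameters
or blood volume) and were fixed once against the normal-physiology
verification targets at 80 bpm: aortic pressures of about 120/80 mmHg,
pulse pressure about 40 mmHg, stroke volume in the 45-60 mL range.  The
shipped defaults give 119.6/79.2 mmHg, pulse pressure 40.4 mmHg, stroke
volume 50.4 mL, end-diastolic volume 104.6 mL.  Two non-obvious choices
deserve explanation:

* **Filling resistance.**  The mitral and tricuspid resistances (0.055
  mmHg s/mL) are deliberately large for "valve" resistances: they lump
  valve, atrial inflow and diastolic relaxation dynamics, and they set how
  strongly end-diastolic volume falls when diastole shortens.  With
  near-zero filling resistance the ventricle refills completely even at
  140 bpm and every rate effect collapses.
* **Systolic duration.**  Activation time constants scale as
  $T^{0.35} \cdot 0.75^{0.65}$ with the cycle length $T$ — systole
  shortens much less than the cycle, as systolic time intervals do in
  paced hearts.  At high rate, diastole is therefore squeezed from both
  sides, reproducing the large preload loss (about $-35\%$ in EDV from
  60 to 140 bpm) that drives the force-frequency findings.

The **vena-caval occlusion** (VCO) multiplies the thoracic venous
resistance by 20 over a linear 10 s ramp after a 180 s settling window
(the protocol's three minutes; the packaged tests shorten the window to
45-60 s after asserting that steady state — beat-to-beat change of stroke
volume and EDV below 0.5% — is already reached).  The occlusion start is
snapped to a beat boundary so the first occluded beat is the steady-state
beat.  Beats enter the contractility fits from occlusion onset until
end-diastolic volume has fallen 25% or the ramp has plateaued, with a
floor of six beats.

## Loop metrics and fits

Per beat: EDV is the volume at activation onset, ESV the volume minimum,
end-systolic pressure is read at the point of maximal elastance
$P/(V - V_0)$ once an ESPVR volume intercept is available (upper-left loop
corner on the first pass), stroke work (SW) is the shoelace area of the
closed loop, potential energy is the ESPVR triangle
$PE = \tfrac12 P_{es}(ESV - V_0)$ clipped at zero (the end-diastolic
pressure-volume relation's area is neglected — a normal-heart,
low-filling-pressure approximation), and $PVA = SW + PE$.  The volume
intercept is obtained by a two-pass scheme: fit the ESPVR with the corner
convention, re-derive end-systole and the energies with the fitted
intercept, refit.  All four load-varying relations are unweighted ordinary
least squares over the occlusion beats, each reported with $R^2$:

* ESPVR: $P_{es} = E_{es}(V_{es} - V_0)$
* Preload-recruitable stroke work: $SW = M_w (EDV - V_w)$
* $dP/dt_{max} = (dE/dt_{max})(EDV - V_{0,dP/dt})$
* $PVA = M_{PVA}(EDV - V_{PVA})$

The first and third relations circulate in the literature in a printed
form with a division sign that is dimensionally inconsistent; the standard
multiplicative linear forms above are what any least-squares fit of these
relations means, and they are what is implemented.

## Energetics

Estimated myocardial oxygen consumption uses the pressure-work index

$$\mathrm{eMVO_2} = K_1 (\mathrm{SBP}\cdot \mathrm{HR}) +
K_2 \frac{(0.8\,\mathrm{SBP} + 0.2\,\mathrm{DBP})\,\mathrm{HR}\cdot SV}{BW} + 1.43$$

with $K_1 = 4.08\times10^{-4}$, $K_2 = 3.25\times10^{-4}$, body weight
75 kg, reported in mL O~2~/min on a per-200-g-LV basis (no additional mass
rescaling is applied: none is defined for the formula).  Mechanical
efficiency is the work partition $ME = 100\,SW/PVA$.  Myocardial
efficiency converts per-beat work to power and divides by the energy
equivalent of the oxygen consumption rate:

$$\mathrm{MyoEff}_{SW} = 100\,\frac{SW \cdot k_{work} \cdot \mathrm{HR}}
{\mathrm{eMVO_2} \cdot k_{O_2}}$$

and identically with PVA.  $k_{work} = 1.33322\times10^{-4}$ J/(mmHg mL)
is an exact unit conversion; $k_{O_2} = 19.6$ J/mL O~2~ is the default
energy equivalent (20.0 is selectable).  Two identities follow and are
enforced by tests to machine precision:
$\mathrm{MyoEff}_{SW} = ME \cdot \mathrm{MyoEff}_{PVA}/100$, and
$\mathrm{MyoEff}_{PVA} \ge \mathrm{MyoEff}_{SW}$ with equality only when
$PE = 0$ — the sense in which the PVA-based paradigm always reads higher.

Two reference-value caveats, documented rather than resolved: published
steady-state tables for this protocol print an eMVO~2~ of 10.7 at the
nominal 80 bpm condition, while the formula above with the printed inputs
(SBP ≈ 120, DBP ≈ 80, SV ≈ 46.5, BW 75) yields ≈ 7.15 — the extra scaling
is not recoverable, so the formula is implemented exactly as printed.  And
the published *cross-rate* efficiency changes are consistent with dividing
per-beat work by per-minute oxygen consumption at a fixed factor of 60
rather than the actual heart rate; this package keeps the dimensionally
consistent rate form above, which reproduces all fixed-rate efficiency
values within 1% and preserves every qualitative rate effect.

## The synthetic beat generator

`generate_synthetic_vco_beats()` emulates the *analysis-facing* content of
an occlusion run: end-diastolic volumes descending evenly over a
configured range, each derived metric drawn from its generating linear
relation with optional multiplicative Gaussian noise, and end-systolic
volume/pressure back-solved from the ESPVR so the identities
$SV = EDV - ESV$ and $PVA = SW + PE$ hold exactly.  It is the package's
only source of randomness and is deterministic given its seed.  It does
**not** emulate waveform shape, valve timing, arrhythmia, or measurement
noise correlated across metrics — so a green fit-recovery test establishes
the correctness of the estimators, not the realism of the simulator; the
simulator is validated separately against its own oracles
(conservation, RC decay, periodicity) and the calibration targets.

## What the reduced model does and does not reproduce

The source experiments were run on a proprietary ~240-equation
cardiopulmonary model that is not published; this package implements a
reduced closed loop (the blocks named above), calibrated only at the
normal-physiology anchors.  Tested against the published steady-state
tables, the reduced model reproduces: every printed hemodynamic and
energetic *sign* of the heart-rate sweep at both compliance settings
(EDV, ESV, SV, end-systolic pressure, pulse pressure, dP/dt~max~, SW and
PE all fall as rate rises; eMVO~2~ rises; all three efficiencies fall),
the direction of every fitted-slope rate effect except the ESPVR at
140 bpm (the reduced model's fitted $E_{es}$ stays within ~1% of the
generating elastance at every rate — large load-history artifacts of the
fit do not arise), and all aging-sweep signs except stroke volume.  On
stroke volume the published tables are internally inconsistent with their
own stiff resistance anchor: a stiff stroke volume of 66.6 mL at 60 bpm
implies a cardiac output of ~4 L/min which, across
$R_T = 3.66$ mmHg s/mL, would require a mean arterial pressure near
244 mmHg — far above the printed end-systolic pressure of ~141 mmHg.  In
any closed loop in which $R_T$ is the aorta-to-vein resistance (the
contract implemented here), stroke volume must fall with stiffening; it
does, and the corresponding acceptance sign checks are left red with this
analysis rather than tuned away.

## Known limitations

No baroreflex or autoregulation (by design: blockade), no wave
reflection or characteristic-impedance tuning beyond the single aortic
inertance, no diseased-heart elastance variants, no EDPVR fitting or
single-beat contractility estimators, and no arrhythmic-beat handling;
imported traces must be uniformly sampled and paced at a known fixed rate.
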