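---
title: "Reduced-order coronary hemodynamics before and after aortic valve replacement"
author: "coroflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-order coronary hemodynamics before and after aortic valve replacement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(coroflow)
```

## The problem

Aortic stenosis (AS) and coronary artery disease frequently coexist. The
pressure-wire indices used to decide on revascularization — FFR (hyperemic
mean Pd/Pa across the stenosis), iFR (resting Pd/Pa over the diastolic
wave-free period) and CFR (hyperemic over resting flow) — are all measured
in a circulation whose driving conditions change radically when the valve
is replaced: the transvalvular gradient disappears, ejection shortens, and
the inflow waveform reshapes. `coroflow` implements a lumped-parameter
(0D) model of the aorto-coronary circulation that makes this question
computable at desk scale: per patient, it builds paired pre/post
valve-replacement models, tunes their boundary conditions to the patient's
pressures and to population-level coronary flow targets, and compares the
coronary indices and a wall-shear-stress surrogate across the
intervention, finishing with the paired statistics of a cohort analysis.

Everything runs on synthetic patients drawn from published cohort summary
statistics; no clinical data is used or required.

## The circulation model

The network is an open loop. A prescribed inflow enters the aortic root;
one RCR Windkessel (proximal resistance `Rp`, compliance `C`, distal
resistance `Rd`, reference pressure 0) represents the systemic
circulation; each epicardial coronary branch (LAD, LCx, RCA; a ramus
intermedius is added when the lesion sits there) leaves the root through
its Poiseuille segment resistance, an optional stenosis element, and a
coronary outlet with small-artery resistance `Ra`, microcirculatory
resistance `Ramicro`, venous resistance `Rv` (micro-venous resistance
fixed at 0), arterial compliance `Ca`, and an intramyocardial compliance
`Cim` compressed by a ventricular pressure source `Pim` — the element that
makes coronary flow diastole-dominant. Left branches are compressed by an
LV-derived `Pim`, the right branch by an RV-derived one (all patients are
right-dominant). Units are CGS internally (1 mmHg = 1333.22 dyn/cm^2);
WSS is reported in Pa.

The state vector holds one pressure per capacitor: the systemic `C` plus
`(Ca, Cim)` per branch — the `Cim` state is carried relative to its `Pim`
source, so the source's time derivative never enters the equations.
Branch flows are algebraic in the nodal pressures; the aortic root
pressure solves the nodal flow balance by a Newton iteration that is
nonlinear only through the stenosis law. Integration uses
`deSolve::lsoda` (the `Cim * Ra` time constants can be stiff) with dense
output on a uniform grid of ~1 ms that lands exactly on every cycle
boundary; all reported quantities are read from the final cycle.

### The stenosis element

The trans-stenotic pressure drop is a viscous-plus-turbulent law:

  dP = Rv q + kt * rho/(2 A0^2) * (A0/As - 1)^2 * q |q|

with `A0` the reference lumen area, `As` the throat area at diameter
reduction `degree`, `Rv` the Poiseuille resistance of the throat radius
over the lesion length, and `kt = 1.52` (configurable). The drop is odd
in `q` and vanishes with the flow; at `degree = 0` only the viscous term
survives. Taking the throat radius over the *whole* lesion length makes
the viscous term an upper bound relative to the tapered geometry used for
the WSS profile; the consequences are discussed under Limitations.

### Driving waveforms

* **Inflow**: a skewed half-sine systolic pulse, zero in diastole, with
  exponent `gamma = 1 + 0.25/AVA`, so a stenotic valve (AVA 0.6 cm^2)
  ejects late-peaking and a replaced valve (2.4 cm^2) nearly half-sine.
  The pulse is normalised to integrate exactly to the stroke volume on
  its 1 ms grid. For the plain half-sine the peak is `pi*SV/(2*ET)`.
* **LV pressure** (`Pim`, left tree): a rise-plateau-decay template whose
  upstroke (150 ms half-cosine) *leads ejection by 60 ms* of isovolumic
  contraction. The peak defaults to aortic systolic pressure plus the
  Gorlin mean gradient `(SV/ET / (44.3*AVA))^2` — about +78 mmHg at AVA
  0.6 and +9 mmHg at 2.4. This gradient is the mechanical link between
  the valve and the coronary tree: pre-AVR the LV squeezes the
  intramyocardial bed far above aortic pressure, driving early-systolic
  flow reversal in the left branches; post-AVR the compression almost
  matches aortic pressure and the reversal disappears. The isovolumic
  lead matters — without it the compression current never beats the
  rising aortic pressure and no reversal occurs at all.
* **RV pressure** (right tree): the same template rescaled to the
  Doppler estimate `4 v_TR^2 + RAP` (simplified Bernoulli, RAP 5 mmHg
  default).

Heart rate is not reported per patient anywhere in the source tables, so
the cycle length is a configuration parameter, 60000/70 ms by default for
all patients and states.

## Boundary-condition tuning

Per patient-state, in order:

1. **Systemic RCR** (`tune_rcr`): total resistance starts at
   `P_mean/CO` on the systemic flow share and is rescaled each iteration
   to match the weighted mean `(P_sys + 2 P_dia)/3`; the compliance
   (initial 0.001 cm^5/dyn) moves proportionally to the pulse-pressure
   error on a 0.0002 cm^5/dyn grid; when that grid stalls, the proximal
   fraction (default 0.09 of total, the 7–11% convention) steps by 0.5%
   of total resistance as a fine pulse-pressure knob. Matching the
   weighted mean and the pulse pressure is equivalent to matching
   systolic and diastolic individually, so two knobs suffice. Iteration
   cap 25, tolerance 2 mmHg, short (2-cycle, warm-started) simulations
   inside the loop; non-convergence returns best-so-far with a flag.
2. **Coronary outlets, rest** (`tune_coronary`): per-branch target flows
   honour the 3:1 left:right *velocity* ratio between sides (velocities
   at a virtual left-main ostium of 2.25 mm radius and the RCA ostium)
   and Murray's law (`r^3`) within each side; total resistances start
   from projected distal pressures `P_mean*(1 - 0.1*degree)` and are
   rescaled multiplicatively (100 dyn s/cm^5 grid) until the simulated
   coronary fraction of cardiac output is within 0.05 pp of 4% and the
   velocity ratio within 1% of 3. On meeting the stopping rule the loop
   re-verifies on a longer near-periodic simulation, because a 2-cycle
   readout can sit ~1% off the converged orbit. Compliance totals
   (3.6e-5 left / 2.5e-5 right cm^5/dyn) are split by area share, 89%
   `Cim` / 11% `Ca`, and not iterated — there are no per-patient ostial
   pressure curves to fit them to.
3. **Hyperemia**: each branch's rest outlet resistance is scaled by
   `f_rest/f_hyper`, redistributed to the stress ratios
   (0.41:0.28:0.31 vs 0.32:0.52:0.16 at rest), and floored at 20% of its
   rest value — the maximal-vasodilation limit of the microvascular bed
   (a flow reserve of up to ~5). The loop then retargets the total
   fraction into the 10–12% band. When the floor binds on a severely
   stenosed branch, its unreachable flow share is redistributed to the
   unfloored branches of the same side: hyperemic flow *adapts to the
   stenosis*, which is exactly what depresses FFR and CFR. Without the
   floor, the tuner would force the Murray share through any stenosis
   and drive Pd toward zero.

## Indices and the WSS surrogate

`Pd` is sampled at the node immediately distal to the stenosis element,
`Pa` at the branch ostium (one negligible node from the aortic root; the
choice is exposed). FFR is the final-cycle mean `Pd/Pa` of the hyperemic
run; iFR the rest-mode ratio averaged over the wave-free window (25% into
diastole to 5 ms before end-diastole, diastole = end of ejection to cycle
end — the inflow is prescribed and noise-free, so no dicrotic-notch
detection); CFR the hyperemic over resting cycle-mean branch flow,
reported for the lesion branch and in total.

The WSS surrogate covers 15 mm upstream of the lesion through the lesion
end on an axial grid (0.25 mm default), with a raised-cosine radius taper
from the reference radius to the throat and back. Shear is Poiseuille,
`tau(x,t) = 4 mu q(t)/(pi r(x)^3)`, signed by the flow. TAWSS is the
cycle-mean of |tau| (trapezoid), OSI the standard
`0.5 (1 - |mean tau| / mean |tau|)`, both summarised over the region by
their mean (and median for TAWSS).

Two high-WSS fractions are computed. The profile-based one — axial
elements whose TAWSS exceeds `k = 4` times the regional mean — is
*invariant to rescaling the flow* under the Poiseuille surrogate: it is a
property of the radius profile alone and therefore identical before and
after the intervention for a fixed lesion. The pipeline's reported
`high_frac` is instead the *exposure* fraction: elements whose peak
instantaneous |tau| exceeds `k` times the regional mean TAWSS. That
depends on the peak-to-mean ratio of the flow waveform, so it responds to
the change in ejection dynamics — it is the formula-level analogue of
counting wall elements that ever see extreme shear.

## The synthetic cohort

`generate_cohort(n = 26, seed)` draws patients whose marginals match the
study population (truncated normals for age, stenosis degree
0.568 ± 0.0853 in [0.40, 0.71], lesion length 15.1 ± 4.36 mm in [8, 23],
stroke volume and ejection time; lognormals matched to the reported
median/IQR for AVA pre and post; a categorical lesion-vessel distribution
62/23/12/3.8%). Post states shorten ejection by 83.9 ms, add 2.31 mL of
stroke volume, replace the valve area, and resample the aortic pressures
with near-zero mean shifts. The paired SDs of those deltas are not
derivable from the published tables; defaults (15 ms, 3 mL, 3–4 mmHg) are
configuration choices.

Three within-pair variability channels are modelled deliberately:

* **Per-state effective stenosis degree** = QCA degree + N(0, 0.02):
  the pre and post geometric models of the study were segmented from
  separate acquisitions, and QCA/CT re-measurement variability of a few
  percent diameter is well documented. Without this channel the model's
  paired FFR noise is several times smaller than the published paired
  variability, and the small systematic flow-driven FFR shift would be
  declared significant — the opposite of the study's finding. The
  *lesion* fields (QCA degree, length, vessel) remain shared between
  states.
* **Per-state coronary fraction targets**: rest N(0.04, 0.002) truncated
  to [0.035, 0.045]; hyperemic N(0.11, 0.0075) truncated to the
  [0.10, 0.12] band — adenosine responses vary between sessions, and the
  band itself is the published tuning target.
* **Post-AVR TR velocity** drops by ~0.25 m/s (truncated at 0): pulmonary
  pressures relax after valve replacement, which lowers the RV `Pim` and
  gives right-coronary patients a same-direction (if small) shear
  response.

A noisy "invasive FFR" channel (`synth_invasive_ffr`) multiplies the
model FFR by `1 + eps/100`, `eps ~ N(-1.486, 1.938)`, mirroring the scale
of the published model-vs-invasive agreement, and feeds the Bland–Altman
analysis on a 10-patient validation subset. Comorbidity indicators are
generated for cohort realism but are inert in the model.

## Statistics

Every index and WSS summary is compared pre vs post with a Shapiro–Wilk
gate (alpha 0.05) on the paired differences choosing between the paired
t-test and the Wilcoxon signed-rank test. The Wilcoxon p-value is exact
(dynamic programming over the — doubled, hence integer — rank lattice,
zeros excluded by Wilcoxon's rule, midranks for ties) up to 25 nonzero
differences, with full sign enumeration available as an independent
oracle; beyond that a normal approximation with continuity correction,
tie-corrected variance and a fourth-cumulant Edgeworth term is used. On
the 3–5-point lattice no continuous approximation can track the exact
distribution to 0.01 (for differences 1,2,3 the exact two-sided p is
0.25); the approximation is validated at the handoff sizes and never used
below them. Bland–Altman differences are `reference - test`, as
percentage of the pair mean by default; limits of agreement are
bias ± 1.96 SD (n−1). Identical paired vectors return p = 1 by sign
symmetry; constant nonzero differences are refused as degenerate. No
multiplicity correction is applied.

## Numerical choices

* Integrator `lsoda`, rtol 1e-6, atol 1e-2 dyn/cm^2, `hmax = T/40`;
  output grid ~1 ms snapped to cycle boundaries.
* Default 7 cycles, results from the 7th; the periodicity residual (max
  relative change of cycle-mean pressure over the aortic root and all
  coronary outlet nodes) falls below 1% by cycle ~5 with the default
  pressure-primed initial state (`initial_state()`: capacitors at the
  mean-pressure target). From an all-zero cold start the arterial time
  constant (`R*C` ≈ 1.3 s) alone dictates ~10 cycles; priming is the
  standard practice and the package default.
* Newton solve of the root-pressure balance: monotone scalar residual,
  warm-started from the previous evaluation, tolerance 1e-6 dyn.
* Tuning loops use 2-cycle warm-chained "first-order" simulations,
  with a longer confirmation simulation before accepting convergence.
* Refinement: halving the output step and the WSS axial grid moves FFR,
  iFR, CFR and the regional TAWSS by well under 2% (the model-level
  analogue of a mesh-independence criterion).
* Problem sizes throughout (n = 26 cohort, 7 cycles, ~860 samples/cycle,
  ~120 axial WSS elements) are the study's own scales and run on one CPU
  in a few minutes.

## What passing tests do and do not show

The generator reproduces the *marginal* cohort statistics and the paired
design of the study, so the test suite demonstrates that the method —
tuning, simulation, indices, WSS summaries, statistics — behaves
correctly and reproduces the study's qualitative pre/post findings under
those conditions (indices stable; OSI and high-WSS exposure reduced;
resting and hyperemic flows slightly increased). It does not demonstrate
agreement with any real patient's hemodynamics: the branch geometry is a
literature-typical default (the study reports none), the stenosis law is
a 1D constitutive choice, and the WSS surrogate has no jets, recirculation
or secondary flow. Quantitative levels differ accordingly — e.g. regional
TAWSS of a few Pa against tens of Pa for 3D near-stenosis fields, and an
OSI change of ~0.02 against 0.32→0.21 in 3D.

## Known limitations

* The stenosis law's viscous term (throat radius over the full lesion
  length) is severe: at the cohort's median degree (~0.57) it yields FFR
  ≈ 0.55–0.63 where the study reports ≈ 0.80. Monotonicity and all
  comparative behaviour are unaffected; absolute index levels are not
  calibrated.
* iFR rises slightly but systematically after valve replacement in this
  model (~+0.03): the wave-free window samples diastole, pre-AVR
  diastole is ~100 ms shorter, so the same resting flow crosses the
  lesion at a higher instantaneous rate during the window. With the
  severe stenosis law this exceeds the within-pair noise, whereas the
  study found iFR unchanged — a documented divergence of the surrogate,
  not a tuning target.
* One lesion per patient; no serial lesions, no collaterals, no
  autoregulation dynamics (rest flow is pinned to its fraction target),
  no adenosine pharmacokinetics (hyperemia is a parameter set), no wall
  mechanics.
* Thresholds (FFR 0.80, iFR 0.89) are reported as classifications only;
  nothing here is clinical advice.

## Reproducing the analysis

```{r, eval = FALSE}
library(coroflow)
cfg <- run_config(n = 26, seed = 0)
res <- run_cohort(cfg)          # ~4 minutes on one CPU
st  <- cohort_stats(res)
st$paired
st$bland_altman
```

The numbered drivers under `analysis/` run the same workflow in stages
(cohort generation, simulation, statistics) and write their tables under
`results/`; `scripts/acceptance.R` recomputes the model-level
verification quantities from scratch.
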