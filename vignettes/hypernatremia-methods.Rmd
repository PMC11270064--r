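---
title: "Simulating acute hypernatremia in human ventricular cardiomyocytes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating acute hypernatremia in human ventricular cardiomyocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Acute hypernatremia — an abrupt rise of extracellular Na⁺, here modelled as
an equimolar NaCl elevation of 10, 20 or 50% — makes the extracellular
medium hyperosmotic. A ventricular cardiomyocyte exposed to such a medium
loses water within minutes: the osmotically active part of its volume
shrinks in inverse proportion to extracellular osmolarity, concentrating
every intracellular solute. In addition, patch-clamp studies of
hyperosmotically challenged ventricular myocytes report direct functional
changes of several membrane transport systems: the delayed rectifier
currents IKr and IKs and the Na⁺–K⁺ pump current INaK are depressed, the
Na⁺–Ca²⁺ exchange current INaCa is enhanced, while IK1 and (on the balance
of evidence) ICaL are unchanged.

`osmoAP` turns a hypernatremia level into this complete perturbation and
applies it to two endocardial human ventricular ionic models, paces them to
quasi-steady state, and extracts the standard action-potential and ionic
biomarkers. The questions it addresses are quantitative: how much does the
resting membrane potential (RMP) hyperpolarize, how much do APD50/APD90
prolong, what happens to the maximum upstroke velocity (dVm/dt)max, to the
threshold stimulus current Ith, and to intracellular Na⁺, K⁺ and Ca²⁺?

## The osmotic perturbation layer

Three ingredients define a condition (`hypernatremia_condition()`):

1. **Milieu.** NaCl is added equimolarly: `[Na⁺]e → (1+level)·[Na⁺]e` and
   `[Cl⁻]e` rises by the same amount; K⁺ and Ca²⁺ are unchanged. The two
   models use slightly different baselines (ToR-ORd: 140/5.0/1.8/150
   mmol/L of Na⁺/K⁺/Ca²⁺/Cl⁻; the BPS2020 slot: 144/5.4/2.7 with Cl⁻ from
   cation charge balance, 154.8).

2. **Current scaling.** Each scaled current has a single experimentally
   derived anchor — IKr 0.60 and IKs 0.50 at 50% hyperosmolarity, INaCa
   1.23 and INaK 0.60 at 30% — and factors at any level lie on the line
   through (0, 1) and that anchor (linear interpolation/extrapolation,
   rejected if a factor would reach zero, which the IKs line does at level
   1.0). ICaL and IK1 keep factor 1 in the default scenario; the apparent
   disagreement between hyperosmotic ICaL experiments is explored instead
   through the explicit scenario factors 0.72 and 1.45.

3. **Volume.** Osmolarity is defined as the plain sum of the four milieu
   concentrations; with an osmotically inactive volume fraction of 32%,
   the relative cell volume is
   `0.32 + 0.68 · osm₀ / osm(level)`.
   This single definition reproduces the working parameter table to two
   decimals (e.g. 78.21% for ToR-ORd and 78.28% for BPS2020 at 50%), and
   the implied concentration gain of a conserved solute in the active
   volume, `osm(level)/osm₀ − 1`, is 47% at 50% hypernatremia. Solute
   amount is conserved exactly:
   `(v − 0.32) · osm(level) = (1 − 0.32) · osm₀`.

Inside the ionic models the condition acts in exactly three places: the
maximal rates of the scaled currents are multiplied by their factors, the
extracellular concentrations are replaced by the perturbed milieu, and all
intracellular compartment volumes (myoplasm, network and junctional SR,
subspace) are multiplied by the relative volume. Membrane capacitance and
capacitive area are never altered — experimentally, osmotic shrinkage
leaves capacitance unchanged.

### Why concentrations are stepped at shrinkage onset

Shrinkage is applied as a step (the acute exposure settles within 2–3
minutes, fast compared to the 10-minute protocol, and no dynamic osmosis
model is attempted). When water leaves, the moles of each intracellular
solute stay behind, so the physically consistent post-shrinkage state has
every intracellular concentration multiplied by `osm(level)/osm₀`. The
package applies this step by default (`step_concentrations = TRUE`).

This default is not cosmetic. The hyperpolarization of the RMP under
hypernatremia is carried almost entirely by the K⁺ equilibrium potential:
with `[K⁺]e` fixed, `ΔEK = −RT/F · ln(1 + gain)`, which at 50%
hypernatremia is −10.3 mV. Membrane K⁺ turnover is orders of magnitude too
slow to concentrate `[K⁺]i` by 47% within 10 minutes of pacing (it would
require more than 1 A/F of sustained net K⁺ influx), so an un-stepped
simulation keeps its baseline `[K⁺]i` — and its baseline RMP — for the
whole protocol. The two initializations therefore do **not** converge on a
10-minute horizon for K⁺-dependent biomarkers; `osmoAP` keeps both code
paths, and the acceptance suite measures the disagreement rather than
hiding it. Fast subsystems (gates, Ca²⁺, and to a large extent Na⁺) do
relax to the same quasi-steady state either way.

## The ionic models

Both models are compiled ODE systems (deSolve's compiled-model interface;
plain C in `src/`) behind one interface: `initial_state()`,
`derivatives()`, `currents()`, `pace()`.

* **ToR-ORd** (`"ToRORd"`, 40 states): a reconstruction of the
  Tomek-Rodriguez endocardial model — Grandi-type Hodgkin-Huxley INa,
  the ToR-ORd ICaL with ionic-activity-corrected GHK driving force and
  80% of the channels facing the junctional subspace, the instantaneous
  ToR-ORd IK1, background and Ca²⁺-activated chloride currents with fixed
  intracellular Cl⁻ (24 mmol/L), and the O'Hara-Rudy pump/exchanger
  schemes at ToR-ORd maximal rates.
* **BPS2020 slot** (`"BPS2020"`, 41 states): the O'Hara-Rudy 2011
  endocardial backbone — the documented parent of the
  Bartolucci-Passini-Severi 2020 model — standing in for BPS2020, whose
  full revised equation set could not be transcribed here. Two of its
  documented contrasts with ToR-ORd are imposed: IKs is set an order of
  magnitude larger than ToR-ORd's, and Ito several-fold smaller.

Three parameters were calibrated once, each against a published baseline
of the corresponding source model, before any perturbation experiment was
run, and never revisited:

| parameter | value | anchor |
|---|---|---|
| ToR-ORd GKr (HH formulation) | 0.0677 mS/µF | baseline APD90 ≈ 270 ms at 1 Hz |
| BPS slot SERCA scale | 0.70 | baseline CaT peak ≈ 0.41 µmol/L at 75 min⁻¹ |
| BPS slot GKr (with GKs = 0.011) | 0.037 mS/µF | baseline APD90 ≈ 270 ms |

Both models use Hodgkin-Huxley IKr gating (Markov channel variants are out
of scope), which is one reason the ToR-ORd reconstruction distributes its
repolarization reserve differently from the original. With this
parameterization the ToR-ORd baseline diastolic `[Na⁺]i` comes out at
12.5 mmol/L at 75 min⁻¹ — matching its documented value without tuning —
which corroborates the reconstructed Na⁺ budget (GNaL, PNaK).

## Protocols

* **Pacing** (`pace()`): 1-ms current pulses at 50, 75 or 100 min⁻¹ for 10
  simulated minutes; the final 5 s are captured with ≤0.05 ms output
  resolution around each upstroke and ≤0.5 ms elsewhere. The stimulus is
  carried by K⁺, following the source models' convention, so long-run
  ionic drift behaves as published.
* **Threshold** (`find_threshold()`): bisection on the pulse amplitude,
  with "fires" defined as Vm exceeding 0 mV within 50 ms of pulse onset;
  convergence to a 0.5% relative bracket; the result is independent of the
  initial bracket and agrees with an exhaustive grid search on the
  analytic toy cell.
* **Self-consistency** (`run_condition()`): a provisional threshold is
  measured on the (stepped) initial state, the cell is paced at 2× that
  amplitude, the threshold is re-measured at the final quasi-steady
  diastolic state, and the cell is re-paced once if 2× threshold moved by
  more than 20%. The reported Ith is always the one measured at the
  quasi-steady state. The stimulus multiple is exactly 2.0.
* **Quasi-steady check** (`quasi_steady_check()`): beat-to-beat changes of
  APD90 and diastolic `[Na⁺]i` across the analysis window must both stay
  below 0.5%.

## Biomarkers

RMP is the pre-stimulus diastolic Vm (the quantity usually labelled RMP in
paced-cell studies); APA is peak minus RMP. APD50/APD90 run from the
instant of maximum upstroke velocity to the amplitude-referenced
repolarization levels `RMP + 0.5·APA` and `RMP + 0.1·APA`, with linear
interpolation between samples; measuring from the upstroke rather than
from stimulus onset removes the 1-ms latency ambiguity. (dVm/dt)max is
computed from pulse onset with the stimulus contribution — exactly
+amplitude while the pulse is on — subtracted, so the stimulus artifact is
excluded without losing upstrokes that complete within the pulse, which
happens at the large 2×-threshold amplitudes of strongly perturbed
conditions. EK and ENa are Nernst potentials from the diastolic
intracellular and the condition's extracellular concentrations at 310 K.
All reported values come from the last complete beat.

## Numerical choices

LSODA (adaptive stiff/non-stiff switching) with relative tolerance 1e-7
and per-variable absolute tolerances (1e-9 mmol/L on the µM-scale Ca²⁺
states, 1e-7 elsewhere, 1e-6 mV on Vm); each stimulus and each diastolic
interval is integrated as its own segment so the pulse is an exact square
wave rather than a discontinuity inside the solver. GHK flux factors use a
second-order series below |zVF/RT| < 1e-5 to avoid cancellation near 0 mV.
Biomarkers are insensitive to halving the output grid to well below 0.1%.
Nothing in the package uses random numbers; every run is bit-reproducible.

## Test fixtures

The analytic toy cell (`toy_model()`) — a K⁺ leak, a Na⁺ leak and a
regenerative inward current with fast activation and slower inactivation —
has a closed-form chord-conductance resting potential and a
threshold monotone in its conductances, so the pacing, bisection and
biomarker machinery is tested in milliseconds against exact oracles.
`synthetic_ap_trace()` provides piecewise-linear AP trains with closed-form
biomarkers for the extractor. Neither fixture mimics full-model AP
morphology; passing fixture tests validates the *machinery*, not the
ionic models, which are exercised by the full-protocol suite.

In the test suite the full 10-minute protocol is run for both models at
50 min⁻¹ (all four levels) and 75 min⁻¹ (baseline and 50%); the
monotone-trend sweep at 75 and 100 min⁻¹ uses a 90 s conditioning phase,
long enough for the trend directions (EK shift and conductance scaling act
immediately) while keeping the property suite fast.

## Fidelity and known limitations

* The BPS2020 slot is an O'Hara-Rudy backbone, not the true BPS2020
  equation set. Effects that hinge on BPS2020's private formulations are
  systematically underestimated: its APD90 prolongation and threshold
  increase at 50% hypernatremia (the latter driven, in the original, by an
  IK1 whose amplitude grows under hyperpolarization — a property of the
  BPS2020 IK1 current-voltage relationship that the backbone's IK1 lacks),
  and the 50%-hypernatremia calcium-transient peak.
* The ToR-ORd reconstruction concentrates more of its repolarization
  reserve in IKr than the original (HH IKr, calibrated GKr), so its APD90
  prolongation at 20–50% hypernatremia overshoots; its (dVm/dt)max
  response flattens slightly between 20% and 50% (ENa decline from the
  doubled `[Na⁺]i` offsets the availability gain) instead of rising
  monotonically.
* Epicardial/mid-myocardial variants, stretch-activated channels,
  T-tubule sealing, tissue-level conduction and contractile mechanics are
  out of scope; above ~22% hypernatremia real myocytes may additionally
  seal their T-tubules, which no single-cell ionic model captures.
* Shrinkage is a step; chronic, slowly developing hypernatremia — where
  cells regulate volume — is expected to show much smaller effects and is
  not modelled.

## A minimal session

```{r, eval = FALSE}
library(osmoAP)

cond <- hypernatremia_condition(0.5, "ToRORd")
cond

# full protocol at 50 stimuli per minute (about 10 s of wall time)
res <- run_condition("ToRORd", level = 0.5, rate = 50)
res$biomarkers

# the whole study grid
tab <- run_grid(models = c("ToRORd", "BPS2020"), rates = 50,
                levels = c(0, 0.1, 0.2, 0.5))
tab[, c("model", "level", "d_rmp", "pct_apd90", "pct_dvdt_max", "pct_ith")]
```
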