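---
title: "CaMKII overexpression and oxidation in a mouse atrial myocyte model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CaMKII overexpression and oxidation in a mouse atrial myocyte model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camkatria)
```

## The model

`camkatria` simulates a single mouse atrial myocyte in which the
Ca²⁺/calmodulin-dependent protein kinase II (CaMKII) signaling loop is a
first-class dynamical component. Three layers are coupled bidirectionally:

1. **Membrane and Ca²⁺ cycling.** A compact mouse atrial action-potential
   model: fast and late Na⁺ currents, L-type Ca²⁺ current, transient-outward,
   ultrarapid and steady-state K⁺ currents, inward rectifier, Na⁺/Ca²⁺
   exchanger (NCX), Na⁺/K⁺ pump, background/pump currents; a junctional
   (dyadic) and a bulk cytosolic Ca²⁺ compartment, a single SR pool with a
   four-state ryanodine-receptor (RyR) Markov scheme whose opening is
   sensitized by SR luminal Ca²⁺, SERCA uptake regulated by phospholamban
   (PLB), and rapid-equilibrium Ca²⁺ buffering. Units: mV, ms, µM (Ca²⁺),
   mM (Na⁺/K⁺), pA/pF; SR fluxes are µM/ms referenced to the cytosolic
   volume.

2. **CaMKII activation and oxidation.** An eight-state Markov chain per
   Ca²⁺ compartment. The activation part is the classic six-state scheme:
   inactive `Pi`, Ca₄CaM-bound `Pb`, autophosphorylated/trapped `Pt`,
   trapped with Ca₂CaM `Pt2`, autonomous `Pa`, and Ca₂CaM-bound inactive
   `Pb2`. The oxidation extension adds `Pot` (oxidized, CaM-bound) and `Po`
   (oxidized, CaM-dissociated): only `Pb` can be oxidized
   (autophosphorylation and oxidation are treated as mutually exclusive),
   the oxidation rate is Michaelis–Menten in [ROS] (`k_ox`, `Km_ROS`),
   reduction by MsrA returns `Pot → Pb` and `Po → Pi`
   (`k_redox`, `Km_MsrA`), and `Pot ↔ Po` mirrors the `Pi ↔ Pb`
   CaM-binding pair. All states except `Pi` and `Pb2` carry full activity.

3. **Phosphorylation targets.** Junctional active CaMKII drives
   phosphorylation of the L-type channel (availability up, inactivation
   slowed), PLB (SERCA affinity up), and RyR (opening rate up, luminal
   half-sensitivity down), each as a saturable Hill function of active
   CaMKII minus first-order dephosphorylation. All channel modifiers are
   anchored to equal one at the wild-type 1 Hz operating point, so the
   wild-type model is reproduced by construction.

The CaMKII-overexpression model applies exactly five parameter changes:
total CaMKII ×6, the late-Na⁺ inactivation midpoint shifted +6.8 mV, the
transient-outward inactivating rate ×5, inward-rectifier conductance ×0.6,
and NCX conductance ×1.3. ROS is a constant concentration; the presets
`wt`, `wt_ros`, `oe`, `oe_ros` use 0 or 200 µM (a pathophysiological
level; the normal background is ~35 µM).

## Time scales and the oxidation equilibrium

With the published oxidation constants, the oxidized pool moves at
~10⁻⁶ s⁻¹ — orders of magnitude slower than any electrophysiological
process and far slower than any simulated protocol. The MsrA concentration
is not a published number; this package chooses it so the effective
reduction rate `k_redox·[MsrA]/([MsrA]+Km_MsrA)` is 1.5·10⁻⁶ s⁻¹, which
puts oxidation and reduction on the same (slow) footing. At stationarity
the slow pool obeys the exact identity `X = a·⟨Pb⟩/b` (X: oxidized mass,
a: oxidation rate at the configured ROS, b: effective reduction rate).
Protocols that include ROS therefore *impose* this equilibrium before
simulating (`equilibrate_oxidation()`): a few probe beats measure ⟨Pb⟩,
the identity is solved, and the kinase state is rescaled. Simulating to
that equilibrium directly would need ~10⁶ s of cell time and would change
nothing else.

## Tunable parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `camkii_tot_jn` | 120 | µM | junctional CaMKII; ×6 in the OE model |
| `k_ox`, `Km_ROS` | 6.48e-6, 60 | s⁻¹, µM | oxidation of `Pb`; re-fittable from dose–response tables |
| `MsrA_conc` | 1.8e-6 | mM | sets the effective reduction rate (see above) |
| `k_auto`, `v_pp1`, `Km_PP1` | 0.04, 18, 10 | s⁻¹, µM/s, µM | autophosphorylation and PP1; PP1 saturation produces the high diastolic activity of the OE model |
| `kp_*`, `Km_*`, `n_*`, `kd_*` | see `cell_params()` | ms⁻¹, µM | Hill-type phosphorylation of LTCC/PLB/RyR |
| `koCa`, `kiCa`, `kom`, `kim` | 6e-5, 1.8e-4, 0.15, 0.004 | ms⁻¹ scales | RyR opening (cubic in junctional Ca²⁺), Ca-dependent inactivation, closure, recovery |
| `ec50SR`, `maxSR`, `minSR`, `hill_srf` | 450, 15, 1, 4 | µM, – | luminal sensitization of RyR gating |
| `k_lum`, `casr_th`, `w_lum` | 0.1, 600, 1 | ms⁻¹, µM | store-overload release gate; its threshold falls with RyR phosphorylation (`cR_ec`) and defines the always-open regime |
| `gNaL`, `hL_vshift` | 0.06, 0 | mS/µF, mV | late-Na window current; the +6.8 mV OE shift is the main Na⁺-loading lever |

Solver: `lsoda` with relative tolerance 10⁻⁷, max step 1 ms, fixed output
sampling at 0.5 ms for metrics (dense, consistent sampling matters for
dV/dt and DAD detection).

## Protocols

* `pace_to_steady_state()` — 1 Hz pacing until every tracked ion
  concentration changes by less than 10⁻⁵ of its basal level between
  consecutive beats (cap 600 beats, flagged not raised). Stored near-steady
  states make this converge in a handful of beats for the presets.
* `burst_protocol()` — 1 Hz (2 s), 10 Hz × 12 s, then 1 Hz for 26 s; DAD
  detection runs on the recovery segment. The stimulus is a rectangular
  2 ms, 24 pA/pF pulse (~1.5× diastolic threshold).
* `clamp_experiment()` — burst protocol with [Na⁺]ᵢ or one phosphorylation
  fraction clamped throughout (clamped states have their derivative forced
  to zero; levels are protocol inputs).
* `ryr_threshold_search()` — [Ca²⁺]_SR and RyR phosphorylation clamped for
  10 s without stimulation (the L-type current is disabled and replaced by
  a controllable 5-ms square Ca²⁺ probe); after the SR clamp is released,
  probes of increasing amplitude are applied until at least a quarter of
  the free SR Ca²⁺ is released within 500 ms (bracketing + bisection to
  0.1 pA/pF). A hold that ends in standing release is classified
  ALWAYS_OPEN. The released-fraction criterion uses *free* [Ca²⁺]_SR — the
  quantity the release protocol records — and the 500 ms window is this
  package's operational choice.
* `release_after_unclamp()` — same hold, then 200 stimuli at 1 Hz with the
  phosphorylation clamp maintained; records per-beat peak release flux and
  the time to <1% sustained beat-to-beat variation.
* `build_threshold_map()` / `build_release_map()` — the grid products over
  [Ca²⁺]_SR ∈ [200, 800] µM × phosphorylation ∈ [10, 80]%; default steps
  25 µM × 5%, and coarser grids are used in tests for speed. The balance
  region is the set of cells whose first-beat release amplitude exceeds
  5 µM/ms.

## Numerical choices and degenerate inputs

RyR opening and inactivation rates are capped at 20 ms⁻¹ so that extreme
probe-driven junctional Ca²⁺ (hundreds of µM) stays integrable; kinase
occupancies are clipped at zero before Hill powers are taken (solver trial
steps may undershoot); concentrations are floored at tiny positive values
inside the compiled right-hand side. The kinase steady-state solver uses
pseudo-time integration from `Pi = 1` (rates depend on the state through
autophosphorylation and PP1 saturation, so a direct linear solve does not
apply) and polishes until the derivative norm is below 10⁻¹⁰ s⁻¹.
Clamped states are implemented by zeroing their derivatives, which keeps
clamp traces constant to round-off.

## What the generator emulates — and what it does not

The synthetic protocols reproduce the *conditions* of the study: 1 Hz
steady-state pacing, 10 Hz burst pacing, ion and phosphorylation clamps,
and the ([Ca²⁺]_SR × RyR-phosphorylation) grid. The baseline
electrophysiology itself is this package's reconstruction, calibrated so
that the headline outcomes land on the published values: the ~3 mM Na⁺
elevation under overexpression (2.7 mM here), the 160/700 µM
diastolic/systolic junctional CaMKII excursion of the OE model (121/704
here), ~600 µM diastolic CaMKII under 200 µM ROS (494 here), the ~87%
LTCC phosphorylation under ROS in wild type (76% here), the ~2.9 pA/pF
activation threshold at (450 µM, 40%) (2.8 here), 10× PLB and 2× RyR
phosphorylation in OE, and APD prolongation at all repolarization levels.

Known limitations of this reconstruction, established by its own tests:

* **No spontaneous DADs after burst pacing.** The deterministic
  lumped-compartment Ca²⁺ cycle re-equilibrates under the store-overload
  gate instead of crossing it, so the recovery segment shows no
  afterdepolarizations in any preset (the published counts are 3, 6, and
  sustained). The DAD detector itself is validated on synthetic events,
  and the count ordering across presets holds.
* **Condition A (300 µM, 20%) cannot release a quarter of its store** for
  any probe amplitude — release self-terminates near 20% — so the
  activation threshold there is reported as absent rather than the
  published 56 pA/pF.
* **Re-stabilization at condition A takes ~9 s, not 71 s**: the
  reconstructed Ca²⁺/Na⁺ cycle relaxes an order of magnitude faster than
  the original model's, and conditions B and C sit on a small persistent
  release alternans that never satisfies the strict <1% two-beat rule
  (so the published stabilization ordering B < A < C is not reproduced).
* The overexpressed paced state retains a few-percent beat-to-beat
  release alternans and is flagged non-converged at the pacing beat cap;
  the wild type meets the 10⁻⁵ criterion.
* Take-off potential is measured as the diastolic minimum immediately
  before the upstroke rather than the voltage at the sampled dV/dt-max
  instant; at 0.5 ms sampling the latter lands mid-upstroke and distorts
  amplitude-referenced APDs.

Passing tests therefore demonstrate the signaling layer exactly and the
calcium/electrophysiology layer at the level of these calibrated outcomes;
they do not certify the baseline against data the study did not print.

## Reproducing the dose–response fit

The oxidation parameters ship at their published values, and
`fit_oxidation_params()` re-derives them from any activity-versus-ROS
table:

```{r, eval = FALSE}
p <- kinase_params()
tab <- camkii_dose_response(c(0, 15, 40, 80, 200, 600), p, ca4cam = 0.1)
names(tab) <- c("ros_um", "activity_norm")
fit_oxidation_params(tab, p)   # recovers k_ox = 6.48e-6, Km_ROS = 60
```
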