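# camkatria

Simulation of CaMKII overexpression and oxidation in a mouse atrial
myocyte: a single-cell electrophysiology and Ca²⁺-cycling model coupled to
an eight-state Markov chain of Ca²⁺/calmodulin-dependent protein kinase II
(CaMKII) activation and oxidation.

## Why

Atrial fibrillation is linked to Ca²⁺-handling instability, and CaMKII sits
at its hub: chronic overexpression and oxidative activation of the kinase
hyper-phosphorylate the L-type Ca²⁺ channel (LTCC), phospholamban (PLB) and
the ryanodine receptor (RyR), reshaping the action potential and
destabilizing SR Ca²⁺ release. This package is for modelers who want to
run those experiments in silico: steady-state and burst pacing, ion and
phosphorylation clamps, and RyR activation-threshold / release-amplitude
maps over the ([Ca²⁺]_SR × RyR-phosphorylation) plane.

## The model in brief

CaMKII occupancies evolve on the chain

```
Pi <-> Pb -> Pt <-> Pa <-> Pt2,  Pa -> Pi,  Pi <-> Pb2   (activation)
Pb -> Pot <-> Po,  Pot -> Pb,  Po -> Pi                  (oxidation)
```

with Ca₄CaM binding `k_ib·[Ca₄CaM]`, dissociation `k_bi`, oxidation of the
bound state at rate `k_ox·[ROS]/([ROS]+Km_ROS)`, and MsrA-catalyzed
reduction at `k_redox·[MsrA]/([MsrA]+Km_MsrA)`. All states except `Pi` and
`Pb2` are fully active; junctional active CaMKII drives Hill-type
phosphorylation of LTCC, PLB and RyR, which feeds back on the L-type
current, SERCA affinity, and RyR Ca²⁺ sensitivity. The CaMKII-overexpression
variant is exactly five parameter changes: CaMKII ×6, late-Na⁺ inactivation
shifted +6.8 mV, transient-outward inactivating rate ×5, I_K1 ×0.6,
NCX ×1.3. The membrane/Ca²⁺ platform is a compact mouse atrial model
(compiled C right-hand side, solved with deSolve's `lsoda`); see the
vignette in `vignettes/` for the full account, assumptions, and known
limitations.

## Worked example

```r
library(camkatria)

wt <- pace_to_steady_state(scenario_presets("wt"))
oe <- pace_to_steady_state(scenario_presets("oe"))

wt$metrics$apd90                       # 73.2 ms
oe$metrics$apd90                       # 108.2 ms  (prolonged under OE)
oe$state["Na_i"] - wt$state["Na_i"]    # 2.70 mM   (Na+ loading under OE)
range(oe$trace[, "camkii_act_jn"])     # 121 .. 704 uM active CaMKII

thr <- ryr_threshold_search(scenario_presets("wt"), 450, 0.4, init = wt)
thr$threshold                          # 2.8 pA/pF at 450 uM / 40% phos.

ryr_threshold_search(scenario_presets("wt"), 600, 0.6, init = wt)$always_open
# TRUE: at high load and phosphorylation the store releases with no probe
```

The numbers above are what the current calibration prints: the
overexpressed cell has a longer action potential at all repolarization
levels, carries ~2.7 mM more Na⁺, and its junctional CaMKII swings between
~120 µM (diastole) and ~700 µM (systole); the RyR activation threshold
collapses from tens of pA/pF at low load/phosphorylation to ~3 pA/pF at
(450 µM, 40%) and to spontaneous release in the upper-right corner of the
map.

A command-line front end wraps the same functions:

```sh
exec/camkii-atria run oe_ros --protocol burst --out out/
exec/camkii-atria map wt --type threshold --out out/
exec/camkii-atria fit inst/extdata/dose_response_synthetic.csv
exec/camkii-atria fixtures fixtures/
```

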