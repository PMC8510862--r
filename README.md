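# clotlyse

Kinetic modelling and turbidimetric analysis of fibrin clot formation and
lysis, for coagulation researchers working with plate-reader clot-lysis
assays and for modellers studying fibrinolysis kinetics.

## What it does

A turbidimetric clot-lysis assay mixes fibrinogen, tPA, plasminogen and
PAI-1, and records light intensity once per minute while a clot forms
(turbidity falls) and then lyses (turbidity recovers). After min-max
normalization (NT ∈ [0, 1]), the lysis phase splits into a *linear slow
regime* and a *sigmoidal fast regime*. `clotlyse` provides:

* **Turbidity analysis** — slicing, Savitzky–Golay smoothing (window 11,
  order 3), normalization, and detectors for the clot formation time (CFT,
  the turbidity minimum), the slow-regime line (least squares between the
  NT = 0.01 and 0.075 crossings), the slow-lysis time (SLT, backward scan
  for the departure from that line by Δ = 0.005), the total lysis time
  (TLT, maximal NT derivative) and the end of lysis (NT = 0.95). TLT = SLT
  + FLT, with regime ratios R_SL = SLT/TLT, R_FL = 1 − R_SL.
* **Clot formation model** — a polymerization cascade (fibrinogen →
  monomers → oligomers → protofibrils → fibers; total fibrin conserved
  exactly) coupled to tPA/Pg adsorption on fibrin binding sites
  (q_tPA = 1.5, q_Pg = 2.4 sites per monomer), Michaelis–Menten plasmin
  generation, and PAI-1 inhibition of free tPA. Fiber radius from
  protofibril packing, R_f = sqrt((f_n^tot/f_r)/(π p₀)), p₀ = 0.01116
  protofibrils/nm².
* **Fibrinolysis model** — bound plasmin cleaves the fibrin exposed on the
  κ outermost protofibril "shells" of each fiber
  (dL/dt = γ·k_Pn2·[Pnᵇ]·Θ_Pn/(K + Θ_Pn), γ = 0.1); the radius shrinks as
  R_f² = R_f0²(1 − L/C_fr0), porosity rises accordingly, and fluid and
  bound phases exchange through (1−ε)/ε. Shell policies: surface-only
  (κ = 0), full volume (κ = κ_max), fixed κ, or an arbitrary schedule.
* **Shell optimizer** — greedy per-step fit of κ(t) against a target lysis
  curve on a 0.1 s grid, plus regime-normalized aggregation of the shell
  fraction φ = κ_opt/κ_max.
* **Surrogate model** — draws φ from regime-specific empirical
  distributions, the regime decided by the normalized radius
  (slow while R̃_f > 0.9; the fast regime ends at 0.6).
* **Parameter machinery** — grid evaluation with fiber-diameter and
  ≥ 80% incorporation filters, rank-based scoring of maximal lysis-curve
  errors (normalized by the worst case S·E), and Sobol sensitivity
  analysis via the Saltelli scheme with bootstrap intervals.
* **Synthetic data** — seeded 8-channel turbidity assays (phenomenological
  piecewise curves or full forward-model traces) with ground truth, plus
  the packaged 19-condition experiment table (74 replicates).

## Worked example

```r
library(clotlyse)

## simulate the control assay's clotting phase (1000 s)
clot <- run_clot_formation(list(fibrinogen = 3, tpa = 0.001,
                                pai1 = 0.01, pg = 13))
clot
#> <clot_state> after 1000 s of clotting
#>   rf0 68.7 nm | incorporation 83.4% | eps0 0.991066
#>   tPA bound 3.01e-07 uM (2.05% of initial) | Pg bound 0.023 uM

## a synthetic assay with the study's mean timescales, analyzed end to end
assay <- generate_phenomenological(synthetic_assay_config(seed = 1))
analyze_trace(assay$traces[[1]], keep_every = 1L)
#> <lysis_timescales> channel ch1
#>   CFT 21.0 min | SLT 82.0 | FLT 55.0 | TLT 137.0 | end of lysis 214.0 min
#>   slow slope 0.001373 NT/min | R_SL 0.599 | R_FL 0.401 | delta turbidity 699.5
```

The clot state says that after 1000 s, fibers of ~69 nm radius hold 83% of
the fibrinogen and about 2% of the tPA is fibrin-bound (the rest is mostly
neutralized by PAI-1 — only bound tPA drives lysis). The trace analysis
recovers the generator's configured landmarks to within a sample or two of
the 0.5% sensor noise: clot formation near 19 min, a slow lysis regime of
~82 min at slope 0.00137 NT/min, the fastest lysis ~137 min after the
minimum, and 60/40 slow/fast regime ratios.

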