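---
title: "Modelling fibrin clot formation and lysis from turbidity assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling fibrin clot formation and lysis from turbidity assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clotlyse)
```

## The system being modelled

In a turbidimetric clot-lysis assay, fibrinogen, tissue plasminogen
activator (tPA), plasminogen (Pg) and plasminogen activator inhibitor 1
(PAI-1) are mixed, a clot forms, and a photodetector records the light
intensity through the cuvette once per minute. The signal first falls as
fibrin fibers assemble and scatter light (clot formation), then rises back
as plasmin dissolves the fibers (lysis). After min-max normalization of the
curve (normalized turbidity, NT, in $[0,1]$), three landmarks summarize the
kinetics:

* **CFT** (clot formation time): time to the turbidity minimum;
* **SLT** (slow lysis time): duration of a remarkably *linear* slow rise of
  NT after the minimum;
* **FLT** (fast lysis time): from the end of the slow regime to the point of
  maximal NT derivative. **TLT** = SLT + FLT.

The package's central hypothesis (shared by the models it implements) is
that the slow/fast dichotomy reflects the *reaction depth* into the fiber
cross-section: early lysis only engages the outermost protofibril layer of
each fiber, late lysis reaches the whole volume. The depth is expressed as
a number of "shells" $\kappa$: concentric protofibril layers of thickness
$r_0$ (a protofibril radius) counted from the fiber surface. $\kappa = 0$
is surface-only chemistry and $\kappa = R_f/r_0$ is full-volume chemistry.

## Clot formation

Polymerization is a number-density cascade (molecules/L): fibrinogen
$f_a$ is activated to monomer $f_1$ at rate $k_A$; monomers add to
oligomers $f_j$ ($j \le 10$) at rate $k_{PI}$; an oligomer of 11 monomers
is a protofibril $f_n$; monomers also elongate protofibrils ($k_{PG}$);
protofibrils aggregate pairwise into fibers ($k_{FI}$), add to fibers
($k_{FG}$), and fibers aggregate ($k_{FA}$). Bookkeeping totals track
protofibrils in fibers ($f_n^{tot}$), fibrin in protofibrils ($C_{fn}$) and
fibrin in fibers ($C_{fr}$). The cascade conserves total fibrin
$f_a + f_1 + \sum_j j f_j + C_{fn} + C_{fr}$ exactly; the test suite checks
this against an independent reaction-by-reaction stoichiometry oracle.

The average fiber radius follows from cylindrical packing,
$R_f = \sqrt{(f_n^{tot}/f_r) / (\pi p_0)}$ with packing density
$p_0 = 0.01116$ protofibrils/nm². The protofibril count in the $\kappa$
outer shells is the annulus integral
$m = \pi p_0 \left( 2 r_0 R_f (1+\kappa) + r_0^2 (1-\kappa^2) \right)$,
and the binding-site concentration for a protein with $q$ sites per fibrin
monomer is
$\Theta = (C_{fr}/f_n^{tot}) \; m \; q \; f_r / N_{av}$
(monomers per protofibril x protofibrils in the reacting shells x sites per
monomer, scaled to a molar concentration by the fiber number density). The
site densities are $q_{tPA} = 1.5$ and $q_{Pg} = 2.4$ per monomer.

Concurrently, tPA and Pg adsorb reversibly to those sites (mass action,
Table-2-style constants), bound tPA activates bound Pg to plasmin through a
Michaelis-Menten term, and PAI-1 inhibits free tPA irreversibly. During
formation only surface adsorption is allowed ($\kappa = 0$). Integration
uses a stiff adaptive solver (`deSolve::lsoda`, rtol $10^{-8}$) for 1000 s,
a typical clot formation time.

```{r formation}
clot <- run_clot_formation(list(fibrinogen = 3, tpa = 0.001,
                                pai1 = 0.01, pg = 13))
clot
```

With the default (best-ranked) rate constants and the control assay
concentrations, about 2% of the initial tPA ends up fibrin-bound -- the
fraction that matters, because free tPA is quickly neutralized by PAI-1
while bound tPA keeps producing plasmin.

### Parameter choices worth knowing about

* **Protofibril radius `r0 = 2.5` nm.** The packing density
  $p_0 = 0.01116$ protofibrils/nm² allots 89.6 nm² of cross-section per
  protofibril. A 2.5 nm protofibril radius (5 nm diameter, the standard
  literature figure) gives a 22% protein packing fraction, matching the
  known protein content of hydrated fibrin fibers; a 5 nm radius would
  imply an implausible 88%. This choice also independently reproduces the
  ~2% bound-tPA benchmark.
* **`kPG = 1e-15` L/(molecules s).** The printed source value of this
  protofibril-growth constant ($10^{15}$) exceeds the diffusion limit by
  roughly thirty orders of magnitude and destabilizes the integration; it
  is treated as a typographic sign loss. The constant is configurable.
* **$\Theta$ as a concentration.** The sites-per-fiber expression is
  multiplied by the fiber number concentration over Avogadro's number so
  that the mass-action binding equations are dimensionally consistent
  (`theta_literal = TRUE` exposes the raw per-fiber count).
* **Molecular weights** (fibrinogen 340, tPA 68, Pg 92, PAI-1 43 kDa) are
  literature standards and configurable.
* The `kFA`-driven term in the protofibril bookkeeping is implemented
  exactly as the model prints it; it affects only the bookkeeping total
  (fiber-fiber aggregation slightly inflates $f_n^{tot}$), not fibrin mass.

## Fibrinolysis

Lysis starts from the end-of-clotting state. Bound plasmin cleaves exposed
fibrin at Michaelis-Menten rate, and a fraction $\gamma = 0.1$ of cleaved
fibrin is solubilized:
$dL/dt = \gamma k_{Pn2} [Pn^b] \, \Theta_{Pn} / (K_{PnM} + \Theta_{Pn})$.
Since degradation proceeds from the fiber surface inward, the radius
shrinks with cumulative lysis, $R_f^2 = R_{f0}^2 (1 - L/C_{fr0})$ -- the
unique normalization consistent with proportionality to $L$, constant fiber
length, and $R_f = 0$ at complete lysis (the grouping of the raw
fiber-length/clot-volume constants in the source expression is ambiguous;
this form pins it by its limits). The porosity follows as
$\varepsilon = 1 - (1-\varepsilon_0)(R_f/R_{f0})^2$, with
$\varepsilon_0$ computed from the fibrin volume fraction at the end of
clotting.

During lysis, bound concentrations are defined per fibrin-phase volume and
free concentrations per fluid-phase volume; the two phases exchange through
the volume ratio $(1-\varepsilon)/\varepsilon$. The coupling is applied to
the adsorption/desorption exchange fluxes (not the full bound derivative),
which is the form that actually satisfies the stated conservation law
$[i] + \frac{1-\varepsilon}{\varepsilon}[i]^b = [i]_0$ for the conserved
lineages: applying it to the full derivative would replenish free Pg upon
activation and drive free plasmin negative. Desorbed plasmin accumulates in
the fluid and does not rebind (fluid-phase plasminogen activation is orders
of magnitude slower than surface activation and is omitted). The lysis rate
carries a $(1-\varepsilon)$ factor so $L$ is expressed per clot volume,
comparable with $C_{fr0}$.

Integration is fixed-step explicit Euler at $\Delta t = 0.1$ s -- the same
grid the shell optimizer uses, so the two run in lockstep. The binding
rates are slow enough (fastest relaxation ~$10^{-2}$/s) that this is
comfortably stable; halving the step moves the lysis timescales by well
under 0.5% (tested). Runs stop at exhaustion
($L \ge (1-10^{-6}) C_{fr0}$, guarding the $(1-\varepsilon)/\varepsilon$
singularity) or at `t_max`.

```{r lysis}
surface <- run_fibrinolysis(clot, "surface", t_max = 20000,
                            record_every = 1000L)
bulk <- run_fibrinolysis(clot, "bulk", t_max = 20000, record_every = 1000L)
trajectory_timescales(bulk)
```

Surface-only chemistry is always slower than full-volume chemistry (a
consequence of $\Theta$ increasing with $\kappa$, verified pointwise in the
tests), bracketing every intermediate policy.

## Fitting the reaction depth to a lysis curve

`fit_shell_schedule()` implements greedy one-step-lookahead fitting: at
each step, a trial step of the lysis equations is evaluated for every
admissible $\kappa \in \{0, \dots, \kappa_{max}\}$
($\kappa_{max} = \lceil R_f/r_0 \rceil$, shrinking with the fiber), and the
$\kappa$ whose next-step lysed fraction is closest (squared error) to the
target curve is committed. NT is used as a proxy for the lysed-fibrin
fraction. Ties break to the smallest $\kappa$ (most conservative reaction
depth). The procedure is deliberately sequential -- no global optimization
-- and its per-step optimality, determinism, and dominance over both fixed
extremes (surface-only and volume-only) are tested by exhaustive candidate
replay.

Two degeneracies are worth knowing. Before any plasmin exists, every
$\kappa$ predicts the same (zero) lysis and the tie rule pins the schedule
at the surface; and past ~99% lysis the candidates become indistinguishable
again. Round-trip accuracy (recovering a known fixed $\kappa^*$ from its
own forward run) is therefore assessed on the informative window between
those regimes, where recovery is essentially exact.

`aggregate_phi()` reproduces the regime-normalized summary of fitted
schedules: each run is split into slow, fast, and end-of-lysis regions
(end of lysis at NT = 0.95), time within each region is normalized to
$[0,1]$ and binned into 10 bins, and the shell fraction
$\phi = \kappa_{opt}/\kappa_{max}$ is summarized per bin by median and
quartiles.

## The surrogate model

The surrogate replaces curve fitting with sampling: per-simulation mean
shell fractions in the slow and fast regimes form two empirical
distributions; at each step of a surrogate run the regime is decided by the
normalized radius ($\tilde R_f > 0.9$: slow; below: fast), $\phi$ is drawn
from the corresponding distribution (uniformly over the stored samples, no
kernel smoothing -- the smallest assumption set), and
$\kappa = \mathrm{round}(\phi \, \kappa_{max})$. The slow-to-fast
transition maps to the first crossing of $\tilde R_f = 0.9$ and the fast
regime ends at $\tilde R_f = 0.6$. The draw cadence defaults to every step
and is configurable (`every_n`, `once_per_regime`); with point-mass
distributions all cadences coincide and the surrogate degenerates exactly
to a fixed-$\kappa$ policy (tested). Draw streams are seeded and the seed
is recorded in the output.

Across seeds, the surrogate's median SLT and FLT fall between the
surface-only and volume-only extremes when the $\phi$ distributions are
spread over interior values, as fitted distributions are. With degenerate
point masses at the extremes (slow $\phi \approx 0$, fast
$\phi \approx 1$) the FLT bracketing can fail for an instructive reason:
the surrogate then enters its fast regime much later than the volume model
does, having accumulated more plasmin, and crosses the fast window more
quickly. The acceptance suite builds the distributions the way the study
does -- from schedules fitted to assay-shaped targets -- and verifies the
bracketing under those conditions.

## Parameter selection and sensitivity

`evaluate_grid()` screens polymerization-rate combinations: each set is
simulated for 1000 s at several fibrinogen concentrations under control
protein levels and kept only if the fiber diameter $2R_{f0}$ falls in a
supplied acceptance window at every concentration and at least 80% of
fibrinogen is incorporated into fibers. The diameter window comes from
electron-microscopy measurements and is deliberately a required argument,
not a default. (Note that the packaged default rate set itself meets the
80% incorporation bar only at fibrinogen $\ge 3$ mg/mL within 1000 s.)

`rank_score()` scores candidate sets across experiments by summed rank of
the maximal lysis-curve error up to the TLT (`max_error()`): per
experiment, sets are ranked by increasing error -- ties get the average
rank, undefined errors rank last -- and ranks are summed and normalized by
the worst case $S \times E$ (with 92 sets and 74 experiments, 6808). Rank
aggregation penalizes a set's worst behavior regardless of error scale.

`sobol_sensitivity()` implements variance-based sensitivity analysis with
the Saltelli radial design (matrices $A$, $B$, $A_B^{(i)}$, and
$B_A^{(i)}$ for second-order terms), the Jansen estimators for first- and
total-order indices, the Saltelli 2002 estimator for second-order indices,
and bootstrap confidence intervals. No installed package provides these
estimators, so they are implemented here and validated against the closed
form for additive functions (for $y = \sum a_i x_i$ with uniform inputs,
$S_1^{(i)} = a_i^2 / \sum a_j^2$). `sobol_clot_formation()` wires the
design to the six polymerization constants (log-uniform) with bound tPA and
$R_{f0}$ as outputs.

## Synthetic assays

No raw turbidity traces are distributed with the assay study, so the
package generates its own, at two levels of realism.

**Phenomenological** (`generate_phenomenological()`): a piecewise curve
with a cosine clotting descent reaching its minimum at the configured CFT,
a linear slow ramp of configured slope and duration, and a logistic fast
rise placing the maximal derivative at CFT + SLT + FLT, mapped affinely to
sensor units with additive Gaussian noise (default s.d. 0.5% of the
dynamic range; sensor noise is otherwise uncharacterized). Defaults follow
the assay study's mean timescales -- CFT 19 min, slow ramp 73 min, fast
regime 67 min -- with the slow slope $0.1/73$ NT/min so the ramp ends near
NT = 0.1, where the slow regime characteristically terminates. Up to 8
channels with independent noise share one ground truth.

Two deliberate design points:

* The logistic steepness is chosen (by default) so the fast segment joins
  the ramp with *matching slope*. A sigmoid whose entry slope is below the
  ramp's makes the curve dip under the regime line and re-cross it, which
  makes the departure point ill-defined.
* The ground-truth SLT is the point where the continuous noise-free curve
  departs from the slow-regime line by the detection threshold
  $\Delta = 0.005$ -- the same operational definition the analysis uses --
  computed at generation time (the end of the linear ramp is also reported,
  as `ramp_end`). A smooth curve cannot leave its tangent line by a finite
  $\Delta$ instantaneously, so anchoring the ground truth at the ramp end
  would build a systematic few-minute bias into every round-trip
  comparison.

Detector accuracy is assessed at the *absolute curve positions* of the
landmarks (CFT, CFT+SLT, CFT+TLT): SLT and TLT are reported as offsets from
the detected CFT, so comparing offsets directly would double-count the
CFT's own one-sample quantization error.

**Mechanistic** (`generate_mechanistic()`): the full forward model --
clot formation, then lysis under a surface-then-bulk schedule (surface
shells while $\tilde R_f > 0.9$, full volume after) -- with the lysed
fraction mapped to intensity. These curves reproduce the qualitative assay
signature (near-linear slow segment, $R^2 > 0.99$ in the fit window, then a
convex fast segment), which is what passing tests demonstrate. What they
do *not* show: real sensor artifacts, baseline drift, channel crosstalk,
or biological variance between replicates; and the turbidity-intensity map
is an affine proxy, not optical physics.

## What the tests run, and why those sizes

The test and acceptance suites scale the simulations to desk size. Lysis
dynamics are exercised on a clot formed with tPA at 0.1 ug/mL (100x the
control assay): plasmin production scales with bound tPA, so complete
lysis takes ~20 simulated minutes instead of many hours, with every
mechanism untouched. The slow/fast/surrogate comparisons that the study
frames on the control condition *are* run on the control clot state (up to
60000 simulated seconds; 50 surrogate seeds). Shell-optimizer round trips
use exact-grid targets from the integrator itself, with a trace of
pre-formed bound plasmin ($10^{-4}$ uM) so the shell candidates are
distinguishable from the first step. Sobol checks use the additive
closed-form oracle at base sample 1024.

## Known limitations

* Fibers shrink homogeneously; transverse cutting and fiber transection
  are not modelled, nor is any spatial structure (no lysis front, no
  diffusion or advection, no network branching).
* No alpha-2-antiplasmin or TAFI: plasmin, once made, is only removed by
  desorption, so late-stage lysis is faster than in plasma.
* The clot-formation model omits fibrinopeptide-B kinetics,
  thrombin-fibrinogen complexes and oligomer-oligomer ligation.
* Porosity enters only through the phase-exchange factor; the printed
  radius-lysis and porosity relations are used in normalized form.
* With the packaged defaults the slow-regime curvature of simulated lysis
  is stronger than in real assays (plasmin keeps accumulating), so the
  turbidity-based SLT and the radius-threshold SLT agree only to within a
  fraction of the slow regime.
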