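---
title: "A reduced neuromuscular model of stick-insect front-leg searching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced neuromuscular model of stick-insect front-leg searching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(sticksearch)
```

## The system being modelled

When a stick insect's front leg finds no foothold it performs rhythmic
*searching* movements.  With the thorax–coxa joint fixed, the leg moves in a
vertical plane and two degrees of freedom remain: the femur elevation
`beta` at the coxa–trochanter (CTr) joint, actuated by the
levator–depressor muscle pair, and the interior femur–tibia (FTi) angle
`gamma` (180° = fully stretched), actuated by the extensor–flexor pair.
The tarsus elevation `alpha` is a derived quantity, computed from `beta`,
`gamma` and the segment lengths; it is never integrated on its own.

Each muscle pair is controlled by a local network with the same layout:

* a half-centre central pattern generator (CPG) of two reciprocally
  inhibitory cells — C3/C4 for the levator–depressor (LD) system, C5/C6
  for the extensor–flexor (EF) system — driven by constant central
  conductances `g_app3..g_app6`;
* four inhibitory premotor interneurons per network (IN7–IN10, IN13–IN16),
  each excited by one CPG cell and inhibiting one motoneuron, themselves
  under constant central inhibition `g_d7..g_d16`;
* four motoneurons per network — fast and slow levator/depressor
  MN(LF), MN(LS), MN(DF), MN(DS), and fast and slow extensor/flexor
  MN(EF), MN(ES), MN(FF), MN(FS) — under a uniform central drive `g_MN`.

The two networks are coupled exclusively by position signals reduced to
*two-valued* synaptic conductances: `g_gamma` acts on IN12 (which inhibits
C3) and `g_beta` acts on IN18 (which inhibits C6).  Each gate takes its
high value when its angle is at or above a threshold (`gamma_thr`,
`beta_thr`) and its low value below, with no hysteresis and ties going to
high.  The canonical thresholds are `gamma_thr` ∈ {83°, 145°} and
`beta_thr` ∈ {−4°, 4°, 16°}.

## Cell, muscle and joint dynamics

The governing equations of the original network are published elsewhere;
this package adopts the simplest dynamics class that reproduces the
constrained behaviour.  Each CPG cell has a fast activity variable $v$ and
a slow recovery (adaptation) variable $a$:

$$\tau_v \dot v = -v + g_\mathrm{app} - b\,a - \textstyle\sum_j w_j y_j,
\qquad \tau_a \dot a = -a + y, \qquad
y = \sigma\!\left(\frac{v - \theta}{k}\right),$$

with sigmoidal outputs in $[0,1]$ and synaptic inputs entering as signed
conductance-weighted outputs.  Reciprocal inhibition plus slow recovery
yields the classic half-centre alternation in the *release/escape* regime:
a cell's burst ends as its recovery variable builds up, and the silent cell
escapes as its own recovery decays.  Interneurons and motoneurons are
first-order sigmoidal units.  No random numbers are used anywhere in the
core: all states start from the quiescent point with a fixed small offset
on C3 so the half-centres leave the symmetric state deterministically.

Muscle pools have first-order activation towards
`mn_output × active_fraction`.  Deactivation (3 ms) is much faster than
activation (25 ms fast, 120 ms slow), so that silencing the drive hands
the posture over to the passive rigidity almost immediately — this is what
lets the leg hold its pose during obstacle contact.  Joints are overdamped
and first order (no inertia, no gravity): each pool pulls its joint
towards its fully contracted angle in proportion to its activation, and a
weak passive stiffness pulls towards each muscle's rest angle.  `gamma` is
clamped to (0°, 180°] with zero rate at the stretched stop.

### Why the two state-diagram shapes emerge

With `gamma_thr = 83°` the `gamma` oscillation stays above threshold, so
`g_gamma` remains high, IN12 stays silent, and the LD system free-runs
(tonic regime).  The flexor cell C6 is gated by `beta` through IN18: it can
only escape while `beta` is below `beta_thr`, which happens around the
`beta` minimum.  The resulting flexion burst produces a rapid `gamma` dip
at the bottom of the `beta` cycle, and tibia re-extension proceeds
*concurrently* with femur elevation — a three-cornered (`triangular`)
`beta`–`gamma` loop.

With `gamma_thr = 145°` the gate switches every cycle.  While
`gamma < 145°` IN12 is active and clamps the levator cell C3, so the femur
is held down until the tibia has re-extended past threshold; the
re-extension and the elevation are *sequential*, which inserts a fourth
corner (`quadrilateral` loop).  The loop shape before the obstacle is thus
decided by `gamma_thr` alone, for every `beta_thr`.

## The obstacle protocol

`run_obstacle_experiment()` implements the perturbation protocol:

1. the unperturbed rhythm is established (detection armed only after
   `pre_duration`, default 9 s, so at least three full cycles precede
   contact);
2. at the first *downward* crossing of the obstacle position `PO` by
   `alpha`, the joint angles are frozen and every motoneuron drive
   multiplier is set to 0 for `contact_duration` (default 100 ms).
   Contact is modelled as a kinematic hold plus silencing, not as a
   contact force: with the drives gone and deactivation fast, the passive
   rigidity keeps the angles essentially constant;
3. on removal, the staged reactivation starts: the fast extensor and
   flexor motoneurons return immediately (they have a single motoneuron
   each, so no gradation is possible); all slow motoneurons ramp to full
   drive within `slow_ramp` (200 ms); and the fast levator and depressor
   pools are *gradually* re-recruited, their active fraction ramping over
   `base_duration × rf(PO)`.

The recruitment slow-down factor is the linear interpolation

$$rf = \frac{rf_1 - rf_0}{PO_1 - PO_0}(PO - PO_0) + rf_0,$$

floored at 1 (`rf = 1` is the normal rate; `rf = 2` means recruitment is
twice as slow).  Two interpolation sets are used: set A for low
`beta_thr` (≤ 6°) and set B for high `beta_thr` (> 10°), with separate
lines for the levator and the depressor.  The published figures do not
print the endpoint values, so the defaults here are documented,
overridable placeholders (set A: levator 1 → 3 and depressor 3 → 1 over
PO ∈ [−40°, 25°]; set B: the same shape with maxima of 2), chosen so that
recruitment at the most effective obstacle positions takes an order of
magnitude longer than one second.

`base_duration` defaults to 4000 ms so that even at `rf = 1` the
re-recruitment spans several movement cycles; this is what makes the
post-removal amplitude growth and the threshold-grazing phenomena below
visible at all.

### Recovery phenomenology

The qualitative recovery regimes arise from one common cause: during
re-recruitment the `beta` oscillation is small, so whether the flexion
gate (`beta < beta_thr`) is ever reached decides the fate of the `gamma`
rhythm.

* **Cessation (stretched leg).**  At `beta_thr = −4°` the recovering
  `beta` band stays above threshold for the whole recruitment ramp: C6 is
  never released, the tibia stays extended near 170°, and only up–down
  movements remain, for essentially every obstacle position.  At
  `beta_thr = 4°` the band reaches threshold earlier and the quiescent
  period is shorter.
* **Alternating amplitude.**  Near the end of the quiescent period the
  `beta` minima *graze* the threshold, and the flexor's slow recovery
  (whose time constant is comparable to the cycle period) is only
  marginally complete at each release window.  A full flexion burst leaves
  the flexor too recovered-depleted for the next window, which yields a
  partial dip, after which a full burst follows again — a period-2
  (alternans-like) `gamma` oscillation.  With the wide release windows of
  `beta_thr = 16°` the flexor always recovers in time, so alternation
  never occurs there.
* **No qualitative change.**  At `beta_thr = 16°` the gate is reached even
  by the small early oscillation and the rhythm simply grows back.

## The analysis layer

* `extract_cycles()` delimits cycles at successive upward mean crossings
  and discards partial cycles.
* `average_loop()` collapses a multi-cycle trace to its cycle-averaged
  `beta`–`gamma` loop on a common phase grid.
* `classify_loop()` operationalises the by-eye triangle/quadrilateral
  distinction: normalise (translation- and scale-invariant), resample by
  arc length, simplify with a perpendicular-distance tolerance of 5% of
  the loop bounding-box diagonal, and count the *dominant* vertices.  A
  vertex is dominant when its turning angle is at least 40°; gentler
  inflections are merged into their edges, and near-coincident vertex
  pairs produced by rounded corners are merged keeping the sharper member.
  The pure distance-tolerance vertex count turned out to be stricter than
  the by-eye judgement it stands in for: cycle-averaged loops of the
  calibrated model carry secondary inflections of 20–30° turning angle
  (8–12% perpendicular deviation) on otherwise straight edges, which the
  eye reads as a bent line, while genuine corners in both the fixture
  suite and the simulated loops turn by 60° or more.  The 40° dominance
  threshold separates the two cleanly; both knobs are arguments.
  Collapsed ranges (< 2°) yield `degenerate-line` (one axis) or
  `quiescent` (both).
* `detect_cessation()` flags intervals whose sliding-window peak-to-peak
  amplitude stays below 2° for at least 500 ms (both configurable).  Note
  that a waveform that *dwells* near one value for longer than the window
  — as the extended-tibia plateau of the quadrilateral rhythm does — is
  reported as a quiescent interval too; for regime work, interval
  durations should be inspected, not just counted.
* `detect_alternating_amplitude()` measures cycle amplitudes as the drop
  from each local maximum to the following minimum on a lightly smoothed
  trace (smoothing window 5% of the period; extrema below 5% prominence
  are merged away) and flags at least four consecutive amplitude pairs
  alternating in sign with relative differences above 10%.
* `oscillation_stats()` reports post-transient ranges, the mean cycle
  period, and per-cycle amplitudes.

`make_fixture()` generates synthetic traces — triangle and rectangle
loops with optional corner rounding and noise, alternating-amplitude
oscillations, cessation, and stretched-bobbing — so the analysis layer is
testable with known ground truth, entirely independent of the simulator.
These fixtures emulate the *geometry* of the phenomena, not the dynamics
that produce them: passing fixture tests shows the detectors implement
their definitions, not that the definitions capture every real trace.

## Calibration and frozen defaults

The defaults in `default_leg_config()` are a single frozen calibration.
The published account constrains the topology, the thresholds, the
angular ranges (`beta` ≈ [−5°, 30°], `gamma` ≈ [85°, 170°] for the
simulated search rhythm), and the qualitative regime table; it does not
print the cell or muscle constants.  The calibration was chosen so that,
from the one deterministic initial condition,

* all six canonical presets sustain an autonomous rhythm with periods of
  1.1–1.8 s and the stated angular ranges;
* the pre-contact loop class is decided by `gamma_thr` alone
  (83° → triangular, 145° → quadrilateral);
* the recovery phenomenology above (cessation at low `beta_thr`,
  alternation in a band of obstacle positions at `beta_thr = 4°`, neither
  at 16°) is reproduced.

Key frozen values: CPG `tau_v` = 40 ms; `tau_a` = 600 ms for C3, C4 and
C5 and 950 ms for the flexor cell C6 (its slow recovery is the alternans
substrate); adaptation gains `b` = 2.5/2.5/2.0/5.0 (C6's high gain keeps
its bursts short); drives `g_app` = 3.0/3.0/3.5/2.6; mutual inhibition
`w_c34/w_c43` = 1.6/1.4, `w_c56/w_c65` = 1.1/2.0; gate interneuron weight
1.8.  Muscle gains place the active equilibria just beyond the observed
angular extremes (levator 33°, depressor −14°, extensor 172°, flexor 84°)
so the rhythm's range, not the gain, sets the excursions.

## Numerical choices

Integration is a fixed-step explicit 4th-order scheme at `dt` = 0.1 ms
(configurable within (0, 1]); gates, drive multipliers and recruitment
fractions are evaluated from the state at the start of each step and held
through the sub-stages, so the stages integrate a smooth field.  Halving
`dt` changes the default 10-s trajectories by well under 0.5°.  Runs are
bit-reproducible: same configuration, same trace.  Traces are sampled
every 5 ms.  The standard problem sizes used throughout the package are
16-s runs with the first 4 s discarded for regime classification, 10-s
runs with 2 s discarded for range statistics, and 9 s of rhythm
establishment plus 12–16 s of recovery for obstacle experiments.

## Open design points, resolved

* **Gate polarity for `beta`.**  Not stated in the source material; the
  package uses the same polarity as the `gamma` gate (high at or above
  threshold) and records the ambiguity as the `polarity_beta` switch.
  The *synapse sign* carrying each gate differs, and is a package wiring
  decision: the `gamma` conductance inhibits IN12, so a permanently high
  `g_gamma` silences IN12 and steadily *disinhibits* the LD system, while
  the `beta` conductance excites IN18, so a tonically high `g_beta`
  clamps the flexor cell — which is what makes the cessation regime
  possible at all.
* **Contact geometry.**  Whether the tarsus stops exactly at `PO` or
  slightly past it is unknowable from the text; the first downward
  crossing freezes the pose exactly at the crossing.
* **Quantised recruitment.**  The fast levator/depressor pools have five
  units each; `quantized_recruitment = TRUE` replaces the continuous
  recruitment ramp by five equal steps.  The continuous ramp is the
  default (minimal reading of gradual recruitment).

## Known limitations

* The model is planar, first order and Hill-free; no load, ground-contact
  or force feedback exists, so "stepping" proper is outside its scope.
* Several presets sit near attractor boundaries — deliberately so, since
  the alternating-amplitude regime *is* a period-doubling phenomenon.
  As a consequence, the (83°, 16°) preset's post-removal rhythm settles
  into a 2:1 pattern (a tibia dip every other femur cycle), and loop
  classes of marginal runs can depend on the analysis window; the
  package therefore fixes the canonical classification protocol above.
* The angular ranges are those of the *simulated* rhythm; experimental
  search movements are wider and far more variable, and comparisons to
  animal data remain qualitative.

```{r example, eval = FALSE}
# the six canonical regimes
for (pr in canonical_presets()$name) {
  tr <- run_search(leg_config(preset = pr), duration = 16000)
  w <- tr$time_ms >= 4000
  cl <- classify_loop(average_loop(tr$beta_deg[w], tr$gamma_deg[w],
                                   tr$time_ms[w]))
  cat(pr, "->", cl$label, "\n")
}

# one obstacle experiment, with the state diagram
tr <- run_obstacle_experiment(leg_config(preset = "g83_b4"), po = 14)
plot(tr, which = "state")
recovery_descriptors(tr)
```
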