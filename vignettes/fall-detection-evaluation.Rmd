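---
title: "Evaluating threshold-based fall detectors across body-worn sensor combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating threshold-based fall detectors across body-worn sensor combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallfusion)
```

## The problem

A fall-detection system watches body-worn inertial sensors and must decide,
movement by movement, whether the wearer fell. Because real falls are rare
and activities of daily living (ADLs) are constant, the practical operating
regime is high specificity: a system that cries wolf a few times a day is
discarded by its users. This package evaluates the four classical
threshold detectors on multi-sensor trials, over every combination of five
worn positions (thigh-pocket smartphone; chest, waist, wrist and ankle
motes), to quantify how detector choice and sensor placement trade
sensitivity against specificity.

The unit of analysis is the *trial*: one labelled movement execution with
one acceleration stream per worn position. A detector returns one boolean
per stream per trial — several threshold crossings within a trial count
once — and per-sensor verdicts are fused with the AND rule: a combination
declares a fall only when every one of its sensors does. AND fusion can
only lower sensitivity and raise specificity as sensors are added, which
is the point: it suppresses false alarms caused by a single limb's
artefact.

## Detectors and their parameters

All signal processing happens in m/s²; thresholds quoted in g are
converted with `gToMs2()` (g₀ = 9.80665 m/s²). Comparisons are strict
(`>`), so a trace that only touches a threshold is a negative and decisions
are monotone in the threshold.

* **Basic thresholding** (`detectBasic`): fall iff the signal magnitude
  vector (SMV, the Euclidean norm of the three acceleration components)
  exceeds `smvTh` anywhere. One parameter, swept directly.
* **Fall Index** (`detectFallIndex`): the trailing sum, over 20 samples
  and three axes, of squared first differences. The quadratic form is
  used exactly as published — no square root — so the threshold unit is
  (m/s²)². The 20-sample window is defined in samples, not seconds; its
  temporal span is therefore rate-dependent (1 s on a 20 Hz mote, 0.1 s
  on the 200 Hz phone). We keep that behaviour, with `windowLen`
  configurable, because the published procedure fixes the sample count.
  The first 20 samples have no defined index and are omitted rather than
  zero-filled, so an artificial start-up zero can never be the trial
  maximum. The index responds to jerk rather than magnitude, which
  suppresses false alarms from sustained but smooth accelerations — and,
  conversely, makes slow falls invisible to it (a constructed slow-ramp
  trace in the test suite passes basic thresholding but not the Fall
  Index).
* **PerFallD** (`detectPerFallD`): dual condition on a sliding window of
  `winP` = 0.5 s — the ranges of SMV and of the vertical acceleration
  `|A_v|` must simultaneously exceed their thresholds within the *same*
  window. Windows slide sample by sample (the finest granularity; the
  published description does not fix a stride). Window durations convert
  to sample counts via each stream's own rate (10 samples at 20 Hz, 100
  at 200 Hz). `|A_v|` projects the reading onto the vertical estimated
  from roll `Φ = atan(Ax/√(Ay²+Az²))` and pitch `θ = atan(−Ay/Az)` of the
  same sample, a static-pose approximation that is knowingly wrong during
  the fall itself but is how the published detector operates. At `Az = 0`
  the pitch expression is undefined; we use the continuous principal-branch
  extension `θ = sign(−Ay)·π/2` so a stream never raises mid-trial.
* **iFall** (`detectIFall`): two-phase. A sample below `smvL` (default
  0.65 g = 6.37 m/s²) signals free fall and opens a `winO` = 0.5 s
  observation window; an impact above `smvU` strictly later inside the
  window is a fall. When a window expires without impact, scanning resumes
  at the first sample *after* the window: "returning to the initial state"
  is interpreted as not re-examining samples already consumed by the
  expired observation. This choice is isolated in one helper
  (`ifallWindowMaxima`) so the alternative reading — re-entering the
  window's samples as fresh triggers — would be a one-line change. It can
  only matter when a second dip occurs inside an expired window, a
  configuration we have not found meaningful in fall-shaped traces.

The sweep engine exploits the fact that each detector's trial decision
equals `statistic > threshold` for a per-stream scalar
(`decisionStatistic()`): the trial SMV maximum, the Fall Index maximum,
the best window's `min(range SMV, range |A_v|/ρ)` for PerFallD, and the
best triggered-window impact peak for iFall (−∞ when nothing ever dips
below `smvL`; such trials are negatives at every threshold). For iFall
the equivalence holds because threshold choice never changes which window
the scan examines before its first success. AND fusion then becomes a
minimum over the combination's statistics, and a 200-point sweep costs no
more than one detector pass. The test suite verifies the equivalence
against direct detector runs, and the streaming window kernels against
naive O(n·w) recomputation.

PerFallD has two thresholds but the evaluation sweeps one axis; we tie
them as `avThP = ρ·smvThP` with ρ = 1 by default (configurable via
`detectorControl(rho = )`). A one-parameter family is required for a 1-D
ROC; ρ = 1 treats both conditions symmetrically, and because `|A_v| ≤ SMV`
pointwise the vertical condition is then the binding one.

## Threshold grids and metrics

Per algorithm, the default grid is 200 linearly spaced values between the
1st and 99.9th percentile of the decision statistics pooled over all
trials and positions — dataset-adaptive so the sweep always spans the
operative range, with the extreme 1% trimmed so single outliers cannot
stretch the grid into an empty region. One shared grid serves all 31
combinations of an algorithm, keeping rows comparable.

From each sweep: ROC points (Se versus 1−Sp) are sorted and anchored at
(0,0) and (1,1) before trapezoidal integration, since a finite sweep need
not reach the corners. `maxGeomean()` reports both `max √(Se·Sp)` and the
raw product at the same argmax (summaries of this kind appear in the
literature under both conventions; we emit both, geometric mean as the
headline). Ties resolve to the smallest threshold, making tables
deterministic. `seMaxAtMinSp()` is the deployment-relevant metric: the
best sensitivity among thresholds with specificity strictly above the
bound (0.90 and 0.95 by default); an empty feasible set scores 0 rather
than NA so tables stay total and a detector that cannot reach the bound
is ranked worst.

`filterActivities()` supports re-analyses that drop an ADL subtype from
the negative class (never fall trials). Dropping hops is the canonical
one: hopping is rare among the population fall detectors target, and it
dominates the false-alarm budget of every threshold detector.

## The synthetic testbed

No recorded data ships with the package; `genDataset()` generates the
study conditions instead. Defaults: 17 subjects (ages 14–55, the 2 oldest
performing no falls, 6:11 female:male), 7 ADL subtypes and 3 fall
subtypes, 3 trials per movement — 357 ADL and 135 fall trials — five
positions, a 200 Hz ±2 g phone (the low-range variant, so fall impacts
genuinely clip; ±16 g selectable) and 20 Hz ±8 g motes, 10 s trials,
additive i.i.d. Gaussian noise of 0.3 m/s² per axis.

Movement templates are invented, piecewise envelopes — this is a
generator of *statistical structure*, not biomechanics. Every trial
starts from quiet standing. Falls contain, in order: standing, a
free-fall dip (SMV below 0.35 g for 0.12–0.28 s), a rectangular impact
transient of 3–6 g lasting 0.06–0.14 s, and rest with gravity rotated to
a lying orientation plus a decaying oscillation. The impact pulse is
rectangular and longer than the 20 Hz sampling interval deliberately, so
a mote never straddles the peak and the sampled maximum equals the
template amplitude. Walking peaks at 1.2–1.4 g, jogging at 1.85–2.05 g,
stair climbing at 1.3–1.6 g with step asymmetry; bending, sitting and
lying are slow orientation changes without impact. Hops are the
engineered confusable: 3–5 landings peaking at 2.5–4 g — overlapping the
fall impact range — preceded only by a brief, shallow flight dip
(0.36–0.6 g for 0.06–0.12 s), deep enough to trigger iFall's 0.65 g
free-fall phase but never resembling a fall's sustained sub-0.35 g dip.
Consequently *no* threshold of any detector can separate the classes
perfectly with hops present, while in the noiseless limit basic
thresholding separates them perfectly once hops are excluded — the
qualitative contrast the hop-exclusion re-analysis is built to show, and
what the acceptance tests assert.

Per-position transfer gains scale the dynamic (non-gravity) part of each
template: wrist 1.25 for fall impacts (protective arm motion), trunk
positions ≈1, ankle 0.8, thigh pocket 0.85 with a small mechanical lag
(loose coupling); hop impacts are ankle-amplified (1.2) instead. The
gain ratios are chosen so hop/fall overlap survives the minimum taken by
AND fusion over *any* combination. All gains sit in one
`defaultTransferGains()` table and can be set uniform for ablations.

Determinism: the dataset is a pure function of `generatorConfig()`
including its seed; each trial draws from a substream seeded by (seed,
subject id, subtype, trial index), so any single trial regenerates
identically in isolation, and generation never perturbs the caller's RNG
state. Features of real data the generator does not emulate: sensor-axis
misalignment between devices, timestamp jitter and packet loss,
subject-specific movement styles, gyroscope/magnetometer realism (those
channels carry orientation-consistent placeholders only). Passing tests
on synthetic data therefore validate the *pipeline* — detectors, fusion,
sweep, metrics — not any claim about detector performance on recorded
human falls.

## Numerical and interface choices

* Single internal unit (m/s²) everywhere; g appears only at the
  configuration boundary, converted once.
* Trace files are UTF-8 CSV with a `# key: value` metadata block, one
  `# device:` line per stream, and samples sorted by (device, time);
  floats carry 6 decimals, making write→read a field-exact round-trip at
  that precision. The reader re-sorts shuffled rows (with a warning),
  preserves unknown metadata keys, and rejects duplicate timestamps,
  out-of-range accelerations (beyond 1% past the device range) and
  malformed headers.
* Timestamps are authoritative and assumed centrally aligned across
  devices; transport jitter is not modelled.
* A `FallDataset` accepts any mix of positions, but metrics require both
  classes, and a trial missing a stream required by a combination raises
  rather than being silently skipped.
* The OR fusion policy exists behind `fuseDecisions(policy = "or")` for
  comparison experiments only; every reported table uses AND.

## Problem sizes

The test suite and the acceptance script run the full default conditions:
492 trials × 5 streams, four algorithms, all 31 combinations, 200-point
grids, plus a noiseless variant for the separability checks — a few
minutes end to end on one core. Oracle-equivalence properties use 100
random 10 s, 20 Hz streams and 100 random ROC staircases.

## Known limitations

* Template realism is deliberately minimal; absolute metric values on
  synthetic data should not be quoted as detector performance.
* The PerFallD threshold coupling (ρ) collapses a 2-D operating surface
  to one curve; other couplings give other ROC curves.
* Subject-level stratification and cross-validation are out of scope; the
  evaluation is a full-dataset sweep, as in the analysis it reimplements.
* The Fall Index quadratic form and sample-count window follow the
  published definition; variants with a square root or time-based windows
  exist and would change threshold scales.

## Session

```{r}
sessionInfo()
```
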