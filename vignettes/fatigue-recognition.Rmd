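---
title: "Methods: self-adaptive fatigue recognition by two-level fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: self-adaptive fatigue recognition by two-level fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drowsefuse)
```

## The recognition problem

A drowsy driver reveals their state through two weakly coupled channels:
the face (slower blinks, sustained eyelid closure, yawns) and the vehicle
(steering inactivity, erratic lane keeping, unstable speed). Either channel
alone is fragile — lighting ruins facial tracking, a blurred lane marking or
a GPS dropout ruins the vehicle channel. `drowsefuse` implements a
recognizer that fuses both channels twice: once at the *feature* level,
where each channel's features are condensed by a fuzzy neural network into
degrees of support for the three states NF/MF/SF (non-, moderate, severe
fatigue), and once at the *decision* level, where the two supports plus the
previous time step's result are combined as evidence under
Dempster–Shafer theory.

The package assumes the upstream computer vision and telemetry already
exist: inputs are numeric per-frame facial series (eye-closed flags, eyelid
heights, mouth geometry) and per-sample vehicle series (steering angle
and/or rate, lane-line slope angles, GPS speed). It makes three modelling
assumptions worth stating. First, windowed features are treated as
approximately Gaussian within a state — this is what the normality screen
checks and what the training encoder relies on. Second, fatigue evolves
slowly relative to the 60 s recognition window, so the previous window's
fused mass is informative evidence, not noise. Third, the three states are
exhaustive and mutually exclusive, which is what licenses the
three-singleton frame of discernment.

## Windowed features

Facial features (`bf`, `ecd`, `meol`, `yf`) and the lane feature (`fald`)
are computed over each full 60 s window; the steering and speed features
(`pns`, `sdsa`, `sdvs`) have a 10 s natural time scale and are computed over
the final 10 s sub-window of each minute. Alignment between the two scales
is not dictated by the measurement definitions, so the package picks one
recognition step per minute with the trailing sub-window (the freshest
vehicle evidence at decision time); computing vehicle features over all six
sub-windows and averaging is a plausible alternative that slightly smooths
`pns` — nothing downstream depends on the choice.

Two definitions need interpretation:

* **Sustained closure (`ecd`).** "Closed for a continuous period of two
  seconds" does not say how partial runs count. The package counts *every
  frame inside a maximal closed run of duration ≥ 2 s* (threshold
  `ecd_min_closure`, default 2 s). This keeps `ecd` in [0, 1], makes
  `ecd ≤ bf` an invariant (its frames are a subset of closed frames), and
  reduces to PERCLOS-like behaviour.
* **Lane deviation (`fald`).** The ratio ξ(k) = (π/2 − θ_L)/(θ_R − π/2)
  equals 1 for symmetric lane geometry, rises when the vehicle drifts left
  and falls below 1 when it drifts right. A literal one-sided rule
  "ξ > λ_L or ξ > λ_R" is degenerate (one condition subsumes the other
  whenever the thresholds differ), so the default `symmetric` rule flags
  ξ > λ_L *or* ξ < 1/λ_R, with λ_L = λ_R = 1.2; the literal rule remains
  selectable via `feature_config(lane_rule = "literal")`. Frames with
  θ_R = π/2 make ξ undefined and are excluded with a warning.

The yawn threshold `t_m` (mouth height/width ratio) defaults to 0.5: a
relaxed mouth is much wider than tall (ratio ≈ 0.2 in the synthetic
streams), a yawn approaches or exceeds parity. The non-steering band is
±0.1 °/s. When only steering angles are recorded, the angular velocity is
estimated by first differences over the sampling interval — the simplest
estimator consistent with the band's definition.

Both dispersion features use the population form (1/N inside the root), as
their definitions are written, not the n−1 sample form.

## Feature screening

Each feature is tested for normality with a one-sample Kolmogorov–Smirnov
statistic against a normal with the sample's own mean and SD, passed when
D < 1.36/√n (the asymptotic 5 % quantile, 0.1297 at n = 110 for
orientation). Using the asymptotic quantile with estimated parameters is
anti-conservative; the Lilliefors-corrected variant is available
(`ks_normality(..., lilliefors = TRUE)`) but the uncorrected form is the
default because it is the form the screening procedure is defined with.
Features failing the check are log-transformed (with a 1 − min shift when
non-positive values are present) and re-tested.

Correlation with the fatigue labels (coded ordinally 0/1/2 — the coding is a
design choice; the states are ordered, so ordinal coding preserves the
monotone trend a correlation can detect) is tested with
t = r·√((n−2)/(1−r²)) against the two-sided Student critical value.
Screening is by |t|: negatively correlated features (eyelid level and
steering dispersion fall with fatigue) are retained as readily as positive
ones. No multiple-testing correction is applied — the screen is a
per-feature relevance filter, not a simultaneous inference.

## The fuzzy neural networks

Each network is the five-layer zero-order Takagi–Sugeno form: Gaussian
fuzzification, product rule firing, normalization, linear output. The rule
count m comes from Chiu subtractive clustering on the min–max-scaled
training features (radii r_a = 0.5, r_b = 1.5·r_a, accept 0.5, reject 0.15 —
Chiu's classic constants; the scaling is stored with the model and applied
at prediction time). Initial centers are the cluster centers; initial widths
are |C₁ − C_S|/2 per coordinate, where C_S is the center nearest the first
center — the printed index usage of that rule is ambiguous, and this reading
(one width vector shared by all rules) is the one that yields well-defined
shapes for any m; with a single cluster the widths fall back to a floor
(0.05 on scaled data). Output targets are soft-coded 0.8 for the true state
and 0.1 for each other state, so outputs approximate state memberships
rather than hard labels and the downstream mass assignment is smooth.

Training is global-best particle swarm optimization over the flattened
(centers, widths, weights) vector: swarm 30, c₁ = c₂ = 2.0, inertia decayed
linearly 0.9 → 0.4, velocities clamped to 20 % of each search range, stop at
MSE ≤ 10⁻⁴ or the iteration budget. Search bounds: centers within the data
range ± 1 SD, weights in [−2, 2], widths in
[2 % of the per-dimension range, the range]. The width *lower* bound is a
deliberate numerical choice: if widths may collapse further (e.g. to a bare
positivity floor of 10⁻³), a swarm will occasionally drive one rule's width
to the floor, turning its membership into a delta that never fires — the
net then behaves as an (m−1)-rule model and the swarm cannot recover the
lost rule. A Gaussian narrower than 2 % of the feature range is
indistinguishable from that degenerate case, so nothing expressible is
lost. Two standard stagnation guards are options in `pso_config()` /
`fit_tsfnn()`: re-seeding the worse half of the swarm after 50 improvement-
free iterations, and multi-start (default 3 starts, best final fitness
wins) — the permutation symmetry of the rule index makes the fitness
surface multimodal, and an occasional swarm commits early to a poor basin.
Training is bit-reproducible given the seed.

Firing strengths are computed in log space and shifted by their maximum
before exponentiation, so the normalized strengths are well defined even
for inputs far from every rule center (where all strengths underflow in
linear arithmetic).

## Evidence fusion

Network outputs become a basic probability assignment by clamping negatives
to zero and normalizing to unit sum; because the weights are unconstrained,
a pathological window can make all outputs non-positive, in which case the
source contributes *vacuous* evidence (all mass on Θ) — the neutral element
of combination — rather than a fabricated opinion. Masses live on the three
singletons plus Θ only; no step of the pipeline ever allocates mass to a
two-element subset, so the implementation fixes that focal structure.

Dempster's rule combines two masses by renormalizing the product mass on
non-empty intersections by 1 − K, K being the conflict degree. The
implementation divides by the *accumulated* retained mass rather than the
separately computed 1 − K: algebraically identical, but exactly normalized
even when K is within rounding of 1, which matters in long sessions where
reinforced masses approach point masses. At K = 1 exactly the rule is
undefined and the recognizer falls back to the previous state.

When K ≥ k_T the raw combination is distrusted: for each source the
pairwise conflict × Euclidean evidence distance gives a confidence level c,
averaged over the *other* sources (the self-term is identically zero and
would only dilute the average; the self-inclusive convention is available
via `include_self = TRUE`), and the belief factor η = (1 − c)e^c discounts
the source's singletons, moving the released mass to Θ. η is analytically ≤ 1
on [0, 1] and strictly decreasing; the clamp in the code guards rounding
only. The default k_T = 0.9 is chosen from the bundled worked examples: a
printed case with K = 0.835 was demonstrably combined without correction,
so the effective threshold must exceed 0.835.

The first fusion result is renormalized (a no-op in exact arithmetic,
retained for procedural fidelity) and fused with the previous step's
decision-level mass using the same k_T-gated rule. This temporal recursion
is the robustness mechanism: when one source goes vacuous (tunnel, lost
face track), the other source and the accumulated prior still dominate the
fused mass, and the decision holds — demonstrated in the dropout test.

The decision rule outputs the arg-max state only when its mass exceeds the
runner-up by ε_T1 = 0.2 *and* exceeds ε_T2 = 0.5 absolutely; otherwise the
previous decision stands. The defaults are the package's own: every
self-consistent bundled worked example's printed decision is reproduced by
(0.2, 0.5), and both are configurable. Exact ties cannot clear the margin,
so tie-breaking (fixed NF < MF < SF order) never decides.

## Ground-truth assessment

Session labels come from a three-way consensus: an observer panel (three
0/1/2 scores, floored mean — the 0/1/2 coding is required for the floored
mean to reach all three states), an EEG drowsiness index
r = (P_α + P_θ)/P_β with thresholds 3 and 4, and the 7-point Stanford
Sleepiness Scale (1–2 / 3–5 / 6–7). Only windows where all three agree
enter the ground truth; the rest are discarded. Band powers are
Welch-estimated (2 s Hann segments, 50 % overlap — a standard, variance-
reducing default; the estimator is not prescribed by the procedure) and
integrated over θ 4–8 Hz, α 8–13 Hz, β 13–22 Hz. The conventional band
labels are used; note the drowsiness ratio sums α and θ, so swapping those
two labels would not change r, only the per-band bookkeeping. Bands are
configurable via `eeg_bands()`.

## The synthetic-data generator

No public dataset accompanies this recognition task, so the generator is a
first-class module. It emulates: a Markov fatigue-state path (default
persistence 0.9 per 60 s window, starting alert); state-conditional
Gaussian feature targets whose default means are monotone in fatigue —
rising for `bf`, `ecd`, `yf`, `pns`, `fald`, `sdvs`, falling for `meol` and
`sdsa`, matching the correlation signs the screen expects — with adjacent
states separated by ≥ 1.5 within-state SDs; and, on request, raw streams
realized from those targets: sustained closures as ≥ 2 s runs plus short
blinks (small closure targets realized probabilistically so the expected
frame count is unbiased), 4 s yawn episodes, lane-angle series with
deviation episodes, steering/speed series rescaled to the target
dispersions. Feature separations of 1.5 SD are the generator's study
conditions for the recovery benchmark, chosen once as a realistic
moderately-separable regime.

Two honest limitations. The steering channel emits `steer_angle` (scaled to
the target angle SD) and `steer_rate` (a mixture realizing the target
non-steering fraction) as separate measured series: a single differentiable
angle series cannot realize both windowed targets at once, and the package
treats them as independently measured channels, as real instrumentation
does. And the generator draws features independently across windows given
the state, with no within-state autocorrelation, sensor noise bursts,
lighting artifacts or inter-driver variability. Consequently, passing the
recovery benchmark shows the *pipeline* is coherent end to end — features
extracted as defined, networks trainable, fusion and decision logic sound —
not that field accuracy on real drivers would match; field rates depend on
real feature distributions this generator does not claim to imitate.

## Problem sizes and verification scale

The test suite trains at the scale the training procedure itself uses: 120
samples per state, swarm 30, 300 iterations (~10 s per network per start),
multi-start 3. The end-to-end benchmark averages 20 sessions of 50 windows
and requires ≥ 80 % state recovery (measured ≈ 90 %). Parameter recovery
retrains a known 2-input/2-rule/2-output network on 200 noiseless samples
to MSE ≤ 10⁻³ within an 800-iteration budget (measured ≈ 2·10⁻⁴). The
Dempster implementation is checked against an exhaustive focal-set
enumeration oracle on 1000 random mass pairs. Monte-Carlo calibration of
the screening tests uses 200 seeded replicates at n = 500 (KS level and
power) and n = 150 (Pearson type-I level). These sizes are the package's
verification choices; all are configurable upward.

## Known limitations

* The recognizer introduces a one-window lag at genuine state transitions:
  the temporal prior and the decision margin both resist a single window of
  contrary evidence. That is the intended robustness–latency trade-off of
  fusing the previous step as evidence.
* Thresholds k_T, ε_T1, ε_T2 are not identified from data within the
  package; the defaults reproduce the bundled worked examples and are
  exposed for calibration.
* The screening stage evaluates features marginally; a feature informative
  only jointly would be dropped.
* Mass functions never allocate to two-element subsets (e.g. "MF or SF");
  the discounting path expresses partial ignorance only through Θ.
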