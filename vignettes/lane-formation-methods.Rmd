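---
title: "Modelling lane formation and its instabilities in bidirectional pedestrian flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lane formation and its instabilities in bidirectional pedestrian flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lanelab` studies a classic self-organisation phenomenon: two streams of
pedestrians walking in opposite directions around a ring corridor
spontaneously segregate into lanes, and this organisation is unstable —
ordered and disordered states alternate. The package provides every stage
of that analysis: an agent-based walking model, a trajectory clustering that
identifies lanes, survival analysis of cluster lifetimes, local density and
radial-speed field maps, and payoff metrics that quantify what the
organisation is worth collectively and individually.

This vignette explains the models and the numerical choices. It states no
empirical result that the package's tests and `scripts/acceptance.R` do not
themselves compute.

## The arena and its data structures

The corridor is an annulus centred at the origin with inner radius 2 m and
outer radius 4.5 m (walkable surface 51.05 m²), matching a laboratory
ring-corridor experiment in which N ∈ {30, 50, 60} participants — half
attributed each circulation direction — walked for 60 s recordings. At
those crowd sizes the global densities are 0.59, 0.98 and 1.18
pedestrians/m². All analyses consume a `trajectory_set`: uniformly sampled
positions of N labelled pedestrians with attributed circulation signs
(+1 anti-clockwise, −1 clockwise), optionally carrying each pedestrian's
comfortable speed. Readers reject irregular time grids rather than
resampling silently.

## The walking model

Each agent adapts its velocity toward a desired velocity with relaxation
time τ = 0.5 s, plus body-contact forces:

dv_i/dt = (v_des · ê(α_des) − v_i)/τ + F_contact,i

The desired heading α_des is chosen by anticipated collision avoidance.
For each candidate heading α in a uniform grid of 61 directions spanning
±45° (the vision field) around the looking direction α₀ (toward the
destination), the agent computes f(α): the distance it could travel along α
at its comfortable speed before first body contact with another pedestrian
— extrapolated linearly at that pedestrian's current velocity — or with a
wall, capped at the horizon d_max = 10 m. The candidate minimising the
distance-to-destination proxy

d(α)² = d_max² + f(α)² − 2 d_max f(α) cos(α₀ − α)

is selected (the law-of-cosines form: the remaining distance to a
destination placed d_max away along α₀ after travelling f(α) along α).
Ties go to the heading closest to α₀; exact symmetric ties are broken by a
seeded coin flip so the model has no systematic chirality. The desired
speed is v_des = min(v₀, d_h/τ), where d_h = f(α_des): walk comfortably,
but never faster than lets you stop before the first obstacle within one
relaxation time.

Contact forces are linear springs: k · g(r_i + r_j − d_ij) along the line
of centres for bodies (g(x) = max(x, 0), k = 1000 in acceleration units per
metre of overlap, body radius 0.2 m), and the analogous term against each
wall circle. To keep an agent circulating, its destination is refreshed
every step at 5 m ahead along the tangent in its attributed sense.

### Numerical choices, and two choices that required care

* **Integration.** Synchronous explicit Euler, velocity then position,
  default dt = 0.01 s. The contact spring has natural frequency
  √k ≈ 32 rad/s; explicit Euler at a step of 0.05 s cannot integrate it —
  the undamped oscillation amplifies until agents are ejected through the
  walls. At dt = 0.01 s, with the −v/τ relaxation always active as
  damping, 60 s crowds stay contained (the test suite checks a 5 cm
  containment margin on full runs).
  Free-flow trajectories shift by less than 1 cm when dt is refined from
  0.01 to 0.002 s (first-order convergence).
* **Contact regime.** During physical contact the intentional heuristic can
  no longer steer the body freely; a repulsive force acts. We implement
  this additively — relaxation term plus contact term — rather than
  replacing the whole acceleration by the repulsion. Full substitution
  removes propulsion for any touching agent; at the N = 60 density
  (1.18 ped/m²) contacts are frequent enough that substitution freezes
  whole simulated crowds into permanent jams, which contradicts the
  sustained flows this model is known to produce. The
  additive form keeps the repulsion dominant during overlaps (contact
  accelerations reach tens of m/s² versus ≈ 2.4 m/s² for the heuristic
  term) while letting agents resume walking as contacts resolve.
* **Steering slack.** Collision anticipation treats bodies as discs shrunk
  by `steering_slack` = 0.04 m in combined diameter (2 cm per body);
  contact forces always act at the full radii. A rigid disc in exact
  contact blocks every anticipated path that has any velocity component
  toward the contact, so for a pedestrian pressed into a dense plug all
  candidate headings report zero free path and head-on encounters at high
  density become absorbing deadlocks. Real pedestrians escape by rotating their
  shoulders, a few centimetres of effective width the disc representation
  cannot express; the slack restores exactly that. The value is the
  anatomical shoulder-rotation scale, fixed once; set it to 0 for strict
  rigid-disc anticipation.
* **Looking direction.** α₀ points toward the current destination (the
  model's stated reference), not along the current velocity.
* **Initial conditions.** Start positions are rejection-sampled uniformly
  over the annulus without body overlaps; agents start at rest; comfortable
  speeds are drawn once per run from a Gaussian with mean 1.2 m/s and
  standard deviation σ, truncated below at 0.3 m/s by resampling (the
  truncation guards σ = 0.3 against non-physical crawls and is essentially
  inactive at the empirical σ = 0.16). Trajectories are recorded at 10 Hz
  regardless of dt. Every run is a pure function of its integer seed.

## Lane clustering

Pedestrian j *follows* pedestrian i at time t if j's trajectory during
[t, t + 1 s] passes within δ = 0.6 m of i's position at t. Clusters are the
connected components of the symmetrised follow graph, restricted by default
to pairs sharing a circulation sign: lanes are files of uniform walking
direction, and without the restriction a single near-pass chains the two
opposite streams into one giant component, erasing the order/disorder
signal. The restriction is a switch (`same_direction_only`) for sensitivity
checking. Partitions are evaluated at 10 Hz; frames within one window of
the recording end are excluded (their forward trajectory is incomplete)
rather than silently shrinking the window.

A crowd state is *ordered* when it has five clusters or fewer and
*disordered* at ten or more. A cluster's identity is its exact membership
set: it is born when the set first appears, and dies at the first
evaluation where its composition has changed by at least one individual.
Lifetimes of sets still alive at the last admissible evaluation are
right-censored and enter the survival analysis as such (discarding them
would bias short a 60 s recording's lifetime distribution); the survival
curve p(t) — the probability that a cluster is still unchanged t seconds
after birth — is the Kaplan–Meier product-limit estimator, computed by the
`survival` package.

`sensitivity_scan()` recomputes time-averaged cluster counts over a
(δ, window) grid; on the concentric-lane fixture the count is exactly the
lane count across δ ∈ [0.4, 0.8] m and windows of 0.5–1.5 s, the
robustness band the method is meant to have.

## Stretched-exponential relaxation and T95

Cluster survival follows a stretched-exponential relaxation law

p(t) = a · exp(−b · t^κ),  0 < κ ≤ 1,

interpolating between exponential (κ = 1) and slower-than-exponential
decay. The fit linearises: for each κ on a grid (0.1 to 1.5, step 0.01),
log p is regressed on t^κ by least squares, and the κ with the highest R²
wins; then a = e^intercept and b = −slope. Two defences against the tail
of the product-limit estimate, which has an almost-empty risk set and
log-space variance that explodes: points supported by fewer than 3
surviving clusters are dropped, and each remaining Kaplan–Meier step is
weighted by the number of deaths it represents, so every observed
composition change contributes equally to the regression. (Equal-weight
fitting of the curve's sampled points is available as
`weighting = "equal"`; on pooled simulation data it lets a handful of
noisy tail points dominate, dragging the exponent down and inflating the
amplitude severalfold.) The amplitude a is fitted rather
than pinned at 1, and a ≈ 1 serves as a sanity check of the law. The
characteristic lifetime T95 — the time by which a cluster has a 95% chance
of having changed — solves p(T) = 0.05 in closed form:
T95 = (ln(a/0.05)/b)^(1/κ).

`sample_stretched_lifetimes()` inverts the unit-amplitude law to generate
ground-truth lifetimes; the test suite verifies that the fit recovers
(κ, b) from 5000 such draws within ±0.05 / ±10% for κ ∈ {0.4, 0.5, 0.6, 1}.

## Field maps

Local density at a point x is a Gaussian-weighted count,
ρ(x) = Σ_j exp(−d_jx²/R²)/(πR²) with R = 0.7 m. The 1/(πR²) prefactor
(our choice; only the Gaussian form itself is prescribed) normalises the
kernel to unit mass so the plane integral of ρ is the number of
pedestrians and a single pedestrian contributes a finite, interpretable
peak of 1/(πR²) ≈ 0.65 m⁻². The density profile ρ(θ, t) averages the point
density over 20 radial sample points spanning the corridor width along
direction θ; profiles use 72 five-degree sectors by default (the sector
width is a configuration choice, not prescribed).

The local radial speed v_r(θ, t) is the mean of |dr_j/dt| over the
pedestrians in each angular sector — the absolute radial component, since
lane-leaving is symmetric in sign — with velocities from central finite
differences at the trajectory sampling rate. Empty sectors are marked
undefined (NA), never imputed as zero, and are excluded from the
density/radial-speed Pearson correlation, which discards the first 10 s of
transient. A negative correlation is the signature of the instability
mechanism: slow walkers open low-density gaps ahead of themselves, and
faster walkers use exactly those gaps to leave their lane and overtake,
meeting the opposite stream head-on.

## Payoffs

Flows are measured by counting crossings of 8 equally spaced radial
cross-sections, in the attributed sense only (wrong-way excursions do not
count), after discarding the first 10 s; the flow is crossings per second
per section. The collective payoff C = (J_cw + J_acw)/J_uni compares
bidirectional throughput against unidirectional runs of the same crowd
(same N, geometry and σ — "same density" fixes N, and we match the speed
heterogeneity too, averaging the baseline over three seeds). C = 1 means
the two streams organise as well as a single stream; both payoff formulas
are reconstructed from their verbal definitions around that anchor and are
isolated in single functions so alternative normalisations are one-line
changes. The individual payoff P_i is the time-averaged projection of
pedestrian i's realised velocity onto its desired direction (the tangent in
its attributed sense) divided by its comfortable speed: 1 when walking
exactly as desired, 0 when stuck. P_i can transiently exceed 1 through
contact pushes; it is reported, not clamped.

`payoff_vs_sigma_sweep()` runs the whole chain over a heterogeneity grid
(σ ∈ [0, 0.3]): seeded bidirectional replications, σ-matched baselines,
v₀-binned individual payoffs (0.1 m/s bins; empty bins are absent, not
zero), and pooled-lifetime relaxation fits per σ.

## Synthetic data: what it emulates and what it does not

The generators make every analysis stage testable without the original
motion-capture recordings, which were never deposited:

* `make_lane_fixture()` — perfectly circular single-file lanes with known
  spacing: the ordered end-member whose cluster count is provable.
* `make_disordered_fixture()` — dispersed slow random walks: the
  disordered end-member.
* `make_switching_fixture()` — alternates between two static
  configurations whose partitions are exactly two prescribed set systems.
  Because following looks forward one window, a naive construction would
  blur partition changes by up to one window; the fixture therefore gives
  every non-shared group fresh, well-separated anchor positions in each
  phase, so the partition flips exactly at the switching instants and all
  completed lifetimes equal the period exactly.
* `add_tracking_noise()` — i.i.d. Gaussian position jitter emulating
  reconstruction error. Note that under the min-over-window follow rule,
  jitter of the order of δ both breaks true edges and creates spurious
  ones; it degrades the lane partition without necessarily inflating the
  cluster count.

These fixtures are deliberately idealised — realism is the simulator's
job. Passing fixture tests demonstrates the analyses' correctness on known
ground truth, not that the model reproduces human crowds; the simulation
criteria (relaxation exponents, order/disorder alternation, trend under
heterogeneity, density/speed anti-correlation) carry that burden, and the
empirically reported quantities that require the undeposited recordings
(T95 = 12.7/8.4/7.8 s; correlation magnitude c = 0.3) are explicitly out
of reach.

## Problem sizes

Simulation-backed checks use 60 s runs at the experimental crowd sizes:
ten replications per N for the relaxation exponents, five replications per
σ level (plus three unidirectional baselines per level) for the
heterogeneity sweep. These sizes give pooled lifetime samples in the
thousands, enough that the fitted exponent is stable to a few hundredths
across seed batches.

## Known limitations

* The negative density/radial-speed correlation is a property of *unstable*
  traffic: in replications where the lanes happen to stay stable for the
  whole recording, the dominant residual coupling is avoidance manoeuvring
  where the opposing streams pass each other — locally higher density
  accompanied by small radial adjustments — which is weakly *positive*.
  Across seeded N = 60 ensembles at σ = 0.16 the correlation is strongly
  negative in congested replications and can be weakly positive in
  fully-laned ones, so the sign-level check is an ensemble statement, not
  a per-run guarantee.

* Bodies are discs; shoulder rotation enters only through the anticipation
  slack, and genuine 3D or marker-level kinematics are out of scope.
* The collision test extrapolates neighbours linearly with no anticipation
  horizon beyond d_max; pedestrians do not predict others' steering.
* The follow-relation window semantics make cluster births sensitive to
  events up to one window ahead; all lifetime statements are at the 0.1 s
  evaluation resolution.
* The unidirectional baseline is itself a model quantity; C therefore
  compares two simulated regimes, not simulation against experiment.
* Only annular geometry is supported, by design.
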