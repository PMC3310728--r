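# lanelab

Tools for studying **lane formation and its instabilities in bidirectional
pedestrian traffic** on a ring corridor.

When two streams of pedestrians walk in opposite directions through shared
space, they spontaneously segregate into lanes of uniform walking
direction — a self-organised pattern that improves traffic with no external
control. The organisation is not stable: ordered phases (few, long files)
and disordered phases (many fragmented groups) alternate, and the driver of
the breakdowns is inter-individual variability in comfortable walking
speed: slow walkers open density gaps ahead of themselves, fast walkers use
those gaps to overtake, leave their lane, and meet the opposite stream
head-on.

`lanelab` implements the full computational chain for this problem:

* **Agent-based walking model** (Rcpp core). Each agent relaxes toward a
  desired velocity with time constant τ = 0.5 s. The desired heading
  minimises the anticipated distance to the destination,
  d(α)² = d_max² + f(α)² − 2 d_max f(α) cos(α₀ − α), over 61 candidate
  headings in a ±45° vision field, where f(α) is the distance to first
  collision along α (capped at d_max = 10 m); the desired speed is
  v_des = min(v₀, d_h/τ). Body contacts add linear repulsion
  k·g(r_i + r_j − d_ij) with k = 10³. Destinations sit 5 m ahead along the
  ring tangent and are refreshed every step.
* **Lane clustering.** Pedestrian j follows i at time t if j's trajectory
  passes within δ = 0.6 m of i's position during [t, t + 1 s]; clusters are
  connected components of the follow graph. A cluster dies when its
  composition changes by one individual; ≤ 5 clusters is order, ≥ 10 is
  disorder.
* **Survival analysis.** Kaplan–Meier curves of cluster lifetimes and a
  grid-search linearised fit of the stretched-exponential relaxation law
  p(t) = a·exp(−b·t^κ), with the T95 lifetime solving p(T) = 0.05.
* **Field measures.** Gaussian-kernel local density ρ(θ, t) (R = 0.7 m) and
  local radial speed v_r(θ, t) maps, and their Pearson correlation.
* **Payoffs.** Collective payoff C = (J_cw + J_acw)/J_uni against a
  unidirectional baseline at the same density, and individual payoff
  P_i = time-mean of (v_i · ê_i)/v₀ᵢ.
* **Synthetic generators** for provable ground truth: concentric-lane,
  dispersed, and partition-switching fixtures, plus tracking noise.

See `vignettes/lane-formation-methods.Rmd` for the models, parameter
meanings and numerical choices.

## Worked example

```r
library(lanelab)

geom <- corridor_geometry(r_inner = 2, r_outer = 4.5)
geom
#> <corridor_geometry> annulus r_inner = 2 m, r_outer = 4.5 m, area = 51.05 m^2

# 60 pedestrians, half per direction, speeds ~ N(1.2, 0.16) m/s, 60 s
traj <- simulate_crowd(n = 60, sigma = 0.16, duration = 60, seed = 42)
traj
#> <trajectory_set> 60 pedestrians (30 acw / 30 cw), 601 frames over 60.0 s at 10 Hz

counts <- cluster_count_series(traj)
summary(classify_phase(counts$n_clusters[counts$time > 10]))
#>        order intermediate     disorder
#>          228          174           88

tl <- track_lifetimes(traj)
tl
#> <cluster_timeline> 591 evaluations over [0.0, 59.0] s: 283 completed lifetimes (median 0.7 s), 2 censored

fit <- fit_stretched_exponential(survival_curve(tl))
fit
#> <relaxation_fit> p(t) = 1.304 * exp(-1.270 * t^0.51),  R^2 = 0.9973,  T95 = 6.36 s

maps <- build_field_maps(traj)
density_speed_correlation(maps)$estimate
#> [1] -0.377
```

Reading the output: after the initial transient this run alternates between
ordered (≤ 5 clusters, 228 evaluations) and disordered (≥ 10 clusters, 88
evaluations) states. Cluster survival linearises cleanly under the
stretched-exponential law (R² = 0.997) with exponent κ ≈ 0.5 — decay slower
than exponential, faster than power law — and a typical cluster has a 95%
chance of having changed composition within ~6.4 s. The negative
density/radial-speed correlation shows lane-leaving manoeuvres concentrate
in low-density gaps, the mechanism behind the instability.

A `sigma` sweep quantifies what heterogeneity costs:

```r
sweep <- payoff_vs_sigma_sweep(sigma_grid = c(0, 0.1, 0.2, 0.3), n = 60,
                               reps = 5, seed = 7)
sweep$relaxation   # kappa and T95 per sigma (T95 decreasing)
sweep$collective   # collective payoff C per run (mean C decreasing)
sweep$individual   # individual payoff by 0.1 m/s speed bin
```

A thin command-line front end over these functions is installed at
`inst/scripts/lanelab` (`simulate`, `clusters`, `clusters-sensitivity`,
`fit-relaxation`, `fields`, `payoff`, `run`).

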