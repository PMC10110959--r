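# modewalk

Long-term 2D single-cell migration tracks — such as dendritic cells
imaged under planar confinement at ~1-minute resolution for up to a day —
rarely follow a single random-walk law. The same cell can idle in a
slow, confined, anti-persistent state, zigzag its way forward, or sprint
almost ballistically, switching between these behaviours on the scale of
an hour. `modewalk` implements a complete, reproducible pipeline for
discovering such discrete migration modes from raw track tables,
annotating each hour of every trajectory with its mode, and quantifying
the switching dynamics.

## What it computes

**Preprocessing.** Short tracking dropouts (< 10 min) are filled by
per-coordinate cubic-spline interpolation; longer gaps (≥ 10 min) split a
track in two. Tracks are then admitted if mean speed ⟨V⟩ ≥ 1.5 µm/min,
duration T ≥ 60 min and maximal displacement max|r(t) − r(t₀)| ≥ 20 µm,
and finally cut into consecutive 1-h windows (admissible at 50–60
points).

**Five per-window descriptors.** With the gyration tensor
R_ij = ⟨(r_i − ⟨r_i⟩)(r_j − ⟨r_j⟩)⟩ and eigenvalues λ₁ ≥ λ₂:

- radius of gyration R_g = √(λ₁ + λ₂) (µm),
- asphericity A = (λ₁ − λ₂)²/(λ₁ + λ₂)² ∈ [0, 1] (0 circular, 1 collinear),
- kinetic energy E = ⟨V_D(t_n)²⟩ over steps ((µm/min)²),
- end-to-end distance R_ete (µm),
- variance of the signed turning angles Var[θ] (rad²), θ counterclockwise-
  positive in [−π, π).

**Hybrid mode discovery.** Features are z-scored; a mean-silhouette scan
(k = 2…8, with the within-cluster average D_W(i) running over the full
cluster including the point itself) selects the cluster count; K-means
pseudo-labels train a gradient-boosted tree classifier (XGBoost, small
cross-validated grid), whose held-out agreement and feature importances
are reported. With k = 3 the clusters are named slow-diffusive (SD),
slow-persistent (SP) and fast-persistent (FP) by mean energy, then mean
asphericity.

**Trajectory statistics.** Time-averaged MSD(Δt) = ⟨|r(t+Δt) − r(t)|²⟩_t
and its anomalous exponent α (MSD ∝ Δt^α), per-segment P(α),
displacement distributions P(x|Δt), turning-angle heatmaps over lag,
(Δθ_n, V_n) phase-space series, successive-angle densities (θ_n, θ_{n+1})
and the zigzag fraction (opposite-sign over same-sign successive turn
pairs; > 1 flags zigzag motion).

**Transition dynamics.** Pooled window-to-window transition matrix P_ij
(self-transitions included), per-mode occupancy fractions, single- vs
multi-mode track fractions, censoring-aware mode-lifetime distributions,
and one- vs two-step cross-transition pathway probabilities.

**Synthetic truth.** A simulator generates the three modes (speeds
2.58 ± 1.90, 2.21 ± 1.61 and 6.27 ± 2.66 µm/min for SD/SP/FP) with
Markov mode switching at 1-h granularity plus analytic fixtures
(ballistic, Brownian, circular, zigzag, stationary walkers), so the whole
pipeline is testable without any experimental data.

## Worked example

```r
library(modewalk)
library(dplyr)

P <- matrix(c(0.80, 0.15, 0.05,
              0.15, 0.80, 0.05,
              0.20, 0.20, 0.60), 3, 3, byrow = TRUE)
sim <- simulate_switching_tracks(30, switching_config(P, duration = 1440),
                                 seed = 42)

feats <- sim$tracks |> segment_tracks() |> track_features()
scan  <- scan_cluster_count(feats[c("rg", "asphericity", "energy",
                                    "rete", "var_theta")], seed = 42)
attr(scan, "best_k")
#> [1] 3

model <- fit_modes(feats, k = 3, seed = 42)
model
#> Hybrid migration-mode model
#>   segments: 720  clusters (k): 3
#>   modes: SP, SD, FP
#>   held-out agreement with pseudo-labels: 0.9978 (train 1.0000)
#>   feature importance (gain):
#>          rg asphericity      energy        rete   var_theta
#>      0.3377      0.0253      0.1740      0.0255      0.4376

modes <- annotate_modes(model, sim$tracks)
transition_matrix(modes)
#> Mode-transition matrix ( 690 transitions )
#>     to
#> from    SD    SP    FP
#>   SD 0.835 0.119 0.045
#>   SP 0.148 0.795 0.057
#>   FP 0.293 0.187 0.520
```

The fitted transition probabilities recover the configured chain, and
the per-window mode labels agree with the simulator's ground truth in
99% of windows in this run. `tidy(model)` gives per-cluster feature
centers in original units; `autoplot()` methods exist for MSD curves,
turning-angle heatmaps, silhouette scans, transition matrices, mode
sequences and displacement distributions. A thin CLI wrapper
(`exec/modewalk`) exposes `simulate` and `run` subcommands over a YAML
config.

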