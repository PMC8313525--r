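# movepredict

Predictability of movement trajectories across spatio-temporal scales.

## The problem

How predictable is an individual's movement? The standard answer treats a
movement history as a symbolic sequence of visited places and computes an
information-theoretic upper bound on the accuracy any prediction algorithm
could reach on it. But the bound is a property of the *sequence*, not of the
person: the same raw GNSS trajectory yields very different sequences —
and very different predictability — depending on how dwells are detected,
how space is tessellated into places, and how time is discretised. This
package implements the full pipeline so those processing choices can be
studied systematically, for researchers in mobility informatics, movement
ecology and epidemiological mobility modelling:

1. **Stay-point detection** — a distance/time threshold scan (`δ`, `τ`)
   extracts dwell episodes from a timestamped point trajectory.
2. **Stay-region aggregation** — stay-points are grouped into labelled
   places either by a regular grid of spacing `G` or by density clustering
   with radius `ε` (minimum cluster size one, i.e. connected components of
   the `ε`-graph).
3. **Sequence construction** — *next time-bin* sequences (the dominant
   region per interval `Δt`, nulls for empty bins) or *next place* sequences
   (visit order with consecutive repeats collapsed).
4. **Entropy and predictability** — for a sequence over `L` places with
   visit frequencies `p_k`:
   - random entropy `S_rand = log2(L)`,
   - uncorrelated entropy `S_unc = -Σ p_k log2 p_k`,
   - actual entropy `S_est = (n / Σ_j Λ_j) · log2 n`, the Lempel-Ziv
     estimate in which `Λ_j` is the length of the shortest substring
     starting at `j` that does not occur in the preceding prefix.

   Each entropy `E` is turned into a predictability bound `Π` by solving
   Fano's inequality
   `E = -Π log2 Π - (1-Π) log2(1-Π) + (1-Π) log2(L-1)` for `Π ∈ [1/L, 1]`,
   giving `Π_rand`, `Π_unc` and `Π_max`.
5. **Missing-data correction** — three estimators of actual entropy for
   sequences with empty bins (`Ĥ_shuff`, `Ĥ_unc`, `Ĥ_Δe`), plus the
   degradation protocol that evaluates them.
6. **Synthetic mobility simulator and sweep harness** — seeded multi-week
   trajectories over anchor locations with known ground truth, and drivers
   that sweep spatial parameters and `Δt`, summarising every metric by
   median and IQR across a population.

## Worked example

Simulate one synthetic individual (five anchor locations on a circle, a
week of data, 4 % of hour windows missing), then run the whole pipeline:

```r
library(movepredict)

ang <- seq(0, 2 * pi, length.out = 6)[1:5]
anchors <- cbind(10000 + 5000 * cos(ang), 10000 + 5000 * sin(ang))
P <- matrix(1 / 4, 5, 5); diag(P) <- 0; P <- P / rowSums(P)
cfg <- mobility_config(anchors, P, duration_days = 7, gnss_noise_sigma = 10,
                       missing_fraction_target = 0.04, seed = 11)
sim <- generate_trajectory(cfg, user_id = "u1")
nrow(sim$trajectory)
#> [1] 2415

sp <- detect_staypoints(sim$trajectory, delta = 300, tau = 600)
nrow(sp)
#> [1] 40
a <- dbscan_aggregate(sp, eps = 300)
a
#> <region_assignment> method=dbscan parameter=300: 40 stay-points in 5 regions

visits <- region_visit_sequence(sp, a)
tb <- build_time_bin_sequence(visits, delta_t = 3600)
np <- build_next_place_sequence(visits)
predictability_profile(tb)
#>     n L s_rand s_unc s_est pi_rand pi_unc pi_max degenerate
#> 1 165 5   2.32  2.24  1.55     0.2  0.343  0.677      FALSE
predictability_profile(np)
#>    n L s_rand s_unc s_est pi_rand pi_unc pi_max degenerate
#> 1 40 5   2.32   2.3  2.05     0.2  0.274  0.476      FALSE
```

The clustering recovers exactly the five anchors. The hourly time-bin
sequence (165 non-null bins) is far more predictable (`Π_max ≈ 0.68`) than
the next place sequence of the same week (`Π_max ≈ 0.48`): hour bins are
dominated by self-transitions — the easy "stays put" predictions — whereas
the next place representation keeps only the genuinely uncertain
transitions between places. `Π_rand = 1/L = 0.2` is the random-guessing
floor over five places.

For population-scale experiments see `simulate_population()`,
`run_spatial_sweep()` and `run_temporal_sweep()`; for incomplete sequences
see `estimate_H_shuff()`, `estimate_H_unc()`, `build_delta_e_curve()` /
`estimate_H_delta_e()` and `evaluate_estimators()`.

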