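# syllakin

Subsecond analysis of rodent open-field locomotion from keypoint
trajectories: segmentation into behavioral **syllables** with a sticky
autoregressive hidden Markov model (AR-HMM), and the downstream kinematic
and sequence statistics used to characterize hypokinetic phenotypes (e.g.,
parkinsonian mouse models) and their response to treatment.

## Who this is for

Behavioral neuroscientists and computational ethologists who have top-down
keypoint tracking (DeepLabCut-dialect CSVs: per-part x, y, likelihood at a
fixed frame rate) of mice in an arena and want, per animal and per group:

- per-syllable **velocity** (mm/s) and **usage** (fraction of time), with
  the conventional >0.5% expression filter;
- syllable **durations**, **transition matrices**, **steady-state
  distributions**, **entropy rate**, and **transition frequency** (/s);
- nonparametric group comparisons: Kruskal–Wallis + Dunn's post hoc with
  Benjamini–Hochberg FDR control across syllables, Mann–Whitney U for
  scalar session metrics, and OLS regressions of Δ-metrics against control
  syllable velocity.

A first-class synthetic-data module simulates multi-animal cohorts with
known ground truth (control, lesion-like, and velocity-rescued "treatment"
conditions), so the entire pipeline is testable without videos.

## The model

Poses are egocentrically aligned (centroid at the origin, tail-base→nose
axis along +x), reduced to 5 principal components, and modeled by a
finite weak-limit sticky AR-HMM: per state *k*, the latent pose
`y_t = A_k [y_{t-1};…;y_{t-L}] + b_k + ε_t`, `ε_t ~ N(0, Σ_k)`, with
Dirichlet transition rows of concentration `α/K_max` per cell plus a
self-transition pseudo-count `κ` on the diagonal (defaults `α = 5.7`,
`γ = 10³`, `K_max = 100`). Fitting is blocked Gibbs sampling
(forward-filter backward-sample labels; conjugate matrix-normal
inverse-Wishart updates for the AR parameters). `κ` sets syllable
durations and is chosen by a **kappa scan**: fit across a grid, keep the
model whose median syllable duration is closest to 400 ms (~12 frames at
30 fps).

Sequence statistics follow the standard motion-sequencing conventions:
transition matrices are built on the run-length-encoded label sequence
(self-transitions excluded), the steady state `π` solves `πA = π`, and the
entropy rate is `H = −Σ_ij π_i A_ij log₂ A_ij` (bits).

## Worked example

```r
library(syllakin)

# a 6-syllable world: control vs a severity-0.8 lesion-like condition
rep0   <- build_repertoire(6, c(0, 160), seed = 11)
trans0 <- build_transition_model(6, target_mean_duration = 0.4, fps = 30,
                                 seed = 12)
lesion <- apply_condition(rep0, trans0, lesion_transform(rep0, severity = 0.8))

sim <- simulate_session(rep0, trans0, duration = 120, fps = 30, seed = 1)
ps  <- egocentric_align(gate_and_interpolate(sim$recording))
sp  <- centroid_speed_series(ps$centroid, 30)
seq0 <- syllable_sequence(sim$truth$labels, fps = 30)

round(syllable_velocity(sp, seq0), 1)
#>     0     1     2     3     4     5
#> 154.9  84.6  51.7  34.4  34.0  31.1
round(usage(seq0), 3)
#>     0     1     2     3     4     5
#> 0.296 0.092 0.212 0.031 0.290 0.079
transition_frequency(seq0)
#> [1] 2.7
```

Syllable 0 is the fastest (true speed 160 mm/s by construction; measured
154.9 over a 2-min session); the slowest syllables are effectively
motionless, and their measured ~31–34 mm/s is the calibrated
tracking-noise baseline (`calibrate_noise(30, 30)` mm jitter per
coordinate). Transition frequency sits near `1/0.4 s ≈ 2.5 /s`, the
reciprocal of the target syllable duration.

A full experiment — simulate cohorts, preprocess, kappa-scan + fit,
decode, metrics, group statistics — runs from one config:

```r
cfg <- experiment_config(groups = list(control = list(n_animals = 6, severity = 0),
                                       lesion  = list(n_animals = 7, severity = 0.8)),
                         seed = 1)
res <- run_experiment(cfg, out_dir = "out")
res$delta$lesion$velocity_regression   # Δvelocity ~ control velocity
```

The package also ships published per-syllable summary tables
(`reference_syllable_table("6ohda")`, `"mitopark"`) as plain-CSV fixtures;
regressing Δvelocity on control velocity over the 21 retained syllables of
the 6-OHDA table gives R² = 0.869, and Δusage gives R² = 0.267 — the
desk-scale reproduction checks in `tests/testthat/test-acceptance.R`.

## Command line

```sh
Rscript inst/scripts/syllakin simulate --seed 4 --out data --n-animals 3 --condition lesion --severity 0.8
Rscript inst/scripts/syllakin run --config cfg.json --out results
```

Verbs: `simulate | preprocess | fit | scan-kappa | apply | metrics |
compare | run`. Exit code 0 on success, 2 on validation errors.

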