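---
title: "Methods: syllable segmentation and kinematic statistics in syllakin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: syllable segmentation and kinematic statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its science: the models and
conventions it implements, the parameters that matter, what the synthetic
generator does and does not emulate, and the design choices made where the
design was genuinely open. It states no empirical result that the test
suite does not itself compute.

## 1. The pipeline

Open-field keypoint recordings (per-part x, y, likelihood at a fixed frame
rate, mm units) pass through five stages:

1. **Confidence gating** (`gate_and_interpolate`): coordinates below a
   likelihood threshold are replaced by per-part linear interpolation
   between the nearest confident frames (nearest-value fill at the edges);
   filled frames keep the threshold as their likelihood so gating is
   auditable. A part with no confident frame at all is an error, not a
   guess.
2. **Egocentric alignment** (`egocentric_align`): per frame, the centroid
   (unweighted mean of all tracked parts) moves to the origin and the pose
   rotates so the tail-base→nose axis points along +x. Only posture
   remains; location and heading are kept separately (`centroid`,
   `heading`). "Cropping" has no meaning for keypoint data, so alignment is
   the whole of this stage.
3. **PCA** (`fit_pca`, 5 components by default): flattened aligned
   coordinates, pooled over sessions, per-feature centering, no whitening
   (a flag exists, default off). Five components comfortably capture the
   postural variance of an 8-part top-down skeleton.
4. **Sticky AR-HMM segmentation** (`fit_arhmm`, `kappa_scan`, `decode`).
5. **Metrics and statistics** (the `*_velocity`, `usage`,
   `transition_matrix`, `entropy`, `kw_dunn`, … family).

## 2. The segmentation model and its knobs

The latent series is modeled by a hidden Markov model whose state-*k*
emission is a linear autoregression of order *L*:

$$y_t = A_k\,[y_{t-1};\dots;y_{t-L}] + b_k + \varepsilon_t,\qquad
\varepsilon_t \sim \mathcal N(0, \Sigma_k).$$

The transition prior is the finite weak-limit realization of the sticky
HDP-HMM: each row is Dirichlet with concentration $\alpha/K_{\max}$ per
cell plus a pseudo-count $\kappa$ on the diagonal. Parameters and defaults:

| knob | default | units / role |
|---|---|---|
| `alpha` | 5.7 | Dirichlet concentration of transition rows |
| `gamma` | 1e3 | top-level HDP concentration; documented but inactive in the finite approximation |
| `kappa` | scanned | self-transition pseudo-count; sets syllable duration |
| `K_max` | 100 | state-space truncation |
| `ar_order` | 3 | AR lags (the model is robust to this; tests use 1 for speed) |
| `mniw_k0`, `mniw_s0`, `mniw_dof` | 1, 1, d+2 | MNIW prior: column precision, innovation scale, inverse-Wishart dof; the prior mean puts the identity on the most recent lag |
| `n_iter`, `burn_in` | 500, 200 | Gibbs sweeps; the **final sample** defines model and labels |

Inference alternates forward-filter backward-sampling of the labels with
conjugate updates (matrix-normal inverse-Wishart per state; Dirichlet rows
with the sticky diagonal). Everything is driven by R's RNG, so a fixed
seed reproduces a fit bit-exactly. Viterbi decoding (`decode`) gives a
deterministic path for applying a fitted model to new sessions.

The number of sweeps, the burn-in, and the single-final-sample convention
are declared choices, not inferences: label-consuming metrics need one
segmentation, and posterior averaging of labels has no canonical meaning
under state relabeling.

**Kappa scan.** `kappa_scan` fits one model per grid value with identical
seeds and hyperparameters, computes each fit's median syllable duration,
and keeps the kappa closest to the 400 ms target (~12 frames at 30 fps);
ties go to the smaller kappa. The companion human criterion used in
practice — do the syllables look behaviorally meaningful on video? — is
not automatable; the scan table is returned in full so that judgment can
be exercised downstream. This is a deliberate, documented narrowing.

## 3. Metric conventions

- **Syllable velocity**: mean of the per-frame centroid displacement norm
  (×fps, mm/s) over the frames carrying each label. Missing syllables are
  *missing*, not zero — zeros would deflate group means.
- **Session velocity**: total path length divided by session time
  (frames/fps).
- **Usage**: fraction of *frames* (time basis), matching per-frame label
  assignment and the ">0.5% of the time" expression filter
  (`filter_expressed`, default threshold 0.005, strictly greater).
- **Transition matrix**: built on the run-length-encoded sequence —
  self-transitions excluded, the standard motion-sequencing convention.
  When filtering to an alphabet removes a run between two runs of the same
  syllable, the resulting self-pair is skipped rather than counted. Rows
  with no outgoing counts stay zero and are excluded from entropy sums.
- **Entropy**: the textbook entropy rate
  $H=-\sum_{ij}\pi_i A_{ij}\log_2 A_{ij}$ returned **positive** and in
  **bits** by default. The field sometimes writes this formula without the
  minus sign and sometimes sums unweighted per-row entropies; both the
  sign convention and the `local_sum` mode are explicit switches recorded
  in the `transition_summary`. Bits were chosen because reported entropy
  values in comparable open-field studies (≈5.2–5.8 over ≤99 states)
  exceed ln 99 ≈ 4.6, which rules out nats.
- **Steady state**: power iteration to 1e-12 on the recurrent support; a
  reducible chain picks the closed class holding the most empirical usage
  and warns.
- **Aggregation**: per animal first, then mean ± sem within groups; the BH
  family is the retained syllable set per metric per comparison (not
  across metrics).

## 4. What the generator emulates — and what it does not

No generative model of mouse behavior is given by observation alone, so
the simulator is a minimal Markov-switching kinematic world containing
exactly the ingredients every downstream metric consumes:

- a per-frame Markov chain of syllables whose self-transition probability
  is set from a target mean duration (geometric dwell times; default
  400 ms at 30 fps);
- per-syllable constant centroid speeds spanning a realistic range
  (defaults 0–172 mm/s, the span seen in open-field mice), sorted so index
  0 is the fastest; the slowest syllable is pinned to the range minimum,
  which for the default range means a true-speed-zero freezing syllable.
  When a nonzero range minimum is requested the invariant "one motionless
  syllable" is deliberately relaxed in favor of covering the requested
  range — the degenerate-range case keeps all speeds identical;
- a heading random walk (sd 0.15 rad/frame, plus a small per-syllable
  drift) so turning exists without modeling turn syllables explicitly;
- stable AR(1) pose dynamics per syllable around a rigid 8-part skeleton
  template (spectral radius < 1, so poses stay bounded);
- reflecting arena walls (a 400×400 mm walled box, not a torus);
- **common-mode tracking jitter** calibrated so a motionless animal shows
  the desired baseline velocity. For i.i.d. Gaussian jitter of sd σ per
  coordinate, the per-frame displacement of a still point is Rayleigh with
  mean σ√π, so σ = v/(fps·√π); v = 30 mm/s by default, the typical
  motionless baseline of keypoint tracking. The jitter is shared across
  parts within a frame (whole-detection wobble) so the calibration holds
  for the *centroid* that velocity metrics actually use; independent
  per-part noise is carried by the AR pose dynamics instead.

Condition transforms deform this world the way dopamine depletion deforms
behavior: speeds shrink proportionally to their control value
(`speed × (1 − severity·slope·speed/max)`, so fast syllables lose most),
off-diagonal transition mass is re-weighted by per-syllable log-odds
(default: down for fast, up for slow syllables, ±0.8 log-odds per sd of
speed), and the diagonal is inflated (stickiness gain 1.5 at severity 1 —
fewer transitions per second). The magnitudes of the usage shifts are free
parameters: the emulated studies report directions, not effect sizes, so
the defaults were chosen once to produce clearly detectable but not
caricatured shifts at cohort sizes of 6–9 animals, and are not revisited.
`restore_velocity_only = TRUE` undoes only the speed scaling — the
velocity-rescuing, sequence-sparing action of dopaminergic treatment — and
severity 0 is the exact identity.

What a green test does **not** establish: real pose dynamics are neither
linear nor constant-speed within syllables; real tracking noise is
heavy-tailed and occlusion-structured, not Gaussian; real usage shifts
need not follow a monotone function of speed; and grooming/rearing
biomechanics, depth (z), and drug pharmacokinetics are entirely absent.
Ground-truth-label recovery therefore validates the *computations*, not
the ethological fidelity of any particular dataset.

## 5. Numerical choices and degenerate inputs

- Durations: run lengths / fps; a single-frame sequence has one run and
  zero transitions; `transition_frequency ≡ (runs − 1)/(frames/fps)`.
- Coincident nose/tail-base frames reuse the previous frame's heading
  (first frame: 0) and warn.
- Gibbs label sampling conditions on frames t > L; the first L frames
  inherit the first effective label (same for Viterbi).
- Posterior covariance draws add 1e-8 to the scale-matrix diagonal before
  Cholesky as insurance against numerically singular updates.
- Ties in the kappa scan and in greedy label matching resolve to the
  smaller kappa / the largest remaining confusion cell.
- Kruskal–Wallis with all values identical returns H = 0, p = 1 rather
  than 0/0.
- Mann–Whitney uses exact enumeration iff n·m ≤ 400 and tie-free,
  otherwise the tie-corrected normal approximation.
- `steady_state` finds closed classes by boolean reachability (repeated
  squaring), so transient states get π = 0 exactly.

## 6. Known limitations

- The segmentation engine is the AR-HMM on PCA latents; the joint
  keypoint-noise model that full keypoint-based motion sequencing adds on
  top is out of scope. Every reported metric consumes only labels, which
  is why the AR-HMM is the right minimal engine, but label boundaries on
  real noisy keypoints can differ.
- `gamma` is exposed but inert under the finite Dirichlet approximation;
  it exists so configs that sweep it remain valid if an HDP backend is
  ever added.
- HDF5 containers are not written (no HDF5 binding is assumed at runtime);
  CSV/JSON cover all interchange.
- The CLI is a thin convenience layer; programmatic use through
  `run_experiment()` is the contract-bearing surface.
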