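# semgdiscrim

Forearm surface-EMG (sEMG) feature extraction and discriminant screening for
hand osteoarthritis (HOA).

Women with HOA recruit their forearm muscles differently from healthy
controls while performing everyday manual tasks. `semgdiscrim` implements the
complete analysis that turns multichannel forearm sEMG recorded during the
Sollerman hand function test (SHFT, 20 daily-living tasks) into screening
classifiers:

* **Signal conditioning** — zero-phase 4th-order Butterworth band-pass
  (25–500 Hz) and 50 Hz band-stop; rectification with Gaussian smoothing
  (σ = 50 ms) into activation envelopes, resampled to 1000 frames.
* **Amplitude normalization** — three per-participant, per-sensor
  denominators: MAX (peak over all functional tasks), MVC (peak over
  maximal-voluntary-contraction movements), GRASP (peak over maximal-effort
  grasps).
* **Features** — per task: the normalized envelope's median *M* and range
  *R* (max − min); and two normalization-free waveform descriptors of the
  band-passed signal, the zero-crossing rate
  `NZC = (1000/L) Σ 1{x_i x_{i+1} < 0}` and the enhanced wavelength
  `EWL = (1000/L) Σ_{i=2}^{L} |x_i − x_{i−1}|^{p_i}` with `p_i = 0.75` for
  `0.2L ≤ i ≤ 0.8L` and `0.5` otherwise, each min–max rescaled to [0, 1]
  across the participant's tasks and averaged over tasks.
* **Statistics** — Shapiro–Wilk-gated two-group tests (one-way ANOVA /
  Kruskal–Wallis) per variable and per task with +/− sign matrices; mixed
  repeated-measures ANOVA on the normalization values (group × sensor ×
  method) with Tukey's-B homogeneous subsets.
* **Discriminant analysis** — Box's M; stepwise linear discriminant
  analysis selected by Wilks' lambda (`Λ = det(W)/det(T)`, entry p < 0.05,
  removal p > 0.10); raw-score Fisher classifier with the clinical sign
  convention (score < 0 ⇒ patient); leave-one-out cross-validation reporting
  accuracy, sensitivity, and specificity; plus five frozen published
  classifiers (`F_MAX`, `F_MVC`, `F_GRASP`, `F_Waveform`, `F_NoMVC`), e.g.
  `F_Waveform = −8.738·EWL1 + 9.624·NZC4 − 1.481`.
* **Synthetic cohorts** — a seeded two-group generator (activation envelopes
  modulating band-limited Gaussian noise) with controllable group effects and
  ground truth, used for null calibration and effect-recovery testing.

## Worked example

Simulate a reduced cohort (10 + 10 participants, 7 sensors, 5 functional
tasks) in which patients reach only 60% of their true maximal effort on
sensors 2 and 4 — pain-limited MVC — and run the whole pipeline:

```r
library(semgdiscrim)

cfg <- cohort_config(n_healthy = 10, n_patients = 10, n_sensors = 7,
                     n_shft_tasks = 5, n_mvc_tasks = 2, n_grasp_tasks = 2,
                     task_duration_s = 0.5, seed = 42,
                     effect = group_effect(mvc_amplitude_scale = 0.6,
                                           affected_sensors = c(2, 4)))
res <- run_full_analysis(run_config(cohort = cfg))
res
#> <semg_analysis> 20 participants, 13/56 variables significant
#>   MAX       no model
#>   MVC       vars: M_MVC2, M_MVC4 | LOOCV acc 100.0% (sens 100.0%, spec 100.0%)
#>   GRASP     vars: M_GRASP4, M_GRASP2 | LOOCV acc 95.0% (sens 90.0%, spec 100.0%)
#>   Waveform  vars: EWL4 | LOOCV acc 75.0% (sens 70.0%, spec 80.0%)
#>   NoMVC     vars: EWL4 | LOOCV acc 75.0% (sens 70.0%, spec 80.0%)
```

The stepwise LDA recovers exactly the injected effect: the MVC- and
GRASP-normalized medians on sensors 2 and 4 — the variables a pain-limited
maximal effort inflates — separate the groups almost perfectly under
leave-one-out cross-validation, while MAX normalization (which never sees the
maximal-effort tasks) finds nothing. Per-variable comparisons, per-task sign
matrices, the repeated-measures ANOVA table, and fitted models with their
Wilks' lambdas are all in the returned object; `output_dir =` writes them as
CSV/JSON with a content-hash manifest.

The frozen published classifiers apply directly to task-averaged SHFT
parameters (score < 0 classifies as patient):

```r
evaluate_published_classifier("F_Waveform", list(EWL1 = 0.3, NZC4 = 0.6))
#> # A tibble: 1 × 2
#>   score class
#>   <dbl> <chr>
#> 1  1.67 healthy
```

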