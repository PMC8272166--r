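# pedometry

Step-detection algorithms and gait-regularity benchmarking for wearable
accelerometry.

Pedometers are accurate when gait is *regular* — the long uninterrupted
periodic walking of exercise — but most daily steps happen in
*semi-regular* gait (walking through buildings, broken by doors, stairs
and stops) or *unstructured* gait (within-room activity: 3–10-step bouts
separated by long idle periods full of non-step motion). Boundary motions
— first/last steps of a bout, pivots, shuffles — are **shifts**: foot
movements outside any repeating pattern, rising from ≈0.4% of events in
regular gait to ≈17% and ≈35% in semi-regular and unstructured gait. This
package lets you study how step counters degrade as regularity falls,
with no data collection required:

* **Simulator** — `gait_profile()` / `simulate_gait()`: tri-axial 15 Hz
  accelerometer recordings (±2 g) for the three regimes and three sensor
  positions (wrist/hip/ankle), with exact ground-truth step/shift
  annotations. Deterministic per seed.
* **Detectors** — `step_detector()` + `detect_steps()` (or `predict()`):
  the three classic families — peak detection with periodicity/similarity/
  continuity gating, dynamic-threshold crossing with timing regulation,
  and adaptive-window normalized autocorrelation.
* **Evaluation** — `evaluate_detection()` / `summarize_reports()`: running
  count accuracy `RCA = #detected / #truth` (1 is ideal, >1 overcounts),
  plus precision/recall/F1 from greedy one-to-one matching within a closed
  0.5 s tolerance; shifts countable or not via the ground-truth mode.
* **Tuning** — `tune_detector()` / `grid_search()`: the train-once
  protocol (grid search on regular-gait wrist recordings, mean |RCA − 1|
  criterion), with unit (`normalize_units()`, m/s² ↔ g by 9.8) and
  sampling-rate (`rescale_sample_indices()`) parameter normalization.
* **Experiment runner** — `run_experiment()`: the full regime × position ×
  algorithm benchmark with aggregate tables, byte-reproducible under a
  fixed seed. A thin CLI lives at `inst/scripts/gaitbench`.

## Worked example

Simulate ten minutes of unstructured (within-room) activity seen from a
wrist sensor, then count steps with each detector family:

```r
library(pedometry)

sim <- simulate_gait(gait_profile("unstructured", "wrist",
                                  duration_s = 600, seed = 7))
print(sim)
#> <gait_simulation> unstructured gait at the wrist: 152 steps + 81 shifts (34.8% shifts)
#> <accel_recording> 9000 samples @ 15 Hz (600.0 s), position: wrist
#>   magnitude: median 1.009 g, range [0.544, 1.644] g

for (a in c("peak", "threshold", "autocorr")) {
  steps <- detect_steps(step_detector(a), sim$recording)
  print(evaluate_detection(steps, sim$events, mode = "steps_only",
                           regime = "unstructured", position = "wrist"))
}
#> <eval_report> peak | unstructured gait | wrist | steps_only
#>   RCA 2.618 (398 detected / 152 truth); TP 123 FP 275 FN 29; P 0.309 R 0.809 F1 0.447
#> <eval_report> threshold | unstructured gait | wrist | steps_only
#>   RCA 3.270 (497 detected / 152 truth); TP 120 FP 377 FN 32; P 0.241 R 0.789 F1 0.370
#> <eval_report> autocorr | unstructured gait | wrist | steps_only
#>   RCA 0.895 (136 detected / 152 truth); TP 89 FP 47 FN 63; P 0.654 R 0.586 F1 0.618
```

The pattern is the central finding in miniature: on this recording the
peak and threshold detectors report 2.6× and 3.3× the true step count —
their false positives are mostly peaks and midline crossings produced by
idle-period fidgeting — while the autocorrelation detector, which demands
window-to-window self-similarity before counting, stays within ≈10% of
truth. On a regular-gait recording all three families land within a few
percent of RCA 1 (try `regime = "regular"` above). Aggregate the same
comparison over many recordings with `run_experiment()`, which prints a
per-algorithm × per-regime RCA table for both ground-truth modes.

The methods vignette (`vignettes/gait-regularity-benchmark.Rmd`) documents
the signal model, every tunable parameter with units and defaults, the
training protocol, and what the simulator does and does not emulate.

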