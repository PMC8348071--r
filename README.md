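# cscine

Arrhythmia degrades segmented cine cardiac MRI: every frame's k-space is
assembled from many heartbeats, so when the RR interval varies, data from
inconsistent cardiac phases are merged and the ventricular wall borders
blur and ghost (arrhythmia-related artifacts, ARA). Single-shot real-time
cine with compressed-sensing (CS) reconstruction acquires every frame
inside one heartbeat and is therefore structurally immune to cross-beat
phase mixing, at the price of heavy random undersampling recovered by an
iterative sparse reconstruction.

`cscine` is an R package for scientists who want to study this trade-off
quantitatively without patient data. It provides:

- **Rhythm** — generators for irregular RR-interval series (atrial
  fibrillation, ectopy, dropped beats), the irregularity index
  CV_RR = 100·SD/mean, and the strict >10 % irregularity classifier.
- **Phantom** — a dynamic 2D left-ventricular phantom with bSSFP-like
  bright-blood contrast and a cosine-smoothed contraction law.
- **Acquisition** — k-space level simulators of both arms: prospectively
  triggered segmented acquisition across many variable heartbeats (13
  views per frame, window clamped to the shortest RR) and single-shot
  real-time acquisition (49 ms frames, 11-fold variable-density random
  undersampling, 12 fully sampled central lines) reconstructed by 40
  cycles of temporal-Fourier soft-thresholding with hard data
  consistency.
- **Metrics** — the edge-spread-function sharpness metric
  ε = 1/d, where d is the distance in pixels between the 20 % and 80 %
  crossings of the local intensity rise across the septum/blood-pool
  edge; the modified EuroCMR artifact score (items 1–8, maximum 10); and
  ARA-rate bookkeeping per slice stack.
- **Statistics** — the paired battery for sequence comparison: Wilcoxon
  signed-rank with midranks and exact enumeration up to n = 25, paired
  t, ICC(2,1)/ICC(3,1), Cohen's kappa (plain or linearly weighted),
  median (range) summaries.
- **Cohort pipeline** — a seeded synthetic-cohort runner pairing both
  arms per patient, plus fixtures transcribing the published paired
  cross-tabulations of a 71-patient clinical comparison.

## Worked example

```r
library(cscine)

# an atrial-fibrillation-like rhythm at 25 % target CV
rr <- generate_rr(arrhythmia_spec(mean_rr = 850, pattern = "afib",
                                  target_cv = 25, n_beats = 128, seed = 42))
glance(rr)
#> # A tibble: 1 x 6
#>   n_beats mean_rr_ms sd_rr_ms cv_rr_pct mean_hr_bpm irregular
#> 1     128       846.     216.      25.5        70.9 TRUE

# acquire the same beating phantom with both schemes
spec  <- phantom_spec(grid = 96)
truth <- truth_stack(spec, n_phases = 20)
seg   <- simulate_segmented(spec, ref_params(seed = 42), rr)
rt    <- temporal_interpolate(simulate_realtime(spec, rt_params(seed = 42), rr), 20)

# end-systolic septal edge sharpness (px^-1)
k <- which.min(abs(truth$phases - spec$systole_fraction))
sapply(list(truth = truth, segmented = seg, realtime = rt), function(st)
  septal_sharpness(st$frames[, , k], spec, truth$phases[k])$epsilon)
#>     truth segmented  realtime
#>    0.6363    0.2801    0.5988

stack_rmse(seg, truth)
#> [1] 0.0557
```

At 25 % RR variability the segmented arm's end-systolic edge sharpness
collapses (0.28 vs 0.64 px⁻¹ for the noiseless reference) while the
real-time CS arm stays close to truth (0.60 px⁻¹) — the package's
mechanistic rendering of why real-time CS cine resists arrhythmia. With a
perfectly regular rhythm the segmented arm reproduces the ground truth to
numerical precision.

The shipped cross-tabulation fixtures reproduce the published paired
summaries directly:

```r
reproduce_printed_tables(cscine_fixture("subjective_quality_crosstab.json"))
#> <crosstab_report> n = 71 | median ref 2.0 (1-4), rt 3.0 (1-3) |
#>   rt equal-or-better 63/71 (88.7%) | Wilcoxon p = 1.83e-06
```

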