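---
title: "Simulating arrhythmia-related artifacts in cine CMR: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating arrhythmia-related artifacts in cine CMR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cscine)
```

## The problem

Segmented cine cardiac MRI splits each frame's k-space over many
heartbeats: heartbeat *h* contributes a block of phase-encode lines to
every frame, under the assumption that a fixed delay after the R peak
always finds the heart in the same state. When the RR interval varies,
that assumption fails — a delay of *t* milliseconds corresponds to
cardiac phase *t*/RR, which differs from beat to beat — and the merged
k-space mixes inconsistent anatomy, producing the blurring and ghosting
of ventricular wall borders known as arrhythmia-related artifacts (ARA).
Single-shot real-time acquisition collects each frame within one
heartbeat, so no cross-beat mixing is possible; the cost is an
undersampling factor around 11, recovered by compressed-sensing (CS)
reconstruction.

`cscine` renders this mechanism end to end: rhythm generation, phantom,
k-space simulation of both arms, the image-quality metrics used
clinically (edge sharpness, a modified EuroCMR artifact score, ARA
rate), and the paired statistics that compare the two sequences. This
vignette records the model assumptions, the tunable parameters, and the
design decisions taken where the problem was genuinely open.

## Rhythm model

`cv_rr()` implements the irregularity index, CV~RR~ = 100·SD/mean of the
beat durations, with the *sample* standard deviation (divisor n − 1) by
default. The divisor is not dictated by the definition; the sample
estimator is the conventional choice on a finite beat list and a
`sd_type = "population"` switch is provided. `classify_irregular()` uses
a strict inequality at the 10 % threshold, matching the usual enrolment
wording ("greater than 10 %").

`generate_rr()` provides three mechanistically distinct rhythm
disturbances, mirroring the main clinical causes of an irregular pulse
(atrial fibrillation, ventricular ectopy, conduction block):

- **afib** — i.i.d. log-normal durations; the log-normal keeps durations
  positive at high CV and its two parameters are solved exactly from the
  (mean, CV) moment equations.
- **ectopy** — a jittered baseline into which pairs of
  (short-coupled beat, compensatory pause) of the form m(1 ∓ δ) are
  interleaved; the pair fraction and coupling δ are solved from the
  variance budget, with δ capped at 0.75 where the budget allows.
- **pauses** — occasional dropped beats double a cycle; the pause
  fraction q solves the variance equation under a baseline rescaling
  that keeps the realised mean at the requested value, with a minimum of
  one pause per series (a pause rhythm with zero pauses is degenerate).

All three are moment-calibrated: across seeds the mean realised CV lands
within a few percent of target, and single series of ≥ 64 beats within
roughly ±20 % relative. Every stochastic operation takes an explicit
seed and restores the caller's RNG state; there is no global default
seed.

## Phantom

The phantom is deliberately minimal: a bright circular blood pool inside
a darker myocardial annulus (blood 1.0, myocardium 0.35, background 0.05
in arbitrary units — bSSFP-like contrast ordering), on a square grid of
168 px by default (echoing the short axis of a typical real-time
acquisition matrix; tests and the desk-scale cohort use 64–96 px). The
endocardial radius contracts from end-diastole (phase 0) to end-systole
(`systole_fraction`, default 0.35 of the cycle, a resting-physiology
value) by `contraction_fraction` (default 0.35) under a cosine-smoothed
envelope, then recovers symmetrically; the epicardial radius follows by
conservation of the annulus area, so the wall thickens in systole. The
cosine smoothing is intentional: the motion model itself must not
introduce velocity discontinuities, so that any k-space ringing is
attributable to arrhythmia, not to the phantom. Rasterisation is
anti-aliased and followed by a Gaussian blur of `edge_softness` = 0.8 px
so the ground-truth edge sharpness is finite and measurable.

A 2D single-slice phantom suffices because every metric in the package
(profile-line sharpness, per-slice artifact flags) is a 2D per-slice
quantity. Papillary muscles, through-plane motion, coil sensitivities and
off-resonance physics are deliberately out of scope.

## Acquisition simulation

**Segmented arm.** `plan_segmented()` assigns heartbeat *h* the
sequential line block [(h−1)·v + 1, h·v] (v = 13 views per frame by
default) for every frame, and records the *true* phase
(f − 1)·Δt/RR~h~ at which those lines are acquired. The acquisition
window `n_phases × temporal_resolution` (20 × 41.2 ms) is clamped to the
shortest RR interval, as prospective triggering requires; clamping
shrinks the effective frame duration, so nominal late frames sample
earlier true phases — exactly the behaviour of a fixed-window prospective
protocol. `simulate_segmented()` then merges, per frame, each
heartbeat's DFT rows of the phantom rendered at that heartbeat's
recorded phase. With constant RR the merge is coherent and reproduces
the ground truth to machine precision; with variable RR the artifacts
emerge mechanistically rather than being painted on. Sequential line
ordering is the default; ordering changes ghost morphology, not the
existence of ghosts.

**Real-time arm.** Frames tile one heartbeat at 49 ms spacing, so a
cycle of length RR yields ⌊RR/49⌋ frames (16 at 75 bpm, fewer above).
Each frame's k-space is sampled on a fresh seeded variable-density
random mask — Gaussian density with σ = n~lines~/6 over the phase-encode
lines, 12 central lines always kept, total lines = n~lines~/acceleration
with acceleration 11 — and reconstructed jointly by `cs_reconstruct()`.

**Reconstruction.** The vendor prototype's sparsifying transform and
regularisation are unpublished, so the package uses the standard
temporal-Fourier soft-thresholding scheme and says so: each of 40
iterations applies (i) soft-thresholding of the temporal-Fourier
coefficients with λ = 0.02 × the maximum coefficient magnitude of the
zero-filled reconstruction, then (ii) hard data consistency (measured
k-space entries restored). The ordering makes two limits exact: with
full sampling the output equals the inverse transform of the data after
one iteration, and with λ = 0 the zero-filled reconstruction is a fixed
point. A numerical note: because data consistency is a hard projection,
the post-projection residual is identically zero and the monitored
residual (recorded before each consistency step) measures the shrinkage
perturbation; it converges to a fixed point but is *not* guaranteed to
decrease monotonically — for temporally static inputs it approaches its
plateau from below. The `residuals` attribute exposes the full sequence
for convergence checks.

`temporal_interpolate()` maps a variable-length real-time stack onto the
standard 20-phase grid by periodic linear interpolation in cardiac
phase, mimicking the standardisation clinical post-processing requires;
the interpolation's smoothing is a real effect the package reproduces
rather than hides.

The reference arm is treated as fully sampled for artifact purposes: its
nominal "acceleration 2" in clinical protocols denotes parallel
imaging, which (like coil arrays generally) is outside this package's
single-coil Cartesian scope. Optional complex Gaussian k-space noise is
available in both arms but off by default so that every simulation is a
deterministic function of its seed.

## Edge sharpness

`edge_sharpness()` implements the edge-spread-function metric: ε = 1/d
with d the distance between the 20 % and 80 % crossings of the intensity
rise between the *local* extrema flanking the steepest edge. Local —
not global — extrema matter because artifact-laden profiles carry extra
peaks (a doubled septal border, ghosts) that corrupt global extrema.
Operationally: the steepest-gradient position is found (inside the
caller's `window`, which mimics a reader's manual line placement when
several edges are present); on each side the flanking plateau is the
region beyond the point where the gradient magnitude falls below 5 % of
its peak (and before it rises above 5 % again); the plateau level is a
robust extreme of that region — the median of its five most extreme
samples. Crossings are located by linear interpolation between samples
taken every 0.1 px along the profile, giving sub-pixel resolution well
below the three decimals at which ε is conventionally reported.

Two details were deliberately chosen. First, taking the plateau level as
a robust extreme (rather than the first few samples past the 5 % point)
makes the estimator agree with the closed form for a Gaussian-blurred
step — d = 1.6832 σ, from 2 Φ⁻¹(0.8) σ — to well under 1 % for σ ≥ 2 px,
which a "first samples past the knee" rule misses by ~1.7 % because the
profile is still rising there. Second, profiles with no plateau at all
(a pure ramp) fall back to the outermost sample, which makes the linear
ramp exact: a 0→100 ramp over 10 px yields x20 = 2, x80 = 8, ε = 1/6
px⁻¹ identically. ε is invariant under positive affine intensity maps
and decreases monotonically in blur width, both of which are enforced by
tests. ε is reported in px⁻¹ and never converted to physical units.

`septal_sharpness()` standardises the measurement on phantom images: a
horizontal profile through the cavity centre crossing the endocardial
border, spanning ±6 px around the current-phase radius — the in-silico
analogue of the mid-cavity line drawn perpendicular across the
septum/blood-pool edge.

## Artifact scoring

`euro_cmr_score()` implements the modified (items 1–8) EuroCMR-style
rubric with maximum 10: coverage (full 0, no apex 2, base or a slice
missing 3, both 5), six per-item slice counts (0/1/2/3 for 0/1/2/≥3
affected slices) whose block contributes min(sum, 3), and coil
activation (inactive 2). The block cap is the only reading under which
the itemised maxima (5 + 3 + 2) reproduce the stated modified maximum of
10; an uncapped per-item sum is available behind
`cap_items_2_7 = FALSE` but is off by default. The score is monotone:
adding an artifact flag never decreases the total.

`ara_rate()` is the percentage of slices flagged with blurring/ARA.
`auto_flag_ara()` automates the reader's blur judgement for simulation
work only: a reconstruction is ARA-flagged when its end-systolic septal
ε falls below 0.75 × the matching ground-truth ε. The threshold is a
package choice (a 25 % sharpness loss is conspicuous on a profile), and
because it references the simulation's own ground truth it has no
clinical analogue — real readers have no artifact-free reference.

## Paired statistics

`wilcoxon_signed_rank()` drops zero differences by default (the classic
convention; the alternative Pratt treatment is behind a flag because
with many tied pairs the choice is material), midranks the absolute
differences, and uses the *exact* null distribution — enumeration over
all 2^n sign assignments via the generating function of the rank sums —
whenever the effective n is ≤ 25, switching to the tie-corrected normal
approximation with continuity correction beyond. The exact path removes
approximation doubt precisely where published cross-tabulations leave
few non-tied pairs. `paired_t()` wraps the classical paired t test and
flags zero-variance differences as degenerate rather than erroring.
`icc_absolute()` defaults to ICC(2,1) — two-way random effects, absolute
agreement, single measure — the standard interobserver choice when
systematic rater offsets should count against agreement; ICC(3,1) is
available. `cohen_kappa()` supports linear weights for ordinal scales.
`median_range()` uses the conventional midpoint of the two central order
statistics for even n, so integer ordinal data can yield half-integer
medians, reported as such.

## Fixtures and the cohort pipeline

Two JSON fixtures transcribe the published paired cross-tabulations of a
71-patient clinical comparison of the two sequences: the 4-point
subjective quality table and the banded artifact-score table (bands 0,
1–3, 4–6, 7–10; per-patient raw scores were not published, so
equal-or-better comparisons are necessarily band-level).
`reproduce_printed_tables()` recomputes medians, equal-or-better
proportions and the Wilcoxon p from the counts alone. One transcription
note: the subjective table's published annotation reports 64/71 patients
equal-or-better, while summing the published cells with
score~rt~ ≥ score~ref~ gives 63/71 (88.7 %); the package reports the
value computed from the counts and ships the published annotation
alongside in the fixture's `printed` block.

`run_cohort()` assembles the full paired experiment: per patient it
draws heart rate (normal, mean 71.8, SD 19 bpm, clipped to 42–116), a
target CV (normal, mean 25, SD 9.4 %, clipped to 10.2–50.9) and a rhythm
pattern (59.2 / 23.9 / 16.9 % for afib / ectopy / pauses) — the
demographic profile of an arrhythmic CMR cohort — regenerates the rhythm
until the >10 % criterion holds, simulates every slice with both arms,
interpolates real time to 20 phases, measures end-diastolic and
end-systolic ε on the mid-stack slice, auto-flags ARA per slice, scores
the rubric, and runs the paired battery. The whole report is a
deterministic function of the configuration and master seed, and
serialises losslessly to JSON.

## Problem sizes and what the tests show

The package's own experiments run at desk scale by choice: the
mechanism study uses a 96-px grid, 20 seeds and CV levels
{0, 10, 25, 40} %; the example cohort uses 8–12 patients with 2–3 slices
on a 64-px grid. At these sizes the simulated study reproduces the
clinical comparison's *direction and mechanism* — segmented-arm error
grows strictly with CV~RR~ while the real-time arm's does not, and the
segmented arm loses end-systolic sharpness that the real-time arm
retains — but not its patient-level magnitudes. Cohort means such as
ε ≈ 0.05 px⁻¹, an 85.9 % ARA rate, or acquisition times depend on true
anatomy, scanner hardware, receive coils and reader behaviour, none of
which the phantom models; the package makes no claim to reproduce them,
and its ε values (≈ 0.6 px⁻¹ on the synthetic edge) are on the
phantom's own scale. Two quantitative honesty notes from the mechanism
study: the real-time arm's error is flat to within ~0.1 % across CV
levels, but a formal slope test can still detect a microscopic positive
trend caused by short cycles yielding fewer acquired frames — a real
protocol property, not an artifact mechanism; and the per-seed
end-systolic ε advantage of real time at CV 25 % holds in roughly three
quarters to 85 % of seeds rather than uniformly, because under
sequential line ordering the heartbeat owning the k-space centre leaves
a sharp low-frequency edge backbone in some draws.

## Known limitations

Single-coil Cartesian simulation; no parallel imaging, SSFP banding,
respiratory motion or reconstruction-failure modes. The CS regulariser
is a standard stand-in, not vendor-faithful. The blur auto-flag requires
ground truth and is simulation-only. Respiratory ghosts, metallic and
shimming artifacts exist only as annotation categories, never simulated.
DICOM support is limited to already-extracted trigger timestamps.
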