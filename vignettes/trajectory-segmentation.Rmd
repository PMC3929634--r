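---
title: "Threshold-based trajectory segmentation: model, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-based trajectory segmentation: model, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skypadr)
```

## The problem

The most common summary of a particle track — the mean of frame-to-frame
("instantaneous") speeds — fails in a characteristic way: a particle that
oscillates inside a confined region has positive instantaneous speed at
almost every frame, yet it is not going anywhere. Instantaneous averages
therefore cannot distinguish an oscillating particle from a moving one,
and they cannot report the fraction of time a particle spends moving at
all. Kymograph analysis solves both problems for one-dimensional motion
by letting the analyst draw line segments only where a *significant* net
displacement occurs, but it is manual, slow and impractical for tracks
that wander in two or three dimensions. The motivating application here
is nuclear movement in differentiating myotubes — nuclei that alternate
between long oscillatory pauses and processive runs — but the method
applies to any tracked particle.

## The segmentation model

This package automates the kymograph reading directly on the coordinates.
Two user parameters define the model:

* **DT — distance threshold** (length units): the smallest net
  displacement the analyst considers significant; a natural choice is the
  particle's own diameter (10 µm for a nucleus).
* **ST — speed threshold** (length/time): the largest speed still
  attributable to oscillatory jiggling; a natural calibration is the
  maximum apparent speed measured during a known oscillatory episode
  (0.20 µm/min in the nuclear-movement setting).

The scan (`skypad_scan()`) anchors at the first frame and computes the
straight-line displacement
\(d(n, n+i) = \lVert \mathbf r_{n+i} - \mathbf r_n \rVert\)
for increasing \(i\) until \(d > DT\) (strictly). That stretch becomes one
segment; its speed is \(d / (i \cdot TF)\), where \(TF\) is the time per
frame; it is classified *moving* if the speed strictly exceeds ST and
*paused* otherwise; the scan restarts from the closing frame. Ties at
either threshold go to the conservative side (not crossed / paused), so
classification is deterministic. If the track ends before DT is crossed
the remaining stretch is emitted as a *residual* segment: a displacement
never confirmed as significant is not called motion. This is why a
particle that is moving right up to the end of a recording scores
slightly below 100% time in motion — the tail cannot be certified.

Segments tile the track exactly (segment \(k+1\) starts at segment
\(k\)'s end frame; spans sum to \(NF-1\) intervals), which the test suite
asserts as an invariant. From the segments, `motion_summary()` derives:

* **mean moving speed** — the unweighted mean of moving-segment speeds,
  mirroring the averaging of kymograph line slopes. When segment
  durations are equal (the common case, since each segment spans roughly
  DT worth of motion) this coincides with the time-weighted mean. A
  particle with no moving segment reports `NA`, not 0, so immobile
  particles do not drag cohort averages down.
* **percent time in motion** — summed moving-segment time over total
  track time \((NF-1) \cdot TF\).
* **pauses** — one pause per maximal run of consecutive non-moving
  segments (paused and residual merged), the granularity at which a
  kymograph reader counts flat stretches; durations are the summed
  elapsed time per run.

## Complementary metrics

**Persistence** (`persistence()`) is the D/T directionality ratio: net
first-to-last displacement over summed step lengths, in \([0,1]\). It is
undefined (and flagged `NA`) for a perfectly stationary track.

**MSD** (`msd_curve()`) uses the overlapping, time-averaged convention:
at lag \(n\) frames, all \(NF-n\) available increments are averaged. The
increment count is returned with each lag because the large lags average
few increments and are noisy; downstream consumers should weight or
truncate accordingly.

**Diffusion coefficient** (`diffusion_coefficient()`) averages the
per-lag estimate \(D_n = \mathrm{MSD}(n \cdot TF)/(2\,d\,n\,TF)\)
(\(d\) = dimensionality) over the first `n_lags_used` lags. The default
window is the first quarter of lags, a sensible compromise for the short
(~50 frame) tracks this analysis targets, where it means averaging about
12 per-lag estimates. For long tracks the variance of the time-averaged
MSD grows roughly linearly with lag, and the quarter window lets the
noisy tail dominate; there we recommend (and use, in our own validation)
a small fixed window such as the first 10 lags — the standard practice of
fitting only the early part of an MSD curve. For purely diffusive motion
all \(D_n\) agree in expectation; a systematic rise of \(D_n\) with lag
is a useful diagnostic of directed motion (ballistic tracks give
\(D_n = v^2 n TF / 2d\), increasing linearly).

**Cohort aggregation** (`cohort_summary()`) averages each statistic over
the particles for which it is defined, reporting the effective n per
statistic, and attaches a dispersion following the original tool's
convention: sample standard deviation below 15 particles, standard error
of the mean at 15 or more. Singleton SD is defined as 0. MSD curves are
averaged lag-wise into a cohort mean curve.

## What the synthetic generators emulate

Every analysis stage is testable without external data because the
package generates tracks with known ground truth:

* `make_staged_track()` concatenates pause / processive / Brownian
  stages. The noise model is deliberately split in two: *localization
  jitter* is isotropic Gaussian added independently at each frame (it
  models detection error and does not accumulate), while *Brownian*
  stages take cumulative Gaussian increments of per-axis variance
  \(2 D \cdot TF\). Per-frame true labels are returned for recovery
  tests.
* `make_random_walk()` is the pure Brownian case, used to validate the
  MSD curve against \(2\,d\,D\,t\) and the diffusion estimator against
  its generating value.
* `make_oscillator()` is a sinusoid of amplitude \(A\) embedded in 2D:
  net displacement from any anchor is bounded by \(2A\), so with
  \(DT > 2A\) the scan provably reports zero motion while the mean
  instantaneous speed stays positive — the central contrast the method
  exists to expose.

What these generators do **not** emulate: heterogeneous localization
error, missing or mislinked detections (tracking gaps are rejected by the
reader rather than interpolated), motion blur, drift of the stage or
tissue, and interactions between particles. Passing tests on synthetic
tracks therefore certify the algorithmic contract — segmentation,
classification, and estimator calibration — not robustness to every
artifact of real imaging data.

## Numerical and design choices

* Threshold comparisons are strict (`>`), ties conservative; this makes
  results deterministic and matches the verbal definition of "higher
  than" / "above".
* Frame numbering within each particle must be 1..NF consecutive; gaps
  are an error, not an interpolation opportunity, because a displacement
  across an unseen interval cannot be attributed to motion at a known
  speed.
* Speeds use net (straight-line) displacement over the segment, not
  summed path length — the same distance definition the scan itself
  thresholds on.
* The stacked input layout (all particles in the same columns, NF rows
  each, header in row 1, particle k starting at data row \((k-1)NF+1\))
  is validated strictly; extra columns such as particle labels are
  ignored. Columns may be addressed by spreadsheet letter or header name.
* Outputs are plain CSV plus a JSON report that echoes every parameter,
  so a run can be reproduced from its own report; numeric cells carry 15
  significant digits so a write/read round trip is lossless to at least
  10.
* Generators take an explicit integer seed, use a local RNG stream, and
  restore the global RNG state, so they are pure functions of their
  arguments.

## Validation problem sizes

The shipped test suite checks the scan against an independently written
brute-force implementation of the verbal algorithm on 1000 mixed random
tracks (up to 200 frames); MSD against a double-loop reference on 100
tracks and against the ballistic closed form to 12 significant digits;
diffusion recovery on twenty 10⁴-frame Brownian tracks at
\(D = 0.05\) µm²/min (each estimate within 15% of truth, the mean within
5%, using the 10-lag window discussed above); and the property suites
(tiling, DT/ST monotonicity, rigid-motion invariance, MSD scaling,
persistence invariance) on 200 random cases each. The boundary
quantization of the scan bounds how precisely percent time in motion can
recover staged ground truth: each phase boundary can be misplaced by up
to one DT-crossing, i.e. \(2 \cdot DT / v\) worth of time across a
track, which the recovery test asserts explicitly.

## Known limitations

* DT and ST are global per run; particles with very different scales of
  motion need separate runs.
* The residual-tail convention slightly underestimates percent time in
  motion for particles moving at the end of the recording (by design —
  see above).
* The diffusion coefficient is a simple MSD-ratio estimate, appropriate
  for summarizing random motility; it is not an anomalous-exponent fit,
  a confinement-model fit, or a maximum-likelihood estimator, and for
  directed motion it is diagnostic rather than meaningful.
* Equal frame counts per particle are required by the stacked layout, as
  in the original spreadsheet workflow.
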