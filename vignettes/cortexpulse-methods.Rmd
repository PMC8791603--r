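---
title: "Quantifying pulsatile cortical myosin and posterior crescents: methods and design"
author: "cortexpulse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pulsatile cortical myosin and posterior crescents: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexpulse)
```

## The measurement problem

In the *Drosophila* oocyte, non-muscle myosin II accumulates at the cortex
in transient foci that appear, brighten, fade and disappear without moving
laterally.  The biologically informative quantity is the *duration* of
these pulses: at the posterior pole — where the Par-1 polarity crescent
forms, adjacent to the polar follicle cells — pulses persist much longer
than at the lateral cortex, and this asymmetry disappears when
myosin-light-chain kinase is inhibited (e.g. with ML-7).  `cortexpulse`
implements the corresponding image analysis as a reusable, testable
pipeline:

1. a user-traced cortical polyline, anchored at the posterior pole, is
   resampled to uniform arc length (`resample_path()`);
2. a position-by-time **kymograph** is extracted from the movie by
   band-averaged bilinear sampling along the path
   (`extract_kymograph()`);
3. "strong-intensity" pixels are thresholded
   (`threshold_kymograph()`), grouped into 8-connected components
   (`segment_pulses()`), and measured as pulse events
   (`measure_pulses()`);
4. durations are pooled in blocks of 25 consecutive measurements
   (`pool_durations()`) and compared between the lateral and posterior
   windows L1, P, L2 by one-way ANOVA with a bootstrap CI on the
   posterior:lateral ratio (`compare_regions()`).

A companion module quantifies cortical polarity crescents (such as
Par-1) on single images as a normalized intensity ratio versus arc
distance from the pole, using the lateral follicle-cell signal as an
internal reference (`profile_along_cortex()`, `normalize_profile()`,
`aggregate_profiles()`).

Because real movies of this system are not publicly deposited, the
package ships a synthetic-data generator (`generate_kymograph()`,
`generate_movie()`, `generate_crescent_image()`) that emulates the
imaging with known ground truth; every stage of the pipeline is tested
against it.

## Coordinate conventions

* Arc length is signed, in micrometres, **0 at the posterior pole**;
  negative on one lateral side, positive on the other.  Resampling
  places samples at exact multiples of the pixel size on both sides of
  the pole, so arc 0 always falls on a sample.
* Frames are indexed from 0; frame $k$ is at time $k\,\Delta t$.
  A component seen in frames $f_{\min}\ldots f_{\max}$ is assigned
  duration $(f_{\max}-f_{\min}+1)\,\Delta t$: an event visible in a
  single frame lasted at most one interval.  Under a uniformly random
  pulse phase this convention is unbiased — the expected number of frame
  ticks inside an interval of length $\ell$ is exactly $\ell/\Delta t$.
* Continuous pixel coordinates follow the R convention (the centre of
  `data[i, j]` is `(i, j)`); sub-pixel sampling is bilinear.

The analysis windows default to P = (−10, +10) µm and
L1/L2 = (∓40, ∓20) µm.  The 10 µm guard gap between P and the lateral
windows keeps events unambiguous about their region; events whose
majority rows fall outside all windows are dropped.

## The synthetic generator

Foci are born as a homogeneous Poisson process in (position, time)
inside each region window, at rate `focus_rate_per_um_per_s` per µm of
cortex per second.  Each focus is spatially a Gaussian of standard
deviation `focus_sigma_um` that **stays stationary** (optionally
jittered frame-to-frame by `drift_sd_um`), and temporally a raised
cosine $h(t)=\tfrac12\bigl(1-\cos 2\pi\frac{t-t_0}{D}\bigr)$ supported
on its lifetime $[t_0, t_0+D]$.  Lifetimes are gamma distributed with a
region-specific mean and a shared shape parameter.  Overlapping foci
superpose additively on a constant background; Gaussian or Poisson
noise is added last.  Identical configurations with identical seeds are
bit-identical.

Why these choices:

* **Raised cosine**: only the fact that foci "oscillate in intensity"
  is established; a smooth rise-and-fall with zero slope at both ends
  avoids thresholding artefacts at the pulse edges and makes the
  above-threshold support a well-defined fraction of the lifetime.
* **Gamma lifetimes** have positive support with tunable dispersion.
  The default shape 10 (CV ≈ 0.32) represents realistic pulse-to-pulse
  variability while keeping the mean identifiable from a few dozen
  events.
* **Defaults** mirror the imaging this analysis is designed for:
  101 frames at 15 s (25 min), 0.198 µm pixels, a 120 µm cortex.  The
  *asymmetric* default sets mean durations L1 = L2 = 40 s and
  P = 100 s (true posterior:lateral ratio 2.5), so the qualitative claim
  "posterior pulses last more than twice as long" is testable with
  margin; `symmetric_scenario()` sets all three means to 40 s,
  emulating the kinase-inhibited cortex.
* **Focus density** (6 × 10⁻⁵ µm⁻¹ s⁻¹, about 2–3 foci per 20 µm window
  per 25 min movie) keeps pulses optically resolvable, as they are in
  real kymographs of this system.  At substantially higher densities
  neighbouring pulses merge into single 8-connected components, which
  corrupts per-event durations — a real limitation of
  connected-component tracking, discussed below.
* **Contrast** (amplitude 400 over background 40, Gaussian noise
  SD 4) corresponds to bright, high-SNR foci.  The robust threshold
  (median + 3·MAD) then sits at only a few percent of the peak
  amplitude, so the measured above-threshold support captures ≥ 85% of
  the true lifetime.  At lower SNR the threshold climbs the envelope
  and durations shrink proportionally in *all* regions — the ratio is
  unaffected (the shrinkage is multiplicative and identical across
  regions), but absolute durations would be underestimated.

The 2D movie embeds the same 1D signal along a semicircular path
(radius = cortex length/π) as a band 3 px wide, and returns the path so
that extraction can be validated end-to-end.  Within the band the
painted intensity varies only along the path, so band-averaged
extraction recovers the 1D signal; the outermost sampling offsets of a
±1 px band touch the band edge, where bilinear support reaches
background pixels, which is why round-trip validation uses either
centreline sampling of the 3 px band or a ±1 px band inside a 5 px
painted band.

What the generator does **not** emulate: photobleaching, the axial
point-spread function, cortical flows (absent in this system), follicle
cell dynamics, uneven illumination, or autofluorescence gradients.
Passing the recovery tests therefore shows that the *measurement logic*
is correct under the stated imaging model, not that the pipeline is
robust to every real-world artefact.

## Detection and measurement choices

* **Threshold.**  The default is median + 3·MAD (MAD scaled for
  SD-consistency): robust to the strong posterior/lateral brightness
  difference, and invariant — like the Otsu alternative — under affine
  intensity rescaling, so detector output does not depend on gain or
  offset.  A constant kymograph has MAD 0 and yields an empty mask with
  a warning.  The mask is strict (`intensity > threshold`).
* **8-connectivity** tolerates the one-pixel positional jitter of
  "stationary" foci between frames; 4-connectivity would split them.
  Component ids are deterministic (sorted by first frame, then lowest
  arc row).
* **min_pixels = 4** suppresses single-pixel noise excursions
  (individually rarer than 10⁻⁵ per pixel at the default SNR, but a
  kymograph has ~60 000 pixels).
* **Censoring.**  Events touching the first or last frame have unknown
  true duration and are excluded from duration statistics by default
  (configurable).  With 25 min movies and 100 s posterior pulses this
  discards roughly 7% of posterior events; the remaining sample is
  length-biased only negligibly because onset times are uniform.
* **Drift gate.**  The per-frame intensity-weighted centroid of a true
  stationary focus moves less than a pixel; components whose centroid
  range exceeds 2 µm are almost always two merged neighbours trading
  intensity, and are flagged non-stationary and excluded from duration
  statistics by default.
* **Pooling.**  Within each region, events ordered by onset are
  averaged in non-overlapping blocks of 25 consecutive measurements;
  the remainder (< 25) is kept in the event counts and raw summary but
  contributes no pooled mean.  Raw per-event durations are always
  carried alongside the pooled means so either unit of analysis can be
  compared.

## Statistics

`compare_regions()` runs a one-way fixed-effects ANOVA of duration
across L1, P, L2 and reports the posterior:lateral ratio (mean of P
over the mean of the pooled lateral events) with a within-group
percentile bootstrap CI (2000 resamples, seeded).  Degenerate inputs
are defined explicitly: equal group means with zero variance everywhere
give F = 0, p = 1; groups with fewer than two observations are
rejected.  Pulse durations are discrete multiples of 15 s and mildly
skewed, so the F-test is used in its robust regime (similar group
sizes); the simulation-based calibration below checks that its level is
honest under exactly the conditions the pipeline produces.

`recovery_experiment()` is the simulation harness: one replicate
generates `n_chambers` movies (events pooled across chambers, as
real analyses pool across egg chambers), runs
threshold → segment → measure on each, and compares regions on the
pooled events.  Problem sizes used by the shipped tests and the
acceptance script, chosen to give stable Monte-Carlo estimates at
interactive runtimes: 10 replicates × 36 chambers for the asymmetric
ratio (≈ 50–65 non-censored events per region per replicate);
20 replicates × 8 chambers for the symmetric ratio; 500 replicates ×
8 chambers for the type-I-error calibration at α = 0.05; one
50-chamber experiment for parameter recovery (≥ 50 non-censored events
per region).

## Numerical notes and edge cases

* Path resampling collapses duplicate consecutive vertices, rejects a
  pole more than 1 px off the path, and projects the pole onto the
  nearest path point.  Sample counts use `floor(length/spacing + 1e-9)`
  so exact multiples are not lost to floating point.
* Band sampling clamps coordinates at the image border and warns with
  the affected rows rather than failing.
* The Otsu threshold is computed on a 256-bin histogram spanning the
  data range; with a wide flat valley between modes the *threshold* is
  ill-conditioned even though the achieved between-class variance is
  not, which is how the test suite compares it to an exhaustive search.
* TIFF output is 32-bit float in [0, 1] with the intensity scale and
  calibration (frame interval, pixel size) in a JSON sidecar; explicit
  arguments always override stored metadata.  Manifests contain no
  timestamps, so a rerun with the same seed is byte-identical.

## Known limitations

* Merged pulses: two foci overlapping in space and time form one
  component.  The drift gate removes most such events, at the cost of
  losing both pulses; at the default density this affects a few percent
  of events.  A mixture/fitting approach would be needed for crowded
  cortices.
* Censored events are discarded, not modelled; for pulse durations
  approaching the movie length a survival formulation would be
  required.
* The crescent reference is the mean (optionally median) over the
  traced follicle band; no sub-structure of the follicle epithelium is
  modelled, and the pole position is an input, not detected.
* Cortex tracing itself is interactive and out of scope: paths are
  inputs.

## A worked example

```{r example, eval = FALSE}
cfg <- scenario_config(seed = 7)
sim <- generate_kymograph(cfg)
plot(sim$kymograph)

events <- detect_pulses(sim$kymograph)
pool_durations(events)

rec <- recovery_experiment(cfg, n_reps = 10, seed = 1)
rec
```
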