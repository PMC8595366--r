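---
title: "Methods: quantifying optogenetic front–rear polarity reversal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying optogenetic front-rear polarity reversal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

Neutrophil-like cells confined in straight microfluidic channels are
front–rear polarized: a Rho-GTPase (Cdc42) activity gradient marks the
protrusive front, myosin II the contractile rear. A light-gated GPCR lets an
experimenter deliver receptor inputs at a chosen subcellular location — in
particular at the rear, asking whether the rear can be re-programmed into a
new front. `polarflip` implements the complete quantitative chain from raw
two-channel fluorescence stacks to the statements such experiments produce:
per-cell FRET-ratio maps, front/middle/rear activity traces, the timing and
order of response events, response-class calls, rear-registered kymographs,
and cohort statistics.

Because raw microscope data of this kind are rarely redistributable, the
package also contains a seeded synthetic-microscopy generator that renders
image stacks from known ground truth. Every analysis stage is tested against
that ground truth or against independent brute-force oracles.

## Image model and corrections

A raw frame is modeled as

    raw = dark + sensitivity × illumination × signal (+ noise),

and `apply_camera_corrections()` inverts the dark/sensitivity part
elementwise. Negative corrected values are kept (flagged, not clipped):
clipping would bias background statistics.

The acceptor/donor ratio additionally carries a smooth multiplicative field
bias (an apparent activity gradient caused by the light path). The empirical
correction (`build_ratio_correction()`) is assembled from many unstimulated
cells imaged at systematically varied positions so that every sensor pixel
is covered by cell pixels at least once:

1. per-pixel **median** of the masked ratio over the stack;
2. **24 × 24-pixel block median** (partial edge blocks use the median of
   the available pixels — the field is never shrunk);
3. **Gaussian smoothing with σ = 5 in block units**.  This is implemented
   as a Gaussian-*weighted local-linear* regression rather than plain
   truncated-kernel convolution: a truncated (or replicate-padded) kernel
   attenuates a linear gradient by tens of percent near the field edge at
   realistic block-grid sizes, which would defeat the correction's own
   purpose.  The local-linear smoother reproduces affine fields exactly
   everywhere, including the boundary;
4. smooth resizing to the full field with a separable natural cubic
   spline (linear fields are again reproduced exactly).

Corrected ratio = measured ratio / correction image. Building the
correction is idempotent: applied to already-corrected data it returns a
map within 1 % of unity. The correction is optional (config
`ratio_correction`); single-reporter (myosin) imaging does not need it.

## Segmentation and background

Segmentation runs on the sum of the two channels. Conservative background
and object seeds are the 25 % / 99 % quantiles of the summed image (the
paperless constants of this step are package decisions; channels here are
narrow, so cells occupy a minority of the field). The background is the
local median of seed pixels in a 64-pixel neighborhood, evaluated on a
coarse grid and interpolated. After background subtraction, edges are
enhanced by subtracting a broad Gaussian blur (σ = 5) from the image —
for channel-confined cells (half-width ≈ 2σ) this acts as a matched
band-pass that is positive over the whole cell body — and the result is
binarized with Otsu's threshold, hole-filled and size-filtered
(≥ 200 px), keeping the largest object.

Two robustness additions matter at low signal-to-noise:

* a mild Gaussian **pre-smoothing (σ = 1 px)** of the summed image,
  applied only when the background actually shows noise (an exactly
  two-level image is thresholded unsmoothed, which keeps noise-free masks
  pixel-exact);
* an **object-intensity gate**: a candidate object is accepted only if its
  mean background-subtracted intensity exceeds 5 × the robust background
  noise (MAD). This converts noise-only frames into an explicit "no cell"
  signal instead of a spurious mask.

The mask then defines undefined (NA) pixels for every downstream sum, and
the FRET ratio is acceptor/donor. (The source description of this analysis
states the ratio in both orientations in different places; the package
standardizes on acceptor/donor — activity rises at a stimulated rear — and
makes the orientation configurable.)

## Tracking, kinematics, geometry

One cell per channel: consecutive masks are linked by overlap, bridging at
most one missing frame; a zero-overlap break splits the track and the
longest segment is kept with a warning. Centroid speed is displacement per
3-s frame (0.21 µm/px); traces are smoothed by local quadratic regression
(loess) with a span of 10 % of the trace (floored at six points, the
minimum for a stable local quadratic). Loess reproduces constant and
linear speed profiles to numerical precision, which the tests pin down.
Signed channel-axis velocity is oriented so the pre-stimulus direction is
positive; the pre-stimulus direction is the majority sign of the last
three frame-to-frame displacements, which tolerates centroid jitter.

The stimulation target is the boundary pixel at a target angle from the
movement direction as seen from the centroid (180° = rear). Ties are broken
deterministically (larger radius, then lexicographic).

## Subcellular quantification

Front and rear regions are the 800 mask pixels nearest the front/rear
extreme boundary points (Euclidean distance, lexicographic tie-break); the
middle region is a full-width window over the central third of the axial
extent. 800 px captures the activity penetration depth at the front; the
detected event *order* is insensitive to halving the depth, and a test
asserts that. Region activity is a **ratio of sums**, not a mean of
per-pixel ratios — it is invariant to common channel rescaling and robust
to low-intensity pixels. Myosin-mode signals are normalized by the
whole-cell sum, giving fractions in [0, 1].

1-D activity profiles are per-row ratios of sums along the channel axis,
centroid-registered. For cohort averaging they are resampled to the cohort
mean cell length with a cubic smoothing spline whose parameter p follows
the convention p = 0 → least-squares line, p = 1 → interpolating spline
(implemented as penalty weight (1−p)/p; p = 1 uses the natural
interpolating spline, the exact λ → 0 limit). Default p = 0.5.
Kymographs average the rear-registered, length-normalized profiles over
cells per time point, excluding undefined entries.

## Events and response classes

All times are relative to the first stimulation pulse (t = 0); cells run
unstimulated for 21 frames (63 s) beforehand. Two baselines deliberately
coexist: event *onsets* are measured against the t = 0 sample, response
*classification* against the 15-s (6-frame) pre-stimulus average.

Event onsets are the first post-stimulus threshold crossings, linearly
interpolated between the bracketing samples: a 1 % rise of rear activity, a
1 % decay of front activity, the zero crossing of signed velocity
(stalling), and the front/rear intersection (cross-point). A crossing must
persist at the following sample; this debounce rejects single-sample noise
spikes and is exact on monotone piecewise-linear traces. Stalling uses the
signed velocity because unsigned speed from noisy centroids rarely touches
zero.

Transient responses are stratified by a cascade: rear rise < 2 % →
*no response*; rear rise ≥ 2 % with an unengaged front
(min front − max rear > 0.03 activity units) → *medium*; otherwise
*reversed* if both the migration direction and the front/rear activity
ordering are flipped over the final 15 s, else *strong*. Persistent runs
are labeled *reverser* iff direction and activity axis both flip; a net
displacement below one cell length is treated as ambiguous
(*non_reverser*, with a warning). For myosin-line data without an activity
sensor a config switch restricts the call to migration criteria.

The center-stimulation assay quantifies whole-cell activity in four
windows: Control1 [−60, −42] s, Control2 [−39, −21] s, Control3 [−18, 0] s
and a peak window of half-width 9 s centered on the activity maximum in
[3, 33] s; control response = mean(C2)/mean(C1), peak response =
mean(Peak)/mean(C3). The responder fraction of a cohort uses the symmetry
of the control distribution about its median m: f = 1 − 2·P(peak < m); a
stringent lower bound counts peaks above the control 95th percentile. Both
thresholds are cohort-derived and reported. **Known limitation**: the peak
window is centered on a maximum, so any within-trace variability that is
slow on the scale of the search window (drift) biases the null peak
response upward; the median-symmetry estimate inherits an upward bias on
null-heavy cohorts. The premise holds when per-sample measurement noise
dominates drift, which the synthetic cohorts emulate (below).

## The synthetic generator

The generator is a forward model of the phenomenology the analysis must
recover, not of optics. A cell is an axially elongated super-ellipse
(exponent 4, default 110 × 22 px ≈ 23 × 4.6 µm) moving along the vertical
channel axis at 0.21 µm/s (3 px per 3-s frame). Its activity profile is
rear-plateau / linear ramp / front-plateau (plateaus cover 40 % of the
length each), so the 800-px region means equal the plateau values exactly
and analysis-side recovery can be asserted to machine precision. Donor
amplitude is uniform (600 counts) and the acceptor carries
amplitude × activity, hence acceptor/donor inside the mask *is* the ground
truth activity in the noise-free flat-field limit. Dark offset,
per-channel illumination, an acceptor-only ratio bias field, Poisson shot
noise and Gaussian read noise are applied per the image model (all off or
flat by default).

Response kinetics are piecewise linear and parameterized by *realized*
event times: slopes are solved so that the 1 % onsets, the stall zero
crossing and the front/rear intersection occur exactly at the configured
schedule (default for a reversing cell: rear 6 s, front 15 s, stall 27 s,
cross-point 51 s — stall and cross-point matching the observed medians;
rear/front onsets are simulation choices, as no quantitative kinetic model
is given for them). `medium` cells rise ≥ 2 % at the rear with the front
held high; `strong` cells engage both edges and transiently flip
direction; `no_response` cells stay at baseline. The default cohort mix is
the observed 56/21/7/6 % (renormalized over classifiable cells).

Trace-level noise (`noisy_region_series()`) adds 0.005 activity units
(≈ 0.5 % of the ratio — the residual noise of an 800-px region mean) and
0.02 µm/s of velocity noise. Cohort-scale checks (100 noisy reversers,
4 × 25-cell classification, n = 500 center stimulation) run at this trace
level; the image chain is exercised end-to-end by the flat-field,
segmentation, kinematics and single-cell event tests. Center-stimulation
traces use white measurement noise of 0.01 plus a weak AR(1) drift
(sd 0.002, τ = 30 s); these scales reproduce the observed control-response
distribution (median ≈ 1.000, 95th percentile ≈ 1.009) and keep the
estimator's exchangeability premise valid.

What the generator does **not** emulate: point-spread blurring beyond the
pixel grid, photobleaching, intensity texture inside the cell, shape
irregularity and neighboring cells, multi-cell channels, and sub-pixel
boundary effects. Passing tests therefore certify the analysis logic and
its numerical contracts, not performance on arbitrary real microscopy.

## Numerical choices and problem sizes

* TIFF storage is 32-bit float scaled into [0, 1] with the full-scale
  constant recorded in the JSON sidecar (float TIFF outside [0, 1] is not
  portable); counts round-trip to ~0.01.
* The flat-field tests render ~100 calibration cells on a 288 × 288 field
  (12 × 12 blocks); segmentation robustness uses 20 seeded SNR-5 fixtures;
  event/classification cohorts use 100 trace-level cells; the responder
  estimator uses n = 500 (and n = 2000 for the null tail rate, keeping the
  binomial sampling error of a 5 % probability well below the assertion
  band). These sizes were chosen so the full suite runs comfortably on a
  laptop-class single core.
* All randomness flows from explicit integer seeds; per-cell seeds are
  derived by hashing (master seed, index), so cohorts are reproducible
  under reordering and identical (params, seed) pairs render bit-identical
  stacks.
* Exact tests (`wilcox.test` exact path, `fisher.test`) are used for small
  samples; larger contingency tables fall back to a seeded Monte-Carlo
  p-value whose standard error is reported. No multiple-testing correction
  is applied, matching the per-comparison reporting convention of the
  source analyses; this is deliberate and documented.
* The persistent-assay displacement guard (one cell length) requires
  persistent runs of ~5 min (101 frames) for an early-reversing cell to
  accumulate an unambiguous net displacement; the transient assay default
  is 61 frames.

## Known limitations

* The medium/no-response boundary for myosin-line data was manually
  curated in the original workflow; the package offers only the
  speed-based rule and labels that split approximate.
* The responder-fraction estimator's null bias under slow drift (above).
* Tracking assumes one cell per channel; crossing cells are out of scope.
* The inter-camera registration of a two-camera FRET rig is assumed done
  upstream (inputs pre-aligned); only a rigid-translation fallback by
  cross-correlation would be appropriate here and is not implemented.
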