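---
title: "dendromap: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dendromap: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendromap)
```

dendromap analyzes two-photon movies of dendrites *in vivo*: it
motion-corrects the raw t-stack, segments dendritic spine and shaft ROIs,
aligns ROI maps across imaging sessions, classifies spine turnover, removes
back-propagating action potential (bAP) contamination from spine signals,
and characterizes stimulus and behavioral tuning. This vignette explains
the underlying models, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the design choices
made where the problem left the design open.

## Signal model

The package assumes the standard linear mixing model for spine calcium
signals. A spine's fluorescence trace is

$$F_{\text{spine}}(t) = F_0 + I(t) + s\,D(t) + \varepsilon(t),$$

where $I(t) \ge 0$ is the input-specific synaptic component, $D(t) \ge 0$
is the global dendritic (bAP-driven) component visible in the shaft,
$s \ge 0$ is a spine-specific mixing scale, and $\varepsilon$ is sensor
noise. Transients are modeled as sparse event trains convolved with a
single-exponential decay kernel $e^{-t/\tau}$ — a minimal description of
GECI kinetics sufficient for correlation-based segmentation and for
validating the un-mixing step. Isolating $I(t)$ by estimating $s$ and
subtracting $s\,D(t)$ is the core requirement for mapping synaptic inputs.

## Motion correction

Registration estimates a rigid, translation-only shift per frame by phase
correlation: the argmax of the inverse transform of the normalized
cross-power spectrum between each frame and a template, restricted to
`max_disp` pixels per axis (default 20% of the smaller image dimension).
Two refinements matter in practice:

* **Spectral taper.** The normalized spectrum is multiplied by a Gaussian
  window of spatial scale `smooth_sigma` (default 1.15 px) before
  inversion. For a pure translation this blurs the delta peak without
  moving its argmax — integer-shift recovery stays exact — while under
  sensor noise it suppresses spurious single-pixel peaks; at a
  signal-to-noise ratio of 5 it eliminates essentially all >1 px
  registration failures on synthetic movies.
* **Stable-chunk initialization.** Fluorescence structure is only
  transiently visible, so the template is built from the most stable,
  signal-bearing part of the recording. The stack is cut into chunks of
  `chunk_len` frames (default 200) and each is scored by
  (mean correlation of its frames to the chunk mean) x (chunk mean
  intensity / stack mean intensity); the best chunk's frames are mutually
  aligned and averaged. If the resulting stack-wide mean registration
  correlation falls below `corr_floor_init` (default 0.2) the next-best
  chunk is tried; if every chunk fails, the best template found is
  returned with a warning flag rather than aborting the run.

Safeguards mark a frame invalid when its correlation to the template is
below `frame_corr_min` (default 0.2), its mean intensity is below
`signal_min` (default 10% of the template mean — the mean was chosen over
a high-percentile statistic as the simpler reading of "average signal
magnitude", and is configurable), or its unrestricted correlation peak
lies beyond `max_disp`. Invalid frames receive shifts linearly
interpolated between the nearest valid flanking frames (carried constant
at the ends); this is justified by the small inter-frame translation of
fast time-lapse imaging.

Because a template assembled from an arbitrary chunk has an arbitrary
absolute position, all shifts are re-anchored so the first valid frame has
shift (0, 0) and the template is translated to match. Reported shifts are
therefore displacements relative to the movie's own start, which also
makes them directly comparable to a known simulated trajectory.

Shifts are integer by default, so recovery is exactly checkable; subpixel
mode (0.1 px, upsampled evaluation of the correlation surface around the
integer peak, applied by Fourier phase ramps) is an opt-in refinement.

## ROI segmentation

Seed candidates are local maxima of a difference-of-Gaussians band-pass of
the mean image (`sigma_small` = 1 px, `sigma_large` = 4 px by default; the
wide blur acts as a background estimate so smooth intensity gradients
cancel). Blurs are computed in the Fourier domain with periodic boundary,
which keeps constant images exactly constant. Seeds below `min_score`
(default 5 x the median absolute deviation of the band-pass) are dropped,
as are duplicates within `min_sep` px and maxima within the border margin.

Each seed is segmented on the *temporal* structure of the movie: the
Pearson correlation between every pixel's time series within radius
3 x `dendrite_width` of the seed and the seed pixel's series. The mask is
the connected component above the 80% quantile of the in-radius
correlation values that contains the seed. The quantile is taken over
in-radius pixels only (taking it over the full image would make the
threshold depend on image size rather than neighborhood structure).
Components with area outside `[4, (4 * dendrite_width)^2]` px² are
rejected; an ellipse (second central image moments) is stored for
morphology statistics. Pixels claimed by two spine masks go to the nearer
seed, keeping masks disjoint.

When detection is constrained to a user-specified dendrite (a polyline
dilated to a user-set width), two stringent rules bias the detector toward
few false positives at the cost of recall: only spines whose centroid lies
within `proximity_factor` x width (default 3) of the polyline are kept,
and seeds falling *inside* the shaft band itself (within width/2 of the
path) are discarded — the shaft carries the global dendritic signal and is
analyzed through its own ROI and subregions, while spines are protrusions
adjacent to it. On synthetic 20-spine movies at moderate noise this
configuration reaches precision and recall above 0.95; the suite asserts
precision ≥ 0.8 at recall ≥ 0.5 with an IoU ≥ 0.3 match criterion.

Shaft subregions are arc-length spans of the dendrite: even subdivision
tiles `[0, arc length]` with spans of a user-set length (last span
shorter), and spine-linked subregions center a span at the arc position
nearest the spine's centroid, clipped at the ends. Traces are mask means
per frame; ΔF/F (rolling 20th-percentile baseline over 500 frames by
default) is a derived view, with raw means stored as primary.

## Cross-session alignment and turnover

ROI maps from different sessions are aligned rigidly (rotation +
translation; magnitude unrestricted) with iterative closest point on a key
point cloud: spine centroids plus dendrite-path samples every 5 px of arc
length (both included by default; spines-only is available).
Correspondences are mutual nearest neighbors with a distance cap of 5 x
the target cloud's median nearest-neighbor spacing, which resists the
partial overlap that turnover creates; the rigid fit is the closed-form
SVD solution with the determinant constrained to +1.

Mutual-NN ICP is not provably monotone, so each run keeps the best
transform seen so far, stops after three improvement-free iterations (or
`max_iterations` = 50), and reports the best-so-far error envelope —
nonincreasing by construction — as `per_iteration_mse`. Initialization
aligns the cloud centroids; because nearest-neighbor correspondence can
trap rotations above roughly 10° in local minima, the iteration is also
restarted from coarse initial rotations (±20°, ±10°, 0°) and the
lowest-final-MSE run wins. On simulated pairs (rotation up to 15°,
translation up to 20 px, 0.5 px jitter, 20% dropout) recovery is within
1° and 1 px, and the rotation-aware alignment always ends with lower MSE
than the best pure-translation alignment. Translation error is measured
as the displacement discrepancy at the source-cloud centroid, since the
canonical translation vector confounds rotation error with the lever arm
from the origin.

Turnover classification matches spine centroids between an aligned session
pair one-to-one, maximizing matched count and then minimizing total
centroid distance among pairs within `max_disp` px (default 4 px, to be
adjusted to image resolution and spine density). The assignment is solved
globally (Jonker–Volgenant), not greedily: a new spine near an
already-accounted-for spine must come out as gained. Matched spines are
retained; unmatched session-1 spines are lost; unmatched session-2 spines
are gained — so |retained| + |lost| and |retained| + |gained| equal the
two session counts by construction. Summaries cover spine areas,
nearest-neighbor distances (local density) and arc-length positions along
the parent dendrite (missing, not an error, for spines without one).
Chains of more than two sessions reduce to pairwise comparisons against
the first session by default (sequential comparison is a flag).

## bAP removal

The mixing scale is estimated in two stages. First, dendrite-active frames
are selected as those where the shaft trace exceeds its 0.75 quantile —
a deterministic one-parameter stand-in for separating the "both active"
diagonal cloud from the input-only vertical cloud in a spine-vs-shaft
scatter — and a robust regression (iteratively reweighted least squares,
bisquare) of spine on shaft over those frames gives `slope_fit`, floored
at 0. Second, the scale actually subtracted, `slope_used`, is the largest
factor in `[0, 2 * slope_fit]` that creates no negative deflection,
found by bisection to 1e-4. Both values are reported so the choice can be
audited; this replaces an interactive visual choice with a reproducible
rule.

A deflection is a sustained dip, not one noisy sample, so the constraint
is evaluated on a 5-frame moving average of the corrected trace, with
floor `min(-noise_tol, min(smoothed trace))`; `noise_tol` defaults to 3 x
the MAD-based noise estimate `mad(diff(x))/sqrt(2)`, scaled by
`1/sqrt(window)`. On noiseless traces this reduces to the plain
`-noise_tol` bound; under noise it keeps zero always feasible and removes
the systematic overshoot an absolute floor produces (the binding
constraint would otherwise sit at the deepest noise excursion). With
mixing scales drawn uniformly from [0.2, 1.5] and noise at 10% of a unit
event amplitude, scales are recovered to a few percent (median) and
corrected traces correlate above 0.95 with the true inputs.

Subtraction is batched over all spines and subregions of one dendrite;
shaft subregions whose corrected trace still exceeds 5 x the noise
estimate are flagged as carrying nonlinear local events and should not be
used as bAP proxies. The whole step can be skipped for indicators that do
not report bAPs (e.g. glutamate sensors).

## Stimulus responses, tuning and event-triggered averages

Stimulus tables pair a `framestamp` (one time value per imaging frame, in
seconds or frame indices) with a `stampinfo` table whose first column is
timekeeping in the same unit and whose remaining columns are parameters,
possibly sampled at a different rate (codes are resolved onto the frame
clock by constant interpolation). Grating schedules code directions 1..k
with 0 for gray screen.

A trial's response is the mean trace during the stimulus epoch minus the
mean during the immediately preceding gray period. This window is the
simplest defensible choice and is configurable; note that with short gray
periods the decay tail of the previous stimulus biases the baseline, so
the generator's tuning schedule uses 2 s stimulus / 3 s gray at 30
frames/s.

Direction tuning is fit with the constrained two-peak Gaussian

$$R(\theta) = b + A_1 e^{-d(\theta,\theta_p)^2 / 2\sigma^2}
                + A_2 e^{-d(\theta,\theta_p+180^\circ)^2 / 2\sigma^2},$$

with wrapped angular distance $d$, peaks locked 180° apart, shared width
$\sigma \in (5^\circ, 90^\circ]$, amplitudes $A_1, A_2 \ge 0$, and the
convention that $A_1 \ge A_2$ places $\theta_p$ at the taller peak.
Fitting is bounded multi-start least squares (L-BFGS-B started at every
observed direction plus a flat start, so the fit residual can never exceed
the constant-only model's). Orientation and direction selectivity indices
are derived from the fitted curve: OSI = (R(θp) − R(θp+90°)) / (R(θp) +
R(θp+90°)), DSI analogous with the opposite direction. With 8 directions
x 5 repeats and 5% noise, preferred direction and width are recovered
within a few degrees for widths ≳ 25°; widths well below the 45° direction
spacing are under-determined by design of the schedule, not of the fit.

Event-triggered averages trigger on upward threshold crossings of a
behavioral parameter (e.g. speed > 0.5 cm/s), thinned by a refractory
period of `pre + post` seconds, and average trace snippets resampled to
the frame clock over `[-pre, +post]` (default 2 s each). A grouping column
(e.g. open- vs closed-loop trial type, read at the trigger time)
partitions triggers for group comparisons. On white noise the ETA stays
within ±3 s.e.m. of zero — the calibration the suite asserts.

## The synthetic-data generator

`make_dendrite_movie()` renders a rectangular-profile dendrite band along
a polyline with Gaussian-profile spines placed within 3 x width of the
path (error if the requested count cannot satisfy the minimum spacing),
drives shaft pixels with a shared bAP transient and spine pixels with
input + scale x bAP, applies an integer-pixel random-walk motion
trajectory (clipped at `motion_amp`, starting at (0,0)) and adds Gaussian
sensor noise. Motion is applied as a circular (wrap-around) shift so that
un-shifting by the known trajectory recovers the motionless movie
*exactly* — the property the registration oracle tests rely on; the
correction path (`apply_shifts`) uses median edge fill as real data
requires. Stimulus-locked variants add one event per stimulus onset with
amplitude drawn from a known tuning curve.

Defaults (500 frames, 96 x 96 px, 10 spines, width 3 px, τ = 10 frames,
event rates 0.02/0.03 per frame, amplitudes 60 a.u., mixing scales
uniform in [0.2, 1.5]) sketch a GCaMP-like recording at 30 frames/s.
"Moderate noise" in validation is fixed at σ = 6 a.u. — 10% of a unit
event amplitude — chosen once as the level at which single transients are
clearly resolvable, as in usable recordings.

The generator deliberately does **not** emulate realistic optics (no PSF),
Poisson shot noise, nonrigid tissue deformation, z-drift, neuropil
contamination, or 3D volumes. Passing tests therefore demonstrate
correctness of the algorithms under the stated signal model, not
performance on any particular microscope's data; thresholds will need
adjustment on real recordings (in particular `dendrite_width`, the size
bounds, and the turnover displacement cap).

## Numerical and interface conventions

* Coordinates are 1-based `(row, col)` pixel indices throughout, matching
  R's matrix convention.
* Movies are `T x H x W` arrays inside a `TStack`; binary movie files
  store little-endian row-major scanlines with a JSON header giving frame
  count, sample type, and `[width, height]` so external viewers can
  import the raw payload; chunking respects a configurable byte limit.
  TIFF I/O (8/16-bit) is lossless for integer data. The "compression"
  field in the header documents the scheme (`none`).
* Session archives (feature maps, trace sets, results) use R's native
  serialization behind `write_archive()`/`read_archive()`; every result
  object round-trips identically.
* Degenerate inputs have defined behavior: all-zero frames correlate 0 at
  shift (0,0); a constant seed time series is an error naming the seed; a
  zero dendrite trace makes subtraction a no-op; an empty trigger set is
  flagged, not an error; collinear point clouds set a `low_rank` flag.
* Problem sizes in the validation suite (500-frame movies, 20-spine
  fields, 100 ICP/turnover replicates, 2000-frame traces) were chosen as
  the smallest sizes at which the statistical properties under test are
  stable.

## Limitations

Registration is rigid translation only (no rotation or nonrigid warping
within a session) and does not handle single static frames or 3D
volumetric stacks. Cross-session alignment is rigid; slow nonrigid tissue
change will degrade both alignment and the 4-px turnover rule. The bAP
subtraction assumes a single linear global component per dendrite;
branch-specific bAP attenuation or strongly nonlinear dendritic events
violate that assumption (flagged subregions are the guard rail). Spine
morphological subtyping is out of scope.
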