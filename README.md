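# dendromap

Functional imaging analysis of dendritic spines for R.

Two-photon calcium imaging now resolves activity in single dendritic
spines of awake animals, but the analysis tools built for somatic signals
do not transfer: spines are micron-scale, only transiently visible, ride
on a dendritic shaft with its own activity, and their signals are
contaminated by back-propagating action potentials (bAPs). dendromap is an
end-to-end pipeline for this regime, aimed at labs doing *in vivo*
synaptic input mapping:

* **Motion correction** — Fourier-domain phase correlation with a
  stable-chunk template search (initialization re-runs with the next
  stable chunk when the mean registration correlation falls below 0.2),
  safeguard rules for low-signal frames (correlation, mean intensity and
  displacement thresholds; failed frames get shifts interpolated from
  their neighbors), binary/TIFF output and subsampled projection images.
* **ROI segmentation** — particle-detection seeding on the mean image,
  segmentation by the correlation map of intensity transients among
  pixels neighboring the seed (threshold: 80% quantile of the
  neighborhood correlation), morphological size bounds, and
  dendrite-proximity gating (default: within 3x the user-set dendrite
  width). Long dendrites, even shaft subdivisions and spine-linked shaft
  subregions are first-class ROIs.
* **Cross-session alignment** — iterative closest point (ICP) on spine
  centroid + dendrite-sample point clouds; rigid rotation + translation
  with unlimited shift, robust to partial feature overlap.
* **Spine turnover** — globally optimal one-to-one centroid matching
  under a displacement cap (default 4 px) classifying spines as lost,
  retained, or gained, with area / nearest-neighbor / linear-position
  summaries.
* **bAP removal** — robust-regression estimate of each spine's mixing
  scale on dendrite-active frames, refined to the largest scale that
  produces no negative deflections: `corrected = spine − α·shaft`.
* **Response mapping** — per-trial stimulus responses against the
  preceding gray period, constrained two-peak Gaussian direction tuning
  `R(θ) = b + A1·G(θ−θp) + A2·G(θ−θp−180°)` with shared width σ and
  derived OSI/DSI, and event-triggered averages around behavioral
  threshold crossings (e.g. speed > 0.5 cm/s) with trial-type grouping.

A seeded synthetic-data generator (`make_dendrite_movie`,
`make_stimulus_table`, `make_point_cloud_pair`) produces ground-truthed
movies, stimulus schedules and point clouds with the statistical
structure the pipeline assumes, so everything is testable without
imaging data.

## Worked example

Simulate a recording of eight spines on one dendrite under a
drifting-grating schedule (8 directions x 5 repeats, 2 s stimulus / 3 s
gray at 30 frames/s), with frame-to-frame motion, sensor noise, and known
per-spine tuning — then run the whole pipeline:

```r
library(dendromap)

st <- make_stimulus_table(list(n_directions = 8L, repeats = 5L,
                               stim_frames = 60L, gray_frames = 90L), seed = 1)
sim <- make_dendrite_movie(list(n_frames = length(st$framestamp),
                                n_spines = 8L, height = 96L, width = 160L,
                                motion_amp = 6, noise_sd = 6, event_rate = 0,
                                bap_rate = 0.01, stimulus = st,
                                tuning = list(theta_pref = seq(0, 315, by = 45),
                                              a1 = rep(1, 8), a2 = rep(0.4, 8),
                                              sigma = rep(30, 8),
                                              baseline = rep(0, 8)),
                                tuning_noise_sd = 0.05), seed = 1)

print(sim$stack)

reg <- register_stack(sim$stack)                       # motion correction
cat(sprintf("max |shift - true trajectory|: %g px\n",
            max(abs(reg$result$shifts + sim$truth$motion_trajectory))))

dd <- build_dendrite(sim$truth$dendrite_path, sim$truth$dendrite_width,
                     dim(reg$corrected)[2:3])
fmap <- detect_spines(reg$corrected, dendrite = dd)    # constrained detection
print(fmap)

traces <- extract_traces(reg$corrected, fmap)
bap <- remove_bap(traces)                              # bAP subtraction
i <- which.min(rowSums(sweep(sim$truth$spine_centroids, 2,
                             fmap$spines[[1]]$centroid)^2))
cat(sprintf("spine 1: slope_fit %.2f, slope_used %.2f; corrected trace vs true input r = %.3f\n",
            bap$models[[1]]$slope_fit, bap$models[[1]]$slope_used,
            cor(bap$trace_set$traces[1, ], sim$truth$per_spine_input_trace[i, ])))

resp <- stimulus_responses(bap$trace_set, st)
fit <- fit_two_peak_gaussian(codes_to_degrees(attr(resp, "direction"), 8),
                             resp[, 1])
print(fit)
cat(sprintf("ground truth: theta_pref %g deg, sigma 30 deg\n",
            seq(0, 315, 45)[i]))
```

Output (as printed by that session):

```
TStack: 6090 frames of 96 x 160 px (float)
  frame rate: 30 Hz
max |shift - true trajectory|: 0 px
FeatureMap (96 x 160 px): 8 spines, 1 dendrites, 0 shaft subregions
spine 1: slope_fit 0.35, slope_used 0.40; corrected trace vs true input r = 0.809
TuningFit: theta_pref 266.8 deg, sigma 31.5 deg, A1 4.65, A2 1.64, b 0.0831 (r^2 = 0.902)
  OSI 0.923, DSI 0.468
ground truth: theta_pref 270 deg, sigma 30 deg
```

Reading these numbers: registration recovered the simulated motion
trajectory exactly (integer shifts, so exact recovery is the expected
outcome at this noise level); constrained auto-detection found all 8
spines with no false positives; the bAP mixing scale fitted for this
spine's *trace* (0.35–0.40 — the pixel-space scale attenuated by the
mask's mean Gaussian profile weight) yields a corrected trace correlating
0.81 with the true synaptic input; and the fitted tuning curve recovers
the generated preferred direction within ~3° and the width within ~2°.

The command-line interface wraps the same functions:

```sh
inst/scripts/dendromap register movie.tif --out out/ --save-format binary
inst/scripts/dendromap detect out/registered_01_bin --dendrite-path path.csv --width 3
inst/scripts/dendromap turnover tp1.rds tp2.rds --max-disp 4
inst/scripts/dendromap map --traces feats.rds --stim-framestamp fs.csv \
    --stim-info info.csv --mode tuning
```

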