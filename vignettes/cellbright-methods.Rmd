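---
title: "Estimating per-cell protein levels from phase-contrast images: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating per-cell protein levels from phase-contrast images: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cellbright)
```

## The problem

Immunofluorescence staining reads out a protein's abundance per cell but is
invasive: fixation kills the culture, and each staining round reports one
marker. Phase-contrast imaging is label-free and can run for days. cellbright
implements an in-silico labeling pipeline for adherent, flat, roughly circular
cells (epidermal keratinocytes are the motivating cell type): a convolutional
encoder–decoder is trained to map a phase-contrast image to a *per-cell
average fluorescence image*, so that, once trained for a set of markers, a
single phase-contrast frame — or every frame of a time-lapse — yields an
estimate of each marker's level in each cell.

The pipeline has five computational stages:

1. **Segmentation** — cell footprints are extracted from a membrane/actin
   fluorescence channel (rhodamine-phalloidin for fixed material, a
   CellMask-type stain for live imaging) by thresholding and
   connected-component labeling.
2. **Target construction** — each marker image is converted into the
   regression target: every cell region is filled with its area-normalized
   mean intensity (total fluorescence / region area), background is
   suppressed to a constant.
3. **Training** — phase/target pairs are cropped to 256×256 and fitted with
   mean-squared-error loss.
4. **Evaluation** — per-cell measured vs estimated means are compared with
   Pearson's product-moment correlation (two-sided t-test, n − 2 degrees of
   freedom; p < 0.05 is the conventional significance line in reports).
5. **Application** — full fields (e.g. 960×720) are predicted by tiled
   inference; time-lapse sequences additionally get trajectory linking,
   density–expression and event–response analyses.

Because no public image set accompanies the method, the package ships a
seeded synthetic scene simulator that stands in for the microscope at every
stage, with known ground truth.

## Per-cell averaging

`measure_cell_means()` computes, for each labeled region, the sum of the
image over the region's pixels divided by its area, in double precision
regardless of input bit depth. `build_target()` writes those means back into
the regions. Two invariants pin the operation down: *conservation* (region
sum of the target equals region sum of the source) and *idempotence*
(re-averaging an averaged image changes nothing). Both are enforced by
tests against brute-force per-pixel accumulation.

Background pixels take `background_value` (default 0): the processed
training images suppress background, and a constant gives the network an
unambiguous non-cell signal. No background-fluorescence subtraction is
applied before averaging; means are reported in the image's intensity units
(images are `[0, 1]` floats internally, quantized to 16 bit only on export).

## Segmentation choices

The binarization threshold, minimum region size and border handling are
not standardized for this kind of data, so they are explicit, logged
configuration (`segmentation_config()`):

* **Otsu threshold** by default — parameter-free and reproducible; a fixed
  threshold remains available (and is what the tests use when they need
  exact control).
* **8-connectivity**, **hole filling**, **opening radius 1 px**, **minimum
  area 100 px** — suppress speckle at typical 20× magnification scales.
* **Border regions excluded** by default: a cell cut by the field edge has a
  biased mean.
* **No watershed/instance splitting**: touching cells are not separated.
  The simulator guarantees disjoint cells, and the method targets
  sub-confluent fields; confluent-sheet segmentation is out of scope.

Coordinates are 0-based and row-major with half-open bounding boxes,
everywhere. `match_regions()` pairs two segmentations of one field by
maximal pixel overlap, greedily, discarding pairs with Jaccard < 0.5; this
backs the live-vs-fixed style paired comparison (`compare_conditions()`).

## Network

`network_config()` describes a U-Net-style encoder–decoder on 256×256
single-channel crops: 3×3 convolutions at each resolution level, 4×4
stride-2 convolutions to downsample, 4×4 transposed convolutions to
upsample, ReLU after every convolution, and skip concatenation between
matching levels. Channel count doubles per level (`base_channels * 2^l`).
The final 3×3 convolution to one channel is linear.

Defaults and their rationale:

* **depth 4, base_channels 16** — the receptive field must span a whole
  cell (~60 px) so the per-cell constant can be inferred; 16 base channels
  are ample for a piecewise-constant target and keep single-CPU training
  practical.
* **Instance normalization** (per-channel, per-sample) between each
  convolution and its ReLU, added because the plain stack converges too
  slowly for desk-scale training; it can be disabled (`norm = "none"`).
* **A full-resolution refinement convolution** before the output layer
  (`refine = TRUE`). Late-training error concentrates in the 1–2 px ring at
  cell boundaries, where the target jumps; this layer adds capacity exactly
  there for ~10% extra cost.
* **Adam, learning rate 2e-3, batch 8, beta2 = 0.9** — the second-moment
  memory is deliberately short: the objective drifts as the network
  sharpens boundaries, and a short memory tracks that drift better than
  the textbook 0.999. All optimizer settings are recorded in every
  checkpoint.
* **Cell-biased cropping**: crops are centered on randomly chosen cell
  centroids with ±24 px jitter. Uniform crops of sparse fields are mostly
  background and stall MSE training; `crop_sampling = "uniform"` remains
  available.
* **Frame-level validation split** (default 20%): splitting by crop would
  leak pixels between training and validation. The best-validation-epoch
  weights are retained. With a single frame, validation is only allowed to
  monitor the training frame itself (`validation_fraction = 0`), which is
  the memorization-test configuration.

Intensities are normalized to dataset mean/SD on both input and output;
the constants live in the checkpoint so the transform is explicit and
reversible. Checkpoints are single JSON files, human-readable except for
the weights, which are base64-encoded IEEE doubles so a save/load round
trip reproduces predictions bit-for-bit.

One model is trained per marker; a multi-head variant is deliberately out
of scope.

## Tiled inference

Fields larger than one crop are predicted from 256×256 tiles at 50%
overlap, blended with a raised-cosine (Hann + small floor) window and
renormalized so weights sum to 1 at every pixel; edge tiles are shifted
inward to keep full coverage. A 256×256 input reduces exactly to the raw
forward pass. Instance normalization uses each tile's own statistics,
which is the standard behaviour of that layer at inference time.

## Statistics

`pearson()` implements r = cov(x, y)/(sd(x) sd(y)) with the two-sided
p-value from the exact t distribution (t = r sqrt((n−2)/(1−r²)), n − 2 df)
rather than a normal approximation, because per-field cell counts can be
small. The suite checks it against `stats::cor.test`, against a permutation
oracle at n = 3, and calibrates the null rejection rate at p < 0.05 over
2,000 seeded replicates. Correlations are pooled over all cells of the
held-out frames of a marker (one scatter per marker); per-frame breakdowns
are available for diagnostics. No multiple-testing correction is applied
across markers — reports carry raw per-marker p-values. Cells lost to
border exclusion or failed matching are excluded listwise and counted.

A known property of the approach, reported but not corrected: estimated
intensities need not be on the measured scale (Pearson r is
scale-invariant; no calibration step is defined).

## The synthetic scene simulator

`scene_spec()`/`generate_frame()` emulate what the pipeline needs from real
acquisitions, not microscope optics:

* cells are randomly oriented ellipses with low-order harmonic boundary
  wobble — the simplest family matching flat, adherent, roughly circular
  morphology; footprints are disjoint by construction (1 px gap, so
  8-connectivity cannot merge neighbours);
* the phase-contrast channel shows textured interiors (seeded smooth noise
  field, per-cell texture scale in [0.3, 1] times `texture_amplitude`) and
  a bright 1 px edge halo — enough visible morphology for the network to
  learn from;
* the membrane channel is ≥ 4× background exactly on footprints, so
  noise-free scenes segment exactly;
* each marker's ground-truth per-cell level is an affine function of
  morphology features (normalized area, elongation, per-cell texture
  scale, local density = centroids within a 96 px disc / disc area) plus
  optional Gaussian link noise, clipped at 0. Default weights put most
  signal on texture and some on area, landing levels in roughly
  [0.4, 0.9];
* pixel noise is additive Gaussian clipped at 0;
* time-lapse sequences (`timelapse_spec()`/`generate_timelapse()`) move
  centroids by seeded random walks (collisions resolved by holding
  position), add cells per frame to grow density, and implement marker
  dynamics: `density_up`/`density_down` (level monotone in local density
  by construction), `static`, and `damage_transient` (a spike of
  configurable amplitude at the event frame decaying with a half-life in
  frames; the damaged cell persists `rupture_lag` frames before removal).

What passing tests on this simulator do **not** show: robustness to real
phase-contrast optics (phase rings, shade-off), to confluent sheets where
membranes touch, to staining variability, or to any real link between
morphology and protein level — the programmed morphology→marker link is an
assumption required for recovery testing, not a biological claim.

## Problem sizes and numerical choices

Test-suite and acceptance-script workloads are sized for a desk-scale
single-CPU run, as the package's own reference conditions:

* end-to-end recovery: 16 training + 4 held-out 512×512 frames with ~25
  cells each (test suite); the acceptance script runs a scaled study of
  8 + 3 frames at 384×384 with ~15 cells;
* memorization check: one 256×256 frame, depth-3/base-16 network, ≤300
  epochs;
* time-lapse analyses: 30 frames, 384×384, with one marker per programmed
  dynamic, analyzed directly from generator truth to isolate the analysis
  stage from network error;
* segmentation recovery: 50 noise-free 320×320 frames.

Numerical details: instance-norm epsilon 1e-5; convolution arithmetic in
single precision (weights and checkpoints in double); Otsu on a 256-bin
histogram with the threshold at the argmax bin's upper edge; Jaccard
matching breaks overlap ties by ascending id; trajectory linking is greedy
nearest-centroid with a 30 px/frame gate and 1-frame gap tolerance —
competitive assignments are resolved by minimal displacement and flagged
`ambiguous`. Degenerate inputs fail loudly: constant images under Otsu
warn and return zero regions, constant vectors refuse a correlation,
impossible cell packings abort rather than silently truncating.

## Limitations

* Only cytoplasm-wide averages are modelled; proteins confined to the
  nucleus are averaged over the whole cell, which dilutes their signal —
  sub-cellular (e.g. nucleus-restricted) averaging is a recognized next
  step, not implemented here.
* No watershed: touching cells merge into one region.
* Estimates are relative, not calibrated to absolute fluorescence units.
* Tracking is nearest-neighbour; cell division is not modelled, and
  damage/rupture events are supplied (from generator truth or user
  annotation), not detected from images.
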