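---
title: "Measuring and tracking single berries on time-lapse bunch images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and tracking single berries on time-lapse bunch images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(berrytrack)
```

## The problem

Grapevine berries on one bunch ripen asynchronously: neighbouring fruits
can differ by weeks in when they soften, recolour and resume expansion.
Averaging volume or colour over a whole bunch therefore convolves the
individual growth curve with the onset spread, and systematically
overestimates the apparent ripening duration. Resolving the dynamics of
*individual* berries requires (i) inferring the full elliptical outline of
each berry even when neighbours occlude part of it, (ii) turning outlines
into size and colour features, and (iii) keeping each berry's identity
stable across hundreds of frames despite bunch and camera motion.

`berrytrack` implements that measurement chain for time-ordered RGB images
of a single bunch (nominally 2048 x 2448 px, one frame every ~8 h), with
the neural detector and segmenter treated as pluggable predictors behind a
fixed interface, and with a fully ground-truthed synthetic bunch simulator
that exercises every stage.

## Shape model and fitting

Every berry is a five-parameter ellipse `(x_e, y_e, w_e, h_e, a_e)`:
centre (px, x = column, y = row, origin top-left), minor and major axis
lengths (px, `h_e >= w_e` enforced), and the major-axis rotation in
degrees, stored in `[0, 180)`. Annotations and segmentation masks yield
sparse or pixelised contour points; `fit_ellipse()` is the direct
algebraic least-squares conic fit (the numerically stable Halir-Flusser
variant, with centring/rescaling for conditioning), which is exact to
round-off on noise-free samples and needs only 5 points. Near-circular
fits carry an intrinsic angle ambiguity; comparisons in the tests treat
`(a_e, w_e, h_e)` and `(a_e + 90, h_e, w_e)` as equivalent when the aspect
ratio is close to 1.

Ellipse IoU — used for evaluation matching — is computed on 128-vertex
polygonal approximations with convex clipping; the area error of that
approximation is below 1e-3 at berry scales, and tests cross-check it
against a brute-force pixel-membership oracle.

## Detection and segmentation plumbing

The detector sees 416 x 416 px tiles placed with at most 270 px between
offsets, so every berry lies fully inside at least one tile; tile-level
boxes clipped by a tile edge are discarded and recovered from the
overlapping neighbour tile. Pooled boxes pass greedy non-maximum
suppression (box IoU > 0.70 suppressed) and a confidence filter
(`score >= 0.89`, the operating point of the trained detector). Each
surviving box is expanded to a square crop of side `max(w_b, h_b)/0.75`,
resampled bilinearly to 128 x 128 px, and handed to the segmenter, which
returns a binary mask of the *complete* berry as if unoccluded. The mask's
largest connected component is contoured at pixel-edge midpoints (a
sub-pixel, approximately unbiased boundary estimate) and refitted with
`fit_ellipse()`; the vignette transform maps the parameters back to image
coordinates exactly.

The `oracle_predictor()` stands in for the trained models on synthetic
renders: it returns the enclosing boxes of berries with at least 50% of
their boundary visible, scored by that visibility, and rasterised
ground-truth masks. Because its scores *are* visibilities, synthetic
end-to-end runs use `run_config(conf_threshold = 0.5)` so the confidence
filter expresses the 50%-visible measurability rule; the 0.89 default is
meaningful only for a trained detector's confidence distribution.

## Features

Volume: the projected area is `A = (w_e/2)(h_e/2)pi` and the volume is
that of the sphere with the same cross-section, `V = (4pi/3)(A/pi)^(3/2)`
px^3, convertible to mL with the fixed chessboard calibration
3.94e-6 mL/px^3. (A variant of the volume formula with a cube root is
sometimes printed; it is dimensionally inconsistent and available only
behind `sphere_volume(..., printed_form = TRUE)` for comparison.) `V` is a
geometric transform of the measured area — the package uses it for
*relative* growth only.

Colour: hue lives on the half-circle 0-180 degree scale (standard 0-360
hue divided by two). A berry's raw hue `h_raw` is the circular mean over
pixels strictly inside its ellipse, at least `dp = max(3, w_e/4)` px from
its edge (computed on the rasterised mask with a Euclidean distance
transform, matching pixel semantics) and inside no other ellipse of the
frame. The centred hue `H = (180 - h_raw - h_50) mod 180` with
`h_50 = 100` anchors mid-colour-change berries; the modulo maps negative
arguments into `[0, 180)`. No saturation-based pixel exclusion is applied
before the circular mean.

## Tracking

Berry centres of frame `t` form a point set `S_t`. Two sets are matched
greedily: closest pairs first, one-to-one, pairs farther than
`delta = 16` px discarded (ties broken by lowest indices, for
determinism). `delta` is deliberately small — about a quarter of a typical
berry width — which strongly favours precision over coverage.

Before matching, the moving set is registered onto the reference set with
an affine coherent point drift (EM over a Gaussian mixture with a uniform
outlier component, weight 0.1, tolerance 1e-6 on the relative objective
change, at most 200 iterations; sets with fewer than 3 points skip
registration). Point sets are internally normalised to zero mean and unit
scale so the outlier term is commensurate with the Gaussian term, and the
recovered transform is mapped back to pixel coordinates.

Frames are not matched chronologically. The directed set distance
`d(S_i, S_j)` is the median over points of `S_i` of the nearest-neighbour
distance into `S_j` (even counts: mean of the two middle values); the
symmetric `D` averages both directions. `D` after registration fills an
`N x N` matrix, from which a layered *matching tree* is grown: at layer
`k`, unplaced frames attach (closest first, by `min(M_ij, M_ji)`) to any
placed frame of depth `< k` while that distance is below `theta = 8` px;
when no candidate qualifies, the single globally closest (unplaced,
placed) pair is bridged as a *long-distance* edge and the next layer
opens. The root is chosen exhaustively as the frame whose tree places the
most nodes before the first long-distance edge, ties broken by the largest
point count, then the smallest frame index. Labels initialise one per
observation at the root and propagate edge by edge in attachment order;
each child is registered onto its parent (local registration is better
conditioned than registering onto the root across a long path) and
matched; unmatched observations stay unlabelled rather than guessing.

The four combinations of `use_registration`/`use_tree` in
`track_series()` reproduce the baseline, +registration, +tree and full
variants; on the simulator's abrupt-rotation scenario the full method
strictly improves coverage over the chronological baseline while the
precision stays at its ceiling.

## Kinetics

Per-label volume series are smoothed with a centred 8-day moving median
(window truncated at the series ends). Berries observed in fewer than 90%
of the frames are excluded, and of the remainder the 10% with the highest
MAPE between raw and smoothed volume are dropped — a fixed-fraction
quantile rule, so even a noise-free cohort loses that fraction; the
fraction dropped is `floor(0.10 n)`, which reproduces the reference
arithmetic of retaining 73 of 81 berries. Each variable `X` (smoothed `V`;
daily-binned `H`) is normalised by its early baseline `X_0` (median over
the first 8 days of the time axis, robust to irregular sampling) and its
late baseline `X_max` (for `V` the maximum of smoothed values over the
last 8 days, for `H` the median): `X_r = (X - X_0)/X_0` and
`X_s = (X - X_0)/(X_max - X_0)`. Degenerate berries (`X_max = X_0`) are
flagged and excluded from descriptor summaries.

Descriptors: growth resumption `t(V_s = 0.15)` and coloration start
`t(H_s = 0.15)` are the *first upward crossings*, linearly interpolated
(series already above the level cross at their first sample); ripening
duration `RD = (t(V_s = 0.85) - t(V_s = 0.15)) / 0.7`; relative speed
`RS = dV_r/dt` over the same interval. Crossings are evaluated on the
smoothed `V_s` and on daily-binned raw `H_s`. The "mean berry" averages
`V` and `H` across berries in calendar-day bins (floor of time in days,
empty days skipped) and runs through the identical pipeline; with
asynchronous onsets its apparent `RD` exceeds the typical individual one
because averaging adds the onset spread to the true rise time.

## The synthetic simulator

The simulator is 2D with a per-berry depth order — sufficient to create
the occlusion and visibility regimes the pipeline must handle without
modelling a 3D bunch. Berries are placed in a Gaussian cluster; each
follows a plateau-logistic-plateau volume curve parameterised by its onset
(the 15% point), a 15-85% rise duration of 18 days and a relative
amplitude of +60% — the regime observed for a ripening bunch — with an
optional linear shrivel after the peak. Raw hue transitions logistically
(green 60 downward, circularly, to dark 150 on the half-circle scale)
with its midpoint lagging the growth midpoint by 4 days. Frames undergo a
*cumulative* similarity jitter (translation sd 1.5 px, rotation sd 0.5
deg, log-scale sd 0.002 per frame) plus scripted events: an abrupt rigid
rotation, or a non-affine rearrangement that redraws positions while
identities persist. Visibility is the fraction of a berry's boundary arc
not covered by shallower berries, matching the visible-contour criterion
(not area overlap). The renderer paints filled ellipses back-to-front at
fixed saturation/value with additive Gaussian pixel noise; the seed fully
determines everything.

Scenario notes. `static` freezes growth and jitter entirely (identical
frames), making it a pure identity-propagation check with exact 100%
coverage/precision expectations. `asynchronous_cohort` (n = 50, 8 h
sampling, 60 days) spreads onsets over 18 days — equal to the rise
duration — and disables shrivel and the scale random walk: its purpose is
parameter recovery for a *known-parameter logistic* cohort, and a
cumulative zoom drift (up to several percent volume) or post-peak
shrinkage would corrupt the very baselines the normalisation relies on.
Its 60-day span guarantees every berry reaches its plateau before the
late 8-day baseline window, as the normalisation requires.

## Numerical choices and limitations

* Rasterisation uses pixel-centre membership at `(col - 0.5, row - 0.5)`;
  mask contours are pixel-edge midpoints, keeping mask-derived parameters
  within a pixel of truth at berry scales.
* The distance matrix registers every ordered frame pair (`O(N^2)` CPD
  runs); for a 100-frame series this is ~2 minutes on one CPU and
  dominates tracking cost. Frames with fewer than 3 points skip
  registration and are flagged.
* First-crossing detection and the late-window maximum are sensitive to
  measurement noise on the volume series: the maximum of a smoothed noisy
  plateau is biased upward, which stretches the apparent 15-85% interval,
  and the first crossing of a noisy series triggers early — both biases
  grow with the per-sample noise level. A related structural effect: when
  a berry's onset falls within a few days of the series start, the
  logistic's left tail leaks into the first-8-days baseline and inflates
  `X_0`, shortening the apparent ripening duration. The
  segmentation-based measurement chain on synthetic renders operates at
  sub-percent volume noise, so recovery there is limited by geometry
  rather than by these estimator biases; users applying the kinetics
  stage to noisier volume series should expect the sensitivity, which the
  MAPE exclusion mitigates but does not remove.
* What passing simulator tests does *not* show: robustness to leaves and
  stems crossing the bunch, photometric drift, defocus, or field
  illumination — the renderer is deliberately minimal (flat colours,
  Gaussian noise), and the oracle predictor is immune to pixel noise by
  construction. Those aspects belong to the trained predictors, which are
  out of scope behind the `PredictorInterface` seam.
* Tracking across a genuine non-affine rearrangement is out of the
  method's design envelope: coverage drops (by design, rather than
  mislabeling), but a few cross-break matches can still fall under
  `delta` after an aggressive affine alignment, so label purity on such
  series is high but not perfect. Appearance-based re-identification
  across long-distance edges is a non-goal.

## Problem sizes used in the shipped checks

The test-suite and acceptance runs use the simulator at its documented
scenario sizes: 100-frame / 60-berry nominal tracking, a 40-frame
rotation-event pair, and the 180-frame / 50-berry asynchronous cohort;
fitting and matching accuracy are established on 1000 random ellipses and
500 random matching instances. These sizes give stable statistics while
keeping a full run in a few minutes on one CPU.
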