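---
title: "milkcv: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{milkcv: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkcv)
```

## The measurement problem

The creamatocrit estimates milk fat from the height of the packed cream
layer in a centrifuged microcapillary (≈ 75 mm long, ≈ 1.1 mm bore), sealed
at one end with a plasticine plug. After centrifugation the tube holds three
stacked phases: the opaque seal, the translucent aqueous serum, and the
bright lipid cream at the far end. The cream fraction $c = h_c / h_t$, with
$h_t = h_s + h_c$ the total liquid-column height, feeds two linear clinical
models:

$$F = \frac{2950}{73}\,c \quad [\%], \qquad ED = 6680\,c + 290 \quad
[\mathrm{kcal/L}].$$

The prefactor $2950/73 \approx 40.41$ makes $F$ a percentage.

### Uncertainty budgets and self-calibration

Logarithmic differentiation of the fat model, taking the worst case where
the height errors add, transfers an instrument resolution $\Delta h$ into

$$\Delta F = \frac{2950}{73}\,\frac{\Delta h}{h_t}\,(1+c), \qquad
\Delta ED = 6680\,\frac{\Delta h}{h_t}\,(1+c).$$

For an analog caliper $\Delta h$ is the half-division, 0.5 mm; for the
camera it is 1 px. Both budgets grow linearly in $c$: lipid-rich samples are
intrinsically harder to measure. Their ratio $\Delta ED / \Delta F = 6680
\cdot 73 / 2950 \approx 165.30$ is constant. Because $c$ is a ratio of
lengths measured on the same axis, any uniform spatial scale factor cancels:
the pixel-domain measurement needs no px-to-mm calibration, and `milkcv`
performs none (`uncertainty_band()` tabulates the budgets on either scale).
The package deliberately reports `relative_error()` as the plain ratio
$100\,\Delta/\bar{x}$; published relative-error tables for this assay do not
always recompute exactly from their own printed means, and where such
printed values are used as *inputs* (e.g. `error_improvement(11.52, 4.90)`)
the package simply evaluates the stated formula.

## Segmentation pipeline

All images are 8-bit RGB arrays indexed `[row, col, channel]`, origin
top-left, y increasing downward; pixel coordinates are 0-based and ROIs
half-open. Grayscale conversion uses ITU-R BT.601 luma
($0.299R + 0.587G + 0.114B$, round-half-up) — the standard for 8-bit camera
output; no convention is imposed by the assay itself.

The stages of `segment_capillary()`:

1. **Binarization** (`binarize`): foreground where gray $> T_b$ (strict).
   $T_b = 20$ separates the tube from a dark enclosure background.
2. **Capillary ROI** (`find_capillary_roi`): 8-connected components
   (4-connected flood fill plus a diagonal-merge union–find), each
   validated by the shoelace area of its border-following contour against
   `min_area` (default 500 px² at the reference resolution — about 60 % of
   the smallest admissible liquid column, so partial fills pass and specks
   fail). The largest-area contour wins; ties break
   topmost-then-leftmost. The axis-aligned bounding box becomes the ROI,
   and the selected component's mask is kept: profile averaging is
   restricted to it, so stray background pixels that cross $T_b$ inside the
   box (inevitable under sensor noise, and heavily represented when tilt
   widens the box) cannot distort the profile.
3. **Midpoint split** (`split_roi`): $y_{mid} = \lfloor h/2 \rfloor$; the
   seal-side half is ROI1 and the cream-side half ROI2, per the configured
   seal orientation (default: seal at the bottom of the photograph).
   Boundaries are reported in *axial* coordinates — row 0 at the seal-end
   extremity, increasing along the tube — so the same invariants hold for
   either orientation; `y_base` records the image row of the origin.
4. **Interface location** (`locate_seal_end`, `locate_cream_start`,
   `locate_cream_end`): first strict exceedance of the absolute first
   forward difference of the component-masked, column-averaged axial
   profile. First crossing (not the global maximum) is used because the
   physical ordering of interfaces along the tube is known. Configurable
   additive offsets (`dy_seal`, `h_seal`, `dy_cream`, `h_cream`, all
   defaulting to 0) absorb instrument-specific displacement corrections.
   The cream-end scan starts two rows past the cream start so the residual
   gradient of the serum/cream meniscus is not mistaken for the cream end;
   when no exceedance exists (incomplete filling reaching the ROI edge) the
   ROI's far edge is used and a warning recorded.
5. **Phase heights** (`phase_height`): pixels in the phase's gray range —
   serum in $[T_{min_g}, T_{max_g}] = [25, 90]$ confined between the seal
   end and the cream start, cream $> T_w = 90$ within the cream-side half —
   are masked, the dominant (largest) component is taken, and the height is
   the longer side of the minimum-area rotated rectangle
   (rotating calipers on the convex hull). The rotated rectangle, not the
   bounding box, is what keeps heights accurate under axial tilt. Extents
   measured on pixel centers get +1 per axis (pixels are unit squares), so
   an axis-aligned 40-row band measures exactly 40 px.
6. **Adaptive crop** (`adaptive_crop`): axial rows
   $[y_{seal\_end}+1,\; y_{cream\_end}-1]$ across the ROI's full width —
   the sub-image holding only biological content, which feeds the feature
   extractor.

### Threshold roles and the gradient threshold

$T_w = 90$ plays its intensity role (cream and seal are brighter than it,
serum and background darker) unchanged. For the *gradient* role the config
carries a separate `grad_thresh`, default 25. A single shared constant
cannot serve both roles: the weakest interface contrast (serum ≈ 60 to
cream ≈ 150) is 90 a.u., exactly the intensity threshold, and tilt plus a
1-px meniscus blend can split that step across up to three profile rows —
leaving a guaranteed per-row gradient of only ≥ 30 a.u. The default 25 sits
below that worst-case floor and roughly fifteen standard deviations above
the masked-profile noise at the default sensor noise, so detection is
neither missed nor spurious. Both thresholds are per-role overridable.

### Degenerate inputs

Empty masks, all-background images, ROIs too small to split, empty phase
ranges, and empty crop windows raise stage-labelled errors
(`"segmentation stage 'roi': ..."`). A gradient step exactly equal to the
threshold is *not* an interface (strict inequality), and collinear or
single-pixel components fall back to length-along-direction rectangles.

## Histogram features

`feature_vector()` concatenates 256-bin per-channel intensity histograms
$H_k(i) = \#\{(x,y): I_k(x,y) = i\}$ in the fixed order R‖G‖B(‖Gray), giving
256 (gray), 768 (rgb) or 1024 (combined) features named `R_0` … `Gray_255`.
The Gray block is recomputed from the crop with the same BT.601 luma as the
segmentation, so it is identical to reusing the segmentation grayscale.
Whether histograms should be raw counts or normalized is not dictated by
the assay; both are implemented and **frequency is the default**, because
crop height varies with the cream fraction and regression features must be
comparable across crops. Counts mode conserves the pixel count per block.

## Illumination quality control

`sample_pixels()` draws 30 000 intensities uniformly with replacement,
pooled across the R, G and B channels (intensity tables for this assay are
reported in plain a.u. without channel annotation, so pooling is assumed);
`intensity_stats()` reports quartiles (linear interpolation between order
statistics — the common default, none being dictated), extrema and dynamic
range $DR = \max - \min$. `compare_conditions()` ranks conditions by
descending DR, ties broken by the lower minimum (deeper noise floor), since
a wide DR with a dark floor is what makes threshold segmentation easy. A
gold/warm low-intensity configuration with $DR = 226$ a.u. tops the
reference table shipped in `inst/extdata/illumination_reference.csv`.

## Cream-fraction regression

The lead model is Gaussian-process regression with the rational quadratic
kernel

$$k(x, x') = \sigma_f^2 \left(1 + \frac{d^2}{2\alpha\ell^2}\right)^{-\alpha},
\qquad d = \lVert x - x' \rVert,$$

a scale mixture of squared-exponential kernels that handles both small- and
large-scale structure and recovers the squared exponential as
$\alpha \to \infty$ (verified numerically at $\alpha = 10^6$).
Squared-exponential, Matérn-5/2 and exponential GP kernels, ordinary least
squares, and Gaussian/polynomial epsilon-SVMs (via `e1071`) are available as
presets; the wider zoo of tree/ensemble/neural presets found in benchmark
exercises adds no method content and is deliberately out of scope.

Fitting (`fit_cream_model`): features are standardized with training-set
mean and standard deviation (constants stored in the model); GP
hyperparameters $(\sigma_f^2, \ell, \sigma_n^2[, \alpha])$ maximize the log
marginal likelihood in log-space (Nelder–Mead, 3 random restarts, seed
recorded), with a constant mean function estimated as the training-target
mean. The Cholesky factorization is retried along a jitter ladder
($0, 10^{-10}, \dots, 10^{-4}$) before failing. Prediction returns the GP
mean and, on request, the latent predictive standard deviation.

`split_dataset()` permutes rows under the seed and assigns
$\lfloor 0.65 n \rfloor$ to training and $\lfloor 0.10 n \rfloor$ to test,
with leftover rows to validation — the unique simple rule that yields
65/25/10 at $n = 100$ and 6/3/1 at $n = 10$. No stratification is applied.
Because hyperparameters are selected on the training rows alone (marginal
likelihood, not validation search), the validation and test rows are both
genuinely held out; benchmark evaluations therefore pool them, which makes
the reported $R^2$ far less noisy than a 10 % test split alone.
`evaluate_predictions()` reports $R^2$, MAE, RMSE, mean relative error (in
percent, over cream fractions, restricted to strictly positive truths),
mean bias, and a two-sided paired t-test p-value. Models serialize to a
single versioned file; loading a mismatched version is refused, and
reloaded models predict bit-identically. `permutation_importance()` (the
drop in held-out $R^2$ when one column is shuffled, one seeded permutation
per column) substitutes for attribution analyses.

## The synthetic generator

`render_capillary()` emulates the acquisition this pipeline assumes: a dark
enclosure (background gray 10), a centered tube of 5 px bore — the bore a
1.1 mm capillary subtends at the reference scale of ≈ 4.7 px/mm — holding a
30 px seal (gray 200), serum (gray 60) and cream (gray 150), under
channel gains that mimic warm ("gold", R-heavy) or cool illumination while
preserving luma. The phase grays are chosen so the fixed thresholds
($T_b = 20$, serum $[25, 90]$, $T_w = 90$) separate phases exactly as the
segmentation presumes. Meniscus curvature is emulated by single blended
rows (70 % inner phase, 30 % neighbor) at the liquid interfaces — the
seal's outer end, a plasticine plug, stays sharp. The scene is rotated
about the image center by the tilt angle with nearest-neighbor sampling
(preserving 8-bit values), then i.i.d. per-channel Gaussian noise
($\sigma = 4$ a.u. by default) is added and clamped. Axial distances are
invariant under the rotation, so ground-truth heights and $c$ carry over
exactly; blend rows are owned by their phase, making noise-free untilted
scenes recoverable *exactly*.

Defaults reproduce the reference digital geometry: $h_s = 215$,
$h_c = 12$, $h_t = 227$ px, $c = 12/227 \approx 0.0529$.
`generate_dataset()` draws $c$ uniformly over the clinically validated
range $[0.0429, 0.0663]$, tilt over $[-5°, 5°]$ and fill over $[0.7, 1]$
(the filled column is $\mathrm{round}(fill \cdot 227)$ px, emulating
incomplete filling), with per-image seeds derived from the master seed.

What the generator does **not** emulate: optical scattering physics, lens
distortion, meniscus *shape* (only its intensity footprint), real cream
chroma (channel gains approximate warm illumination, but no spectral ground
truth exists for milk phases), multi-capillary scenes, or texture within
phases. Passing tests therefore demonstrate correctness of the geometry,
thresholds and statistical machinery under the stated optical model — not
clinical performance on hospital images, whose artifacts (bubbles, smudges,
uneven illumination) are outside this model.

## Validation problem sizes

The shipped suite validates segmentation recovery on 100 generated scenes
spanning the full $c$/tilt/fill ranges (≥ 95 % of cream heights within
±1 px; MAE($\hat c, c$) well under 0.005 — observed ≈ 0.0002), and the
regression path on a 400-image benchmark per seed (65/25/10 split, five
seeds, gray-mode features): median held-out $R^2 \ge 0.85$ (observed
≈ 0.87) and median MAE ≤ 0.006 (observed ≈ 0.002). Gray-mode features are
used for the benchmark because the generator's channels are fixed gains of
one luminance signal — rgb/combined modes triple the dimension without
adding information there, which degrades an isotropic-kernel GP; on real
sensors the color blocks carry independent signal and the wider modes are
the ones to reach for.

## Known limitations

- Interface location assumes one capillary, dark background, and phases
  ordered seal → serum → cream along the tube.
- Heights rely on the phase gray ranges; illumination drifting outside the
  QC envelope (serum leaving $[25, 90]$, cream dipping below $T_w$) breaks
  the intensity-role thresholds before it breaks the gradient role.
- The GP uses one isotropic length scale over standardized features;
  strongly anisotropic feature relevance is only captured through
  standardization, not per-dimension length scales.
- The analog/digital uncertainty comparison takes the printed experimental
  means as given; it is a model evaluation, not a new measurement.
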