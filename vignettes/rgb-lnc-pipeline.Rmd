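---
title: "Estimating rice leaf nitrogen from RGB color indices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating rice leaf nitrogen from RGB color indices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgbLNC)
```

## The problem and the model

Leaf nitrogen concentration (LNC, percent of leaf dry mass) is the
standard diagnostic for rice nitrogen status. Chlorophyll content — and
therefore visible leaf color — tracks nitrogen closely enough that
ordinary RGB cameras can serve as a cheap proxy for laboratory Kjeldahl
analysis. The statistical model is deliberately simple:

$$\widehat{\mathrm{LNC}} = \beta_0 + \sum_{j \in S} \beta_j x_j,$$

where the $x_j$ are color indices computed from the mean red, green, and
blue digital numbers (DN, 0–255) of the *vegetation* pixels of an image,
and the subset $S$ of the 13 candidate indices is chosen by stepwise
multiple linear regression (SMLR): forward entry when a term's two-sided
coefficient t-test is significant at 5%, backward elimination of any
retained term at 10%. Coefficient t-tests on a single added or deleted
term are equivalent to the corresponding partial F-tests, so this is the
classical p-value stepwise procedure.

The pipeline has four stages, each an exported function group:

1. **Segmentation** — isolate vegetation before averaging channels.
   Leaf scans (`segmentLeaf()`): Otsu's threshold on the rounded
   per-pixel channel mean, foreground = the darker class. Field scenes
   (`segmentByGMR()`): vegetation iff $G - R > t$, $t$ swept over
   $\{0, 5, 10, 15, 20\}$ DN. Plot mosaics: clip to plot polygons
   (`clipToPolygon()`) and intersect with the GMR mask
   (`intersectMasks()`; intersection commutes, so clip-then-segment
   equals segment-then-clip).
2. **Color indices** (`computeColorIndices()`) — the 13 indices listed in
   the README, computed **from the channel means**, not averaged
   per-pixel indices. The two conventions differ for the ratio indices;
   the index-of-means convention is recorded in serialized model output.
3. **Regression** (`stepwiseSelect()`, `loocvEvaluate()`) — SMLR plus
   leave-one-out cross-validation.
4. **Evaluation** (`computeFitMetrics()`, `classifyNRMSE()`, and the
   experiment drivers) — $R^2$, RMSE (LNC percentage points), NRMSE
   ($100\,\mathrm{RMSE}/\bar O$, %), banded excellent/good/fair/poor at
   10/20/30%.

## Key parameters

| Parameter | Units | Default | Rationale |
|---|---|---|---|
| GMR threshold | DN | swept 0–20 by 5 | the candidate set tested in the field protocol; strict `>` so threshold 0 excludes achromatic pixels |
| `pEnter` / `pRemove` | significance | 0.05 / 0.10 | the forward/backward criteria of the SMLR procedure; `pEnter <= pRemove` enforced to prevent add/remove oscillation |
| LOOCV `selection` | — | `"fixed"` | variable set selected once on all data, coefficients refit per fold; `"per-fold"` reselection also implemented, mode always recorded |
| NRMSE bands | % | 10 / 20 / 30 | half-open, lower-inclusive from 10 up: NRMSE = 10 is "good" under the strict "< 10%" reading of "excellent" |
| `noiseSd` | DN | 8 | generator pixel noise; consumer-camera shot/JPEG noise scale |
| `gmrMargin` | DN | 25 | minimum pre-noise vegetation $G-R$; above the largest swept threshold so noiseless scenes are exactly separable |
| `vegFraction` | fraction | 0.65 canopy / 0.35 leaf | typical reproductive-stage canopy cover; leaf occupies about a third of a scan |

## What the synthetic generator emulates — and what it does not

The original study's imagery and LNC measurements are not publicly
deposited, so the package carries a first-class generator whose defaults
*are* the study conditions the analysis assumes:

* **LNC distributions.** Per site × stage, LNC is drawn from
  $\mathcal N(\mu, \sigma)$ truncated to $[0.5, 4.5]$%, with the default
  `fieldDesign()` using the observed two-site summary (booting
  2.31 ± 0.41 and 3.00 ± 0.49; flowering 2.01 ± 0.35 and 2.55 ± 0.39;
  filling 1.71 ± 0.42 and 1.98 ± 0.50; n = 40 and 30 per stage).
  Truncation keeps draws inside a physically plausible envelope around
  the observed range 0.93–3.95%.
* **Leaf color.** A linear map per channel,
  $\mathrm{DN}_c = a_c + b_c\,\mathrm{LNC}$, clipped to $[0, 255]$;
  defaults $R = 140 - 28\,\mathrm{LNC}$, $G = 150 - 10\,\mathrm{LNC}$,
  $B = 45 + 10\,\mathrm{LNC}$. This is the simplest mechanism that
  reproduces the empirical sign structure (NBI rises with LNC, NRI
  falls: nitrogen-rich leaves are darker and bluer-green) and keeps
  vegetation $G - R = 10 + 18\,\mathrm{LNC}$ above the default 25-DN
  margin over the observed LNC range. It is a stand-in for the measured
  leaf-color/nitrogen relation, not a radiometric model.
* **Scenes.** Leaf scans: an ellipse (area = `vegFraction` × image) on a
  DN-250 background. Canopy: a per-pixel Bernoulli vegetation field over
  a soil/residue/water palette whose colors all have $G - R \le -12$, so
  green-minus-red separation is meaningful by construction; spatial
  arrangement is irrelevant because the indices only use channel means.
  Plot mosaics: a rectangular grid of canopy scenes separated by
  background bunds, with polygons that exactly enclose each plot's
  pixels. Noise is i.i.d. Gaussian per pixel and channel, rounded and
  clipped to 8 bits — the simplest model consistent with camera DN
  quantization.
* **Reproducibility.** Every scene and every plot's LNC draw runs in its
  own RNG stream derived from the master seed and the (site, stage,
  plot) key (`sceneSeed()`), so inserting or removing plots never
  perturbs other scenes, and identical seeds give bit-identical output.

Not emulated: bidirectional reflectance, shadows, specular water
highlights, panicle/senescence spectra, photogrammetric distortion, or
any altitude physics (altitude is a pass-through tag). Consequently,
passing tests demonstrate that the *pipeline machinery* is correct —
segmentation recovers known truth, selection recovers known generating
models, validation is leak-free — not that field-scale accuracy would
reach the same $R^2$; synthetic scenes are far cleaner than field
imagery, and the package's near-unity synthetic $R^2$ values are upper
bounds. One scene stands in for one plot per stage; real protocols may
photograph several.

The regression test-bed (`simulateIndexTable()`) draws *independent*
random channel means instead of image-derived ones: indices computed
from a single underlying LNC are perfectly confounded along a curve, so
generating-set recovery is only identifiable with independent channel
variation.

## Numerical choices

* **Otsu**: exhaustive argmax of the between-class variance over all 256
  thresholds, computed from exact integer cumulative sums with the
  constant factor dropped; ties broken by the smallest maximizing
  threshold, so results are deterministic across implementations. A
  single-bin histogram is an error, not a threshold.
* **Grayscale for Otsu** is the rounded mean of R, G, B (no channel is
  privileged; sums of three 8-bit values are never exactly halfway, so
  rounding is unambiguous).
* **GMR rule is strict** (`> t`): thresholds above zero classify darker,
  shaded material as background, and at $t = 0$ achromatic pixels fall
  to the background.
* **Point-in-polygon**: even-odd ray cast on pixel *centers*, 0-based
  coordinates with the center of pixel $(i, j)$ at $(i+0.5, j+0.5)$ —
  integer-vertex polygons therefore never intersect a pixel center, and
  an axis-aligned rectangle with vertices at $r_0, r_1$ selects exactly
  rows $r_0 \ldots r_1 - 1$.
* **$R^2$ denominator** is $\sum_i (O_i - \bar O)^2$ (observed
  deviations): with the predicted-deviation variant, perfect prediction
  would not generally give $R^2 = 1$. RMSE carries no extra 100× factor;
  it is on the LNC percentage-point scale, matching the magnitudes the
  quality bands assume.
* **Degenerate fits**: a numerically exact fit (residual SS below
  machine precision relative to the response variance) halts forward
  selection, and NaN p-values from zero residual variance count as 1, so
  spurious terms are never retained on the back of an exact fit.
  Candidates whose addition would make the design rank-deficient are
  skipped — NRI + NGI + NBI = 1 and ExG = 3 NGI − 1 hold exactly, so
  collinear combinations arise routinely.
* **Tie-breaks** in selection follow the fixed index-table column order,
  making the whole procedure deterministic.
* **Empty foregrounds** are tolerated at segmentation time (a sweep cell
  is marked failed and the sweep continues) but are an error when
  channel statistics are requested, naming the method and threshold.

## Open design decisions

* Whether reported per-stage accuracies in this literature are
  resubstitution or cross-validated values is often ambiguous; the
  package always computes both and records the LOOCV selection mode.
* Segmentation "improvement" percentages are **relative** changes in
  $R^2$ (`r2Improvement()`), which is the reading consistent with the
  one recomputable pre/post pair (0.54 → 0.59 = +9.26%); an
  absolute-difference mode is available behind `method = "absolute"`.
* Stage declines are signed internally (declines negative); prose-style
  "decline" magnitudes are the absolute values.
* Unsegmented ("before segmentation") statistics use the all-pixel mask
  at canopy scale and the clip mask alone at plot scale.
* Raw DNs are used throughout; no white-balance correction is attempted
  (field cameras ran automatic white balance, and no calibration target
  is available to invert it).

## Problem sizes

The test suite and the acceptance script run deliberately small
configurations — scenes of 32–128 px on a side, 10–60 samples per
regression, 2 000 draws for distribution-recovery checks, 10-seed
replication for the segmentation-benefit property — chosen so the full
suite completes in well under a minute while keeping every statistical
check comfortably powered.

## Known limitations

* The canopy generator's Bernoulli vegetation field has no spatial
  autocorrelation; any analysis depending on patch structure (e.g.
  morphological cleanup, texture features) is out of scope.
* Linear single-channel color response cannot represent reflectance
  saturation at high leaf-area index, one of the mechanisms that degrades
  booting-stage canopy models on real data.
* Stepwise selection with exactly collinear candidate identities can
  return an algebraically equivalent reparameterization of the
  generating set when noise is non-zero; the tests therefore check exact
  recovery only in the noiseless limit and stability (membership in the
  exhaustively enumerated set of stable subsets) otherwise.
* `classifyNRMSE()` applies fixed 10/20/30% bands; they are conventions,
  not calibrated error bars.
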