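---
title: "Quantifying organoid swelling screens: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying organoid swelling screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgaswell)
```

## The measurement problem

Airway (nasal) organoids secrete fluid into their lumen when an ion channel in
their epithelium opens; the cross-sectional area of each organoid then grows
roughly linearly over a few hours. In a medium-throughput drug screen this is
read out by time-lapse brightfield imaging of 384-well plates: an upstream
detector (a convolutional network such as OrgaQuant, or the classical blob
detector shipped here for synthetic frames) emits one bounding box per
organoid per frame, and everything downstream is statistics:

1. **Area from a box.** An organoid is treated as a disk. A box of width $w$
   and height $h$ gives an effective diameter $d = (w + h)/2$ and area
   $A = \pi (d/2)^2$. The mean-extent rule is exact for square boxes and
   symmetric in the two extents; `min`, `max` and `geometric_mean` are
   available as alternatives since the reduction of a non-square box to a
   diameter is a genuine free choice.
2. **Tracking.** Per well, consecutive frames are linked by a
   minimum-total-displacement one-to-one assignment (Hungarian algorithm)
   among candidates within a displacement gate; a track may miss up to
   `memory` consecutive frames (its gate grows proportionally with the gap).
3. **Swell rate.** For each track, ordinary least squares of area on frame
   index: the slope $\hat\beta$ (pixel² per time point) is the organoid's
   swell rate, with the usual residual-based standard error
   $\mathrm{SE}(\hat\beta) = \sqrt{\hat\sigma^2 / S_{xx}}$.
4. **Quality control.** An organoid is excluded when (a) it was recognized in
   fewer than 8 of the 13 time points, or (b) its slope SE exceeds 2.5
   (strictly). The frame rule is checked first. Remaining slopes are averaged
   per well.
5. **Plate normalization and hit calling.** Per plate,
   $z = (\text{rate}_\text{well} - \mathrm{median}_\text{plate}) /
   \mathrm{IQR}_\text{plate}$; compound scores are averaged across wells,
   plates and donors, and a compound is a hit when its mean normalized rate
   is strictly above 1 — one interquartile range above the plate median.

Companion readouts use the same package: the conventional calcein
fluorescence quantification (per-well total area normalized to 100 % at
$t=0$, trapezoidal AUC of the excess percent over 0–120 min, optional
subtraction of the same-plate DMSO mean), Ussing-chamber current steps
($\Delta I_{sc}$: mean of five samples after minus five before an addition,
per cm² membrane), and halide-sensitive YFP quenching (steepest negative
sliding-window slope of the trace normalized to its initial fluorescence).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `n_frames` / `frame_interval` | 13 / 15 | – / min | the 3-h primary screen cadence |
| `min_frames` | `ceiling(8*n_frames/13)` | frames | the 8-of-13 recognition rule, scaled proportionally for other acquisition lengths |
| `se_max` | 2.5 | pixel²/time point | the protocol's SE cutoff. The protocol states it in "pixels/time point" while areas are in pixel²; we apply the cutoff to the slope SE in the fit's own area units and keep the number configurable, since the intended unit is ambiguous |
| `max_displacement` | 30 | px/frame | tracking gate; organoids are essentially stationary, so this mostly guards against detector jitter |
| `memory` | 5 | frames | an organoid may miss 5 of 13 frames and still pass QC, so the linker must survive 5 consecutive misses |
| `diameter_rule` | `"mean"` | – | see above |
| `control_policy` | `"compounds"` | – | the hit threshold is defined relative to the compound-well distribution, so DMSO/Eact wells are excluded from the median/IQR reference by default; `"all"` is available |
| `quantile_type` | 7 | – | linear interpolation between order statistics, R's default; recorded because the hit set is threshold-sensitive |
| `hit_threshold` | 1.0 | IQR units | strict `>` |
| AUC `t_end` / `baseline` | 120 / 100 | min / % | integrating (normalized − 100) makes a non-swelling well score 0 and keeps shrinkage negative; set `baseline = 0` to integrate raw percent instead |
| $\Delta I_{sc}$ `n_points` / `gap` | 5 / 0 | samples | five-point windows immediately adjacent to the addition; the addition sample itself belongs to neither window |
| quench `window` | 5 | samples | the protocol fits a slope at every position of the post-injection trace without fixing a window width; 5 samples is the default and the width is reported with the result |

## What the synthetic generator emulates — and what it does not

`simulate_screen()` is first-class, tested code: it is the only way to give
every downstream stage a known ground truth without the study's unreleased
raw images. Per organoid it draws a baseline area
$\mathcal N(300, 75^2)$ px², a true slope
$\mathcal N(\mu_\text{condition}, 2^2)$ px²/time point, then per frame an
observed area with $\mathcal N(0, 8^2)$ px² observation noise, converts it to
a square box of side $2\sqrt{A/\pi}$ (the exact inverse of the analysis-side
disk assumption), jitters each edge independently
($\sigma = 0.5$ px), and drops each frame's detection independently with
probability 0.05. Plate artifacts act on slopes as
`plate_scale * slope + plate_shift`, emulating the variation in
baseline swelling among assay plates and donors, and plate normalization is
expected to remove them. Random streams are split per (plate, well) from the
master seed, so adding wells or plates never perturbs existing draws.

Chosen once, as plausible assay conditions, and not revisited:

* **15 organoids per well (Poisson).** The assay protocol fixes no per-well count; 10–20
  recognizable organoids per 384-well is typical for Matrigel droplet
  seeding.
* **Noise scales.** Defaults were chosen so that a typical organoid's slope
  SE is about 1–1.5 px²/time point: the 2.5 cutoff then excludes a
  small tail (about 1 % of organoids at the defaults) rather than nothing or
  everything. Note the implied detector precision: box-edge jitter of
  $\sigma_j$ px on a disk of diameter $d$ induces area noise of roughly
  $(\pi/2)\,d\,\sigma_j$ px² per frame, which for $d \approx 20$ px
  dominates the direct area noise. `nominal_well_iqr()` documents this
  arithmetic and is used to express spiked effects in IQR units.
* **Condition effects.** DMSO and inactive compounds drift at +2 px²/time
  point; Eact at +60 (a strong calcium-activated secretion response);
  spiked actives at the inactive effect plus `active_effect_iqr` (default 3)
  nominal well-IQRs. Pooled wells combine their two compounds additively
  relative to the inactive baseline.

Not emulated: organoid morphology and texture (rendered frames are plain
bright rings with darker lumina — enough geometry to exercise detection and
tracking, nothing more), organoid motion, division or fusion, touching
organoids (centers are separated by twice the largest plausible radius by
default, so the noise-free tracking problem is unambiguous; set
`min_separation` smaller to stress the tracker), focus drift, and
edge-of-well optics. Passing tests on this generator therefore validate the
*statistics* of the pipeline — area conversion, linking, regression, QC,
normalization, hit calling — not the upstream computer vision on real
brightfield images, where detector bias and missed/merged organoids are the
dominant error sources.

## Numerical choices and degenerate inputs

* **Quantiles** use type 7 throughout (median and IQR), so "median + 1 IQR
  scores exactly 1.0" holds to machine precision.
* **Assignment ties** are broken deterministically: observations are
  processed in canonical (frame, y, x) order, tracks in (last y, last x)
  order, and track ids are relabelled by (plate, well, first frame, first y,
  first x) — output is invariant to input row order.
* **Unmatched cost.** Leaving a track or observation unmatched costs
  `max_displacement * (memory + 1)`, an upper bound on any admissible
  displacement, so a gated match is always preferred and the total
  displacement is globally minimized per frame pair.
* **Two-point fits** have an undefined residual SE, reported as `Inf`; they
  pass the SE rule never and the frame rule only in acquisitions of three or
  fewer frames.
* **Degenerate plates** (IQR = 0, or fewer than four eligible wells) abort
  single-plate normalization with the plate named; the screen-level wrapper
  drops such plates and reports compounds that thereby lose all wells.
* **Zero-area and negative simulated areas** are floored at `min_area`
  (1 px²) and the clips counted.
* **Otsu on empty frames** always returns *some* threshold; `detect_blobs`
  additionally requires a minimum contrast between the two intensity classes
  (`min_contrast = 0.1` gray levels) before believing any foreground, so a
  noise-only frame yields zero detections.
* **CSV precision.** Stage files store doubles with 17 significant digits,
  so re-running any stage from its input CSV reproduces downstream outputs
  byte-identically.

## Open design points, resolved

* **SE-cutoff units** — applied in area units, configurable (above).
* **Reference set for the plate median/IQR** — compound wells only by
  default, since the hit threshold is defined relative to the compound
  distribution; a flag includes controls.
* **Replicate weighting** — unweighted per-well averaging by default
  (`weighting = "well"`); `"plate"` first averages within plate/donor.
* **Pooled-well attribution** — a pooled well's normalized rate is credited
  fully to both compounds; deconvolution of hit wells carries both compounds
  forward with set semantics. No deconvolution model is attempted, matching
  the carry-both-to-secondary design. A direct consequence, visible in the
  end-to-end tests: the pooled partner of every true active is always called
  a hit too, which bounds the compound-level false-positive rate from below
  at (number of actives)/(number of inactives).
* **Specificity of IQR hit calling.** For symmetric well noise, a single
  plate flags roughly 9 % of inactive wells (median + 1 IQR sits near the
  91st percentile of a normal distribution); exact specificity is a property
  of replicate-averaged compound scores, which is why the end-to-end
  fixtures average 4–6 plates, as the screen averaged replicates and donors.

## Problem sizes used in the shipped tests

The validation suite runs a full 4-plate × 384-well screen (about 23,000
simulated organoids and 285,000 detections) for end-to-end hit recovery,
10,000 tracks for the regression oracle, 500 random instances against the
brute-force matching oracle, and 200 random plates for normalization
equivariance — sizes chosen so each property is measured well inside
sampling error while the whole suite stays comfortably interactive.

## A worked miniature

```{r example, fig.width = 6, fig.height = 4}
lay <- screen_layout("P1", sprintf("C%03d", 1:40), n_dmso = 4, n_eact = 4)
sim <- simulate_screen(lay, sim_config(seed = 1))
fit <- fit_swell(link_tracks(boxes_to_areas(sim$detections)))
fit
scr <- screen_organoids(fit$wells, lay)
summary(scr)
plot(fit, well = "A01")
```

## Known limitations

Real brightfield screens add detector bias (systematically tight or loose
boxes), non-disk organoid shapes, and occasional merged detections — none of
which the disk-area model can see; the per-organoid SE rule catches only the
noisy end of these failures. The tracker assumes near-stationary organoids
and will not follow genuine migration beyond the gate. AUC and trace
analysis assume regularly sampled, time-aligned inputs from upstream
software. Statistical significance testing of compound effects
(ANOVA/t-tests on validated hits) is deliberately out of scope and left to
standard tools.
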