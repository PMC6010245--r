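---
title: "Region-aware collagen morphometry and the SHG B-index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-aware collagen morphometry and the SHG B-index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shgfib)
```

## The problem

In non-alcoholic fatty liver disease (NAFLD), fibrosis severity is graded on
the Brunt scale: stage 0 (none), 1 (perisinusoidal), 2 (periportal),
3 (bridging), 4 (cirrhosis). The stage is defined as much by *where*
collagen sits in the hepatic lobule as by *how much* there is — stages 1 and
2 carry similar collagen loads in different places. Second-harmonic
generation (SHG) microscopy images fibrillar collagen directly in unstained
sections, with a two-photon-excited fluorescence (TPEF) channel supplying
the tissue context. `shgfib` implements an automated staging pipeline on
such two-channel images:

1. **Preprocessing** — speckle suppression, background-offset removal, and
   Otsu segmentation of collagen from the SHG channel.
2. **Region segmentation** — holes in the TPEF channel (vessel lumina, bile
   ducts, steatosis vacuoles, cracks) are detected and classified by a
   decision tree; vessel/duct holes are grouped into structures; a second
   tree separates portal tracts (PT) from central veins (CV); everything
   else is perisinusoidal (PS).
3. **Morphometry** — collagen "strings" (connected components) are
   skeletonized and classified as aggregated/distributed, thick/thin,
   short/long, yielding 100 named features per subject: 28 per region plus
   16 whole-tissue analogues.
4. **Staging model** — sequential forward selection (residual-sum-of-squares
   criterion) picks 14 features; ordinary least squares on them defines the
   SHG B-index, clamped below at 0; leave-one-out cross-validation (LOOCV)
   yields out-of-sample scores.
5. **Diagnostics** — Spearman correlation with stage, AUROC with DeLong
   confidence intervals, Youden-optimal cutoffs, and
   sensitivity/specificity/likelihood-ratio/predictive-value tables for the
   four standard dichotomizations (mild / significant / bridging fibrosis,
   cirrhosis).

No clinical images or fitted clinical coefficients are distributed with
the package; a synthetic generator with pixel-level ground truth makes
every stage of the pipeline testable end to end.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| tile geometry | 512 px = 200 µm | — | native acquisition tile |
| `otsu_levels` | 256 | bins | histogram resolution for thresholding |
| `tissue_frac` | 0.2 | fraction of max TPEF | tissue / background split |
| `min_hole_area_um2` | 5 | µm² | smallest retained hole |
| `density_radius_um` | 100 | µm | neighbour count radius (hole density) |
| `annulus_um` | 15 | µm | surrounding-collagen annulus |
| `link_distance_um` | 50 | µm | single-linkage hole grouping |
| `halo_radius_um` | 25 | µm | region halo around structures |
| `min_string_pixels` | 4 | px | smallest collagen component |
| `thick_ratio` | 0.25 | — | thick iff width/length > 0.25 (strict) |
| `length_cutoff_um` | `NULL` | µm | `NULL` = per-subject median rule |
| `k_max` | 14 | features | B-index model size |

All geometric settings are physical (µm), converted through the pixel size,
so they are resolution-independent. The hole-density definition (count of
neighbouring holes within `density_radius_um`) and the short/long median
rule are package conventions: the quantities they operationalize are named
but not numerically specified in the underlying method, and both are
configurable.

## Numerical choices

* **Otsu** is computed on a 256-bin histogram spanning the observed
  intensity range, with exact per-bin intensity sums (not bin midpoints)
  so the maximizer agrees with a brute-force scan over raw values. Ties in
  the between-class variance break toward the *lowest* threshold, which is
  inclusive of faint collagen; the mask takes pixels strictly above the
  threshold. Adding a constant to an image shifts the threshold and leaves
  the mask unchanged.
* **Noise removal** replaces pixels exceeding their 8-neighbour maximum by
  more than 25% of the dynamic range (isolated salt speckle) and subtracts
  the modal intensity of the below-Otsu class, clipping at zero. Both steps
  are designed to be idempotent: speckle removal cannot fire twice on the
  same pixel when speckles are isolated, and after one subtraction the
  background mode sits exactly at the lower edge of the first histogram
  bin. A median filter was deliberately avoided: it erodes 1-px fiber tips
  and is not idempotent.
* **Skeleton length** sums skeleton adjacencies (1 per orthogonal step,
  √2 per diagonal) and adds one step per skeleton endpoint. Zhang–Suen
  thinning erodes roughly half the ribbon width (≈1 px) from each fiber
  end; the endpoint term compensates, and makes an isolated skeleton pixel
  one pixel long (the floor convention). On a 10 × 2 px bar this recovers
  the analytic 9-step centerline exactly; on 1-px-wide lines it
  overestimates by ≤2 px, which is negligible at realistic string lengths.
* **Width** is area/length (ribbon model), making the thick/thin ratio
  scale-free. **Aggregated** means the skeleton has ≥1 branch point (a
  skeleton pixel with ≥3 skeleton neighbours) — the operational reading of
  "cross-linked". Components smaller than 4 px have no meaningful skeleton
  and are treated as noise.
* **Percentages** count pixels of retained strings, so aggregated% +
  distributed% equals collagen% exactly in every scope; string counts are
  per mm² of scope area; means over an empty string set are 0, with absent
  regions flagged.
* **Clamping** of the B-index applies per prediction (including inside
  LOOCV); there is no upper clamp.
* **Youden cutoffs** scan the observed score values with a strict
  `score > cutoff` positive call; ties in J (within 1e-9) break toward the
  smallest cutoff.
* **DeLong** confidence intervals are used for AUROCs (bootstrap available
  by option); with a single observation in a class the DeLong variance is
  undefined and the bounds are `NA`.

## Design decisions

* **The two CARTs are trained, not transcribed.** The clinical instrument's
  fitted trees are not public. The package trains both trees (Gini
  impurity, depth ≤ 4, ≥ 5 cases per leaf) on a fixed-seed synthetic cohort
  with pixel-level ground truth and ships them as JSON fixtures in
  `inst/extdata` (`tools/make_cart_fixtures.R` regenerates them). This
  reproduces the *method*; it cannot reproduce unpublished parameters. The
  learned trees are anatomically sensible: holes are vessels/ducts when
  ringed by collagen, and a structure is a central vein when it consists of
  a single (larger) hole.
* **Structure linkage uses centroid distance only by default.** Linking
  holes bridged by contiguous collagen is available (`link_by_collagen`),
  but off: in bridging fibrosis the septa *are* contiguous collagen
  connecting portal tracts to central veins, and collagen linkage would
  merge exactly the structures the classifier must keep apart.
* **Selection is performed once on the full table** before LOOCV (the
  model-development reading), with `reselect_per_fold = TRUE` exposing the
  stricter leakage-free variant. Exhaustive leave-one-out iteration is
  used; every subject is held out exactly once.
* **Features are z-scored for selection** (greedy ordering is then
  scale-free); coefficients are reported on the original scale.
* **Stopping rule** is fixed k = 14 by default; an RSS-improvement
  tolerance is available via `tol`.

## The synthetic generator

`generate_tile()` renders a 512 × 512 two-channel tile whose geometry
follows the Brunt progression: stage 0 has collagen only in vessel walls;
stage 1 adds short thin distributed strings in PS; stage 2 adds branched
periportal collagen; stage 3 adds long branched strings bridging
structures; stage 4 adds septa enclosing nodules. Central veins are single
larger lumina with collagen rims; portal tracts are a vessel plus 1–2 rimmed
bile ducts; steatosis vacuoles are rimless circles kept clear of
perisinusoidal strings (lipid droplets displace sinusoidal collagen);
cracks are elongated low-solidity polylines. Channels get additive Gaussian
noise plus isolated salt speckle on SHG; the background offset scales with
`noise_sd` so a noise-free tile has an exactly-zero background. Each string
has a single SHG brightness so speckle suppression never fires on genuine
collagen. Structures sit on a jittered 2 × 2 grid, keeping inter-structure
hole distances above the 50 µm linkage default.

Aggregation labels in the ground truth are derived from the emitted
geometry (a drawn string is labelled aggregated iff its emitted pixels
skeletonize with a branch point), so ground truth and morphometric
definition cannot drift apart.

What the generator does **not** emulate: real SHG optics (no point-spread
function, depth effects, or polarization), irregular biopsy boundaries,
fragmented cores, inflammation, true collagen texture, or inter-patient
variability in structure counts. Passing tests therefore demonstrate that
the pipeline correctly implements its stated geometry and statistics — not
that it would reach any particular accuracy on clinical slides.

`generate_feature_table()` is the fast cohort-level counterpart: stages are
drawn from the reference NAFLD distribution
(22.9/30.1/8.4/16.9/21.7% for stages 0–4), 14 informative columns carry a
linear stage signal with unit between-subject spread, and one informative
column closes the identity `stage = intercept + X β + ε`, with
`ε ~ N(0, noise_sd²)`. A pure "function of stage plus noise" design would
be rank-deficient at zero noise (five stage levels cannot support 14
coefficients), so between-subject spread is always present and `noise_sd`
controls only the measurement noise: at `noise_sd = 0` ordinary least
squares recovers the generating coefficients to machine precision. The
default `noise_sd = 0.5` gives realistic stage overlap (adjacent stages are
hard to separate, distant ones easy); parameter-recovery experiments use
`noise_sd = 0.05`, the small-noise regime in which greedy selection can be
expected to find the informative set against 86 nuisance columns.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
desk scale, chosen as the smallest sizes that exercise every code path:
a shared 10-subject image cohort (two subjects per stage, one tile each)
for region accuracy and B-index monotonicity; 83-subject feature tables
(the reference cohort size) for selection, LOOCV and diagnostics; 100
random instances per statistical-primitive oracle; the bundled trees are
trained on 60 tiles. The complete suite runs in under two minutes on one
CPU.

## Known limitations

* Synthetic effect sizes are free parameters of the generator; per-stage
  collagen quantities are not calibrated to any cohort, so absolute
  feature values and fitted coefficients are not comparable to clinical
  ones.
* The AUROCs, cutoffs and correlation printed by `staging_report()` on
  synthetic cohorts characterize the synthetic signal-to-noise setting
  only.
* Greedy forward selection is order-unstable under strong collinearity;
  with many nuisance columns and very low signal it can admit a few
  nuisance features before the weakest informative ones.
* The hole-density feature and the short/long median rule are package
  conventions (flagged above), and the PS-distributed string-length
  feature is registered under its historical name `StrLengthSFD`.
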