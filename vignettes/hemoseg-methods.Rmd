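---
title: "Methods: rule-based hemorrhage segmentation for pelvic CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based hemorrhage segmentation for pelvic CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemoseg)
```

## The problem and the model

Active hemorrhage on contrast-enhanced pelvic CT has no characteristic
gray level: it is brightest near its center, fades into soft tissue at
its rim, and its absolute grays shift with the contrast phase (arterial
scans show it at near-artery brightness; veinal scans much closer to
tissue). Bone and arteries occupy overlapping or brighter gray ranges in
the same field of view. `hemoseg` therefore never segments with a single
global threshold; it composes five stages, each with a narrow, testable
contract.

**Masking convention.** Gray 0 is reserved for background. Bone and
artery pixels are removed by setting them to 0, which simultaneously
takes them out of every later histogram, census, and window statistic.
A consequence worth knowing: the grower and the rules never recruit a
gray-0 pixel, so masked anatomy can never re-enter the region.

**Detection.** After artifact removal (largest 8-connected non-zero
component) and bone masking (threshold, closing, small-component
filtering), pixels whose gray lies in the artery range form the seed
`C_d`. The premise is anatomical: extravasated, contrast-carrying blood
is at artery-like gray levels. The seed is deliberately allowed to be
incomplete — the faded rim is usually below the artery range — because
the later stages only need its gray statistics and location.

**Matching.** A `q`×`q` region of interest around the seed centroid
bounds the search. For every candidate minimum gray in the seed's
observed range, the candidate region (threshold, then small-component
removal and closing) is scored by mutual information against the seed,
both rendered as binary membership images over the ROI. MI is maximal
when the candidate reproduces the seed's support as closely as a
threshold can, so the argmax `G_opt` is the gray level that best
explains the detection — typically at or just below the seed's minimum.

**Rule stage.** The boundary of `B_opt` is where the decision is hard.
Each boundary pixel's `m`×`m` window is classified by how many of its
pixels clear `G_opt`, and the per-case linear rules decide which window
pixels join. The rules' features are cheap and local: the pixel gray,
its Euclidean distance to the hemorrhage foci (the region's
maximum-gray pixel), the gray difference to the window center, and the
central-difference gradient magnitude. Their weights are re-learned for
every image by a linear soft-margin SVM, because absolute grays and
contrasts vary image to image.

**Region growing.** A conservative mop-up: only windows already
dominated by the region (more than `eta` percent membership) may
recruit, and only pixels at or above the window's own
mean-plus-standard-deviation threshold join. On a smoothly fading rim
this adds little — by design; its job is bright pixels the rule pass
missed, not extending the fade. Termination is structural: the area is
bounded and strictly increases in any epoch that continues.

**Evaluation.** The missegmented area |K|/|A1|·100 (K the symmetric
difference with ground truth) penalizes over- and under-segmentation
symmetrically in pixels but normalizes by the truth area, so it can
exceed 100% for gross oversegmentation. Bands: good below 10%,
acceptable from 10% to 20% inclusive (the boundary assignment is a
package choice, configurable), unacceptable above.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `roi_size` (q) | 100 | px | Large enough to hold a whole bleed on a 512-px slice, small enough to exclude unrelated tissue. |
| `rule_m`, `grow m` | 3 | px | A 9-pixel window makes the majority census unambiguous; odd so a center exists. Must stay below `q`. |
| `eta` | 50 | % | Below 50 the grower recruits from windows it does not dominate (oversegmentation risk); far above it, it never recruits. |
| `penalty_grid` | 0.1, 0.01, 0.001 | – | Soft-margin penalties tried per image; ties resolve to the larger C (fewer training misclassifications). |
| `band_width` | 2 | px | Sampling bands hug the boundary, where the gray statistics of the two classes actually meet. |
| `cap` | 100 | px/class | Bounds the per-image training set; bands are balanced by construction. |
| `bone_threshold` | 232 | gray | Above artery/hemorrhage peaks at 8-bit depth; configurable because bit depth is a property of the input. |
| `min_object_area` | 20 | px | Small bright specks (noise, residual bone) are unwanted objects. |
| `good_max`, `acceptable_max` | 10, 20 | % | Clinical banding boundaries. |

Gray-level constants are configuration, not constants, because the
working bit depth of the input is not fixed; `ct_slice` carries
`gray_depth` (255 default, 4095 for 12-bit data).

## The SVM, exactly

The dual maximized is `sum(a) - 0.5 aᵀHa` with `H = (y yᵀ) ∘ (X Xᵀ)`,
under `yᵀa = 0`, `0 ≤ a ≤ C`. The solver is pairwise coordinate ascent
on the maximal KKT-violating pair, which keeps the equality constraint
exact at every step; it stops when the violating-pair gap falls below
1e-6 (or 1e5 iterations, never reached at these sizes). `w0` is the
support-vector sum; `b0` averages `y - xᵀw0` over free support vectors,
falling back to the midpoint between the innermost decision values of
the two classes (flagged) when no free support vector exists. A zero
decision value classifies as +1.

Features are standardized (zero mean, unit variance) before solving —
raw grays near 150 against distances near 5 would otherwise dominate the
margin geometry — and the hyperplane is mapped back to raw-feature space
afterwards, so the published rule inequalities apply to raw pixel
values.

One training-time subtlety: the gray-variation feature is defined at
application time relative to a rule window's center. Training pixels
have no window, so the package uses the nearest boundary pixel as the
reference — the training-time analog of the window center, which at
application time is itself a boundary pixel.

In the test suite the solver is checked against an exact brute-force
quadratic program (KKT active-set enumeration over all 3^n
configurations, n ≤ 8); the dual objectives agree to 1e-6 on every
random instance tried.

## The phantom generator

The generator emulates exactly the image properties the method relies
on: a mid-gray soft-tissue ellipse (mean 100, Gaussian noise sd 5),
high-gray bone blobs (235–250), small bright artery dots, and a
hemorrhage blob whose noiseless profile is
`peak * exp(-decay (r/radius)^2)` painted over tissue (peak 220, radius
10 px, decay 0.35 — edge gray ≈ 155), radially monotone before noise.
The truth masks are the exact painted supports.

Two generator choices deserve their rationale on record:

* The artery gray range (160–230) *brackets* the hemorrhage range from
  just below its faded edge to its peak. That is the method's working
  premise — arteries and active bleeding carry similar contrast-enhanced
  grays — and it is what makes the artery range a usable search range
  for the bleed.
* Artery dots are painted with a bright lumen center fading linearly to
  the range minimum at the dot edge (a partial-volume fade), rather than
  i.i.d. random grays. Real vessel cross-sections fade at their rim, and
  it makes the estimated artery range a stable quantity instead of an
  extreme-value statistic of a few dozen random draws.

The veinal phase multiplies blob-minus-tissue contrast by 0.45,
reproducing the qualitative loss of conspicuity after tissue uptake; a
strongly faded veinal blob is, by brute-force sweep, not separable by any
global threshold — the regime the multi-stage design exists for.

What the phantom does **not** emulate: anatomy (no real pelvis shapes,
no fracture lines), partial-volume mixtures along bone, streak or beam-
hardening artifacts, multiple confluent bleeds, and the inter-patient
variability of real contrast timing. Passing the phantom battery
demonstrates the pipeline's mechanics — seed recovery, threshold
selection, boundary learning, termination — not clinical performance.

## Numerical choices and degenerate inputs

* **MI ties** resolve to the lowest candidate gray: boundary pixels can
  sit below the optimum, so the inclusive side is the safe side.
* **Foci ties** (equal maximum gray) resolve to the first pixel in
  row-major order.
* **ROI clipping** keeps the window inside the image rather than
  padding; windows at image edges census only their present pixels.
* **Degenerate seed range** (`g_min == g_max`) short-circuits matching
  to the thresholded ROI at that single level.
* **All-background windows** in the grower are skipped via an NA
  sentinel from `window_threshold`.
* **Empty regions** error loudly everywhere (`extract_boundary`,
  `locate_foci`, `grow_region`, `missegmented_area` with empty truth);
  failed detection is not an error but an explicit no-hemorrhage result
  that short-circuits the pipeline into a no-hemorrhage report.
* **Connectivity**: 4-neighborhood defines boundaries, 8-neighborhood
  defines components. Coordinates are 1-based (row, col), R's native
  indexing.
* **Rule windows are placed once** on the boundary of `B_opt`; growth
  continuation is the grower's job, not a re-placement loop.
* The **dominance precondition** of the grower counts pixels already in
  the region (default); counting in-range pixels instead is available as
  `grow_config(dominance = "in_range")`.

## Problem sizes in the test suite

The packaged tests run the full pipeline on 160×160 phantoms (50-seed
battery in the acceptance tests, smaller 96×96 phantoms in unit tests)
with the default ROI of 100 px; a battery run takes well under a minute
on one core. These sizes were chosen so the suite exercises every stage
at realistic structure scales while staying fast enough to run on every
change.

## Known limitations

* Single-slice operation: no cross-slice continuity, no 3-D masks.
* Artery information must be supplied (mask or gray range); the package
  does not localize arteries itself.
* Bone segmentation is threshold-plus-morphology; heavily osteopenic or
  contrast-flooded cases may need a tuned threshold.
* One hemorrhage region per run; multiple seeds should be run
  independently.
* DICOM files are not read directly; convert to PNG/TIFF (or pass pixel
  matrices) first.
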