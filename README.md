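# hemoseg

Rule-based segmentation of active hemorrhage in 2-D pelvic trauma CT
slices.

Pelvic fractures bleed, and the bleeding — not the fracture — is what
kills within the first 24 hours. On contrast-enhanced CT, extravasated
blood shows up at roughly the gray levels of the enhanced arteries, is
brightest at its center, and fades into soft tissue at its edges, so no
single global threshold delineates it. `hemoseg` implements a multi-stage
pipeline that segments such a hemorrhage from one grayscale slice, given
the locations of the arteries (or a configured artery gray range):

1. **Detection.** Scanner artifacts are removed (largest connected
   component), bone is thresholded and masked to gray 0, arteries are
   masked to gray 0, and the remaining pixels whose gray level falls in
   the artery range form the detected seed *C_d* with centroid and
   observed gray range [*G_min*, *G_max*].
2. **Matching (MIM).** Inside a *q*×*q* region of interest around the
   seed centroid, every candidate minimum gray level
   *G_mi* ∈ [*G_min*, *G_max*] defines a candidate region
   *B_i* = {pixels with gray ∈ [*G_mi*, *G_max*]} (morphologically
   cleaned). The mutual information
   MI(*C_d*, *B_i*) = H(*C_d*) + H(*B_i*) − H(*C_d*, *B_i*)
   is maximized over the sweep; the argmax is the optimum minimum
   hemorrhage gray *G_opt* with region *B_opt*.
3. **Rule optimization.** Around every boundary pixel of *B_opt* an
   *m*×*m* window is classified by its census against *G_opt*: all pixels
   ≥ *G_opt* (Case 1: every in-range pixel joins the region), a majority
   ≥ *G_opt* (Case 2: a pixel joins when
   *w₁·gray + w₂·D + b > 0*, with *D* the distance to the hemorrhage
   foci), or a majority below (Case 3:
   *w₃·gray + w₄·D + w₅·V + w₆·|∇f| + b₁ > 0*, adding the gray-variation
   and gradient-magnitude features). The weights are optimized **per
   image** by a from-scratch soft-margin linear SVM solved in the dual
   (pairwise coordinate ascent under 0 ≤ α ≤ C, yᵀα = 0), trained on
   pixel bands just inside (hemorrhage) and outside (soft tissue) the
   boundary, with C picked from {0.1, 0.01, 0.001} by stratified 10-fold
   cross-validation.
4. **Region growing.** Boundary windows already dominated by the region
   (> η percent membership) may recruit: outside pixels at or above the
   local threshold *t₁ = me₁ + std₁* (moments of the window's
   non-background grays) join. Epochs repeat while the growth rate
   (*E_c* − *E_p*)/*E_c* × 100 is positive.
5. **Evaluation.** Against a ground-truth mask *A₁*, the missegmented
   area is |K|/|A₁| × 100 with K the symmetric difference of truth and
   segmentation, banded as good (< 10%), acceptable (10–20%), or
   unacceptable (> 20%).

Because clinical trauma CTs cannot ship with a package, `hemoseg`
includes a deterministic synthetic **phantom generator** — a soft-tissue
ellipse, bone blobs, bright artery dots, and a hemorrhage blob whose gray
fades radially from its peak — with exact ground-truth masks, so the
whole pipeline is testable end to end.

## Worked example

```r
library(hemoseg)

spec <- phantom_spec(seed = 42)            # default arterial-phase phantom
cfg  <- pipeline_config(seed = 42)
rep  <- run_phantom_pipeline(spec, cfg)
print(rep)
#> <segmentation_report 'phantom-42': G_opt 158, final area 315>
#>   missegmented area 0.00% -> good
str(rep$stage_areas)
#> $ seed                    : int 296
#> $ b_opt                   : int 303
#> $ post_rules              : int 315
#> $ final                   : int 315
#> $ growth_mim_to_rules_pct : num 3.81
#> $ growth_rules_to_grow_pct: num 0
```

The detection stage finds a 296-px seed; MIM settles on *G_opt* = 158 and
a 303-px *B_opt*; the SVM-optimized rules add the faded boundary fringe
(3.81% of the post-rule area); region growing finds nothing further to
add (one epoch, growth rate 0); the final 315-px region matches the
315-px ground truth exactly, so the missegmented area is 0% — a "good"
segmentation.

The same stages are exposed individually (`detect_hemorrhage`,
`mim_search`, `optimize_rule_weights`, `apply_rules`, `grow_region`,
`evaluate_segmentation`) for use on real slices read with `read_slice()`
(PNG/TIFF) plus an artery mask from `read_mask_png()`.

## Command line

A thin wrapper script is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "hemoseg.R", package = "hemoseg"))')
Rscript $CLI phantom --seed 42 --out ph
Rscript $CLI run --image ph/slice.png --artery-mask ph/truth_artery.png \
        --truth ph/truth_hemorrhage.png --out run42
Rscript $CLI evaluate --truth ph/truth_hemorrhage.png \
        --segmented run42/mask_final.png
```

Subcommands: `phantom`, `detect`, `segment`, `run`, `evaluate`, `batch`.
Each run echoes its effective YAML configuration and writes per-stage
masks (PNG + run-length JSON), the MI sweep curve (CSV), the optimized
rule weights, the epoch trace, and a JSON report.

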