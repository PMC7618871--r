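---
title: "Few-shot subcortical segmentation in 3D fetal ultrasound: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Few-shot subcortical segmentation in 3D fetal ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalsubcort)
```

## The problem

During the second trimester, four subcortical structures are routinely
assessed in fetal brain ultrasound: the choroid plexus (CP), the lateral
posterior ventricle horns (LPVH), the cavum septum pellucidum et vergae
(CSPV) and the cerebellum (CB). Voxel-wise manual annotation of 3D
ultrasound is slow and noisy — speckle, acoustic shadowing of the hemisphere
proximal to the transducer, and ill-defined soft-tissue boundaries make even
expert annotations variable — so large labelled training sets do not exist.
This package implements a few-shot pipeline around that constraint:

1. train a multi-label 3D U-Net from a handful (`n_a` around 9) of expertly
   annotated volumes (*expert labels*), or
2. annotate per-gestational-week *templates* built by groupwise registration
   and propagate those annotations to many unlabelled volumes through the
   inverse deformation fields (*atlas labels* — many, but weak), and compare
   the two regimes;
3. post-process and evaluate predictions (Dice, 95th-percentile Hausdorff
   distance, relative volume differences);
4. turn predicted labelmaps from an analysis cohort into volumetric growth
   curves with significance-gated quadratic terms and 95% prediction
   intervals.

All stages run end-to-end on synthetic ultrasound phantoms, so the package
needs no clinical data.

## The phantom generator

`make_phantom()` builds a 3D scene from ellipsoids: a brain ellipsoid
(semi-axis ratios 0.95 : 1.25 : 0.85) containing the four structures at
fixed anatomical offsets — CB posterior-inferior at the midline, CSPV at the
midline, CP and LPVH lateral in one hemisphere. Structure sizes follow
gestational-age (GA) growth laws:

* LPVH: linear, 0.1 cm³ at 18 weeks to 0.3 cm³ at 26 weeks;
* CSPV: linear, 0.01 cm³ to 0.6 cm³;
* CP: brain-relative, a very small absolute increase that corresponds to a
  *relative* decline from about 12% of brain volume at 18 weeks to about 3%
  at 27 weeks;
* CB: brain-relative quadratic, holding 1.5–2.5% of brain volume;
* reference whole-brain volume: quadratic, 30 cm³ at 18 weeks to 120 cm³ at
  26 weeks (consistent with fetal imaging literature; only CP and CB scale
  with it).

Rather than rasterising an analytic ellipsoid and hoping the voxel count
matches, the generator solves for the ellipsoid level set whose *clipped,
voxelized* region (inside the brain, inside the visible hemisphere for
CP/LPVH, excluding previously placed structures) matches the law volume via
an order statistic of the quadratic form — the realised label volume is
exact to half a voxel at any grid size or pose.

Image corruptions emulate ultrasound physics qualitatively, not a beam
simulation: a Gaussian point-spread blur (`psf_sigma_vox`, default 0.8
voxels), unit-mean multiplicative gamma speckle (`speckle_sd`, default
0.25), and a smooth logistic attenuation ramp (`shadow_strength`, default
0.5 over a 6 mm width) that darkens the hemisphere proximal to the virtual
transducer. The CP/LPVH intensity pattern is painted in *both* hemispheres
(the anatomy is bilateral) while labels exist only in the visible
hemisphere, matching the annotation convention for real scans; with
`mirror_structures = FALSE`, `speckle_sd = 0`, `shadow_strength = 0` and
`psf_sigma_vox = 0` the image is piecewise constant with level sets equal to
the label regions, which the tests exploit.

Poses are random rigid transforms (rotations up to ±10°, translations up to
±3 mm by default); "aligned" data are produced by resampling through the
inverse pose, as rigid manual alignment would.

**Scale.** The acquisition-scale grid is 160³ at 0.6 mm. The desk-scale
default is 64³ at 1.2 mm (a 76.8 mm field of view), in which a
literature-sized brain at 26 weeks does not fit with rotation margin; the
generator therefore applies a volume factor `brain_scale` (desk default
0.5) to the brain and to the brain-relative structures, while the absolute
LPVH/CSPV laws are untouched. Network training experiments use 48³ at
1.2 mm with `brain_scale = 0.35` for the same reason. These factors are part
of the phantom's study conditions, fixed once here.

What the phantom does *not* emulate: reverberation and refraction artifacts,
skull calcification, anatomical shape detail beyond ellipsoids, or
pathological anatomy. Passing tests on phantoms demonstrates that the
pipeline's machinery is correct and that its comparative findings
(expert-vs-atlas, clustered-vs-single templates) can be reproduced on data
with known truth — not that the trained weights transfer to clinical scans.

## Templates and weak atlas labels

`groupwise_template()` iterates: register every member to the current
voxelwise-mean template with diffeomorphic demons, deform, re-average. The
demons implementation is a classic multi-resolution compositive scheme
(3-level pyramid; fluid-like Gaussian smoothing of each update, diffusion-like
smoothing of the total field, both sigma 1 voxel; per-level iteration caps
30/20/8 with early stop when SSD stops improving). Inverse displacement
fields come from fixed-point inversion (20 iterations); the inversion
residual is checked against 0.1 voxel and warned about beyond 1% of checked
voxels.

Per-week templates use 1-week GA bins (ties at x.5 round down) and are built
separately per visible hemisphere, then fused at the central sagittal
lattice plane (the phantom is constructed symmetric about it). If a bin has
members of only one hemisphere, the missing side is obtained by mirroring —
acceptable for a bilaterally symmetric phantom. Template annotation, a
manual step on real data, is emulated by consensus: each member's
ground-truth labelmap is forward-warped into template space and the
per-voxel majority class is taken. Propagated (weak) atlas labels then come
from nearest-neighbour resampling of template labels through each member's
inverse field, with CP/LPVH restricted to the member's visible hemisphere to
match the ground-truth convention.

## Cluster-based LPVH templates

A single template per week under-represents LPVH shape variability (the
phantom plants 2–4 discrete LPVH shape modes so there is structure to
recover). For each two-week window ({18–19, 20–21, 22–23, 24–25, 26}),
volumes are mirrored to a common hemisphere, cropped around the LPVH with
one fixed bounding box per window, histogram-equalized to [0, 1], pairwise
registered, and summarised by an SSD matrix over a dilated LPVH region of
interest. The directed SSD matrix is symmetrized as `(D + t(D))/2` — the
directed values differ only by registration asymmetry. K-medoids (PAM-style
best-improvement swaps from random medoid initialisations; restart `r` uses
seed `seed + r`; restarts with any cluster below `min_size` discarded; cost
ties broken by the lexicographically smallest medoid set) groups the crops;
outliers — flagged beforehand when their median distance exceeds the cohort
mean by 2 standard deviations, a reproducible stand-in for visual exclusion
— are assigned to their nearest medoid afterwards, and per-cluster templates
are built including them. At full scale the defaults are `k = 4`, 500
restarts and `min_size = 3`; phantom-scale cohorts use `k = 2` (matching the
planted modes) and proportionally smaller restart counts.

## The segmentation network

A standard 3D U-Net: per level two (3×3×3 convolution → batch normalisation
→ ReLU) blocks, 2× max pooling, nearest-neighbour upsampling followed by a
channel-halving convolution, skip concatenation, channel doubling per level,
and a 1×1×1 linear head with a softmax across the five channels (background
+ four structures). The full-scale configuration is depth 5 with 16 initial
feature maps; desk-scale experiments use depth 3 with 8 features at 48³.
The implementation (forward, loss and backpropagation) is single-precision
and built on blocked im2col convolutions in compiled code; a pure-R
double-precision reference implementation of the same network is kept and
the test suite checks the two agree, alongside finite-difference gradient
checks.

**Loss.** `L_total = L_MD + lambda * L_CE` with `lambda = 1`. `L_MD` is one
minus the mean over the four *foreground* classes of the smoothed soft Dice
`(2 sum(p t) + eps) / (sum(p) + sum(t) + eps)`, `eps = 1e-5`; background is
excluded because the Dice term exists to counter the extreme class
imbalance. `L_CE` is the voxel-mean cross-entropy over all five classes.
(Whether a sum or squared denominator is used in the Dice, and plain or
smoothed CE targets, are exposed as options `dice_squared` / `label_smooth`;
the defaults are the plain forms.)

**Training.** ADAM, batch size 4 (desk scale: 2), a fixed iteration budget
(default `100 * ceiling(n_train / batch_size)`, i.e. the equivalent of 100
epochs over the full atlas-labelled set, so expert and atlas modes receive
identical optimization effort), last-iteration weights as the deliverable,
10% validation split recorded in atlas mode and none in expert mode. The
head bias is initialized to the log class priors of the training labels, so
early iterations refine boundaries instead of re-learning that 99% of voxels
are background. The full-scale learning rate is 0.001; desk-scale runs use
0.01 because their budget (200 iterations) is roughly 25× smaller than the
full-scale schedule and ADAM's parameter drift scales with the learning
rate × step count. Augmentation per sample: midline flip (p = 0.5),
rotations up to ±30° per axis, translations up to ±10 voxels (±6 at 48³,
where ±10 would push the brain against the field-of-view edge), and
isotropic scaling within the GA-dependent range
`s_min(w) = max((0.9 V(18)/V(w))^(1/3), 1/1.5)`,
`s_max(w) = min((1.1 V(26)/V(w))^(1/3), 1.5)`, which confines scaling to
brain sizes that exist between 18 and 26 weeks. Identical geometric
transforms are applied to image (trilinear) and labels (nearest neighbour).

**Prediction.** Per-voxel argmax of the softmax; exact ties resolve to the
lowest class index. Post-processing keeps the largest connected component
per class (26-connectivity), which removes the small spurious predictions in
the occluded hemisphere that the bilateral anatomy invites.

## Evaluation metrics

* Dice: `2|A n B| / (|A| + |B|)`; two empty masks score 1 — a convention,
  logged here: absence agreeing with absence is not an error.
* H95: boundary voxels are foreground voxels with at least one background
  neighbour under the chosen connectivity (grid edge counts as background);
  directed distances between boundary voxel centres in mm; the 95th
  percentile is linear-interpolated; the reported value is the max of the
  two directed percentiles. An empty mask makes the comparison undefined
  (`NA` with a warning), never 0.
* Signed/unsigned relative volume difference: `(V_pred - V_gt)/V_gt`;
  positive signed values mean over-segmentation.

Brute-force oracles (set arithmetic; all-pairs boundary distances) back
these implementations in the tests.

## Growth curves

Structure volumes are voxel counts of the post-processed predicted class
times the voxel volume. Whole-brain volume is obtained by registering a
binary whole-brain template mask to the image with an affine transform
(rigid + isotropic scale, Nelder-Mead on a subsampled grid over translation,
rotation and log-scale, initialized from intensity moments, with an
error if the cost does not improve); template masks are selected by rounded
gestational week with a configurable floor week for ages below the template
range. Relative volume is the ratio of the two.

Per structure and per response (absolute and relative), `fit_growth_curve()`
fits OLS polynomials in GA per model tag (`expert` / `atlas`). The quadratic
term is kept only when its two-sided t-test is significant at `alpha = 0.05`
for *every* tag — the anatomy does not depend on which network measured it.
Each fit is gated independently for the absolute and relative response.
Degenerate zero-residual fits report the quadratic as non-significant. 95%
prediction intervals are the standard OLS prediction intervals.

## Numerical choices and degenerate inputs

* Demons keeps the best-SSD field and stops when SSD increases; identical
  images produce exactly zero fields.
* Field inversion tolerance 0.1 voxel, warning cap 1% of mask voxels.
* Histogram equalization is rank-based; a constant image maps to a single
  level.
* K-medoids cost ties break to the lexicographically smallest medoid set;
  nearest-medoid assignment ties break to the lowest medoid index.
* Largest-component size ties break to the component containing the
  lexicographically smallest voxel coordinate.
* `structure_volume()` of an absent class is 0 with a warning;
  `hausdorff95()` of an empty mask is `NA` with a warning;
  `volume_differences()` with empty ground truth is an error.

## Problem sizes used by the tests and the acceptance script

Unit tests run on 24³–32³ phantoms. The weak-label fidelity study uses a
20-phantom cohort at the desk default 64³/1.2 mm; scaled-down training uses
16 phantoms at 48³/1.2 mm (`brain_scale` 0.35), depth-3/8-feature networks,
200 iterations, batch 2; the overfit check uses 2 phantoms at 32³ for 500
iterations (its loss-reduction milestone is read from the training log at
iteration 300); the expert-vs-atlas comparison uses depth-2/8-feature
networks at 32³ over three seeds. These sizes are the package's desk-scale study
conditions: large enough for every qualitative contrast to be measurable,
small enough to re-run routinely.

## Known limitations

* The phantom's ellipsoid anatomy makes segmentation easier than clinical
  ultrasound; absolute Dice values here exceed what the same pipeline
  achieves on real scans and should be read only comparatively.
* The demons implementation targets the stated contracts (monotone SSD,
  invertibility) rather than maximal registration accuracy.
* Hemisphere fusion assumes the midsagittal plane is the central lattice
  plane after rigid alignment — true for the phantom, approximate for real
  data.
* Single-precision training is deterministic for a fixed seed on a given
  BLAS, but loss trajectories may differ in the last digits across BLAS
  builds.
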