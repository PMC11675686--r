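---
title: "Latent-space scoring of false-lumen thrombosis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-space scoring of false-lumen thrombosis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

After a Frozen Elephant Trunk (FET) operation for aortic dissection, the
false lumen (FL) — the pathological blood channel inside the dissected aortic
wall — should thrombose: a fully clotted FL indicates favorable aortic
remodeling, while a patent or partially thrombosed FL signals ongoing risk.
Follow-up CT angiography (CTA) is read slice by slice by clinicians, which is
slow and observer-dependent. `fltvae` implements an unsupervised alternative:
cross-sections perpendicular to the aortic centerline are embedded by a
variational autoencoder (VAE) into a 2D latent space, the latent space is
split into a thrombus and a no-thrombus subspace, and every slice receives a
thrombus score

    ts = (x - x0) / (xmin - x0)   for x inside the thrombus subspace,
    ts = 0                        otherwise,

where `x` is the slice's latent coordinate on the partition axis, `x0` the
subspace boundary, and `xmin` the extreme latent coordinate of the reference
cohort on the thrombus side (so `ts` ramps linearly from 0 at the boundary to
1 at the most thrombus-like slice). A subject's dataset score is the
arithmetic mean of its per-slice scores. No patient data ship with the
package; a phantom generator provides ground-truth-labelled synthetic
cohorts so every stage is testable.

## Pipeline

```{r}
library(fltvae)
cfg <- default_run_config()
cfg$output_dir <- tempfile("fltvae")
manifest <- run_pipeline(cfg)  # simulate, reslice, train, score, report
```

The five stages are independently re-runnable from their on-disk artifacts
(NIfTI volumes and image stacks, plain-text centerlines, CSV manifests and
score tables, an RDS model checkpoint, a JSON partition record). A single
config seed fans out to per-stage seeds through a stage-name hash, so adding
or removing a stage never silently changes another stage's random draws;
rerunning an identical config reproduces the score CSVs bit for bit.

## The phantom generator

Each synthetic cross-section is built from two disk sectors separated by a
straight septum stripe: the true lumen (TL) is the half-disk on one side, the
false lumen the half-disk on the other, and thrombus fills an angular
fraction of the FL sector, sweeping from the bottom. The thrombus cut is
placed at the empirical angular quantile of the FL pixels, so the pixel-count
fraction matches the requested fraction to within one pixel of the analytic
sector area — this keeps the generator closed-form checkable. Intensities
emulate windowed CTA: one per-slice uniform draw per tissue class (patent
lumen high, thrombus mid, background mid-low), additive Gaussian pixel noise,
then clamping to [0, 1]. Four slice labels mirror the clinical FL categories:
`NO_FL`, `PATENT_FL`, `PARTIAL_FL`, `THROMBOSED_FL`.

Default parameter choices, and why:

* **Radii** (`tl_radius_mm` 8–14, `fl_radius_mm` 6–12): adult aortic
  dimensions; dissected slices draw from the upper half of each range and
  non-dissected from the lower half, reproducing the clinical observation
  that dissected aortas are systematically wider — the aorta is wide *where
  the false lumen adds width*, so a no-FL cross-section is normal-caliber
  patent aorta even in a dissected subject. Within a volume, radii follow a
  smooth per-slice caliber profile inside the allowed subrange (a random
  low-frequency sinusoid; a degenerate range gives an exactly constant
  radius): real aortic caliber varies along the vessel, and without that
  variation a small cohort would contain only a handful of distinct
  geometries, letting the VAE encode subject identity instead of appearance
  class.
* **`thrombus_fraction`** (default 0.9–1.0) applies to thrombus-bearing
  labels: `THROMBOSED_FL` draws from it directly, `PARTIAL_FL` draws from it
  and clamps into [0.05, 0.95] so a partial slice is never empty or full.
* **Intensities** (lumen 0.85–0.95, thrombus 0.35–0.50, background
  0.15–0.30, noise sd 0.03): the generator works on the window-normalized
  [0, 1] scale the VAE consumes. No HU calibration is implied — contrast
  protocols vary — only the ordering "lumen hyperintense, thrombus
  isointense, above background" is required, and it is validated at spec
  construction.
* **Volumes**: a tube whose centerline bends sinusoidally along one axis
  (amplitude `curvature_amplitude_mm`, one period over the tube length).
  The sinusoid has closed-form tangents, which the frame tests exploit. The
  ground-truth centerline runs through the TL half-disk centroid, so it
  always lies inside the patent lumen.
* **Study size**: six subjects of 200 slices (three dissected with contiguous
  no-FL / thrombosed / partial / patent segments, three all-`NO_FL`
  controls), about 1200 training images. This matches the scale of a small
  clinical cohort (a few hundred slices per subject) while keeping a full
  training run in the minutes range on one CPU core.

What the phantoms deliberately do **not** model: CT physics (beam hardening,
contrast kinetics, partial-volume blur), branch vessels, stent-graft
artifacts, motion, or anatomically irregular lumen shapes. Passing the
synthetic study therefore demonstrates that the implementation is correct and
that the method behaves as described on idealized data — it says nothing
about clinical performance on real CTA.

## Reslicing

The centerline is resampled at uniform arc-length steps (default 1 mm) along
the piecewise-linear input path, endpoints preserved. Perpendicular frames
use discrete rotation-minimizing transport (the double-reflection
construction) rather than Frenet frames, whose normals flip at inflection
points and would spin the cross-sections. Tangents come from central
differences, one-sided at the ends. Cross-sections are sampled by trilinear
interpolation on the plane spanned by the two frame normals (64×64 grid,
configurable field of view, default 44.8 mm so the default in-plane spacing
is 0.7 mm/pixel); samples outside the volume fill with 0, the
post-normalization background value.

Conventions that had to be fixed (the method description leaves them open):
pixel coordinates are 0-based with pixel-center semantics, the grid center is
((n−1)/2, (n−1)/2), and world coordinates are in mm with voxel centers at
(index − 1) × spacing. Segmentation masking and auto-centering are one
operation: pixels outside the mask are zeroed, then the image is translated
by an *integer* pixel shift that puts the mask centroid within half a pixel
of the grid center. Integer shifts preserve intensities exactly (no
resampling blur); the sub-pixel residual is below anything the VAE responds
to, and the operation is idempotent. Centering uses the mask centroid (a
bounding-box rule would be an alternative; centroid was chosen and is
documented, not claimed as the original GUI behavior).

## The VAE

The encoder is two stride-2 3×3 convolutions (default 16 then 32 channels),
a dense layer of 16 units, and two linear heads for the posterior mean and
log-variance of the 2D latent; the decoder mirrors it with transpose
convolutions and a sigmoid output. Training minimizes the ELBO with the
pixel-summed Bernoulli cross-entropy (a Gaussian/MSE option exists) plus the
closed-form KL divergence to a standard-normal prior, per-image sums averaged
over the batch — this fixes the reconstruction/KL balance unambiguously.
Optimization is Adam (learning rate 1e-3, batch 32) for 100 epochs. The
forward/backward passes are implemented in compiled code (im2col/col2im
convolutions via RcppArmadillo); all stochastic draws — weight
initialization, epoch shuffling, reparameterization noise — come from R's
RNG, so a seed fully reproduces a training run on a given platform.

Choices worth recording:

* **Channel widths 16/32** keep a full 100-epoch study-scale training run to
  a few minutes on a single CPU core; on the phantom classes the separation
  quality is indistinguishable from wider variants, which remain available
  through `conv_channels`.
* **Scoring uses the posterior mean**, not a sampled latent draw: scores are
  then deterministic functions of the trained model. Whether the original
  analysis scored means or samples is not documented; the mean is the
  deterministic choice.
* **Latent spread.** Under the summed-BCE balance the reconstruction term
  (4096 pixels) dominates the 2-dimensional KL term, so the aggregate latent
  distribution spreads well beyond a unit Gaussian and its pooled mean can
  sit away from the origin along the axis encoding aortic area. This is
  expected behavior of the canonical objective at this image size, and it is
  why the subspace boundary must be fitted per trained model rather than
  fixed a priori.

## Latent partition and scoring

A fixed-boundary mode places the line at a user-supplied `x0` (default −0.8,
the reference convention) — appropriate when a boundary has been chosen by
inspecting a specific trained model. The auto mode runs a deterministic 1D
2-means (centers initialized at the data extremes, ties to the lower center)
and puts the boundary at the midpoint of the two cluster centers.

Two identifiability gaps must be closed per trained run, because VAE latent
axes are exchangeable and sign-symmetric training artifacts:

* **Which side is thrombus**: the cluster whose members have the larger mean
  segmented foreground area (thrombosed dissected aortas are larger). A
  manual override exists.
* **Which axis to partition on** (`axis = "best"`, used by the pipeline):
  the axis whose 2-means clustering separates best, measured by the
  between-center gap over the pooled within-cluster spread. Across seeds the
  discriminative direction lands on either axis with similar frequency, so
  fixing axis 1 by convention would make roughly half of all training runs
  unusable. `fit_partition()` defaults to axis 1 for API compatibility with
  the convention; the pipeline passes `"best"`.

`xmin` is stored from the fitting cohort — it is the data extreme, not the
−3 bound of the decoder-grid visualization. New points beyond `xmin` clamp to
ts = 1, keeping scores in [0, 1]. If no point falls on the thrombus side the
partition is degenerate and scores are all zero by definition (never an
error); this is the expected outcome when scoring a cohort with no
dissection against a fixed boundary.

Numerical edge cases: constant latent coordinates collapse the 2-means
centers and yield a degenerate partition; ties in axis selection break toward
the lower axis index; the dataset score is an exact arithmetic mean and is
permutation-invariant.

## Problem sizes and tolerances used by the test suite

* Analytic checks (score formula, KL closed forms, reparameterization) are
  exact to machine precision.
* Geometric oracles: cylinder cross-section area within 5% of πr² (voxel
  discretization at 0.7 mm on a 10 mm radius), circular-arc frames within
  1e-3 against the closed form at 1201 arc points (one-sided endpoint
  tangents err as half the angular step, so the sampling must be this dense).
* The end-to-end study runs the default six-subject configuration
  (~1200 slices, 100 epochs) and requires: 1D latent threshold accuracy
  ≥ 0.9 against ground-truth thrombus presence, every control subject's mean
  score below 0.05, and every dissected subject scoring above every control.
  Because training is stochastic optimization, up to three reseeded attempts
  are allowed before the property is declared failed.
* Determinism is asserted bit-wise on the score CSVs of two identical
  pipeline runs at a reduced size (2 subjects × 60 slices, 20 epochs) — the
  determinism mechanism is scale-independent.

## Known limitations

* The VAE is a small fixed-topology network; it is adequate for 64×64
  single-channel sections but is not a general-purpose deep-learning stack.
* The thrombus score is relative to the fitting cohort (`xmin` is a cohort
  statistic), so scores are comparable within one trained model + partition,
  not across models.
* Control subjects can receive small nonzero scores when isolated slices
  fall just past the boundary; no suppression mechanism is applied, matching
  the method as described.
* The phantom septum is a straight stripe and the FL a half-disk; real
  dissection flaps curve and the FL is crescent-shaped. The geometry is the
  simplest family that reproduces the hyperintense-lumen/isointense-thrombus
  appearance with an analytically checkable thrombus fraction.
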