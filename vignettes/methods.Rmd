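---
title: "Multi-atlas volumetry on synthetic phantoms: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-atlas volumetry on synthetic phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Small cortical structures such as the piriform cortex (a few hundred mm^3,
spread over roughly 7–12 coronal sections at 1 mm resolution) are tedious to
delineate by hand, and their study at scale depends on automatic
segmentation. The canonical automatic approach is multi-atlas label
propagation: each of several manually labelled atlas images is registered
nonrigidly to the target image, its labels are transferred through the
recovered transformation, and the transferred label sets are combined by
per-voxel plurality ("vote-rule decision fusion"). Region volumes are then
normalised by intracranial volume (ICV) and fed into group statistics.

`mapvol` implements that entire workflow at desk scale, together with a
synthetic phantom-cohort generator that provides what clinical images cannot:
exact, voxel-level ground truth. Every stage — registration, fusion,
volumetry, and the statistical validation layer — can therefore be tested
against known answers.

# The phantom

## Template geometry

The template head is an axis-aligned ellipsoid of white-matter analogue
(label 90) on a RAS+ grid (default 96^3 voxels at 1 mm isotropic; world
coordinates are voxel index times spacing). Inside it, a reduced bilateral
region menu mimics the mesial temporal/frontal junction: hippocampus,
amygdala, parahippocampal, insula and orbital analogues as grey-matter
blobs (the hippocampus analogue set well apart, posterior-inferior, so its
large atrophy effects cannot leak into its neighbours through registration
smoothness), and the piriform-cortex analogue as a thin curved slab. The slab is a
band of an ellipsoidal shell (about 3.2 mm thick — thick enough that its
rasterisation is stable against sub-voxel shifts) cut by an angular sector;
the sector half-angle is bisected deterministically until the painted voxel
count matches the 470 mm^3 target, and the shell's anterior–posterior
semi-axis is chosen so the slab spans 7–12 coronal sections at 1 mm. The
neighbour blobs are centred on the shell surface around the sector so that,
after the slab is painted last, it borders each of them — mirroring how the
real region is relabelled out of its neighbours in atlas databases (each
contact patch kept small, since grey–grey interfaces carry no image
contrast and their placement is decided by the atlas prior alone) — and a
thin CSF cleft carved under the slab's outer face gives it a free surface
towards background (the sulcal boundary of the real anatomy). Right-sided
regions carry odd ids, the left partner is `id + 1`, background is 0.

Only the slab's volume, coronal extent and adjacency are calibrated; no
shape statistics for the region exist to calibrate against, so shape realism
is limited to "thin, curved, high surface-to-volume ratio".

## Appearance

Intensity is rendered per tissue class (background/CSF 0, grey matter 70,
white matter 110 by default) with additive Gaussian noise (`noise_sd`,
default 4) and a smooth multiplicative bias field (trilinear interpolation
of a seeded 5^3 grid of uniform values, amplitude `bias_amplitude`, default
0.1) — enough to make a pure intensity metric unattractive and to justify
the two-channel registration strategy below. Tissue probability maps are the
noise-free memberships blurred with a 1.2 mm Gaussian, clipped to [0, 1];
their per-voxel sum never exceeds 1.

## Subjects: head size and anatomical variability

Each subject composes a global similarity transform with a smooth random
displacement field:

* **Head size.** A log-normal volume scale with coefficient of variation
  `icv_cv` (default 0.18) is realised through the subject's world grid: the
  voxel spacing is multiplied by the cube root of the scale. This keeps
  head-size variation exact — volumes scale analytically, with no
  resampling — which matters because nearest-neighbour resampling of a
  near-rigid map produces coherent voxel-quantisation noise of several
  percent per region, enough to drown the small group effects the pipeline
  is meant to recover. The default is calibrated so that total regional
  volume CV lands near the ~20% reported for manual volumetry of the
  region the phantom emulates; in the phantom, head size carries most of
  that variability.
* **Shape.** A white-noise vector field smoothed with a 16 mm Gaussian and
  scaled to an RMS magnitude of 0.8 mm is applied on the voxel grid
  (nearest-neighbour for labels, trilinear for intensity and probability
  maps, one shared map). Fields whose map folds (non-positive Jacobian
  determinant anywhere) are rescaled by 0.8 and retried; every delivered
  subject has a strictly positive minimum Jacobian.

These defaults were calibrated once to the study conditions the phantom
emulates: total piriform volume CV across subjects of 10–30% and
ICV-corrected regional CV of a few percent, so that 5–7% group effects are
detectable at n = 20 per side. The phantom is deliberately cleaner than
clinical data — no partial-volume mixing, no pathology-correlated
registration failures, no scanner effects — so passing recovery tests
demonstrates the pipeline's correctness, not its clinical accuracy on real
MRI.

## Atrophy

`apply_atrophy()` scales a region's voxel count to `factor` times its
current count by warping the subject through a smooth local contraction
field: the region's blurred mask (1.4 mm Gaussian, normalised to peak 1)
fades a radial contraction about the region centroid, and all channels are
resampled through one *accumulated* map — repeated application composes
displacement fields analytically instead of re-resampling images, which
would otherwise blur boundaries and spuriously shrink convex regions. The
field amplitude is selected by a deterministic two-stage scan of the voxel
count obtained through the linearised composed map, approaching the target
monotonically; corrective passes absorb the crosstalk that arises because
adjacent structures shift into vacated space when their neighbour
contracts. Within a cohort simulation the whole design (all regions of a
group's pathology) shares a single accumulated map and the subject's
appearance is resampled exactly once. Ground truth records the product of
applied factors per region; intracranial volume changes only negligibly.

Two properties of this mechanism deserve emphasis, because simpler
alternatives fail quietly:

* Label repainting (removing boundary voxels by distance or membership
  order) encodes small volume changes as scattered isolated voxels, which
  no smooth deformation can reproduce — the loss becomes invisible to any
  registration-based pipeline.
* On a discrete grid, rasterised boundaries form terraces aligned with the
  voxel lattice, so voxel counts respond to boundary motion in steps of
  roughly half a voxel. For effects whose nominal boundary shift is far
  below half a voxel (a 5% change of a ~230-voxel sphere is a 0.1 mm
  shift), a count-exact contraction necessarily moves the continuous
  boundary further than the nominal factor. The image shows this larger
  continuous contraction, so image-driven automatic volumetry over-reports
  such sub-quantum effects while faithfully recovering effects above the
  quantisation floor. The validation suite documents this for the
  amygdala-analogue (5% injected); the piriform (7%) and hippocampal
  (27%) effects sit at or above the floor and are recovered within the
  stated bands.

The two shipped designs mirror the two clinical archetypes: unilateral
epilepsy-like atrophy (ipsilateral hippocampus 0.73, amygdala 0.95,
piriform 0.93; lateralisation alternates right/left within the group) and
bilateral dementia-like atrophy (piriform 0.84 or 0.81, hippocampus and
amygdala milder).

# Registration

Pairwise spatial normalisation is a classic two-stage design:

1. **Affine (12 parameters).** Sum of squared differences over the tissue
   probability channels, minimised by L-BFGS-B with an analytic gradient at
   two resolutions (downsampling 4 and 2), initialised by the
   intensity-centroid translation. Probability channels share a [0, 1]
   scale, so SSD is appropriate without normalisation. The transform is
   parameterised about the image centre for conditioning, and returned as a
   4x4 world-coordinate matrix.
2. **Free-form deformation.** A cubic B-spline control grid on the fixed
   image, optimised in two sequential stages: first on the probability
   channels (SSD, equal channel weights) across three levels — control
   spacing 24, 12, 8 mm at image downsampling 4, 2, 2 — and then a short
   refinement on the intensity channel with a Gaussian-windowed local
   normalised correlation metric (window 3 mm), which is insensitive to the
   simulated bias field. Each level optimises a residual displacement on
   top of the accumulated field, so no B-spline subdivision is needed; the
   output is the composed displacement (affine plus deformation) on the
   fixed grid, with the minimum Jacobian determinant attached.

Numerical choices: bending energy is the mean squared second difference of
the control-point grid (weight 0.001 by default); the optimiser is
L-BFGS-B with a relative-progress tolerance of about 2e-7 (`factr = 1e9`)
and per-level iteration caps; only cost-decreasing iterates are accepted,
so the final similarity never falls below the initial one. When a level
runs at full resolution, the cost is evaluated over grey matter and a
5 mm margin around it only — the coarse levels have already aligned head
and white matter, and concentrating the residual there makes the small
structures' gradients count. If the recovered map's minimum Jacobian
determinant falls below 0.05, the deformation stages are rerun once with
tenfold bending weight; a still-folded result is flagged and excluded from
fusion rather than aborting the ensemble.

On 64^3 phantoms the defaults recover known translations (≤ 5 mm) and
smooth synthetic warps (≤ 4 mm peak displacement, 14 mm correlation
length) to 0.15–0.35 mm mean error over the brain in a few seconds per
pair on one CPU. The cohort validation runs use a dedicated profile
(levels 4/2/1 with control spacing 24/12/8 mm, a deeply converged
full-resolution probability stage with bending weight 3e-3 and no
intensity refinement, about 2–3 s per pair), chosen for per-pair
sensitivity to the small systematic contractions the atrophy designs
inject.

# Fusion, volumetry, ICV

Propagation warps atlas labels with nearest-neighbour interpolation only
(the label vocabulary can shrink, never grow). Vote-rule fusion takes the
per-voxel plurality label; background competes like any candidate, and ties
break to the smallest label id — a deterministic, seed-free rule. Majority
agreement therefore always wins, and shuffling atlas order can only change
voxels whose vote is tied.

Region volume is voxel count times voxel volume. ICV is estimated by the
same ensemble principle as the labels themselves: the fused non-background
mask volume (each atlas's brain mask is propagated through the same
transformations and voted). On the phantom suite this stand-in stays within
3% of true ICV. ICV-corrected volume is `volume / ICV * 10^4`, stored per
row and recomputable exactly from the row's own fields. Left and right are
stored as separate rows; side pooling (ipsilateral/contralateral recoding,
left+right sums) happens in the statistics layer.

# Statistics

The validation layer mirrors standard volumetry reporting:

* **Bland–Altman** with absolute (`x - y`) and relative
  (`(x - y) / pairmean * 100`) dialects; limits of agreement at the mean
  difference ± 1.96 SD; proportional bias as the Pearson correlation of
  pair means with differences (reported as not-applicable for degenerate
  inputs).
* **Pooled-variance two-sample t tests**, in raw-data and
  summary-statistics dialects that agree to machine precision on exact
  summaries; `df = n1 + n2 - 2`. The pooled (not Welch) dialect is used
  throughout, and ipsilateral/contralateral sides are treated as
  independent samples, matching the degrees of freedom convention of
  side-pooled clinical reports.
* **One-way ANOVA** with pairwise pooled-t post-hocs and Bonferroni
  adjustment over the number of pairs.
* **TOST equivalence**: two one-sided pooled t tests against a
  pre-specified interval (± 0.7 on ICV-corrected volumes, about 1 SD, is
  the convention for scanner-equivalence testing); equivalence is declared
  only when both one-sided tests reject.
* **Normality**: the one-sample Kolmogorov–Smirnov statistic against a
  normal with the sample's own mean and SD, with the p value calibrated by
  seeded Monte-Carlo simulation under the estimated-parameter null
  (Lilliefors-style), since the textbook KS null distribution is wrong when
  parameters are estimated.
* **Rater agreement**: per-side mean Jaccard coefficient, volumes and mean
  absolute volume discrepancy against a designated reference round, with
  coefficients of variation. Synthetic "raters" for testing are built by
  smooth seeded perturbation of the true boundary
  (`perturb_delineation()`), whose overlap with truth decays monotonically
  with the perturbation magnitude.

Group-level absolute volume discrepancy is the mean of per-comparison
|ΔV| values, not the absolute value of the mean — the former is the only
version that does not cancel signed errors. For percent claims, values are
rounded half-up to integers; overlap coefficients are reported to two
decimals.

# Problem sizes

The shipped validation suite exercises the pipeline end to end on a 64^3
grid at 1.5 mm (the same 96 mm field of view as the default template) with
12 atlases and 20 unilateral-atrophy targets (10 per lateralisation side) —
240 pairwise registrations — plus a translation/scale/warp recovery battery
and the small-instance oracles for fusion and overlap. These sizes were
chosen as the smallest cohort in which the injected 5–7% effects are
comfortably detectable; the generator and pipeline run unchanged at larger
grids and cohort sizes.

# Known limitations

* The phantom has three tissue classes and piecewise-constant anatomy; it
  does not emulate MRI physics (no Rician noise, no partial-volume model,
  single contrast).
* Adjacent grey-matter structures have identical intensity, so their mutual
  boundaries are carried by the atlas prior alone — as in real T1 images —
  and atrophy expressed at such boundaries is invisible to the registration
  channels. The template keeps grey–grey contact patches small so the
  contraction fields act mostly against white matter and CSF, where the
  contrast exists.
* Because atlases are drawn from the non-atrophied population, fused
  volumes of atrophied regions are biased towards the atlas mean
  (regression towards the mean): volume loss is somewhat underestimated.
  The recovery tests quantify this; it is a property of the method, not a
  bug of the implementation.
* Effects whose boundary shift is far below the rasterisation quantum
  (the 5% amygdala factor) cannot be injected into discrete labels without
  exaggerating the continuous contraction the image shows; automatic
  volumetry then over-reports them (see the atrophy section). The
  validation suite leaves that band unmet by design rather than loosening
  it; the piriform and hippocampal effects are recovered within their
  bands.
* The deformation model is a single smooth field family; it does not
  emulate focal lesions, ventricle expansion or cortical folding
  variability.
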