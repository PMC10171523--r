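# mapvol

Multi-atlas label propagation, vote-rule decision fusion and
intracranial-volume (ICV) normalised brain volumetry — with a synthetic
phantom cohort generator that provides exact ground truth, so the whole
workflow can be validated end to end on one desk-scale machine.

## Who this is for

Groups building or validating automatic volumetry of small brain structures
(the motivating case is the piriform cortex, a thin curved cortical region
of roughly 470 mm^3 per side) in cohorts with unilateral atrophy
(temporal-lobe-epilepsy-like) or bilateral atrophy (dementia-like). Real
atlas databases and patient images are not required: the package simulates
labelled heads with known region volumes, injected atrophy factors and
per-subject head-size variation, then measures how well the automatic
pipeline recovers what was injected.

## The method

Given an atlas database of labelled images and an unlabelled target:

1. each atlas is registered to the target — affine initialisation, then a
   cubic B-spline free-form deformation driven first by tissue probability
   maps (sum of squared differences) and then by the intensity image
   (local normalised correlation);
2. the atlas labels are resliced to the target grid with nearest-neighbour
   interpolation;
3. the propagated label sets are combined by **vote-rule decision fusion**:
   at every voxel the plurality label wins, background competes like any
   candidate, and ties break to the smallest label id.

Agreement between label sets uses the Jaccard coefficient
JC = |A∩B| / |A∪B| (with Dice = 2·JC/(1+JC)) and the signed volume
discrepancy

    ΔV = 200 · (vol_ref − vol_test) / (vol_ref + vol_test),

bounded in [−200, 200]; |ΔV| is averaged across comparisons. Volumes are
normalised as vol/ICV × 10^4, with ICV estimated by fusing the atlases'
brain masks through the same registrations. The statistics layer provides
pooled two-sample t tests (raw-data and summary-statistics dialects),
one-way ANOVA with Bonferroni post-hocs, Bland–Altman limits of agreement
with proportional-bias testing, TOST equivalence tests, Monte-Carlo
(Lilliefors-style) normality testing and rater-agreement reporting.

## A worked example

```r
library(mapvol)

# a labelled template head, 64^3 voxels at 1.5 mm
tpl <- make_template_phantom(phantom_spec(grid_shape = 64,
                                          voxel_spacing_mm = 1.5))

# a small study: 6 atlases, 4 patients with unilateral atrophy
# (ipsilateral hippocampus x0.73, amygdala x0.95, piriform x0.93)
co <- cohort_spec(c(atlas = 6, patient = 4),
                  atrophy_design = list(patient = design_unilateral_tle()),
                  seed = 7)
sim <- simulate_cohort(tpl, co)
db  <- atlas_db(Filter(function(s) s$group == "atlas", sim$subjects))

tg    <- sim$subjects$patient_01        # lateralisation: right
fused <- segment_target(db, tg)
fused$records[fused$records$region == "piriform",
              c("region", "side", "jc", "dice", "delta_v")]
```

```
   region  side    jc  dice delta_v
 piriform right 0.928 0.963   -7.46
 piriform  left 1.000 1.000    0.00
```

The fused automatic segmentation reproduces the healthy (left) piriform
exactly and overlaps the atrophied (right) side with a Jaccard coefficient
of 0.93; the negative signed volume discrepancy on the atrophied side says
the automatic volume slightly overestimates it — the expected
regression-towards-the-atlas-mean bias. `fused$icv_mm3` gives the
fused-mask ICV estimate (248429 mm^3 against a true 249057 mm^3 here,
−0.25%). Group statistics run on the ICV-corrected volume table:

```r
segs <- ...                             # one segment_target() per patient
vt   <- cohort_volume_table(Filter(function(s) s$group == "patient",
                                   sim$subjects), segs)
lat  <- lateralise_sides(vt[vt$source == "automatic", ])
two_sample_t(lat$icv_corrected[lat$region == "piriform" & lat$side == "ipsi"],
             lat$icv_corrected[lat$region == "piriform" & lat$side == "contra"])
```

```
pooled two-sample t (raw-data pooled): t = -1.68, df = 6, p = 0.144
```

With only four patients the 7% effect is directional but not significant;
the shipped validation study (12 atlases, 20 patients, see below) detects
it at p < 0.05.

`run_pipeline(config)` executes the whole chain (simulate → segment →
volumetry → statistics) from a single JSON configuration and writes
seed-stamped CSV artifacts; `inst/cli/mapvol.R` exposes the same stages as
shell verbs (`simulate`, `register`, `segment`, `loo`, `run`).

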