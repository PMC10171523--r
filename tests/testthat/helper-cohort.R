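# The end-to-end validation cohort: one unilateral-atrophy study at the
# shipped study conditions (12 atlases, 10 targets per lateralisation side,
# 64^3 grids at 1.5 mm), segmented once and shared by the tests that grade
# recovery and ICV accuracy.

validation_cohort_run <- function() {
  if (!is.null(.fixtures$cohort_run)) return(.fixtures$cohort_run)
  tpl <- make_template_phantom(
    phantom_spec(grid_shape = 64, voxel_spacing_mm = 1.5, seed = 101L))
  co <- cohort_spec(
    c(atlas = 12, tle = 20),
    atrophy_design = list(tle = design_unilateral_tle()),
    seed = 101L)
  sim <- simulate_cohort(tpl, co)
  db <- atlas_db(Filter(function(s) s$group == "atlas", sim$subjects))
  targets <- Filter(function(s) s$group == "tle", sim$subjects)
  params <- reg_params(ffd_levels = c(4, 2, 1), ctrl_spacing_mm = c(24, 12, 8),
                       ffd_maxit = c(60, 30, 80), intensity_maxit = 0,
                       bending_weight = 3e-3)
  segs <- list()
  for (tg in targets) {
    segs[[tg$subject_id]] <- segment_target(db, tg, params)
  }
  vt <- cohort_volume_table(targets, segs)
  .fixtures$cohort_run <- list(template = tpl, sim = sim, db = db,
                               targets = targets, segs = segs, volumes = vt)
  .fixtures$cohort_run
}

# Reconstruct a sample with exactly the given mean and SD (any n >= 2), so
# summary statistics printed in reports can be fed to raw-data routines.
sample_with_moments <- function(m, s, n) {
  z <- scale(seq_len(n))[, 1]
  m + s * z
}
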