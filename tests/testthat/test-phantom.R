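# Phantom template, subject sampling and atrophy.

adjacent_ids <- function(lab, id) {
  dm <- dim(lab)
  w <- which(lab == id, arr.ind = TRUE)
  nb <- integer(0)
  for (d in 1:3) for (s in c(-1L, 1L)) {
    w2 <- w
    w2[, d] <- pmin(pmax(w2[, d] + s, 1L), dm[d])
    nb <- union(nb, unique(lab[w2]))
  }
  sort(setdiff(nb, id))
}

test_that("default template meets the piriform volume, extent and adjacency
           contract", {
  spec <- phantom_spec()
  tpl <- make_template_phantom(spec)
  tv <- tpl$true_volumes_mm3
  for (side in c("right", "left")) {
    v <- tv$volume_mm3[tv$region_name == "piriform" & tv$side == side]
    expect_gte(v, 376)            # 470 mm^3 within +-20%
    expect_lte(v, 564)
  }
  # coronal extent at 1 mm: 7 to 12 sections
  for (id in c(11L, 12L)) {
    ys <- unique(which(tpl$labels == id, arr.ind = TRUE)[, 2])
    expect_gte(length(ys), 7L)
    expect_lte(length(ys), 12L)
  }
  # neighbour contract: amygdala, parahippocampal, insula, orbital analogues
  # and background all touch the slab
  expect_true(all(c(0L, 3L, 9L, 21L, 71L) %in% adjacent_ids(tpl$labels, 11L)))
  expect_true(all(c(0L, 4L, 10L, 22L, 72L) %in% adjacent_ids(tpl$labels, 12L)))
  # ground truth is exact voxel bookkeeping
  expect_equal(tv$volume_mm3[tv$region_id == 11],
               sum(tpl$labels == 11L) * voxel_volume(tpl$labels))
  expect_equal(tpl$icv_mm3, sum(tpl$labels != 0L) * voxel_volume(tpl$labels))
  # determinism
  tpl2 <- make_template_phantom(spec)
  expect_identical(tpl$labels, tpl2$labels)
  expect_identical(tpl$intensity, tpl2$intensity)
})

test_that("voxel counts scale inversely with voxel volume at fixed head size", {
  tpl1 <- small_template()                       # 48^3 at 2 mm
  n48 <- sum(tpl1$labels == 11L)
  n96 <- round(470 / 8)                          # same mm^3 target at 8 mm^3
  expect_lt(abs(n48 - n96) / n96, 0.15)
})

test_that("an unsatisfiable region target fails with a sizing error naming
           the region", {
  expect_error(phantom_spec(grid_shape = 16), "at least 32")
  menu <- default_region_menu()
  menu$target_volume_mm3[menu$name == "piriform"] <- 5e4   # cannot fit
  expect_error(
    make_template_phantom(phantom_spec(grid_shape = 48, voxel_spacing_mm = 2,
                                       region_menu = menu)),
    "piriform")
})

test_that("intensity rendering honours the noise and probability contracts", {
  tpl <- small_template()
  spec0 <- phantom_spec(grid_shape = 48, voxel_spacing_mm = 2,
                        noise_sd = 0, bias_amplitude = 0)
  r0 <- render_intensity(tpl$labels, spec0, seed = 1)
  vals <- unique(as.numeric(r0$intensity))
  expect_setequal(vals, unname(spec0$tissue_means))
  # noisy render: within-tissue SD close to noise_sd, modulated by bias
  spec1 <- phantom_spec(grid_shape = 48, voxel_spacing_mm = 2,
                        noise_sd = 4, bias_amplitude = 0.1)
  r1 <- render_intensity(tpl$labels, spec1, seed = 1)
  wm_sd <- sd(r1$intensity[tpl$labels == 90L])
  expect_gt(wm_sd, 4 * 0.8)
  expect_lt(wm_sd, 4 * 1.2 + 110 * 0.1)   # noise plus bias spread of the mean
  # probability maps: [0,1], per-voxel sum bounded by 1
  ps <- r1$tissue_probs
  expect_true(all(ps$gm >= 0 & ps$gm <= 1))
  expect_true(all(ps$gm + ps$wm <= 1 + 1e-12))
  # rendering is deterministic in the seed
  r2 <- render_intensity(tpl$labels, spec1, seed = 1)
  expect_identical(r1$intensity, r2$intensity)
})

test_that("subject sampling preserves bookkeeping and avoids folding", {
  tpl <- small_template()
  co <- cohort_spec(c(h = 1), seed = 5)
  s <- sample_subject(tpl, co, 42)
  tv <- s$true_volumes_mm3
  for (i in seq_len(nrow(tv))) {
    ids <- tv$region_id[i]
    expect_equal(tv$volume_mm3[i],
                 sum(s$labels == ids) * voxel_volume(s$labels))
  }
  expect_gt(s$meta$min_jacobian, 0)
  # all labelled voxels inside the brain mask (non-background)
  expect_true(all(s$labels[s$labels != 0L] != 0L))
  # determinism
  s2 <- sample_subject(tpl, co, 42)
  expect_identical(s$labels, s2$labels)
  # zero deformation and zero scale variation reproduce the template
  s0 <- sample_subject(tpl, cohort_spec(c(h = 1), deformation_magnitude_mm = 0,
                                        icv_cv = 0, seed = 1), 7)
  expect_identical(as.integer(s0$labels), as.integer(tpl$labels))
  expect_equal(as.numeric(s0$intensity), as.numeric(tpl$intensity))
})

test_that("across-subject piriform volume variability sits in the calibrated
           band", {
  tpl <- reg_template()
  co <- cohort_spec(c(h = 30), seed = 17)
  vols <- vapply(1:30, function(i) {
    s <- sample_subject(tpl, co, derive_seed(17, paste("cv", i)))
    tv <- s$true_volumes_mm3
    sum(tv$volume_mm3[tv$region_name == "piriform"])
  }, 1)
  cv <- coefficient_of_variation(vols)
  expect_gte(cv, 10)
  expect_lte(cv, 30)
})

test_that("atrophy hits exact voxel targets, composes, and leaves the rest
           of the anatomy alone", {
  tpl <- small_template()
  s <- sample_subject(tpl, cohort_spec(c(h = 1), seed = 2), 1234)
  n0 <- sum(s$labels == 11L)
  a <- apply_atrophy(s, "piriform", 0.93, "right")
  expect_lt(abs(sum(a$labels == 11L) - 0.93 * n0), 0.02 * n0 + 0.5)
  expect_equal(a$true_volumes_mm3$atrophy_factor[
    a$true_volumes_mm3$region_id == 11], 0.93)
  # other regions move at most marginally with the local field
  expect_identical(sum(a$labels == 12L), sum(s$labels == 12L))
  other <- setdiff(unique(s$spec$region_menu$id), c(11L, 90L))
  for (id in other) {
    expect_lte(abs(sum(a$labels == id) - sum(s$labels == id)),
               0.01 * sum(s$labels == id) + 1)
  }
  # identity factor
  expect_identical(apply_atrophy(s, "piriform", 1, "right")$labels, s$labels)
  # determinism
  a2 <- apply_atrophy(s, "piriform", 0.93, "right")
  expect_identical(a$labels, a2$labels)
  # composition: 0.5 twice is a quarter within compounded tolerance
  h0 <- sum(s$labels == 1L)
  b <- apply_atrophy(apply_atrophy(s, "hippocampus", 0.5, "right"),
                     "hippocampus", 0.5, "right")
  expect_lt(abs(sum(b$labels == 1L) - 0.25 * h0), 0.05 * h0 + 2)
  # growth expands into the adjacent filler only
  g <- apply_atrophy(s, "amygdala", 1.2, "both")
  expect_lt(abs(sum(g$labels == 3L) - 1.2 * sum(s$labels == 3L)),
            0.02 * sum(s$labels == 3L) + 0.5)
  # intracranial volume is essentially untouched by focal change
  expect_lt(abs(g$icv_mm3 - s$icv_mm3) / s$icv_mm3, 0.005)
  expect_lt(abs(a$icv_mm3 - s$icv_mm3) / s$icv_mm3, 0.005)
})

test_that("cohort simulation applies designs per lateralisation and is
           reproducible", {
  # 64^3 grid: the 5% amygdala factor is below the rasterisation quantum of
  # the coarser unit-test grid
  tpl <- reg_template()
  co <- cohort_spec(
    c(atlas = 2, tle = 4),
    atrophy_design = list(tle = design_unilateral_tle()), seed = 31)
  sim <- simulate_cohort(tpl, co)
  expect_length(sim$subjects, 6L)
  gt <- sim$ground_truth
  expect_equal(nrow(gt), 6L * nrow(tpl$spec$region_menu))
  # lateralisation alternates right/left within the patient group
  lats <- vapply(Filter(function(s) s$group == "tle", sim$subjects),
                 `[[`, "", "lateralisation")
  expect_equal(as.integer(table(lats)[c("left", "right")]), c(2L, 2L))
  # factors recorded exactly as applied, on the correct side
  tle <- gt[gt$group == "tle" & gt$region_name == "hippocampus", ]
  ipsi <- tle$atrophy_factor[tle$side == tle$lateralisation]
  contra <- tle$atrophy_factor[tle$side != tle$lateralisation]
  expect_true(all(ipsi == 0.73))
  expect_true(all(contra == 1))
  # ground-truth mean ipsi/contra ratio recovers the injected factor
  vol_i <- tle$volume_mm3[tle$side == tle$lateralisation]
  vol_c <- tle$volume_mm3[tle$side != tle$lateralisation]
  expect_lt(abs(mean(vol_i) / mean(vol_c) - 0.73), 0.05)
  # determinism of the ground-truth table
  sim2 <- simulate_cohort(tpl, co)
  expect_identical(sim$ground_truth, sim2$ground_truth)
  # degenerate cohort: no variability, no atrophy -> template copies
  sim0 <- simulate_cohort(tpl, cohort_spec(
    c(g1 = 1, g2 = 1), deformation_magnitude_mm = 0, icv_cv = 0, seed = 1))
  expect_identical(as.integer(sim0$subjects[[1]]$labels),
                   as.integer(tpl$labels))
  expect_identical(as.integer(sim0$subjects[[2]]$labels),
                   as.integer(tpl$labels))
})
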