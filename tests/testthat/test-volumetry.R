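# Raw and ICV-normalised volumetry.

test_that("region volume is voxel count times voxel volume, additive over
           disjoint id sets", {
  lab <- with_spacing(array(0L, c(10, 10, 10)), c(1, 1, 1))
  lab[1:5, 1, 1] <- 1L
  lab[1:3, 2, 1] <- 2L
  expect_equal(region_volume(lab, 1), 5)
  expect_equal(region_volume(lab, 2), 3)
  expect_equal(region_volume(lab, c(1, 2)),
               region_volume(lab, 1) + region_volume(lab, 2))
  attr(lab, "spacing") <- c(2, 2, 2)
  expect_equal(region_volume(lab, 1), 5 * 8)
  expect_error(region_volume(lab, integer(0)), "empty")
})

test_that("ICV correction is volume/ICV x 10^4 and scale-invariant", {
  expect_identical(icv_correct(0, 1.5e6), 0)
  expect_equal(icv_correct(485, 1.318e6), 3.68, tolerance = 0.002)
  expect_identical(icv_correct(500, 1e6), icv_correct(1000, 2e6))
  expect_error(icv_correct(100, 0), "positive")
})

test_that("cohort volume table pairs manual truth with automatic rows", {
  tpl <- small_template()
  fake_seg <- structure(list(labels = tpl$labels, icv_mm3 = tpl$icv_mm3),
                        class = "fusion_result")
  vt <- cohort_volume_table(list(tpl), setNames(list(fake_seg), "template"))
  n_regions <- length(unique(tpl$spec$region_menu$name[
    tpl$spec$region_menu$side != "both"]))
  expect_equal(nrow(vt), n_regions * 2 * 2)
  # perfect segmentation: manual and automatic rows agree exactly
  man <- vt[vt$source == "manual-truth", ]
  aut <- vt[vt$source == "automatic", ]
  expect_equal(man$volume_mm3, aut$volume_mm3)
  expect_equal(man$icv_corrected, aut$icv_corrected)
  # bookkeeping identity: icv_corrected recomputes from its own row
  expect_equal(vt$icv_corrected, vt$volume_mm3 / vt$icv_mm3 * 1e4)
  expect_error(cohort_volume_table(list(tpl), list()), "missing segmentation")
})

test_that("estimated ICV reuses fused labels when provided", {
  tpl <- small_template()
  fake_seg <- structure(list(labels = tpl$labels, icv_mm3 = tpl$icv_mm3),
                        class = "fusion_result")
  expect_equal(estimate_icv(tpl, NULL, fusion = fake_seg), tpl$icv_mm3)
})

test_that("lateralise_sides recodes relative to each subject's focus side", {
  vt <- data.frame(
    subject_id = c("a", "a", "b", "b", "c", "c"),
    lateralisation = c("right", "right", "left", "left", "none", "none"),
    region = "piriform", side = c("right", "left", "right", "left",
                                  "right", "left"),
    volume_mm3 = 1:6
  )
  lat <- lateralise_sides(vt)
  expect_equal(nrow(lat), 4L)
  expect_equal(lat$side, c("ipsi", "contra", "contra", "ipsi"))
})
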