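# Affine and free-form deformation registration.

test_that("warping with the identity is exact and label sets never grow", {
  tpl <- small_template()
  idt <- identity_affine(tpl)
  expect_equal(as.numeric(warp_intensity(tpl$intensity, idt)),
               as.numeric(tpl$intensity))
  expect_identical(as.integer(warp_labels(tpl$labels, idt)),
                   as.integer(tpl$labels))
  # integral-voxel translation: exact shift
  m <- unclass(idt)
  m[1, 4] <- 2 * spacing_of(tpl$labels)[1]
  tr <- mapvol:::new_affine(m, mapvol:::as_reg_image(tpl),
                            mapvol:::as_reg_image(tpl))
  shifted <- warp_labels(tpl$labels, tr)
  dm <- dim(tpl$labels)
  expect_identical(shifted[1:(dm[1] - 2), , ],
                   array(tpl$labels, dm)[3:dm[1], , ])
  expect_true(all(shifted[(dm[1] - 1):dm[1], , ] == 0L))
  # warped label vocabulary is a subset of the source vocabulary
  disp <- random_smooth_field(dim(tpl$labels), spacing_of(tpl$labels),
                              magnitude_mm = 4, smoothness_mm = 10, seed = 8)
  fld <- as_deformation_field(disp, spacing_of(tpl$labels))
  wl <- warp_labels(tpl$labels, fld)
  expect_true(all(unique(as.integer(wl)) %in%
                    c(0L, unique(as.integer(tpl$labels)))))
})

test_that("self-registration is a near-identity for both stages", {
  tpl <- reg_template()
  aff <- affine_register(tpl, tpl)
  g <- mapvol:::grid_world(dim(tpl$labels), spacing_of(tpl$labels))
  m <- unclass(aff)
  brain <- as.integer(tpl$labels) != 0L
  dx <- (m[1, 1] - 1) * g$x + m[1, 2] * g$y + m[1, 3] * g$z + m[1, 4]
  dy <- m[2, 1] * g$x + (m[2, 2] - 1) * g$y + m[2, 3] * g$z + m[2, 4]
  dz <- m[3, 1] * g$x + m[3, 2] * g$y + (m[3, 3] - 1) * g$z + m[3, 4]
  expect_lt(max(sqrt(dx^2 + dy^2 + dz^2)[brain]), 0.1)
  ffd <- ffd_register(tpl, tpl, init = aff,
                      params = reg_params(ffd_maxit = c(10, 5, 5),
                                          intensity_maxit = 2))
  mag <- sqrt(ffd$disp[, , , 1]^2 + ffd$disp[, , , 2]^2 + ffd$disp[, , , 3]^2)
  expect_lt(mean(mag[brain]), 0.2)
  # monotone improvement contract
  expect_lte(ffd$similarity["post"], ffd$similarity["pre"] + 1e-12)
})

test_that("known translations and similarity scalings are recovered", {
  tpl <- reg_template()
  sp <- spacing_of(tpl$labels)
  g <- mapvol:::grid_world(dim(tpl$labels), sp)
  brain <- as.integer(tpl$labels) != 0L

  check_affine <- function(m_true, tol_mm) {
    mv <- list(
      probs = lapply(tpl$tissue_probs, function(p) {
        warp_intensity(p, mapvol:::new_affine(
          solve(m_true), mapvol:::as_reg_image(tpl), mapvol:::as_reg_image(tpl)))
      }),
      intensity = NULL, spacing = sp)
    aff <- affine_register(tpl, mv)
    m <- unclass(aff)
    err <- sqrt(
      ((m[1, 1] - m_true[1, 1]) * g$x + (m[1, 2] - m_true[1, 2]) * g$y +
         (m[1, 3] - m_true[1, 3]) * g$z + m[1, 4] - m_true[1, 4])^2 +
      ((m[2, 1] - m_true[2, 1]) * g$x + (m[2, 2] - m_true[2, 2]) * g$y +
         (m[2, 3] - m_true[2, 3]) * g$z + m[2, 4] - m_true[2, 4])^2 +
      ((m[3, 1] - m_true[3, 1]) * g$x + (m[3, 2] - m_true[3, 2]) * g$y +
         (m[3, 3] - m_true[3, 3]) * g$z + m[3, 4] - m_true[3, 4])^2)
    mean(err[brain])
  }

  m_tr <- diag(4); m_tr[1:3, 4] <- c(3, -1.5, 0)   # 3.35 mm shift
  expect_lt(check_affine(m_tr, 0.5), 0.5)

  ctr <- (dim(tpl$labels) - 1) * sp / 2
  m_sc <- diag(c(1.1, 1.1, 1.1, 1))
  m_sc[1:3, 4] <- ctr - 1.1 * ctr                  # 10% scale about centre
  aff_err <- check_affine(m_sc, 1)
  expect_lt(aff_err, 1)                            # ~2% of the brain radius
})

test_that("composition of transforms matches sequential application", {
  tpl <- small_template()
  sp <- spacing_of(tpl$labels)
  a1 <- identity_affine(tpl); m1 <- unclass(a1); m1[1:3, 4] <- c(2, 0, -2)
  a1 <- mapvol:::new_affine(m1, mapvol:::as_reg_image(tpl),
                            mapvol:::as_reg_image(tpl))
  a2 <- identity_affine(tpl); m2 <- unclass(a2)
  m2[1:3, 1:3] <- diag(c(1.05, 1, 0.95)); m2[1:3, 4] <- c(0, 1, 0)
  a2 <- mapvol:::new_affine(m2, mapvol:::as_reg_image(tpl),
                            mapvol:::as_reg_image(tpl))
  comp <- compose_transforms(a1, a2)
  expect_equal(unclass(comp)[1:4, 1:4], (m2 %*% m1)[1:4, 1:4],
               tolerance = 1e-12)
  # field-then-affine: analytic composition equals applying the maps in turn
  disp <- random_smooth_field(dim(tpl$labels), sp, 2, 12, seed = 3)
  fld <- as_deformation_field(disp, sp)
  comp2 <- compose_transforms(fld, a2)
  g <- mapvol:::grid_world(dim(tpl$labels), sp)
  y1 <- cbind(g$x + as.numeric(disp[, , , 1]), g$y + as.numeric(disp[, , , 2]),
              g$z + as.numeric(disp[, , , 3]))
  y2 <- y1 %*% t(m2[1:3, 1:3]) + rep(m2[1:3, 4], each = nrow(y1))
  expect_equal(as.numeric(comp2$disp[, , , 1]), y2[, 1] - g$x,
               tolerance = 1e-6)
  expect_equal(as.numeric(comp2$disp[, , , 3]), y2[, 3] - g$z,
               tolerance = 1e-6)
})

test_that("an overwhelming bending weight collapses the FFD to its affine
           initialisation", {
  tpl <- small_template()
  mv <- sample_subject(tpl, cohort_spec(c(h = 1), seed = 4), 9)
  aff <- affine_register(tpl, mv)
  ffd <- ffd_register(tpl, mv, init = aff,
                      params = reg_params(ffd_maxit = c(10, 5, 5),
                                          intensity_maxit = 2,
                                          bending_weight = 1e9))
  # residual non-affine displacement tends to zero
  m <- unclass(aff)
  g <- mapvol:::grid_world(dim(tpl$labels), spacing_of(tpl$labels))
  res <- sqrt(
    (ffd$disp[, , , 1] - ((m[1, 1] - 1) * g$x + m[1, 2] * g$y + m[1, 3] * g$z + m[1, 4]))^2 +
    (ffd$disp[, , , 2] - (m[2, 1] * g$x + (m[2, 2] - 1) * g$y + m[2, 3] * g$z + m[2, 4]))^2 +
    (ffd$disp[, , , 3] - (m[3, 1] * g$x + m[3, 2] * g$y + (m[3, 3] - 1) * g$z + m[3, 4]))^2)
  expect_lt(mean(res), 0.05)
})

test_that("registration recovers label overlap lost to an inter-subject warp", {
  tpl <- small_template()
  mv <- sample_subject(tpl, cohort_spec(c(h = 1), seed = 12,
                                        deformation_magnitude_mm = 4,
                                        deformation_smoothness_mm = 12), 77)
  pre_jc <- jaccard(tpl$labels, mv$labels, ids = 11L)
  expect_lt(pre_jc, 1)
  prop <- propagate(mv, tpl, reg_params(ffd_maxit = c(30, 20, 10),
                                        intensity_maxit = 3))
  post_jc <- jaccard(tpl$labels, prop, ids = 11L)
  expect_gt(post_jc, pre_jc)
})
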