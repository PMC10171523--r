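# Overlap and volume-discrepancy measures.

test_that("jaccard handles identity, disjointness and counted examples", {
  m <- with_spacing(array(FALSE, c(6, 6, 6)), c(1, 1, 1))
  a <- m; a[2:4, 2:4, 2:4] <- TRUE
  expect_identical(jaccard(a, a), 1)
  b <- m; b[5:6, 5:6, 5:6] <- TRUE
  expect_identical(jaccard(a, b), 0)
  # boxes with intersection 4 voxels, union 12
  x <- m; x[1:2, 1:2, 1:2] <- TRUE          # 8 voxels
  y <- m; y[1:2, 1:2, 2:3] <- TRUE          # 8 voxels, 4 shared
  expect_equal(jaccard(x, y), 1 / 3)
  expect_identical(jaccard(m, m), 1)        # both empty: perfect agreement
  expect_error(jaccard(a, with_spacing(array(FALSE, c(5, 6, 6)), 1)), "grid")
})

test_that("jaccard equals an exhaustive per-voxel count on random masks", {
  set.seed(42)
  for (i in 1:50) {
    dm <- sample(3:8, 3, replace = TRUE)
    a <- array(runif(prod(dm)) < runif(1), dm)
    b <- array(runif(prod(dm)) < runif(1), dm)
    inter <- 0; uni <- 0
    for (j in seq_len(prod(dm))) {
      inter <- inter + (a[j] && b[j])
      uni <- uni + (a[j] || b[j])
    }
    expected <- if (uni == 0) 1 else inter / uni
    expect_equal(jaccard(with_spacing(a, 1), with_spacing(b, 1)), expected)
  }
})

test_that("dice follows 2*JC/(1+JC) and dominates JC", {
  expect_identical(dice_from_jaccard(1), 1)
  expect_identical(dice_from_jaccard(0), 0)
  expect_equal(dice_from_jaccard(0.5), 2 / 3)
  jc <- seq(0, 1, by = 0.01)
  expect_true(all(dice_from_jaccard(jc) >= jc))
  expect_error(dice_from_jaccard(1.2), "\\[0, 1\\]")
})

test_that("signed volume discrepancy is antisymmetric and bounded", {
  expect_identical(signed_volume_discrepancy(50, 50), 0)
  expect_identical(signed_volume_discrepancy(100, 0), 200)
  expect_equal(signed_volume_discrepancy(523, 489), 6.719368, tolerance = 1e-6)
  set.seed(1)
  v1 <- runif(100, 0, 1000); v2 <- runif(100, 0, 1000)
  dv <- signed_volume_discrepancy(v1, v2)
  expect_equal(dv, -signed_volume_discrepancy(v2, v1))
  expect_true(all(dv >= -200 & dv <= 200))
  expect_error(signed_volume_discrepancy(0, 0), "zero")
})

test_that("percent reduction matches the worked group comparisons", {
  expect_equal(round(percent_reduction(523, 489)), 7)
  expect_equal(round(percent_reduction(16.69, 12.15)), 27)
  expect_identical(percent_reduction(100, 100), 0)
  expect_error(percent_reduction(0, 10), "positive")
})

test_that("coefficient of variation matches hand computations", {
  expect_identical(coefficient_of_variation(rep(5, 10)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2 * 100)
  x <- 473 + 94 * scale(c(379, 567, 470, 476))[, 1]  # mean 473, sd 94 exactly
  expect_equal(mean(x), 473)
  expect_equal(sd(x), 94)
  expect_equal(round(coefficient_of_variation(x)), 20)
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
  expect_error(coefficient_of_variation(3), "at least two")
})
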