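# Vote-rule decision fusion and the leave-one-out machinery.

test_that("vote_fuse matches exhaustive counting on random small instances", {
  set.seed(99)
  for (i in 1:40) {
    dm <- sample(2:8, 3, replace = TRUE)
    n_atl <- sample(2:5, 1)
    n_lab <- sample(2:4, 1)
    props <- lapply(seq_len(n_atl), function(j) random_labels(dm, n_lab))
    fused <- vote_fuse(props)
    expect_identical(array(as.integer(fused$labels), dm), brute_vote(props))
    # winning vote count never below the tied-candidate floor
    expect_true(all(fused$votes >= 1))
  }
})

test_that("tie-break picks the smallest label id, background included", {
  mk <- function(v) with_spacing(array(as.integer(v), c(1, 1, 1)), 1)
  expect_identical(as.integer(vote_fuse(list(mk(5), mk(5), mk(3)))$labels), 5L)
  expect_identical(as.integer(vote_fuse(list(mk(5), mk(3)))$labels), 3L)
  expect_identical(as.integer(vote_fuse(list(mk(5), mk(0)))$labels), 0L)
  one <- random_labels(c(4, 4, 4), 3)
  expect_identical(as.integer(vote_fuse(list(one))$labels), as.integer(one))
  expect_error(vote_fuse(list(mk(1), random_labels(c(2, 2, 2), 2))), "grid")
})

test_that("majority label always wins and atlas order only matters at ties", {
  set.seed(7)
  for (i in 1:20) {
    dm <- c(5, 4, 3)
    n_atl <- 5
    props <- lapply(seq_len(n_atl), function(j) random_labels(dm, 3))
    fused <- vote_fuse(props)
    lab <- vapply(props, as.integer, integer(prod(dm)))
    for (v in seq_len(prod(dm))) {
      tab <- table(lab[v, ])
      if (max(tab) > n_atl / 2) {
        expect_identical(as.integer(fused$labels)[v],
                         as.integer(names(tab)[which.max(tab)]))
      }
    }
    # permutation invariance away from ties
    perm <- vote_fuse(props[sample(n_atl)])
    tied <- apply(lab, 1, function(r) {
      tb <- table(r); sum(tb == max(tb)) > 1
    })
    expect_identical(as.integer(perm$labels)[!tied],
                     as.integer(fused$labels)[!tied])
  }
})

test_that("a database of copies of the target reproduces the target exactly", {
  tpl <- small_template()
  db <- atlas_db(list(a = tpl, b = tpl, c = tpl))
  # identical atlases: propagation must return the target's own labels and
  # fusion must therefore reproduce them
  fused <- segment_target(db, tpl, reg_params(
    affine_maxit = c(10, 5), ffd_maxit = c(5, 3, 3), intensity_maxit = 0))
  expect_identical(as.integer(fused$labels), as.integer(tpl$labels))
  expect_true(all(fused$records$jc == 1))
  expect_equal(fused$icv_mm3, tpl$icv_mm3)
})

test_that("leave-one-out bookkeeping covers every target, region and side", {
  tpl <- small_template()
  db <- atlas_db(list(s1 = tpl, s2 = tpl))
  loo <- leave_one_out(db, reg_params(
    affine_maxit = c(5, 3), ffd_maxit = c(3, 2, 2), intensity_maxit = 0))
  n_regions <- length(unique(tpl$spec$region_menu$name[
    tpl$spec$region_menu$side != "both"]))
  expect_equal(nrow(loo), 2 * n_regions * 2)
  expect_true(all(loo$jc == 1))
  expect_true(all(loo$n_atlases == 1))
  expect_setequal(unique(loo$side), c("right", "left"))
  icv <- attr(loo, "icv")
  expect_equal(icv$icv_mm3, icv$true_icv_mm3)
  expect_error(leave_one_out(atlas_db(list(tpl))), "at least two")
})
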