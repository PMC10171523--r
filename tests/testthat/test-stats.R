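# Statistical validation layer.

test_that("bland_altman reproduces a hand computation and degenerate cases", {
  ba <- bland_altman(c(10, 20, 30), c(8, 24, 27))
  expect_equal(ba$mean_diff, 1 / 3)
  expect_equal(ba$sd_diff,
               sqrt(((2 - 1 / 3)^2 + (-4 - 1 / 3)^2 + (3 - 1 / 3)^2) / 2))
  expect_equal(ba$loa, ba$mean_diff + c(-1.96, 1.96) * ba$sd_diff)
  # identical pairs: zero-width limits, proportional bias not applicable
  ba0 <- bland_altman(c(5, 6, 7), c(5, 6, 7))
  expect_equal(ba0$mean_diff, 0)
  expect_equal(diff(ba0$loa), 0)
  expect_true(is.na(ba0$bias_r))
  expect_error(bland_altman(c(1, 2), c(1, 2)), "at least 3")
})

test_that("bland_altman relative dialect and limits-of-agreement coverage", {
  ba <- bland_altman(c(11, 22, 44), c(9, 18, 36), dialect = "relative")
  expect_equal(ba$diffs, c(2 / 10, 4 / 20, 8 / 40) * 100)
  with_seed(2024, {
    x <- rnorm(2000, 100, 10)
    y <- x + rnorm(2000, 0, 5)
  })
  ba2 <- bland_altman(x, y)
  cover <- mean(ba2$diffs >= ba2$loa[1] & ba2$diffs <= ba2$loa[2])
  expect_gt(cover, 0.95 - 3 * sqrt(0.95 * 0.05 / 2000))
  expect_lt(cover, 0.95 + 3 * sqrt(0.95 * 0.05 / 2000))
})

test_that("pooled t behaves identically in summary and raw dialects", {
  with_seed(7, {
    x <- rnorm(23, 10, 2)
    y <- rnorm(31, 11, 3)
  })
  a <- two_sample_t(x, y)
  b <- pooled_t_from_summaries(mean(x), sd(x), length(x),
                               mean(y), sd(y), length(y))
  expect_equal(a$t, b$t, tolerance = 1e-10)
  expect_equal(a$p, b$p, tolerance = 1e-10)
  expect_identical(a$df, length(x) + length(y) - 2)
  # independent oracle: stats::t.test with pooled variance
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(a$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(a$p, tt$p.value, tolerance = 1e-10)
  # sign convention and degenerate input
  expect_lt(two_sample_t(c(1, 2, 3), c(4, 5, 6))$t, 0)
  expect_identical(pooled_t_from_summaries(5, 1, 10, 5, 1, 10)$t, 0)
  expect_error(pooled_t_from_summaries(1, 0, 5, 1, 0, 5), "degenerate")
})

test_that("one-way ANOVA matches the two-group t-squared identity and a
           brute-force sum-of-squares oracle", {
  with_seed(11, {
    g <- list(a = rnorm(12, 0), b = rnorm(15, 0.5), c = rnorm(9, 1))
  })
  an2 <- one_way_anova(g[1:2])
  tt <- two_sample_t(g$a, g$b)
  expect_equal(an2$F, tt$t^2, tolerance = 1e-10)
  expect_equal(an2$p, tt$p, tolerance = 1e-10)
  # brute-force decomposition
  an3 <- one_way_anova(g)
  values <- unlist(g)
  gm <- mean(values)
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - gm)^2, 1))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 1))
  Fref <- (ssb / (length(g) - 1)) / (ssw / (length(values) - length(g)))
  expect_equal(an3$F, Fref, tolerance = 1e-10)
  expect_equal(an3$df, c(2, length(values) - 3))
  expect_equal(nrow(an3$posthoc), 3L)
  expect_equal(an3$adjusted_alpha, 0.05 / 3)
  # identical groups
  expect_equal(one_way_anova(list(a = c(1, 2, 3), b = c(1, 2, 3)))$F, 0,
               tolerance = 1e-12)
})

test_that("TOST verdicts flip across the equivalence bound and are
           exchange-invariant", {
  with_seed(5, {
    x <- rnorm(50, 0, 0.5)
    y0 <- rnorm(50, 0, 0.5)
  })
  eq <- tost_equivalence(x, y0, interval = c(-0.7, 0.7), alpha = 0.008)
  expect_identical(eq$verdict, "equivalent")
  expect_true(all(eq$p < 0.008))
  # a true difference on the bound cannot demonstrate equivalence
  ne <- tost_equivalence(x + 0.7, y0, interval = c(-0.7, 0.7), alpha = 0.008)
  expect_identical(ne$verdict, "not demonstrated")
  # exchanging the series does not change the verdict
  eq_sw <- tost_equivalence(y0, x, interval = c(-0.7, 0.7), alpha = 0.008)
  expect_identical(eq$verdict, eq_sw$verdict)
  expect_error(tost_equivalence(x, y0, interval = c(1, -1)), "lower < upper")
})

test_that("Monte-Carlo normality test accepts normal and rejects skewed
           samples", {
  with_seed(21, {
    xn <- rnorm(200)
    xe <- rexp(200)
  })
  rn <- ks_normality(xn, n_sim = 499)
  re <- ks_normality(xe, n_sim = 499)
  expect_gt(rn$p, 0.05)
  expect_lt(re$p, 0.05)
  expect_error(ks_normality(rep(1, 10)), "constant")
  expect_error(ks_normality(c(1, 2, 3)), "n >= 5")
})

test_that("pearson correlation matches the closed form on a 5-point table", {
  x <- c(1, 2, 4, 5, 8)
  y <- c(2, 3, 3, 6, 9)
  pc <- pearson_correlation(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pc$r, r_hand, tolerance = 1e-12)
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(pc$p, 2 * pt(-abs(t_hand), 3), tolerance = 1e-12)
  expect_equal(pearson_correlation(x, 2 * x)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  expect_error(pearson_correlation(x, rep(1, 5)), "constant")
})

test_that("rater agreement report degrades with perturbation magnitude", {
  tpl <- small_template()
  ids <- list(right = 11L, left = 12L)
  subjects <- lapply(1:3, function(i) {
    sample_subject(tpl, cohort_spec(c(h = 1), icv_cv = 0, seed = i),
                   subject_seed = 100 + i)$labels
  })
  rounds <- list(reference = subjects)
  for (mag in c(0.5, 1.5, 3)) {
    rounds[[paste0("rater_", mag)]] <- lapply(seq_along(subjects), function(i) {
      l <- perturb_delineation(subjects[[i]], 11L, mag, seed = 50 + i)
      perturb_delineation(l, 12L, mag, seed = 80 + i)
    })
  }
  rep <- rater_agreement_report(rounds, ids)
  expect_equal(nrow(rep), 8L)                   # 4 sets x 2 sides
  expect_true(all(is.na(rep$mean_jc[rep$set == "reference"])))
  jc_r <- rep$mean_jc[rep$side == "right" & rep$set != "reference"]
  expect_true(all(diff(jc_r) < 0))              # monotone decay
  # a round compared against itself scores perfect overlap
  self <- rater_agreement_report(list(a = subjects, b = subjects), ids)
  expect_true(all(self$mean_jc[self$set == "b"] == 1))
})
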