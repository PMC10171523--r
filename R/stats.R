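# Statistical validation layer: agreement statistics, Bland-Altman,
# pooled t tests (raw and summary dialects), one-way ANOVA with Bonferroni
# post-hocs, TOST equivalence, normality, correlation.

#' Bland-Altman agreement analysis
#'
#' Per-pair means against differences, with limits of agreement at the mean
#' difference plus/minus 1.96 standard deviations, and a proportional-bias
#' check as the Pearson correlation of pair means with differences. The
#' `relative` dialect expresses differences as a percentage of the pair
#' mean.
#'
#' @param x,y Paired measurement series (same length, `n >= 3`), or `x` a
#'   two-column matrix/data.frame.
#' @param dialect `"absolute"` (`x - y`) or `"relative"`
#'   (`(x - y) / mean * 100`).
#' @return Object of class `bland_altman`: means, differences, mean
#'   difference, SD, limits of agreement, proportional-bias `r` and `p`
#'   (`NA` when differences are constant).
#' @export
bland_altman <- function(x, y = NULL, dialect = c("absolute", "relative")) {
  dialect <- match.arg(dialect)
  if (is.null(y)) {
    x <- as.matrix(x)
    stopifnot(ncol(x) == 2)
    y <- x[, 2]
    x <- x[, 1]
  }
  if (length(x) != length(y)) stop("paired series must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("Bland-Altman analysis needs at least 3 pairs")
  means <- (x + y) / 2
  diffs <- switch(dialect, absolute = x - y,
                  relative = (x - y) / means * 100)
  md <- mean(diffs)
  sdd <- sd(diffs)
  loa <- md + c(-1.96, 1.96) * sdd
  if (sdd == 0 || sd(means) == 0) {
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- stats::cor.test(means, diffs)
    r <- unname(ct$estimate)
    p <- ct$p.value
  }
  structure(list(means = means, diffs = diffs, mean_diff = md, sd_diff = sdd,
                 loa = loa, bias_r = r, bias_p = p, dialect = dialect,
                 n = length(x)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("Bland-Altman (", x$dialect, " differences, n = ", x$n, ")\n", sep = "")
  cat("  mean difference:", signif(x$mean_diff, 4),
      " SD:", signif(x$sd_diff, 4), "\n")
  cat("  limits of agreement: [", signif(x$loa[1], 4), ",",
      signif(x$loa[2], 4), "]\n")
  if (is.na(x$bias_r)) cat("  proportional bias: not applicable\n")
  else cat("  proportional bias: r =", signif(x$bias_r, 3),
           ", p =", signif(x$bias_p, 3), "\n")
  invisible(x)
}

#' Plot method for Bland-Altman results
#'
#' Pair means against differences with the mean difference and the 1.96-SD
#' limits of agreement.
#'
#' @param x A `bland_altman` object.
#' @param ... Passed to [plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs, xlab = "pair mean", ylab = "difference",
                 ...)
  graphics::abline(h = x$mean_diff, col = "blue")
  graphics::abline(h = x$loa, col = "red")
  invisible(x)
}

new_t_result <- function(t, df, p, dialect, mean_diff) {
  structure(list(t = t, df = df, p = p, dialect = dialect,
                 mean_diff = mean_diff),
            class = "pooled_t_result")
}

#' @export
print.pooled_t_result <- function(x, ...) {
  cat("pooled two-sample t (", x$dialect, "): t = ", signif(x$t, 4),
      ", df = ", x$df, ", p = ", signif(x$p, 4), "\n", sep = "")
  invisible(x)
}

#' Pooled two-sample t test from summary statistics
#'
#' Pooled-variance two-sided t test computed from group means, standard
#' deviations and sizes, with `df = n1 + n2 - 2`.
#'
#' @param mean1,sd1,n1 First group summaries.
#' @param mean2,sd2,n2 Second group summaries.
#' @return A `pooled_t_result` (fields `t`, `df`, `p`).
#' @export
pooled_t_from_summaries <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (sd1 < 0 || sd2 < 0 || (sd1 == 0 && sd2 == 0)) {
    stop("degenerate variances: at least one SD must be positive")
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(t), df)
  new_t_result(t, df, p, "summary-statistics pooled", mean1 - mean2)
}

#' Pooled two-sample t test on raw data
#'
#' Identical to [pooled_t_from_summaries()] applied to the exact sample
#' summaries.
#'
#' @param x,y Numeric series, each `n >= 2`.
#' @return A `pooled_t_result`.
#' @export
two_sample_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  res <- pooled_t_from_summaries(mean(x), sd(x), length(x),
                                 mean(y), sd(y), length(y))
  res$dialect <- "raw-data pooled"
  res
}

#' One-way ANOVA with Bonferroni pairwise post-hocs
#'
#' Standard one-way fixed-effects F test, followed by pairwise pooled
#' two-sample t tests with Bonferroni-adjusted p values.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each `n >= 2`).
#' @param alpha Family significance threshold before adjustment.
#' @return Object of class `anova_result` with `F`, `df`, `p` and a
#'   `posthoc` table.
#' @export
one_way_anova <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(vapply(groups, length, 1L) < 2)) stop("each group needs n >= 2")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), vapply(groups, length, 1L)),
                levels = names(groups))
  if (sd(values) == 0) {
    Fstat <- 0
    df1 <- length(groups) - 1L
    df2 <- length(values) - length(groups)
    p <- 1
  } else {
    ow <- stats::oneway.test(values ~ fac, var.equal = TRUE)
    Fstat <- unname(ow$statistic)
    df1 <- unname(ow$parameter[1])
    df2 <- unname(ow$parameter[2])
    p <- ow$p.value
  }
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  ph <- do.call(rbind, lapply(pairs, function(pr) {
    tt <- two_sample_t(groups[[pr[1]]], groups[[pr[2]]])
    data.frame(group1 = pr[1], group2 = pr[2], t = tt$t, df = tt$df,
               p = tt$p, p_adjusted = min(1, tt$p * length(pairs)),
               stringsAsFactors = FALSE)
  }))
  ph$significant <- ph$p_adjusted < alpha
  structure(list(F = Fstat, df = c(df1, df2), p = p, posthoc = ph,
                 alpha = alpha, adjusted_alpha = alpha / length(pairs)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("one-way ANOVA: F(", x$df[1], ", ", x$df[2], ") = ", signif(x$F, 4),
      ", p = ", signif(x$p, 4), "\n", sep = "")
  cat("pairwise pooled t (Bonferroni-adjusted):\n")
  print(x$posthoc, digits = 4, row.names = FALSE)
  invisible(x)
}

#' TOST equivalence test
#'
#' Two one-sided pooled t tests of the mean difference against the bounds
#' of a pre-specified equivalence interval; equivalence is declared when
#' both one-sided tests reject at `alpha`.
#'
#' @param x,y Numeric series, each `n >= 2`.
#' @param interval Length-2 equivalence interval, lower < upper.
#' @param alpha One-sided significance level (after any Bonferroni
#'   adjustment by the caller).
#' @return Object of class `tost_result` with one-sided t statistics,
#'   p values and the verdict (`"equivalent"` or `"not demonstrated"`).
#' @export
tost_equivalence <- function(x, y, interval = c(-0.7, 0.7), alpha = 0.05) {
  if (interval[1] >= interval[2]) stop("equivalence interval must have lower < upper")
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("both series need n >= 2")
  if (sd(x) == 0 && sd(y) == 0) stop("degenerate input: no variance")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd(x)^2 + (n2 - 1) * sd(y)^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  d <- mean(x) - mean(y)
  t_lower <- (d - interval[1]) / se   # H0: d <= lower
  t_upper <- (d - interval[2]) / se   # H0: d >= upper
  p_lower <- pt(t_lower, df, lower.tail = FALSE)
  p_upper <- pt(t_upper, df, lower.tail = TRUE)
  verdict <- if (p_lower < alpha && p_upper < alpha) "equivalent"
             else "not demonstrated"
  structure(list(mean_diff = d, se = se, df = df, interval = interval,
                 t = c(lower = t_lower, upper = t_upper),
                 p = c(lower = p_lower, upper = p_upper),
                 alpha = alpha, verdict = verdict),
            class = "tost_result")
}

#' @export
print.tost_result <- function(x, ...) {
  cat("TOST equivalence vs [", x$interval[1], ",", x$interval[2], "]:\n")
  cat("  mean difference:", signif(x$mean_diff, 4), "\n")
  cat("  one-sided p:", signif(x$p["lower"], 4), "/",
      signif(x$p["upper"], 4), " (alpha =", signif(x$alpha, 4), ")\n")
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' Normality test with estimated parameters
#'
#' One-sample Kolmogorov-Smirnov statistic against a normal distribution
#' with the sample's own mean and standard deviation, with the p value
#' calibrated by Monte-Carlo simulation under the estimated-parameter null
#' (Lilliefors-style), at a fixed seed.
#'
#' @param x Numeric series, `n >= 5`, non-constant.
#' @param n_sim Monte-Carlo replicates.
#' @param seed Simulation seed.
#' @return List with `statistic` and `p`.
#' @export
ks_normality <- function(x, n_sim = 1999, seed = 1L) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 5) stop("normality testing needs n >= 5")
  if (sd(x) == 0) stop("constant series: normality test undefined")
  stat_of <- function(v) {
    suppressWarnings(unname(
      stats::ks.test(v, "pnorm", mean(v), sd(v))$statistic))
  }
  D <- stat_of(x)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_sim), function(i) stat_of(rnorm(n)), 1) >= D)
  })
  list(statistic = D, p = (1 + exceed) / (n_sim + 1))
}

#' Two-tailed Pearson correlation
#'
#' @param x,y Numeric series, `n >= 3`, non-constant.
#' @return List with `r`, `p`, `df`.
#' @export
pearson_correlation <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input: correlation undefined")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value,
       df = unname(ct$parameter))
}

#' Rater-agreement report
#'
#' Summarises agreement of repeated delineations against a reference round:
#' per delineation set and side, the mean Jaccard coefficient, mean volume,
#' and mean absolute volume discrepancy, each with its coefficient of
#' variation across subjects.
#'
#' @param delineations Named list of delineation rounds; each round is a
#'   list of label volumes over the same subjects in the same order. The
#'   first round is the reference.
#' @param region_ids Named list `list(right = id, left = id)` of the region
#'   to evaluate.
#' @return data.frame with one row per round x side (reference round
#'   reports volumes only).
#' @export
rater_agreement_report <- function(delineations, region_ids) {
  if (length(delineations) < 2) stop("need at least two delineation rounds")
  ns <- vapply(delineations, length, 1L)
  if (length(unique(ns)) != 1) stop("rounds cover different subjects")
  ref <- delineations[[1]]
  rows <- list()
  for (ri in seq_along(delineations)) {
    rnd <- delineations[[ri]]
    for (side in c("right", "left")) {
      id <- region_ids[[side]]
      voxvol <- voxel_volume(rnd[[1]])
      vols <- vapply(rnd, function(l) sum(as.integer(l) == id) * voxvol, 1)
      if (ri == 1) {
        jc <- NA_real_; jc_cv <- NA_real_
        adv <- NA_real_; adv_cv <- NA_real_
      } else {
        jcs <- mapply(function(a, b) jaccard(a, b, ids = id), ref, rnd)
        ref_vols <- vapply(ref, function(l) sum(as.integer(l) == id) * voxvol, 1)
        dvs <- abs(signed_volume_discrepancy(ref_vols, vols))
        jc <- mean(jcs); jc_cv <- coefficient_of_variation(jcs)
        adv <- mean(dvs)
        adv_cv <- if (mean(dvs) > 0) coefficient_of_variation(dvs) else 0
      }
      rows[[paste(ri, side)]] <- data.frame(
        set = names(delineations)[ri], side = side, n = length(rnd),
        mean_jc = jc, jc_cv = jc_cv,
        mean_volume_mm3 = mean(vols),
        volume_cv = coefficient_of_variation(vols),
        mean_abs_delta_v = adv, abs_delta_v_cv = adv_cv,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
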