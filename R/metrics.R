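# Pairwise segmentation-agreement measures.

as_mask <- function(x, ids = NULL) {
  if (is.logical(x)) return(x)
  if (is.null(ids)) x != 0 else {
    m <- array(as.integer(x) %in% as.integer(ids), dim(x))
    m
  }
}

#' Jaccard overlap coefficient
#'
#' Intersection over union of two binary masks on the same grid. Two empty
#' masks agree perfectly and return 1.
#'
#' @param a,b Logical masks or label volumes (non-zero treated as mask),
#'   same grid.
#' @param ids Optional label ids defining the mask when `a`/`b` are label
#'   volumes.
#' @return Jaccard coefficient in `[0, 1]`.
#' @export
jaccard <- function(a, b, ids = NULL) {
  if (!identical(dim(a), dim(b))) stop("masks must share a grid")
  ma <- as_mask(a, ids)
  mb <- as_mask(b, ids)
  uni <- sum(ma | mb)
  if (uni == 0) return(1)
  sum(ma & mb) / uni
}

#' Dice coefficient from a Jaccard coefficient
#'
#' `Dice = 2 * JC / (1 + JC)`.
#'
#' @param jc Jaccard coefficient(s) in `[0, 1]`.
#' @export
dice_from_jaccard <- function(jc) {
  if (any(jc < 0 | jc > 1)) stop("Jaccard coefficients must lie in [0, 1]")
  2 * jc / (1 + jc)
}

#' Signed volume discrepancy
#'
#' `200 * (vol_ref - vol_test) / (vol_ref + vol_test)`: a symmetrised,
#' percent-like index bounded in `[-200, 200]`. Also used with left/right
#' volumes as (ref, test) to assess asymmetry.
#'
#' @param vol_ref,vol_test Non-negative volumes, not both zero.
#' @export
signed_volume_discrepancy <- function(vol_ref, vol_test) {
  if (any(vol_ref + vol_test <= 0)) stop("volumes must not both be zero")
  (vol_ref - vol_test) / (vol_ref + vol_test) * 200
}

#' Percent reduction of a test volume relative to a reference
#'
#' `(vol_ref - vol_test) / vol_ref * 100`.
#'
#' @param vol_ref Positive reference volume.
#' @param vol_test Test volume.
#' @export
percent_reduction <- function(vol_ref, vol_test) {
  if (any(vol_ref <= 0)) stop("reference volume must be positive")
  (vol_ref - vol_test) / vol_ref * 100
}

#' Coefficient of variation (percent)
#'
#' Sample standard deviation over mean, times 100.
#'
#' @param values Numeric vector, `n >= 2`, non-zero mean.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) stop("need at least two values")
  m <- mean(values)
  if (m == 0) stop("coefficient of variation undefined for zero mean")
  sd(values) / m * 100
}

# One agreement record comparing a test label volume against a reference.
agreement_record <- function(ref_labels, test_labels, ids, region, side,
                             comparison = "auto-vs-manual") {
  voxvol <- voxel_volume(ref_labels)
  mref <- as_mask(ref_labels, ids)
  mtest <- as_mask(test_labels, ids)
  vol_ref <- sum(mref) * voxvol
  vol_test <- sum(mtest) * voxvol
  jc <- jaccard(mref, mtest)
  dv <- if (vol_ref + vol_test > 0)
    signed_volume_discrepancy(vol_ref, vol_test) else NA_real_
  data.frame(region = region, side = side, comparison = comparison,
             jc = jc, dice = dice_from_jaccard(jc),
             delta_v = dv, abs_delta_v = abs(dv),
             vol_ref_mm3 = vol_ref, vol_test_mm3 = vol_test,
             stringsAsFactors = FALSE)
}
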