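# Multi-atlas label propagation and vote-rule decision fusion.

#' Atlas database
#'
#' An ordered collection of labelled subjects used as atlases.
#'
#' @param subjects List of `phantom_subject` entries (or a `phantom_cohort`,
#'   whose subjects are taken in order).
#' @param name Provenance label.
#' @return Object of class `atlas_db`.
#' @export
atlas_db <- function(subjects, name = "phantom-atlas-db") {
  if (inherits(subjects, "phantom_cohort")) subjects <- subjects$subjects
  if (length(subjects) < 1) stop("an atlas database needs at least one entry")
  menus <- lapply(subjects, function(s) s$spec$region_menu$id)
  if (!all(vapply(menus, identical, logical(1), y = menus[[1]]))) {
    stop("all atlases must share the region id vocabulary")
  }
  structure(list(subjects = subjects, name = name), class = "atlas_db")
}

#' @export
print.atlas_db <- function(x, ...) {
  cat("<atlas_db>", x$name, "with", length(x$subjects), "atlases\n")
  invisible(x)
}

#' Propagate one atlas's labels to a target
#'
#' Registers the atlas to the target (affine, then free-form deformation)
#' and transfers the atlas labels to the target grid with nearest-neighbour
#' interpolation.
#'
#' @param atlas,target `phantom_subject` objects.
#' @param params A [reg_params()].
#' @return Label volume on the target grid, with the `deformation_field`
#'   attached as attribute `"transform"`.
#' @export
propagate <- function(atlas, target, params = reg_params()) {
  aff <- affine_register(target, atlas, params)
  ffd <- ffd_register(target, atlas, init = aff, params = params)
  out <- warp_labels(atlas$labels, ffd)
  attr(out, "transform") <- ffd
  attr(out, "atlas_id") <- atlas$subject_id
  out
}

#' Vote-rule decision fusion
#'
#' Per-voxel plurality vote over propagated label volumes. Background
#' (label 0) competes like any other candidate; ties are broken
#' deterministically in favour of the smallest label id.
#'
#' @param propagated List of label volumes on a common grid.
#' @return Object of class `fusion_result`: fused `labels`, per-voxel
#'   `votes` for the winning label, and `n_atlases`.
#' @export
vote_fuse <- function(propagated) {
  if (length(propagated) < 1) stop("need at least one label volume")
  dm <- dim(propagated[[1]])
  for (p in propagated) {
    if (!identical(dim(p), dm)) stop("propagated label volumes must share a grid")
  }
  lab <- vapply(propagated, function(p) as.integer(p), integer(prod(dm)))
  if (is.null(dim(lab))) lab <- matrix(lab, nrow = 1L)
  res <- cpp_vote_fuse(lab)
  sp <- spacing_of(propagated[[1]])
  structure(
    list(labels = with_spacing(array(res$label, dm), sp),
         votes = with_spacing(array(res$votes, dm), sp),
         n_atlases = length(propagated)),
    class = "fusion_result"
  )
}

#' @export
print.fusion_result <- function(x, ...) {
  cat("<fusion_result>", x$n_atlases, "atlases;",
      sum(x$labels != 0), "foreground voxels\n")
  if (!is.null(x$records)) {
    cat("  agreement vs target truth:\n")
    print(x$records[, c("region", "side", "jc", "dice", "delta_v")],
          digits = 3)
  }
  invisible(x)
}

evaluated_regions <- function(menu) {
  unique(menu$name[menu$side %in% c("left", "right")])
}

# Agreement records of a fused (or single propagated) segmentation against
# the target's own labels, one row per region x side.
fusion_agreement <- function(target, fused_labels, comparison, target_id) {
  menu <- target$spec$region_menu
  recs <- list()
  for (nm in evaluated_regions(menu)) {
    for (side in c("right", "left")) {
      id <- menu$id[menu$name == nm & menu$side == side]
      recs[[paste(nm, side)]] <-
        agreement_record(target$labels, fused_labels, id, nm, side, comparison)
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out$target_id <- target_id
  out
}

#' Segment a target with the whole atlas database
#'
#' Propagates every atlas to the target and fuses the propagated label sets
#' by vote rule. Pairs whose registration is flagged as folded are excluded
#' with a warning rather than aborting the ensemble. When the target carries
#' its own labels, per-region agreement records are attached.
#'
#' @param db An [atlas_db()].
#' @param target A `phantom_subject`.
#' @param params A [reg_params()].
#' @param keep_propagated Retain the per-atlas propagated label volumes.
#' @return A `fusion_result` with agreement `records` and the estimated
#'   intracranial volume `icv_mm3` (fused non-background volume).
#' @export
segment_target <- function(db, target, params = reg_params(),
                           keep_propagated = FALSE) {
  props <- list()
  for (atl in db$subjects) {
    p <- tryCatch(propagate(atl, target, params), error = function(e) e)
    if (inherits(p, "error")) {
      warning("propagation of atlas ", atl$subject_id, " failed (",
              conditionMessage(p), "); pair excluded from fusion")
      next
    }
    tr <- attr(p, "transform")
    if (isTRUE(tr$folded)) {
      warning("propagation of atlas ", atl$subject_id,
              " folded; pair excluded from fusion")
      next
    }
    props[[atl$subject_id]] <- p
  }
  if (!length(props)) stop("all atlas-target pairs failed")
  fused <- vote_fuse(props)
  fused$target_id <- target$subject_id
  fused$icv_mm3 <- sum(fused$labels != 0) * voxel_volume(fused$labels)
  if (!is.null(target$labels)) {
    fused$records <- fusion_agreement(target, fused$labels, "auto-vs-manual",
                                      target$subject_id)
    fused$per_atlas_records <- do.call(rbind, lapply(names(props), function(id) {
      r <- fusion_agreement(target, props[[id]], "single-atlas",
                            target$subject_id)
      r$atlas_id <- id
      r
    }))
  }
  if (keep_propagated) fused$propagated <- props
  fused
}

#' Leave-one-out cross-comparison over an atlas database
#'
#' Each entry is segmented using all remaining entries; agreement between
#' the fused automatic labels and the entry's own labels is recorded per
#' region and side.
#'
#' @param db An [atlas_db()] with at least two entries.
#' @param params A [reg_params()].
#' @param progress Print one line per completed target.
#' @return data.frame of agreement records (`target_id`, `region`, `side`,
#'   `n_atlases`, `jc`, `dice`, `delta_v`, `abs_delta_v`, `vol_ref_mm3`,
#'   `vol_test_mm3`), plus fused ICV per target in attribute `"icv"`.
#' @export
leave_one_out <- function(db, params = reg_params(), progress = FALSE) {
  n <- length(db$subjects)
  if (n < 2) stop("leave-one-out needs at least two atlases")
  recs <- list()
  icv <- data.frame(target_id = character(0), icv_mm3 = numeric(0),
                    true_icv_mm3 = numeric(0))
  for (i in seq_len(n)) {
    target <- db$subjects[[i]]
    sub_db <- atlas_db(db$subjects[-i], name = paste0(db$name, "-loo"))
    fused <- segment_target(sub_db, target, params)
    r <- fused$records
    r$n_atlases <- fused$n_atlases
    recs[[i]] <- r
    icv <- rbind(icv, data.frame(target_id = target$subject_id,
                                 icv_mm3 = fused$icv_mm3,
                                 true_icv_mm3 = target$icv_mm3))
    if (progress) {
      message("leave-one-out ", i, "/", n, ": ", target$subject_id,
              " mean JC = ", signif(mean(r$jc), 3))
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out <- out[, c("target_id", "region", "side", "n_atlases", "jc", "dice",
                 "delta_v", "abs_delta_v", "vol_ref_mm3", "vol_test_mm3")]
  attr(out, "icv") <- icv
  out
}
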