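# Raw and ICV-normalised volumetry.

#' Volume of a label id set
#'
#' Voxel count of the ids times the voxel volume.
#'
#' @param labels Integer label volume with spacing.
#' @param region_ids Non-empty set of label ids.
#' @return Volume in mm^3.
#' @export
region_volume <- function(labels, region_ids) {
  if (length(region_ids) < 1) stop("region id set must not be empty")
  sum(as.integer(labels) %in% as.integer(region_ids)) * voxel_volume(labels)
}

#' Estimate intracranial volume by brain-mask fusion
#'
#' Propagates every atlas's brain mask (all non-background labels) to the
#' target through the usual registration chain and fuses them by vote rule;
#' the ICV estimate is the fused mask volume. When a `fusion_result` for
#' this target is supplied the already-propagated labels are reused.
#'
#' @param target A `phantom_subject`.
#' @param db An [atlas_db()].
#' @param params A [reg_params()].
#' @param fusion Optional `fusion_result` from [segment_target()] on the
#'   same target, to avoid re-registering.
#' @return Estimated ICV in mm^3.
#' @export
estimate_icv <- function(target, db, params = reg_params(), fusion = NULL) {
  if (is.null(fusion)) fusion <- segment_target(db, target, params)
  sum(fusion$labels != 0) * voxel_volume(fusion$labels)
}

#' ICV-corrected volume
#'
#' Region volume divided by intracranial volume, scaled by 10^4 for ease of
#' reading.
#'
#' @param volume_mm3 Region volume (mm^3).
#' @param icv_mm3 Positive intracranial volume (mm^3).
#' @export
icv_correct <- function(volume_mm3, icv_mm3) {
  if (any(icv_mm3 <= 0)) stop("ICV must be positive")
  volume_mm3 / icv_mm3 * 1e4
}

#' Cohort volume table
#'
#' Assembles one `VolumeRecord` row per subject x region x side x source:
#' manual-truth rows from the subjects' own labels and ICV, automatic rows
#' from the fused segmentations and fused-mask ICV estimates.
#'
#' @param subjects List of `phantom_subject` (or a `phantom_cohort`).
#' @param segmentations Named list of `fusion_result`, one per subject id.
#' @param regions Region names to tabulate (default: all paired regions).
#' @return data.frame with columns `subject_id`, `group`, `lateralisation`,
#'   `region`, `side`, `source`, `volume_mm3`, `icv_mm3`, `icv_corrected`.
#' @export
cohort_volume_table <- function(subjects, segmentations, regions = NULL) {
  if (inherits(subjects, "phantom_cohort")) subjects <- subjects$subjects
  rows <- list()
  for (sub in subjects) {
    seg <- segmentations[[sub$subject_id]]
    if (is.null(seg)) stop("missing segmentation for subject ", sub$subject_id)
    menu <- sub$spec$region_menu
    regs <- regions %||% evaluated_regions(menu)
    for (nm in regs) {
      for (side in c("right", "left")) {
        id <- menu$id[menu$name == nm & menu$side == side]
        man_v <- region_volume(sub$labels, id)
        aut_v <- region_volume(seg$labels, id)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sub$subject_id, group = sub$group,
          lateralisation = sub$lateralisation, region = nm, side = side,
          source = c("manual-truth", "automatic"),
          volume_mm3 = c(man_v, aut_v),
          icv_mm3 = c(sub$icv_mm3, seg$icv_mm3),
          icv_corrected = c(icv_correct(man_v, sub$icv_mm3),
                            icv_correct(aut_v, seg$icv_mm3)),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relabel sides as ipsilateral/contralateral
#'
#' For laterised designs, recodes `side` so that the side matching each
#' subject's lateralisation becomes `"ipsi"` and the other `"contra"`.
#' Subjects without lateralisation are dropped.
#'
#' @param volume_table Output of [cohort_volume_table()].
#' @return The table with a recoded `side` column.
#' @export
lateralise_sides <- function(volume_table) {
  keep <- volume_table$lateralisation %in% c("left", "right")
  vt <- volume_table[keep, , drop = FALSE]
  vt$side <- ifelse(vt$side == vt$lateralisation, "ipsi", "contra")
  vt
}
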