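# NIfTI and table I/O.

#' Read a NIfTI volume
#'
#' Reads a 3D NIfTI-1 file, preserving grid and spacing metadata. With
#' `labels = TRUE` the values are validated as integers and returned as an
#' integer label volume.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param labels Validate and return integer labels.
#' @return 3D array with a `spacing` attribute.
#' @export
read_volume <- function(path, labels = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  a <- array(as.numeric(img), dim(img)[1:3])
  if (labels) {
    if (any(abs(a - round(a)) > 1e-6)) {
      stop("non-integer values in label file: ", path)
    }
    a <- array(as.integer(round(a)), dim(a))
  }
  with_spacing(a, sp)
}

#' Write a volume to NIfTI
#'
#' @param volume 3D array with a `spacing` attribute (labels are written as
#'   integers, intensities as float).
#' @param path Output path (.nii or .nii.gz).
#' @export
write_volume <- function(volume, path) {
  sp <- spacing_of(volume)
  storage <- if (is.integer(volume)) "uint16" else "float"
  a <- array(volume, dim(volume))
  attr(a, "pixdim") <- sp
  img <- RNifti::asNifti(a, datatype = storage)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a deformation field as a 4D NIfTI displacement volume
#' @param field A `deformation_field`.
#' @param path Output path.
#' @export
write_deformation <- function(field, path) {
  a <- field$disp
  attr(a, "pixdim") <- c(field$fixed_spacing, 1)
  img <- RNifti::asNifti(a, datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write/read a 4x4 affine as a plain-text matrix
#' @param transform An `affine_transform`.
#' @param path Text file path.
#' @export
write_affine <- function(transform, path) {
  write.table(format(unclass(transform)[1:4, 1:4], digits = 17),
              path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_affine
#' @param fixed,moving Grid metadata donors (see [affine_register()]).
#' @export
read_affine <- function(path, fixed, moving) {
  m <- as.matrix(read.table(path))
  dimnames(m) <- NULL
  new_affine(m, as_reg_image(fixed), as_reg_image(moving))
}

#' Write one subject's volumes to a directory
#'
#' Writes intensity, labels and per-tissue probability NIfTIs, named by the
#' subject id.
#'
#' @param subject A `phantom_subject`.
#' @param dir Output directory (created if needed).
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, subject$subject_id)
  write_volume(subject$intensity, paste0(stem, "_t1.nii.gz"))
  lab <- subject$labels
  storage.mode(lab) <- "integer"
  write_volume(lab, paste0(stem, "_labels.nii.gz"))
  for (tn in names(subject$tissue_probs)) {
    write_volume(subject$tissue_probs[[tn]],
                 paste0(stem, "_prob_", tn, ".nii.gz"))
  }
  invisible(stem)
}

#' Read pipeline configuration
#'
#' JSON configuration mirroring the phantom/cohort/registration parameter
#' blocks. Unknown keys are errors.
#'
#' @param path JSON file.
#' @return Named list of validated configuration blocks.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("phantom", "cohort", "registration", "seed", "stages", "out_dir",
             "atlas_group", "target_groups", "verbosity")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stop("unknown configuration keys: ",
                          paste(extra, collapse = ", "))
  cfg
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}
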