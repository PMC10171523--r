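# Shared helpers: voxel grids, spacing bookkeeping, seeds.

#' Attach voxel spacing to a 3D array
#'
#' Volumes in this package are plain 3D arrays carrying a `"spacing"`
#' attribute (mm per voxel along each axis). World coordinates are
#' `(index - 1) * spacing` on an axis-aligned RAS+ grid.
#'
#' @param data 3D array.
#' @param spacing Numeric length-3, mm per voxel (recycled if length 1).
#' @return The array with a `spacing` attribute.
#' @export
with_spacing <- function(data, spacing) {
  stopifnot(length(dim(data)) == 3L)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("voxel spacing must be positive")
  attr(data, "spacing") <- spacing
  data
}

#' Voxel spacing of a volume
#' @param x 3D array with (optional) `spacing` attribute.
#' @return Numeric length-3 spacing in mm (1 mm isotropic if unset).
#' @export
spacing_of <- function(x) {
  sp <- attr(x, "spacing")
  if (is.null(sp)) c(1, 1, 1) else rep_len(as.numeric(sp), 3L)
}

#' Volume of one voxel in mm^3
#' @param x 3D array with spacing attribute.
#' @export
voxel_volume <- function(x) prod(spacing_of(x))

# World coordinates (mm) of every voxel centre, as three vectors in
# column-major voxel order.
grid_world <- function(dim, spacing) {
  dim <- as.integer(dim)
  list(
    x = rep.int((seq_len(dim[1]) - 1) * spacing[1], dim[2] * dim[3]),
    y = rep.int(rep((seq_len(dim[2]) - 1) * spacing[2], each = dim[1]), dim[3]),
    z = rep((seq_len(dim[3]) - 1) * spacing[3], each = dim[1] * dim[2])
  )
}

same_grid <- function(a, b) {
  identical(dim(a), dim(b)) &&
    isTRUE(all.equal(spacing_of(a), spacing_of(b), tolerance = 1e-9))
}

#' Derive a stage seed from a global seed
#'
#' Deterministic integer hash of `(seed, label)`, kept below 2^31 so it is a
#' valid R seed. Every stochastic stage of the pipeline derives its own seed
#' this way, which makes full runs reproducible from one global seed.
#'
#' @param seed Integer global seed.
#' @param label Character stage label.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, label) {
  h <- as.double(seed %% 2147483647)
  for (code in utf8ToInt(as.character(label))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Gaussian smoothing of a 3D array, sigma in mm.
smooth3d <- function(x, sigma_mm) {
  sp <- spacing_of(x)
  out <- cpp_gaussian_smooth(as.numeric(x), dim(x), rep_len(sigma_mm, 3L) / sp)
  out <- array(out, dim(x))
  with_spacing(out, sp)
}
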