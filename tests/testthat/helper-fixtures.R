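# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

# Small reference-head template (48^3 at 2 mm; same physical head as the
# default 96 mm field of view).
small_template <- function() {
  if (is.null(.fixtures$tpl48)) {
    .fixtures$tpl48 <- make_template_phantom(
      phantom_spec(grid_shape = 48, voxel_spacing_mm = 2, seed = 3L))
  }
  .fixtures$tpl48
}

# Mid-size template used by the registration checks (64^3 at 1.5 mm).
reg_template <- function() {
  if (is.null(.fixtures$tpl64)) {
    .fixtures$tpl64 <- make_template_phantom(
      phantom_spec(grid_shape = 64, voxel_spacing_mm = 1.5, seed = 3L))
  }
  .fixtures$tpl64
}

# Random small label volumes for fusion/overlap oracles.
random_labels <- function(dm, n_labels, spacing = c(1, 1, 1)) {
  with_spacing(array(sample.int(n_labels + 1L, prod(dm), replace = TRUE) - 1L,
                     dm), spacing)
}

random_mask <- function(dm, p = 0.5) {
  with_spacing(array(runif(prod(dm)) < p, dm), c(1, 1, 1))
}

# Brute-force per-voxel plurality vote with smallest-id tie-break.
brute_vote <- function(mats) {
  dm <- dim(mats[[1]])
  out <- array(0L, dm)
  for (i in seq_len(prod(dm))) {
    vals <- vapply(mats, function(m) m[[i]], integer(1))
    tab <- table(vals)
    best <- max(tab)
    out[i] <- min(as.integer(names(tab)[tab == best]))
  }
  out
}
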