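# Synthetic head phantom: template geometry and intensity rendering.
#
# The template emulates the layout of a manually labelled atlas head at desk
# scale: a brain ellipsoid filled with white-matter analogue, a reduced menu
# of bilateral grey-matter regions around the mesial temporal/frontal
# junction, and a thin curved slab as the piriform-cortex analogue. The slab
# sits on an ellipsoidal shell, bordered below by a CSF cleft (background),
# so that it touches the amygdala-, parahippocampal-, insula- and
# orbital-analogues as well as background, mirroring the neighbour set from
# which the region is relabelled in real atlas work.

#' Default region menu
#'
#' Bilateral region descriptors for the phantom. Right-sided ids are odd and
#' the matching left id is `right id + 1`; id 90 is the brain-tissue filler
#' whose voxel count defines the phantom's intracranial volume; id 0 is
#' background. `target_volume_mm3` is the nominal per-side volume at the
#' reference head size (96 mm field of view); actual painted volumes of the
#' neighbour regions vary with clipping, only the piriform target is enforced.
#'
#' @return data.frame with columns `id`, `name`, `side`, `target_volume_mm3`.
#' @export
default_region_menu <- function() {
  data.frame(
    id = c(11L, 12L, 3L, 4L, 1L, 2L, 9L, 10L, 21L, 22L, 71L, 72L, 90L),
    name = c("piriform", "piriform", "amygdala", "amygdala",
             "hippocampus", "hippocampus", "parahippocampal",
             "parahippocampal", "insula", "insula", "orbital", "orbital",
             "brain"),
    side = c("right", "left", "right", "left", "right", "left", "right",
             "left", "right", "left", "right", "left", "both"),
    target_volume_mm3 = c(470, 470, 900, 900, 1150, 1150, 1100, 1100,
                          1000, 1000, 900, 900, NA),
    stringsAsFactors = FALSE
  )
}

#' Phantom specification
#'
#' @param grid_shape Integer length-3 (or 1, recycled), voxels per axis;
#'   each must be at least 32.
#' @param voxel_spacing_mm Numeric length-3 (or 1), mm per voxel.
#' @param region_menu Region descriptor table, see [default_region_menu()].
#' @param tissue_means Named intensities for tissue classes `background`,
#'   `gm`, `wm`.
#' @param noise_sd Additive Gaussian intensity noise (before bias).
#' @param bias_amplitude Relative amplitude of the smooth multiplicative
#'   bias field; the field takes values in `1 +- bias_amplitude`.
#' @param prob_sigma_mm Gaussian blur (mm) applied to tissue memberships to
#'   form the probability maps.
#' @param seed Integer seed for intensity rendering.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 96L),
                         voxel_spacing_mm = 1,
                         region_menu = default_region_menu(),
                         tissue_means = c(background = 0, gm = 70, wm = 110),
                         noise_sd = 4,
                         bias_amplitude = 0.1,
                         prob_sigma_mm = 1.2,
                         seed = 1L) {
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  voxel_spacing_mm <- rep_len(as.numeric(voxel_spacing_mm), 3L)
  if (any(grid_shape < 32L)) stop("grid_shape must be at least 32 voxels per axis")
  if (any(voxel_spacing_mm <= 0)) stop("voxel_spacing_mm must be positive")
  ids <- region_menu$id
  if (anyDuplicated(ids) || any(ids <= 0)) {
    stop("region ids must be unique and positive (0 is reserved for background)")
  }
  paired <- region_menu[region_menu$side %in% c("left", "right"), ]
  for (nm in unique(paired$name)) {
    pr <- paired[paired$name == nm, ]
    r_id <- pr$id[pr$side == "right"]
    l_id <- pr$id[pr$side == "left"]
    if (length(r_id) != 1L || length(l_id) != 1L || r_id %% 2L != 1L ||
        l_id != r_id + 1L) {
      stop("left/right pair for '", nm,
           "' must use the odd (right) / even (left) id convention")
    }
  }
  if (!all(c("background", "gm", "wm") %in% names(tissue_means))) {
    stop("tissue_means must name background, gm and wm classes")
  }
  structure(
    list(grid_shape = grid_shape, voxel_spacing_mm = voxel_spacing_mm,
         region_menu = region_menu, tissue_means = tissue_means,
         noise_sd = noise_sd, bias_amplitude = bias_amplitude,
         prob_sigma_mm = prob_sigma_mm, seed = as.integer(seed),
         geom_cache = new.env(parent = emptyenv())),
    class = "phantom_spec"
  )
}

#' Evaluate code under a temporary RNG state
#'
#' Sets the seed, runs the expression, and restores the caller's random
#' number generator state afterwards.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The expression's value.
#' @export
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

region_ids <- function(menu, name, side = c("both", "left", "right")) {
  side <- match.arg(side)
  rows <- menu[menu$name == name, , drop = FALSE]
  if (nrow(rows) == 0L) stop("region '", name, "' is not in the menu")
  if (side != "both") rows <- rows[rows$side %in% c(side, "both"), , drop = FALSE]
  rows$id
}

unit <- function(v) v / sqrt(sum(v^2))

# The phantom's geometry lives in continuous template-world coordinates
# (mm): every region is an implicit surface, so labels can be rasterised at
# arbitrary coordinates. The slab's sector angle is calibrated once per
# spec against its own grid.

# Deterministic geometry parameters; the slab angle is calibrated on the
# spec's own grid and memoised.
phantom_geometry <- function(spec) {
  cache <- spec$geom_cache
  if (!is.null(cache) && !is.null(cache$geom)) return(cache$geom)
  dm <- spec$grid_shape
  sp <- spec$voxel_spacing_mm
  fov <- dm * sp
  s <- prod(fov)^(1 / 3) / 96
  voxvol <- prod(sp)
  menu <- spec$region_menu
  geom <- list(s = s, fov = fov, bc = fov * c(0.5, 0.52, 0.5),
               ba = fov * c(0.40, 0.45, 0.38), sides = list())
  g <- grid_world(dm, sp)
  brain <- ((g$x - geom$bc[1]) / geom$ba[1])^2 +
    ((g$y - geom$bc[2]) / geom$ba[2])^2 +
    ((g$z - geom$bc[3]) / geom$ba[3])^2 <= 1
  sphere_radius <- function(target) (3 * target * s^3 / (4 * pi))^(1 / 3)

  for (side in c("right", "left")) {
    sgn <- if (side == "right") 1 else -1
    tgt_of <- function(name) {
      menu$target_volume_mm3[menu$name == name & menu$side == side]
    }
    C <- c(fov[1] * (0.5 + sgn * 0.17), fov[2] * 0.56, fov[3] * 0.46)
    semi <- 96 * s * c(0.115, 0.066, 0.115)
    rbar <- prod(semi)^(1 / 3)
    d_pc <- unit(c(sgn * 0.55, 0.15, -0.82))
    t2 <- unit(c(-d_pc[1] * d_pc[2], 1 - d_pc[2]^2, -d_pc[3] * d_pc[2]))
    t3 <- unit(c(d_pc[2] * t2[3] - d_pc[3] * t2[2],
                 d_pc[3] * t2[1] - d_pc[1] * t2[3],
                 d_pc[1] * t2[2] - d_pc[2] * t2[1]))
    rot <- function(a, t, ang) unit(cos(ang) * a + sin(ang) * t)
    nb_dirs <- list(
      parahippocampal = rot(d_pc, -t2, 1.0),
      insula = rot(d_pc, t3, 1.09),
      orbital = rot(d_pc, t2, 1.12),
      amygdala = rot(d_pc, -t3, 1.06)
    )
    nb <- lapply(names(nb_dirs), function(nm) {
      dn <- nb_dirs[[nm]]
      list(name = nm, ctr = C + dn / sqrt(sum((dn / semi)^2)),
           r = sphere_radius(tgt_of(nm)))
    })
    hsemi0 <- c(6.5, 8, 5.5)
    k <- (tgt_of("hippocampus") * s^3 / (4 / 3 * pi * prod(hsemi0)))^(1 / 3)

    # calibrate the slab sector half-angle against the spec's grid
    dx <- g$x - C[1]; dy <- g$y - C[2]; dz <- g$z - C[3]
    rho <- sqrt((dx / semi[1])^2 + (dy / semi[2])^2 + (dz / semi[3])^2)
    rr <- pmax(sqrt(dx^2 + dy^2 + dz^2), 1e-9)
    cosang <- (dx * d_pc[1] + dy * d_pc[2] + dz * d_pc[3]) / rr
    t_rho <- 3.2 * s / rbar
    band <- abs(rho - 1) <= t_rho / 2 & brain
    target_n <- round(tgt_of("piriform") * s^3 / voxvol)
    count_at <- function(theta) sum(band & cosang >= cos(theta))
    lo <- 0.05; hi <- 1.45
    if (count_at(hi) < target_n) {
      stop("grid too small to fit region 'piriform' at its target volume")
    }
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (count_at(mid) < target_n) lo <- mid else hi <- mid
    }
    theta <- hi
    if (abs(count_at(theta) - target_n) / target_n > 0.05) {
      stop("grid too small to fit region 'piriform' at its target volume")
    }

    geom$sides[[side]] <- list(
      sgn = sgn, C = C, semi = semi, rbar = rbar, d_pc = d_pc,
      theta = theta, t_rho = t_rho, cleft_rho = 1.7 * s / rbar,
      nb = nb, hc = C + s * c(sgn * 5, -25, -4), hsemi = hsemi0 * k
    )
  }
  if (!is.null(cache)) cache$geom <- geom
  geom
}

#' Rasterise the phantom labels at arbitrary template-space coordinates
#'
#' Evaluates the template's continuous region geometry at the given
#' template-world coordinates (mm).
#'
#' @param spec A [phantom_spec()].
#' @param cx,cy,cz Coordinate vectors in template-world mm.
#' @return Integer label vector.
#' @export
paint_at <- function(spec, cx, cy, cz) {
  menu <- spec$region_menu
  geom <- phantom_geometry(spec)
  g <- list(x = cx, y = cy, z = cz)
  lab <- integer(length(cx))
  brain <- ((g$x - geom$bc[1]) / geom$ba[1])^2 +
    ((g$y - geom$bc[2]) / geom$ba[2])^2 +
    ((g$z - geom$bc[3]) / geom$ba[3])^2 <= 1
  lab[brain] <- 90L
  for (side in c("right", "left")) {
    G <- geom$sides[[side]]
    id_of <- function(name) menu$id[menu$name == name & menu$side == side]
    hip <- ((g$x - G$hc[1]) / G$hsemi[1])^2 + ((g$y - G$hc[2]) / G$hsemi[2])^2 +
      ((g$z - G$hc[3]) / G$hsemi[3])^2 <= 1
    lab[hip & brain] <- id_of("hippocampus")
    for (nbv in G$nb) {
      m <- (g$x - nbv$ctr[1])^2 + (g$y - nbv$ctr[2])^2 +
        (g$z - nbv$ctr[3])^2 <= nbv$r^2
      lab[m & brain] <- id_of(nbv$name)
    }
    dx <- g$x - G$C[1]; dy <- g$y - G$C[2]; dz <- g$z - G$C[3]
    rho <- sqrt((dx / G$semi[1])^2 + (dy / G$semi[2])^2 + (dz / G$semi[3])^2)
    rr <- pmax(sqrt(dx^2 + dy^2 + dz^2), 1e-9)
    cosang <- (dx * G$d_pc[1] + dy * G$d_pc[2] + dz * G$d_pc[3]) / rr
    pc <- abs(rho - 1) <= G$t_rho / 2 & cosang >= cos(G$theta) & brain
    lab[pc] <- id_of("piriform")
    cleft <- rho > 1 + G$t_rho / 2 & rho <= 1 + G$t_rho / 2 + G$cleft_rho &
      cosang >= cos(0.8 * G$theta)
    lab[cleft] <- 0L
  }
  lab
}

build_template_labels <- function(spec) {
  dm <- spec$grid_shape
  sp <- spec$voxel_spacing_mm
  g <- grid_world(dm, sp)
  lab <- paint_at(spec, g$x, g$y, g$z)
  menu <- spec$region_menu
  for (i in seq_len(nrow(menu))) {
    if (!any(lab == menu$id[i])) {
      stop("grid too small to fit region '", menu$name[i], "' (",
           menu$side[i], ")")
    }
  }
  with_spacing(array(lab, dm), sp)
}

tissue_memberships <- function(labels) {
  lab <- as.integer(labels)
  list(gm = lab > 0L & lab != 90L, wm = lab == 90L)
}

#' Render intensity and tissue probability maps from a label volume
#'
#' Produces a T1-like image: per-tissue mean intensity, additive Gaussian
#' noise, and a smooth multiplicative bias field (trilinear interpolation of
#' a seeded coarse grid). Probability maps are the noise-free tissue
#' memberships blurred with a small Gaussian kernel and clipped to `[0, 1]`;
#' their per-voxel sum never exceeds 1.
#'
#' @param labels Integer label volume with spacing attribute.
#' @param spec A [phantom_spec()].
#' @param seed Integer seed for noise and bias.
#' @return List with `intensity` (3D array) and `tissue_probs`
#'   (list of `gm`, `wm` arrays).
#' @export
render_intensity <- function(labels, spec, seed = spec$seed) {
  dm <- dim(labels)
  sp <- spacing_of(labels)
  mem <- tissue_memberships(labels)
  means <- spec$tissue_means
  base <- rep(as.numeric(means[["background"]]), prod(dm))
  base[mem$gm] <- means[["gm"]]
  base[mem$wm] <- means[["wm"]]

  with_seed(seed, {
    noise <- if (spec$noise_sd > 0) rnorm(prod(dm), 0, spec$noise_sd) else 0
    bias <- 1
    if (spec$bias_amplitude > 0) {
      coarse <- array(runif(125, -1, 1), c(5, 5, 5))
      cx <- (seq_len(dm[1]) - 1) / (dm[1] - 1) * 4
      cy <- (seq_len(dm[2]) - 1) / (dm[2] - 1) * 4
      cz <- (seq_len(dm[3]) - 1) / (dm[3] - 1) * 4
      b <- cpp_resample_trilinear(
        as.numeric(coarse), dim(coarse),
        rep.int(cx, dm[2] * dm[3]),
        rep.int(rep(cy, each = dm[1]), dm[3]),
        rep(cz, each = dm[1] * dm[2]), 0
      )
      bias <- 1 + spec$bias_amplitude * b
    }
    intensity <- (base + noise) * bias
  })

  probs <- lapply(mem, function(m) {
    p <- smooth3d(with_spacing(array(as.numeric(m), dm), sp), spec$prob_sigma_mm)
    p[p < 0] <- 0
    p[p > 1] <- 1
    p
  })
  tot <- probs$gm + probs$wm
  over <- tot > 1
  if (any(over)) {
    probs$gm[over] <- probs$gm[over] / tot[over]
    probs$wm[over] <- probs$wm[over] / tot[over]
  }
  list(
    intensity = with_spacing(array(intensity, dm), sp),
    tissue_probs = probs
  )
}

# Ground-truth volume table for one label volume.
truth_table <- function(labels, menu) {
  voxvol <- voxel_volume(labels)
  counts <- tabulate(as.integer(labels) + 1L, nbins = max(menu$id) + 1L)
  data.frame(
    region_id = menu$id, region_name = menu$name, side = menu$side,
    volume_mm3 = counts[menu$id + 1L] * voxvol,
    atrophy_factor = 1,
    stringsAsFactors = FALSE
  )
}

new_subject <- function(subject_id, group, lateralisation, labels, rendered,
                        spec, meta = list()) {
  truth <- truth_table(labels, spec$region_menu)
  structure(
    list(
      subject_id = subject_id, group = group, lateralisation = lateralisation,
      intensity = rendered$intensity, labels = labels,
      tissue_probs = rendered$tissue_probs,
      true_volumes_mm3 = truth,
      icv_mm3 = sum(as.integer(labels) != 0L) * voxel_volume(labels),
      spec = spec, meta = meta,
      cache = new.env(parent = emptyenv())
    ),
    class = "phantom_subject"
  )
}

#' Build the template phantom
#'
#' Renders the full region menu bilaterally on the requested grid. The
#' piriform-cortex analogue is a thin curved slab whose per-side volume is
#' driven to the menu target (470 mm^3 at the reference head size) and which
#' touches the amygdala-, parahippocampal-, insula- and orbital-analogues as
#' well as background.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_subject`: intensity, labels, tissue probability maps,
#'   exact ground-truth volumes and intracranial volume.
#' @export
make_template_phantom <- function(spec = phantom_spec()) {
  labels <- build_template_labels(spec)
  rendered <- render_intensity(labels, spec, seed = spec$seed)
  new_subject("template", "template", "none", labels, rendered, spec,
              meta = list(seed = spec$seed))
}

#' @export
print.phantom_subject <- function(x, ...) {
  cat("<phantom_subject>", x$subject_id, "\n")
  cat("  group:", x$group, " lateralisation:", x$lateralisation, "\n")
  cat("  grid:", paste(dim(x$labels), collapse = "x"),
      " spacing:", paste(signif(spacing_of(x$labels), 3), collapse = "x"), "mm\n")
  cat("  ICV:", format(round(x$icv_mm3)), "mm^3\n")
  pc <- x$true_volumes_mm3[x$true_volumes_mm3$region_name == "piriform", ]
  if (nrow(pc)) {
    cat("  piriform volume (R/L):",
        paste(round(pc$volume_mm3[match(c("right", "left"), pc$side)]),
              collapse = " / "), "mm^3\n")
  }
  invisible(x)
}
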