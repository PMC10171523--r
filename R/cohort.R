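# Cohort simulation: inter-subject variability, atrophy, group designs.

#' Cohort specification
#'
#' Defines group sizes, atrophy designs and the sources of inter-subject
#' anatomical variability. Each design entry is a list of
#' `list(region = <name>, side_mode = "ipsilateral"|"bilateral"|"none",
#' factor = <volume factor>)`; ipsilateral entries are applied on each
#' subject's lateralisation side, which alternates right/left within the
#' group.
#'
#' @param n_per_group Named integer vector, subjects per group.
#' @param atrophy_design Named list (one entry per group) of atrophy items;
#'   groups without an entry receive no atrophy.
#' @param deformation_magnitude_mm Root-mean-square magnitude of the random
#'   smooth displacement field (mm).
#' @param deformation_smoothness_mm Gaussian kernel width (mm) used to
#'   smooth the white-noise displacement field.
#' @param icv_cv Coefficient of variation of the per-subject global volume
#'   scale (log-normal).
#' @param seed Integer cohort seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group, atrophy_design = list(),
                        deformation_magnitude_mm = 0.8,
                        deformation_smoothness_mm = 16,
                        icv_cv = 0.18, seed = 1L) {
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group)))) {
    stop("n_per_group must be a named vector")
  }
  if (any(n_per_group < 1)) stop("group counts must be at least 1")
  for (grp in names(atrophy_design)) {
    for (item in atrophy_design[[grp]]) {
      if (!all(c("region", "side_mode", "factor") %in% names(item))) {
        stop("atrophy design items need region, side_mode and factor")
      }
      if (item$factor <= 0 || item$factor > 1.5) {
        stop("volume factors must lie in (0, 1.5]")
      }
      if (!item$side_mode %in% c("ipsilateral", "bilateral", "none")) {
        stop("side_mode must be ipsilateral, bilateral or none")
      }
    }
  }
  structure(
    list(n_per_group = n_per_group, atrophy_design = atrophy_design,
         deformation_magnitude_mm = deformation_magnitude_mm,
         deformation_smoothness_mm = deformation_smoothness_mm,
         icv_cv = icv_cv, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Unilateral epilepsy-like atrophy design
#'
#' Ipsilateral volume factors emulating hippocampal-sclerosis pathology:
#' piriform 0.93 (7\% loss), hippocampus 0.73 (27\%), amygdala 0.95 (5\%).
#'
#' @param pc,hippocampus,amygdala Volume factors.
#' @return Design list usable in [cohort_spec()].
#' @export
design_unilateral_tle <- function(pc = 0.93, hippocampus = 0.73,
                                  amygdala = 0.95) {
  list(
    list(region = "hippocampus", side_mode = "ipsilateral", factor = hippocampus),
    list(region = "amygdala", side_mode = "ipsilateral", factor = amygdala),
    list(region = "piriform", side_mode = "ipsilateral", factor = pc)
  )
}

#' Bilateral dementia-like atrophy design
#'
#' Bilateral piriform volume factor (default 0.84, a 16\% loss as in mild
#' cognitive impairment; use 0.81 for an Alzheimer-like 19\% loss), with
#' milder hippocampal and amygdalar involvement.
#'
#' @param pc,hippocampus,amygdala Volume factors.
#' @return Design list usable in [cohort_spec()].
#' @export
design_bilateral_mci <- function(pc = 0.84, hippocampus = 0.93,
                                 amygdala = 0.89) {
  list(
    list(region = "piriform", side_mode = "bilateral", factor = pc),
    list(region = "hippocampus", side_mode = "bilateral", factor = hippocampus),
    list(region = "amygdala", side_mode = "bilateral", factor = amygdala)
  )
}

# Smooth random displacement field with target RMS magnitude (mm).
# Returns an n x 3 matrix on the grid of `dm`.
sample_displacement <- function(dm, sp, magnitude_mm, smoothness_mm) {
  n <- prod(dm)
  if (magnitude_mm <= 0) return(matrix(0, n, 3))
  u <- vapply(1:3, function(d) {
    w <- array(rnorm(n), dm)
    as.numeric(cpp_gaussian_smooth(w, dm, rep_len(smoothness_mm, 3) / sp))
  }, numeric(n))
  rms <- sqrt(mean(u[, 1]^2 + u[, 2]^2 + u[, 3]^2))
  u * (magnitude_mm / rms)
}

# Minimum Jacobian determinant of the map phi (n x 3 world mm coordinates,
# on a dm grid with spacing sp), via central differences.
min_jacobian <- function(phi, dm, sp) {
  comp <- lapply(1:3, function(d) array(phi[, d], dm))
  # central differences, one-sided at the edges
  d_axis <- function(a, axis) {
    n <- dim(a)[axis]
    lo <- pmax(seq_len(n) - 1L, 1L)
    hi <- pmin(seq_len(n) + 1L, n)
    den <- (hi - lo) * sp[axis]
    if (axis == 1) (a[hi, , , drop = FALSE] - a[lo, , , drop = FALSE]) / den
    else if (axis == 2) (a[, hi, , drop = FALSE] - a[, lo, , drop = FALSE]) /
      rep(den, each = dim(a)[1])
    else (a[, , hi, drop = FALSE] - a[, , lo, drop = FALSE]) /
      rep(den, each = dim(a)[1] * dim(a)[2])
  }
  g <- vector("list", 9)
  for (ci in 1:3) for (ax in 1:3) g[[(ci - 1) * 3 + ax]] <- d_axis(comp[[ci]], ax)
  det <- g[[1]] * (g[[5]] * g[[9]] - g[[6]] * g[[8]]) -
    g[[4]] * (g[[2]] * g[[9]] - g[[3]] * g[[8]]) +
    g[[7]] * (g[[2]] * g[[6]] - g[[3]] * g[[5]])
  min(det)
}

warp_subject_arrays <- function(template, phi_vox, out_spacing) {
  dm <- dim(template$labels)
  labels <- cpp_resample_nn(as.integer(template$labels), dm,
                            phi_vox[, 1], phi_vox[, 2], phi_vox[, 3], 0L)
  intensity <- cpp_resample_trilinear(
    as.numeric(template$intensity), dm,
    phi_vox[, 1], phi_vox[, 2], phi_vox[, 3],
    as.numeric(template$spec$tissue_means[["background"]])
  )
  probs <- lapply(template$tissue_probs, function(p) {
    q <- cpp_resample_trilinear(as.numeric(p), dm, phi_vox[, 1], phi_vox[, 2],
                                phi_vox[, 3], 0)
    q[q < 0] <- 0
    q[q > 1] <- 1
    with_spacing(array(q, dm), out_spacing)
  })
  list(labels = with_spacing(array(labels, dm), out_spacing),
       intensity = with_spacing(array(intensity, dm), out_spacing),
       tissue_probs = probs)
}

#' Sample one subject from the template
#'
#' Composes a global similarity transform with a smooth random displacement
#' field. The global volume scale (log-normal with the cohort's `icv_cv`)
#' is realised through the subject's world grid — the voxel spacing is
#' multiplied by the linear scale — so head-size variation is exact and
#' introduces no resampling loss; the random field is applied on the voxel
#' grid, warping labels with nearest-neighbour and intensity/probability
#' maps with trilinear interpolation through the same map. Fields whose map
#' folds (non-positive Jacobian determinant) are rescaled by 0.8 and
#' retried.
#'
#' @param template A `phantom_subject` from [make_template_phantom()].
#' @param cohort A [cohort_spec()].
#' @param subject_seed Integer seed for this subject's scale and field.
#' @param subject_id,group,lateralisation Subject metadata.
#' @return A `phantom_subject` with exact ground-truth volumes.
#' @export
sample_subject <- function(template, cohort, subject_seed,
                           subject_id = paste0("s", subject_seed),
                           group = "healthy", lateralisation = "none") {
  dm <- dim(template$labels)
  sp <- spacing_of(template$labels)
  n <- prod(dm)

  with_seed(subject_seed, {
    gscale <- if (cohort$icv_cv > 0) exp(rnorm(1, 0, cohort$icv_cv)) else 1
    u <- sample_displacement(dm, sp, cohort$deformation_magnitude_mm,
                             cohort$deformation_smoothness_mm)
  })
  s_lin <- gscale^(1 / 3)
  sp_sub <- sp * s_lin

  # map on the shared index grid: psi(i) = i + v(i), v in voxel units of the
  # template; the similarity scale lives entirely in the world grid
  idx <- cbind(rep.int(seq_len(dm[1]) - 1, dm[2] * dm[3]),
               rep.int(rep(seq_len(dm[2]) - 1L, each = dm[1]), dm[3]),
               rep(seq_len(dm[3]) - 1L, each = dm[1] * dm[2]))
  v <- sweep(u, 2, sp, "/")
  scale_try <- 1
  mj <- 1
  for (attempt in 1:12) {
    psi <- idx + v * scale_try
    if (all(u == 0)) break
    phi_world <- sweep(psi, 2, sp, "*")
    mj <- min_jacobian(phi_world, dm, sp)
    if (mj > 0.02) break
    scale_try <- scale_try * 0.8
    message("displacement field folded for ", subject_id,
            "; retrying at magnitude scale ", signif(scale_try, 3))
  }
  w <- warp_subject_arrays(template, psi, sp_sub)

  sub <- new_subject(subject_id, group, lateralisation, w$labels,
                     list(intensity = w$intensity, tissue_probs = w$tissue_probs),
                     template$spec,
                     meta = list(seed = subject_seed, gscale = gscale,
                                 min_jacobian = mj,
                                 displacement_scale = scale_try,
                                 vox_map = psi,
                                 src = list(labels = template$labels,
                                            intensity = template$intensity,
                                            probs = template$tissue_probs)))
  sub
}

# One region's contraction toward an absolute voxel target, folded into a
# shared accumulated map into template space. The amplitude of each
# envelope-faded radial contraction about the region centroid is selected
# by a two-stage scan of the voxel count obtained by resampling the
# template labels through the linearised composed map; the scan approaches
# the target monotonically (never overshooting, since the capped reverse
# field may be too weak to come back). Returns the updated map and labels.
contract_region <- function(lab0, lab_cur, Tmap, id, target, dm, sp,
                            envelope_mm, idx, max_rounds = 6L) {
  gw <- grid_world_memo(dm, sp)
  for (round_i in seq_len(max_rounds)) {
    n0 <- sum(lab_cur == id)
    if (abs(n0 - target) <= 1L) break
    mask <- array(as.numeric(lab_cur == id), dm)
    m <- smooth3d(with_spacing(mask, sp), envelope_mm)
    g_env <- as.numeric(m) / max(m)
    w_mask <- which(mask > 0)
    ctr <- c(mean(gw$x[w_mask]), mean(gw$y[w_mask]), mean(gw$z[w_mask]))
    dir_sign <- if (target < n0) 1 else -1
    ux <- (gw$x - ctr[1]) * g_env * dir_sign / sp[1]   # voxel units
    uy <- (gw$y - ctr[2]) * g_env * dir_sign / sp[2]
    uz <- (gw$z - ctr[3]) * g_env * dir_sign / sp[3]
    maxdisp <- sqrt(max((ux * sp[1])^2 + (uy * sp[2])^2 + (uz * sp[3])^2))
    if (maxdisp <= 0) break
    # per-round boundary travel cap: enough to cross a voxel at any grid
    a_cap <- max(1.8, 1.1 * max(sp)) / maxdisp
    # linearise the accumulated map along the field: T(psi_a(x)) is
    # approximated by T(x) + a * D(x), so every amplitude in the scan is
    # evaluated against the composed map rather than the quantised labels
    eps <- a_cap / 4
    Teps <- Tmap
    for (d in 1:3) {
      Teps[, d] <- cpp_resample_trilinear(
        array(Tmap[, d], dm), dm,
        pmin(pmax(idx[, 1] + eps * ux, 0), dm[1] - 1),
        pmin(pmax(idx[, 2] + eps * uy, 0), dm[2] - 1),
        pmin(pmax(idx[, 3] + eps * uz, 0), dm[3] - 1), 0)
    }
    Dmap <- (Teps - Tmap) / eps
    count_at <- function(a) {
      sum(cpp_resample_nn(lab0, dm, Tmap[, 1] + a * Dmap[, 1],
                          Tmap[, 2] + a * Dmap[, 2],
                          Tmap[, 3] + a * Dmap[, 3], 0L) == id)
    }
    pick <- function(alphas) {
      counts <- vapply(alphas, count_at, 1L)
      keep <- if (dir_sign > 0) counts >= target else counts <= target
      i <- if (any(keep)) {
        which(keep)[which.min(abs(counts[keep] - target))]
      } else {
        which.min(abs(counts - target))
      }
      list(i = i, counts = counts)
    }
    alphas <- seq(0, a_cap, length.out = 49)[-1]
    p1 <- pick(alphas)
    lo <- if (p1$i > 1) alphas[p1$i - 1] else 0
    hi <- if (p1$i < length(alphas)) alphas[p1$i + 1] else alphas[p1$i]
    fine <- seq(lo, hi, length.out = 33)[-1]
    p2 <- pick(fine)
    if (abs(p2$counts[p2$i] - target) >= abs(n0 - target)) break
    alpha <- fine[p2$i]
    psi1 <- pmin(pmax(idx[, 1] + alpha * ux, 0), dm[1] - 1)
    psi2 <- pmin(pmax(idx[, 2] + alpha * uy, 0), dm[2] - 1)
    psi3 <- pmin(pmax(idx[, 3] + alpha * uz, 0), dm[3] - 1)
    for (d in 1:3) {
      Tmap[, d] <- cpp_resample_trilinear(array(Tmap[, d], dm), dm,
                                          psi1, psi2, psi3, 0)
    }
    lab_cur <- cpp_resample_nn(lab0, dm, Tmap[, 1], Tmap[, 2], Tmap[, 3], 0L)
  }
  list(Tmap = Tmap, lab = lab_cur)
}

# Apply a resolved atrophy design (list of list(id, factor)) through one
# accumulated map into template space, with corrective passes for the
# crosstalk between adjacent regions, and a single final resampling of all
# channels from the template sources.
apply_design <- function(subject, items, tol = 0.02, envelope_mm = 1.4) {
  if (!length(items)) return(subject)
  spec <- subject$spec
  dm <- dim(subject$labels)
  sp <- spec$voxel_spacing_mm            # template grid spacing
  sp_sub <- spacing_of(subject$labels)   # subject world spacing
  idx <- cbind(rep.int(seq_len(dm[1]) - 1, dm[2] * dm[3]),
               rep.int(rep(seq_len(dm[2]) - 1L, each = dm[1]), dm[3]),
               rep(seq_len(dm[3]) - 1L, each = dm[1] * dm[2]))
  # the map accumulates the atrophy warp only, over the subject's own grid
  Tmap <- idx * 1.0
  lab0 <- as.integer(subject$labels)
  lab_cur <- lab0
  targets <- list()
  n_starts <- list()
  for (it in items) {
    key <- as.character(it$id)
    n_start <- sum(lab_cur == it$id)
    if (n_start == 0L) stop("region id ", it$id, " is empty")
    targets[[key]] <- round(it$factor * n_start)
    n_starts[[key]] <- n_start
    if (targets[[key]] < 8L && it$factor != 1) {
      stop("unreachable target volume for region id ", it$id)
    }
  }
  for (pass in 1:4) {
    moved <- FALSE
    ord <- if (pass %% 2 == 0) rev(seq_along(items)) else seq_along(items)
    for (ii in ord) {
      id <- items[[ii]]$id
      key <- as.character(id)
      if (abs(sum(lab_cur == id) - targets[[key]]) <= 1L) next
      res <- contract_region(lab0, lab_cur, Tmap, id, targets[[key]],
                             dm, sp, envelope_mm, idx)
      Tmap <- res$Tmap
      lab_cur <- res$lab
      moved <- TRUE
    }
    if (!moved) break
  }
  for (it in items) {
    key <- as.character(it$id)
    achieved <- sum(lab_cur == it$id)
    if (abs(achieved - targets[[key]]) > tol * n_starts[[key]]) {
      stop("unreachable target volume for region id ", it$id,
           " (achieved ", achieved, " of ", targets[[key]], " voxels)")
    }
  }
  if (identical(lab_cur, lab0)) return(subject)

  # one resampling of the appearance channels through the composed map
  src_int <- subject$intensity
  src_probs <- subject$tissue_probs
  intensity <- cpp_resample_trilinear(
    as.numeric(src_int), dm, Tmap[, 1], Tmap[, 2], Tmap[, 3],
    as.numeric(spec$tissue_means[["background"]]))
  probs <- lapply(src_probs, function(p) {
    q <- cpp_resample_trilinear(as.numeric(p), dm, Tmap[, 1], Tmap[, 2],
                                Tmap[, 3], 0)
    q[q < 0] <- 0
    q[q > 1] <- 1
    with_spacing(array(q, dm), sp_sub)
  })
  subject$labels <- with_spacing(array(lab_cur, dm), sp_sub)
  subject$intensity <- with_spacing(array(intensity, dm), sp_sub)
  subject$tissue_probs <- probs
  subject$cache <- new.env(parent = emptyenv())
  old_factors <- subject$true_volumes_mm3$atrophy_factor
  subject$true_volumes_mm3 <- truth_table(subject$labels, spec$region_menu)
  subject$true_volumes_mm3$atrophy_factor <- old_factors
  for (it in items) {
    hit <- subject$true_volumes_mm3$region_id == it$id
    subject$true_volumes_mm3$atrophy_factor[hit] <-
      subject$true_volumes_mm3$atrophy_factor[hit] * it$factor
  }
  subject$icv_mm3 <- sum(lab_cur != 0L) * prod(sp_sub)
  subject
}

#' Apply focal atrophy to one region
#'
#' Scales the voxel count of a region to `factor` times its current count
#' by warping the subject through a smooth local contraction field: the
#' region's blurred mask fades a radial contraction about the region
#' centroid, and labels (nearest-neighbour), intensity and probability
#' maps (trilinear) are resampled through one accumulated map, so the
#' subject stays anatomically consistent — the boundary recedes, adjacent
#' tissue moves into the vacated space, and the image carries the
#' sub-voxel shift exactly as real tissue loss does. The field amplitude is
#' selected by a deterministic two-stage scan that approaches the target
#' count monotonically; `factor > 1` reverses the field and grows the
#' region.
#'
#' @param subject A `phantom_subject`.
#' @param region Region name (e.g. `"piriform"`) or id.
#' @param factor Volume factor in (0, 1.5].
#' @param side `"left"`, `"right"` or `"both"`.
#' @param tol Relative tolerance on the achieved voxel count.
#' @param envelope_mm Gaussian width of the contraction envelope.
#' @return The modified `phantom_subject` with updated ground truth.
#' @export
apply_atrophy <- function(subject, region, factor, side = "both",
                          tol = 0.02, envelope_mm = 1.4) {
  if (factor <= 0 || factor > 1.5) stop("factor must lie in (0, 1.5]")
  menu <- subject$spec$region_menu
  ids <- if (is.numeric(region)) as.integer(region)
         else region_ids(menu, region, side)
  ids <- setdiff(ids, 90L)
  if (!length(ids)) stop("no matching region ids")
  items <- lapply(ids, function(id) list(id = id, factor = factor))
  apply_design(subject, items, tol = tol, envelope_mm = envelope_mm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a cohort with known ground truth
#'
#' Draws subjects per group from the template, applies the group's atrophy
#' design (ipsilateral items on the subject's lateralisation side, which
#' alternates right/left within each group), and assembles the ground-truth
#' table.
#'
#' @param template A `phantom_subject`.
#' @param cohort A [cohort_spec()].
#' @return Object of class `phantom_cohort`: list with `subjects` (list of
#'   `phantom_subject`) and `ground_truth` (one row per subject x region x
#'   side: true volume, applied atrophy factor, ICV, group, lateralisation).
#' @export
simulate_cohort <- function(template, cohort) {
  subjects <- list()
  gt <- list()
  for (grp in names(cohort$n_per_group)) {
    n_g <- cohort$n_per_group[[grp]]
    design <- cohort$atrophy_design[[grp]] %||% list()
    needs_side <- any(vapply(design, function(it) it$side_mode == "ipsilateral",
                             logical(1)))
    for (i in seq_len(n_g)) {
      lat <- if (needs_side) c("right", "left")[(i - 1L) %% 2L + 1L] else "none"
      sid <- sprintf("%s_%02d", grp, i)
      sseed <- derive_seed(cohort$seed, paste("subject", grp, i))
      sub <- sample_subject(template, cohort, sseed, subject_id = sid,
                            group = grp, lateralisation = lat)
      # resolve the design to per-id items and apply jointly through one
      # accumulated contraction map (single resampling per subject)
      items <- list()
      for (item in design) {
        side <- switch(item$side_mode,
                       ipsilateral = lat,
                       bilateral = "both",
                       none = NA_character_)
        if (is.na(side)) next
        for (id in setdiff(region_ids(template$spec$region_menu,
                                      item$region, side), 90L)) {
          items[[length(items) + 1L]] <- list(id = id, factor = item$factor)
        }
      }
      sub <- apply_design(sub, items)
      subjects[[sid]] <- sub
      tt <- sub$true_volumes_mm3
      tt$subject_id <- sid
      tt$group <- grp
      tt$lateralisation <- lat
      tt$icv_mm3 <- sub$icv_mm3
      gt[[sid]] <- tt
    }
  }
  ground_truth <- do.call(rbind, gt)
  rownames(ground_truth) <- NULL
  ground_truth <- ground_truth[, c("subject_id", "group", "lateralisation",
                                   "region_id", "region_name", "side",
                                   "volume_mm3", "atrophy_factor", "icv_mm3")]
  structure(list(subjects = subjects, ground_truth = ground_truth,
                 cohort = cohort),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat("<phantom_cohort>", length(x$subjects), "subjects\n")
  print(table(vapply(x$subjects, `[[`, "", "group")))
  invisible(x)
}

#' Perturb a delineation (synthetic rater)
#'
#' Emulates an independent manual delineation of one region by shifting its
#' boundary with a smooth random field: the region's signed boundary
#' distance is perturbed and re-thresholded. Larger magnitudes yield lower
#' overlap with the original.
#'
#' @param labels Integer label volume.
#' @param region_id Region id to perturb.
#' @param magnitude_mm RMS amplitude of the boundary shift (mm).
#' @param seed Integer seed.
#' @param smoothness_mm Kernel width of the perturbation field.
#' @return Label volume with the perturbed region.
#' @export
perturb_delineation <- function(labels, region_id, magnitude_mm, seed,
                                smoothness_mm = 6) {
  dm <- dim(labels)
  sp <- spacing_of(labels)
  lab <- as.integer(labels)
  mask <- lab == region_id
  if (!any(mask)) stop("region id ", region_id, " is empty")
  d_out <- cpp_edt(as.integer(!mask), dm, sp)   # distance to region, outside
  d_in <- cpp_edt(as.integer(mask), dm, sp)     # distance to complement, inside
  sdist <- d_out - d_in                          # negative inside
  eps <- with_seed(seed, {
    w <- array(rnorm(prod(dm)), dm)
    e <- as.numeric(cpp_gaussian_smooth(w, dm, rep_len(smoothness_mm, 3) / sp))
    e * (magnitude_mm / sqrt(mean(e^2)))
  })
  new_mask <- (sdist + eps) < 0 & lab != 0L     # stay inside the head
  lab[mask & !new_mask] <- 90L
  lab[new_mask & !mask] <- region_id
  with_spacing(array(lab, dm), sp)
}
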