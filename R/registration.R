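# Pairwise spatial normalisation: affine initialisation followed by
# multi-resolution cubic B-spline free-form deformation (FFD), driven first
# by tissue-probability channels (sum of squared differences) and then
# refined on the intensity channel (local normalised correlation, robust to
# the simulated bias field). All transforms map fixed-grid world
# coordinates (mm) into the moving image.

#' Registration parameters
#'
#' @param affine_levels Downsampling factors for the affine stage.
#' @param affine_maxit Optimiser iteration caps per affine level.
#' @param ffd_levels Downsampling factors for the FFD stage.
#' @param ctrl_spacing_mm Control-point spacing per FFD level (must decrease).
#' @param ffd_maxit Optimiser iteration caps per FFD level.
#' @param bending_weight Weight of the bending-energy penalty on the
#'   control-point grid.
#' @param intensity_maxit Iteration cap for the intensity refinement stage
#'   (0 disables it).
#' @param lncc_sigma_mm Gaussian window of the local correlation metric.
#' @param jac_min Minimum admissible Jacobian determinant; below it the FFD
#'   is retried once with tenfold regularisation, then flagged.
#' @param background Background value for out-of-field intensity samples.
#' @return Object of class `reg_params`.
#' @export
reg_params <- function(affine_levels = c(4, 2), affine_maxit = c(60, 30),
                       ffd_levels = c(4, 2, 2),
                       ctrl_spacing_mm = c(24, 12, 8),
                       ffd_maxit = c(60, 40, 40),
                       bending_weight = 0.001,
                       intensity_maxit = 5, lncc_sigma_mm = 3,
                       jac_min = 0.05, background = 0) {
  stopifnot(length(ffd_levels) >= 1, length(ctrl_spacing_mm) == length(ffd_levels),
            length(ffd_maxit) == length(ffd_levels),
            length(affine_maxit) == length(affine_levels))
  if (any(diff(ctrl_spacing_mm) > 0)) {
    stop("control-point spacings must decrease monotonically across levels")
  }
  structure(list(affine_levels = affine_levels, affine_maxit = affine_maxit,
                 ffd_levels = ffd_levels, ctrl_spacing_mm = ctrl_spacing_mm,
                 ffd_maxit = ffd_maxit, bending_weight = bending_weight,
                 intensity_maxit = intensity_maxit,
                 lncc_sigma_mm = lncc_sigma_mm, jac_min = jac_min,
                 background = background),
            class = "reg_params")
}

# Normalise registration inputs to a common structure. Subjects carry a
# cache environment so image pyramids survive across repeated pairings
# (every atlas is re-registered once per target).
as_reg_image <- function(x) {
  ri <- if (inherits(x, "phantom_subject")) {
    list(probs = x$tissue_probs, intensity = x$intensity,
         spacing = spacing_of(x$labels), dim = dim(x$labels),
         cache = x$cache)
  } else if (is.array(x) && length(dim(x)) == 3L) {
    list(probs = list(ch1 = x), intensity = x, spacing = spacing_of(x),
         dim = dim(x), cache = NULL)
  } else if (is.list(x) && !is.null(x$probs)) {
    sp <- x$spacing %||% spacing_of(x$probs[[1]])
    list(probs = x$probs, intensity = x$intensity,
         spacing = sp, dim = dim(x$probs[[1]]), cache = x$cache)
  } else {
    stop("cannot interpret registration input; supply a phantom_subject, ",
         "a 3D array, or list(probs=, intensity=, spacing=)")
  }
  if (!is.null(ri$cache) && !is.environment(ri$cache)) ri$cache <- NULL
  ri
}

# Downsampled channels plus gradients at one pyramid level, memoised on the
# subject's cache environment when available.
reg_level <- function(ri, f, intensity = FALSE) {
  build <- function() {
    ch <- if (intensity) list(int = ri$intensity) else ri$probs
    if (f > 1) ch <- lapply(ch, downsample_channel, f = f)
    list(ch = ch, grads = lapply(ch, image_gradient),
         dm = dim(ch[[1]]), sp = spacing_of(ch[[1]]))
  }
  if (is.null(ri$cache)) return(build())
  key <- paste0(if (intensity) "int" else "prob", f)
  hit <- ri$cache[[key]]
  if (!is.null(hit)) return(hit)
  data <- build()
  assign(key, data, envir = ri$cache)
  data
}

# World-coordinate grids recur for a handful of shapes; memoise globally.
.grid_memo <- new.env(parent = emptyenv())

grid_world_memo <- function(dm, sp) {
  key <- paste(c(dm, signif(sp, 10)), collapse = "_")
  hit <- .grid_memo[[key]]
  if (!is.null(hit)) return(hit)
  g <- grid_world(dm, sp)
  assign(key, g, envir = .grid_memo)
  g
}

downsample_channel <- function(vol, f) {
  if (f == 1) return(vol)
  sp <- spacing_of(vol)
  sm <- smooth3d(vol, 0.45 * f * sp)
  dm <- dim(vol)
  ix <- seq(1, dm[1], by = f)
  iy <- seq(1, dm[2], by = f)
  iz <- seq(1, dm[3], by = f)
  with_spacing(sm[ix, iy, iz, drop = FALSE], sp * f)
}

# Central-difference gradient (per mm) of a 3D array, returned as a list of
# three arrays.
image_gradient <- function(vol) {
  dm <- dim(vol)
  sp <- spacing_of(vol)
  g <- vector("list", 3)
  for (ax in 1:3) {
    n <- dm[ax]
    lo <- pmax(seq_len(n) - 1L, 1L)
    hi <- pmin(seq_len(n) + 1L, n)
    den <- (hi - lo) * sp[ax]
    g[[ax]] <- if (ax == 1) (vol[hi, , , drop = FALSE] - vol[lo, , , drop = FALSE]) / den
      else if (ax == 2) (vol[, hi, , drop = FALSE] - vol[, lo, , drop = FALSE]) /
        rep(den, each = dm[1])
      else (vol[, , hi, drop = FALSE] - vol[, , lo, drop = FALSE]) /
        rep(den, each = dm[1] * dm[2])
  }
  g
}

intensity_centroid <- function(vol) {
  sp <- spacing_of(vol)
  w <- as.numeric(vol) - min(vol)
  tw <- sum(w)
  if (tw <= 0) return((dim(vol) - 1) * sp / 2)
  g <- grid_world(dim(vol), sp)
  c(sum(w * g$x), sum(w * g$y), sum(w * g$z)) / tw
}

new_affine <- function(mat, fixed, moving, similarity = c(NA, NA),
                       converged = TRUE) {
  structure(mat, class = "affine_transform",
            fixed_dim = fixed$dim, fixed_spacing = fixed$spacing,
            moving_dim = moving$dim, moving_spacing = moving$spacing,
            similarity = similarity, converged = converged)
}

#' Identity affine transform between two grids
#' @param fixed,moving Registration inputs (see [affine_register()]).
#' @export
identity_affine <- function(fixed, moving = fixed) {
  new_affine(diag(4), as_reg_image(fixed), as_reg_image(moving))
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform> world (mm) matrix:\n")
  print(unclass(x)[1:4, 1:4])
  sim <- attr(x, "similarity")
  if (!all(is.na(sim))) cat("  cost pre/post:", signif(sim, 5), "\n")
  invisible(x)
}

# Shared memoised objective wrapper for optim(): fn and gr evaluate once.
memo_objective <- function(fg) {
  env <- new.env()
  env$p <- NULL
  eval_at <- function(p) {
    if (is.null(env$p) || !identical(p, env$p)) {
      res <- fg(p)
      env$p <- p
      env$val <- res$value
      env$grad <- res$gradient
    }
    invisible(NULL)
  }
  list(fn = function(p) { eval_at(p); env$val },
       gr = function(p) { eval_at(p); env$grad })
}

#' Affine registration
#'
#' Twelve-parameter affine alignment by multi-resolution gradient-based
#' minimisation of the sum of squared differences over the tissue
#' probability channels, initialised by the intensity-centroid translation.
#' The transform maps fixed-grid world coordinates to moving-image world
#' coordinates.
#'
#' @param fixed,moving A `phantom_subject`, a 3D array, or
#'   `list(probs =, intensity =, spacing =)`.
#' @param params A [reg_params()].
#' @return An `affine_transform` (4x4 matrix with grid metadata).
#' @export
affine_register <- function(fixed, moving, params = reg_params()) {
  fx <- as_reg_image(fixed)
  mv <- as_reg_image(moving)
  ctr <- (fx$dim - 1) * fx$spacing / 2
  t0 <- intensity_centroid(
    with_spacing(Reduce(`+`, mv$probs), mv$spacing)) -
    intensity_centroid(with_spacing(Reduce(`+`, fx$probs), fx$spacing))
  p <- c(rep(0, 9), t0)
  sim_pre <- NA_real_
  sim_post <- NA_real_
  conv <- TRUE

  for (li in seq_along(params$affine_levels)) {
    f <- params$affine_levels[li]
    flev <- reg_level(fx, f)
    mlev <- reg_level(mv, f)
    fc <- flev$ch
    mc <- mlev$ch
    mg <- mlev$grads
    dmf <- flev$dm
    spf <- flev$sp
    spm <- mlev$sp
    dmm <- mlev$dm
    g <- grid_world_memo(dmf, spf)
    xr <- cbind(g$x - ctr[1], g$y - ctr[2], g$z - ctr[3])
    nvox <- nrow(xr)

    fg <- function(p) {
      M <- diag(3) + matrix(p[1:9], 3, 3)
      tt <- p[10:12]
      y <- xr %*% t(M)
      y1 <- (y[, 1] + ctr[1] + tt[1]) / spm[1]
      y2 <- (y[, 2] + ctr[2] + tt[2]) / spm[2]
      y3 <- (y[, 3] + ctr[3] + tt[3]) / spm[3]
      val <- 0
      gM <- matrix(0, 3, 3)
      gt <- numeric(3)
      for (ch in seq_along(fc)) {
        s4 <- cpp_sample4(as.numeric(mc[[ch]]),
                          as.numeric(mg[[ch]][[1]]), as.numeric(mg[[ch]][[2]]),
                          as.numeric(mg[[ch]][[3]]), dmm, y1, y2, y3, 0)
        r <- s4[, 1] - as.numeric(fc[[ch]])
        val <- val + sum(r * r) / nvox
        for (d in 1:3) {
          v <- 2 * r * s4[, d + 1] / nvox
          gt[d] <- gt[d] + sum(v)
          gM[d, ] <- gM[d, ] + c(sum(v * xr[, 1]), sum(v * xr[, 2]),
                                 sum(v * xr[, 3]))
        }
      }
      list(value = val, gradient = c(as.numeric(gM), gt))
    }
    obj <- memo_objective(fg)
    if (li == 1) sim_pre <- obj$fn(p)
    res <- optim(p, obj$fn, obj$gr, method = "L-BFGS-B",
                 control = list(maxit = params$affine_maxit[li], factr = 1e9))
    if (res$value <= obj$fn(p)) p <- res$par
    if (res$convergence == 1) conv <- FALSE
    sim_post <- min(res$value, obj$fn(p))
  }
  if (!conv) warning("affine registration hit the iteration cap; ",
                     "returning best-so-far transform")
  M <- diag(3) + matrix(p[1:9], 3, 3)
  tt <- p[10:12]
  mat <- diag(4)
  mat[1:3, 1:3] <- M
  mat[1:3, 4] <- ctr - M %*% ctr + tt
  new_affine(mat, fx, mv, similarity = c(pre = sim_pre, post = sim_post),
             converged = conv)
}

# Map fixed-grid voxels through a transform; returns moving-space voxel
# coordinates (0-based) as a list of three vectors.
transform_coords <- function(transform) {
  if (inherits(transform, "affine_transform")) {
    dmf <- attr(transform, "fixed_dim")
    spf <- attr(transform, "fixed_spacing")
    spm <- attr(transform, "moving_spacing")
    g <- grid_world(dmf, spf)
    m <- unclass(transform)
    list(
      x = (m[1, 1] * g$x + m[1, 2] * g$y + m[1, 3] * g$z + m[1, 4]) / spm[1],
      y = (m[2, 1] * g$x + m[2, 2] * g$y + m[2, 3] * g$z + m[2, 4]) / spm[2],
      z = (m[3, 1] * g$x + m[3, 2] * g$y + m[3, 3] * g$z + m[3, 4]) / spm[3],
      dim = dmf
    )
  } else if (inherits(transform, "deformation_field")) {
    dmf <- transform$fixed_dim
    spf <- transform$fixed_spacing
    spm <- transform$moving_spacing
    g <- grid_world(dmf, spf)
    list(
      x = (g$x + as.numeric(transform$disp[, , , 1])) / spm[1],
      y = (g$y + as.numeric(transform$disp[, , , 2])) / spm[2],
      z = (g$z + as.numeric(transform$disp[, , , 3])) / spm[3],
      dim = dmf
    )
  } else {
    stop("unknown transform type")
  }
}

# Bending energy of the control-point grid and its gradient: sum of squared
# second differences along each axis, per displacement component.
bending_penalty <- function(coef, cdim) {
  co <- array(coef, c(cdim, 3))
  val <- 0
  grad <- array(0, c(cdim, 3))
  for (ax in 1:3) {
    n <- cdim[ax]
    if (n < 3) next
    i0 <- 1:(n - 2); i1 <- 2:(n - 1); i2 <- 3:n
    if (ax == 1) {
      d2 <- co[i0, , , , drop = FALSE] - 2 * co[i1, , , , drop = FALSE] +
        co[i2, , , , drop = FALSE]
      val <- val + sum(d2^2)
      grad[i0, , , ] <- grad[i0, , , , drop = FALSE] + 2 * d2
      grad[i1, , , ] <- grad[i1, , , , drop = FALSE] - 4 * d2
      grad[i2, , , ] <- grad[i2, , , , drop = FALSE] + 2 * d2
    } else if (ax == 2) {
      d2 <- co[, i0, , , drop = FALSE] - 2 * co[, i1, , , drop = FALSE] +
        co[, i2, , , drop = FALSE]
      val <- val + sum(d2^2)
      grad[, i0, , ] <- grad[, i0, , , drop = FALSE] + 2 * d2
      grad[, i1, , ] <- grad[, i1, , , drop = FALSE] - 4 * d2
      grad[, i2, , ] <- grad[, i2, , , drop = FALSE] + 2 * d2
    } else {
      d2 <- co[, , i0, , drop = FALSE] - 2 * co[, , i1, , drop = FALSE] +
        co[, , i2, , drop = FALSE]
      val <- val + sum(d2^2)
      grad[, , i0, ] <- grad[, , i0, , drop = FALSE] + 2 * d2
      grad[, , i1, ] <- grad[, , i1, , drop = FALSE] - 4 * d2
      grad[, , i2, ] <- grad[, , i2, , drop = FALSE] + 2 * d2
    }
  }
  nc <- length(coef)
  list(value = val / nc, gradient = as.numeric(grad) / nc)
}

# Local normalised correlation cost (negated, averaged) and its derivative
# with respect to the warped image W.
lncc_cost <- function(Fv, W, dm, sigma_vox, pre) {
  S <- function(a) as.numeric(cpp_gaussian_smooth(a, dm, sigma_vox))
  mW <- S(W)
  vW <- S(W * W) - mW^2
  cov <- S(Fv * W) - pre$mF * mW
  eps <- pre$eps
  den <- (pre$vF + eps) * (vW + eps)
  cc <- cov^2 / den
  grad <- -(2 * cov / den * (Fv - pre$mF) -
              2 * cov^2 / (den * (vW + eps)) * (W - mW)) / length(W)
  list(value = -sum(cc) / length(W), grad_w = grad)
}

# One FFD optimisation pass on a given level grid. Returns the updated base
# displacement (n x 3, mm) and the achieved cost.
ffd_level <- function(fc, mc, mgrad, y_aff, u_base, ctrl_mm, maxit,
                      bending_weight, metric = "ssd", lncc_pre = NULL,
                      sigma_vox = NULL, subset = integer(0)) {
  dmf <- dim(fc[[1]])
  spf <- spacing_of(fc[[1]])
  spm <- spacing_of(mc[[1]])
  dmm <- dim(mc[[1]])
  nvox <- prod(dmf)
  hv <- ctrl_mm / spf
  cdim <- cpp_ffd_ctrl_dim(dmf, hv)
  fvals <- lapply(fc, as.numeric)
  ybase <- cbind(y_aff[, 1] + u_base[, 1], y_aff[, 2] + u_base[, 2],
                 y_aff[, 3] + u_base[, 3])

  fg <- if (metric == "ssd") {
    mvals <- lapply(mc, as.numeric)
    mg1 <- lapply(mgrad, function(gg) as.numeric(gg[[1]]))
    mg2 <- lapply(mgrad, function(gg) as.numeric(gg[[2]]))
    mg3 <- lapply(mgrad, function(gg) as.numeric(gg[[3]]))
    function(coef) {
      res <- cpp_ffd_ssd(coef, cdim, hv, dmf, ybase, spm, dmm,
                         fvals, mvals, mg1, mg2, mg3, subset)
      bp <- bending_penalty(coef, cdim)
      list(value = res$value + bending_weight * bp$value,
           gradient = as.numeric(res$gradient) + bending_weight * bp$gradient)
    }
  } else {
    function(coef) {
      u <- cpp_ffd_disp(coef, cdim, hv, dmf)
      y1 <- (ybase[, 1] + u[, 1]) / spm[1]
      y2 <- (ybase[, 2] + u[, 2]) / spm[2]
      y3 <- (ybase[, 3] + u[, 3]) / spm[3]
      val <- 0
      v <- matrix(0, nvox, 3)
      for (ch in seq_along(fc)) {
        s4 <- cpp_sample4(as.numeric(mc[[ch]]),
                          as.numeric(mgrad[[ch]][[1]]),
                          as.numeric(mgrad[[ch]][[2]]),
                          as.numeric(mgrad[[ch]][[3]]), dmm, y1, y2, y3, 0)
        lc <- lncc_cost(fvals[[ch]], s4[, 1], dmf, sigma_vox, lncc_pre[[ch]])
        val <- val + lc$value
        coeff <- lc$grad_w
        for (d in 1:3) v[, d] <- v[, d] + coeff * s4[, d + 1]
      }
      bp <- bending_penalty(coef, cdim)
      gr <- as.numeric(cpp_ffd_grad(v, dmf, hv, cdim)) +
        bending_weight * bp$gradient
      list(value = val + bending_weight * bp$value, gradient = gr)
    }
  }

  coef0 <- numeric(prod(cdim) * 3)
  obj <- memo_objective(fg)
  res <- optim(coef0, obj$fn, obj$gr, method = "L-BFGS-B",
               control = list(maxit = maxit, factr = 1e9))
  coef <- if (res$value <= obj$fn(coef0)) res$par else coef0
  u <- cpp_ffd_disp(coef, cdim, hv, dmf)
  list(u_base = u_base + u, cost = min(res$value, obj$fn(coef0)))
}

# Resample an n x 3 displacement (mm) from a coarse grid to a finer grid.
upsample_disp <- function(u, dm_from, sp_from, dm_to, sp_to) {
  g <- grid_world(dm_to, sp_to)
  cx <- g$x / sp_from[1]
  cy <- g$y / sp_from[2]
  cz <- g$z / sp_from[3]
  out <- matrix(0, prod(dm_to), 3)
  for (d in 1:3) {
    # clamp to the coarse field of view so border voxels extrapolate flatly
    out[, d] <- cpp_resample_trilinear(
      u[, d], dm_from,
      pmin(pmax(cx, 0), dm_from[1] - 1),
      pmin(pmax(cy, 0), dm_from[2] - 1),
      pmin(pmax(cz, 0), dm_from[3] - 1), 0)
  }
  out
}

#' Free-form deformation registration
#'
#' Two sequential stages on top of an affine initialisation: a
#' multi-resolution cubic B-spline FFD driven by the tissue probability
#' channels (sum of squared differences, equal channel weights), then a
#' refinement on the intensity channel with a local normalised correlation
#' metric. Returns the composed displacement (affine plus deformation) on
#' the fixed grid. If the map's minimum Jacobian determinant falls below
#' `params$jac_min`, the deformation stages are rerun once with tenfold
#' bending weight; a still-folded result is flagged.
#'
#' @param fixed,moving Registration inputs (see [affine_register()]).
#' @param init An `affine_transform`, or `NULL` to compute one.
#' @param params A [reg_params()].
#' @return A `deformation_field`: total displacement array `(dim, 3)` in mm
#'   on the fixed grid, with control spacing, minimum Jacobian determinant
#'   and pre/post cost attached.
#' @export
ffd_register <- function(fixed, moving, init = NULL, params = reg_params()) {
  fx <- as_reg_image(fixed)
  mv <- as_reg_image(moving)
  if (is.null(init)) init <- affine_register(fx, mv, params)
  A <- unclass(init)

  run_stages <- function(bending_weight) {
    u_base <- NULL
    dm_prev <- NULL
    sp_prev <- NULL
    cost <- c(NA_real_, NA_real_)
    for (li in seq_along(params$ffd_levels)) {
      f <- params$ffd_levels[li]
      flev <- reg_level(fx, f)
      mlev <- reg_level(mv, f)
      fc <- flev$ch
      mc <- mlev$ch
      mgrad <- mlev$grads
      dmf <- flev$dm
      spf <- flev$sp
      g <- grid_world_memo(dmf, spf)
      y_aff <- cbind(A[1, 1] * g$x + A[1, 2] * g$y + A[1, 3] * g$z + A[1, 4],
                     A[2, 1] * g$x + A[2, 2] * g$y + A[2, 3] * g$z + A[2, 4],
                     A[3, 1] * g$x + A[3, 2] * g$y + A[3, 3] * g$z + A[3, 4])
      u_base <- if (is.null(u_base)) matrix(0, prod(dmf), 3)
        else upsample_disp(u_base, dm_prev, sp_prev, dmf, spf)
      subset <- integer(0)
      if (f == 1) {
        # the coarse levels align head and white matter; the full-resolution
        # refinement concentrates on grey matter and a margin around it,
        # where all evaluated structures live
        key <- "gm_subset"
        subset <- if (!is.null(fx$cache)) fx$cache[[key]] else NULL
        if (is.null(subset)) {
          gm_ch <- which(names(fc) == "gm")
          gm <- as.numeric(fc[[if (length(gm_ch)) gm_ch[1] else 1L]])
          hs <- cpp_gaussian_smooth(array(gm, dmf), dmf, 5 / spf)
          subset <- which(as.numeric(hs) > 0.01) - 1L
          if (!is.null(fx$cache)) assign(key, subset, envir = fx$cache)
        }
      }
      lev <- ffd_level(fc, mc, mgrad, y_aff, u_base,
                       params$ctrl_spacing_mm[li], params$ffd_maxit[li],
                       bending_weight, subset = subset)
      if (li == 1 && is.na(cost[1])) cost[1] <- lev$cost
      u_base <- lev$u_base
      dm_prev <- dmf
      sp_prev <- spf
      cost[2] <- lev$cost
    }
    # intensity refinement at full resolution
    if (params$intensity_maxit > 0 && !is.null(fx$intensity) &&
        !is.null(mv$intensity)) {
      filev <- reg_level(fx, 1, intensity = TRUE)
      milev <- reg_level(mv, 1, intensity = TRUE)
      fi <- filev$ch
      mi <- milev$ch
      mgrad <- milev$grads
      dmf <- filev$dm
      spf <- filev$sp
      sigma_vox <- rep_len(params$lncc_sigma_mm, 3) / spf
      pre <- NULL
      lkey <- paste0("lncc", signif(params$lncc_sigma_mm, 6))
      if (!is.null(fx$cache)) pre <- fx$cache[[lkey]]
      if (is.null(pre)) {
        Fv <- as.numeric(fi[[1]])
        S <- function(a) as.numeric(cpp_gaussian_smooth(a, dmf, sigma_vox))
        mF <- S(Fv)
        pre <- list(int = list(mF = mF, vF = S(Fv * Fv) - mF^2,
                               eps = (1e-3 * max(diff(range(Fv)), 1))^2))
        if (!is.null(fx$cache)) assign(lkey, pre, envir = fx$cache)
      }
      g <- grid_world_memo(dmf, spf)
      y_aff <- cbind(A[1, 1] * g$x + A[1, 2] * g$y + A[1, 3] * g$z + A[1, 4],
                     A[2, 1] * g$x + A[2, 2] * g$y + A[2, 3] * g$z + A[2, 4],
                     A[3, 1] * g$x + A[3, 2] * g$y + A[3, 3] * g$z + A[3, 4])
      u_base <- if (!identical(dm_prev, dmf))
        upsample_disp(u_base, dm_prev, sp_prev, dmf, spf) else u_base
      lev <- ffd_level(fi, mi, mgrad, y_aff, u_base,
                       params$ctrl_spacing_mm[length(params$ctrl_spacing_mm)],
                       params$intensity_maxit, bending_weight,
                       metric = "lncc", lncc_pre = pre, sigma_vox = sigma_vox)
      u_base <- lev$u_base
      dm_prev <- dmf
      sp_prev <- spf
    }
    list(u = u_base, dm = dm_prev, sp = sp_prev, cost = cost)
  }

  st <- run_stages(params$bending_weight)
  make_phi <- function(u) {
    g <- grid_world(fx$dim, fx$spacing)
    cbind(A[1, 1] * g$x + A[1, 2] * g$y + A[1, 3] * g$z + A[1, 4] + u[, 1],
          A[2, 1] * g$x + A[2, 2] * g$y + A[2, 3] * g$z + A[2, 4] + u[, 2],
          A[3, 1] * g$x + A[3, 2] * g$y + A[3, 3] * g$z + A[3, 4] + u[, 3])
  }
  u_full <- if (!identical(st$dm, fx$dim))
    upsample_disp(st$u, st$dm, st$sp, fx$dim, fx$spacing) else st$u
  mj <- min_jacobian(make_phi(u_full), fx$dim, fx$spacing)
  folded <- FALSE
  if (mj < params$jac_min) {
    st <- run_stages(params$bending_weight * 10)
    u_full <- if (!identical(st$dm, fx$dim))
      upsample_disp(st$u, st$dm, st$sp, fx$dim, fx$spacing) else st$u
    mj <- min_jacobian(make_phi(u_full), fx$dim, fx$spacing)
    if (mj < params$jac_min) {
      folded <- TRUE
      warning("deformation remains close to folding (min |J| = ",
              signif(mj, 3), "); result flagged")
    }
  }

  g <- grid_world(fx$dim, fx$spacing)
  disp <- array(0, c(fx$dim, 3))
  disp[, , , 1] <- make_phi(u_full)[, 1] - g$x
  disp[, , , 2] <- make_phi(u_full)[, 2] - g$y
  disp[, , , 3] <- make_phi(u_full)[, 3] - g$z
  structure(
    list(disp = disp, fixed_dim = fx$dim, fixed_spacing = fx$spacing,
         moving_dim = mv$dim, moving_spacing = mv$spacing,
         ctrl_spacing_mm = params$ctrl_spacing_mm,
         min_jacobian = mj, folded = folded,
         similarity = c(pre = st$cost[1], post = st$cost[2])),
    class = "deformation_field"
  )
}

#' Construct a deformation field from a displacement array
#'
#' Wraps a raw displacement array (fixed-grid world mm, dimensions
#' `c(dim, 3)`) as a `deformation_field`, e.g. to apply a known synthetic
#' warp with [warp_intensity()]/[warp_labels()].
#'
#' @param disp 4D displacement array `(nx, ny, nz, 3)` in mm.
#' @param spacing Fixed-grid voxel spacing (mm).
#' @param moving_dim,moving_spacing Moving grid (defaults to the fixed grid).
#' @return A `deformation_field`.
#' @export
as_deformation_field <- function(disp, spacing = c(1, 1, 1),
                                 moving_dim = dim(disp)[1:3],
                                 moving_spacing = spacing) {
  stopifnot(length(dim(disp)) == 4L, dim(disp)[4] == 3L)
  dm <- dim(disp)[1:3]
  spacing <- rep_len(as.numeric(spacing), 3L)
  g <- grid_world(dm, spacing)
  phi <- cbind(g$x + as.numeric(disp[, , , 1]),
               g$y + as.numeric(disp[, , , 2]),
               g$z + as.numeric(disp[, , , 3]))
  structure(
    list(disp = disp, fixed_dim = dm, fixed_spacing = spacing,
         moving_dim = moving_dim, moving_spacing = moving_spacing,
         ctrl_spacing_mm = NA_real_,
         min_jacobian = min_jacobian(phi, dm, spacing), folded = FALSE,
         similarity = c(pre = NA_real_, post = NA_real_)),
    class = "deformation_field"
  )
}

#' Random smooth displacement field
#'
#' Seeded white-noise vector field smoothed with a Gaussian kernel and
#' scaled to a target root-mean-square magnitude: the same family the
#' cohort generator uses for inter-subject variability.
#'
#' @param dim Grid dimensions (length 3).
#' @param spacing Voxel spacing (mm).
#' @param magnitude_mm Target RMS magnitude (mm).
#' @param smoothness_mm Gaussian kernel width (mm).
#' @param seed Integer seed.
#' @return 4D displacement array `(dim, 3)` in mm.
#' @export
random_smooth_field <- function(dim, spacing = c(1, 1, 1), magnitude_mm = 3,
                                smoothness_mm = 14, seed = 1L) {
  dim <- as.integer(rep_len(dim, 3L))
  spacing <- rep_len(as.numeric(spacing), 3L)
  u <- with_seed(seed, sample_displacement(dim, spacing, magnitude_mm,
                                           smoothness_mm))
  array(u, c(dim, 3L))
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(x$disp[, , , 1]^2 + x$disp[, , , 2]^2 + x$disp[, , , 3]^2)
  cat("<deformation_field>", paste(x$fixed_dim, collapse = "x"),
      "grid; mean |u| =", signif(mean(mag), 4), "mm; min |J| =",
      signif(x$min_jacobian, 4), "\n")
  invisible(x)
}

#' Warp an intensity volume
#'
#' Resamples `volume` (living on the transform's moving grid) onto the
#' fixed grid with trilinear interpolation; out-of-field voxels take the
#' background value.
#'
#' @param volume 3D array on the moving grid.
#' @param transform `affine_transform` or `deformation_field`.
#' @param background Fill value outside the moving field of view.
#' @return 3D array on the fixed grid.
#' @export
warp_intensity <- function(volume, transform, background = 0) {
  co <- transform_coords(transform)
  out <- cpp_resample_trilinear(as.numeric(volume), dim(volume),
                                co$x, co$y, co$z, background)
  with_spacing(array(out, co$dim),
               if (inherits(transform, "affine_transform"))
                 attr(transform, "fixed_spacing") else transform$fixed_spacing)
}

#' Warp a label volume
#'
#' Nearest-neighbour resampling only: no label value is ever interpolated,
#' so the output label set is a subset of the input's (plus background).
#'
#' @inheritParams warp_intensity
#' @param labels Integer label volume on the moving grid.
#' @export
warp_labels <- function(labels, transform) {
  co <- transform_coords(transform)
  out <- cpp_resample_nn(as.integer(labels), dim(labels),
                         co$x, co$y, co$z, 0L)
  with_spacing(array(out, co$dim),
               if (inherits(transform, "affine_transform"))
                 attr(transform, "fixed_spacing") else transform$fixed_spacing)
}

#' Compose two transforms
#'
#' Returns the transform equivalent to applying `first` and then `second`
#' (i.e. the map `x -> second(first(x))`). Two affines compose exactly by
#' matrix product; a deformation field composed with an affine is evaluated
#' analytically at the grid points.
#'
#' @param first,second Transforms.
#' @return An `affine_transform` or `deformation_field`.
#' @export
compose_transforms <- function(first, second) {
  if (inherits(first, "affine_transform") &&
      inherits(second, "affine_transform")) {
    m <- unclass(second) %*% unclass(first)
    return(new_affine(m, list(dim = attr(first, "fixed_dim"),
                              spacing = attr(first, "fixed_spacing")),
                      list(dim = attr(second, "moving_dim"),
                           spacing = attr(second, "moving_spacing"))))
  }
  if (inherits(first, "deformation_field") &&
      inherits(second, "affine_transform")) {
    A <- unclass(second)
    dmf <- first$fixed_dim
    spf <- first$fixed_spacing
    g <- grid_world(dmf, spf)
    y <- cbind(g$x + as.numeric(first$disp[, , , 1]),
               g$y + as.numeric(first$disp[, , , 2]),
               g$z + as.numeric(first$disp[, , , 3]))
    z <- cbind(A[1, 1] * y[, 1] + A[1, 2] * y[, 2] + A[1, 3] * y[, 3] + A[1, 4],
               A[2, 1] * y[, 1] + A[2, 2] * y[, 2] + A[2, 3] * y[, 3] + A[2, 4],
               A[3, 1] * y[, 1] + A[3, 2] * y[, 2] + A[3, 3] * y[, 3] + A[3, 4])
    disp <- array(0, c(dmf, 3))
    disp[, , , 1] <- z[, 1] - g$x
    disp[, , , 2] <- z[, 2] - g$y
    disp[, , , 3] <- z[, 3] - g$z
    out <- first
    out$disp <- disp
    out$moving_dim <- attr(second, "moving_dim")
    out$moving_spacing <- attr(second, "moving_spacing")
    return(out)
  }
  stop("unsupported composition")
}
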