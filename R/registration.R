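## Spatial transforms and the two-stage (rigid/landmark + demons) registration
## used by both the bone-atlas and synCT-to-planCT alignment steps.

#' Spatial transform: affine plus optional dense displacement field
#'
#' The transform maps world coordinates of the *fixed* (target) image into
#' the *moving* (source) image as `T(x) = A (x + u(x))`, where `u` is a dense
#' displacement field defined on the fixed grid (zero when absent). Warping a
#' moving image onto the fixed grid samples it at `T(x)` (pull-back).
#'
#' @param affine 4x4 affine matrix (row `[0 0 0 1]` last).
#' @param field optional list of three arrays (`x`, `y`, `z`; mm) on the
#'   fixed grid.
#' @param grid a `volume_grid` (or list with `spacing`/`origin`) describing
#'   the fixed grid when a field is present.
#' @param trace optional numeric vector of the similarity metric across
#'   accepted iterations.
#' @return object of class `spatial_transform`.
#' @export
spatial_transform <- function(affine = diag(4), field = NULL, grid = NULL,
                              trace = NULL) {
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4, 4)))
  if (abs(det(affine[1:3, 1:3])) < 1e-12) stop("affine must be invertible")
  structure(list(affine = affine, field = field, grid = grid, trace = trace),
            class = "spatial_transform")
}

#' @export
print.spatial_transform <- function(x, ...) {
  t3 <- x$affine[1:3, 4]
  cat(sprintf("<spatial_transform> translation (%.2f, %.2f, %.2f) mm%s\n",
              t3[1], t3[2], t3[3],
              if (is.null(x$field)) "" else
                sprintf(", dense field (max %.2f mm)", max_field_norm(x))))
  invisible(x)
}

max_field_norm <- function(t) {
  if (is.null(t$field)) return(0)
  max(sqrt(t$field$x^2 + t$field$y^2 + t$field$z^2))
}

is_identity_transform <- function(t, tol = 1e-6) {
  max(abs(t$affine - diag(4))) < tol && max_field_norm(t) < tol
}

#' Map world points through a spatial transform
#' @param t a `spatial_transform`.
#' @param points n-by-3 matrix of world coordinates (mm).
#' @return n-by-3 matrix of mapped coordinates.
#' @export
transform_points <- function(t, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  p <- points
  if (!is.null(t$field)) {
    g <- t$grid
    for (a in 1:3) {
      u <- sample_points_cpp(as.numeric(t$field[[a]]), dim(t$field[[a]]),
                             g$spacing, g$origin, points, 0)
      p[, a] <- p[, a] + u
    }
  }
  ph <- cbind(p, 1) %*% t(t$affine)
  ph[, 1:3, drop = FALSE]
}

#' Warp a volume through a spatial transform onto a target grid
#'
#' @param volume moving `volume_grid`.
#' @param t a `spatial_transform` mapping target world coords into the
#'   moving image.
#' @param target `volume_grid` providing the output geometry (default: the
#'   moving volume's own grid).
#' @param method interpolation; use `"nearest"` for labels and masks.
#' @param fill value outside the moving volume.
#' @return `volume_grid` on the target grid. An exact identity transform on
#'   an identical grid returns the input unchanged.
#' @export
apply_transform <- function(volume, t, target = volume,
                            method = c("trilinear", "nearest"), fill = NA) {
  method <- match.arg(method)
  if (is.na(fill)) fill <- min(volume$values)
  if (is_identity_transform(t) && same_grid(volume, target)) return(volume)
  d <- dim(target$values)
  if (is.null(t$field)) {
    vals <- affine_warp_cpp(as.numeric(volume$values), dim(volume$values),
                            volume$spacing, volume$origin, t$affine,
                            d, target$spacing, target$origin,
                            method == "nearest", fill)
  } else {
    # compose: sample at A(x + u(x)); fold affine into shifted points by
    # computing an effective displacement on the target grid
    cc <- voxel_centers(target)
    pts <- cbind(as.numeric(cc$x), as.numeric(cc$y), as.numeric(cc$z))
    g <- t$grid
    for (a in 1:3) {
      u <- sample_points_cpp(as.numeric(t$field[[a]]), dim(t$field[[a]]),
                             g$spacing, g$origin, pts, 0)
      pts[, a] <- pts[, a] + u
    }
    ph <- cbind(pts, 1) %*% t(t$affine)
    ux <- array(ph[, 1] - as.numeric(cc$x), d)
    uy <- array(ph[, 2] - as.numeric(cc$y), d)
    uz <- array(ph[, 3] - as.numeric(cc$z), d)
    vals <- warp_field_cpp(as.numeric(volume$values), dim(volume$values),
                           volume$spacing, volume$origin,
                           as.numeric(ux), as.numeric(uy), as.numeric(uz),
                           d, target$spacing, target$origin,
                           method == "nearest", fill)
  }
  volume_grid(array(vals, d), target$spacing, target$origin,
              role = volume$role)
}

rigid_affine <- function(par, center) {
  cx <- cos(par[4]); sx <- sin(par[4])
  cy <- cos(par[5]); sy <- sin(par[5])
  cz <- cos(par[6]); sz <- sin(par[6])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  R <- Rz %*% Ry %*% Rx
  A <- diag(4)
  A[1:3, 1:3] <- R
  A[1:3, 4] <- center - R %*% center + par[1:3]
  A
}

#' Rigid (6-DOF) intensity registration
#'
#' Minimises the mean squared intensity difference between the fixed image
#' and the warped moving image by Nelder-Mead over three translations and
#' three rotations, on a downsampled grid for speed. Near-zero solutions are
#' snapped to the exact identity so that already-aligned inputs round-trip
#' without resampling.
#'
#' @param moving,fixed `volume_grid`s.
#' @param downsample integer resolution reduction factor for the metric.
#' @param maxit Nelder-Mead iteration cap.
#' @return `spatial_transform` (affine only) with the metric trace attached.
#' @export
register_rigid <- function(moving, fixed, downsample = 3L, maxit = 200L) {
  ds <- function(v) {
    if (downsample <= 1L) return(v)
    resample_volume(v, v$spacing * downsample, fill = min(v$values))
  }
  mv <- ds(moving); fx <- ds(fixed)
  center <- fx$origin + dim(fx$values) * fx$spacing / 2
  fvals <- as.numeric(fx$values)
  mvals <- as.numeric(mv$values)
  mdim <- dim(mv$values); fdim <- dim(fx$values)
  fill <- min(moving$values)
  metric <- function(par) {
    A <- rigid_affine(par, center)
    w <- affine_warp_cpp(mvals, mdim, mv$spacing, mv$origin, A,
                         fdim, fx$spacing, fx$origin, FALSE, fill)
    mean((w - fvals)^2)
  }
  m0 <- metric(rep(0, 6))
  if (m0 == 0) return(spatial_transform(diag(4), trace = 0))
  scale <- c(rep(1, 3), rep(0.02, 3))
  opt <- optim(rep(0, 6), function(p) metric(p * scale),
               method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-8))
  par <- opt$par * scale
  if (opt$value > m0) par <- rep(0, 6) # never accept a worse-than-start fit
  if (max(abs(par[1:3])) < 5e-3 && max(abs(par[4:6])) < 1e-5)
    return(spatial_transform(diag(4), trace = c(m0, min(opt$value, m0))))
  spatial_transform(rigid_affine(par, center), trace = c(m0, opt$value))
}

#' Demons-style deformable refinement
#'
#' Thirion-type demons: per-iteration force
#' `(m - f) grad(f) / (|grad f|^2 + (m - f)^2 / s^2)` with Gaussian field
#' regularisation, run coarse-to-fine. Iterations are accepted only while
#' the mean-squared-difference metric improves; if the metric never improves
#' on its starting value the registration is declared divergent and errors
#' with the iteration log.
#'
#' @param moving,fixed `volume_grid`s on the same grid (pre-align with
#'   [register_rigid()] or a landmark affine first; pass the pre-warped
#'   moving image).
#' @param iterations demons iterations: a scalar, or one value per
#'   resolution level (coarsest first).
#' @param sigma_field Gaussian smoothing SD of the field, in voxels.
#' @param levels resolution levels (2 = half then full).
#' @param step_cap maximum per-iteration displacement update (mm).
#' @return `spatial_transform` with identity affine and a dense field on the
#'   fixed grid, metric trace attached.
#' @export
register_demons <- function(moving, fixed, iterations = c(30L, 10L),
                            sigma_field = 2.0, levels = 2L, step_cap = 2.0) {
  stopifnot_same_grid(moving, fixed, "demons inputs")
  if (length(iterations) == 1L) iterations <- rep(iterations, levels)
  if (length(iterations) != levels)
    stop("iterations must have length 1 or `levels`")
  rng <- range(fixed$values)
  scl <- if (diff(rng) > 0) diff(rng) else 1
  norm_m <- volume_grid((moving$values - rng[1]) / scl, moving$spacing,
                        moving$origin)
  norm_f <- volume_grid((fixed$values - rng[1]) / scl, fixed$spacing,
                        fixed$origin)
  field <- NULL
  trace_all <- numeric(0)
  improved_any <- FALSE
  for (lev in seq(levels, 1)) {
    fac <- 2^(lev - 1)
    f_l <- if (fac > 1) resample_volume(norm_f, norm_f$spacing * fac, fill = 0) else norm_f
    m_l <- if (fac > 1) resample_volume(norm_m, norm_m$spacing * fac, fill = 0) else norm_m
    d <- dim(f_l$values)
    if (is.null(field)) {
      u <- list(x = array(0, d), y = array(0, d), z = array(0, d))
    } else {
      u <- lapply(field, function(ua) {
        vg <- volume_grid(ua, f_prev$spacing, f_prev$origin)
        resample_volume(vg, f_l$spacing, dim = d, origin = f_l$origin,
                        fill = 0)$values
      })
      names(u) <- c("x", "y", "z")
    }
    g <- gradient_cpp(as.numeric(f_l$values), d, f_l$spacing)
    gx <- array(g$x, d); gy <- array(g$y, d); gz <- array(g$z, d)
    g2 <- gx^2 + gy^2 + gz^2
    s2 <- mean(f_l$spacing)^2
    warp_m <- function(u) apply_displacement(m_l, u, fill = 0)
    best <- mean((warp_m(u)$values - f_l$values)^2)
    trace_lvl <- best
    for (it in seq_len(iterations[levels - lev + 1L])) {
      mw <- warp_m(u)$values
      diffv <- mw - f_l$values
      den <- g2 + diffv^2 / s2
      den[den < 1e-12] <- 1e-12
      fct <- -diffv / den
      dux <- fct * gx; duy <- fct * gy; duz <- fct * gz
      nrm <- sqrt(dux^2 + duy^2 + duz^2)
      over <- nrm > step_cap
      if (any(over)) {
        s <- step_cap / nrm[over]
        dux[over] <- dux[over] * s; duy[over] <- duy[over] * s
        duz[over] <- duz[over] * s
      }
      u_new <- list(
        x = array(gauss_smooth_cpp(as.numeric(u$x + dux), d, rep(sigma_field, 3)), d),
        y = array(gauss_smooth_cpp(as.numeric(u$y + duy), d, rep(sigma_field, 3)), d),
        z = array(gauss_smooth_cpp(as.numeric(u$z + duz), d, rep(sigma_field, 3)), d))
      m_new <- mean((warp_m(u_new)$values - f_l$values)^2)
      if (m_new >= best) break
      u <- u_new
      best <- m_new
      trace_lvl <- c(trace_lvl, best)
    }
    if (length(trace_lvl) > 1L && trace_lvl[length(trace_lvl)] < trace_lvl[1])
      improved_any <- TRUE
    trace_all <- c(trace_all, trace_lvl)
    field <- u
    f_prev <- f_l
  }
  # metrics are only comparable within a level; divergence means no level
  # ever improved on its own starting value (a perfect start counts as fine)
  if (!improved_any && trace_all[1] > 0) {
    err <- simpleError("deformable registration diverged: metric never improved")
    err$trace <- trace_all
    stop(err)
  }
  spatial_transform(diag(4), field = field,
                    grid = list(spacing = fixed$spacing, origin = fixed$origin),
                    trace = trace_all)
}

compose_affine_field <- function(affine_t, field_t) {
  # T(x) = A (x + u(x)): affine from stage 1, field from stage 2
  spatial_transform(affine_t$affine, field = field_t$field,
                    grid = field_t$grid,
                    trace = c(affine_t$trace, field_t$trace))
}

#' Least-squares landmark transform (affine, or rigid when rank-deficient)
#'
#' @param from n-by-3 landmark coordinates in the fixed image (mm).
#' @param to matching coordinates in the moving image.
#' @return `spatial_transform` mapping fixed world coords to moving.
#' @export
landmark_transform <- function(from, to) {
  from <- matrix(as.numeric(from), ncol = 3)
  to <- matrix(as.numeric(to), ncol = 3)
  n <- nrow(from)
  if (n < 3L) stop("at least 3 non-collinear landmarks are required")
  cf <- colMeans(from)
  sv <- svd(sweep(from, 2, cf))
  if (sum(sv$d > 1e-8 * sv$d[1]) < 2L)
    stop("at least 3 non-collinear landmarks are required (landmarks are collinear)")
  X <- cbind(from, 1)
  if (n >= 4L && qr(X)$rank == 4L) {
    B <- qr.solve(X, to) # 4x3; rows: linear part + offset
    A <- diag(4)
    A[1:3, 1:3] <- t(B[1:3, ])
    A[1:3, 4] <- B[4, ]
    return(spatial_transform(A))
  }
  # Kabsch rigid fallback
  ct <- colMeans(to)
  H <- t(sweep(from, 2, cf)) %*% sweep(to, 2, ct)
  sv <- svd(H)
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  A <- diag(4)
  A[1:3, 1:3] <- R
  A[1:3, 4] <- ct - R %*% cf
  spatial_transform(A)
}
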