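## Digital thorax phantom: ground-truth CT, tissue labels, structures,
## simulated Dixon pair, controlled misalignment.

#' Tissue class codes, attenuation coefficients and Hounsfield units
#'
#' Integer label codes used throughout (`air = 0`, `fat = 1`, `lung = 2`,
#' `soft_tissue = 3`, `bone = 4`), the 511 keV linear attenuation
#' coefficients assigned to the four soft classes (cm^-1), their CT
#' Hounsfield units, and the bone LAC/HU anchor points of the piecewise
#' conversion (bone LAC 0.1 -> 70 HU, 0.2485 -> 2661 HU).
#'
#' @format Named numeric vectors.
#' @export
TISSUE_CODES <- c(air = 0L, fat = 1L, lung = 2L, soft_tissue = 3L, bone = 4L)

#' @rdname TISSUE_CODES
#' @export
TISSUE_LAC <- c(air = 0.0, fat = 0.0854, lung = 0.0224, soft_tissue = 0.1)

#' @rdname TISSUE_CODES
#' @export
TISSUE_HU <- c(air = -1000, fat = -110, lung = -767, soft_tissue = 70)

#' @rdname TISSUE_CODES
#' @export
BONE_LAC_RANGE <- c(0.1, 0.2485)

#' @rdname TISSUE_CODES
#' @export
BONE_HU_RANGE <- c(70, 2661)

#' PTV size classes: mean and SD of sphere volume in cm^3
#' @rdname TISSUE_CODES
#' @export
PTV_SIZE_CLASSES <- list(
  small  = c(mean = 11.9,  sd = 5.5),
  medium = c(mean = 83.5,  sd = 14.5),
  large  = c(mean = 222.3, sd = 39.8)
)

#' Specification of a digital thorax phantom
#'
#' Geometry is a body ellipsoid with a subcutaneous fat shell, two lung
#' ellipsoids, a spherical heart, a vertebral column (bone cylinder) holding
#' the spinal cord, and one spherical PTV inside a lung. Per-tissue true HU
#' means default to the class values the synthetic CT itself assigns (plus
#' spine bone at 336 HU), so that perfect classification reproduces the
#' ground truth exactly; per-tissue Gaussian noise SDs are free parameters.
#'
#' @param dim grid size in voxels (length 3).
#' @param spacing voxel size in mm (length 1 or 3).
#' @param ptv_size_class `"small"`, `"medium"` or `"large"` (means 11.9,
#'   83.5, 222.3 cm^3).
#' @param ptv_location `"apex"`, `"mediastinum"`, `"ribs"` or `"spine"`.
#' @param ptv_volume_cm3 explicit PTV volume; `NULL` draws from the size
#'   class (truncated at 1.5 SD so every draw stays placeable and within the
#'   class's mean +/- 2 SD).
#' @param ptv_lung which lung hosts the PTV.
#' @param hu_mean named per-tissue true HU means.
#' @param noise_sd named per-tissue CT noise SDs (HU).
#' @param mr_spacing spacing of the simulated Dixon grid; `NULL` = CT grid.
#' @param dixon_signals 5 x 2 matrix of (water, fat) signal means per class.
#' @param dixon_noise_sd Gaussian noise SD of the simulated Dixon signals.
#' @param seed integer random seed; fixed seed gives byte-identical phantoms.
#' @param ptv_seed optional separate seed for the PTV volume draw, so that
#'   several PTVs can share one patient's anatomy and noise realisation.
#' @param body_semiaxes,fat_shell_mm,lung_semiaxes,lung_center_x,lung_center_y,
#'   heart_center,heart_radius,spine_y,spine_radius,cord_radius geometry (mm).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(96, 96, 96), spacing = 2.5,
                         ptv_size_class = c("medium", "small", "large"),
                         ptv_location = c("mediastinum", "apex", "ribs", "spine"),
                         ptv_volume_cm3 = NULL,
                         ptv_lung = c("right", "left"),
                         hu_mean = c(air = -1000, fat = -110, lung = -767,
                                     soft_tissue = 70, bone = 336),
                         noise_sd = c(air = 5, fat = 20, lung = 30,
                                      soft_tissue = 20, bone = 40),
                         mr_spacing = NULL,
                         dixon_signals = NULL,
                         dixon_noise_sd = 20,
                         seed = 1L, ptv_seed = NULL,
                         body_semiaxes = c(105, 82, 115),
                         fat_shell_mm = 7,
                         lung_semiaxes = c(44, 58, 90),
                         lung_center_x = 50, lung_center_y = -4,
                         heart_center = c(10, 5, -25), heart_radius = 32,
                         spine_y = 55, spine_radius = 14, cord_radius = 5) {
  spacing <- if (length(spacing) == 1L) rep(spacing, 3L) else as.numeric(spacing)
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  if (is.null(dixon_signals)) {
    # (water, fat) signal means; arbitrary consistent units. Bone is given a
    # marrow-like soft signal so the 4-class Dixon classifier maps it to
    # soft tissue, which is where the atlas later re-inserts bone.
    dixon_signals <- rbind(air = c(0, 0), fat = c(150, 1000),
                           lung = c(40, 20), soft_tissue = c(1000, 100),
                           bone = c(600, 250))
    colnames(dixon_signals) <- c("water", "fat")
  }
  need <- c("air", "fat", "lung", "soft_tissue", "bone")
  if (!all(need %in% names(hu_mean))) stop("hu_mean must name all five tissues")
  if (!all(need %in% names(noise_sd))) stop("noise_sd must name all five tissues")
  structure(list(
    dim = as.integer(dim), spacing = spacing,
    ptv_size_class = match.arg(ptv_size_class),
    ptv_location = match.arg(ptv_location),
    ptv_volume_cm3 = ptv_volume_cm3,
    ptv_lung = match.arg(ptv_lung),
    hu_mean = hu_mean[need], noise_sd = noise_sd[need],
    mr_spacing = mr_spacing,
    dixon_signals = dixon_signals[need, , drop = FALSE],
    dixon_noise_sd = dixon_noise_sd, seed = as.integer(seed),
    ptv_seed = if (is.null(ptv_seed)) NULL else as.integer(ptv_seed),
    body_semiaxes = body_semiaxes, fat_shell_mm = fat_shell_mm,
    lung_semiaxes = lung_semiaxes, lung_center_x = lung_center_x,
    lung_center_y = lung_center_y, heart_center = heart_center,
    heart_radius = heart_radius, spine_y = spine_y,
    spine_radius = spine_radius, cord_radius = cord_radius
  ), class = "phantom_spec")
}

#' Named set of binary structure masks sharing one grid
#'
#' @param masks named list of logical 3D arrays (or 0/1 `volume_grid`s).
#' @param grid a `volume_grid` carrying the shared geometry.
#' @return an object of class `structure_set`.
#' @export
structure_set <- function(masks, grid) {
  masks <- lapply(masks, as_mask)
  d <- dim(grid$values)
  for (nm in names(masks))
    if (!identical(dim(masks[[nm]]), d))
      stop(sprintf("mask '%s' is not on the shared grid", nm))
  structure(list(masks = masks, spacing = grid$spacing, origin = grid$origin),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat("<structure_set>\n")
  for (nm in names(x$masks))
    cat(sprintf("  %-12s %d voxels (%.1f cm3)\n", nm, sum(x$masks[[nm]]),
                sum(x$masks[[nm]]) * prod(x$spacing) / 1000))
  invisible(x)
}

mask_grid <- function(ss, name) {
  volume_grid(ss$masks[[name]] * 1, ss$spacing, ss$origin, role = "mask")
}

# largest offset t along `dir` keeping a sphere of radius r centred at
# L + t*dir inside the axis-aligned ellipsoid (semi-axes s, centre L);
# checked on a dense set of surface directions.
max_sphere_offset <- function(s, r, dir) {
  if (r > min(s)) return(-1)
  u <- as.matrix(expand.grid(th = seq(0, pi, length.out = 25),
                             ph = seq(0, 2 * pi, length.out = 49)))
  du <- cbind(sin(u[, 1]) * cos(u[, 2]), sin(u[, 1]) * sin(u[, 2]), cos(u[, 1]))
  fits <- function(t) {
    ctr <- t * dir
    p <- sweep(du * r, 2, ctr, "+")
    max(rowSums(sweep(p, 2, s, "/")^2)) <= 1
  }
  if (!fits(0)) return(-1)
  lo <- 0; hi <- max(s)
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    if (fits(mid)) lo <- mid else hi <- mid
  }
  lo
}

#' Build a digital thorax phantom
#'
#' Rasterises the geometry into a tissue label map, draws the ground-truth CT
#' as per-tissue HU means plus seeded Gaussian noise, and assembles the
#' structure set (body, lungs, heart, spinal cord, spine, PTV). The PTV is a
#' sphere of the requested volume placed inside a lung according to the
#' location class; it is rasterised as the exact number of lung voxels
#' closest to the sphere centre, so its volume matches the request to within
#' one voxel volume.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `thorax_phantom`: list with `labels` (integer
#'   `volume_grid`), `ct` (HU `volume_grid`), `structures`
#'   (a [structure_set()]), `landmarks` (matrix, mm), `ptv_volume_cm3`, `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$dim; sp <- spec$spacing
  origin <- -d * sp / 2
  tmpl <- volume_grid(array(0, d), sp, origin)
  cc <- voxel_centers(tmpl)
  X <- cc$x; Y <- cc$y; Z <- cc$z

  # the lungs need a solid wall to the outside: their surface must keep
  # clear of the outer body surface (scaled ellipsoid value <= 0.96, about
  # a two-voxel margin), or classification drains the cavity
  th <- seq(0, pi, length.out = 19)
  phh <- seq(0, 2 * pi, length.out = 37)
  du <- cbind(rep(sin(th), each = 37) * cos(phh),
              rep(sin(th), each = 37) * sin(phh),
              rep(cos(th), each = 37))
  for (side in c(-1, 1)) {
    ctr <- c(side * spec$lung_center_x, spec$lung_center_y, 0)
    surf <- sweep(du %*% diag(spec$lung_semiaxes), 2, ctr, "+")
    if (max(rowSums(sweep(surf, 2, spec$body_semiaxes, "/")^2)) > 0.96)
      stop("lung ellipsoid reaches the body surface; ",
           "enlarge the body or shrink the lungs")
  }

  ell <- function(ctr, s) ((X - ctr[1]) / s[1])^2 + ((Y - ctr[2]) / s[2])^2 +
    ((Z - ctr[3]) / s[3])^2 <= 1
  body <- ell(c(0, 0, 0), spec$body_semiaxes)
  inner <- ell(c(0, 0, 0), pmax(spec$body_semiaxes - spec$fat_shell_mm, 1))
  lungL_ctr <- c(-spec$lung_center_x, spec$lung_center_y, 0)
  lungR_ctr <- c(spec$lung_center_x, spec$lung_center_y, 0)
  lungL <- ell(lungL_ctr, spec$lung_semiaxes)
  lungR <- ell(lungR_ctr, spec$lung_semiaxes)
  heart <- (X - spec$heart_center[1])^2 + (Y - spec$heart_center[2])^2 +
    (Z - spec$heart_center[3])^2 <= spec$heart_radius^2
  spine <- (X^2 + (Y - spec$spine_y)^2 <= spec$spine_radius^2) & inner
  cord <- (X^2 + (Y - spec$spine_y)^2 <= spec$cord_radius^2) & inner

  lab <- array(TISSUE_CODES["air"], d)
  lab[body] <- TISSUE_CODES["fat"]
  lab[inner] <- TISSUE_CODES["soft_tissue"]
  lab[lungL | lungR] <- TISSUE_CODES["lung"]
  lab[heart] <- TISSUE_CODES["soft_tissue"]
  lab[spine] <- TISSUE_CODES["bone"]
  lab[cord] <- TISSUE_CODES["soft_tissue"]

  lungL_mask <- lungL & lab == TISSUE_CODES["lung"]
  lungR_mask <- lungR & lab == TISSUE_CODES["lung"]
  spine <- spine & lab == TISSUE_CODES["bone"] # the cord tunnels through

  # --- PTV placement -------------------------------------------------------
  cls <- PTV_SIZE_CLASSES[[spec$ptv_size_class]]
  vol <- spec$ptv_volume_cm3
  if (is.null(vol)) {
    if (!is.null(spec$ptv_seed)) set.seed(spec$ptv_seed)
    v <- rnorm(1, cls["mean"], cls["sd"])
    vol <- min(max(v, cls["mean"] - 1.5 * cls["sd"]), cls["mean"] + 1.5 * cls["sd"])
    if (!is.null(spec$ptv_seed)) set.seed(spec$seed)
  }
  r <- (3 * vol * 1000 / (4 * pi))^(1 / 3)
  host_ctr <- if (spec$ptv_lung == "right") lungR_ctr else lungL_ctr
  host_mask <- if (spec$ptv_lung == "right") lungR_mask else lungL_mask
  side <- if (spec$ptv_lung == "right") 1 else -1
  dir <- switch(spec$ptv_location,
                apex = c(0, 0, 1),
                mediastinum = c(-side, 0, 0),
                ribs = c(side, 0, 0),
                spine = c(0, 1, 0))
  margin <- 2
  tmax <- max_sphere_offset(spec$lung_semiaxes, r + margin, dir)
  if (tmax < 0)
    stop(sprintf(paste0("PTV of %.1f cm3 (radius %.1f mm) cannot be placed ",
                        "inside the %s lung for location '%s': sphere exceeds ",
                        "the lung"), vol, r, spec$ptv_lung, spec$ptv_location))
  ptv_ctr <- host_ctr + max(tmax - margin, 0) * dir
  n_vox <- round(vol * 1000 / prod(sp))
  dist2 <- (X - ptv_ctr[1])^2 + (Y - ptv_ctr[2])^2 + (Z - ptv_ctr[3])^2
  cand <- which(host_mask)
  if (length(cand) < n_vox)
    stop("PTV cannot be placed inside lung: not enough lung voxels")
  sel <- cand[order(dist2[cand])][seq_len(n_vox)]
  ptv <- array(FALSE, d)
  ptv[sel] <- TRUE

  ct_vals <- unname(spec$hu_mean[lab + 1L]) +
    rnorm(length(lab)) * unname(spec$noise_sd[lab + 1L])
  ct <- volume_grid(array(ct_vals, d), sp, origin, role = "hu")

  structures <- structure_set(list(
    body = body, lung_left = lungL_mask, lung_right = lungR_mask,
    heart = heart, spinal_cord = cord, spine = spine, PTV = ptv), tmpl)

  lm <- rbind(
    lung_left_apex  = lungL_ctr + c(0, 0, spec$lung_semiaxes[3]),
    lung_right_apex = lungR_ctr + c(0, 0, spec$lung_semiaxes[3]),
    lung_left_base  = lungL_ctr - c(0, 0, spec$lung_semiaxes[3]),
    lung_right_base = lungR_ctr - c(0, 0, spec$lung_semiaxes[3]),
    heart_center    = spec$heart_center,
    spine_top       = c(0, spec$spine_y, 0.8 * spec$body_semiaxes[3]),
    spine_bottom    = c(0, spec$spine_y, -0.8 * spec$body_semiaxes[3]))
  colnames(lm) <- c("x", "y", "z")

  structure(list(labels = volume_grid(lab, sp, origin, role = "labels"),
                 ct = ct, structures = structures, landmarks = lm,
                 ptv_volume_cm3 = n_vox * prod(sp) / 1000, spec = spec),
            class = "thorax_phantom")
}

#' @export
print.thorax_phantom <- function(x, ...) {
  cat(sprintf("<thorax_phantom> %s grid, %s/%s PTV of %.1f cm3 (seed %d)\n",
              paste(dim(x$labels$values), collapse = "x"),
              x$spec$ptv_size_class, x$spec$ptv_location,
              x$ptv_volume_cm3, x$spec$seed))
  invisible(x)
}

#' Simulate a two-point Dixon water/fat signal pair from a label map
#'
#' Each tissue class emits declared mean water and fat signals (fat voxels
#' fat-dominant, soft tissue water-dominant, lung faint, air zero, bone
#' marrow-like) plus seeded Gaussian noise, clipped at zero. When the spec
#' requests a coarser MR grid the labels are first resampled there with
#' nearest-neighbour interpolation.
#'
#' @param labels integer label `volume_grid` (from [build_phantom()]).
#' @param spec the generating [phantom_spec()].
#' @return an object of class `dixon_pair`: `water` and `fat` `volume_grid`s
#'   plus the noise SD used.
#' @export
simulate_dixon <- function(labels, spec) {
  stopifnot(inherits(labels, "volume_grid"))
  if (!is.null(spec$mr_spacing)) {
    labels <- resample_volume(labels, spec$mr_spacing, method = "nearest",
                              fill = TISSUE_CODES["air"])
  }
  set.seed(spec$seed + 1L)
  lab <- labels$values
  sig <- spec$dixon_signals
  w <- array(sig[lab + 1L, "water"], dim(lab))
  f <- array(sig[lab + 1L, "fat"], dim(lab))
  if (spec$dixon_noise_sd > 0) {
    w <- w + rnorm(length(w)) * spec$dixon_noise_sd
    f <- f + rnorm(length(f)) * spec$dixon_noise_sd
  }
  w[w < 0] <- 0; f[f < 0] <- 0
  structure(list(
    water = volume_grid(w, labels$spacing, labels$origin, role = "mr"),
    fat = volume_grid(f, labels$spacing, labels$origin, role = "mr"),
    noise_sd = spec$dixon_noise_sd), class = "dixon_pair")
}

#' @export
print.dixon_pair <- function(x, ...) {
  cat(sprintf("<dixon_pair> %s voxels, noise SD %.3g\n",
              paste(dim(x$water$values), collapse = "x"), x$noise_sd))
  invisible(x)
}

#' Apply a smooth random misalignment to a volume
#'
#' Emulates the residual breath-hold-MR versus free-breathing-CT mismatch: a
#' smooth random displacement field (trilinear upsampling of a coarse random
#' control grid) scaled so its maximum norm equals `magnitude`, applied as a
#' pull-back warp `out(x) = in(x + u(x))`. The true field is returned for
#' registration-recovery tests.
#'
#' @param volume a `volume_grid`.
#' @param magnitude maximum displacement norm in mm (0 returns the input and
#'   a zero field).
#' @param seed integer seed.
#' @param n_control control points per axis of the coarse random grid.
#' @param method interpolation for the warp.
#' @return list with `volume` (warped), `field` (list of 3 arrays, mm) and
#'   `magnitude`.
#' @export
perturb_geometry <- function(volume, magnitude, seed = 1L, n_control = 5L,
                             method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(magnitude >= 0)
  d <- dim(volume$values)
  if (magnitude == 0) {
    zero <- array(0, d)
    return(list(volume = volume, field = list(x = zero, y = zero, z = zero),
                magnitude = 0))
  }
  set.seed(as.integer(seed))
  field <- lapply(1:3, function(a) {
    coarse <- volume_grid(array(rnorm(n_control^3), rep(n_control, 3)),
                          spacing = d * volume$spacing / n_control,
                          origin = volume$origin)
    fine <- resample_volume(coarse, volume$spacing, dim = d,
                            origin = volume$origin, fill = 0)
    gauss_smooth_cpp(as.numeric(fine$values), d, rep(1.5, 3))
  })
  nrm <- sqrt(field[[1]]^2 + field[[2]]^2 + field[[3]]^2)
  scl <- magnitude / max(nrm)
  field <- lapply(field, function(u) array(u * scl, d))
  warped <- apply_displacement(volume, field, method = method)
  list(volume = warped,
       field = list(x = field[[1]], y = field[[2]], z = field[[3]]),
       magnitude = magnitude)
}

#' Warp a volume by a dense displacement field (pull-back)
#'
#' @param volume a `volume_grid`.
#' @param field list of three arrays (`x`, `y`, `z`) of displacements in mm on
#'   the same grid.
#' @param method interpolation.
#' @param fill value outside the source.
#' @return warped `volume_grid`.
#' @export
apply_displacement <- function(volume, field, method = c("trilinear", "nearest"),
                               fill = NA) {
  method <- match.arg(method)
  d <- dim(volume$values)
  if (is.na(fill)) fill <- min(volume$values)
  if (max(abs(field[[1]])) == 0 && max(abs(field[[2]])) == 0 &&
      max(abs(field[[3]])) == 0) return(volume)
  vals <- warp_field_cpp(as.numeric(volume$values), d, volume$spacing,
                         volume$origin, as.numeric(field[[1]]),
                         as.numeric(field[[2]]), as.numeric(field[[3]]),
                         d, volume$spacing, volume$origin,
                         method == "nearest", fill)
  volume_grid(array(vals, d), volume$spacing, volume$origin, role = volume$role)
}
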