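#' 3D scalar volume on a regular grid
#'
#' The common carrier for CT Hounsfield units, Dixon MR signals, linear
#' attenuation coefficients, relative electron density and absorbed dose.
#' World coordinates follow the voxel-centre convention
#' `world = origin + (index - 1 + 0.5) * spacing` (R's 1-based indices;
#' internally 0-based), axes in LPS-like order (x, y, z); `spacing` and
#' `origin` are in mm.
#'
#' @param values numeric 3D array (or vector with `dim` attribute).
#' @param spacing positive length-3 numeric, voxel size in mm.
#' @param origin length-3 numeric, world position of the grid corner in mm.
#' @param role optional tag ("hu", "lac", "density", "dose", "mr", "mask").
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(values, spacing, origin = NULL, role = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers (mm)")
  if (is.null(origin)) origin <- -dim(values) * spacing / 2
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must have length 3")
  structure(list(values = values, spacing = spacing, origin = origin,
                 role = role),
            class = "volume_grid")
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_grid%s> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              if (is.null(x$role)) "" else paste0(" ", x$role),
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.1f, %.1f, %.1f) mm, range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Volume of one voxel in cm^3
#' @param x a `volume_grid`.
#' @return scalar, cm^3.
#' @export
voxel_volume_cm3 <- function(x) prod(x$spacing) / 1000

#' World coordinates of all voxel centres
#'
#' @param x a `volume_grid`.
#' @return list of three arrays (`x`, `y`, `z`) with the grid's dimensions.
#' @export
voxel_centers <- function(x) {
  d <- dim(x$values)
  cx <- x$origin[1] + (seq_len(d[1]) - 0.5) * x$spacing[1]
  cy <- x$origin[2] + (seq_len(d[2]) - 0.5) * x$spacing[2]
  cz <- x$origin[3] + (seq_len(d[3]) - 0.5) * x$spacing[3]
  list(x = array(cx, d),
       y = array(rep(cy, each = d[1]), d),
       z = array(rep(cz, each = d[1] * d[2]), d))
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("%s are not on the same grid (%s vs %s)", what,
                 paste(dim(a$values), collapse = "x"),
                 paste(dim(b$values), collapse = "x")))
  invisible(TRUE)
}

as_mask <- function(m) {
  if (inherits(m, "volume_grid")) m <- m$values
  storage.mode(m) <- "logical"
  m
}

#' Resample a volume onto a new grid
#'
#' Trilinear interpolation for continuous-valued volumes, nearest neighbour
#' for labels and masks. The world-coordinate extent is preserved: the target
#' grid covers the source bounding box with the requested spacing (dimensions
#' rounded up), unless `dim`/`origin` are given explicitly. Resampling onto
#' the identical grid returns the input unchanged.
#'
#' @param x a `volume_grid`.
#' @param spacing target spacing (mm), length 1 or 3.
#' @param method `"trilinear"` or `"nearest"`.
#' @param dim,origin optional explicit target geometry.
#' @param fill value used outside the source volume.
#' @return a `volume_grid` on the target grid.
#' @export
resample_volume <- function(x, spacing, method = c("trilinear", "nearest"),
                            dim = NULL, origin = NULL, fill = NA) {
  method <- match.arg(method)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop("target spacing must be positive")
  sdim <- base::dim(x$values)
  if (is.null(dim)) dim <- as.integer(ceiling(sdim * x$spacing / spacing - 1e-9))
  if (is.null(origin)) origin <- x$origin
  tgt <- volume_grid(array(0, dim), spacing, origin, role = x$role)
  if (same_grid(x, tgt)) return(x)
  if (is.na(fill)) fill <- min(x$values)
  vals <- resample_grid_cpp(as.numeric(x$values), sdim, x$spacing, x$origin,
                            as.integer(dim), spacing, as.numeric(origin),
                            method == "nearest", fill)
  volume_grid(array(vals, dim), spacing, origin, role = x$role)
}

#' Sample a volume at arbitrary world points (trilinear)
#' @param x a `volume_grid`.
#' @param points n-by-3 matrix of world coordinates (mm).
#' @param fill value returned outside the volume.
#' @return numeric vector of length `nrow(points)`.
#' @export
sample_volume <- function(x, points, fill = 0) {
  points <- matrix(as.numeric(points), ncol = 3)
  sample_points_cpp(as.numeric(x$values), dim(x$values), x$spacing, x$origin,
                    points, fill)
}
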