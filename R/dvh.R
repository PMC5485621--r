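## Cumulative DVH construction and the Dx / Vx / Dmax metric set.
## Conventions (used consistently): Vx counts voxels with dose strictly
## greater than x Gy; Dx is the largest dose still covering at least x% of
## the structure (exact sorting on voxel doses; curve queries interpolate
## linearly between bins and return the larger dose on plateaus).

#' Cumulative dose-volume histogram
#'
#' Exact voxel counting into bins of `bin_width` Gy: `volume[i]` is the
#' percentage of structure voxels with dose >= `dose[i]`. Starts at 100%
#' and falls to 0% beyond the maximum dose.
#'
#' @param dose dose `volume_grid`.
#' @param mask logical structure mask on the dose grid.
#' @param bin_width bin width in Gy.
#' @return object of class `dvh_curve` with `dose` (bin edges, Gy) and
#'   `volume` (%).
#' @export
cumulative_dvh <- function(dose, mask, bin_width = 0.01) {
  mask <- as_mask(mask)
  if (!identical(dim(mask), dim(dose$values)))
    stop("mask is not on the dose grid")
  if (!any(mask)) stop("structure mask is empty")
  dv <- dose$values[mask]
  edges <- seq(0, max(dv) + bin_width, by = bin_width)
  # volume receiving >= edge (exact counting at the bin edges)
  cnt <- length(dv) - findInterval(edges - 1e-9, sort(dv))
  structure(list(dose = edges, volume = 100 * cnt / length(dv),
                 bin_width = bin_width, n_voxels = length(dv)),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %d voxels, %d bins of %.3g Gy, max dose %.2f Gy\n",
              x$n_voxels, length(x$dose), x$bin_width, max(x$dose)))
  invisible(x)
}

#' Dose covering x% of a structure (Dx)
#'
#' `Dx` is the largest dose `d` such that at least `x`% of the structure
#' receives `>= d`. On a `volume_grid` + mask the computation is exact
#' (the `ceiling(x/100 * n)`-th largest voxel dose); on a `dvh_curve` it
#' interpolates linearly between the bounding bins.
#'
#' @param x a dose `volume_grid` or a `dvh_curve`.
#' @param ... method arguments.
#' @export
dose_at_volume <- function(x, ...) UseMethod("dose_at_volume")

#' @rdname dose_at_volume
#' @param mask logical structure mask.
#' @param pct volume percentage in (0, 100].
#' @export
dose_at_volume.volume_grid <- function(x, mask, pct, ...) {
  stopifnot(pct > 0, pct <= 100)
  mask <- as_mask(mask)
  dv <- sort(x$values[mask], decreasing = TRUE)
  dv[ceiling(pct / 100 * length(dv))]
}

#' @rdname dose_at_volume
#' @export
dose_at_volume.dvh_curve <- function(x, pct, ...) {
  stopifnot(pct > 0, pct <= 100)
  ok <- x$volume >= pct
  if (!any(ok)) return(x$dose[1])
  i <- max(which(ok)) # largest dose with coverage >= pct (plateau: larger dose)
  if (i == length(x$dose) || x$volume[i] == pct) return(x$dose[i])
  v1 <- x$volume[i]; v2 <- x$volume[i + 1]
  if (v1 == v2) return(x$dose[i])
  x$dose[i] + (v1 - pct) / (v1 - v2) * (x$dose[i + 1] - x$dose[i])
}

#' Volume percentage receiving more than x Gy (Vx)
#'
#' Strict inequality: `Vx = 100 * #(dose > x) / n`.
#'
#' @param x a dose `volume_grid` or `dvh_curve`.
#' @param ... method arguments.
#' @export
volume_at_dose <- function(x, ...) UseMethod("volume_at_dose")

#' @rdname volume_at_dose
#' @param mask logical structure mask.
#' @param dose_gy dose threshold in Gy.
#' @export
volume_at_dose.volume_grid <- function(x, mask, dose_gy, ...) {
  mask <- as_mask(mask)
  if (!any(mask)) stop("structure mask is empty")
  100 * mean(x$values[mask] > dose_gy)
}

#' @rdname volume_at_dose
#' @export
volume_at_dose.dvh_curve <- function(x, dose_gy, ...) {
  if (dose_gy >= max(x$dose)) return(0)
  if (dose_gy < x$dose[1]) return(100)
  approx(x$dose, x$volume, xout = dose_gy + x$bin_width / 2, rule = 2)$y
}

#' Maximum structure dose
#' @param dose dose `volume_grid`.
#' @param mask logical structure mask.
#' @return Dmax in Gy.
#' @export
max_dose <- function(dose, mask) {
  mask <- as_mask(mask)
  if (!any(mask)) stop("structure mask is empty")
  max(dose$values[mask])
}

#' The clinical lung-plan metric set for one dose distribution
#'
#' PTV D95/D98/D100 as percentages of the prescription; lung (both lungs
#' minus the PTV) V10 and V20; heart V40; spinal cord Dmax (Gy).
#'
#' @param dose dose `volume_grid`.
#' @param structures a [structure_set()] with PTV, lungs, heart, spinal cord.
#' @param prescription prescription dose in Gy.
#' @return named numeric vector of class `dvh_metric_set`.
#' @export
dvh_metric_set <- function(dose, structures, prescription) {
  m <- structures$masks
  lung <- (m$lung_left | m$lung_right) & !m$PTV
  if (!any(lung)) stop("lung mask is empty after PTV exclusion")
  out <- c(
    D95 = 100 * dose_at_volume(dose, m$PTV, 95) / prescription,
    D98 = 100 * dose_at_volume(dose, m$PTV, 98) / prescription,
    D100 = 100 * dose_at_volume(dose, m$PTV, 100) / prescription,
    lung_V10 = volume_at_dose(dose, lung, 10),
    lung_V20 = volume_at_dose(dose, lung, 20),
    heart_V40 = volume_at_dose(dose, m$heart, 40),
    cord_Dmax = max_dose(dose, m$spinal_cord)
  )
  class(out) <- c("dvh_metric_set", class(out))
  out
}
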