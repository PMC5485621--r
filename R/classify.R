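## Rule-based Dixon tissue classification and 511 keV attenuation assignment.

#' Classification thresholds
#'
#' The classifier is rule-based: voxels outside the body mask are air; inside
#' the body a voxel is fat when its fat fraction `F/(W+F)` reaches
#' `fat_fraction` (ties classify as fat), lung when it belongs to a
#' sufficiently large low-signal component enclosed by the body, and soft
#' tissue otherwise. `body_signal_min` and `lung_signal_max` are absolute
#' thresholds on the combined signal `W+F` (signal units of the Dixon pair);
#' fat fraction is scale-invariant.
#'
#' @param fat_fraction fat fraction at or above which a voxel is fat.
#' @param body_signal_min combined-signal threshold for the body mask.
#' @param lung_signal_max combined signal below which an inside-body voxel is
#'   a lung candidate.
#' @param lung_min_volume_cm3 minimum connected lung-candidate volume; smaller
#'   pockets fall back to soft tissue.
#' @return list of class `classification_config`.
#' @export
classification_config <- function(fat_fraction = 0.5, body_signal_min = 200,
                                  lung_signal_max = 200,
                                  lung_min_volume_cm3 = 10) {
  structure(list(fat_fraction = fat_fraction,
                 body_signal_min = body_signal_min,
                 lung_signal_max = lung_signal_max,
                 lung_min_volume_cm3 = lung_min_volume_cm3),
            class = "classification_config")
}

#' Body mask from a Dixon pair
#'
#' Thresholds the combined water+fat signal, keeps the largest 6-connected
#' component and fills interior holes (so the low-signal lungs are inside the
#' body).
#'
#' @param dixon a `dixon_pair`.
#' @param config a [classification_config()].
#' @return logical 3D array.
#' @export
compute_body_mask <- function(dixon, config = classification_config()) {
  stopifnot(inherits(dixon, "dixon_pair"))
  total <- dixon$water$values + dixon$fat$values
  if (any(total < 0)) stop("Dixon signals must be non-negative")
  fg <- total > config$body_signal_min
  if (!any(fg)) stop("no body detected: no voxel above the body signal threshold")
  d <- dim(total)
  # detect enclosed cavities on a one-voxel-closed copy: pinholes in thinly
  # rasterised walls would otherwise drain the lung cavities to the outside.
  # The closing is used only for cavity detection, so the outer body
  # boundary remains exactly the thresholded voxel set.
  closed <- dilate6(fg)
  filled <- array(fill_holes_cpp(as.logical(closed), d), d)
  cavity <- filled & !closed
  cavity <- dilate6(cavity) & !fg    # restore the cavity layer the closing ate
  # the plain fill is exact whenever the wall is already watertight (it also
  # keeps thin cavity tips the closing eats); the closed-cavity term rescues
  # grids whose rasterised wall leaks
  plain <- array(fill_holes_cpp(as.logical(fg), d), d)
  solid <- fg | cavity | plain
  lab <- cc_label_cpp(as.logical(solid), d)
  keep <- which.max(tabulate(lab))
  array(lab == keep, d)
}

#' Classify Dixon voxels into air / fat / lung / soft tissue
#'
#' @param dixon a `dixon_pair`.
#' @param body optional precomputed body mask; computed when `NULL`.
#' @param config a [classification_config()].
#' @return integer label `volume_grid` (codes in [TISSUE_CODES], no bone).
#' @export
classify_voxels <- function(dixon, body = NULL,
                            config = classification_config()) {
  stopifnot(inherits(dixon, "dixon_pair"))
  stopifnot_same_grid(dixon$water, dixon$fat, "Dixon channels")
  if (is.null(body)) body <- compute_body_mask(dixon, config)
  body <- as_mask(body)
  w <- dixon$water$values; f <- dixon$fat$values
  d <- dim(w)
  total <- w + f
  lab <- array(TISSUE_CODES[["air"]], d)

  # signal-void guard: W+F = 0 inside the body is treated as lung candidate
  ff <- ifelse(total > 0, f / total, 0)

  lab[body] <- ifelse(ff[body] >= config$fat_fraction,
                      TISSUE_CODES[["fat"]], TISSUE_CODES[["soft_tissue"]])

  cand <- body & total < config$lung_signal_max
  if (any(cand)) {
    comp <- array(cc_label_cpp(as.logical(cand), d), d)
    sizes <- tabulate(comp)
    vox_cm3 <- prod(dixon$water$spacing) / 1000
    big <- which(sizes * vox_cm3 >= config$lung_min_volume_cm3)
    if (length(big)) lab[comp %in% big] <- TISSUE_CODES[["lung"]]
  }
  volume_grid(lab, dixon$water$spacing, dixon$water$origin, role = "labels")
}

#' Assign 511 keV linear attenuation coefficients to tissue classes
#'
#' Pure lookup: air 0.0, fat 0.0854, lung 0.0224, soft tissue 0.1 cm^-1.
#' Bone labels are rejected here — bone enters the map later through the
#' atlas model ([insert_bones()]).
#'
#' @param labels integer label `volume_grid`.
#' @return attenuation `volume_grid` (cm^-1).
#' @export
assign_lac <- function(labels) {
  stopifnot(inherits(labels, "volume_grid"))
  lab <- labels$values
  if (any(lab == TISSUE_CODES[["bone"]]))
    stop("bone labels are not allowed at the classification stage; ",
         "bone is inserted by the atlas model")
  if (any(!lab %in% TISSUE_CODES[c("air", "fat", "lung", "soft_tissue")]))
    stop("unknown tissue labels present")
  mu <- array(unname(TISSUE_LAC[lab + 1L]), dim(lab))
  volume_grid(mu, labels$spacing, labels$origin, role = "lac")
}

#' Per-class voxel counts of a label map
#' @param labels integer label `volume_grid`.
#' @return named integer vector.
#' @export
class_counts <- function(labels) {
  lab <- labels$values
  vapply(TISSUE_CODES, function(code) sum(lab == code), integer(1))
}
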