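## Attenuation map -> synthetic CT: HU conversion, planning-grid resampling,
## registration to the reference CT, PTV density override, organ HU report.

#' Convert a 511 keV attenuation map to CT Hounsfield units
#'
#' The four soft tissue classes map exactly to their printed HUs (air
#' 0.0 -> -1000, lung 0.0224 -> -767, fat 0.0854 -> -110, soft tissue
#' 0.1 -> 70 HU); LACs in the bone interval (0.1, 0.2485] map linearly with
#' anchors 0.1 -> 70 and 0.2485 -> 2661 HU. The mapping is monotone
#' non-decreasing over its defined inputs. Any other LAC value is an error
#' naming the offending voxel count.
#'
#' @param amap attenuation `volume_grid` (cm^-1).
#' @return CT `volume_grid` (HU), provenance tag `"synCT"` in `$provenance`.
#' @export
lac_to_hu <- function(amap) {
  stopifnot(inherits(amap, "volume_grid"))
  mu <- amap$values
  tol <- 1e-9
  if (any(mu < -tol | mu > BONE_LAC_RANGE[2] + tol))
    stop(sprintf("%d voxel(s) carry LACs outside [0, 0.2485] cm^-1",
                 sum(mu < -tol | mu > BONE_LAC_RANGE[2] + tol)))
  hu <- array(NA_real_, dim(mu))
  for (cls in names(TISSUE_LAC)) {
    sel <- abs(mu - TISSUE_LAC[[cls]]) < tol
    hu[sel] <- TISSUE_HU[[cls]]
  }
  bone <- mu > BONE_LAC_RANGE[1] + tol
  hu[bone] <- BONE_HU_RANGE[1] +
    (mu[bone] - BONE_LAC_RANGE[1]) / diff(BONE_LAC_RANGE) * diff(BONE_HU_RANGE)
  bad <- sum(is.na(hu))
  if (bad > 0)
    stop(sprintf(paste0("%d voxel(s) carry LACs that are neither a tissue-",
                        "class value nor in the bone interval"), bad))
  hu <- pmin(pmax(hu, -1024), 3071)
  out <- volume_grid(hu, amap$spacing, amap$origin, role = "hu")
  out$provenance <- "synCT"
  out
}

#' Register a synthetic CT to the reference planning CT
#'
#' First a rigid (6-DOF) intensity registration, then a demons deformable
#' refinement; the synCT is resampled onto the planCT grid through the
#' composed transform. The similarity metric trace (accepted iterations
#' only) is attached to the transform.
#'
#' @param synct,planct CT `volume_grid`s.
#' @param rigid_only skip the deformable stage.
#' @param ... passed to [register_demons()].
#' @return list with `transform` (a `spatial_transform`) and `synct_reg`
#'   (the synCT on the planCT grid).
#' @export
register_synct_to_ct <- function(synct, planct, rigid_only = FALSE, ...) {
  rig <- register_rigid(synct, planct)
  if (rigid_only) {
    reg <- apply_transform(synct, rig, target = planct, fill = -1000)
    return(list(transform = rig, synct_reg = reg))
  }
  warped <- apply_transform(synct, rig, target = planct, fill = -1000)
  dem <- register_demons(warped, planct, ...)
  tr <- compose_affine_field(rig, dem)
  reg <- apply_transform(synct, tr, target = planct, fill = -1000)
  list(transform = tr, synct_reg = reg)
}

#' Override the PTV density to water
#'
#' Every PTV voxel is set to -4 HU (water-like tumour density, replacing the
#' lung air the artificial target sits in); all other voxels are unchanged.
#' Applied identically to synCT and planCT before dose calculation; the
#' operation is idempotent.
#'
#' @param ct CT `volume_grid`.
#' @param ptv logical PTV mask on the same grid.
#' @return CT `volume_grid`.
#' @export
override_ptv_density <- function(ct, ptv) {
  ptv <- as_mask(ptv)
  if (!identical(dim(ptv), dim(ct$values)))
    stop("PTV mask is not on the CT grid")
  if (!any(ptv)) {
    warning("PTV mask is empty; nothing overridden")
    return(ct)
  }
  out <- ct
  out$values[ptv] <- -4
  out
}

#' Crop a CT to the region covered by a structure set
#'
#' Axis-aligned bounding box of the union of all masks, expanded by
#' `margin_mm`, clipped to the volume.
#'
#' @param ct CT `volume_grid`.
#' @param structures a [structure_set()].
#' @param margin_mm margin around the union bounding box.
#' @return cropped `volume_grid`.
#' @export
crop_to_structures <- function(ct, structures, margin_mm = 10) {
  u <- Reduce(`|`, structures$masks)
  idx <- which(u, arr.ind = TRUE)
  mvox <- ceiling(margin_mm / ct$spacing)
  lo <- pmax(apply(idx, 2, min) - mvox, 1)
  hi <- pmin(apply(idx, 2, max) + mvox, dim(ct$values))
  vals <- ct$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  origin <- ct$origin + (lo - 1) * ct$spacing
  out <- volume_grid(vals, ct$spacing, origin, role = ct$role)
  out$provenance <- ct$provenance
  out
}

#' Mean Hounsfield units per organ
#'
#' Arithmetic mean HU over each structure mask for one or several CT
#' volumes (e.g. synCT and planCT), emitted as a paired table. Empty masks
#' are flagged rather than propagated as NaN.
#'
#' @param cts a CT `volume_grid` or named list of them
#'   (e.g. `list(synCT = ..., planCT = ...)`).
#' @param structures a [structure_set()].
#' @param organs which structures to report (default: all but body and PTV).
#' @return data.frame with one row per organ and one column per CT.
#' @export
organ_mean_hu <- function(cts, structures,
                          organs = setdiff(names(structures$masks),
                                           c("body", "PTV"))) {
  if (inherits(cts, "volume_grid")) {
    nm <- if (!is.null(cts$provenance)) cts$provenance else "CT"
    cts <- stats::setNames(list(cts), nm)
  }
  out <- data.frame(organ = organs, stringsAsFactors = FALSE)
  for (nm in names(cts)) {
    vals <- vapply(organs, function(org) {
      m <- structures$masks[[org]]
      if (is.null(m) || !any(m)) return(NA_real_)
      mean(cts[[nm]]$values[m])
    }, numeric(1))
    out[[nm]] <- vals
  }
  empty <- vapply(organs, function(org) {
    m <- structures$masks[[org]]
    is.null(m) || !any(m)
  }, logical(1))
  out$flag <- ifelse(empty, "empty mask", "")
  out
}
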