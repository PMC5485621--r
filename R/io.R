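## Volume / plan / config I/O. NIfTI is the native volume interchange (with
## a JSON sidecar preserving the exact grid metadata and role), plans are
## JSON, configs YAML. Round trips are lossless; orientation is restricted
## to axis-aligned grids — anything oblique errors rather than silently
## reorienting.

sidecar_path <- function(path) paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")

#' Write a volume to NIfTI (+ JSON sidecar)
#'
#' @param volume a `volume_grid`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing
  mat <- diag(4)
  diag(mat)[1:3] <- volume$spacing
  # NIfTI stores the centre of voxel (0,0,0): our origin + spacing/2
  mat[1:3, 4] <- volume$origin + volume$spacing / 2
  RNifti::qform(img) <- structure(mat, code = 2L)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(spacing = volume$spacing, origin = volume$origin,
                            role = volume$role),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' Prefers the JSON sidecar written by [write_volume()]; otherwise the grid
#' is reconstructed from the NIfTI transform, which must be axis-aligned
#' (oblique orientations are an error, never silently reoriented).
#'
#' @param path NIfTI file.
#' @return a `volume_grid`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim(img))
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    return(volume_grid(vals, meta$spacing, meta$origin,
                       role = if (is.null(meta$role)) NULL else meta$role))
  }
  mat <- RNifti::xform(img)
  rot <- mat[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-6)
    stop("oblique NIfTI orientation; reorient to axis-aligned before loading")
  spacing <- abs(diag(rot))
  if (any(spacing <= 0)) stop("non-positive spacing in NIfTI header")
  origin <- mat[1:3, 4] - spacing / 2
  volume_grid(vals, spacing, origin)
}

#' Write / read a treatment plan as JSON
#'
#' @param plan a [plan_spec()].
#' @param path JSON file path.
#' @return `write_plan` the path; `read_plan` a `plan_spec`.
#' @export
write_plan <- function(plan, path) {
  beams <- lapply(plan$beams, function(b)
    list(gantry_deg = b$gantry_deg, iso = b$iso, field_size = b$field_size,
         weight = b$weight, sad = b$sad))
  jsonlite::write_json(list(beams = beams, prescription = plan$prescription,
                            dose_per_fraction = plan$dose_per_fraction,
                            n_fractions = plan$n_fractions,
                            scheme = plan$scheme,
                            normalization = plan$normalization),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  beams <- lapply(seq_len(nrow(j$beams)), function(i) {
    b <- j$beams[i, ]
    beam_spec(b$gantry_deg, unlist(b$iso), unlist(b$field_size), b$weight,
              b$sad)
  })
  p <- plan_spec(beams, prescription = j$prescription,
                 dose_per_fraction = j$dose_per_fraction,
                 n_fractions = j$n_fractions,
                 scheme = if (j$scheme %in% c("IMRT", "SBRT")) j$scheme else "custom")
  if (!is.null(j$normalization)) p$normalization <- j$normalization
  p
}

#' Write / read a run configuration as YAML
#'
#' @param config a [run_config()] (any plain list works).
#' @param path YAML file path.
#' @return `write_run_config` the path; `read_run_config` a `run_config`.
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$noise_sd <- as.list(cfg$noise_sd)   # YAML drops names of plain vectors
  if (is.data.frame(cfg$ptvs)) cfg$ptvs <- as.list(cfg$ptvs)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$noise_sd <- unlist(cfg$noise_sd)
  if (!is.null(cfg$ptvs)) cfg$ptvs <- as.data.frame(cfg$ptvs)
  do.call(run_config, cfg)
}
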