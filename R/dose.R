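## Simplified heterogeneity-corrected photon dose engine: exponential
## attenuation along water-equivalent depth, inverse-square divergence and a
## density-scaled lateral Gaussian penumbra. A declared stand-in for a
## commercial convolution/superposition engine: it preserves the sensitivity
## of dose to HU differences through photon attenuation and lateral
## transport, which is the property under test.

#' HU to relative electron density calibration curve
#'
#' Ordered control points interpolated piecewise-linearly and clamped at the
#' ends. The shipped default is a typical simulation-CT curve with water at
#' (0 HU, 1.00) and air at (-1000 HU, 0.00).
#'
#' @param hu strictly increasing HU control points covering `[-1024, 3071]`.
#' @param density matching non-negative, non-decreasing relative electron
#'   densities.
#' @return object of class `calibration_curve`.
#' @export
calibration_curve <- function(hu = c(-1024, -1000, -767, -110, -4, 0, 70,
                                     336, 1365, 2661, 3071),
                              density = c(0, 0.001, 0.26, 0.93, 0.995, 1.0,
                                          1.05, 1.19, 1.76, 2.53, 2.78)) {
  hu <- as.numeric(hu); density <- as.numeric(density)
  if (length(hu) != length(density) || length(hu) < 2)
    stop("curve needs matching hu/density vectors with >= 2 points")
  if (any(diff(hu) <= 0)) stop("calibration curve HU must be strictly increasing")
  if (any(density < 0) || any(diff(density) < 0))
    stop("calibration curve densities must be non-negative and non-decreasing")
  if (hu[1] > -1024 || hu[length(hu)] < 3071)
    stop("calibration curve must cover [-1024, 3071] HU")
  structure(list(hu = hu, density = density), class = "calibration_curve")
}

#' Convert a CT volume to relative electron density
#'
#' @param ct CT `volume_grid` (HU).
#' @param curve a [calibration_curve()].
#' @return density `volume_grid`.
#' @export
hu_to_density <- function(ct, curve = calibration_curve()) {
  stopifnot(inherits(curve, "calibration_curve"))
  vals <- approx(curve$hu, curve$density, xout = as.numeric(ct$values),
                 rule = 2)$y
  volume_grid(array(vals, dim(ct$values)), ct$spacing, ct$origin,
              role = "density")
}

#' Exact radiological path length along a ray
#'
#' Siddon-style voxel-intersection ray tracing: the water-equivalent depth is
#' the running sum of (density x geometric intersection length) over the
#' voxels the ray crosses.
#'
#' @param density density `volume_grid`.
#' @param origin ray origin, world mm.
#' @param direction ray direction (any non-zero length).
#' @return data.frame with one row per crossed voxel: 1-based voxel indices,
#'   intersection `length` (mm), `density`, and cumulative water-equivalent
#'   depth `wed` (mm) at the segment exit. Empty when the ray misses.
#' @export
radiological_depth <- function(density, origin, direction) {
  if (sqrt(sum(direction^2)) < 1e-12) stop("direction must be non-zero")
  tr <- siddon_trace_cpp(as.numeric(density$values), dim(density$values),
                         density$spacing, density$origin,
                         as.numeric(origin), as.numeric(direction))
  data.frame(i = tr$i + 1L, j = tr$j + 1L, k = tr$k + 1L,
             length = tr$length, density = tr$density, wed = tr$wed)
}

#' Dose engine configuration
#'
#' @param mu_eff effective linear attenuation of the beam in water, mm^-1
#'   (default 0.005, roughly 6 MV-like depth dose).
#' @param sigma_lat lateral penumbra Gaussian SD in water, mm; the effective
#'   SD at a voxel is `sigma_lat / max(density, 0.5)` so the penumbra
#'   broadens in low-density lung (clamped so near-vacuum voxels stay
#'   finite).
#' @param mode `"divergent"` (point source at the source-axis distance) or
#'   `"parallel"` (closed-form friendly).
#' @param depth_method `"sweep"` (incremental plane sweep, O(nvox)) or
#'   `"siddon"` (exact per-voxel ray trace, for validation on small grids).
#' @return object of class `engine_config`.
#' @export
engine_config <- function(mu_eff = 0.005, sigma_lat = 3,
                          mode = c("divergent", "parallel"),
                          depth_method = c("sweep", "siddon")) {
  structure(list(mu_eff = mu_eff, sigma_lat = sigma_lat,
                 mode = match.arg(mode),
                 depth_method = match.arg(depth_method)),
            class = "engine_config")
}

#' Beam specification
#'
#' Coplanar beam at a gantry angle; at 0 degrees the beam travels along -y.
#' `weight` is the monitor-unit surrogate: dose is exactly linear in it.
#'
#' @param gantry_deg gantry angle in degrees.
#' @param iso isocentre, world mm.
#' @param field_size `c(width, length)` of the aperture at the isocentre
#'   plane, mm.
#' @param weight non-negative beam weight (MU surrogate).
#' @param sad source-axis distance, mm.
#' @return object of class `beam_spec`.
#' @export
beam_spec <- function(gantry_deg, iso = c(0, 0, 0), field_size = c(80, 80),
                      weight = 1, sad = 1000) {
  if (weight < 0) stop("beam weight must be non-negative")
  if (any(field_size <= 0)) stop("field size must be positive")
  structure(list(gantry_deg = gantry_deg, iso = as.numeric(iso),
                 field_size = as.numeric(field_size), weight = weight,
                 sad = sad), class = "beam_spec")
}

beam_axes <- function(beam) {
  th <- beam$gantry_deg * pi / 180
  d <- c(sin(th), -cos(th), 0)
  u <- c(cos(th), sin(th), 0)
  v <- c(0, 0, 1)
  list(d = d, u = u, v = v, src = beam$iso - beam$sad * d)
}

#' Treatment plan specification
#'
#' @param beams list of [beam_spec()]s, or an integer number of equispaced
#'   coplanar beams.
#' @param prescription total prescription dose, Gy. The two clinical schemes
#'   are IMRT 59.40 Gy = 33 x 1.8 Gy and SBRT 60 Gy = 3 x 20 Gy.
#' @param dose_per_fraction,n_fractions fractionation; must multiply to the
#'   prescription.
#' @param scheme `"IMRT"`, `"SBRT"` or `"custom"`.
#' @param iso,field_size,sad forwarded to [beam_spec()] when `beams` is a
#'   count.
#' @return object of class `plan_spec`.
#' @export
plan_spec <- function(beams = 7L, prescription = 59.4,
                      dose_per_fraction = 1.8, n_fractions = 33,
                      scheme = c("IMRT", "SBRT", "custom"),
                      iso = c(0, 0, 0), field_size = c(80, 80), sad = 1000) {
  scheme <- match.arg(scheme)
  if (scheme == "SBRT" && missing(dose_per_fraction)) {
    dose_per_fraction <- 20; n_fractions <- 3
    if (missing(prescription)) prescription <- 60
  }
  if (abs(dose_per_fraction * n_fractions - prescription) > 1e-6)
    stop("prescription must equal dose_per_fraction * n_fractions")
  if (is.numeric(beams) && length(beams) == 1L) {
    n <- as.integer(beams)
    if (n < 1L) stop("at least one beam is required")
    angles <- seq(0, 360, length.out = n + 1L)[seq_len(n)]
    beams <- lapply(angles, beam_spec, iso = iso, field_size = field_size,
                    sad = sad)
  }
  structure(list(beams = beams, prescription = prescription,
                 dose_per_fraction = dose_per_fraction,
                 n_fractions = n_fractions, scheme = scheme,
                 normalization = NULL), class = "plan_spec")
}

#' @export
print.plan_spec <- function(x, ...) {
  cat(sprintf("<plan_spec %s> %d beam(s), %.2f Gy = %d x %.3g Gy%s\n",
              x$scheme, length(x$beams), x$prescription, x$n_fractions,
              x$dose_per_fraction,
              if (is.null(x$normalization)) "" else
                sprintf(", normalised (s = %.4f)", x$normalization)))
  invisible(x)
}

#' Dose of a single beam
#'
#' `dose = weight x inverse-square x exp(-mu_eff x WED) x lateral profile`,
#' with the water-equivalent depth (WED) computed through the density grid
#' and an error-function aperture penumbra whose width scales inversely with
#' local density. Zero density everywhere yields a valid unattenuated beam.
#'
#' @param beam a [beam_spec()].
#' @param density density `volume_grid`.
#' @param config an [engine_config()].
#' @return dose `volume_grid` (Gy per unit weight times `beam$weight`).
#' @export
beam_dose <- function(beam, density, config = engine_config()) {
  ax <- beam_axes(beam)
  d <- dim(density$values)
  parallel <- config$mode == "parallel"
  if (all(density$values == 0))
    message("beam_dose: zero density everywhere; beam is unattenuated")
  wed_fun <- if (config$depth_method == "sweep") wed_sweep_cpp else wed_siddon_cpp
  wed <- wed_fun(as.numeric(density$values), d, density$spacing,
                 density$origin, ax$src, ax$d, parallel)
  cc <- voxel_centers(density)
  rx <- as.numeric(cc$x) - beam$iso[1]
  ry <- as.numeric(cc$y) - beam$iso[2]
  rz <- as.numeric(cc$z) - beam$iso[3]
  t_along <- rx * ax$d[1] + ry * ax$d[2] + rz * ax$d[3]
  lu <- rx * ax$u[1] + ry * ax$u[2] + rz * ax$u[3]
  lv <- rx * ax$v[1] + ry * ax$v[2] + rz * ax$v[3]
  if (parallel) {
    isq <- 1
  } else {
    dist <- beam$sad + t_along
    dist[dist < 1] <- 1
    isq <- (beam$sad / dist)^2
    proj <- beam$sad / dist
    lu <- lu * proj
    lv <- lv * proj
  }
  sig <- config$sigma_lat / pmax(as.numeric(density$values), 0.5)
  hw <- beam$field_size / 2
  pu <- pnorm((hw[1] - lu) / sig) - pnorm((-hw[1] - lu) / sig)
  pv <- pnorm((hw[2] - lv) / sig) - pnorm((-hw[2] - lv) / sig)
  dose <- beam$weight * isq * exp(-config$mu_eff * wed) * pu * pv
  volume_grid(array(dose, d), density$spacing, density$origin, role = "dose")
}

#' Per-beam unit doses of a plan
#'
#' Doses of every beam at unit weight, for reuse by the weight optimiser and
#' by [compose_plan()].
#'
#' @inheritParams compose_plan
#' @return list of dose `volume_grid`s.
#' @export
unit_beam_doses <- function(plan, density, config = engine_config()) {
  lapply(plan$beams, function(b) {
    b$weight <- 1
    beam_dose(b, density, config)
  })
}

#' Total plan dose
#'
#' Weighted sum of per-beam doses; exactly linear in the beam weights and
#' invariant under beam order.
#'
#' @param plan a [plan_spec()].
#' @param density density `volume_grid`.
#' @param config an [engine_config()].
#' @param unit_doses optional precomputed [unit_beam_doses()].
#' @return dose `volume_grid`.
#' @export
compose_plan <- function(plan, density, config = engine_config(),
                         unit_doses = NULL) {
  if (length(plan$beams) < 1L) stop("plan has no beams")
  if (is.null(unit_doses)) unit_doses <- unit_beam_doses(plan, density, config)
  acc <- array(0, dim(density$values))
  for (i in seq_along(plan$beams))
    acc <- acc + plan$beams[[i]]$weight * unit_doses[[i]]$values
  volume_grid(acc, density$spacing, density$origin, role = "dose")
}

#' Conventional planning objectives for a lung target
#'
#' A PTV mean-dose target plus upper bounds on the organs at risk. The
#' defaults are the package's own conventional set, expressed relative to
#' the prescription.
#'
#' @param prescription prescription dose, Gy.
#' @return list of objective terms.
#' @export
default_objectives <- function(prescription) {
  list(
    list(structure = "PTV", type = "target", dose = prescription, weight = 100),
    list(structure = "lung", type = "max", dose = 0.7 * prescription, weight = 1),
    list(structure = "heart", type = "max", dose = 0.6 * prescription, weight = 1),
    list(structure = "spinal_cord", type = "max", dose = 0.8 * prescription,
         weight = 2)
  )
}

objective_voxels <- function(structures, name, max_n = 1500L) {
  if (name == "lung") {
    m <- (structures$masks$lung_left | structures$masks$lung_right) &
      !structures$masks$PTV
  } else m <- structures$masks[[name]]
  if (is.null(m)) return(integer(0))
  idx <- which(m)
  if (length(idx) > max_n)
    idx <- idx[round(seq(1, length(idx), length.out = max_n))]
  idx
}

#' Optimise beam weights against dose objectives
#'
#' Non-negative least squares on per-beam unit dose contributions sampled in
#' the PTV and OAR voxels: the PTV term is a squared deviation from the
#' target dose, OAR terms are one-sided squared overshoots of their bounds.
#' Solved by bound-constrained quasi-Newton (L-BFGS-B, weights >= 0) with an
#' analytic gradient; the objective is non-increasing across accepted
#' iterations by construction of the line search.
#'
#' @param plan a [plan_spec()].
#' @param density density `volume_grid`.
#' @param structures a [structure_set()] with at least a PTV.
#' @param objectives list of objective terms; see [default_objectives()].
#' @param config an [engine_config()].
#' @param unit_doses optional precomputed [unit_beam_doses()].
#' @return the plan with optimised weights (and `$objective_value`).
#' @export
optimize_weights <- function(plan, density, structures,
                             objectives = default_objectives(plan$prescription),
                             config = engine_config(), unit_doses = NULL) {
  has_target <- any(vapply(objectives, function(o) o$type == "target", TRUE))
  if (!has_target) stop("objectives must include a PTV target term")
  if (is.null(unit_doses)) unit_doses <- unit_beam_doses(plan, density, config)
  nb <- length(plan$beams)
  terms <- lapply(objectives, function(o) {
    idx <- objective_voxels(structures, o$structure)
    if (!length(idx)) return(NULL)
    A <- vapply(unit_doses, function(ud) ud$values[idx], numeric(length(idx)))
    A <- matrix(A, nrow = length(idx))
    list(A = A, o = o, n = length(idx))
  })
  terms <- Filter(Negate(is.null), terms)
  fn <- function(w) {
    val <- 0
    for (tm in terms) {
      dvox <- as.numeric(tm$A %*% w)
      if (tm$o$type == "target") {
        val <- val + tm$o$weight * mean((dvox - tm$o$dose)^2)
      } else {
        val <- val + tm$o$weight * mean(pmax(dvox - tm$o$dose, 0)^2)
      }
    }
    val
  }
  gr <- function(w) {
    g <- numeric(nb)
    for (tm in terms) {
      dvox <- as.numeric(tm$A %*% w)
      r <- if (tm$o$type == "target") dvox - tm$o$dose else pmax(dvox - tm$o$dose, 0)
      g <- g + tm$o$weight * 2 * as.numeric(crossprod(tm$A, r)) / tm$n
    }
    g
  }
  tgt <- objectives[[which(vapply(objectives, function(o) o$type == "target",
                                  TRUE))[1]]]
  ptv_idx <- objective_voxels(structures, tgt$structure)
  mean_unit <- vapply(unit_doses, function(ud) mean(ud$values[ptv_idx]),
                      numeric(1))
  w0 <- rep(tgt$dose / max(sum(mean_unit), 1e-12), nb)
  f0 <- fn(w0)
  opt <- optim(w0, fn, gr, method = "L-BFGS-B", lower = rep(0, nb),
               control = list(maxit = 200))
  w <- if (opt$value <= f0) opt$par else w0
  mean_ptv <- sum(w * mean_unit)
  if (mean_ptv < 0.98 * tgt$dose)
    warning(sprintf(paste0("objectives look infeasible: best-effort mean PTV ",
                           "dose %.2f Gy vs target %.2f Gy"), mean_ptv, tgt$dose))
  for (i in seq_len(nb)) plan$beams[[i]]$weight <- w[i]
  plan$objective_value <- min(opt$value, f0)
  plan
}

#' Normalise a plan so the prescription covers 95% of the PTV
#'
#' A single global scale factor `s = prescription / D95(PTV)` is applied to
#' every beam weight and to the dose; afterwards the PTV volume at or above
#' the prescription is 95% (within DVH interpolation tolerance). Normalising
#' an already-normalised plan yields a second scale factor of 1.
#'
#' @param plan a [plan_spec()].
#' @param dose the plan's dose `volume_grid`.
#' @param ptv logical PTV mask on the dose grid.
#' @param prescription target dose, Gy (default: the plan's).
#' @return list with the scaled `plan`, scaled `dose` and `scale`.
#' @export
normalize_plan <- function(plan, dose, ptv, prescription = plan$prescription) {
  ptv <- as_mask(ptv)
  if (!any(ptv)) stop("PTV mask is empty")
  d95 <- dose_at_volume(dose, ptv, 95)
  if (!is.finite(d95) || d95 <= 0) stop("PTV D95 is zero; cannot normalise")
  s <- prescription / d95
  for (i in seq_along(plan$beams))
    plan$beams[[i]]$weight <- plan$beams[[i]]$weight * s
  plan$normalization <- if (is.null(plan$normalization)) s else
    plan$normalization * s
  dose$values <- dose$values * s
  list(plan = plan, dose = dose, scale = s)
}

#' Recompute a plan's dose on another CT with identical monitor units
#'
#' The beam geometry and weights are kept bit-identical; only the density
#' grid differs (the second CT run through the same calibration curve).
#'
#' @param plan the (normalised) plan.
#' @param other_ct CT `volume_grid` (e.g. the reference planning CT).
#' @param curve a [calibration_curve()].
#' @param config an [engine_config()].
#' @param reference_grid optional `volume_grid` the CT must match (errors on
#'   mismatch, e.g. registration failure upstream).
#' @return dose `volume_grid`.
#' @export
recompute_on <- function(plan, other_ct, curve = calibration_curve(),
                         config = engine_config(), reference_grid = NULL) {
  if (!is.null(reference_grid))
    stopifnot_same_grid(other_ct, reference_grid, "CT and reference grid")
  dens <- hu_to_density(other_ct, curve)
  compose_plan(plan, dens, config)
}
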