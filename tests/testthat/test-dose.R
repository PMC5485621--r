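test_that("calibration curve interpolates linearly and validates monotonicity", {
  curve <- calibration_curve()
  ct <- volume_grid(array(c(0, -1000, -438.5), c(3, 1, 1)), 1)
  dens <- hu_to_density(ct, curve)
  expect_equal(dens$values[1], 1.0)
  expect_lt(dens$values[2], 0.01)
  # midway between the -767 and -110 control points
  expect_equal(dens$values[3], (0.26 + 0.93) / 2, tolerance = 1e-12)
  expect_error(calibration_curve(hu = c(-1024, 0, -5, 3071),
                                 density = c(0, 1, 1, 2)), "increasing")
  expect_error(calibration_curve(hu = c(-1024, 0, 3071),
                                 density = c(0.5, 0.2, 1)), "non-decreasing")
})

test_that("Siddon ray tracing matches hand-computed and closed-form cases", {
  d3 <- volume_grid(array(c(1, 0.25, 1), c(3, 1, 1)), 1, origin = c(0, 0, 0))
  pr <- radiological_depth(d3, origin = c(-1, 0.5, 0.5), direction = c(1, 0, 0))
  expect_equal(pr$wed, c(1, 1.25, 2.25))
  # uniform density: radiological equals geometric depth
  u <- volume_grid(array(1, c(20, 20, 20)), 1, origin = c(0, 0, 0))
  pu <- radiological_depth(u, c(-5, 10, 10), c(1, 0, 0))
  expect_equal(max(pu$wed), 20)
  # oblique 45-degree ray through a 2D slab: sqrt(2) x thickness
  slab <- volume_grid(array(1, c(30, 30, 1)), 1, origin = c(0, 0, 0))
  po <- radiological_depth(slab, c(-1, -1, 0.5), c(1, 1, 0))
  expect_equal(max(po$wed), sqrt(2) * 30, tolerance = 1e-9)
})

test_that("Siddon depths agree with a fine-step ray integral on random rays", {
  set.seed(10)
  dens <- smooth_field(24, spacing = 2, offset = 0.2)
  n <- 200
  worst <- 0
  for (i in seq_len(n)) {
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    org <- runif(3, -60, -40) * sign(dir)
    pr <- radiological_depth(dens, org, dir)
    if (!nrow(pr)) next
    wed_sid <- max(pr$wed)
    # independent fine-step integral: nearest-voxel density x step
    h <- 0.01
    tmax <- 2 * sqrt(3) * 24 * 2
    tt <- seq(h / 2, tmax, by = h)
    pts <- cbind(org[1] + tt * dir[1], org[2] + tt * dir[2],
                 org[3] + tt * dir[3])
    ci <- sweep(sweep(pts, 2, dens$origin), 2, dens$spacing, "/")
    inside <- ci[, 1] > 0 & ci[, 2] > 0 & ci[, 3] > 0 &
      ci[, 1] < 24 & ci[, 2] < 24 & ci[, 3] < 24
    ii <- pmin(pmax(ceiling(ci[inside, , drop = FALSE]), 1), 24)
    wed_fine <- sum(dens$values[ii] * h)
    if (wed_fine > 5) worst <- max(worst, abs(wed_sid - wed_fine) / wed_fine)
  }
  expect_lt(worst, 0.005)
})

test_that("the sweep depth field agrees with exact per-voxel Siddon", {
  dens <- smooth_field(20, spacing = 2.5, offset = 0.2)
  for (ang in c(0, 55, 120)) {
    b <- beam_spec(ang, iso = c(0, 0, 0))
    ax <- synctdose:::beam_axes(b)
    d <- dim(dens$values)
    sweep_w <- synctdose:::wed_sweep_cpp(as.numeric(dens$values), d,
                                         dens$spacing, dens$origin, ax$src,
                                         ax$d, TRUE)
    sid_w <- synctdose:::wed_siddon_cpp(as.numeric(dens$values), d,
                                        dens$spacing, dens$origin, ax$src,
                                        ax$d, TRUE)
    keep <- sid_w > 5
    expect_lt(median(abs(sweep_w[keep] - sid_w[keep]) / sid_w[keep]), 0.02)
  }
})

test_that("water depth-dose follows the exponential closed form on-axis", {
  dens <- uniform_density(1, n = 41, spacing = 2)
  b <- beam_spec(0, iso = c(0, 0, 0), field_size = c(60, 60))
  dd <- beam_dose(b, dens, engine_config(mode = "parallel"))
  prof <- dd$values[21, 41:1, 21]   # along the beam, entry first
  depth <- (seq_along(prof) - 0.5) * 2
  i <- 6:36
  ratio <- prof[i] / prof[6]
  closed <- exp(-0.005 * (depth[i] - depth[6]))
  expect_lt(max(abs(ratio - closed) / closed), 0.001)
})

test_that("dose is exactly linear in beam weight and lung transmits more than water", {
  dens <- uniform_density(1, n = 21, spacing = 2)
  b1 <- beam_spec(90, weight = 1)
  b2 <- beam_spec(90, weight = 2)
  d1 <- beam_dose(b1, dens, engine_config(mode = "parallel"))
  d2 <- beam_dose(b2, dens, engine_config(mode = "parallel"))
  expect_equal(d2$values, 2 * d1$values)

  lungd <- uniform_density(0.26, n = 21, spacing = 2)
  dl <- beam_dose(b1, lungd, engine_config(mode = "parallel"))
  exit <- c(21, 11, 11)  # far side along the 90-degree beam
  expect_gt(dl$values[exit[1], exit[2], exit[3]],
            d1$values[exit[1], exit[2], exit[3]])
})

test_that("plan composition is a weighted, order-invariant sum with symmetry", {
  dens <- uniform_density(1, n = 25, spacing = 2)
  p1 <- plan_spec(list(beam_spec(40, weight = 0.7)), prescription = 2,
                  dose_per_fraction = 2, n_fractions = 1, scheme = "custom")
  expect_equal(compose_plan(p1, dens)$values,
               beam_dose(p1$beams[[1]], dens)$values)
  # two opposed beams in a symmetric phantom give a symmetric dose
  p2 <- plan_spec(list(beam_spec(90), beam_spec(270)), prescription = 2,
                  dose_per_fraction = 2, n_fractions = 1, scheme = "custom")
  dd <- compose_plan(p2, dens, engine_config(mode = "parallel"))
  flipped <- dd$values[25:1, , ]
  expect_equal(dd$values, flipped, tolerance = 1e-9)
  # order invariance
  p2r <- p2; p2r$beams <- rev(p2r$beams)
  expect_equal(compose_plan(p2r, dens)$values, compose_plan(p2, dens)$values)
  # zero weights give zero dose
  p0 <- p2
  for (i in 1:2) p0$beams[[i]]$weight <- 0
  expect_true(all(compose_plan(p0, dens)$values == 0))
})

test_that("weight optimisation solves the scalar and two-beam toys", {
  d <- c(20L, 20L, 20L)
  dens <- volume_grid(array(1, d), 2)
  ptv <- array(FALSE, d); ptv[9:12, 9:12, 9:12] <- TRUE
  structs <- structure_set(list(PTV = ptv), dens)
  # single beam, PTV-only objective, near-uniform unit dose:
  # weight = target / mean unit-weight PTV dose
  p1 <- plan_spec(list(beam_spec(0, field_size = c(60, 60))),
                  prescription = 60, dose_per_fraction = 20, n_fractions = 3,
                  scheme = "SBRT")
  cfg <- engine_config(mode = "parallel")
  ud <- unit_beam_doses(p1, dens, cfg)
  opt <- optimize_weights(p1, dens, structs,
                          objectives = list(list(structure = "PTV",
                                                 type = "target", dose = 60,
                                                 weight = 1)),
                          config = cfg, unit_doses = ud)
  scalar <- 60 * mean(ud[[1]]$values[ptv]) / mean(ud[[1]]$values[ptv]^2)
  expect_equal(opt$beams[[1]]$weight, scalar, tolerance = 1e-3)
  # objectives already met: weights unchanged within tolerance
  opt2 <- optimize_weights(opt, dens, structs,
                           objectives = list(list(structure = "PTV",
                                                  type = "target", dose = 60,
                                                  weight = 1)),
                           config = cfg, unit_doses = ud)
  expect_equal(opt2$beams[[1]]$weight, opt$beams[[1]]$weight, tolerance = 1e-2)
  # two-beam toy against the analytic 2x2 normal equations
  p2 <- plan_spec(list(beam_spec(0, field_size = c(60, 60)),
                       beam_spec(90, field_size = c(60, 60))),
                  prescription = 60, dose_per_fraction = 20, n_fractions = 3,
                  scheme = "SBRT")
  ud2 <- unit_beam_doses(p2, dens, cfg)
  opt3 <- optimize_weights(p2, dens, structs,
                           objectives = list(list(structure = "PTV",
                                                  type = "target", dose = 60,
                                                  weight = 1)),
                           config = cfg, unit_doses = ud2)
  A <- cbind(ud2[[1]]$values[ptv], ud2[[2]]$values[ptv])
  w_exact <- solve(crossprod(A), crossprod(A, rep(60, sum(ptv))))
  got <- c(opt3$beams[[1]]$weight, opt3$beams[[2]]$weight)
  expect_equal(got, as.numeric(w_exact), tolerance = 1e-3)
})

test_that("normalisation scales to 95% coverage and is idempotent", {
  d <- c(16L, 16L, 16L)
  set.seed(5)
  dose <- volume_grid(array(50 + rnorm(prod(d), sd = 2), d), 2)
  ptv <- array(FALSE, d); ptv[5:12, 5:12, 5:12] <- TRUE
  plan <- plan_spec(1L, prescription = 60, dose_per_fraction = 20,
                    n_fractions = 3, scheme = "SBRT")
  d95 <- dose_at_volume(dose, ptv, 95)
  nrm <- normalize_plan(plan, dose, ptv, prescription = 60)
  expect_equal(nrm$scale, 60 / d95)
  cover <- 100 * mean(nrm$dose$values[ptv] >= 60)
  expect_gte(cover, 95 - 0.5)
  expect_lte(cover, 95 + 0.5)
  again <- normalize_plan(nrm$plan, nrm$dose, ptv, prescription = 60)
  expect_equal(again$scale, 1, tolerance = 1e-12)
  expect_error(normalize_plan(plan, volume_grid(array(0, d), 2), ptv, 60),
               "D95")
})

test_that("recomputation with identical monitor units is faithful", {
  ph <- build_phantom(noiseless_spec())
  curve <- calibration_curve()
  ct <- override_ptv_density(ph$ct, ph$structures$masks$PTV)
  dens <- hu_to_density(ct, curve)
  plan <- plan_spec(3L, iso = c(50, -4, 0), field_size = c(100, 100))
  for (i in 1:3) plan$beams[[i]]$weight <- 10
  dose1 <- compose_plan(plan, dens)
  # same CT: bitwise-equal dose
  expect_identical(recompute_on(plan, ct, curve)$values, dose1$values)
  # all-air CT: in-field dose can only go up (less attenuation)
  air <- volume_grid(array(-1000, dim(ct$values)), ct$spacing, ct$origin)
  dose_air <- recompute_on(plan, air, curve)
  # compare well inside the aperture: at the penumbra fringe the broader
  # low-density lateral spread can locally undercut the sharper water edge
  cc <- voxel_centers(dose1)
  hit <- dose1$values > 0.7 * max(dose1$values) & abs(cc$z) < 30
  expect_true(all(dose_air$values[hit] >= dose1$values[hit] - 1e-9))
  # grid mismatch is an error
  shrunk <- resample_volume(ct, ct$spacing * 2)
  expect_error(recompute_on(plan, shrunk, curve, reference_grid = ct),
               "not on the same grid")
})

test_that("a 30 HU lung shift moves the PTV D95 by less than 1%", {
  ph <- build_phantom(noiseless_spec(ptv_size_class = "medium"))
  ptv <- ph$structures$masks$PTV
  ct <- override_ptv_density(ph$ct, ptv)
  curve <- calibration_curve()
  idx <- which(ptv, arr.ind = TRUE)
  iso <- ph$ct$origin + (colMeans(idx) - 0.5) * ph$ct$spacing
  plan <- plan_spec(5L, iso = iso, field_size = c(90, 90))
  for (i in seq_along(plan$beams)) plan$beams[[i]]$weight <- 2
  d95_ref <- dose_at_volume(recompute_on(plan, ct, curve), ptv, 95)
  shifted <- ct
  lung <- (ph$structures$masks$lung_left | ph$structures$masks$lung_right) & !ptv
  shifted$values[lung] <- shifted$values[lung] + 30
  d95_shift <- dose_at_volume(recompute_on(plan, shifted, curve), ptv, 95)
  expect_lt(abs(d95_shift - d95_ref) / d95_ref * 100, 1)
  expect_false(d95_shift == d95_ref)  # the engine does feel the density change
})
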