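test_that("bone HU/LAC conversion anchors are exact and invertible", {
  expect_equal(bone_lac_for_hu(70), 0.1)
  expect_equal(bone_lac_for_hu(2661), 0.2485)
  expect_error(bone_lac_for_hu(3000), "70, 2661")
  hu <- seq(70, 2661, length.out = 11)
  amap <- volume_grid(array(bone_lac_for_hu(hu), c(11, 1, 1)), 1)
  expect_equal(as.numeric(lac_to_hu(amap)$values), hu, tolerance = 1e-10)
})

test_that("gradient atlas LACs run from cortical rim to marrow core", {
  atlas <- make_bone_atlas(noiseless_spec(), lac_model = "gradient")
  bm <- atlas$bone_masks$spine
  lac <- bm$lac[bm$mask]
  expect_true(all(lac >= 0.1 - 1e-12 & lac <= 0.2485 + 1e-12))
  expect_equal(max(lac), 0.2485)
  expect_equal(min(lac), 0.1)
  # rim voxels (6-neighbour of outside) carry the cortical value
  rim <- bm$mask & !synctdose:::erode6(bm$mask)
  expect_true(all(bm$lac[rim] == 0.2485))
})

test_that("atlas registration handles identity and known-shift cases", {
  spec <- noiseless_spec(seed = 2)
  ph <- build_phantom(spec)
  dx <- simulate_dixon(ph$labels, spec)
  atlas <- make_bone_atlas(noiseless_spec(), lac_model = "uniform")
  # identity: same anatomy
  tr <- register_atlas(atlas, dx, ph$landmarks, deformable = TRUE)
  expect_lt(max(abs(tr$affine - diag(4))), 1e-6)
  expect_lt(synctdose:::max_field_norm(tr), 0.5 * small_spacing)
  # patient shifted by a known translation: landmark stage must recover it
  dx_shift <- dx
  dx_shift$water$origin <- dx$water$origin + c(3, -2, 5)
  dx_shift$fat$origin <- dx$fat$origin + c(3, -2, 5)
  lm_shift <- sweep(ph$landmarks, 2, c(3, -2, 5), "+")
  tr2 <- register_atlas(atlas, dx_shift, lm_shift, deformable = FALSE)
  expect_lt(max(abs(tr2$affine[1:3, 4] - c(-3, 2, -5))), 0.5)
})

test_that("atlas registration recovers a warped patient to < 1 mm at the landmarks", {
  spec <- noiseless_spec(seed = 2)
  ph <- build_phantom(spec)
  dx <- simulate_dixon(ph$labels, spec)
  atlas <- make_bone_atlas(noiseless_spec(), lac_model = "uniform")
  pw <- perturb_geometry(dx$water, 3, seed = 17)
  dx_w <- dx
  dx_w$water <- pw$volume
  dx_w$fat <- apply_displacement(dx$fat, pw$field)
  # warped_patient(x) = patient(x + u(x)): atlas positions of the landmarks
  # seen at x are x + u(x); the registration must reproduce that mapping
  u_at <- function(pts) cbind(
    sample_volume(volume_grid(pw$field$x, dx$water$spacing, dx$water$origin), pts),
    sample_volume(volume_grid(pw$field$y, dx$water$spacing, dx$water$origin), pts),
    sample_volume(volume_grid(pw$field$z, dx$water$spacing, dx$water$origin), pts))
  lm_p <- ph$landmarks  # same world positions; content moved under them
  tr <- register_atlas(atlas, dx_w, lm_p, deformable = TRUE)
  mapped <- transform_points(tr, lm_p)
  tru <- lm_p + u_at(lm_p)
  err <- sqrt(rowSums((mapped - tru)^2))
  expect_lt(mean(err), 1)
})

test_that("bone insertion overwrites only fat/soft tissue and is idempotent", {
  d <- c(10L, 10L, 10L)
  mu <- array(TISSUE_LAC[["soft_tissue"]], d)
  mu[, , 1:3] <- TISSUE_LAC[["lung"]]
  mu[, , 10] <- 0
  mu[, , 4] <- TISSUE_LAC[["fat"]]
  amap <- volume_grid(mu, 3)
  mask <- array(TRUE, d)
  lac <- array(0.2485, d)
  atlas <- structure(list(mr = volume_grid(array(1, d), 3),
                          bone_masks = list(all = list(mask = mask, lac = lac)),
                          landmarks = NULL, lac_model = "uniform"),
                     class = "bone_atlas")
  id <- spatial_transform(diag(4))
  out <- suppressWarnings(insert_bones(amap, atlas, id))
  expect_true(all(out$values[, , 5:9] == 0.2485))  # soft overwritten
  expect_true(all(out$values[, , 4] == 0.2485))    # fat overwritten
  expect_true(all(out$values[, , 1:3] == TISSUE_LAC[["lung"]]))  # lung kept
  expect_true(all(out$values[, , 10] == 0))        # air kept
  expect_lte(max(out$values), 0.2485)
  again <- suppressWarnings(insert_bones(out, atlas, id))
  expect_identical(again$values, out$values)
  # empty mask leaves the map untouched
  atlas$bone_masks$all$mask <- array(FALSE, d)
  expect_identical(insert_bones(amap, atlas, id)$values, amap$values)
})
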