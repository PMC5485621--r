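test_that("LAC to HU conversion reproduces every printed anchor exactly", {
  mu <- c(0, 0.0224, 0.0854, 0.1, 0.2485, 0.17425)
  amap <- volume_grid(array(mu, c(6, 1, 1)), 1)
  hu <- as.numeric(lac_to_hu(amap)$values)
  expect_identical(hu[1:4], c(-1000, -767, -110, 70))
  expect_equal(hu[5], 2661)
  expect_equal(hu[6], (70 + 2661) / 2)  # bone midpoint is linear
  expect_true(all(diff(hu[order(mu)]) >= 0))  # monotone over defined inputs
})

test_that("LAC to HU conversion rejects out-of-range and unmapped values", {
  bad <- volume_grid(array(c(0.3, 0.1, 0.26), c(3, 1, 1)), 1)
  expect_error(lac_to_hu(bad), "2 voxel")
  gap <- volume_grid(array(c(0.05, 0.1), c(2, 1, 1)), 1)
  expect_error(lac_to_hu(gap), "1 voxel")
})

test_that("a noiseless phantom synthesis reproduces the ground truth CT", {
  spec <- noiseless_spec(seed = 3)
  ph <- build_phantom(spec)
  dx <- simulate_dixon(ph$labels, spec)
  amap <- assign_lac(classify_voxels(dx))
  atlas <- make_bone_atlas(noiseless_spec(), lac_model = "uniform")
  tr <- register_atlas(atlas, dx, ph$landmarks, deformable = FALSE)
  synct <- lac_to_hu(insert_bones(amap, atlas, tr))
  expect_equal(synct$values, ph$ct$values, tolerance = 1e-12)
  # pre-noise HU histogram: the four class values plus the bone interval
  vals <- unique(as.numeric(synct$values))
  soft4 <- unname(TISSUE_HU)
  bone_vals <- setdiff(round(vals, 6), round(soft4, 6))
  expect_true(all(bone_vals >= 70 & bone_vals <= 2661))
})

test_that("MR can live on the coarser clinical grid and still classify", {
  spec <- noiseless_spec(seed = 3, mr_spacing = c(2.6, 2.6, 3.12) * 1.5)
  ph <- build_phantom(spec)
  dx <- simulate_dixon(ph$labels, spec)
  expect_false(identical(dim(dx$water$values), dim(ph$ct$values)))
  lab <- classify_voxels(dx)
  hu <- lac_to_hu(assign_lac(lab))
  onplan <- resample_volume(hu, spec$spacing, dim = spec$dim,
                            origin = ph$ct$origin)
  expect_identical(dim(onplan$values), dim(ph$ct$values))
  # away from class boundaries the resampled synCT matches the truth
  lung <- ph$structures$masks$PTV
  expect_lt(mean(abs(onplan$values[lung] - (-767))), 30)
})

test_that("PTV density override sets -4 HU, leaves the rest, and is idempotent", {
  ph <- build_phantom(noiseless_spec())
  ptv <- ph$structures$masks$PTV
  ct1 <- override_ptv_density(ph$ct, ptv)
  expect_true(all(ct1$values[ptv] == -4))
  expect_identical(ct1$values[!ptv], ph$ct$values[!ptv])
  ct2 <- override_ptv_density(ct1, ptv)
  expect_identical(ct2$values, ct1$values)
  expect_warning(override_ptv_density(ph$ct, array(FALSE, dim(ph$ct$values))),
                 "empty")
})

test_that("organ mean HU table is exact on constants and behaves on noise", {
  spec <- noiseless_spec()
  ph <- build_phantom(spec)
  tab <- organ_mean_hu(list(synCT = ph$ct), ph$structures)
  expect_equal(tab$synCT[tab$organ == "lung_left"], -767)
  expect_equal(tab$synCT[tab$organ == "spine"], 336)
  one <- ph$structures
  m1 <- array(FALSE, dim(ph$ct$values)); m1[30, 30, 30] <- TRUE
  one$masks$single <- m1
  t1 <- organ_mean_hu(list(ct = ph$ct), one, organs = "single")
  expect_equal(t1$ct, ph$ct$values[30, 30, 30])
  # noisy lung mean lands within 3 standard errors of the truth
  spec_n <- noisy_spec(seed = 44)
  phn <- build_phantom(spec_n)
  m <- phn$structures$masks$lung_left
  se <- 30 / sqrt(sum(m))
  tabn <- organ_mean_hu(list(ct = phn$ct), phn$structures)
  expect_lt(abs(tabn$ct[tabn$organ == "lung_left"] - (-767)), 3 * se)
  # empty masks are flagged, not NaN
  ph$structures$masks$heart[] <- FALSE
  te <- organ_mean_hu(list(ct = ph$ct), ph$structures)
  expect_equal(te$flag[te$organ == "heart"], "empty mask")
})

test_that("cropping keeps the structures plus margin and the grid metadata", {
  ph <- build_phantom(noiseless_spec())
  cr <- crop_to_structures(ph$ct, ph$structures, margin_mm = 5)
  expect_true(all(dim(cr$values) <= dim(ph$ct$values)))
  # world position of retained voxels is preserved
  idx <- which(ph$structures$masks$body, arr.ind = TRUE)[1, ]
  w_old <- ph$ct$origin + (idx - 0.5) * ph$ct$spacing
  v <- sample_volume(cr, matrix(w_old, ncol = 3))
  expect_equal(v, ph$ct$values[idx[1], idx[2], idx[3]])
})
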