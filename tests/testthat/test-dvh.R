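mk_dose <- function(values) {
  n <- length(values)
  volume_grid(array(values, c(n, 1, 1)), 1)
}
full_mask <- function(dose) array(TRUE, dim(dose$values))

test_that("cumulative DVH reproduces step functions and the sort oracle", {
  d <- mk_dose(rep(60, 100))
  cv <- cumulative_dvh(d, full_mask(d))
  expect_true(all(cv$volume[cv$dose <= 60] == 100))
  expect_true(all(cv$volume[cv$dose > 60] == 0))

  d2 <- mk_dose(c(rep(20, 50), rep(40, 50)))
  cv2 <- cumulative_dvh(d2, full_mask(d2))
  mid <- cv2$dose > 20 & cv2$dose <= 40
  expect_true(all(cv2$volume[mid] == 50))

  set.seed(2)
  dr <- mk_dose(runif(500, 0, 70))
  cvr <- cumulative_dvh(dr, full_mask(dr))
  sorted <- sort(dr$values)
  oracle <- vapply(cvr$dose, function(e)
    100 * sum(sorted >= e - 1e-9) / 500, numeric(1))
  expect_equal(cvr$volume, oracle)
  expect_equal(cvr$volume[1], 100)
  expect_equal(cvr$volume[length(cvr$volume)], 0)
  expect_true(all(diff(cvr$volume) <= 0))
  expect_error(cumulative_dvh(dr, array(FALSE, dim(dr$values))), "empty")
})

test_that("Dx follows the exact counting convention", {
  d <- mk_dose(1:100)
  m <- full_mask(d)
  # brute-force oracle over all integer thresholds
  brute_dx <- function(x) max(Filter(function(t) mean(d$values >= t) >= x / 100,
                                     1:100))
  expect_equal(dose_at_volume(d, m, 95), 6)
  expect_equal(dose_at_volume(d, m, 95), brute_dx(95))
  expect_equal(dose_at_volume(d, m, 50), brute_dx(50))
  expect_equal(dose_at_volume(d, m, 100), 1)   # the minimum
  u <- mk_dose(rep(60, 10))
  for (x in c(5, 50, 95, 100))
    expect_equal(dose_at_volume(u, full_mask(u), x), 60)
})

test_that("Vx uses the strictly-greater convention and Dmax is the maximum", {
  d <- mk_dose(1:100)
  m <- full_mask(d)
  expect_equal(volume_at_dose(d, m, 20), 80)   # not 81
  expect_equal(volume_at_dose(d, m, 200), 0)
  expect_equal(max_dose(d, m), 100)
  u <- mk_dose(rep(42, 7))
  expect_equal(max_dose(u, full_mask(u)), 42)
})

test_that("curve-based metrics match the exact ones within a bin width", {
  set.seed(9)
  d <- mk_dose(rnorm(2000, 40, 12))
  m <- full_mask(d)
  cv <- cumulative_dvh(d, m, bin_width = 0.01)
  for (x in c(20, 50, 90, 98)) {
    expect_lt(abs(dose_at_volume(cv, x) - dose_at_volume(d, m, x)), 0.011)
  }
  for (g in c(10, 30, 55)) {
    exact <- volume_at_dose(d, m, g)
    expect_lt(abs(volume_at_dose(cv, g) - exact), 100 * 1 / 2000 + 0.25)
  }
})

test_that("Dx and Vx are monotone and near-inverse", {
  set.seed(3)
  d <- mk_dose(runif(800, 0, 60))
  m <- full_mask(d)
  xs <- c(5, 25, 50, 75, 95, 100)
  dx <- vapply(xs, function(x) dose_at_volume(d, m, x), numeric(1))
  expect_true(all(diff(dx) <= 0))
  gs <- c(5, 15, 30, 45)
  vx <- vapply(gs, function(g) volume_at_dose(d, m, g), numeric(1))
  expect_true(all(diff(vx) <= 0))
  expect_true(all(max_dose(d, m) >= dx))
  # V at Dx recovers at least x (within the one-voxel granularity)
  for (x in c(20, 60, 95)) {
    dxx <- dose_at_volume(d, m, x)
    expect_gte(100 * mean(d$values[m] >= dxx), x - 100 / 800)
  }
})

test_that("the metric set applies the structure rules", {
  ph <- build_phantom(noiseless_spec(ptv_size_class = "small"))
  d <- dim(ph$ct$values)
  dosev <- volume_grid(array(30, d), ph$ct$spacing, ph$ct$origin)
  dosev$values[ph$structures$masks$PTV] <- 60
  ms <- dvh_metric_set(dosev, ph$structures, prescription = 60)
  expect_equal(unname(ms["D95"]), 100)
  expect_equal(unname(ms["lung_V20"]), 100)  # lung minus PTV all at 30 Gy
  expect_equal(unname(ms["cord_Dmax"]), 30)
  expect_true(ms["D100"] <= ms["D98"] && ms["D98"] <= ms["D95"])
  # PTV exclusion: lung voxels at 60 Gy would flip V40, PTV ones must not
  expect_equal(unname(ms["lung_V10"]), 100)
  ph$structures$masks$lung_left[] <- FALSE
  ph$structures$masks$lung_right <- ph$structures$masks$PTV
  expect_error(dvh_metric_set(dosev, ph$structures, 60), "empty")
})
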