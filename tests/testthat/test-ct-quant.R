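test_that("HU calibration maps water to 0 and air to -1000", {
  raw <- array(c(0.2, 0.0, 0.1), dim = c(3, 1, 1))
  v <- hu_calibrate(raw, mu_water = 0.2, mu_air = 0.0, spacing_mm = 1)
  expect_equal(as.vector(v$values), c(0, -1000, -500))
  expect_error(hu_calibrate(raw, 0.2, 0.2), "degenerate")
})

test_that("region growing matches the brute-force flood-fill oracle", {
  set.seed(101)
  for (rep in 1:12) {
    d <- sample(4:12, 3, replace = TRUE)
    conn <- sample(c(6L, 26L), 1)
    vals <- array(sample(c(100, 400), prod(d), replace = TRUE,
                         prob = c(0.4, 0.6)), dim = d)
    vol <- voxel_volume(vals, spacing_mm = 1)
    in_range <- which(vals == 400, arr.ind = TRUE)
    seeds <- in_range[sample(nrow(in_range), sample(1:3, 1)), , drop = FALSE]
    got <- grow_region(vol, seeds, c(300, 600), conn)
    want <- flood_fill_oracle(vals == 400, seeds, conn)
    expect_identical(got, want)
  }
})

test_that("region growing respects walls and validates seeds", {
  vals <- array(400, dim = c(10, 10, 10))
  vals[5, , ] <- 100                       # out-of-range wall splits the grid
  vol <- voxel_volume(vals, spacing_mm = 1)
  m <- grow_region(vol, matrix(c(2, 5, 5), ncol = 3), c(300, 600))
  expect_true(all(which(m, arr.ind = TRUE)[, 1] < 5))
  expect_identical(sum(m), 4L * 100L)
  # uniform in-range volume floods completely
  uni <- voxel_volume(array(400, dim = c(6, 6, 6)), spacing_mm = 1)
  expect_true(all(grow_region(uni, matrix(c(1, 1, 1), ncol = 3), c(300, 600))))
  expect_error(grow_region(vol, matrix(c(5, 5, 5), ncol = 3), c(300, 600)),
               "seed 1 rejected")
  expect_error(grow_region(vol, matrix(c(99, 5, 5), ncol = 3), c(300, 600)),
               "outside the grid")
  expect_error(grow_region(vol, NULL, c(300, 600)), "no seed")
})

test_that("noise-free blood segmentation equals the ground-truth label", {
  sp <- small_spec(noise_sd_hu = 0)
  for (phase in c("diastole", "systole")) {
    ph <- build_heart_phantom(sp, phase, 13, agent = "blood_pool")
    expect_identical(segment_lv_blood(ph$volume), label_eq(ph$mask, 2))
  }
})

test_that("noisy blood segmentation overlaps truth with Dice >= 0.95", {
  sp <- small_spec(noise_sd_hu = 30, seed = 8)
  dia <- build_heart_phantom(sp, "diastole", 13, agent = "blood_pool", seed = 1)
  sys <- build_heart_phantom(sp, "systole", 13, agent = "blood_pool", seed = 2)
  md <- segment_lv_blood(dia$volume)
  ms <- segment_lv_blood(sys$volume)
  expect_gte(dice(md, label_eq(dia$mask, 2)), 0.95)
  expect_gte(dice(ms, label_eq(sys$mask, 2)), 0.95)
  expect_lt(sum(ms), sum(md))    # systolic cavity is smaller
})

test_that("mask volume and ejection fraction arithmetic", {
  expect_identical(mask_volume_mm3(array(FALSE, dim = c(3, 3, 3)), 1), 0)
  expect_equal(mask_volume_mm3(array(TRUE, dim = c(10, 10, 10)), 1), 1000)
  m <- array(FALSE, dim = c(20, 10, 10)); m[1:10, , ] <- TRUE
  expect_equal(mask_volume_mm3(m, 0.077), 1000 * 0.077^3, tolerance = 1e-12)
  expect_equal(ejection_fraction(50, 32), 0.36)
  expect_identical(ejection_fraction(5, 5), 0)
  expect_identical(ejection_fraction(5, 0), 1)
  expect_error(ejection_fraction(0, 1), "> 0")
  expect_warning(ef <- ejection_fraction(10, 12), "exceeds")
  expect_equal(ef, -0.2)
})

test_that("myocardial band hugs the wall and excludes the blood pool", {
  sp <- small_spec(noise_sd_hu = 30, seed = 3)
  bp <- build_heart_phantom(sp, "diastole", 13, agent = "blood_pool", seed = 4)
  de <- build_heart_phantom(sp, "diastole", 13, agent = "iohexol", seed = 5)
  bm <- segment_lv_blood(bp$volume)
  myo <- segment_myocardium(de$volume, bm, wall_thickness_mm = 0.9)
  expect_gte(dice(myo, label_in(de$mask, c(1, 3))), 0.9)
  expect_identical(sum(myo & bm), 0L)
  zero <- segment_myocardium(de$volume, bm, wall_thickness_mm = 0)
  expect_false(any(zero))
  expect_error(segment_myocardium(de$volume, array(FALSE, dim(bm))), "empty")
})

test_that("noise-free infarct segmentation is exact; absent infarct gives an empty mask", {
  sp <- small_spec(noise_sd_hu = 0, infarct_fraction = 0.32)
  de <- build_heart_phantom(sp, "diastole", 13, agent = "iohexol")
  bm <- segment_lv_blood(
    build_heart_phantom(sp, "diastole", 13, agent = "blood_pool")$volume)
  myo <- segment_myocardium(de$volume, bm, wall_thickness_mm = 0.9)
  inf <- segment_infarct(de$volume, myo)
  expect_identical(inf, label_eq(de$mask, 3))
  sp0 <- small_spec(noise_sd_hu = 0, infarct_fraction = 0)
  de0 <- build_heart_phantom(sp0, "diastole", 13, agent = "iohexol")
  myo0 <- segment_myocardium(de0$volume, segment_lv_blood(
    build_heart_phantom(sp0, "diastole", 13, agent = "blood_pool")$volume),
    wall_thickness_mm = 0.9)
  expect_false(any(segment_infarct(de0$volume, myo0)))
  expect_error(segment_infarct(de0$volume, array(FALSE, dim(myo0))), "empty")
})

test_that("noisy infarct volume is recovered within 10%", {
  sp <- small_spec(noise_sd_hu = 30, infarct_fraction = 0.3, seed = 12)
  de <- build_heart_phantom(sp, "diastole", 13, agent = "iohexol", seed = 13)
  bm <- segment_lv_blood(
    build_heart_phantom(sp, "diastole", 13, agent = "blood_pool", seed = 14)$volume)
  myo <- segment_myocardium(de$volume, bm, wall_thickness_mm = 0.9)
  inf <- segment_infarct(de$volume, myo)
  truth <- sum(de$mask$labels == 3)
  expect_lt(abs(sum(inf) - truth) / truth, 0.1)
})

test_that("percent infarct of the wall is bounded and correctly normalized", {
  d <- c(5, 5, 4)
  myo <- array(FALSE, dim = d); myo[1:70] <- TRUE
  inf <- array(FALSE, dim = d); inf[71:100] <- TRUE
  expect_equal(percent_infarct_ct(inf, myo), 30)
  expect_identical(percent_infarct_ct(array(FALSE, dim = d), myo), 0)
  expect_error(percent_infarct_ct(array(FALSE, dim = d),
                                  array(FALSE, dim = d)), "empty")
  set.seed(5)
  for (i in 1:10) {
    a <- array(runif(60) < 0.4, dim = c(5, 4, 3))
    b <- array(runif(60) < 0.4, dim = c(5, 4, 3))
    if (!any(a | b)) next
    p <- percent_infarct_ct(a, b)
    expect_true(p >= 0 && p <= 100)
  }
})

test_that("segmentation is invariant to a global HU offset with shifted thresholds", {
  sp <- small_spec(noise_sd_hu = 30, infarct_fraction = 0.3, seed = 21)
  de <- build_heart_phantom(sp, "diastole", 13, agent = "iohexol", seed = 22)
  bp <- build_heart_phantom(sp, "diastole", 13, agent = "blood_pool", seed = 23)
  off <- 250
  shift_vol <- function(v) voxel_volume(v$values + off, v$spacing_mm, v$origin_mm)
  p0 <- segmentation_params()
  p1 <- segmentation_params(blood_hu_range = p0$blood_hu_range + off,
                            tissue_hu_min = p0$tissue_hu_min + off)
  bm0 <- segment_lv_blood(bp$volume, p0)
  bm1 <- segment_lv_blood(shift_vol(bp$volume), p1)
  expect_identical(bm0, bm1)
  myo0 <- segment_myocardium(de$volume, bm0, p0, 0.9)
  myo1 <- segment_myocardium(shift_vol(de$volume), bm1, p1, 0.9)
  expect_identical(myo0, myo1)
  expect_identical(segment_infarct(de$volume, myo0, p0),
                   segment_infarct(shift_vol(de$volume), myo1, p1))
})

test_that("ROI statistics handle constant and single-voxel regions", {
  v <- voxel_volume(array(rep(c(100, 200), each = 4), dim = c(2, 2, 2)), 1)
  m <- array(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), dim = c(2, 2, 2))
  st <- roi_mean_hu(v, m)
  expect_equal(st$mean_hu, 100)
  expect_identical(st$sd_hu, 0)
  expect_identical(st$n_voxels, 4L)
  single <- array(FALSE, dim = c(2, 2, 2)); single[2, 2, 2] <- TRUE
  expect_equal(roi_mean_hu(v, single)$mean_hu, 200)
  expect_identical(roi_mean_hu(v, single)$sd_hu, 0)
  expect_error(roi_mean_hu(v, array(FALSE, dim = c(2, 2, 2))), "empty")
})
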