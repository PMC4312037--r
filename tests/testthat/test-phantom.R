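test_that("noise-free ROI means equal the washout model at both time points", {
  sp <- small_spec(noise_sd_hu = 0)
  for (t in c(13, 30)) {
    ph <- build_heart_phantom(sp, "diastole", t_min = t)
    v <- ph$volume; m <- ph$mask
    expect_equal(roi_mean_hu(v, label_eq(m, 2))$mean_hu,
                 washout_hu(sp$washout, t, "blood"), tolerance = 1e-12)
    expect_equal(roi_mean_hu(v, label_eq(m, 1))$mean_hu,
                 washout_hu(sp$washout, t, "myocardium"), tolerance = 1e-12)
    expect_equal(roi_mean_hu(v, label_eq(m, 3))$mean_hu,
                 washout_hu(sp$washout, t, "infarct"), tolerance = 1e-12)
  }
})

test_that("blood-pool-agent rendering puts the infarct at myocardial HU", {
  sp <- small_spec(noise_sd_hu = 0)
  ph <- build_heart_phantom(sp, "diastole", 13, agent = "blood_pool")
  expect_equal(roi_mean_hu(ph$volume, label_eq(ph$mask, 3))$mean_hu,
               washout_hu(sp$washout, 13, "myocardium"), tolerance = 1e-12)
  expect_equal(roi_mean_hu(ph$volume, label_eq(ph$mask, 2))$mean_hu,
               washout_hu(sp$washout, 13, "blood"), tolerance = 1e-12)
})

test_that("labels partition the grid and the infarct sits inside the wall", {
  ph <- build_heart_phantom(small_spec(noise_sd_hu = 20), "diastole", 13)
  lab <- ph$mask$labels
  cnt <- tabulate(lab + 1L, nbins = 4L)
  expect_identical(sum(cnt), length(lab))
  # infarct voxels lie within the anatomical shell: rebuilding without a
  # wedge turns exactly those voxels into myocardium
  sp0 <- small_spec(noise_sd_hu = 20, infarct_fraction = 0)
  lab0 <- build_heart_phantom(sp0, "diastole", 13)$mask$labels
  expect_true(all(lab0[lab == 3] == 1))
})

test_that("zero-extent wedge produces no infarct voxels", {
  sp <- small_spec(infarct_fraction = 0)
  ph <- build_heart_phantom(sp, "diastole", 13)
  expect_identical(sum(ph$mask$labels == 3), 0L)
})

test_that("voxelized cavity volume converges to the analytic ellipsoid volume", {
  ana <- 4 / 3 * pi * prod(c(1.6, 1.6, 2.6))
  err <- vapply(c(0.15, 0.075), function(sp_mm) {
    ph <- build_heart_phantom(small_spec(spacing_mm = sp_mm), "diastole", 13)
    abs(mask_volume_mm3(label_eq(ph$mask, 2), sp_mm) - ana) / ana
  }, 0)
  expect_true(all(err < 0.05))
  expect_lt(err[2], err[1])
})

test_that("systolic scaling reproduces the requested ejection fraction", {
  for (ef in c(0.36, 0.59)) {
    sp <- small_spec(true_ef = ef, spacing_mm = 0.11)
    vd <- sum(build_heart_phantom(sp, "diastole", 13)$mask$labels == 2)
    vs <- sum(build_heart_phantom(sp, "systole", 13)$mask$labels == 2)
    expect_equal(1 - vs / vd, ef, tolerance = 0.02)
  }
  expect_error(phantom_spec(true_ef = 0.3,
                            lv_cavity_semiaxes_sys_mm = c(1.7, 1.7, 3.0)),
               "inconsistent")
})

test_that("wedge solver hits the target infarct fraction of the wall", {
  for (frac in c(0.15, 0.32, 0.45)) {
    sp <- small_spec(infarct_fraction = frac, spacing_mm = 0.11)
    tr <- build_heart_phantom(sp, "diastole", 13)$truth
    expect_equal(tr$percent_infarct, 100 * frac, tolerance = 0.08 * 100 * frac + 1)
  }
  expect_error(infarct_wedge_for_fraction(c(1.6, 1.6, 2.6), 0.9, 0.9),
               "not reachable")
})

test_that("phantom generation is bit-reproducible under a fixed seed", {
  sp <- small_spec(noise_sd_hu = 30, seed = 42)
  a <- build_heart_phantom(sp, "diastole", 13)
  b <- build_heart_phantom(sp, "diastole", 13)
  expect_identical(a$volume$values, b$volume$values)
  c2 <- build_heart_phantom(sp, "diastole", 13, seed = 43)
  expect_false(identical(a$volume$values, c2$volume$values))
})

test_that("too-coarse spacing for the wall is rejected", {
  sp <- small_spec(spacing_mm = 0.5)    # wall 0.9 < 2 * 0.5
  expect_error(build_heart_phantom(sp, "diastole", 13), "too coarse")
})

test_that("motion streaks: identity at severity 0, infarct over-count above", {
  sp <- small_spec(noise_sd_hu = 30, infarct_fraction = 0.3, seed = 5)
  de <- build_heart_phantom(sp, "diastole", 13, agent = "iohexol")
  expect_identical(add_motion_streaks(de$volume, 0), de$volume)
  bp <- build_heart_phantom(sp, "diastole", 13, agent = "blood_pool",
                            seed = 6)
  bm <- segment_lv_blood(bp$volume)
  myo <- segment_myocardium(de$volume, bm, wall_thickness_mm = 0.9)
  pct_clean <- percent_infarct_ct(segment_infarct(de$volume, myo), myo)
  cor <- add_motion_streaks(de$volume, 1, seed = 9)
  myoc <- segment_myocardium(cor, bm, wall_thickness_mm = 0.9)
  pct_cor <- percent_infarct_ct(segment_infarct(cor, myoc), myoc)
  expect_gte(pct_cor, pct_clean)
})

test_that("cohort simulation matches the group structure and is deterministic", {
  specs <- simulate_cohort(7, 7, seed = 3)
  expect_length(specs, 14)
  n_no_inf <- sum(vapply(specs, function(s)
    s$infarct_wedge$azimuth_end_deg == s$infarct_wedge$azimuth_start_deg, TRUE))
  expect_identical(n_no_inf, 7L)
  expect_identical(vapply(specs, function(s) s$group, ""),
                   rep(c("IR", "control"), each = 7))
  again <- simulate_cohort(7, 7, seed = 3)
  expect_identical(specs, again)
  # large-n group means approach the published EF distributions
  big <- simulate_cohort(300, 300, seed = 11)
  efs <- vapply(big, function(s) s$true_ef, 0)
  expect_equal(mean(efs[1:300]), 0.36, tolerance = 0.03)
  expect_equal(mean(efs[301:600]), 0.59, tolerance = 0.02)
})
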