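# build a clean synthetic slice image directly: white background, a viable
# disk with a pale wedge, known pixel areas
synthetic_face <- function(n = 120, wedge_deg = c(-60, 60), r_mm = 2,
                           pixel_size_mm = 0.05, jitter_sd = 0, seed = 1) {
  set.seed(seed)
  xs <- (seq_len(n) - (n + 1) / 2) * pixel_size_mm
  r2 <- outer(xs^2, xs^2, "+")
  az <- outer(xs, xs, function(x, y) atan2(y, x) * 180 / pi)
  tissue <- r2 <= r_mm^2
  infarct <- tissue & az >= wedge_deg[1] & az <= wedge_deg[2]
  img <- array(1, dim = c(n, n, 3))
  for (ch in 1:3) {
    chan <- img[, , ch]
    chan[tissue] <- c(180, 40, 50)[ch] / 255
    chan[infarct] <- c(235, 190, 190)[ch] / 255
    img[, , ch] <- chan
  }
  if (jitter_sd > 0) {
    img <- img + array(rnorm(length(img), 0, jitter_sd), dim = dim(img))
    img[img < 0] <- 0; img[img > 1] <- 1
  }
  list(image = img, tissue_px = sum(tissue), infarct_px = sum(infarct),
       pixel_size_mm = pixel_size_mm)
}

test_that("tissue segmentation recovers the rendered area and rejects blanks", {
  f <- synthetic_face(jitter_sd = 10 / 255, seed = 2)
  m <- segment_tissue(f$image)
  expect_equal(sum(m), f$tissue_px, tolerance = 0.05)
  expect_error(segment_tissue(array(1, dim = c(40, 40, 3))), "blank")
  expect_error(segment_tissue(array(1, dim = c(40, 40))), "RGB")
})

test_that("tissue mask is unchanged by a 90-degree image rotation", {
  f <- synthetic_face(jitter_sd = 10 / 255, seed = 3)
  rot <- function(a) aperm(a, c(2, 1, 3))[dim(a)[2]:1, , , drop = FALSE]
  m1 <- segment_tissue(f$image)
  m2 <- segment_tissue(rot(f$image))
  expect_identical(m2, t(m1)[ncol(m1):1, ])
})

test_that("viability classification partitions the tissue and hits the truth", {
  f <- synthetic_face(jitter_sd = 10 / 255, seed = 4)
  tis <- segment_tissue(f$image)
  cls <- classify_viability(f$image, tis)
  expect_identical(cls$viable | cls$infarct, tis)
  expect_false(any(cls$viable & cls$infarct))
  expect_equal(sum(cls$infarct), f$infarct_px, tolerance = 0.1)
  # all-viable slice
  f0 <- synthetic_face(wedge_deg = c(0, 0), jitter_sd = 10 / 255, seed = 5)
  cls0 <- classify_viability(f0$image, segment_tissue(f0$image))
  expect_lt(sum(cls0$infarct) / sum(f0$tissue_px), 0.02)
})

test_that("percent infarct arithmetic from slice measurements", {
  mk <- function(tis, inf) structure(
    list(tissue_area_front_mm2 = tis, tissue_area_back_mm2 = tis,
         infarct_area_front_mm2 = inf, infarct_area_back_mm2 = inf,
         thickness_mm = 1), class = "slice_measurement")
  expect_equal(percent_infarct_histology(list(mk(100, 25), mk(100, 25))), 25)
  expect_identical(percent_infarct_histology(list(mk(100, 0))), 0)
  expect_error(percent_infarct_histology(list(mk(0, 0))), "zero total")
  expect_error(percent_infarct_histology(list()), "at least one")
})

test_that("end-to-end histology estimate recovers the phantom infarct percent", {
  sp <- small_spec(noise_sd_hu = 0, infarct_fraction = 0.32, seed = 6)
  truth <- build_heart_phantom(sp, "diastole", 13)$truth$percent_infarct
  slices <- render_ttc_slices(sp, 1.0, pixel_size_mm = 0.05, seed = 7)
  est <- percent_infarct_histology(slices)
  expect_lt(abs(est - truth), 3)
})

test_that("finer slicing reduces the out-of-plane discretization bias", {
  # For one geometry the error depends on where the wedge's apical cut
  # falls within a slab, so the improvement is a property of the average
  # over geometries, not of any single heart.
  bias_for <- function(seed, th) {
    set.seed(seed)
    frac <- runif(1, 0.2, 0.4)
    apical <- runif(1, 0.45, 0.8)
    sp <- small_spec()
    sp$infarct_wedge <- infarct_wedge_for_fraction(
      sp$lv_cavity_semiaxes_dia_mm, sp$wall_thickness_mm, frac, apical)
    slices <- render_ttc_slices(sp, th, pixel_size_mm = 0.06, seed = seed,
                                jitter_sd = 0)
    meas <- lapply(slices, function(s) structure(
      list(tissue_area_front_mm2 = s$true_tissue_area_front_mm2,
           tissue_area_back_mm2 = s$true_tissue_area_back_mm2,
           infarct_area_front_mm2 = s$true_infarct_area_front_mm2,
           infarct_area_back_mm2 = s$true_infarct_area_back_mm2,
           thickness_mm = th), class = "slice_measurement"))
    # the wedge solver makes the analytic infarct fraction exactly `frac`
    abs(percent_infarct_histology(meas) - 100 * frac)
  }
  coarse <- vapply(1:10, bias_for, 0, th = 1.0)
  fine <- vapply(1:10, bias_for, 0, th = 0.5)
  expect_lt(mean(fine), mean(coarse))
})

test_that("percent infarct is invariant to photograph resolution", {
  sp <- small_spec(infarct_fraction = 0.3, seed = 10)
  p1 <- percent_infarct_histology(render_ttc_slices(sp, 1, 0.05, seed = 11))
  p2 <- percent_infarct_histology(render_ttc_slices(sp, 1, 0.1, seed = 11))
  expect_lt(abs(p1 - p2), 1.5)
})
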