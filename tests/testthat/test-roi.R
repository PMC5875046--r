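test_that("noise is the mean of ROI standard deviations", {
  lay <- uniform_layout()
  sp <- 120 / 128
  rois <- background_rois(0.4, radius_mm = 30)
  img <- matrix(0, 128, 128)
  sds <- c(2, 3, 4)
  for (i in 1:3) img <- fill_roi(img, rois[[i]], 100, sds[i], sp, seed = i)
  st <- make_stack(list(img), sp, lay)
  expect_equal(measure_noise(st, rois)$summary, 3, tolerance = 1e-10)
  # constant image -> zero noise
  st0 <- make_stack(list(matrix(7, 128, 128)), sp, lay)
  expect_identical(measure_noise(st0, rois)$summary, 0)
})

test_that("noise measurement recovers the generator sigma and is
           scale-equivariant", {
  lay <- uniform_layout()
  st <- simulate_stack(lay, scan_condition("FBP", 6), white_model(10), 10,
                       seed = 12, matrix_size = 128)
  rois <- background_rois(0.4, radius_mm = 30)
  nm <- measure_noise(st, rois)
  expect_lt(abs(nm$summary - 10), 0.6)
  st2 <- st
  st2$images <- st$images * 3
  expect_equal(measure_noise(st2, rois)$summary, 3 * nm$summary)
})

test_that("tiny ROIs are rejected as unstable", {
  lay <- uniform_layout()
  st <- make_stack(list(matrix(0, 128, 128)), 120 / 128, lay)
  expect_error(measure_noise(st, roi_spec(c(0, 0), 0.005, "dot")),
               "fewer than 10 pixels")
})

test_that("CNR follows |object - background| / background SD", {
  lay <- disk_layout()
  sp <- 120 / 128
  t_roi <- roi_spec(c(0, 0), 0.4, "t")
  b_rois <- background_rois(0.4, radius_mm = 20)
  img <- matrix(0, 128, 128)
  t_idx <- ctiq:::roi_index(t_roi, 128, sp)
  img[t_idx] <- 10
  for (i in 1:3) img <- fill_roi(img, b_rois[[i]], 0, 5, sp, seed = 10 + i)
  st <- make_stack(list(img), sp, lay)
  cm <- measure_cnr(st, t_roi, b_rois)
  pooled <- unlist(lapply(b_rois, ctiq:::roi_index, matrix_size = 128,
                          spacing = sp))
  expect_equal(cm$per_replicate,
               abs(10 - mean(img[pooled])) / sd(img[pooled]))
  # zero contrast -> zero CNR
  img0 <- img
  img0[t_idx] <- mean(img[pooled])
  expect_equal(measure_cnr(make_stack(list(img0), sp, lay), t_roi,
                           b_rois)$summary, 0)
})

test_that("CNR on printed sensitometry values: acrylic vs background", {
  # acrylic 126 HU, background 103 HU with SD 1.0 -> CNR 23.0
  lay <- disk_layout()
  sp <- 120 / 128
  t_roi <- roi_spec(c(0, 0), 0.4, "t")
  b_rois <- background_rois(0.4, radius_mm = 20)
  img <- matrix(103, 128, 128)
  img[ctiq:::roi_index(t_roi, 128, sp)] <- 126
  for (i in 1:3) img <- fill_roi(img, b_rois[[i]], 103, 1, sp, seed = i)
  st <- make_stack(list(img), sp, lay)
  cm <- measure_cnr(st, t_roi, b_rois)
  pooled <- unlist(lapply(b_rois, ctiq:::roi_index, matrix_size = 128,
                          spacing = sp))
  expect_equal(cm$summary, 23 / sd(img[pooled]), tolerance = 1e-10)
  expect_lt(abs(cm$summary - 23.0), 0.3)
})

test_that("CNR is invariant to global HU offsets and errors on noiseless
           input", {
  lay <- disk_layout()
  st <- simulate_stack(lay, scan_condition("FBP", 6), white_model(2), 5,
                       seed = 3, matrix_size = 128)
  t_roi <- roi_spec(c(0, 0), 0.4, "t")
  b_rois <- background_rois(0.4, radius_mm = 20)
  cm <- measure_cnr(st, t_roi, b_rois)
  st2 <- st
  st2$images <- st$images + 500
  expect_equal(measure_cnr(st2, t_roi, b_rois)$per_replicate,
               cm$per_replicate)
  st0 <- simulate_stack(lay, scan_condition("FBP", 6), white_model(0), 1,
                        seed = 3, matrix_size = 128)
  expect_error(measure_cnr(st0, t_roi, b_rois), "zero")
  expect_error(measure_cnr(st, roi_spec(c(0, 0), 0.5, "t"), b_rois),
               "identical")
})

test_that("CNR converges to |dHU + dbias| / sigma on generator truth", {
  lay <- disk_layout(target_hu = 110)
  m <- algorithm_model("biased", noise_ref = 4, dose_ref = 1,
                       dose_exponent = 0, psf_sigma = 0,
                       hu_bias = function(hu, dose) ifelse(hu > 105, -5, 0),
                       noise_correlation_mm = 0)
  st <- simulate_stack(lay, scan_condition("MBIR", 6), m, 20, seed = 8,
                       matrix_size = 256)
  cm <- measure_cnr(st, roi_spec(c(0, 0), 0.4, "t"),
                    background_rois(0.4, radius_mm = 20))
  expect_lt(abs(cm$summary - abs(10 - 5) / 4), 0.15)
})

test_that("insert HU measurement reads generator truth and bias through", {
  lay <- builtin_layouts("ctp404")
  quiet <- algorithm_model("quiet", noise_ref = 0, psf_sigma = 0,
                           noise_correlation_mm = 0)
  st <- simulate_stack(lay, scan_condition("FBP", 24), quiet, 1, seed = 1,
                       matrix_size = 256)
  hu <- measure_hu(st, insert_rois(lay))
  expect_equal(hu$mean[hu$material == "Teflon"], 990)
  expect_equal(hu$mean[hu$material == "air"], -1000)
  expect_true(all(hu$sd == 0))
  mbir <- algorithm_model("mbir", noise_ref = 0, psf_sigma = 0,
                          hu_bias = -10, noise_correlation_mm = 0)
  st2 <- simulate_stack(lay, scan_condition("MBIR", 24), mbir, 1, seed = 1,
                        matrix_size = 256)
  hu2 <- measure_hu(st2, insert_rois(lay, "acrylic"))
  expect_equal(hu2$mean, 110)
  expect_error(measure_hu(st, list(unobtainium = roi_spec(c(0, 0), 0.4))),
               "unobtainium")
})

test_that("per-material SD recovers the generator noise level", {
  lay <- builtin_layouts("ctp404")
  st <- simulate_stack(lay, scan_condition("FBP", 24), white_model(5), 10,
                       seed = 77, matrix_size = 512)
  hu <- measure_hu(st, insert_rois(lay, c("acrylic", "LDPE")))
  expect_true(all(abs(hu$sd - 5) < 0.5))
})

test_that("fold improvement is oriented so >1 is better for both metrics", {
  df <- data.frame(algorithm = c("FBP", "MBIR"), dose = 1,
                   value = c(66.5, 13.3))
  fi <- fold_improvement(df, "noise", "FBP")
  expect_equal(fi$ratio, c(1, 5))
  cf <- data.frame(algorithm = c("FBP", "MBIR"), dose = 1,
                   value = c(0.2, 1.0))
  fc <- fold_improvement(cf, "cnr", "FBP")
  expect_equal(fc$ratio, c(1, 5))
  expect_error(fold_improvement(df[df$algorithm != "FBP", ], "noise",
                                "FBP"), "reference")
})

test_that("HU deltas subtract the FBP high-dose reference per material", {
  # printed sensitometry cells: acrylic MBIR@1 120 vs FBP@24 126 -> -6;
  # LDPE MBIR@3 -86 vs FBP@24 -79 -> -7
  df <- data.frame(
    material = c("acrylic", "acrylic", "LDPE", "LDPE"),
    algorithm = c("FBP", "MBIR", "FBP", "MBIR"),
    dose = c(24, 1, 24, 3),
    mean = c(126, 120, -79, -86))
  d <- hu_difference_from_reference(df, "FBP", 24)
  expect_equal(d$delta_hu[d$algorithm == "MBIR" & d$material == "acrylic"],
               -6)
  expect_equal(d$delta_hu[d$algorithm == "MBIR" & d$material == "LDPE"], -7)
  expect_true(all(d$delta_hu[d$algorithm == "FBP"] == 0))
  expect_error(hu_difference_from_reference(df, "FBP", 12), "material")
})
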