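test_that("esf_to_lsf: step -> impulse, ramp -> constant, erf -> Gaussian", {
  step <- 0.35
  esf <- c(rep(0, 10), rep(1, 10))
  lsf <- esf_to_lsf(esf, step)
  expect_equal(max(lsf), 1 / (2 * step))   # central difference of unit step
  expect_equal(sum(lsf) * step, 1, tolerance = 0.08)
  ramp <- seq(0, 19) * 0.5
  expect_true(all(abs(esf_to_lsf(ramp, step) - 0.5 / step) < 1e-12))
  # erf edge with sigma 0.8 mm -> Gaussian LSF with moment SD 0.8
  # (a fine grid keeps the central-difference variance inflation, h^2/3,
  # below the tolerance)
  x <- seq(0, 14, by = 0.1)
  erf_esf <- pnorm(x, mean = 6.1, sd = 0.8)
  lsf2 <- esf_to_lsf(erf_esf, 0.1)
  mu <- sum(lsf2 * x) / sum(lsf2)
  s <- sqrt(sum(lsf2 * (x - mu)^2) / sum(lsf2))
  expect_lt(abs(s - 0.8), 0.02)
  expect_error(esf_to_lsf(cbind(c(0, 1, 3, 4, 5), 1:5)), "uniform")
  expect_error(esf_to_lsf(c(1, 2, 3), 0.1), "at least 5")
})

test_that("lsf_to_mtf matches closed forms: impulse, Gaussian, rectangle", {
  step <- 0.1
  imp <- c(rep(0, 128), 1, rep(0, 128))
  flat <- lsf_to_mtf(imp, step, tail_correct = FALSE)
  expect_equal(flat$modulation, rep(1, length(flat$modulation)))
  expect_equal(flat$nyquist_lp_cm, 10 / (2 * step))
  # Gaussian LSF, sigma in mm; MTF = exp(-2 pi^2 sigma^2 f^2), f in cyc/mm
  sigma <- 0.8
  x <- seq(-10, 10, by = step)
  g <- lsf_to_mtf(dnorm(x, sd = sigma), step, tail_correct = FALSE)
  f_cyc <- g$frequency / 10
  analytic <- exp(-2 * pi^2 * sigma^2 * f_cyc^2)
  sel <- analytic >= 0.05
  expect_lt(max(abs(g$modulation[sel] / analytic[sel] - 1)), 0.01)
  # rectangular LSF of width w -> |sinc(f w)| before the first null
  m <- 32
  rect <- c(rep(0, 64), rep(1, m), rep(0, 64))
  r <- lsf_to_mtf(rect, step, tail_correct = FALSE)
  w <- m * step
  sel2 <- r$frequency / 10 < 1 / w * 0.95 & r$frequency > 0
  sinc <- abs(sin(pi * r$frequency / 10 * w) / (pi * r$frequency / 10 * w))
  expect_lt(max(abs(r$modulation[sel2] - sinc[sel2])), 0.02)
  expect_error(lsf_to_mtf(rep(0, 32), step), "zero DC")
})

test_that("mtf_at_frequency interpolates linearly within the grid", {
  curve <- ctiq:::new_mtf_curve(frequency = c(0, 4, 6),
                                modulation = c(1, 0.6, 0.4),
                                nyquist = 6, step_mm = 0.5, n_profiles = 1L)
  expect_identical(mtf_at_frequency(curve, 0), 1)
  expect_equal(mtf_at_frequency(curve, 5), 0.5)
  expect_error(mtf_at_frequency(curve, 7), "Nyquist")
})

test_that("aggregation is sum-then-normalize and scale invariant", {
  lay <- disk_layout(target_hu = -1000, background_hu = 100,
                     diameter_mm = 12.2)
  st <- simulate_stack(lay, scan_condition("FBP", 6), white_model(60), 2,
                       seed = 14, matrix_size = 256)
  p1 <- extract_edge_profiles(ctiq:::replicate_image(st, 1), c(0, 0))
  p2 <- extract_edge_profiles(ctiq:::replicate_image(st, 2), c(0, 0))
  # identical profiles and positively scaled profiles leave the curve alone
  same <- aggregate_mtf(list(p1, p1))
  expect_equal(same$modulation, aggregate_mtf(p1)$modulation)
  p3 <- p1
  p3$values <- p1$values * 3
  expect_equal(aggregate_mtf(list(p1, p3))$modulation,
               aggregate_mtf(p1)$modulation, tolerance = 1e-12)
  # sum-then-normalize differs from normalize-then-average on noisy data
  agg <- aggregate_mtf(list(p1, p2))
  spectra <- lapply(list(p1, p2), function(p) {
    rowSums(ctiq:::profile_spectra(p)$magnitudes)
  })
  manual_sum <- Reduce(`+`, spectra)
  expect_equal(agg$modulation, manual_sum / manual_sum[1])
  norm_then_avg <- rowMeans(vapply(spectra, function(s) s / s[1],
                                   numeric(length(manual_sum))))
  expect_gt(max(abs(agg$modulation - norm_then_avg)), 1e-4)
  expect_error(aggregate_mtf(list(p1, extract_edge_profiles(
    ctiq:::replicate_image(st, 1), c(0, 0), length_mm = 10))),
    "mismatched")
})

test_that("edge profiles are geometrically faithful", {
  lay <- disk_layout(target_hu = -1000, background_hu = 100,
                     diameter_mm = 12.2)
  img <- render_layout(lay, 512)
  p <- extract_edge_profiles(img, c(0, 0))
  # interior sample well inside the air target
  expect_equal(p$values[which.min(abs(p$distance - 3)), 1], -1000)
  # 0 vs 180 degrees mirror-identical on a centred symmetric phantom
  expect_equal(p$values[, 1], p$values[, 2], tolerance = 1e-9)
  # blurred edge: LSF peak at the disk radius within one sample step
  m <- algorithm_model("b", noise_ref = 0, psf_sigma = 0.8,
                       noise_correlation_mm = 0)
  st <- simulate_stack(lay, scan_condition("FBP", 6), m, 1, seed = 1)
  pb <- extract_edge_profiles(ctiq:::replicate_image(st, 1), c(0, 0))
  lsf <- esf_to_lsf(pb$values[, 1], pb$step_mm)
  expect_lt(abs(pb$distance[which.max(abs(lsf))] - 6.1), pb$step_mm + 1e-9)
  expect_error(extract_edge_profiles(img, c(170, 0)), "leaves the image")
})

test_that("MTF is invariant to affine HU rescaling", {
  lay <- disk_layout(target_hu = -1000, background_hu = 100,
                     diameter_mm = 12.2)
  st <- simulate_stack(lay, scan_condition("FBP", 6), white_model(10), 3,
                       seed = 6, matrix_size = 256)
  st2 <- st
  st2$images <- 2.5 * st$images + 40
  c1 <- measure_mtf(st, edge_label = "target", correction = "none")
  c2 <- measure_mtf(st2, edge_label = "target", correction = "none")
  expect_equal(c1$modulation, c2$modulation, tolerance = 1e-9)
})

test_that("recovered MTF preserves the ordering of generator PSFs", {
  lay <- builtin_layouts("ctp404")
  mk <- function(s) algorithm_model("m", noise_ref = 0, psf_sigma = s,
                                    noise_correlation_mm = 0)
  cond <- scan_condition("FBP", 6)
  c1 <- measure_mtf(simulate_stack(lay, cond, mk(0.4), 1, seed = 1))
  c2 <- measure_mtf(simulate_stack(lay, cond, mk(0.9), 1, seed = 1))
  sel <- c1$frequency <= c1$nyquist_lp_cm / 2 & c1$frequency > 0 &
    !is.na(c1$modulation) & !is.na(c2$modulation)
  expect_true(all(c1$modulation[sel] >= c2$modulation[sel] - 1e-3))
})

test_that("bar-pattern modulation tracks the square-wave response", {
  # fine grid so raster aperture effects sit below the oracle tolerance
  body <- list(center = c(0, 0), semi_axes = c(35, 35), hu = 100)
  bars <- bar_pattern_feature("bars", c(0, 0), freq_lp_cm = 7, hu = 990,
                              n_periods = 4L, bar_length_mm = 10)
  lay <- phantom_layout("bars", body, features = list(bars), dfov_cm = 8)
  img <- render_layout(lay, 512)
  expect_gt(bar_pattern_modulation(img, bars), 0.95)
  # PSF far wider than the bar period washes the pattern out
  wide <- algorithm_model("wide", noise_ref = 0, psf_sigma = 3,
                          noise_correlation_mm = 0)
  stw <- simulate_stack(lay, scan_condition("FBP", 6), wide, 1, seed = 1,
                        matrix_size = 512)
  expect_lt(bar_pattern_modulation(ctiq:::replicate_image(stw, 1), bars),
            0.05)
  # Gaussian sigma 0.5 mm vs a brute-force 1-D convolution oracle
  m05 <- algorithm_model("m", noise_ref = 0, psf_sigma = 0.5,
                         noise_correlation_mm = 0)
  st <- simulate_stack(lay, scan_condition("FBP", 6), m05, 1, seed = 1,
                       matrix_size = 512)
  meas <- bar_pattern_modulation(ctiq:::replicate_image(st, 1), bars)
  du <- 0.002
  u <- seq(-20, 20, by = du)
  period <- 10 / 7
  w <- 4 * period
  square <- as.numeric(u >= -w / 2 & u < w / 2 &
                         ((u + w / 2) %% period) < period / 2)
  kern <- dnorm(seq(-4 * 0.5, 4 * 0.5, by = du), sd = 0.5)
  kern <- kern / sum(kern)
  smooth <- stats::filter(square, kern, sides = 2)
  at <- function(uu) smooth[round((uu + 20) / du) + 1]
  mm <- seq_len(4) - 1
  oracle <- mean(at(-w / 2 + (mm + 0.25) * period)) -
    mean(at(-w / 2 + (mm + 0.75) * period))
  expect_lt(abs(meas - oracle), 0.05)
  expect_error(bar_pattern_modulation(img, bar_pattern_feature(
    "b2", c(0, 0), 7, 990, n_periods = 2L)), "3 resolvable periods")
})
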