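# shared fixtures: tiny layouts, white-noise models, hand-built stacks

uniform_layout <- function(hu = 100, dfov_cm = 12) {
  phantom_layout("uniform",
                 body = list(center = c(0, 0), semi_axes = c(60, 60),
                             hu = hu),
                 dfov_cm = dfov_cm)
}

disk_layout <- function(target_hu = 110, background_hu = 100,
                        diameter_mm = 15, dfov_cm = 12) {
  phantom_layout("disk",
                 body = list(center = c(0, 0), semi_axes = c(60, 60),
                             hu = background_hu),
                 features = list(disk_feature("target", c(0, 0), diameter_mm,
                                              target_hu)),
                 dfov_cm = dfov_cm)
}

# white-noise model with fixed sigma at every dose (exponent 0 disables the
# dose law) and no blur, for exact-recovery tests
white_model <- function(sigma = 10, psf_sigma = 0) {
  algorithm_model("white", noise_ref = sigma, dose_ref = 1,
                  dose_exponent = 0, noise_factor = 1,
                  psf_sigma = psf_sigma, noise_correlation_mm = 0)
}

# assemble a ct_stack directly from a list of matrices
make_stack <- function(images, spacing_mm, layout = uniform_layout(),
                       condition = scan_condition("FBP", 6)) {
  n <- nrow(images[[1]])
  arr <- array(0, dim = c(n, n, length(images)))
  for (k in seq_along(images)) arr[, , k] <- images[[k]]
  structure(list(images = arr, spacing_mm = spacing_mm,
                 condition = condition, model_name = condition$algorithm,
                 sigma_hu = NA_real_, psf_sigma_mm = 0,
                 noise_correlation_mm = 0, seed = 0L, layout = layout,
                 layout_name = layout$name),
            class = "ct_stack")
}

# fill ROI pixels of an image so the ROI has exactly the given sample mean/sd
fill_roi <- function(img, roi, mean, sd, spacing, seed = 1) {
  idx <- ctiq:::roi_index(roi, nrow(img), spacing)
  set.seed(seed)
  x <- stats::rnorm(length(idx))
  x <- (x - base::mean(x)) / stats::sd(x) * sd + mean
  img[idx] <- x
  img
}
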