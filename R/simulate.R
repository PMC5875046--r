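#' Simulate a replicate stack of CT phantom images
#'
#' Each replicate is the rendered layout with the model's material HU bias
#' applied, convolved with the Gaussian PSF for the condition's dose, plus
#' zero-mean (optionally correlated) Gaussian noise whose marginal standard
#' deviation equals [noise_sigma_model()]. Replicate noise fields are drawn
#' from per-replicate substreams derived deterministically from the master
#' seed, so replicate `k` is reproducible in isolation and a stack of `n`
#' replicates shares its first `k` replicates with a stack of `k`.
#'
#' @param layout a [phantom_layout()].
#' @param condition a [scan_condition()].
#' @param model an [algorithm_model()].
#' @param n_replicates number of replicate images (>= 1; studies of this
#'   kind conventionally use 10 repeat acquisitions).
#' @param seed master integer seed.
#' @param matrix_size image matrix (default 512).
#' @param dfov_cm display field of view in cm (default from layout).
#' @param supersample rasterization supersampling factor.
#' @param .clean optional prerendered output of [render_layout()] for this
#'   layout/size/dfov, to skip re-rasterization in tight loops.
#' @return a `ct_stack`: list with `images` (size x size x n array),
#'   `spacing_mm`, `condition`, `model_name`, `sigma_hu`, `seed`, `layout`.
#' @export
simulate_stack <- function(layout, condition, model, n_replicates = 10L,
                           seed = 1L, matrix_size = 512L, dfov_cm = NULL,
                           supersample = 4L, .clean = NULL) {
  stopifnot(inherits(layout, "phantom_layout"),
            inherits(condition, "scan_condition"),
            inherits(model, "algorithm_model"), n_replicates >= 1)
  if (condition$ctdi_vol <= 0) stop("dose must be positive")
  clean <- .clean %||% render_layout(layout, matrix_size, dfov_cm, supersample)
  spacing <- attr(clean, "spacing_mm")
  n <- nrow(clean)
  dose <- condition$ctdi_vol
  biased <- clean + model$hu_bias(as.vector(clean), dose)
  psf <- psf_sigma_model(model, condition)
  blurred <- if (psf / spacing > 1e-3) {
    gaussian_blur(biased, psf / spacing)
  } else biased
  sigma <- noise_sigma_model(model, condition)
  corr_px <- model$noise_correlation_mm / spacing
  images <- array(0, dim = c(n, n, n_replicates))
  for (k in seq_len(n_replicates)) {
    images[, , k] <- blurred + sigma * noise_field(n, corr_px,
                                                   substream_seed(seed, k))
  }
  structure(list(images = images, spacing_mm = spacing,
                 condition = condition, model_name = model$name,
                 sigma_hu = sigma, psf_sigma_mm = psf,
                 noise_correlation_mm = model$noise_correlation_mm,
                 seed = as.integer(seed), layout = layout,
                 layout_name = layout$name),
            class = "ct_stack")
}

#' @export
print.ct_stack <- function(x, ...) {
  d <- dim(x$images)
  cat("ct_stack: ", d[3], " replicate(s) of ", d[1], "x", d[2],
      " (", format(x$spacing_mm, digits = 4), " mm/px), ",
      x$condition$algorithm, " @ ", x$condition$ctdi_vol, " mGy, sigma ",
      format(x$sigma_hu, digits = 4), " HU\n", sep = "")
  invisible(x)
}

n_replicates <- function(stack) dim(stack$images)[3]

replicate_image <- function(stack, k) {
  img <- stack$images[, , k]
  attr(img, "spacing_mm") <- stack$spacing_mm
  img
}

# deterministic per-replicate substream seed (counter-based Lehmer mixing;
# all intermediates stay below 2^53 so double arithmetic is exact)
substream_seed <- function(master, k) {
  m <- 2147483647
  x <- as.numeric(master) %% m
  x <- (x * 48271) %% m
  x <- (x + as.numeric(k) * 2654435) %% m
  x <- (x * 69621) %% m
  as.integer(x)
}

# unit-variance Gaussian noise field, optionally shaped by an isotropic
# Gaussian of sigma corr_px pixels and renormalized to unit marginal variance
noise_field <- function(n, corr_px, seed) {
  set.seed(seed)
  eps <- matrix(stats::rnorm(n * n), n, n)
  if (corr_px > 1e-3) {
    k <- gauss_kernel(corr_px)
    eps <- separable_convolve(eps, k)
    eps <- eps / sum(k^2)  # separable: var scales by (sum k^2)^2
  }
  eps
}

gauss_kernel <- function(sigma_px) {
  r <- max(1L, ceiling(4 * sigma_px))
  k <- stats::dnorm(seq(-r, r), sd = sigma_px)
  k / sum(k)
}

# separable 2-D convolution with replicate-edge padding; kernel sums to 1 so
# flat regions are preserved exactly
gaussian_blur <- function(img, sigma_px) {
  separable_convolve(img, gauss_kernel(sigma_px))
}

separable_convolve <- function(img, k) {
  r <- (length(k) - 1L) / 2L
  pass <- function(m) {
    n <- nrow(m)
    padded <- m[c(rep(1L, r), seq_len(n), rep(n, r)), , drop = FALSE]
    out <- stats::filter(padded, k, method = "convolution", sides = 2)
    matrix(out[(r + 1):(r + n), ], n, ncol(m))
  }
  t(pass(t(pass(img))))
}
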