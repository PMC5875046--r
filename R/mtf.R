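#' Extract edge-spread profiles from an air-target edge
#'
#' Line profiles start at the target centre and run outward, crossing the
#' insert edge into the surrounding material; by default two run
#' horizontally (0 and 180 degrees) and two diagonally (45 and 225), to
#' avoid directional sampling bias. HU values are sampled by bilinear
#' interpolation at uniform steps (default half the pixel spacing).
#'
#' @param image HU matrix with a `spacing_mm` attribute (e.g. from
#'   [render_layout()] or one replicate of a `ct_stack`).
#' @param center numeric length-2, target centre in mm.
#' @param length_mm profile length from the centre (default 14 mm).
#' @param orientations_deg profile angles in degrees.
#' @param step_mm sample step; must not exceed the pixel spacing.
#' @return an `edge_profile_set`: `distance` (mm), `values`
#'   (samples x profiles matrix), `orientations_deg`, `step_mm`, `center`.
#' @export
extract_edge_profiles <- function(image, center, length_mm = 14,
                                  orientations_deg = c(0, 180, 45, 225),
                                  step_mm = NULL) {
  spacing <- pixel_spacing(image)
  step_mm <- step_mm %||% (spacing / 2)
  if (step_mm > spacing + 1e-12) {
    stop("step_mm must not exceed the pixel spacing (", spacing, " mm)")
  }
  s <- seq(0, length_mm, by = step_mm)
  n <- nrow(image)
  half <- n * spacing / 2
  values <- vapply(orientations_deg, function(a) {
    th <- a * pi / 180
    x <- center[1] + s * cos(th)
    y <- center[2] + s * sin(th)
    xp <- (x + half) / spacing + 0.5
    yp <- (y + half) / spacing + 0.5
    if (any(xp < 1 | xp > n | yp < 1 | yp > n)) {
      stop("profile at ", a, " degrees leaves the image")
    }
    bilinear_sample(image, xp, yp)
  }, numeric(length(s)))
  structure(list(distance = s, values = values,
                 orientations_deg = orientations_deg, step_mm = step_mm,
                 center = center),
            class = "edge_profile_set")
}

bilinear_sample <- function(img, x_px, y_px) {
  n <- nrow(img)
  x0 <- pmin(pmax(floor(x_px), 1L), n - 1L)
  y0 <- pmin(pmax(floor(y_px), 1L), n - 1L)
  fx <- x_px - x0
  fy <- y_px - y0
  v00 <- img[cbind(y0, x0)]
  v10 <- img[cbind(y0, x0 + 1L)]
  v01 <- img[cbind(y0 + 1L, x0)]
  v11 <- img[cbind(y0 + 1L, x0 + 1L)]
  (1 - fy) * ((1 - fx) * v00 + fx * v10) + fy * ((1 - fx) * v01 + fx * v11)
}

#' Differentiate an edge-spread function into a line-spread function
#'
#' Central finite differences on the uniform grid; one-sided differences at
#' the endpoints, so the output length equals the input length.
#'
#' @param esf numeric vector of ESF samples, or a 2-column matrix/data.frame
#'   of (distance, value) pairs with uniform spacing.
#' @param step_mm sample step (required for the vector form).
#' @return numeric LSF samples (HU/mm).
#' @export
esf_to_lsf <- function(esf, step_mm = NULL) {
  if (is.matrix(esf) || is.data.frame(esf)) {
    d <- as.numeric(esf[, 1])
    v <- as.numeric(esf[, 2])
    dd <- diff(d)
    if (max(abs(dd - dd[1])) > 1e-8 * abs(dd[1])) {
      stop("ESF samples are not uniformly spaced")
    }
    step_mm <- dd[1]
    esf <- v
  }
  if (is.null(step_mm)) stop("step_mm is required for vector input")
  n <- length(esf)
  if (n < 5) stop("need at least 5 ESF samples")
  lsf <- numeric(n)
  lsf[1] <- (esf[2] - esf[1]) / step_mm
  lsf[n] <- (esf[n] - esf[n - 1]) / step_mm
  mid <- 2:(n - 1)
  lsf[mid] <- (esf[mid + 1] - esf[mid - 1]) / (2 * step_mm)
  lsf
}

# complex FFT of the (tail-corrected, zero-padded) LSF up to Nyquist.
# The mean of the last 10% of samples is subtracted as a far-field baseline,
# so an edge that has not fully settled within the profile keeps a finite DC.
lsf_spectrum_complex <- function(lsf, step_mm, pad_factor = 4,
                                 tail_correct = TRUE) {
  n <- length(lsf)
  if (tail_correct) {
    tail_n <- max(1L, ceiling(0.1 * n))
    lsf <- lsf - mean(lsf[(n - tail_n + 1L):n])
  }
  nfft <- 2^ceiling(log2(max(pad_factor * n, n, 8)))
  z <- stats::fft(c(lsf, rep(0, nfft - n)))
  keep <- seq_len(nfft %/% 2 + 1L)
  freq_lp_cm <- 10 * (keep - 1L) / (nfft * step_mm)
  list(frequency = freq_lp_cm, spectrum = z[keep],
       nyquist_lp_cm = 10 / (2 * step_mm))
}

lsf_spectrum <- function(lsf, step_mm, pad_factor = 4, tail_correct = TRUE) {
  sp <- lsf_spectrum_complex(lsf, step_mm, pad_factor, tail_correct)
  list(frequency = sp$frequency, magnitude = Mod(sp$spectrum),
       nyquist_lp_cm = sp$nyquist_lp_cm)
}

#' Fourier-transform a line-spread function into an MTF curve
#'
#' The magnitude of the discrete Fourier transform of the zero-padded LSF is
#' normalized to its zero-frequency value; the frequency axis is reported in
#' line pairs per cm, up to the Nyquist frequency `10 / (2 * step_mm)`.
#'
#' @param lsf numeric LSF samples.
#' @param step_mm sample step in mm.
#' @param pad_factor zero-padding factor (>= 1) for frequency-grid density.
#' @param tail_correct subtract the far-field tail mean before transforming.
#' @return an `mtf_curve`: `frequency` (lp/cm), `modulation` (1 at 0),
#'   `nyquist_lp_cm`, `step_mm`, `n_profiles`.
#' @export
lsf_to_mtf <- function(lsf, step_mm, pad_factor = 4, tail_correct = TRUE) {
  stopifnot(all(is.finite(lsf)), step_mm > 0)
  sp <- lsf_spectrum(lsf, step_mm, pad_factor, tail_correct)
  if (sp$magnitude[1] <= 1e-9 * max(sp$magnitude, 1e-300)) {
    stop("zero DC term: the profile carries no edge contrast")
  }
  new_mtf_curve(sp$frequency, sp$magnitude / sp$magnitude[1],
                sp$nyquist_lp_cm, step_mm, n_profiles = 1L)
}

new_mtf_curve <- function(frequency, modulation, nyquist, step_mm,
                          n_profiles, provenance = NULL) {
  structure(list(frequency = frequency, modulation = modulation,
                 nyquist_lp_cm = nyquist, step_mm = step_mm,
                 n_profiles = n_profiles, provenance = provenance),
            class = "mtf_curve")
}

#' @export
print.mtf_curve <- function(x, ...) {
  cat("mtf_curve: ", length(x$frequency), " bins to ",
      format(x$nyquist_lp_cm, digits = 4), " lp/cm, ", x$n_profiles,
      " profile(s) aggregated\n", sep = "")
  invisible(x)
}

profile_spectra <- function(pset, pad_factor = 4, tail_correct = TRUE) {
  stopifnot(inherits(pset, "edge_profile_set"))
  specs <- apply(pset$values, 2, function(v) {
    lsf_spectrum(esf_to_lsf(v, pset$step_mm), pset$step_mm, pad_factor,
                 tail_correct)$magnitude
  })
  sp <- lsf_spectrum(esf_to_lsf(pset$values[, 1], pset$step_mm),
                     pset$step_mm, pad_factor, tail_correct)
  list(frequency = sp$frequency, magnitudes = specs,
       nyquist_lp_cm = sp$nyquist_lp_cm)
}

#' Aggregate edge profiles into a smoothed MTF
#'
#' FFT magnitudes of all contributing profiles (e.g. 4 profiles from each of
#' 10 replicates) are summed first and the summed spectrum is then
#' normalized at zero frequency - the sum-then-normalize ordering, which on
#' noisy data differs from normalizing each curve before averaging.
#'
#' @param profile_sets an `edge_profile_set` or a list of them; all must
#'   share the same sample step and length.
#' @param pad_factor zero-padding factor.
#' @param tail_correct subtract the far-field tail mean per profile.
#' @return an `mtf_curve` with `n_profiles` = total profiles aggregated.
#' @export
aggregate_mtf <- function(profile_sets, pad_factor = 4, tail_correct = TRUE) {
  if (inherits(profile_sets, "edge_profile_set")) {
    profile_sets <- list(profile_sets)
  }
  steps <- vapply(profile_sets, `[[`, 0, "step_mm")
  lens <- vapply(profile_sets, function(p) nrow(p$values), 0L)
  if (max(abs(steps - steps[1])) > 1e-12 || any(lens != lens[1])) {
    stop("profile sets have mismatched sampling grids")
  }
  specs <- lapply(profile_sets, profile_spectra, pad_factor = pad_factor,
                  tail_correct = tail_correct)
  total <- Reduce(`+`, lapply(specs, function(s) rowSums(s$magnitudes)))
  if (total[1] <= 0) stop("zero DC term after aggregation")
  new_mtf_curve(specs[[1]]$frequency, total / total[1],
                specs[[1]]$nyquist_lp_cm, steps[1],
                n_profiles = sum(vapply(profile_sets,
                                        function(p) ncol(p$values), 0L)))
}

#' Interpolate an MTF curve at a frequency
#'
#' Linear interpolation between adjacent frequency bins.
#'
#' @param curve an `mtf_curve`.
#' @param f_lp_cm frequency in lp/cm, within `[0, nyquist]`.
#' @return modulation value(s).
#' @export
mtf_at_frequency <- function(curve, f_lp_cm) {
  stopifnot(inherits(curve, "mtf_curve"))
  if (any(f_lp_cm < 0 | f_lp_cm > curve$nyquist_lp_cm + 1e-9)) {
    stop("frequency beyond the Nyquist limit (", curve$nyquist_lp_cm,
         " lp/cm)")
  }
  stats::approx(curve$frequency, curve$modulation, xout = f_lp_cm,
                rule = 1)$y
}

#' Measure the MTF of a simulated stack by the edge method
#'
#' Extracts the default four 14 mm edge profiles from every replicate, sums
#' all FFT magnitudes and normalizes at zero frequency. With
#' `correction = "sampling"` (the default) the identical profile ->
#' derivative -> |FFT| chain is also run on the noiseless, unblurred render
#' of the same layout, and the measured spectrum is divided by that
#' reference: because every step of the chain is linear and the blur kernel
#' commutes with the interpolation, the ratio cancels the measurement
#' chain's own attenuation (pixel aperture of the area-weighted raster,
#' bilinear interpolation, finite-difference derivative, edge curvature) and
#' isolates the reconstruction PSF transfer. `correction = "none"` returns
#' the uncorrected system curve.
#'
#' @param stack a `ct_stack` whose layout contains the edge target.
#' @param edge_label feature used as the edge target (default `"air"`).
#' @param length_mm,orientations_deg,step_mm,pad_factor see
#'   [extract_edge_profiles()] and [lsf_to_mtf()].
#' @param correction `"sampling"` or `"none"`.
#' @param reference_floor reference-modulation level below which the
#'   corrected curve is set to `NA` (correction no longer well conditioned).
#' @param noise_debias with two or more replicates, estimate the noise power
#'   of each orientation's spectrum from the across-replicate scatter of the
#'   complex FFT (replicates share identical profile geometry, so the signal
#'   part is common) and debias each magnitude as `sqrt(max(m^2 - nu, 0))`
#'   before summing. Summed noisy magnitudes are otherwise biased upward
#'   (Rician folding), which inflates the curve where the modulation is low.
#' @param per_replicate if `TRUE`, return a list of per-replicate curves
#'   (each aggregating that replicate's profiles) instead of one pooled
#'   curve; used for statistical comparison across replicates.
#' @return an `mtf_curve` (or list of them); corrected curves carry the
#'   reference curve as `$reference_modulation`.
#' @export
measure_mtf <- function(stack, edge_label = "air", length_mm = 14,
                        orientations_deg = c(0, 180, 45, 225),
                        step_mm = NULL, pad_factor = 4,
                        correction = c("sampling", "none"),
                        reference_floor = 0.05, noise_debias = TRUE,
                        per_replicate = FALSE) {
  correction <- match.arg(correction)
  stopifnot(inherits(stack, "ct_stack"))
  center <- layout_feature(stack$layout, edge_label)$center
  nrep <- n_replicates(stack)
  psets <- lapply(seq_len(nrep), function(k) {
    extract_edge_profiles(replicate_image(stack, k), center, length_mm,
                          orientations_deg, step_mm)
  })
  step <- psets[[1]]$step_mm
  # complex spectra: [frequency, orientation, replicate]
  sp1 <- lsf_spectrum_complex(esf_to_lsf(psets[[1]]$values[, 1], step),
                              step, pad_factor)
  nf <- length(sp1$frequency)
  nor <- length(orientations_deg)
  z <- array(0i, dim = c(nf, nor, nrep))
  for (k in seq_len(nrep)) {
    for (j in seq_len(nor)) {
      z[, j, k] <- lsf_spectrum_complex(
        esf_to_lsf(psets[[k]]$values[, j], step), step, pad_factor)$spectrum
    }
  }
  mags <- Mod(z)
  pooled_orient <- mags[, , 1, drop = FALSE][, , 1, drop = FALSE]
  dim(pooled_orient) <- c(nf, nor)
  if (nrep >= 2) {
    # replicates image the same deterministic profile geometry, so their
    # spectra share the signal part: average them coherently (noise down by
    # sqrt(R)), estimate the residual noise power from the across-replicate
    # scatter and remove it from the squared magnitude (Rician debias)
    for (j in seq_len(nor)) {
      zc <- z[, j, , drop = TRUE]
      zbar <- rowMeans(zc)
      m2 <- Mod(zbar)^2
      if (noise_debias) {
        nu <- rowSums(Mod(zc - zbar)^2) / (nrep - 1)
        m2 <- pmax(m2 - nu / nrep, 0)
        mags[, j, ] <- sqrt(pmax(mags[, j, ]^2 - nu, 0))
      }
      pooled_orient[, j] <- sqrt(m2)
    }
  }
  # zero-frequency magnitude per orientation, estimated from the ESF
  # plateau contrast (inner vs outer 10% of samples, replicate-averaged):
  # |sum(LSF)| equals edge contrast / step for a settled edge, but the raw
  # DC bin inherits the tail-baseline noise of ~4 samples and multiplies
  # the whole normalized curve; the plateau estimate is the same quantity
  # averaged over many samples
  ns <- nrow(psets[[1]]$values)
  edge_n <- max(1L, ceiling(0.1 * ns))
  dc_orient <- vapply(seq_len(nor), function(j) {
    esf_bar <- rowMeans(vapply(psets, function(p) p$values[, j],
                               numeric(ns)))
    abs(mean(esf_bar[(ns - edge_n + 1L):ns]) -
          mean(esf_bar[seq_len(edge_n)])) / step
  }, 0)
  ref_mod <- NULL
  if (correction == "sampling") {
    n <- dim(stack$images)[1]
    clean <- render_layout(stack$layout, n,
                           dfov_cm = n * stack$spacing_mm / 10)
    ref <- aggregate_mtf(extract_edge_profiles(clean, center, length_mm,
                                               orientations_deg, step_mm),
                         pad_factor)
    ref_mod <- ref$modulation
  }
  finish <- function(total, dc, n_prof) {
    if (dc <= 0 || total[1] <= 0) stop("zero DC term after aggregation")
    mod <- total / dc
    mod[1] <- 1
    curve <- new_mtf_curve(sp1$frequency, mod,
                           sp1$nyquist_lp_cm, step, n_profiles = n_prof,
                           provenance = list(condition = stack$condition,
                                             seed = stack$seed,
                                             correction = correction,
                                             noise_debias = noise_debias))
    if (!is.null(ref_mod)) {
      m <- curve$modulation / ref_mod
      m[ref_mod < reference_floor] <- NA_real_
      m[1] <- 1
      curve$modulation <- m
      curve$reference_modulation <- ref_mod
    }
    curve
  }
  if (per_replicate) {
    lapply(seq_len(nrep), function(k) {
      finish(rowSums(mags[, , k, drop = FALSE]), sum(dc_orient), nor)
    })
  } else {
    finish(rowSums(pooled_orient), sum(dc_orient), nor * nrep)
  }
}

#' Peak-to-trough modulation of a bar pattern
#'
#' Samples the image at the known bar and gap centres of a bar-pattern
#' feature (bilinear interpolation along the sweep axis through the pattern
#' centre) and reports `(mean peak - mean trough) / plateau_contrast`, the
#' square-wave modulation relative to the unresolved plateau contrast.
#'
#' @param image HU matrix with `spacing_mm` attribute.
#' @param pattern a [bar_pattern_feature()] (at least 3 periods).
#' @param plateau_contrast HU contrast of an unresolved bar over background
#'   (defaults to `pattern$hu - background_hu`).
#' @param background_hu background material HU (default 100, the Catphan
#'   sensitometry background).
#' @return modulation in `[0, 1]` up to noise.
#' @export
bar_pattern_modulation <- function(image, pattern, plateau_contrast = NULL,
                                   background_hu = 100) {
  stopifnot(inherits(pattern, "ct_feature"), pattern$shape == "bar_pattern")
  if (pattern$n_periods < 3) {
    stop("bar pattern has fewer than 3 resolvable periods")
  }
  plateau_contrast <- plateau_contrast %||% (pattern$hu - background_hu)
  stopifnot(plateau_contrast != 0)
  spacing <- pixel_spacing(image)
  n <- nrow(image)
  half <- n * spacing / 2
  th <- pattern$angle_deg * pi / 180
  p <- pattern$period_mm
  w <- pattern$n_periods * p
  m <- seq_len(pattern$n_periods) - 1L
  peak_u <- -w / 2 + (m + 0.25) * p
  trough_u <- -w / 2 + (m + 0.75) * p
  sample_u <- function(u) {
    x <- pattern$center[1] + u * cos(th)
    y <- pattern$center[2] + u * sin(th)
    bilinear_sample(image, (x + half) / spacing + 0.5,
                    (y + half) / spacing + 0.5)
  }
  (mean(sample_u(peak_u)) - mean(sample_u(trough_u))) / plateau_contrast
}
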