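#' Circular region of interest
#'
#' ROIs are circles given by centre (mm, relative to the phantom centre) and
#' area in cm^2, matching how phantom analyses are specified. A pixel belongs
#' to the ROI iff its centre lies inside the circle.
#'
#' @param center numeric length-2 centre (x, y) in mm.
#' @param area_cm2 ROI area in cm^2 (> 0); the radius is `sqrt(area/pi)` cm.
#' @param label ROI label.
#' @return an `roi_spec`.
#' @export
roi_spec <- function(center, area_cm2 = 0.4, label = "roi") {
  stopifnot(is.numeric(center), length(center) == 2L, area_cm2 > 0)
  structure(list(center = as.numeric(center), area_cm2 = area_cm2,
                 radius_mm = sqrt(area_cm2 / pi) * 10, label = label),
            class = "roi_spec")
}

# linear indices of pixels whose centres fall inside the ROI
roi_index <- function(roi, matrix_size, spacing) {
  half <- matrix_size * spacing / 2
  if (any(abs(roi$center) + roi$radius_mm > half)) {
    stop("ROI '", roi$label, "' is not fully inside the image")
  }
  cx <- (roi$center[1] + half) / spacing + 0.5
  cy <- (roi$center[2] + half) / spacing + 0.5
  rpx <- roi$radius_mm / spacing
  cols <- max(1L, floor(cx - rpx)):min(matrix_size, ceiling(cx + rpx))
  rows <- max(1L, floor(cy - rpx)):min(matrix_size, ceiling(cy + rpx))
  dx <- (cols - cx)
  dy <- (rows - cy)
  inside <- outer(dy^2, dx^2, `+`) <= rpx^2
  idx <- which(inside)
  rr <- rows[((idx - 1L) %% length(rows)) + 1L]
  cc <- cols[((idx - 1L) %/% length(rows)) + 1L]
  (cc - 1L) * matrix_size + rr
}

#' Default noise and CNR region placements
#'
#' Three equal ROIs at 120 degree spacing, mirroring the conventional
#' placement of background regions around a phantom centre or target.
#'
#' @param area_cm2 ROI area (cm^2).
#' @param radius_mm placement radius from `center` (mm).
#' @param center placement centre (mm).
#' @param start_deg angle of the first ROI (degrees).
#' @return list of three [roi_spec()]s.
#' @export
background_rois <- function(area_cm2 = 0.4, radius_mm = 30,
                            center = c(0, 0), start_deg = 30) {
  ang <- (start_deg + c(0, 120, 240)) * pi / 180
  lapply(seq_along(ang), function(i) {
    roi_spec(center + radius_mm * c(cos(ang[i]), sin(ang[i])), area_cm2,
             label = paste0("bg", i))
  })
}

#' Measure image noise from ROI standard deviations
#'
#' Per replicate, the sample standard deviation (n-1 denominator) is taken
#' within each ROI and averaged across ROIs; the summary is the mean across
#' replicates. This is the conventional "mean of ROI SDs" phantom noise
#' statistic.
#'
#' @param stack a `ct_stack`.
#' @param rois list of [roi_spec()]s (>= 1), all fully inside the image and
#'   each containing at least 10 pixels.
#' @return a `noise_measurement`: list with `condition`, `per_replicate`,
#'   `summary`, `n_rois`.
#' @export
measure_noise <- function(stack, rois) {
  stopifnot(inherits(stack, "ct_stack"), length(rois) >= 1)
  if (inherits(rois, "roi_spec")) rois <- list(rois)
  n <- dim(stack$images)[1]
  idx <- lapply(rois, roi_index, matrix_size = n, spacing = stack$spacing_mm)
  npx <- lengths(idx)
  if (any(npx < 10)) {
    stop("ROI '", rois[[which(npx < 10)[1]]]$label,
         "' contains fewer than 10 pixels; SD would be unstable")
  }
  per_rep <- vapply(seq_len(n_replicates(stack)), function(k) {
    img <- stack$images[, , k]
    mean(vapply(idx, function(i) stats::sd(img[i]), 0))
  }, 0)
  structure(list(condition = stack$condition, per_replicate = per_rep,
                 summary = mean(per_rep), n_rois = length(rois)),
            class = "noise_measurement")
}

#' @export
print.noise_measurement <- function(x, ...) {
  cat("noise: ", format(x$summary, digits = 4), " HU (mean of ", x$n_rois,
      " ROI SDs over ", length(x$per_replicate), " replicates)\n", sep = "")
  invisible(x)
}

#' Measure contrast-to-noise ratio
#'
#' CNR = |object HU - background HU| / background SD, per replicate, then
#' averaged. The object HU is the target-ROI mean; background HU and SD are
#' taken over the pooled pixels of the background ROIs by default (set
#' `pooled_sd = FALSE` to average per-ROI SDs instead). Target and
#' background ROIs must have identical specified areas.
#'
#' @param stack a `ct_stack`.
#' @param target_roi [roi_spec()] on the contrast target.
#' @param bg_rois list of background [roi_spec()]s of the same area.
#' @param pooled_sd use pooled background pixels for the SD (default) or the
#'   mean of per-ROI SDs.
#' @return a `cnr_measurement` with per-replicate and summary values.
#' @export
measure_cnr <- function(stack, target_roi, bg_rois, pooled_sd = TRUE) {
  stopifnot(inherits(stack, "ct_stack"), inherits(target_roi, "roi_spec"))
  if (inherits(bg_rois, "roi_spec")) bg_rois <- list(bg_rois)
  areas <- vapply(bg_rois, `[[`, 0, "area_cm2")
  if (any(abs(areas - target_roi$area_cm2) > 1e-9)) {
    stop("target and background ROI areas must be identical")
  }
  n <- dim(stack$images)[1]
  t_idx <- roi_index(target_roi, n, stack$spacing_mm)
  b_idx <- lapply(bg_rois, roi_index, matrix_size = n,
                  spacing = stack$spacing_mm)
  pooled <- unlist(b_idx)
  reps <- seq_len(n_replicates(stack))
  obj <- bg <- bsd <- cnr <- numeric(length(reps))
  for (k in reps) {
    img <- stack$images[, , k]
    obj[k] <- mean(img[t_idx])
    bg[k] <- mean(img[pooled])
    bsd[k] <- if (pooled_sd) stats::sd(img[pooled]) else {
      mean(vapply(b_idx, function(i) stats::sd(img[i]), 0))
    }
    if (bsd[k] == 0) {
      stop("background SD is zero (noiseless input); CNR is undefined")
    }
    cnr[k] <- abs(obj[k] - bg[k]) / bsd[k]
  }
  structure(list(condition = stack$condition, object_hu = obj,
                 background_hu = bg, background_sd = bsd,
                 per_replicate = cnr, summary = mean(cnr)),
            class = "cnr_measurement")
}

#' @export
print.cnr_measurement <- function(x, ...) {
  cat("CNR: ", format(x$summary, digits = 4), " over ",
      length(x$per_replicate), " replicates\n", sep = "")
  invisible(x)
}

#' Interior ROIs for layout insert features
#'
#' Builds one circular ROI per disk feature, concentric with the insert and
#' strictly interior to it (default radius 70% of the insert radius), for
#' HU-accuracy measurement.
#'
#' @param layout a [phantom_layout()].
#' @param labels feature labels (default: all disk features).
#' @param frac ROI radius as a fraction of the insert radius.
#' @return named list of [roi_spec()]s.
#' @export
insert_rois <- function(layout, labels = NULL, frac = 0.7) {
  stopifnot(frac > 0, frac < 1)
  feats <- Filter(function(f) f$shape == "disk", layout$features)
  if (!is.null(labels)) {
    feats <- lapply(labels, function(l) layout_feature(layout, l))
  }
  rois <- lapply(feats, function(f) {
    r_mm <- frac * f$radius_mm
    roi_spec(f$center, area_cm2 = pi * (r_mm / 10)^2, label = f$label)
  })
  stats::setNames(rois, vapply(feats, `[[`, "", "label"))
}

#' Measure insert Hounsfield units
#'
#' Mean and sample SD of the pixels in each insert ROI, pooled across
#' replicates, one row per material.
#'
#' @param stack a `ct_stack`.
#' @param rois named list of [roi_spec()]s keyed by material label; each
#'   label must match a feature of the stack's layout.
#' @return data.frame with columns `material`, `mean`, `sd`, `n_pixels`.
#' @export
measure_hu <- function(stack, rois) {
  stopifnot(inherits(stack, "ct_stack"), length(rois) >= 1)
  labs <- names(rois) %||% vapply(rois, `[[`, "", "label")
  for (l in labs) layout_feature(stack$layout, l)  # errors on unknown label
  n <- dim(stack$images)[1]
  rows <- lapply(seq_along(rois), function(i) {
    idx <- roi_index(rois[[i]], n, stack$spacing_mm)
    vals <- as.vector(apply(stack$images, 3, `[`, idx))
    data.frame(material = labs[i], mean = mean(vals), sd = stats::sd(vals),
               n_pixels = length(vals))
  })
  out <- do.call(rbind, rows)
  out$algorithm <- stack$condition$algorithm
  out$dose <- stack$condition$ctdi_vol
  out$pitch <- stack$condition$pitch
  out
}

#' Fold improvement relative to a reference algorithm
#'
#' Ratios are oriented so that values above 1 always mean "better than the
#' reference": noise ratios are reference/value, CNR (and other
#' higher-is-better metrics) are value/reference.
#'
#' @param summaries data.frame with columns `algorithm`, `dose`, `pitch`
#'   (optional) and `value`.
#' @param metric `"noise"` (inverted orientation) or `"cnr"`.
#' @param reference_algorithm reference label (default `"FBP"`).
#' @return input rows (reference rows included, ratio 1) with columns
#'   `ratio` and `orientation`.
#' @export
fold_improvement <- function(summaries, metric = c("noise", "cnr"),
                             reference_algorithm = "FBP") {
  metric <- match.arg(metric)
  stopifnot(all(c("algorithm", "dose", "value") %in% names(summaries)))
  if (!"pitch" %in% names(summaries)) summaries$pitch <- NA_real_
  key <- paste(summaries$dose, summaries$pitch)
  ref_rows <- summaries$algorithm == reference_algorithm
  out <- summaries
  out$ratio <- NA_real_
  for (cell in unique(key)) {
    in_cell <- key == cell
    ref <- summaries$value[in_cell & ref_rows]
    if (length(ref) != 1L || is.na(ref) || ref == 0) {
      stop("missing or degenerate reference (", reference_algorithm,
           ") value in cell dose/pitch = ", cell)
    }
    v <- summaries$value[in_cell]
    out$ratio[in_cell] <- if (metric == "noise") ref / v else v / ref
  }
  out$orientation <- if (metric == "noise") "reference/value" else
    "value/reference"
  out
}

#' HU difference from a reference condition
#'
#' Per-material deltas `mean(condition) - mean(reference)`, conventionally
#' against FBP at the highest dose.
#'
#' @param measurements data.frame as returned by (rbound) [measure_hu()]
#'   rows: columns `material`, `algorithm`, `dose`, `mean`.
#' @param reference_algorithm,reference_dose the reference cell.
#' @return the non-reference rows with a `delta_hu` column.
#' @export
hu_difference_from_reference <- function(measurements,
                                         reference_algorithm = "FBP",
                                         reference_dose = 24) {
  stopifnot(all(c("material", "algorithm", "dose", "mean") %in%
                  names(measurements)))
  ref <- measurements[measurements$algorithm == reference_algorithm &
                        measurements$dose == reference_dose, ]
  missing <- setdiff(unique(measurements$material), ref$material)
  if (length(missing)) {
    stop("reference condition lacks material(s): ",
         paste(missing, collapse = ", "))
  }
  ref_mean <- stats::setNames(ref$mean, ref$material)
  out <- measurements
  out$delta_hu <- out$mean - ref_mean[out$material]
  out
}
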