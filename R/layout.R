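#' Phantom feature primitives
#'
#' Features are geometric primitives with a nominal Hounsfield unit (HU),
#' placed inside a phantom body. Coordinates are millimetres relative to the
#' phantom centre; the y axis points down the image rows.
#'
#' @param label unique feature label.
#' @param center numeric length-2, centre (x, y) in mm.
#' @param diameter_mm disk diameter in mm.
#' @param hu nominal HU of the feature material, finite and in [-1000, 3000].
#' @return a `ct_feature` list.
#' @export
disk_feature <- function(label, center, diameter_mm, hu) {
  new_feature("disk", label, center, hu,
              diameter_mm = diameter_mm, radius_mm = diameter_mm / 2)
}

#' @rdname disk_feature
#' @param outer_mm,inner_mm outer and inner diameters of the annulus (mm).
#' @export
annulus_feature <- function(label, center, outer_mm, inner_mm, hu) {
  stopifnot(outer_mm > inner_mm, inner_mm >= 0)
  new_feature("annulus", label, center, hu,
              outer_mm = outer_mm, inner_mm = inner_mm,
              radius_mm = outer_mm / 2)
}

#' @rdname disk_feature
#' @param freq_lp_cm bar frequency in line pairs per cm; the bar period is
#'   `10 / freq_lp_cm` mm and each bar is half a period wide.
#' @param n_periods number of line-pair periods (bars) rendered.
#' @param bar_length_mm length of the bars perpendicular to the sweep (mm).
#' @param angle_deg rotation of the bar sweep axis (degrees; 0 sweeps along x).
#' @export
bar_pattern_feature <- function(label, center, freq_lp_cm, hu,
                                n_periods = 4L, bar_length_mm = 10,
                                angle_deg = 0) {
  stopifnot(freq_lp_cm > 0, n_periods >= 1, bar_length_mm > 0)
  period <- 10 / freq_lp_cm
  width <- n_periods * period
  new_feature("bar_pattern", label, center, hu,
              freq_lp_cm = freq_lp_cm, period_mm = period,
              n_periods = as.integer(n_periods),
              bar_length_mm = bar_length_mm, angle_deg = angle_deg,
              radius_mm = sqrt(width^2 + bar_length_mm^2) / 2)
}

new_feature <- function(shape, label, center, hu, ...) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label),
            is.numeric(center), length(center) == 2L, all(is.finite(center)))
  if (!is.finite(hu) || hu < -1000 || hu > 3000) {
    stop("feature '", label, "': nominal HU must be finite and in [-1000, 3000]")
  }
  structure(list(shape = shape, label = label, center = as.numeric(center),
                 hu = hu, ...),
            class = "ct_feature")
}

#' Define a phantom slice layout
#'
#' A layout is the geometric scene of HU-labelled primitives defining one
#' phantom slice: an elliptical body, an optional surrounding annular ring
#' (e.g. a fat-equivalent oval), and a list of features painted on top.
#'
#' @param name layout name.
#' @param body list with `center` (mm), `semi_axes` (mm, length 2) and `hu`.
#' @param ring optional list with `center`, `outer_semi_axes`,
#'   `inner_semi_axes` (mm) and `hu`; rendered between the two ellipses.
#' @param features list of [disk_feature()]-style primitives.
#' @param dfov_cm default display field of view used when rendering (cm).
#' @param background_hu HU outside the body (air, -1000).
#' @return a validated `phantom_layout` object.
#' @export
phantom_layout <- function(name, body, ring = NULL, features = list(),
                           dfov_cm = 36, background_hu = -1000) {
  layout <- structure(
    list(name = name, body = body, ring = ring, features = features,
         dfov_cm = dfov_cm, background_hu = background_hu),
    class = "phantom_layout")
  validate_layout(layout)
}

validate_layout <- function(layout) {
  b <- layout$body
  stopifnot(is.list(b), length(b$semi_axes) == 2L, all(b$semi_axes > 0),
            is.finite(b$hu))
  labels <- vapply(layout$features, `[[`, "", "label")
  if (anyDuplicated(labels)) {
    stop("feature labels must be unique; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  for (f in layout$features) {
    if (!is.finite(f$hu) || f$hu < -1000 || f$hu > 3000) {
      stop("feature '", f$label, "': nominal HU out of range")
    }
    if (!feature_inside_ellipse(f, b)) {
      stop("feature '", f$label, "' lies outside the phantom body")
    }
  }
  layout
}

# boundary-sampled containment check of a feature in the body ellipse
feature_inside_ellipse <- function(f, body) {
  ang <- seq(0, 2 * pi, length.out = 33L)[-33L]
  px <- f$center[1] + f$radius_mm * cos(ang) - body$center[1]
  py <- f$center[2] + f$radius_mm * sin(ang) - body$center[2]
  all((px / body$semi_axes[1])^2 + (py / body$semi_axes[2])^2 <= 1 + 1e-9)
}

#' @export
print.phantom_layout <- function(x, ...) {
  cat("phantom_layout '", x$name, "': body ", paste(x$body$semi_axes,
      collapse = "x"), " mm @ ", x$body$hu, " HU, ",
      length(x$features), " feature(s)\n", sep = "")
  invisible(x)
}

#' Built-in phantom layouts
#'
#' Simplified scenes of the Catphan 600 modules (wrapped in a fat-equivalent
#' oval ring) and of an abdomen phantom:
#' * `ctp404` - sensitometry module: eight 12.2 mm cylindrical inserts
#'   (air -1000, PMP -200, LDPE -100, water 0, polystyrene -35, acrylic 120,
#'   Delrin 340, Teflon 990 HU) on a 58 mm circle in a +100 HU background.
#' * `ctp515` - low-contrast module: a 15 mm supraslice target whose contrast
#'   defaults to +10 HU over the +100 HU background (the conventional reading
#'   of a "1%" target; configurable).
#' * `ctp528` - high-contrast module: bar patterns at 3, 5 and 7 lp/cm.
#' * `abdomen` - soft-tissue ellipse with spleen, liver, pancreas and kidney
#'   disks, rendered at a 30 cm field of view.
#'
#' @param name one of `"ctp404"`, `"ctp515"`, `"ctp528"`, `"abdomen"`.
#' @param contrast_hu supraslice target contrast over background (HU,
#'   `ctp515` only).
#' @return a [phantom_layout()].
#' @export
builtin_layouts <- function(name = c("ctp404", "ctp515", "ctp528", "abdomen"),
                            contrast_hu = 10) {
  name <- match.arg(name)
  catphan_body <- list(center = c(0, 0), semi_axes = c(150, 115), hu = 100)
  fat_ring <- list(center = c(0, 0), outer_semi_axes = c(150, 115),
                   inner_semi_axes = c(100, 100), hu = -90)
  switch(name,
    ctp404 = {
      mats <- c(air = -1000, PMP = -200, LDPE = -100, water = 0,
                polystyrene = -35, acrylic = 120, Delrin = 340, Teflon = 990)
      ang <- (seq_along(mats) - 1L) * 45 * pi / 180
      feats <- mapply(function(lab, hu, a) {
        disk_feature(lab, 58 * c(cos(a), sin(a)), diameter_mm = 12.2, hu = hu)
      }, names(mats), mats, ang, SIMPLIFY = FALSE)
      phantom_layout("ctp404", catphan_body, fat_ring, unname(feats),
                     dfov_cm = 36)
    },
    ctp515 = {
      target <- disk_feature("supraslice15", c(0, -25), diameter_mm = 15,
                             hu = 100 + contrast_hu)
      phantom_layout("ctp515", catphan_body, fat_ring, list(target),
                     dfov_cm = 36)
    },
    ctp528 = {
      freqs <- c(3, 5, 7)
      ang <- c(90, 210, 330) * pi / 180
      feats <- mapply(function(f, a) {
        bar_pattern_feature(paste0("bars_", f, "lpcm"),
                            45 * c(cos(a), sin(a)), freq_lp_cm = f, hu = 990,
                            n_periods = 4L, bar_length_mm = 10)
      }, freqs, ang, SIMPLIFY = FALSE)
      phantom_layout("ctp528", catphan_body, fat_ring, unname(feats),
                     dfov_cm = 36)
    },
    abdomen = {
      body <- list(center = c(0, 0), semi_axes = c(140, 95), hu = 40)
      feats <- list(
        disk_feature("liver", c(-55, 0), 50, 60),
        disk_feature("spleen", c(65, 10), 25, 55),
        disk_feature("pancreas", c(0, -10), 20, 45),
        disk_feature("kidney", c(35, 45), 25, 35))
      phantom_layout("abdomen", body, ring = NULL, features = feats,
                     dfov_cm = 30)
    })
}

#' Read and write layouts as YAML or JSON
#'
#' Layout files carry the same fields as [phantom_layout()]; the format is
#' chosen from the file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param layout a `phantom_layout`.
#' @param path file path.
#' @return `read_layout()` returns a validated `phantom_layout`;
#'   `write_layout()` returns `path` invisibly.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "phantom_layout"))
  x <- unclass(layout)
  x$features <- lapply(x$features, unclass)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  feats <- lapply(x$features, function(f) {
    f$center <- as.numeric(unlist(f$center))
    switch(f$shape,
      disk = disk_feature(f$label, f$center, f$diameter_mm, f$hu),
      annulus = annulus_feature(f$label, f$center, f$outer_mm, f$inner_mm,
                                f$hu),
      bar_pattern = bar_pattern_feature(f$label, f$center, f$freq_lp_cm,
                                        f$hu, f$n_periods, f$bar_length_mm,
                                        f$angle_deg),
      stop("unknown feature shape: ", f$shape))
  })
  norm_ellipse <- function(e) {
    if (is.null(e)) return(NULL)
    lapply(e, function(v) if (is.list(v)) as.numeric(unlist(v)) else v)
  }
  phantom_layout(x$name, norm_ellipse(x$body), norm_ellipse(x$ring), feats,
                 dfov_cm = x$dfov_cm %||% 36,
                 background_hu = x$background_hu %||% -1000)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

layout_feature <- function(layout, label) {
  for (f in layout$features) if (f$label == label) return(f)
  stop("layout '", layout$name, "' has no feature labelled '", label, "'")
}
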