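#' Rasterize a phantom layout to a noiseless HU image
#'
#' Pixels are squares of side `dfov_cm * 10 / matrix_size` mm; pixel centres
#' sit at `(i - 0.5) * spacing` from the top-left corner and the phantom
#' centre coincides with the image centre. Primitives are painted in order
#' (background, body, ring, features) with area-weighted coverage at the
#' edges: an edge pixel takes `cov * hu + (1 - cov) * underlying`, where
#' `cov` is the fraction of the pixel inside the primitive estimated on a
#' `supersample x supersample` subgrid.
#'
#' @param layout a [phantom_layout()].
#' @param matrix_size image matrix size in pixels (>= 64; default 512).
#' @param dfov_cm display field of view in cm (default from the layout).
#' @param supersample subpixel sampling factor for coverage estimation.
#' @return numeric `matrix_size x matrix_size` matrix of HU with attribute
#'   `spacing_mm`.
#' @export
render_layout <- function(layout, matrix_size = 512L, dfov_cm = NULL,
                          supersample = 4L) {
  stopifnot(inherits(layout, "phantom_layout"), matrix_size >= 64)
  dfov_cm <- dfov_cm %||% layout$dfov_cm
  stopifnot(dfov_cm > 0)
  spacing <- dfov_cm * 10 / matrix_size
  half <- matrix_size * spacing / 2
  for (f in layout$features) {
    ext <- abs(f$center) + f$radius_mm
    if (any(ext > half)) {
      stop("feature '", f$label, "' extends outside the ", dfov_cm,
           " cm image grid")
    }
  }
  img <- matrix(layout$background_hu, matrix_size, matrix_size)
  b <- layout$body
  img <- paint(img, spacing, inside_ellipse(b$center, b$semi_axes), b$hu,
               bbox_ellipse(b$center, b$semi_axes), supersample)
  if (!is.null(layout$ring)) {
    r <- layout$ring
    inside <- function(x, y) {
      o <- inside_ellipse(r$center, r$outer_semi_axes)(x, y)
      i <- inside_ellipse(r$center, r$inner_semi_axes)(x, y)
      o & !i
    }
    img <- paint(img, spacing, inside, r$hu,
                 bbox_ellipse(r$center, r$outer_semi_axes), supersample)
  }
  for (f in layout$features) {
    img <- paint(img, spacing, feature_inside_fun(f), f$hu,
                 feature_bbox(f), supersample)
  }
  attr(img, "spacing_mm") <- spacing
  img
}

feature_bbox <- function(f) {
  c(f$center[1] - f$radius_mm, f$center[1] + f$radius_mm,
    f$center[2] - f$radius_mm, f$center[2] + f$radius_mm)
}

bbox_ellipse <- function(center, semi) {
  c(center[1] - semi[1], center[1] + semi[1],
    center[2] - semi[2], center[2] + semi[2])
}

inside_ellipse <- function(center, semi) {
  force(center); force(semi)
  function(x, y) {
    ((x - center[1]) / semi[1])^2 + ((y - center[2]) / semi[2])^2 <= 1
  }
}

feature_inside_fun <- function(f) {
  switch(f$shape,
    disk = {
      r2 <- f$radius_mm^2
      function(x, y) (x - f$center[1])^2 + (y - f$center[2])^2 <= r2
    },
    annulus = {
      ro2 <- (f$outer_mm / 2)^2
      ri2 <- (f$inner_mm / 2)^2
      function(x, y) {
        d2 <- (x - f$center[1])^2 + (y - f$center[2])^2
        d2 <= ro2 & d2 > ri2
      }
    },
    bar_pattern = {
      th <- f$angle_deg * pi / 180
      w <- f$n_periods * f$period_mm
      function(x, y) {
        u <- cos(th) * (x - f$center[1]) + sin(th) * (y - f$center[2])
        v <- -sin(th) * (x - f$center[1]) + cos(th) * (y - f$center[2])
        inx <- u >= -w / 2 & u < w / 2 & abs(v) <= f$bar_length_mm / 2
        inx & ((u + w / 2) %% f$period_mm) < f$period_mm / 2
      }
    },
    stop("unknown feature shape: ", f$shape))
}

# paint one primitive with supersampled coverage restricted to its bbox
paint <- function(img, spacing, inside, hu, bbox, supersample) {
  n <- nrow(img)
  half <- n * spacing / 2
  # pixel index range touched by the bbox (1-based, clamped)
  cols <- max(1L, floor((bbox[1] + half) / spacing) ):
          min(n, ceiling((bbox[2] + half) / spacing + 1))
  rows <- max(1L, floor((bbox[3] + half) / spacing) ):
          min(n, ceiling((bbox[4] + half) / spacing + 1))
  cols <- cols[cols >= 1 & cols <= n]
  rows <- rows[rows >= 1 & rows <= n]
  if (!length(cols) || !length(rows)) return(img)
  s <- as.integer(supersample)
  off <- (seq_len(s) - 0.5) / s            # subpixel offsets in [0, 1]
  # subsample coordinates along each axis, in mm relative to phantom centre
  sub_x <- rep((cols - 1) * spacing - half, each = s) +
    rep(off * spacing, times = length(cols))
  sub_y <- rep((rows - 1) * spacing - half, each = s) +
    rep(off * spacing, times = length(rows))
  m <- inside(matrix(sub_x, nrow = length(sub_y) * 1L, ncol = length(sub_x),
                     byrow = TRUE),
              matrix(sub_y, nrow = length(sub_y), ncol = length(sub_x)))
  # average s x s blocks -> coverage per pixel
  cov <- block_mean(m * 1, s)
  idx_r <- rep(rows, times = length(cols))
  idx_c <- rep(cols, each = length(rows))
  cv <- as.vector(cov)
  keep <- cv > 0
  if (any(keep)) {
    ij <- cbind(idx_r[keep], idx_c[keep])
    img[ij] <- img[ij] * (1 - cv[keep]) + hu * cv[keep]
  }
  img
}

# mean over s x s blocks of a matrix whose dims are multiples of s
block_mean <- function(m, s) {
  nr <- nrow(m) / s
  nc <- ncol(m) / s
  dim(m) <- c(s, nr, s, nc)
  colMeans(colMeans(aperm(m, c(1, 3, 2, 4))))
}

#' Pixel spacing of a rendered image or stack
#' @param x a rendered image matrix or a `ct_stack`.
#' @return spacing in mm/pixel.
#' @export
pixel_spacing <- function(x) {
  if (inherits(x, "ct_stack")) return(x$spacing_mm)
  sp <- attr(x, "spacing_mm")
  if (is.null(sp)) stop("object carries no spacing_mm attribute")
  sp
}
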