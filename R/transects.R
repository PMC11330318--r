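#' Radial transect geometry
#'
#' A transect is a straight strip of pixels sampled from the focus centre
#' outward at a fixed angle. Angles are measured in degrees,
#' counter-clockwise from the image +x axis, so 90 degrees points towards the
#' top of the image (y decreasing). The strip has `length` columns spaced
#' 1 px along the ray (column 0 at the origin) and `width` rows spaced 1 px
#' across the ray, centred on the ray.
#'
#' @param origin Numeric `(x, y)`: the pivot, normally the focus-box centre.
#' @param angle Angle in degrees.
#' @param width Strip width in integer pixels, at least 1.
#' @param length Number of along-ray sample columns, at least 1.
#' @return An object of class `transect_spec`.
#' @export
transect_spec <- function(origin, angle, width, length) {
  stopifnot(length(origin) == 2, width >= 1, length >= 1)
  structure(
    list(origin = as.numeric(origin), angle = as.numeric(angle),
         width = as.integer(width), length = as.integer(length)),
    class = "transect_spec"
  )
}

#' @export
print.transect_spec <- function(x, ...) {
  cat(sprintf("<transect_spec> origin (%.1f, %.1f), angle %g deg, %d x %d px\n",
              x$origin[1], x$origin[2], x$angle, x$width, x$length))
  invisible(x)
}

## Unit along-ray direction for an angle in degrees (y grows downwards).
ray_direction <- function(angle) {
  th <- angle * pi / 180
  c(cos(th), -sin(th))
}

## Unit across-ray normal: the ray direction rotated +90 degrees.
ray_normal <- function(angle) ray_direction(angle + 90)

#' Transect width from a focus bounding box
#'
#' The strip width is half the smallest focus-box edge, floored to an integer
#' (minimum 1 px). All transects of one scale therefore share the same width,
#' whatever their angle.
#'
#' @param focus_box A one-row box table.
#' @return Integer width in pixels.
#' @examples
#' transect_width(bbox(0, 0, 80, 120)) # 40
#' @export
transect_width <- function(focus_box) {
  validate_bbox(focus_box)
  stopifnot(nrow(focus_box) == 1)
  w <- focus_box$x_max - focus_box$x_min
  h <- focus_box$y_max - focus_box$y_min
  max(1L, as.integer(floor(min(w, h) / 2)))
}

#' Transect length from the origin to the image edge
#'
#' Returns the largest number of 1 px along-ray sample columns that fit
#' strictly inside the image: the column positions `origin + c * u`,
#' `c = 0 .. length - 1`, all satisfy `0 < x < image_width` and
#' `0 < y < image_height` (column 0 sits at the origin). This is the pixel
#' run from the scale centre to its edge at the given angle.
#'
#' @param origin Numeric `(x, y)` inside the image.
#' @param angle Angle in degrees.
#' @param image_width,image_height Image dimensions in pixels.
#' @return Integer number of columns.
#' @examples
#' transect_length(c(50, 50), 0, 200, 200) # 150
#' transect_length(c(50, 50), 90, 200, 200) # 50
#' @export
transect_length <- function(origin, angle, image_width, image_height) {
  stopifnot(length(origin) == 2)
  if (origin[1] <= 0 || origin[1] >= image_width ||
      origin[2] <= 0 || origin[2] >= image_height) {
    stop("transect origin must lie strictly inside the image")
  }
  u <- ray_direction(angle)
  # for each axis, the largest column index c with 0 < p + c*d < bound
  axis_max <- function(p, d, bound) {
    if (abs(d) < 1e-12) return(Inf)
    t_exit <- if (d > 0) (bound - p) / d else p / (-d)
    # columns are integers strictly below the exit parameter
    ceiling(t_exit) - 1
  }
  c_max <- min(axis_max(origin[1], u[1], image_width),
               axis_max(origin[2], u[2], image_height))
  as.integer(c_max + 1)
}

## Continuous sample coordinates of a strip: returns list(x, y) matrices of
## dimension width x length. Row r (1-based) offsets the ray by
## (r - 1 - (width - 1)/2) times the +90-degree normal.
transect_sample_coords <- function(spec) {
  u <- ray_direction(spec$angle)
  nrm <- ray_normal(spec$angle)
  cols <- seq_len(spec$length) - 1
  rows <- (seq_len(spec$width) - 1) - (spec$width - 1) / 2
  x <- outer(rows * nrm[1], cols * u[1], `+`) + spec$origin[1]
  y <- outer(rows * nrm[2], cols * u[2], `+`) + spec$origin[2]
  list(x = x, y = y)
}

## Bilinear interpolation of image (matrix rows = y, cols = x, 0-based pixel
## centres) at continuous coordinates; coordinates are clamped to the pixel
## grid so exact-boundary samples are valid.
bilinear_sample <- function(image, x, y) {
  h <- nrow(image)
  w <- ncol(image)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- pmin(floor(x), w - 2)
  y0 <- pmin(floor(y), h - 2)
  fx <- as.vector(x - x0)
  fy <- as.vector(y - y0)
  r0 <- as.vector(y0) + 1
  c0 <- as.vector(x0) + 1
  v <- (1 - fx) * (1 - fy) * image[cbind(r0, c0)] +
    fx * (1 - fy) * image[cbind(r0, c0 + 1)] +
    (1 - fx) * fy * image[cbind(r0 + 1, c0)] +
    fx * fy * image[cbind(r0 + 1, c0 + 1)]
  matrix(v, nrow = nrow(x))
}

#' Extract a radial transect strip from an image
#'
#' Samples the full-resolution image by bilinear interpolation on the strip
#' geometry of `spec`: the sample point of (row r, column c), both 0-based,
#' is `origin + c * u + (r - (width - 1)/2) * n`, with `u` the unit along-ray
#' direction and `n` the unit normal (`u` rotated +90 degrees). Errors if any
#' sample point falls outside the image.
#'
#' @param image Numeric matrix (rows = y, columns = x), intensities
#'   typically in `[0, 1]`.
#' @param spec A [transect_spec()].
#' @return An object of class `transect_image`: list with `strip` (matrix
#'   `width` x `length`) and `spec`.
#' @export
extract_transect <- function(image, spec) {
  stopifnot(is.matrix(image), inherits(spec, "transect_spec"))
  coords <- transect_sample_coords(spec)
  eps <- 1e-9
  if (any(coords$x < -eps) || any(coords$x > ncol(image) - 1 + eps) ||
      any(coords$y < -eps) || any(coords$y > nrow(image) - 1 + eps)) {
    stop("transect exceeds image bounds; shorten its length or width")
  }
  strip <- bilinear_sample(image, coords$x, coords$y)
  structure(list(strip = strip, spec = spec), class = "transect_image")
}

#' @export
print.transect_image <- function(x, ...) {
  cat(sprintf("<transect_image> %d x %d px at %g deg\n",
              nrow(x$strip), ncol(x$strip), x$spec$angle))
  invisible(x)
}

#' Map transect strip coordinates back to image coordinates
#'
#' The forward sampling map of [extract_transect()], so that detections made
#' in strip coordinates can be reported on the scale of the original image.
#' Composing with the strip geometry is the identity.
#'
#' @param spec A [transect_spec()].
#' @param point Numeric `(row, column)`, 0-based continuous strip
#'   coordinates.
#' @return Numeric `(x, y)` in original-image pixels.
#' @examples
#' sp <- transect_spec(c(50, 50), 0, width = 5, length = 100)
#' to_scale_coords(sp, c(2, 0)) # the origin (50, 50)
#' @export
to_scale_coords <- function(spec, point) {
  stopifnot(inherits(spec, "transect_spec"), length(point) == 2)
  u <- ray_direction(spec$angle)
  nrm <- ray_normal(spec$angle)
  r <- point[1]
  cc <- point[2]
  off <- r - (spec$width - 1) / 2
  c(x = spec$origin[1] + cc * u[1] + off * nrm[1],
    y = spec$origin[2] + cc * u[2] + off * nrm[2])
}

## Inverse of to_scale_coords: image (x, y) -> strip (row, column).
from_scale_coords <- function(spec, xy) {
  u <- ray_direction(spec$angle)
  nrm <- ray_normal(spec$angle)
  d <- c(xy[1] - spec$origin[1], xy[2] - spec$origin[2])
  cc <- d[1] * u[1] + d[2] * u[2]
  off <- d[1] * nrm[1] + d[2] * nrm[2]
  c(row = off + (spec$width - 1) / 2, column = cc)
}

#' Longest transect length that fits a strip of the given width
#'
#' [transect_length()] measures the run of the ray itself; a strip of width
#' greater than 1 also needs its outer rows inside the image. This helper
#' shortens the length until every sample row fits, so the resulting
#' [transect_spec()] is always valid for [extract_transect()].
#'
#' @inheritParams transect_length
#' @param width Strip width, pixels.
#' @return Integer number of columns (0 if no column fits).
#' @export
transect_length_for_width <- function(origin, angle, image_width,
                                      image_height, width) {
  u <- ray_direction(angle)
  nrm <- ray_normal(angle)
  offs <- c(-(width - 1) / 2, (width - 1) / 2)
  lens <- vapply(offs, function(o) {
    start <- origin + o * nrm
    if (start[1] < 0 || start[1] > image_width - 1 ||
        start[2] < 0 || start[2] > image_height - 1) {
      return(0L)
    }
    axis_max <- function(p, d, bound) {
      if (abs(d) < 1e-12) return(Inf)
      t_exit <- if (d > 0) (bound - 1 - p) / d else p / (-d)
      floor(t_exit)
    }
    c_max <- min(axis_max(start[1], u[1], image_width),
                 axis_max(start[2], u[2], image_height))
    as.integer(c_max + 1)
  }, integer(1))
  min(lens)
}
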