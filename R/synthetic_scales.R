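#' Parameters of the synthetic scale-image simulator
#'
#' The simulator emulates the structure the detection pipeline assumes in a
#' scale impression image: a dark, compact focus at the origin of growth,
#' surrounded by concentric near-elliptical dark circuli bands on a bright
#' background. Band spacing is narrow and approximately constant in the inner
#' freshwater zone and wider, with sinusoidal seasonal modulation, in the
#' outer marine zone. The major axis of the ellipses is vertical, matching
#' the imaging convention of mounting scales with the longest radial axis
#' upright.
#'
#' Defaults describe a mid-resolution impression: a 768 px square image, a
#' 12 px focus radius, 12 freshwater rings at 8 px spacing and 18 marine
#' rings at 12 px base spacing with a 3 px seasonal swing over an 8-ring
#' cycle. All lengths are in pixels, intensities in `[0, 1]`.
#'
#' @param image_width,image_height Image dimensions in pixels.
#' @param focus_center Numeric `(x, y)` of the focus centre.
#' @param focus_radius Radius of the dark focus disc, pixels.
#' @param n_freshwater_rings,n_marine_rings Ring counts in each zone.
#' @param fw_base_spacing Freshwater inter-ring spacing, pixels. Must be
#'   smaller than `marine_base_spacing`: the freshwater zone is where circuli
#'   spacings are narrowest.
#' @param marine_base_spacing Marine base inter-ring spacing, pixels.
#' @param seasonal_amplitude Amplitude of the sinusoidal modulation of marine
#'   spacings, pixels.
#' @param seasonal_period Marine rings per seasonal cycle.
#' @param jitter Multiplicative spacing jitter as a fraction of each spacing
#'   (uniform in `±jitter`); `0` disables it.
#' @param band_sigma Gaussian cross-section width of a ring band, pixels.
#'   Every spacing must exceed `2 * band_sigma` so rings stay resolvable.
#' @param band_contrast Intensity depth of a ring band, in `[0, 1]`.
#' @param noise_sigma Standard deviation of additive Gaussian pixel noise.
#' @param eccentricity Minor-axis shortfall ratio in `[0, 1)`: minor radius
#'   is `major * (1 - eccentricity)`.
#' @param breakage_prob Probability that a ring band is locally erased over a
#'   random angular segment.
#' @param seed Integer seed; rendering is deterministic given the seed.
#' @return An object of class `scale_sim_params`.
#' @export
scale_sim_params <- function(image_width = 768, image_height = 768,
                             focus_center = c(image_width / 2, image_height / 2),
                             focus_radius = 12,
                             n_freshwater_rings = 12, n_marine_rings = 18,
                             fw_base_spacing = 8, marine_base_spacing = 12,
                             seasonal_amplitude = 3, seasonal_period = 8,
                             jitter = 0.05,
                             band_sigma = 1, band_contrast = 0.45,
                             noise_sigma = 0.03, eccentricity = 0.12,
                             breakage_prob = 0.05, seed = 1L) {
  p <- structure(
    list(image_width = as.integer(image_width),
         image_height = as.integer(image_height),
         focus_center = as.numeric(focus_center),
         focus_radius = as.numeric(focus_radius),
         n_freshwater_rings = as.integer(n_freshwater_rings),
         n_marine_rings = as.integer(n_marine_rings),
         fw_base_spacing = as.numeric(fw_base_spacing),
         marine_base_spacing = as.numeric(marine_base_spacing),
         seasonal_amplitude = as.numeric(seasonal_amplitude),
         seasonal_period = as.numeric(seasonal_period),
         jitter = as.numeric(jitter),
         band_sigma = as.numeric(band_sigma),
         band_contrast = as.numeric(band_contrast),
         noise_sigma = as.numeric(noise_sigma),
         eccentricity = as.numeric(eccentricity),
         breakage_prob = as.numeric(breakage_prob),
         seed = as.integer(seed)),
    class = "scale_sim_params"
  )
  validate_sim_params(p)
}

validate_sim_params <- function(p) {
  stopifnot(inherits(p, "scale_sim_params"))
  if (p$image_width < 8 || p$image_height < 8) stop("image too small")
  if (length(p$focus_center) != 2) stop("focus_center must be (x, y)")
  if (p$focus_radius <= 0) stop("focus_radius must be positive")
  if (p$n_freshwater_rings < 0 || p$n_marine_rings < 0) {
    stop("ring counts must be non-negative")
  }
  if (!(p$fw_base_spacing < p$marine_base_spacing)) {
    stop("fw_base_spacing must be smaller than marine_base_spacing: ",
         "freshwater circuli are the most narrowly spaced")
  }
  min_marine <- p$marine_base_spacing - p$seasonal_amplitude
  min_spacing <- min(p$fw_base_spacing, min_marine) * (1 - p$jitter)
  if (min_spacing <= 2 * p$band_sigma) {
    stop("spacings must all exceed 2 * band_sigma so rings stay resolvable ",
         sprintf("(minimum spacing %.2f px vs 2*band_sigma = %.2f px)",
                 min_spacing, 2 * p$band_sigma))
  }
  if (p$band_contrast < 0 || p$band_contrast > 1) {
    stop("band_contrast must be in [0, 1]")
  }
  if (p$eccentricity < 0 || p$eccentricity >= 1) {
    stop("eccentricity must be in [0, 1)")
  }
  if (p$breakage_prob < 0 || p$breakage_prob > 1) {
    stop("breakage_prob must be in [0, 1]")
  }
  if (p$jitter < 0 || p$jitter >= 0.5) stop("jitter must be in [0, 0.5)")
  p
}

## Run expr with a private RNG stream, leaving the global stream untouched.
with_private_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate ring major radii for a synthetic scale
#'
#' Radii start at `focus_radius + fw_base_spacing`. The first
#' `n_freshwater_rings` spacings equal `fw_base_spacing`; the following
#' `n_marine_rings` spacings equal
#' `marine_base_spacing + seasonal_amplitude * sin(2 * pi * i / seasonal_period)`
#' for marine ring index `i = 1, 2, ...`. Each spacing receives seeded
#' multiplicative jitter (`±jitter` fraction). The result is strictly
#' increasing by construction.
#'
#' @param params A [scale_sim_params()].
#' @return Numeric vector of strictly increasing major radii, pixels.
#' @export
generate_ring_radii <- function(params) {
  validate_sim_params(params)
  n_fw <- params$n_freshwater_rings
  n_ma <- params$n_marine_rings
  fw <- rep(params$fw_base_spacing, n_fw)
  ma <- if (n_ma > 0) {
    params$marine_base_spacing +
      params$seasonal_amplitude *
        sin(2 * pi * seq_len(n_ma) / params$seasonal_period)
  } else numeric()
  spacings <- c(fw, ma)
  if (length(spacings) == 0) return(numeric())
  if (params$jitter > 0) {
    mult <- with_private_seed(params$seed, {
      stats::runif(length(spacings), 1 - params$jitter, 1 + params$jitter)
    })
    spacings <- spacings * mult
  }
  radii <- params$focus_radius + cumsum(spacings)
  stopifnot(all(diff(radii) > 0))
  radii
}

#' Render a synthetic scale image with exact ground truth
#'
#' Draws a bright background with additive Gaussian noise, a dark focus disc
#' at the focus centre, and one dark band of Gaussian cross-section per ring
#' along an ellipse with vertical major axis (major radius from
#' [generate_ring_radii()], minor radius `major * (1 - eccentricity)`). With
#' positive `breakage_prob`, individual rings may be erased over a random
#' angular segment, emulating the broken bands seen in real impressions. The
#' focus disc is drawn darker than the ring bands, as the dense first-formed
#' material of a real focus images darker than single circuli.
#'
#' @param params A [scale_sim_params()].
#' @return An object of class `synthetic_scale` with elements `image` (a
#'   numeric matrix in `[0, 1]`, rows = y, columns = x), `focus_box` (box
#'   table), `ring_major_radii`, and `params`.
#' @export
render_scale <- function(params) {
  validate_sim_params(params)
  radii <- generate_ring_radii(params)
  w <- params$image_width
  h <- params$image_height
  cx <- params$focus_center[1]
  cy <- params$focus_center[2]
  ecc <- params$eccentricity
  if (length(radii) > 0) {
    r_max <- max(radii)
    fits <- (cy - r_max) >= 0 && (cy + r_max) <= h &&
      (cx - r_max * (1 - ecc)) >= 0 && (cx + r_max * (1 - ecc)) <= w
    if (!fits) {
      stop(sprintf(
        "image %d x %d too small to contain the outermost ring (major radius %.1f px)",
        w, h, r_max))
    }
  }

  # pixel centre coordinates (0-based)
  xs <- seq_len(w) - 1
  ys <- seq_len(h) - 1
  dx <- matrix(xs, nrow = h, ncol = w, byrow = TRUE) - cx
  dy <- matrix(ys, nrow = h, ncol = w) - cy

  background <- 0.92
  img <- matrix(background, nrow = h, ncol = w)

  # focus: smooth-edged dark disc, deeper than the ring bands
  focus_depth <- min(0.95, 1.5 * params$band_contrast)
  r_euclid <- sqrt(dx^2 + dy^2)
  edge <- params$band_sigma
  img <- img - focus_depth / (1 + exp((r_euclid - params$focus_radius) / (edge / 2)))

  # elliptical radius in major-axis units; multiply by the local metric to
  # get an approximate Euclidean distance from the band so band_sigma keeps
  # its pixel meaning along every direction
  minor_ratio <- 1 - ecc
  rho <- sqrt((dx / minor_ratio)^2 + dy^2)
  phi <- atan2(dy, dx)

  breakage <- with_private_seed(params$seed + 1L, {
    broken <- stats::runif(length(radii)) < params$breakage_prob
    start <- stats::runif(length(radii), -pi, pi)
    extent <- stats::runif(length(radii), pi / 6, pi / 3)
    list(broken = broken, start = start, extent = extent)
  })

  for (i in seq_along(radii)) {
    band <- params$band_contrast *
      exp(-((rho - radii[i])^2) / (2 * params$band_sigma^2))
    if (length(breakage$broken) && breakage$broken[i]) {
      d <- (phi - breakage$start[i]) %% (2 * pi)
      band[d < breakage$extent[i]] <- 0
    }
    img <- img - band
  }

  if (params$noise_sigma > 0) {
    noise <- with_private_seed(params$seed + 2L, {
      matrix(stats::rnorm(h * w, 0, params$noise_sigma), nrow = h)
    })
    img <- img + noise
  }
  img <- pmin(pmax(img, 0), 1)

  focus_box <- bbox(cx - params$focus_radius, cy - params$focus_radius,
                    cx + params$focus_radius, cy + params$focus_radius,
                    label = "focus")
  structure(
    list(image = img, focus_box = focus_box,
         ring_major_radii = radii, params = params),
    class = "synthetic_scale"
  )
}

#' @export
print.synthetic_scale <- function(x, ...) {
  cat(sprintf("<synthetic_scale> %d x %d px, %d ring(s), seed %d\n",
              x$params$image_width, x$params$image_height,
              length(x$ring_major_radii), x$params$seed))
  invisible(x)
}

## Along-ray distance from the focus centre to the intersection of the ray at
## `angle` (degrees, counter-clockwise from +x, y down) with the ellipse of
## vertical major radius r. Closed form for a centred axis-aligned ellipse.
ray_ellipse_distance <- function(r_major, angle_deg, eccentricity) {
  th <- angle_deg * pi / 180
  ux <- cos(th)
  uy <- -sin(th) # y grows downwards
  b <- r_major * (1 - eccentricity) # horizontal minor radius
  1 / sqrt((ux / b)^2 + (uy / r_major)^2)
}

#' Ground-truth circuli boxes along a transect
#'
#' For each ring of a synthetic scale, computes the distance from the focus
#' centre to the ray--ellipse intersection at the requested angle and wraps
#' it in a bounding box in transect coordinates: the box is centred on that
#' column, extends `±2 * band_sigma` horizontally (half-width at least
#' 1.5 px) and spans the full strip height. Rings beyond the transect length
#' (the ray's run from the focus to the image border) are omitted. Boxes are
#' ordered by column.
#'
#' @param scale A [render_scale()] result.
#' @param angle Transect angle in degrees (counter-clockwise from the +x
#'   axis; 90 points to the image top).
#' @param width Strip width (height of the boxes), pixels.
#' @return A box table in transect coordinates with one row per visible ring.
#' @export
ground_truth_for_transect <- function(scale, angle, width) {
  stopifnot(inherits(scale, "synthetic_scale"), width >= 1)
  p <- scale$params
  len <- transect_length(p$focus_center, angle, p$image_width, p$image_height)
  d <- ray_ellipse_distance(scale$ring_major_radii, angle, p$eccentricity)
  d <- d[d <= len - 1] # boxes centred beyond the last column are not visible
  if (length(d) == 0) return(bbox())
  half <- max(2 * p$band_sigma, 1.5)
  bbox(d - half, rep(0, length(d)), d + half, rep(width, length(d)),
       label = "circulus")
}
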