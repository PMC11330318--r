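#' Circuli centre distances from detections
#'
#' Extracts the `center_column` values (distance from the focus in pixels
#' along the ray) from a sorted circuli detection table. Centres that
#' coincide within 1e-9 px are collapsed to one with a warning.
#'
#' @param detections A detection table from [detect_circuli()] (sorted by
#'   ascending `center_column`).
#' @return Strictly increasing numeric vector of distances (possibly empty).
#' @export
centers_to_distances <- function(detections) {
  if (nrow(detections) == 0) return(numeric())
  d <- detections$center_column
  if (is.null(d)) d <- (detections$x_min + detections$x_max) / 2
  if (is.unsorted(d)) {
    stop("detections must be sorted by ascending centre column")
  }
  dup <- c(FALSE, diff(d) < 1e-9)
  if (any(dup)) {
    warning(sum(dup), " duplicate circuli centre(s) collapsed")
    d <- d[!dup]
  }
  d
}

#' Inter-circuli spacings
#'
#' First differences of the ordered centre distances. A single distance (or
#' none) yields an empty result with a warning: no spacing can be formed.
#'
#' @param distances Strictly increasing numeric vector.
#' @return Numeric vector of length `length(distances) - 1` (or empty).
#' @export
compute_spacings <- function(distances) {
  if (length(distances) < 2) {
    warning("fewer than 2 circuli distances; no spacings computed")
    return(numeric())
  }
  if (any(diff(distances) <= 0)) stop("distances must be strictly increasing")
  diff(distances)
}

#' Spacing series of one transect
#'
#' @param transect_id Identifier string.
#' @param angle Transect angle in degrees.
#' @param distances Strictly increasing circuli centre distances, pixels.
#' @param scores Optional per-circulus detection scores.
#' @return An object of class `spacing_series` with `distances` and their
#'   first differences as `spacings`.
#' @export
spacing_series <- function(transect_id, angle, distances, scores = NULL) {
  stopifnot(is.character(transect_id), length(transect_id) == 1)
  if (length(distances) >= 2 && any(diff(distances) <= 0)) {
    stop("distances must be strictly increasing")
  }
  structure(
    list(transect_id = transect_id, angle = as.numeric(angle),
         distances = as.numeric(distances),
         spacings = if (length(distances) >= 2) diff(distances) else numeric(),
         scores = scores),
    class = "spacing_series"
  )
}

#' @export
print.spacing_series <- function(x, ...) {
  cat(sprintf("<spacing_series> %s (%g deg): %d circuli, %d spacing(s)\n",
              x$transect_id, x$angle, length(x$distances),
              length(x$spacings)))
  invisible(x)
}

#' Normalize a spacing series by its transect maximum
#'
#' Distances are divided by the maximum distance observed on the transect, so
#' profiles from transects of different lengths share the `(0, 1]` axis.
#' Spacings are carried over unchanged; optionally they are also divided by
#' their own maximum.
#'
#' @param series A [spacing_series()].
#' @param normalize_spacings Also divide spacings by `max(spacings)`.
#' @return An object of class `normalized_profile`.
#' @export
normalize_profile <- function(series, normalize_spacings = FALSE) {
  stopifnot(inherits(series, "spacing_series"))
  if (length(series$distances) == 0) {
    stop("cannot normalize an empty spacing series")
  }
  nd <- series$distances / max(series$distances)
  out <- list(transect_id = series$transect_id, angle = series$angle,
              normalized_distances = nd, spacings = series$spacings)
  if (normalize_spacings && length(series$spacings) > 0) {
    out$normalized_spacings <- series$spacings / max(series$spacings)
  }
  structure(out, class = "normalized_profile")
}

#' Aggregate spacing profiles across transects
#'
#' Each profile's spacing-versus-normalized-distance curve (each spacing
#' attributed to the midpoint of its two bounding circuli distances) is
#' linearly interpolated onto a common grid in `[0, 1]`; the pointwise mean
#' and requested quantiles are taken across profiles. Grid points outside a
#' profile's support do not contribute. This is a deliberately simple
#' aggregator for visualising a common growth pattern across transects;
#' smoothing-model alternatives (e.g. hierarchical GAMs) are left to
#' downstream analysis.
#'
#' @param profiles List of [normalize_profile()] results, each with at least
#'   2 spacings.
#' @param grid_size Number of grid points.
#' @param quantiles Lower and upper quantile levels for the band.
#' @return An object of class `aggregated_profile`: list with `grid`,
#'   `mean_spacing`, `lower_q`, `upper_q`, `n_profiles` and per-grid-point
#'   contribution counts `n_at_grid`.
#' @export
aggregate_transects <- function(profiles, grid_size = 100,
                                quantiles = c(0.05, 0.95)) {
  if (length(profiles) == 0) stop("no profiles to aggregate")
  stopifnot(grid_size >= 2, length(quantiles) == 2,
            quantiles[1] < quantiles[2])
  grid <- seq(0, 1, length.out = grid_size)
  curves <- vapply(profiles, function(p) {
    stopifnot(inherits(p, "normalized_profile"))
    if (length(p$spacings) < 2) {
      stop("each profile needs at least 2 spacings; got ",
           length(p$spacings), " for ", p$transect_id)
    }
    nd <- p$normalized_distances
    mids <- (nd[-length(nd)] + nd[-1]) / 2
    stats::approx(mids, p$spacings, xout = grid, rule = 1)$y
  }, numeric(grid_size))
  curves <- matrix(curves, nrow = grid_size)
  n_at_grid <- rowSums(!is.na(curves))
  qs <- t(apply(curves, 1, function(v) {
    if (all(is.na(v))) c(NA_real_, NA_real_)
    else stats::quantile(v, quantiles, na.rm = TRUE, names = FALSE)
  }))
  structure(
    list(grid = grid,
         mean_spacing = ifelse(n_at_grid > 0, rowMeans(curves, na.rm = TRUE),
                               NA_real_),
         lower_q = qs[, 1], upper_q = qs[, 2],
         n_profiles = length(profiles), n_at_grid = n_at_grid),
    class = "aggregated_profile"
  )
}

#' @export
print.aggregated_profile <- function(x, ...) {
  cat(sprintf("<aggregated_profile> %d grid points, %d profile(s)\n",
              length(x$grid), x$n_profiles))
  invisible(x)
}

#' Tidy table of spacings
#'
#' Flattens spacing series into one row per spacing, ready for CSV export or
#' plotting: each spacing sits at the midpoint of its two bounding circuli.
#'
#' @param series_list List of [spacing_series()] objects.
#' @param scale_id Optional scale identifier added as a column.
#' @return A data frame with columns `scale_id`, `transect_id`, `angle`,
#'   `distance_px`, `normalized_distance`, `spacing_px`, `score`.
#' @export
spacings_table <- function(series_list, scale_id = NA_character_) {
  rows <- lapply(series_list, function(s) {
    stopifnot(inherits(s, "spacing_series"))
    if (length(s$spacings) == 0) return(NULL)
    d <- s$distances
    mids <- (d[-length(d)] + d[-1]) / 2
    sc <- if (!is.null(s$scores) && length(s$scores) == length(d)) {
      # score of the outer circulus bounding each spacing
      s$scores[-1]
    } else {
      rep(NA_real_, length(s$spacings))
    }
    data.frame(scale_id = scale_id, transect_id = s$transect_id,
               angle = s$angle, distance_px = mids,
               normalized_distance = mids / max(d),
               spacing_px = s$spacings, score = sc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(scale_id = character(), transect_id = character(),
                      angle = numeric(), distance_px = numeric(),
                      normalized_distance = numeric(), spacing_px = numeric(),
                      score = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
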