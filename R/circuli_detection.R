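#' Column-mean intensity profile of a transect
#'
#' The per-column mean across strip rows: the 1-D pixel-intensity profile
#' that semi-automated increment tools work on.
#'
#' @param transect A [transect_image()][extract_transect()].
#' @return Numeric vector of length `spec$length`.
#' @export
profile_from_transect <- function(transect) {
  stopifnot(inherits(transect, "transect_image"))
  colMeans(transect$strip)
}

## Gaussian smoothing of a 1-D signal, reflective boundary.
gaussian_smooth_1d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  pad <- c(x[pmin(half:1, n)], x, x[pmax(n - (1:half) + 1, 1)])
  as.numeric(stats::filter(pad, k, sides = 2))[half + seq_len(n)]
}

## Local maxima, their prominences, and their widths at half prominence.
## Prominence of a peak is its height minus the higher of the two interval
## minima between it and the nearest higher point on each side (signal edges
## act as higher points of infinite height when no higher point exists).
peak_prominences <- function(s) {
  n <- length(s)
  if (n < 3) {
    return(data.frame(index = integer(), height = numeric(),
                      prominence = numeric(), left = numeric(),
                      right = numeric()))
  }
  is_peak <- which(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n]) + 1
  if (length(is_peak) == 0) {
    return(data.frame(index = integer(), height = numeric(),
                      prominence = numeric(), left = numeric(),
                      right = numeric()))
  }
  out <- lapply(is_peak, function(i) {
    h <- s[i]
    # walk left to the nearest strictly higher sample
    li <- i - 1
    left_min <- h
    while (li >= 1 && s[li] <= h) {
      left_min <- min(left_min, s[li])
      li <- li - 1
    }
    ri <- i + 1
    right_min <- h
    while (ri <= n && s[ri] <= h) {
      right_min <- min(right_min, s[ri])
      ri <- ri + 1
    }
    base <- if (li >= 1 && ri <= n) {
      max(left_min, right_min)
    } else if (li >= 1) {
      right_min
    } else if (ri <= n) {
      left_min
    } else {
      min(left_min, right_min)
    }
    prom <- h - base
    # width at half prominence: interpolated crossings of h - prom/2,
    # bounded by the nearest higher point on each side
    level <- h - prom / 2
    j <- i
    while (j > 1 && s[j - 1] > level && s[j - 1] <= h) j <- j - 1
    xl <- if (j > 1 && s[j - 1] <= level) {
      (j - 1) + (level - s[j - 1]) / (s[j] - s[j - 1])
    } else {
      j
    }
    j <- i
    while (j < n && s[j + 1] > level && s[j + 1] <= h) j <- j + 1
    xr <- if (j < n && s[j + 1] <= level) {
      j + (s[j] - level) / (s[j] - s[j + 1])
    } else {
      j
    }
    data.frame(index = i, height = h, prominence = prom,
               left = xl, right = xr)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Classical reference circuli detector
#'
#' A trained-model-free circuli detector working on the 1-D column-mean
#' profile of a transect strip: the profile is Gaussian-smoothed, inverted
#' (circuli image as dark bands), and local maxima of the inverted signal
#' with prominence at least `min_prominence` are taken as circuli. Peaks
#' closer than `min_separation` columns are reduced to the most prominent
#' one. Each surviving peak becomes a detection box centred on the peak
#' column, with horizontal extent equal to the peak's width at half
#' prominence, capped at half the distance to each adjacent surviving peak
#' (so bands in dense trains keep individual boxes) and at least 3 px, and
#' vertical extent the full strip height. The
#' confidence score is `min(1, prominence / reference_prominence)`: deeper,
#' better-separated bands score higher, so narrow freshwater-zone circuli
#' naturally receive lower confidence.
#'
#' @param transect A transect strip ([extract_transect()]).
#' @param smooth_sigma Gaussian smoothing sigma for the profile, pixels.
#' @param min_prominence Minimum peak prominence (intensity units).
#' @param min_separation Minimum distance between accepted peaks, pixels.
#' @param reference_prominence Prominence mapped to score 1.
#' @param invert If `TRUE` (default) circuli are dark bands; set `FALSE` for
#'   negative images where they are bright.
#' @return A box table in transect coordinates with a `score` column, ordered
#'   by ascending box centre column.
#' @export
reference_circuli_detector <- function(transect, smooth_sigma = 2,
                                       min_prominence = 0.05,
                                       min_separation = 3,
                                       reference_prominence = 0.15,
                                       invert = TRUE) {
  stopifnot(inherits(transect, "transect_image"))
  p <- profile_from_transect(transect)
  if (min(p) < -1e-9 || max(p) > 1 + 1e-9) {
    stop("strip intensities must be in [0, 1]")
  }
  s <- gaussian_smooth_1d(p, smooth_sigma)
  if (invert) s <- max(s) - s
  peaks <- peak_prominences(s)
  peaks <- peaks[peaks$prominence >= min_prominence, , drop = FALSE]
  if (nrow(peaks) == 0) return(bbox())

  # enforce min separation: keep the most prominent of any close group
  keep <- logical(nrow(peaks))
  for (i in order(-peaks$prominence, peaks$index)) {
    if (!any(keep & abs(peaks$index - peaks$index[i]) < min_separation)) {
      keep[i] <- TRUE
    }
  }
  peaks <- peaks[keep, , drop = FALSE]

  height <- nrow(transect$strip)
  peaks <- peaks[order(peaks$index), , drop = FALSE]
  center <- peaks$index - 1 # 0-based column
  half <- (peaks$right - peaks$left) / 2
  if (nrow(peaks) > 1) {
    gaps <- diff(peaks$index)
    basin <- pmin(c(Inf, gaps), c(gaps, Inf)) / 2
    half <- pmin(half, basin)
  }
  half <- pmax(half, 1.5)
  out <- bbox(center - half, rep(0, nrow(peaks)),
              center + half, rep(height, nrow(peaks)),
              label = "circulus",
              score = pmin(1, peaks$prominence / reference_prominence))
  out <- out[order((out$x_min + out$x_max) / 2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Make a reference circuli backend
#'
#' Wraps [reference_circuli_detector()] with fixed settings into a
#' [detector_backend()]. The wrapped function accepts a `transect_image` (or
#' a bare strip matrix, taken as a width-`nrow` strip).
#'
#' @param ... Settings passed on to [reference_circuli_detector()].
#' @return A `detector_backend`.
#' @export
reference_circuli_backend <- function(...) {
  args <- list(...)
  detector_backend(
    function(transect) {
      if (is.matrix(transect)) {
        transect <- structure(
          list(strip = transect,
               spec = transect_spec(c(0, 0), 0, nrow(transect),
                                    ncol(transect))),
          class = "transect_image")
      }
      do.call(reference_circuli_detector, c(list(transect), args))
    },
    name = "reference-circuli"
  )
}

## Greedy non-maximum suppression: process by descending score, drop any box
## with IOU above `iou_max` with an already kept box.
nms_boxes <- function(boxes, iou_max = 0.5) {
  if (nrow(boxes) <= 1) return(boxes)
  ord <- order(-boxes$score)
  keep <- integer()
  for (i in ord) {
    ok <- TRUE
    for (j in keep) {
      if (iou(boxes[i, ], boxes[j, ]) > iou_max) {
        ok <- FALSE
        break
      }
    }
    if (ok) keep <- c(keep, i)
  }
  boxes[sort(keep), , drop = FALSE]
}

#' Detect circuli along a transect
#'
#' Runs a detector backend on the transect strip, applies the score threshold
#' (default 0.3, the accepting threshold of the trained circuli stage),
#' suppresses overlapping boxes greedily so no two survivors have IOU above
#' 0.5, and returns the detections sorted by ascending centre column, with a
#' `center_column` convenience column.
#'
#' @param transect A transect strip ([extract_transect()]).
#' @param backend A [detector_backend()]; default the reference detector.
#' @param threshold Minimum confidence score, default 0.3.
#' @param nms_iou IOU above which the lower-scoring of two boxes is dropped.
#' @return A box table in transect coordinates with `score` and
#'   `center_column` columns; possibly empty.
#' @export
detect_circuli <- function(transect, backend = reference_circuli_backend(),
                           threshold = 0.3, nms_iou = 0.5) {
  stopifnot(inherits(transect, "transect_image"))
  det <- backend(transect)
  det <- apply_score_threshold(det, threshold)
  det <- nms_boxes(det, nms_iou)
  det$center_column <- if (nrow(det) > 0) (det$x_min + det$x_max) / 2 else numeric()
  det <- det[order(det$center_column), , drop = FALSE]
  rownames(det) <- NULL
  det
}
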