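#' Classical reference focus detector
#'
#' A trained-model-free focus detector built from standard image operations:
#' the image is Gaussian-smoothed, dark pixels are thresholded at an
#' intensity quantile, a small morphological opening removes thin band
#' fragments, and connected components within a plausible area range become
#' candidate detections. Each candidate is scored as its darkness contrast --
#' the depth of the component's dark core (its 10th intensity percentile)
#' below the median image intensity, relative to the image's darkest
#' extreme -- multiplied by its centrality (1 minus the normalized distance
#' of the component centroid from the image centre), clipped to `[0, 1]`. Candidates are returned ordered by
#' descending score; ties break towards the larger component, then the
#' component whose box centre has the smaller y.
#'
#' The focus of a scale impression is a compact dark blob near the middle of
#' a well-framed image, which is exactly what this scoring favours; it is not
#' a replacement for a trained detector on difficult real material.
#'
#' @param image Numeric matrix, intensities in `[0, 1]`.
#' @param smooth_sigma Gaussian smoothing sigma, pixels.
#' @param dark_quantile Intensity quantile defining "dark" pixels.
#' @param opening_radius Radius of the morphological opening brush, pixels;
#'   0 disables opening.
#' @param min_area,max_area Component area range in pixels (after
#'   thresholding); `max_area = NULL` defaults to 10% of the image area.
#' @return A box table with one row per candidate and a `score` column.
#' @export
reference_focus_detector <- function(image, smooth_sigma = 1.5,
                                     dark_quantile = 0.0015,
                                     opening_radius = 2,
                                     min_area = 40, max_area = NULL) {
  stopifnot(is.matrix(image))
  if (min(image) < -1e-9 || max(image) > 1 + 1e-9) {
    stop("image intensities must be in [0, 1]; run preprocess() first")
  }
  h <- nrow(image)
  w <- ncol(image)
  if (is.null(max_area)) max_area <- 0.1 * h * w

  # EBImage images are indexed [x, y]
  eb <- EBImage::Image(t(image))
  smoothed <- EBImage::gblur(eb, sigma = smooth_sigma)
  sm <- t(EBImage::imageData(smoothed))

  med <- stats::median(image)
  # a whisker above the quantile so flat dark plateaus are kept whole
  thr <- stats::quantile(sm, dark_quantile, names = FALSE) + 1e-6
  if (med - thr < 0.02) {
    # no pixels meaningfully darker than the background: nothing to detect
    return(bbox())
  }
  mask <- sm <= thr
  mask_eb <- EBImage::Image(t(mask * 1))
  if (opening_radius > 0) {
    brush <- EBImage::makeBrush(2 * opening_radius + 1, shape = "disc")
    mask_eb <- EBImage::opening(mask_eb, brush)
  }
  labels <- t(EBImage::imageData(EBImage::bwlabel(mask_eb)))
  n_comp <- max(labels)
  if (n_comp == 0) return(bbox())

  darkest <- stats::quantile(sm, 0.001, names = FALSE)
  cand <- lapply(seq_len(n_comp), function(k) {
    idx <- which(labels == k, arr.ind = TRUE)
    area <- nrow(idx)
    if (area < min_area || area > max_area) return(NULL)
    ys <- idx[, 1] - 1
    xs <- idx[, 2] - 1
    core <- stats::quantile(sm[idx], 0.1, names = FALSE)
    contrast <- (med - core) / max(med - darkest, 1e-9)
    centroid <- c(mean(xs), mean(ys))
    d_norm <- sqrt(sum((centroid - c((w - 1) / 2, (h - 1) / 2))^2)) /
      (sqrt(w^2 + h^2) / 2)
    score <- min(1, max(0, contrast)) * min(1, max(0, 1 - d_norm))
    # the quantile mask keeps only the darkest core of a blob; grow the box
    # to the blob's full extent at a level part-way back towards background
    level <- core + 0.25 * (med - core)
    pad <- round(0.75 * max(diff(range(xs)), diff(range(ys))) + 4)
    rows <- max(1, min(ys) + 1 - pad):min(h, max(ys) + 1 + pad)
    cols <- max(1, min(xs) + 1 - pad):min(w, max(xs) + 1 + pad)
    wm <- which(sm[rows, cols, drop = FALSE] <= level, arr.ind = TRUE)
    if (nrow(wm) > 0) {
      ys <- rows[range(wm[, 1])] - 1
      xs <- cols[range(wm[, 2])] - 1
    }
    data.frame(x_min = min(xs), y_min = min(ys),
               x_max = max(xs) + 1, y_max = max(ys) + 1,
               label = "focus", score = min(1, max(0, score)),
               area = area, stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) == 0) return(bbox())
  yc <- (cand$y_min + cand$y_max) / 2
  ord <- order(-cand$score, -cand$area, yc)
  cand <- cand[ord, setdiff(names(cand), "area"), drop = FALSE]
  rownames(cand) <- NULL
  validate_bbox(cand)
}

#' Make a reference focus backend
#'
#' Wraps [reference_focus_detector()] with fixed settings into a
#' [detector_backend()].
#'
#' @param ... Settings passed on to [reference_focus_detector()].
#' @return A `detector_backend`.
#' @export
reference_focus_backend <- function(...) {
  args <- list(...)
  detector_backend(
    function(image) do.call(reference_focus_detector, c(list(image), args)),
    name = "reference-focus"
  )
}

#' Detect the scale focus
#'
#' Runs a detector backend on the image, applies the score threshold
#' (default 0.5), and returns the single highest-scoring surviving detection
#' as the focus. For speed, the backend sees a copy downscaled so its longest
#' side is at most `max_side` pixels (1376 by default, the working input
#' resolution of the trained focus stage); the returned box is mapped back to
#' original-image pixels. If no detection survives the threshold a
#' `focus_not_found` error is signalled: such a scale must be excluded rather
#' than processed with a guessed centre.
#'
#' @param image Numeric matrix, intensities in `[0, 1]`.
#' @param backend A [detector_backend()]; default the reference detector.
#' @param threshold Minimum confidence score, default 0.5.
#' @param max_side Longest image side passed to the backend, pixels.
#' @return An object of class `focus_result`: list with `box` (one-row box
#'   table in original-image pixels), `score`, and `center` (`(x, y)` box
#'   midpoint).
#' @export
detect_focus <- function(image, backend = reference_focus_backend(),
                         threshold = 0.5, max_side = 1376) {
  stopifnot(is.matrix(image), nrow(image) > 0, ncol(image) > 0)
  scale_factor <- max(1, max(dim(image)) / max_side)
  work <- image
  if (scale_factor > 1) {
    eb <- EBImage::Image(t(image))
    work <- t(EBImage::imageData(EBImage::resize(
      eb, w = round(ncol(image) / scale_factor))))
    work <- pmin(pmax(work, 0), 1)
    scale_factor <- ncol(image) / ncol(work)
  }
  det <- backend(work)
  det <- apply_score_threshold(det, threshold)
  if (nrow(det) == 0) {
    stop(structure(
      class = c("focus_not_found", "error", "condition"),
      list(message = "no focus detection above the score threshold; exclude this scale",
           call = sys.call())
    ))
  }
  # deterministic argmax: ties broken by larger box area, then smaller centre y
  area <- (det$x_max - det$x_min) * (det$y_max - det$y_min)
  yc <- (det$y_min + det$y_max) / 2
  best <- det[order(-det$score, -area, yc)[1], , drop = FALSE]
  if (scale_factor > 1) {
    best$x_min <- best$x_min * scale_factor
    best$x_max <- best$x_max * scale_factor
    best$y_min <- best$y_min * scale_factor
    best$y_max <- best$y_max * scale_factor
  }
  rownames(best) <- NULL
  structure(
    list(box = best, score = best$score,
         center = as.numeric(bbox_centers(best)[1, ])),
    class = "focus_result"
  )
}

#' @export
print.focus_result <- function(x, ...) {
  cat(sprintf("<focus_result> centre (%.1f, %.1f), score %.3f\n",
              x$center[1], x$center[2], x$score))
  invisible(x)
}
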