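#' Read a scale image from PNG or TIFF
#'
#' Returns the raster as a numeric matrix (rows = y, columns = x). RGB(A)
#' images are reduced to luminance at read time by [preprocess()] callers;
#' this reader only loads pixel data.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix or 3-D array (height x width x channels).
#' @export
read_scale_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)")
  )
  img
}

#' Write a grayscale or RGB raster as PNG
#'
#' @param image Numeric matrix or height x width x 3 array in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scale_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Preprocess an image for detection
#'
#' Converts RGB(A) to luminance (Rec. 601 weights), rescales intensities to
#' `[0, 1]`, and optionally inverts polarity (for negatives in which circuli
#' are bright). A constant image degenerates to all zeros with a warning.
#' Already-normalized grayscale input passes through unchanged.
#'
#' @param image Numeric matrix or height x width x channels array.
#' @param invert Flip polarity after rescaling.
#' @param rescale Rescale intensities to span `[0, 1]`. When `FALSE`, values
#'   are only clipped to `[0, 1]` (integer-like 8-bit input is divided
#'   by 255 first).
#' @return Numeric matrix in `[0, 1]`.
#' @export
preprocess <- function(image, invert = FALSE, rescale = TRUE) {
  if (length(image) == 0) stop("empty image")
  if (length(dim(image)) == 3) {
    ch <- dim(image)[3]
    image <- if (ch >= 3) {
      0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
    } else {
      image[, , 1]
    }
  }
  if (!is.matrix(image)) stop("image must be a matrix or 3-D array")
  if (max(image) > 1) image <- image / 255
  rng <- range(image)
  if (rescale) {
    if (rng[2] - rng[1] < 1e-12) {
      warning("constant image; rescaled to all zeros")
      image[] <- 0
    } else if (rng[1] > 0 || rng[2] < 1) {
      image <- (image - rng[1]) / (rng[2] - rng[1])
    }
  } else {
    image <- pmin(pmax(image, 0), 1)
  }
  if (invert) image <- 1 - image
  image
}

#' Pipeline configuration
#'
#' Settings for the end-to-end pipeline: transect angles (default the
#' 0/45/90/135/180-degree fan sweeping the upper half of the scale), the two
#' stage score thresholds (0.5 for the focus stage, 0.3 for the circuli
#' stage), detector backends, preprocessing flags, and a seed recorded in
#' output manifests.
#'
#' @param angles Transect angles in degrees, non-empty.
#' @param focus_threshold,circuli_threshold Stage score thresholds in
#'   `[0, 1]`.
#' @param focus_backend,circuli_backend [detector_backend()]s; defaults are
#'   the classical reference detectors.
#' @param invert Polarity flag passed to [preprocess()].
#' @param seed Integer seed recorded in manifests.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(angles = c(0, 45, 90, 135, 180),
                            focus_threshold = 0.5,
                            circuli_threshold = 0.3,
                            focus_backend = reference_focus_backend(),
                            circuli_backend = reference_circuli_backend(),
                            invert = FALSE,
                            seed = 1L) {
  if (length(angles) == 0) stop("at least one transect angle is required")
  stopifnot(focus_threshold >= 0, focus_threshold <= 1,
            circuli_threshold >= 0, circuli_threshold <= 1)
  structure(
    list(angles = as.numeric(angles),
         focus_threshold = focus_threshold,
         circuli_threshold = circuli_threshold,
         focus_backend = focus_backend,
         circuli_backend = circuli_backend,
         invert = invert,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Process one scale image
#'
#' The five pipeline steps for a single image: preprocess, detect the focus,
#' derive the transect width from the focus box, then for each configured
#' angle extract the transect, detect circuli, and reduce them to distances
#' and spacings. A missing focus yields a skipped result, not an error.
#'
#' @param image Raster (matrix or array) or a path readable by
#'   [read_scale_image()].
#' @param config A [pipeline_config()].
#' @param image_id Identifier used in outputs.
#' @return An object of class `scale_result` with `status` either
#'   `"processed"` (fields `focus`, `width`, `series` keyed by angle,
#'   `detections` keyed by angle) or `"skipped"` (field `reason`).
#' @export
process_scale <- function(image, config = pipeline_config(),
                          image_id = "scale") {
  if (is.character(image)) {
    image_id <- sub("\\.[^.]+$", "", basename(image))
    image <- read_scale_image(image)
  }
  img <- preprocess(image, invert = config$invert)
  focus <- tryCatch(
    detect_focus(img, config$focus_backend, config$focus_threshold),
    focus_not_found = function(e) NULL
  )
  if (is.null(focus)) {
    return(structure(list(image_id = image_id, status = "skipped",
                          reason = "focus-not-found"),
                     class = "scale_result"))
  }
  width <- transect_width(focus$box)
  series <- list()
  detections <- list()
  for (angle in config$angles) {
    key <- format(angle)
    len <- transect_length_for_width(focus$center, angle,
                                     ncol(img), nrow(img), width)
    if (len < 2) {
      series[[key]] <- spacing_series(
        paste0(image_id, "_a", key), angle, numeric())
      detections[[key]] <- bbox()
      next
    }
    tr <- extract_transect(img, transect_spec(focus$center, angle, width, len))
    det <- detect_circuli(tr, config$circuli_backend,
                          config$circuli_threshold)
    detections[[key]] <- det
    d <- centers_to_distances(det)
    series[[key]] <- spacing_series(paste0(image_id, "_a", key), angle, d,
                                    scores = det$score)
  }
  structure(
    list(image_id = image_id, status = "processed", focus = focus,
         width = width, series = series, detections = detections),
    class = "scale_result"
  )
}

#' @export
print.scale_result <- function(x, ...) {
  if (x$status == "skipped") {
    cat(sprintf("<scale_result> %s skipped (%s)\n", x$image_id, x$reason))
  } else {
    n <- sum(vapply(x$series, function(s) length(s$distances), numeric(1)))
    cat(sprintf("<scale_result> %s: focus (%.1f, %.1f), %d transect(s), %d circuli\n",
                x$image_id, x$focus$center[1], x$focus$center[2],
                length(x$series), n))
  }
  invisible(x)
}

#' Run the pipeline over a batch of images
#'
#' Applies [process_scale()] to each image. Per-image failures (including a
#' missing focus) are isolated: the batch continues and the failure is
#' recorded in the result's `status`. Given the same images, configuration
#' and backends, output is identical between runs.
#'
#' @param images Character vector of paths, or a named list of rasters.
#' @param config A [pipeline_config()].
#' @return List of `scale_result` objects.
#' @export
run_pipeline <- function(images, config = pipeline_config()) {
  if (length(images) == 0) stop("no images to process")
  ids <- if (is.character(images)) {
    sub("\\.[^.]+$", "", basename(images))
  } else {
    if (is.null(names(images))) {
      sprintf("scale_%03d", seq_along(images))
    } else {
      names(images)
    }
  }
  out <- vector("list", length(images))
  for (i in seq_along(images)) {
    out[[i]] <- tryCatch(
      process_scale(images[[i]], config, image_id = ids[i]),
      error = function(e) {
        structure(list(image_id = ids[i], status = "skipped",
                       reason = conditionMessage(e)),
                  class = "scale_result")
      }
    )
  }
  names(out) <- ids
  out
}

#' Results as a tidy spacing table
#'
#' @param results List of `scale_result`s from [run_pipeline()].
#' @return One data frame of spacings across all processed scales (see
#'   [spacings_table()]).
#' @export
pipeline_spacings <- function(results) {
  rows <- lapply(results, function(r) {
    if (r$status != "processed") return(NULL)
    spacings_table(r$series, scale_id = r$image_id)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- spacings_table(list())
  rownames(out) <- NULL
  out
}

## Draw an axis-aligned box outline into an RGB array (in place, returned).
draw_box <- function(rgb, box, color = c(1, 0, 0), lwd = 1) {
  h <- dim(rgb)[1]
  w <- dim(rgb)[2]
  x1 <- max(1, round(box$x_min) + 1)
  x2 <- min(w, round(box$x_max) + 1)
  y1 <- max(1, round(box$y_min) + 1)
  y2 <- min(h, round(box$y_max) + 1)
  if (x1 > x2 || y1 > y2) return(rgb)
  for (k in 1:3) {
    for (t in seq_len(lwd) - 1) {
      rgb[pmin(pmax(c(y1 + t, y2 - t), 1), h), x1:x2, k] <- color[k]
      rgb[y1:y2, pmin(pmax(c(x1 + t, x2 - t), 1), w), k] <- color[k]
    }
  }
  rgb
}

gray_to_rgb <- function(image) {
  array(rep(pmin(pmax(image, 0), 1), 3), dim = c(dim(image), 3))
}

#' Overlay detection boxes on a transect strip
#'
#' Renders the strip as RGB with ground-truth boxes in green and detections
#' in red, the standard visual check of detector behaviour along a transect.
#'
#' @param transect A transect strip ([extract_transect()]).
#' @param detections Box table in transect coordinates (red).
#' @param ground_truths Optional box table in transect coordinates (green).
#' @return RGB array (height x width x 3).
#' @export
overlay_transect <- function(transect, detections,
                             ground_truths = NULL) {
  rgb <- gray_to_rgb(transect$strip)
  if (!is.null(ground_truths)) {
    for (i in seq_len(nrow(ground_truths))) {
      rgb <- draw_box(rgb, ground_truths[i, ], c(0, 0.8, 0))
    }
  }
  for (i in seq_len(nrow(detections))) {
    rgb <- draw_box(rgb, detections[i, ], c(1, 0, 0))
  }
  rgb
}

#' Diagnostics for one processed scale
#'
#' Produces the per-scale diagnostic artifacts: (a) a table of detection
#' score versus normalized distance from the focus for every transect (the
#' confidence-versus-distance pattern makes weak zones, typically the
#' narrowly spaced freshwater region, visible); (b) transect strips overlaid
#' with detection boxes; (c) a whole-scale overlay with the focus box and
#' transect rays.
#'
#' @param result A processed `scale_result`.
#' @param image The preprocessed raster the result came from.
#' @param out_dir Directory to write into; `NULL` returns artifacts without
#'   writing.
#' @return Invisibly, a list with `score_table` (data frame) and `overlay`
#'   (RGB array); files are written when `out_dir` is given.
#' @export
diagnostics <- function(result, image, out_dir = NULL) {
  stopifnot(inherits(result, "scale_result"))
  if (result$status != "processed") stop("diagnostics need a processed result")
  img <- preprocess(image)

  rows <- lapply(names(result$series), function(key) {
    s <- result$series[[key]]
    if (length(s$distances) == 0) return(NULL)
    data.frame(transect_id = s$transect_id, angle = s$angle,
               distance_px = s$distances,
               normalized_distance = s$distances / max(s$distances),
               score = if (!is.null(s$scores)) s$scores else NA_real_,
               stringsAsFactors = FALSE)
  })
  score_table <- do.call(rbind, rows)
  if (is.null(score_table)) {
    score_table <- data.frame(transect_id = character(), angle = numeric(),
                              distance_px = numeric(),
                              normalized_distance = numeric(),
                              score = numeric(), stringsAsFactors = FALSE)
  }

  overlay <- gray_to_rgb(img)
  overlay <- draw_box(overlay, result$focus$box, c(1, 0.6, 0))
  for (key in names(result$series)) {
    s <- result$series[[key]]
    u <- ray_direction(s$angle)
    len <- transect_length_for_width(result$focus$center, s$angle,
                                     ncol(img), nrow(img), result$width)
    if (len < 2) next
    cols <- seq(0, len - 1)
    xs <- round(result$focus$center[1] + cols * u[1]) + 1
    ys <- round(result$focus$center[2] + cols * u[2]) + 1
    ok <- xs >= 1 & xs <= ncol(img) & ys >= 1 & ys <= nrow(img)
    overlay[cbind(ys[ok], xs[ok], 1)] <- 1
    overlay[cbind(ys[ok], xs[ok], 2)] <- 0.2
    overlay[cbind(ys[ok], xs[ok], 3)] <- 0.2
    # spacing-coloured circuli points along the ray (dark = narrow)
    d <- s$distances
    if (length(d) >= 2) {
      sp <- c(s$spacings[1], s$spacings)
      rel <- (sp - min(sp)) / max(1e-9, diff(range(sp)))
      px <- round(result$focus$center[1] + d * u[1]) + 1
      py <- round(result$focus$center[2] + d * u[2]) + 1
      for (i in seq_along(d)) {
        if (px[i] < 2 || px[i] > ncol(img) - 1 ||
            py[i] < 2 || py[i] > nrow(img) - 1) next
        overlay[py[i] + (-1:1), px[i] + (-1:1), 1] <- 0.3 + 0.7 * rel[i]
        overlay[py[i] + (-1:1), px[i] + (-1:1), 2] <- 0.2 + 0.75 * rel[i]
        overlay[py[i] + (-1:1), px[i] + (-1:1), 3] <- 0.5 - 0.4 * rel[i]
      }
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(score_table,
                     file.path(out_dir, paste0(result$image_id, "_scores.csv")),
                     row.names = FALSE)
    write_scale_image(overlay,
                      file.path(out_dir, paste0(result$image_id, "_overlay.png")))
    for (key in names(result$detections)) {
      det <- result$detections[[key]]
      len <- transect_length_for_width(result$focus$center, as.numeric(key),
                                       ncol(img), nrow(img), result$width)
      if (len < 2) next
      tr <- extract_transect(img, transect_spec(result$focus$center,
                                                as.numeric(key),
                                                result$width, len))
      write_scale_image(
        overlay_transect(tr, det),
        file.path(out_dir, sprintf("%s_a%s_strip.png", result$image_id, key)))
    }
  }
  invisible(list(score_table = score_table, overlay = overlay))
}
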