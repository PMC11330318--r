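#' Detector backend contract
#'
#' A detector backend is any function taking an image raster (numeric matrix,
#' rows = y, columns = x, intensities in `[0, 1]`) and returning a box table
#' ([bbox()]) with a `score` column of confidences in `[0, 1]`. Backends must
#' be pure with respect to their configuration: the same image and the same
#' configuration always yield the same detections. The package ships
#' classical reference backends ([reference_focus_detector()],
#' [reference_circuli_detector()]); externally trained convolutional
#' detectors plug in through the same contract.
#'
#' @param fn A function `image -> box table`.
#' @param name Backend name used in logs and manifests.
#' @return `fn`, classed as `detector_backend`.
#' @export
detector_backend <- function(fn, name = "backend") {
  stopifnot(is.function(fn))
  structure(fn, class = c("detector_backend", "function"), name = name)
}

#' @export
print.detector_backend <- function(x, ...) {
  cat(sprintf("<detector_backend> %s\n", attr(x, "name")))
  invisible(x)
}

#' Filter detections by confidence score
#'
#' Keeps detections whose score is at least `threshold` (inclusive: the
#' threshold is the minimum score required when accepting a detection),
#' preserving input order. Idempotent, and monotone in the threshold.
#'
#' @param detections A box table with a `score` column.
#' @param threshold Minimum score in `[0, 1]`.
#' @return The filtered box table.
#' @export
apply_score_threshold <- function(detections, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (nrow(detections) == 0) return(detections)
  if (anyNA(detections$score)) stop("detections must all carry a score")
  detections[detections$score >= threshold, , drop = FALSE]
}

## Table-1-style defaults for the two pipeline stages.
training_config_defaults <- function(stage = c("focus", "circuli")) {
  stage <- match.arg(stage)
  if (stage == "focus") {
    list(input_height = 1376L, input_width = 1376L, batch_size = 6L,
         epochs = 250L, early_stop_patience = 8L, learning_rate = 0.001,
         schedule_factor = NA_real_, schedule_patience = NA_integer_,
         score_threshold = 0.5, iou_threshold = 0.5)
  } else {
    list(input_height = 64L, input_width = 3904L, batch_size = 8L,
         epochs = 250L, early_stop_patience = 8L, learning_rate = 0.001,
         schedule_factor = 0.66, schedule_patience = 3L,
         score_threshold = 0.3, iou_threshold = 0.5)
  }
}

#' Training configuration for an external detector
#'
#' Holds the settings an externally trained convolutional detector needs to
#' reproduce the pipeline's two stages: the focus detector runs on square
#' 1376 x 1376 inputs with a 0.5 score threshold; the circuli detector runs
#' on wide, short 64 x 3904 transect strips with a 0.3 score threshold. Both
#' stages evaluate at an IOU threshold of 0.5. Training itself is outside
#' this package: the configuration plus the backend contract fully specify
#' what a trained model must provide.
#'
#' @param stage `"focus"` or `"circuli"`; unspecified fields take this
#'   stage's defaults.
#' @param ... Named overrides of the default fields.
#' @return An object of class `training_config`.
#' @export
training_config <- function(stage = c("focus", "circuli"), ...) {
  stage <- match.arg(stage)
  cfg <- training_config_defaults(stage)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown training-config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  cfg$stage <- stage
  for (f in c("batch_size", "epochs", "early_stop_patience",
              "input_height", "input_width")) {
    if (!is.na(cfg[[f]]) && cfg[[f]] <= 0) {
      stop("training-config field '", f, "' must be positive")
    }
  }
  for (f in c("score_threshold", "iou_threshold")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop("training-config field '", f, "' must be in [0, 1]")
    }
  }
  if (!is.na(cfg$learning_rate) && cfg$learning_rate <= 0) {
    stop("training-config field 'learning_rate' must be positive")
  }
  structure(cfg, class = "training_config")
}

#' Load a training configuration from a YAML or JSON file
#'
#' The file may specify any subset of the fields of [training_config()];
#' missing fields take the defaults of the named stage. An empty file is
#' valid and yields the stage defaults.
#'
#' @param path Path to a YAML (`.yml`/`.yaml`) or JSON file.
#' @param stage `"focus"` or `"circuli"`.
#' @return A `training_config`.
#' @export
load_training_config <- function(path, stage = c("focus", "circuli")) {
  stage <- match.arg(stage)
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  do.call(training_config, c(list(stage = stage), raw))
}

#' @export
print.training_config <- function(x, ...) {
  cat(sprintf("<training_config> stage %s: input %d x %d, batch %d, score >= %g, IOU %g\n",
              x$stage, x$input_height, x$input_width, x$batch_size,
              x$score_threshold, x$iou_threshold))
  invisible(x)
}
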