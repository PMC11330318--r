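#' Construct a bounding-box table
#'
#' Axis-aligned boxes in continuous pixel coordinates. The coordinate
#' convention used throughout the package is 0-based with the origin at the
#' top-left image corner: x increases rightwards, y increases downwards.
#' A box set is an ordinary data frame with one row per box, which makes
#' detector outputs, annotations and evaluation inputs interchangeable.
#'
#' @param x_min,y_min,x_max,y_max Numeric vectors of box corners in pixels.
#'   Must satisfy `x_min < x_max` and `y_min < y_max` row-wise.
#' @param label Character vector of class labels (recycled).
#' @param score Optional numeric vector of detection confidences in `[0, 1]`;
#'   `NA` marks an unscored (ground-truth) box.
#' @return A `data.frame` with columns `x_min`, `y_min`, `x_max`, `y_max`,
#'   `label`, `score`.
#' @examples
#' bbox(0, 0, 10, 10, label = "focus", score = 0.9)
#' @export
bbox <- function(x_min = numeric(), y_min = numeric(),
                 x_max = numeric(), y_max = numeric(),
                 label = "object", score = NA_real_) {
  n <- length(x_min)
  recycle <- function(v) {
    if (length(v) == n) return(v)
    if (length(v) == 1) return(rep(v, n))
    stop("box corner vectors must match x_min's length (or have length 1)")
  }
  y_min <- recycle(y_min)
  x_max <- recycle(x_max)
  y_max <- recycle(y_max)
  b <- data.frame(
    x_min = as.numeric(x_min), y_min = as.numeric(y_min),
    x_max = as.numeric(x_max), y_max = as.numeric(y_max),
    label = rep_len(as.character(label), n),
    score = rep_len(as.numeric(score), n),
    stringsAsFactors = FALSE
  )
  validate_bbox(b)
}

#' Validate a bounding-box table
#'
#' Checks the box invariants: positive extent in both axes and, where a score
#' is present, a value in `[0, 1]`.
#'
#' @param boxes A data frame as returned by [bbox()].
#' @return The validated data frame, invisibly unchanged.
#' @export
validate_bbox <- function(boxes) {
  stopifnot(is.data.frame(boxes))
  required <- c("x_min", "y_min", "x_max", "y_max")
  missing <- setdiff(required, names(boxes))
  if (length(missing) > 0) {
    stop("box table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(boxes) > 0) {
    if (any(boxes$x_min >= boxes$x_max) || any(boxes$y_min >= boxes$y_max)) {
      stop("degenerate bounding box: x_min < x_max and y_min < y_max required")
    }
    if ("score" %in% names(boxes)) {
      s <- boxes$score[!is.na(boxes$score)]
      if (any(s < 0 | s > 1)) stop("box scores must lie in [0, 1]")
    }
  }
  boxes
}

#' Box centres
#'
#' @param boxes A box table.
#' @return A two-column matrix of (x, y) centre coordinates.
#' @export
bbox_centers <- function(boxes) {
  cbind(
    x = (boxes$x_min + boxes$x_max) / 2,
    y = (boxes$y_min + boxes$y_max) / 2
  )
}

## Empty box table with the canonical column set.
empty_bbox <- function() bbox()
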