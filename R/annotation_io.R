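#' Image annotation container
#'
#' Bundles the bounding boxes annotated on one image together with the image
#' identity and pixel dimensions, mirroring one Pascal-VOC XML file.
#'
#' @param image_id Image identifier (usually the file stem).
#' @param image_width,image_height Image dimensions in pixels.
#' @param boxes A box table ([bbox()]); boxes are kept in file order.
#' @return An object of class `image_annotation`.
#' @export
image_annotation <- function(image_id, image_width, image_height,
                             boxes = bbox()) {
  stopifnot(is.character(image_id), length(image_id) == 1,
            image_width > 0, image_height > 0)
  validate_bbox(boxes)
  structure(
    list(image_id = image_id,
         image_width = as.numeric(image_width),
         image_height = as.numeric(image_height),
         boxes = boxes),
    class = "image_annotation"
  )
}

#' @export
print.image_annotation <- function(x, ...) {
  cat(sprintf("<image_annotation> %s [%g x %g px], %d box(es)\n",
              x$image_id, x$image_width, x$image_height, nrow(x$boxes)))
  invisible(x)
}

#' Read a Pascal-VOC XML annotation file
#'
#' Parses the VOC dialect written by common labelling tools (one `<object>`
#' element per box with `<name>` and `<bndbox>` children, and a `<size>`
#' block with the image dimensions). Boxes are returned in file order. Boxes
#' that overshoot the image bounds are clamped to the image with a warning;
#' real annotation files routinely contain slight overshoots. An optional
#' `<score>` child of `<object>` (written by [write_annotation()] for
#' detector output) is recovered into the `score` column.
#'
#' @param path Path to the XML file.
#' @return An [image_annotation()].
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed XML in ", path, ": ",
                                           conditionMessage(e)))
  size <- xml2::xml_find_first(doc, "./size")
  if (inherits(size, "xml_missing")) {
    stop("annotation ", path, " is missing the <size> element")
  }
  w <- as.numeric(xml2::xml_text(xml2::xml_find_first(size, "./width")))
  h <- as.numeric(xml2::xml_text(xml2::xml_find_first(size, "./height")))
  if (is.na(w) || is.na(h)) {
    stop("annotation ", path, " has a malformed <size> block (width/height)")
  }
  fname <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  image_id <- if (is.na(fname) || !nzchar(fname)) {
    sub("\\.xml$", "", basename(path))
  } else {
    sub("\\.[^.]+$", "", basename(fname))
  }

  objs <- xml2::xml_find_all(doc, "./object")
  field <- function(node, xp) {
    v <- xml2::xml_find_first(node, xp)
    if (inherits(v, "xml_missing")) NA_real_ else as.numeric(xml2::xml_text(v))
  }
  if (length(objs) == 0) {
    boxes <- bbox()
  } else {
    x_min <- vapply(objs, field, numeric(1), xp = "./bndbox/xmin")
    y_min <- vapply(objs, field, numeric(1), xp = "./bndbox/ymin")
    x_max <- vapply(objs, field, numeric(1), xp = "./bndbox/xmax")
    y_max <- vapply(objs, field, numeric(1), xp = "./bndbox/ymax")
    label <- vapply(objs, function(o) {
      xml2::xml_text(xml2::xml_find_first(o, "./name"))
    }, character(1))
    score <- vapply(objs, field, numeric(1), xp = "./score")
    if (anyNA(x_min) || anyNA(y_min) || anyNA(x_max) || anyNA(y_max)) {
      stop("annotation ", path, " has an <object> with a malformed <bndbox>")
    }
    clamped_x <- x_min < 0 | x_max > w
    clamped_y <- y_min < 0 | y_max > h
    if (any(clamped_x | clamped_y)) {
      warning(sprintf("%d box(es) in %s exceed image bounds; clamped",
                      sum(clamped_x | clamped_y), basename(path)))
    }
    boxes <- bbox(pmax(x_min, 0), pmax(y_min, 0),
                  pmin(x_max, w), pmin(y_max, h),
                  label = label, score = score)
  }
  image_annotation(image_id, w, h, boxes)
}

#' Write a Pascal-VOC XML annotation file
#'
#' Emits XML in the dialect understood by [read_annotation()] and common
#' labelling tools. Scores, when present, are serialized as an auxiliary
#' `<score>` element (VOC has no standard slot for confidences) and are
#' recovered on read.
#'
#' @param annotation An [image_annotation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "image_annotation"))
  validate_bbox(annotation$boxes)
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", paste0(annotation$image_id, ".png"))
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", format(annotation$image_width))
  xml2::xml_add_child(size, "height", format(annotation$image_height))
  xml2::xml_add_child(size, "depth", "1")
  b <- annotation$boxes
  num <- function(v) format(v, digits = 15, scientific = FALSE, trim = TRUE)
  for (i in seq_len(nrow(b))) {
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "name", b$label[i])
    if ("score" %in% names(b) && !is.na(b$score[i])) {
      xml2::xml_add_child(obj, "score", num(b$score[i]))
    }
    bb <- xml2::xml_add_child(obj, "bndbox")
    xml2::xml_add_child(bb, "xmin", num(b$x_min[i]))
    xml2::xml_add_child(bb, "ymin", num(b$y_min[i]))
    xml2::xml_add_child(bb, "xmax", num(b$x_max[i]))
    xml2::xml_add_child(bb, "ymax", num(b$y_max[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Split image ids into train/validation/test sets
#'
#' Ids are shuffled with a seeded generator and partitioned. The train and
#' validation counts are obtained by half-up rounding of `fraction * n`; the
#' test set takes the remainder. With 1035 ids and fractions 70:20:10 this
#' yields 725/207/103.
#'
#' @param ids Character vector of image ids (non-empty, duplicates not
#'   allowed).
#' @param fractions Numeric triple `(train, validation, test)` summing to 1.
#' @param seed Integer seed making the split reproducible.
#' @return An object of class `dataset_split` with elements `train_ids`,
#'   `val_ids`, `test_ids` and `seed`.
#' @examples
#' split_dataset(sprintf("scale_%04d", 1:10), c(0.7, 0.2, 0.1), seed = 1)
#' @export
split_dataset <- function(ids, fractions = c(0.7, 0.2, 0.1), seed = 1L) {
  if (length(ids) == 0) stop("cannot split an empty id set")
  if (anyDuplicated(ids)) stop("duplicate ids in input")
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be three non-negative numbers summing to 1")
  }
  n <- length(ids)
  # round-half-up: floor(x + 0.5); R's round() would round half to even
  n_train <- min(n, floor(fractions[1] * n + 0.5))
  n_val <- min(n - n_train, floor(fractions[2] * n + 0.5))
  perm <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
    sample.int(n)
  })
  ids <- ids[perm]
  structure(
    list(train_ids = ids[seq_len(n_train)],
         val_ids = ids[seq_len(n_val) + n_train],
         test_ids = ids[setdiff(seq_len(n), seq_len(n_train + n_val))],
         seed = as.integer(seed)),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train %d / val %d / test %d (seed %d)\n",
              length(x$train_ids), length(x$val_ids), length(x$test_ids),
              x$seed))
  invisible(x)
}
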