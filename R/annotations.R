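#' @keywords internal
"_PACKAGE"

ANNOTATION_GROUPS <- c("model", "expert", "nonexpert")
ANNOTATION_LABELS <- c("live", "dead", "unknown")

annotation_columns <- c(
  "image_id", "annotator_id", "group",
  "x_min", "y_min", "x_max", "y_max",
  "label", "confidence"
)

#' Assemble an annotation table
#'
#' Builds the canonical annotation table used throughout the package: one row
#' per bounding box drawn by one annotator on one image. Boxes are axis-aligned
#' in pixel coordinates with the origin at the top-left corner. Human
#' annotators (`group` `"expert"` or `"nonexpert"`) label each box `"live"`,
#' `"dead"` or `"unknown"`; the detection model (`group` `"model"`) emits only
#' `"live"` boxes, each with a confidence in (0, 1].
#'
#' @param image_id,annotator_id character vectors (recycled to common length).
#' @param group one of `"model"`, `"expert"`, `"nonexpert"`.
#' @param x_min,y_min,x_max,y_max box corners in pixels; `x_min < x_max`,
#'   `y_min < y_max`, all finite and non-negative.
#' @param label `"live"`, `"dead"` or `"unknown"`; `"live"` forced for model.
#' @param confidence model detection confidence in \[0, 1\]; must be `NA` for
#'   human annotators and present for model annotations.
#' @return a [tibble::tibble] with the canonical annotation columns.
#' @export
annotations <- function(image_id, annotator_id, group,
                        x_min, y_min, x_max, y_max,
                        label, confidence = NA_real_) {
  out <- tibble::tibble(
    image_id = as.character(image_id),
    annotator_id = as.character(annotator_id),
    group = as.character(group),
    x_min = as.numeric(x_min), y_min = as.numeric(y_min),
    x_max = as.numeric(x_max), y_max = as.numeric(y_max),
    label = as.character(label),
    confidence = as.numeric(confidence)
  )
  validate_annotations(out)
  out
}

empty_annotations <- function() {
  tibble::tibble(
    image_id = character(), annotator_id = character(), group = character(),
    x_min = numeric(), y_min = numeric(), x_max = numeric(), y_max = numeric(),
    label = character(), confidence = numeric()
  )
}

#' Validate an annotation table
#'
#' Checks the structural invariants of the annotation table: required columns,
#' valid groups and labels, well-formed boxes (`x_min < x_max`,
#' `y_min < y_max`, finite, non-negative), and the model contract (model rows
#' are `"live"` with a confidence in \[0, 1\]; human rows carry no confidence).
#'
#' @param x a data frame of annotations.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_annotations <- function(x) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(setdiff(annotation_columns, "confidence"), names(x))
  if (length(missing_cols) > 0) {
    stop("annotation table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(x) == 0) return(invisible(x))
  bad_group <- !x$group %in% ANNOTATION_GROUPS
  if (any(bad_group)) {
    stop("unknown annotator group(s): ",
         paste(unique(x$group[bad_group]), collapse = ", "), call. = FALSE)
  }
  bad_label <- !x$label %in% ANNOTATION_LABELS
  if (any(bad_label)) {
    stop("unknown class label(s): ",
         paste(unique(x$label[bad_label]), collapse = ", "), call. = FALSE)
  }
  coords <- as.matrix(x[, c("x_min", "y_min", "x_max", "y_max")])
  if (!all(is.finite(coords)) || any(coords < 0)) {
    stop("box coordinates must be finite and >= 0", call. = FALSE)
  }
  if (any(x$x_min >= x$x_max) || any(x$y_min >= x$y_max)) {
    stop("degenerate boxes: require x_min < x_max and y_min < y_max",
         call. = FALSE)
  }
  conf <- if ("confidence" %in% names(x)) x$confidence else rep(NA_real_, nrow(x))
  is_model <- x$group == "model"
  if (any(is_model & x$label != "live")) {
    stop("model annotations must be labelled 'live'", call. = FALSE)
  }
  if (any(is_model & (is.na(conf) | conf < 0 | conf > 1))) {
    stop("model annotations require a confidence in [0, 1]", call. = FALSE)
  }
  if (any(!is_model & !is.na(conf))) {
    stop("human annotations must not carry a model confidence", call. = FALSE)
  }
  invisible(x)
}

#' Assemble an image metadata table
#'
#' One row per surveyed image with its interpretability quality score (QS),
#' an integer grade from 0 (no visibility of the features of interest) to 4
#' (exceptional quality throughout the frame).
#'
#' @param image_id character vector of unique image identifiers.
#' @param quality_score integer vector in `0:4`.
#' @return a [tibble::tibble] with columns `image_id`, `quality_score`.
#' @export
image_records <- function(image_id, quality_score) {
  out <- tibble::tibble(
    image_id = as.character(image_id),
    quality_score = as.integer(quality_score)
  )
  validate_images(out)
  out
}

#' @rdname image_records
#' @param x a data frame of image records.
#' @export
validate_images <- function(x) {
  stopifnot(is.data.frame(x))
  if (!all(c("image_id", "quality_score") %in% names(x))) {
    stop("image table needs columns image_id, quality_score", call. = FALSE)
  }
  if (anyDuplicated(x$image_id)) {
    stop("image_id values must be unique", call. = FALSE)
  }
  if (nrow(x) > 0 && !all(x$quality_score %in% 0:4)) {
    stop("quality_score must be an integer in 0..4", call. = FALSE)
  }
  invisible(x)
}

#' Apply the study's admission filters
#'
#' Drops annotations on images whose quality score is below 2 (scores 0 and 1
#' mark uninterpretable imagery) and drops model detections whose confidence
#' does not exceed `model_cutoff` (the cutoff is strict: a confidence exactly
#' equal to the cutoff is dropped). Human annotations are never filtered by
#' confidence. Row order is preserved and the operation is idempotent.
#'
#' @param annotations annotation table (see [annotations()]).
#' @param images image metadata table (see [image_records()]); every
#'   annotation's `image_id` must appear here.
#' @param model_cutoff minimum (exclusive) model confidence; default 0.5.
#' @return the filtered annotation table.
#' @export
filter_admissible <- function(annotations, images, model_cutoff = 0.5) {
  validate_annotations(annotations)
  validate_images(images)
  orphans <- setdiff(unique(annotations$image_id), images$image_id)
  if (length(orphans) > 0) {
    stop("annotations reference image_id(s) absent from metadata: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  if (nrow(annotations) == 0) return(annotations)
  qs <- images$quality_score[match(annotations$image_id, images$image_id)]
  keep_qs <- qs >= 2
  is_model <- annotations$group == "model"
  keep_conf <- !is_model | (annotations$confidence > model_cutoff)
  annotations[keep_qs & keep_conf, , drop = FALSE]
}
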