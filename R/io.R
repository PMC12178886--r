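#' Read bounding-box annotations
#'
#' Reads one annotation file in any of the three supported dialects and
#' normalizes it to the canonical annotation table (pixel coordinates, origin
#' top-left, `x_min < x_max`, `y_min < y_max`). Record order is preserved.
#'
#' Dialects:
#' \describe{
#'   \item{`csv`}{columns `image_id,annotator_id,group,x_min,y_min,x_max,
#'     y_max,label` with an optional ninth column `confidence`. This schema is
#'     defined by this package and is frozen.}
#'   \item{`coco_json`}{standard COCO keys `images` / `annotations` /
#'     `categories`; boxes are `[x, y, width, height]`. Each annotation may
#'     carry `annotator_id`, `group` and `score` fields (written by
#'     [write_annotations()]); otherwise supply `annotator_id` and `group`.}
#'   \item{`yolo_txt`}{one file per (image, annotator): lines
#'     `class cx cy w h [confidence]` with coordinates normalized to the image
#'     size. Requires `image_id`, `annotator_id`, `group`, a `class_map`
#'     (class index -> label) and the image pixel dimensions.}
#' }
#'
#' @param path file to read.
#' @param dialect one of `"csv"`, `"coco_json"`, `"yolo_txt"`.
#' @param class_map named character vector mapping class index (as character)
#'   to label, e.g. `c("0" = "live", "1" = "dead", "2" = "unknown")`.
#'   Required for `yolo_txt`.
#' @param image_id,annotator_id,group metadata for dialects that do not encode
#'   them in the file (`yolo_txt` always; `coco_json` when the fields are
#'   absent from the records).
#' @param image_width,image_height image pixel dimensions, required for
#'   `yolo_txt`.
#' @return an annotation table (see [annotations()]).
#' @seealso [write_annotations()], [filter_admissible()]
#' @export
read_annotations <- function(path,
                             dialect = c("csv", "coco_json", "yolo_txt"),
                             class_map = NULL,
                             image_id = NULL, annotator_id = NULL,
                             group = NULL,
                             image_width = NULL, image_height = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  out <- switch(dialect,
    csv = read_annotations_csv(path),
    coco_json = read_annotations_coco(path, annotator_id, group),
    yolo_txt = read_annotations_yolo(path, class_map, image_id, annotator_id,
                                     group, image_width, image_height)
  )
  validate_annotations(out)
  out
}

read_annotations_csv <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (nrow(raw) == 0) return(empty_annotations())
  needed <- c("image_id", "annotator_id", "group",
              "x_min", "y_min", "x_max", "y_max", "label")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("csv dialect: ", path, " is missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & nzchar(raw[[col]]))
    if (length(bad) > 0 || anyNA(v)) {
      idx <- if (length(bad) > 0) bad[1] else which(is.na(v))[1]
      stop("csv dialect: malformed numeric field '", col, "' in ", path,
           " at record ", idx, call. = FALSE)
    }
    v
  }
  conf <- if ("confidence" %in% names(raw)) {
    suppressWarnings(as.numeric(raw$confidence))
  } else {
    rep(NA_real_, nrow(raw))
  }
  annotations(
    image_id = raw$image_id, annotator_id = raw$annotator_id,
    group = raw$group,
    x_min = num("x_min"), y_min = num("y_min"),
    x_max = num("x_max"), y_max = num("y_max"),
    label = raw$label, confidence = conf
  )
}

read_annotations_coco <- function(path, annotator_id, group) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("coco_json dialect: cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(doc$annotations) || length(doc$annotations) == 0) {
    return(empty_annotations())
  }
  cats <- vapply(doc$categories, function(c) as.character(c$name), "")
  names(cats) <- vapply(doc$categories, function(c) as.character(c$id), "")
  img_names <- vapply(doc$images, function(im) {
    as.character(if (!is.null(im$file_name)) im$file_name else im$id)
  }, "")
  names(img_names) <- vapply(doc$images, function(im) as.character(im$id), "")
  rows <- lapply(seq_along(doc$annotations), function(i) {
    a <- doc$annotations[[i]]
    if (is.null(a$bbox) || length(a$bbox) != 4) {
      stop("coco_json dialect: malformed bbox in ", path, " at record ", i,
           call. = FALSE)
    }
    bb <- as.numeric(a$bbox)
    lab <- cats[[as.character(a$category_id)]]
    if (is.null(lab)) {
      stop("coco_json dialect: unknown category_id in ", path, " at record ",
           i, call. = FALSE)
    }
    tibble::tibble(
      image_id = img_names[[as.character(a$image_id)]],
      annotator_id = as.character(
        if (!is.null(a$annotator_id)) a$annotator_id else annotator_id),
      group = as.character(if (!is.null(a$group)) a$group else group),
      x_min = bb[1], y_min = bb[2],
      x_max = bb[1] + bb[3], y_max = bb[2] + bb[4],
      label = lab,
      confidence = if (!is.null(a$score)) as.numeric(a$score) else NA_real_
    )
  })
  do.call(rbind, rows)
}

read_annotations_yolo <- function(path, class_map, image_id, annotator_id,
                                  group, image_width, image_height) {
  if (is.null(image_width) || is.null(image_height)) {
    stop("yolo_txt dialect requires image_width and image_height",
         call. = FALSE)
  }
  if (is.null(class_map)) {
    stop("yolo_txt dialect requires a class_map (index -> label)",
         call. = FALSE)
  }
  if (is.null(image_id) || is.null(annotator_id) || is.null(group)) {
    stop("yolo_txt dialect requires image_id, annotator_id and group",
         call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_annotations())
  rows <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (!length(parts) %in% c(5, 6)) {
      stop("yolo_txt dialect: malformed line ", i, " in ", path, call. = FALSE)
    }
    lab <- class_map[[parts[1]]]
    if (is.null(lab) || is.na(lab)) {
      stop("yolo_txt dialect: class index '", parts[1],
           "' not in class_map (", path, ", line ", i, ")", call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(parts[2:5]))
    if (anyNA(v)) {
      stop("yolo_txt dialect: malformed coordinates at line ", i, " in ",
           path, call. = FALSE)
    }
    cx <- v[1] * image_width; cy <- v[2] * image_height
    w <- v[3] * image_width;  h <- v[4] * image_height
    tibble::tibble(
      image_id = as.character(image_id),
      annotator_id = as.character(annotator_id),
      group = as.character(group),
      x_min = cx - w / 2, y_min = cy - h / 2,
      x_max = cx + w / 2, y_max = cy + h / 2,
      label = lab,
      confidence = if (length(parts) == 6) as.numeric(parts[6]) else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Write bounding-box annotations
#'
#' Writes an annotation table in any supported dialect so that
#' [read_annotations()] recovers it (exactly for `csv` and `coco_json`; within
#' 0.5 px for `yolo_txt`, which stores normalized coordinates).
#'
#' @inheritParams read_annotations
#' @param annotations annotation table to write.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path,
                              dialect = c("csv", "coco_json", "yolo_txt"),
                              class_map = NULL,
                              image_width = NULL, image_height = NULL) {
  dialect <- match.arg(dialect)
  validate_annotations(annotations)
  if (!"confidence" %in% names(annotations)) {
    annotations$confidence <- NA_real_
  }
  switch(dialect,
    csv = {
      utils::write.csv(annotations[, annotation_columns], path,
                       row.names = FALSE, quote = FALSE, na = "")
    },
    coco_json = write_annotations_coco(annotations, path),
    yolo_txt = write_annotations_yolo(annotations, path, class_map,
                                      image_width, image_height)
  )
  invisible(path)
}

write_annotations_coco <- function(annotations, path) {
  img_ids <- unique(annotations$image_id)
  images <- lapply(seq_along(img_ids), function(i) {
    list(id = i, file_name = img_ids[i])
  })
  labs <- ANNOTATION_LABELS
  categories <- lapply(seq_along(labs), function(i) {
    list(id = i, name = labs[i])
  })
  anns <- lapply(seq_len(nrow(annotations)), function(i) {
    r <- annotations[i, ]
    a <- list(
      id = i,
      image_id = match(r$image_id, img_ids),
      category_id = match(r$label, labs),
      bbox = c(r$x_min, r$y_min, r$x_max - r$x_min, r$y_max - r$y_min),
      annotator_id = r$annotator_id,
      group = r$group
    )
    if (!is.na(r$confidence)) a$score <- r$confidence
    a
  })
  jsonlite::write_json(
    list(images = images, annotations = anns, categories = categories),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

write_annotations_yolo <- function(annotations, path, class_map,
                                   image_width, image_height) {
  if (is.null(image_width) || is.null(image_height)) {
    stop("yolo_txt dialect requires image_width and image_height",
         call. = FALSE)
  }
  if (is.null(class_map)) {
    stop("yolo_txt dialect requires a class_map (index -> label)",
         call. = FALSE)
  }
  if (length(unique(annotations$image_id)) > 1 ||
      length(unique(annotations$annotator_id)) > 1) {
    stop("yolo_txt files hold one image and one annotator each", call. = FALSE)
  }
  inv_map <- stats::setNames(names(class_map), class_map)
  if (nrow(annotations) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  missing_lab <- setdiff(unique(annotations$label), names(inv_map))
  if (length(missing_lab) > 0) {
    stop("class_map has no index for label(s): ",
         paste(missing_lab, collapse = ", "), call. = FALSE)
  }
  cx <- (annotations$x_min + annotations$x_max) / 2 / image_width
  cy <- (annotations$y_min + annotations$y_max) / 2 / image_height
  w <- (annotations$x_max - annotations$x_min) / image_width
  h <- (annotations$y_max - annotations$y_min) / image_height
  conf <- ifelse(is.na(annotations$confidence), "",
                 sprintf(" %.9f", annotations$confidence))
  lines <- sprintf("%s %.9f %.9f %.9f %.9f%s",
                   inv_map[annotations$label], cx, cy, w, h, conf)
  writeLines(lines, path)
  invisible(path)
}

#' Read image metadata
#'
#' Reads the image metadata CSV (`image_id,quality_score`).
#'
#' @param path CSV file path.
#' @return an image record table (see [image_records()]).
#' @export
read_image_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (!all(c("image_id", "quality_score") %in% names(raw))) {
    stop("metadata csv needs columns image_id,quality_score", call. = FALSE)
  }
  image_records(raw$image_id, as.integer(raw$quality_score))
}

#' @rdname read_image_metadata
#' @param images image record table to write.
#' @export
write_image_metadata <- function(images, path) {
  validate_images(images)
  utils::write.csv(images, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
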