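#' Configuration for the synthetic multi-annotator generator
#'
#' Parameterizes the annotation-generating process the package uses in place
#' of field data: a set of survey images graded by quality score (QS), true
#' objects scattered on each image, and three rater tiers — one detection
#' model emitting live-only boxes with a confidence, and two human groups —
#' each with its own detection probability, label-confusion behaviour, false
#' positive rate, and localization jitter. QS modulates detection and jitter
#' through per-level multipliers. True object classes are only `live` or
#' `dead`: "unknown" is a reporting outcome (a column of the confusion
#' matrices), not a state of nature.
#'
#' The defaults emulate the study design this package was built around:
#' 150 images with QS drawn over \{2, 3, 4\} in proportions 54/75/21, about a
#' dozen objects per image, and 1 model + 5 expert + 5 non-expert raters whose
#' skill parameters are plausibility choices calibrated so per-image
#' label counts land near the reported per-group means (model ~4 live boxes
#' per image; experts ~2.8 live / 3.1 dead / 3.5 unknown; non-experts lower
#' live and dead but more unknown).
#'
#' @param n_images number of images.
#' @param qs_probs probabilities of quality scores 2, 3, 4 (named "2","3","4",
#'   summing to 1).
#' @param objects_per_image Poisson mean of true objects per image.
#' @param class_mix probabilities of true classes `live`, `dead` (sums to 1).
#' @param image_width,image_height image size in pixels.
#' @param box_size_range min/max true box edge length in pixels.
#' @param groups list of rater-tier settings; each element has
#'   `n_annotators`, `detection_prob`, `label_confusion` (2x3 row-stochastic
#'   matrix, rows = true `live`/`dead`, cols = reported
#'   `live`/`dead`/`unknown`; ignored for the model tier, which always reports
#'   `live`), `fp_rate` (mean spurious boxes per image per rater),
#'   `fp_label_probs` (label distribution of spurious human boxes) and
#'   `jitter_sd` (pixel s.d. of corner noise).
#' @param qs_effect list with numeric vectors `detect` and `jitter`, named by
#'   QS level, multiplying each tier's detection probability (capped at 1)
#'   and jitter s.d. on images of that QS.
#' @param seed integer seed; the generator derives one substream per image so
#'   images are independently reproducible.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(
    n_images = 150,
    qs_probs = c("2" = 54 / 150, "3" = 75 / 150, "4" = 21 / 150),
    objects_per_image = 12,
    class_mix = c(live = 0.55, dead = 0.45),
    image_width = 1920, image_height = 1080,
    box_size_range = c(40, 160),
    groups = default_groups(),
    qs_effect = list(detect = c("2" = 0.8, "3" = 1.0, "4" = 1.1),
                     jitter = c("2" = 1.5, "3" = 1.0, "4" = 0.7)),
    seed = 1L) {
  for (g in names(groups)) {
    if (!is.null(groups[[g]]$label_confusion)) {
      dimnames(groups[[g]]$label_confusion) <-
        list(c("live", "dead"), ANNOTATION_LABELS)
    }
  }
  cfg <- list(
    n_images = as.integer(n_images), qs_probs = qs_probs,
    objects_per_image = objects_per_image, class_mix = class_mix,
    image_width = image_width, image_height = image_height,
    box_size_range = box_size_range, groups = groups, qs_effect = qs_effect,
    seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

default_groups <- function() {
  list(
    model = list(
      n_annotators = 1, detection_prob = 0.30,
      label_confusion = NULL,  # live-only
      fp_rate = 1.0, fp_label_probs = c(live = 1, dead = 0, unknown = 0),
      jitter_sd = 4
    ),
    expert = list(
      n_annotators = 5, detection_prob = 0.75,
      label_confusion = matrix(c(0.65, 0.10, 0.25,
                                 0.08, 0.62, 0.30), 2, 3, byrow = TRUE,
                               dimnames = list(c("live", "dead"),
                                               ANNOTATION_LABELS)),
      fp_rate = 0.4, fp_label_probs = c(live = 0.3, dead = 0.3, unknown = 0.4),
      jitter_sd = 3
    ),
    nonexpert = list(
      n_annotators = 5, detection_prob = 0.70,
      label_confusion = matrix(c(0.45, 0.12, 0.43,
                                 0.08, 0.45, 0.47), 2, 3, byrow = TRUE,
                               dimnames = list(c("live", "dead"),
                                               ANNOTATION_LABELS)),
      fp_rate = 0.3, fp_label_probs = c(live = 0.2, dead = 0.3, unknown = 0.5),
      jitter_sd = 6
    )
  )
}

validate_synthetic_config <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid synthetic config field '", field, "': ", why, call. = FALSE)
  }
  if (is.na(cfg$n_images) || cfg$n_images < 1) fail("n_images", "must be >= 1")
  if (length(cfg$qs_probs) != 3 ||
      !isTRUE(all.equal(sum(cfg$qs_probs), 1)) || any(cfg$qs_probs < 0)) {
    fail("qs_probs", "need 3 non-negative probabilities summing to 1")
  }
  if (!setequal(names(cfg$qs_probs), c("2", "3", "4"))) {
    fail("qs_probs", "must be named '2','3','4'")
  }
  if (cfg$objects_per_image < 0) fail("objects_per_image", "must be >= 0")
  if (length(cfg$class_mix) != 2 || any(cfg$class_mix < 0) ||
      !isTRUE(all.equal(sum(cfg$class_mix), 1)) ||
      !setequal(names(cfg$class_mix), c("live", "dead"))) {
    fail("class_mix", "need probabilities named live, dead summing to 1")
  }
  if (cfg$image_width <= 0 || cfg$image_height <= 0) {
    fail("image_width/image_height", "must be positive")
  }
  if (length(cfg$box_size_range) != 2 || cfg$box_size_range[1] <= 0 ||
      diff(cfg$box_size_range) < 0) {
    fail("box_size_range", "need 0 < min <= max")
  }
  if (!setequal(names(cfg$groups), ANNOTATION_GROUPS)) {
    fail("groups", "must have entries model, expert, nonexpert")
  }
  for (g in names(cfg$groups)) {
    gr <- cfg$groups[[g]]
    if (gr$n_annotators < 1) fail(paste0("groups$", g), "n_annotators >= 1")
    if (gr$detection_prob < 0 || gr$detection_prob > 1) {
      fail(paste0("groups$", g), "detection_prob must lie in [0, 1]")
    }
    if (gr$fp_rate < 0) fail(paste0("groups$", g), "fp_rate must be >= 0")
    if (gr$jitter_sd < 0) fail(paste0("groups$", g), "jitter_sd must be >= 0")
    if (g != "model") {
      lc <- gr$label_confusion
      if (!is.matrix(lc) || !all(dim(lc) == c(2, 3)) || any(lc < 0) ||
          !isTRUE(all.equal(unname(rowSums(lc)), c(1, 1)))) {
        fail(paste0("groups$", g, "$label_confusion"),
             "need a 2x3 row-stochastic matrix")
      }
    }
  }
  for (part in c("detect", "jitter")) {
    v <- cfg$qs_effect[[part]]
    if (length(v) != 3 || !setequal(names(v), c("2", "3", "4")) || any(v < 0)) {
      fail(paste0("qs_effect$", part),
           "need non-negative multipliers named '2','3','4'")
    }
  }
  invisible(cfg)
}

# deterministic 32-bit substream seed per image
image_substream_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + i * 16807) %% 2147483647
}

#' Generate a synthetic multi-annotator dataset
#'
#' Draws images, true objects and per-rater annotations under a
#' [synthetic_config()]. For each true object and rater, the object is
#' detected with probability `detection_prob` times the QS multiplier; a
#' detected object's reported label is drawn from the rater tier's confusion
#' row (the model always reports `live` with a confidence uniform on
#' (0.5, 1\]); the reported box jitters each true corner with Gaussian noise.
#' Each rater also adds Poisson(`fp_rate`) spurious boxes per image, placed by
#' rejection sampling to overlap no true object beyond IoU 0.1 so ground-truth
#' linkage stays unambiguous. Identical seeds give identical output.
#'
#' @param config a [synthetic_config()].
#' @return a list:
#'   `annotations` (canonical annotation table plus an `annotation_id`
#'   column), `images` (image records), and `ledger` — a list of `objects`
#'   (`image_id`, `object_id`, `true_class`, box) and `links` (`annotation_id`
#'   -> `object_id`, `spurious` flag).
#' @export
generate_annotations <- function(config) {
  validate_synthetic_config(config)
  cfg <- config
  set.seed(cfg$seed)
  qs_levels <- c(2L, 3L, 4L)
  image_ids <- sprintf("img%04d", seq_len(cfg$n_images))
  qs <- sample(qs_levels, cfg$n_images, replace = TRUE,
               prob = cfg$qs_probs[c("2", "3", "4")])
  images <- image_records(image_ids, qs)
  annotator_ids <- unlist(lapply(ANNOTATION_GROUPS, function(g) {
    sprintf("%s%d", g, seq_len(cfg$groups[[g]]$n_annotators))
  }))
  annotator_groups <- rep(ANNOTATION_GROUPS,
                          vapply(cfg$groups, function(g) g$n_annotators, 1)[
                            ANNOTATION_GROUPS])
  obj_list <- vector("list", cfg$n_images)
  ann_list <- vector("list", cfg$n_images)
  link_list <- vector("list", cfg$n_images)
  for (i in seq_len(cfg$n_images)) {
    set.seed(image_substream_seed(cfg$seed, i))
    img <- image_ids[i]
    qmult_d <- cfg$qs_effect$detect[[as.character(qs[i])]]
    qmult_j <- cfg$qs_effect$jitter[[as.character(qs[i])]]
    objs <- place_true_objects(cfg, img)
    obj_list[[i]] <- objs
    per_rater <- lapply(seq_along(annotator_ids), function(a) {
      simulate_rater(cfg, objs, img,
                     annotator_id = annotator_ids[a],
                     group = annotator_groups[a],
                     qmult_d = qmult_d, qmult_j = qmult_j)
    })
    per_rater <- per_rater[vapply(per_rater, nrow, 1L) > 0]
    if (length(per_rater) > 0) {
      block <- do.call(rbind, per_rater)
      ann_list[[i]] <- block[, setdiff(names(block), c("object_id", "spurious")),
                             drop = FALSE]
      link_list[[i]] <- block[, c("image_id", "annotator_id", "object_id",
                                  "spurious"), drop = FALSE]
    }
  }
  objects <- do.call(rbind, obj_list)
  keep <- !vapply(ann_list, is.null, TRUE)
  if (any(keep)) {
    anns <- do.call(rbind, ann_list[keep])
    links <- do.call(rbind, link_list[keep])
    anns$annotation_id <- sprintf("a%06d", seq_len(nrow(anns)))
    links$annotation_id <- anns$annotation_id
    links <- links[, c("annotation_id", "image_id", "annotator_id",
                       "object_id", "spurious")]
  } else {
    anns <- empty_annotations()
    anns$annotation_id <- character()
    links <- tibble::tibble(annotation_id = character(), image_id = character(),
                            annotator_id = character(), object_id = character(),
                            spurious = logical())
  }
  validate_annotations(anns)
  list(annotations = anns, images = images,
       ledger = list(objects = objects, links = links,
                     annotators = tibble::tibble(annotator_id = annotator_ids,
                                                 group = annotator_groups)))
}

place_true_objects <- function(cfg, img) {
  n_obj <- stats::rpois(1, cfg$objects_per_image)
  if (n_obj == 0) {
    return(tibble::tibble(image_id = character(), object_id = character(),
                          true_class = character(), x_min = numeric(),
                          y_min = numeric(), x_max = numeric(),
                          y_max = numeric()))
  }
  boxes <- matrix(NA_real_, 0, 4)
  for (j in seq_len(n_obj)) {
    for (try in seq_len(200)) {
      w <- stats::runif(1, cfg$box_size_range[1], cfg$box_size_range[2])
      h <- stats::runif(1, cfg$box_size_range[1], cfg$box_size_range[2])
      x <- stats::runif(1, 0, cfg$image_width - w)
      y <- stats::runif(1, 0, cfg$image_height - h)
      cand <- c(x, y, x + w, y + h)
      ok <- nrow(boxes) == 0 ||
        all(apply(boxes, 1, function(b) iou(b, cand)) <= 0.3)
      if (ok) {
        boxes <- rbind(boxes, cand)
        break
      }
    }
  }
  n_placed <- nrow(boxes)
  cls <- sample(c("live", "dead"), n_placed, replace = TRUE,
                prob = cfg$class_mix[c("live", "dead")])
  tibble::tibble(
    image_id = img,
    object_id = sprintf("%s/obj%02d", img, seq_len(n_placed)),
    true_class = cls,
    x_min = boxes[, 1], y_min = boxes[, 2],
    x_max = boxes[, 3], y_max = boxes[, 4]
  )
}

simulate_rater <- function(cfg, objs, img, annotator_id, group,
                           qmult_d, qmult_j) {
  gr <- cfg$groups[[group]]
  d <- min(1, gr$detection_prob * qmult_d)
  jit <- gr$jitter_sd * qmult_j
  boxes <- matrix(numeric(), 0, 4)
  labels <- character()
  conf <- numeric()
  object_id <- character()
  spurious <- logical()
  if (nrow(objs) > 0) {
    hit <- which(stats::runif(nrow(objs)) < d)
    if (length(hit) > 0) {
      tb <- as.matrix(objs[hit, c("x_min", "y_min", "x_max", "y_max")])
      jb <- t(vapply(seq_len(nrow(tb)), function(j) {
        jitter_box(tb[j, ], jit, cfg$image_width, cfg$image_height)
      }, numeric(4)))
      if (group == "model") {
        lab <- rep("live", length(hit))
        cf <- stats::runif(length(hit), 0.5, 1)
      } else {
        lab <- vapply(hit, function(j) {
          row <- match(objs$true_class[j], c("live", "dead"))
          sample(ANNOTATION_LABELS, 1, prob = gr$label_confusion[row, ])
        }, "")
        cf <- rep(NA_real_, length(hit))
      }
      boxes <- rbind(boxes, jb)
      labels <- c(labels, lab)
      conf <- c(conf, cf)
      object_id <- c(object_id, objs$object_id[hit])
      spurious <- c(spurious, rep(FALSE, length(hit)))
    }
  }
  n_fp <- stats::rpois(1, gr$fp_rate)
  for (f in seq_len(n_fp)) {
    b <- place_spurious_box(cfg, objs)
    if (is.null(b)) next
    boxes <- rbind(boxes, b)
    labels <- c(labels,
                if (group == "model") "live" else
                  sample(ANNOTATION_LABELS, 1,
                         prob = gr$fp_label_probs[ANNOTATION_LABELS]))
    conf <- c(conf,
              if (group == "model") stats::runif(1, 0.5, 1) else NA_real_)
    object_id <- c(object_id, NA_character_)
    spurious <- c(spurious, TRUE)
  }
  if (length(labels) == 0) {
    out <- empty_annotations()
    out$object_id <- character(); out$spurious <- logical()
    return(out)
  }
  tibble::tibble(
    image_id = img, annotator_id = annotator_id, group = group,
    x_min = boxes[, 1], y_min = boxes[, 2],
    x_max = boxes[, 3], y_max = boxes[, 4],
    label = labels, confidence = conf,
    object_id = object_id, spurious = spurious
  )
}

jitter_box <- function(b, sd, width, height) {
  if (sd > 0) b <- b + stats::rnorm(4, 0, sd)
  x <- sort(c(max(0, min(b[1], width - 1)), max(1, min(b[3], width))))
  y <- sort(c(max(0, min(b[2], height - 1)), max(1, min(b[4], height))))
  if (x[2] - x[1] < 1) x[2] <- x[1] + 1
  if (y[2] - y[1] < 1) y[2] <- y[1] + 1
  c(x[1], y[1], x[2], y[2])
}

place_spurious_box <- function(cfg, objs) {
  for (try in seq_len(100)) {
    w <- stats::runif(1, cfg$box_size_range[1], cfg$box_size_range[2])
    h <- stats::runif(1, cfg$box_size_range[1], cfg$box_size_range[2])
    x <- stats::runif(1, 0, cfg$image_width - w)
    y <- stats::runif(1, 0, cfg$image_height - h)
    cand <- c(x, y, x + w, y + h)
    if (nrow(objs) == 0) return(cand)
    ious <- apply(objs[, c("x_min", "y_min", "x_max", "y_max")], 1,
                  function(b) iou(as.numeric(b), cand))
    if (all(ious <= 0.1)) return(cand)
  }
  NULL
}

#' Recovery report against the generator's ground truth
#'
#' Measures how well the pipeline recovered the generator's known truth:
#' \describe{
#'   \item{clustering purity}{fraction of clusters whose members all trace to
#'     the same true object (or are all spurious).}
#'   \item{per-class recovery}{for every true object with at least one linked
#'     annotation, the object's dominant cluster (most links; ties to the
#'     lexicographically first cluster id) must have consensus truth equal to
#'     the object's true class.}
#'   \item{detection-probability estimates}{per rater group, the fraction of
#'     (true object, rater) pairs with a linked annotation.}
#' }
#'
#' @param ledger the `ledger` element of [generate_annotations()] output.
#' @param clustered clustered annotation table (with `annotation_id`).
#' @param consensus consensus table for the same clustering.
#' @return a list: `purity`, `recovery` (tibble per class plus `"overall"`),
#'   `detection_prob` (named per group), `n_true_objects`, `n_clusters`.
#' @export
oracle_metrics <- function(ledger, clustered, consensus) {
  stopifnot("annotation_id" %in% names(clustered))
  links <- ledger$links
  origin <- links$object_id
  origin[links$spurious] <- "(spurious)"
  names(origin) <- links$annotation_id
  miss <- setdiff(clustered$annotation_id, links$annotation_id)
  if (length(miss) > 0) {
    stop("clustered annotations missing from ledger: run ids do not match",
         call. = FALSE)
  }
  cl_origin <- origin[clustered$annotation_id]
  purity <- mean(vapply(split(cl_origin, clustered$cluster_id),
                        function(o) length(unique(o)) == 1, TRUE))
  # dominant cluster per true object
  real <- !links$spurious & links$annotation_id %in% clustered$annotation_id
  link_cluster <- clustered$cluster_id[match(links$annotation_id,
                                             clustered$annotation_id)]
  truth_by_cluster <- stats::setNames(consensus$truth, consensus$cluster_id)
  per_obj <- split(link_cluster[real], links$object_id[real])
  rec_rows <- lapply(names(per_obj), function(oid) {
    tab <- sort(table(per_obj[[oid]]), decreasing = TRUE)
    dom <- names(tab)[order(-tab, names(tab))][1]
    true_class <- ledger$objects$true_class[
      match(oid, ledger$objects$object_id)]
    tibble::tibble(object_id = oid, true_class = true_class,
                   consensus = unname(truth_by_cluster[dom]))
  })
  rec <- do.call(rbind, rec_rows)
  recovery <- if (is.null(rec) || nrow(rec) == 0) {
    tibble::tibble(class = character(), n = integer(), recovered = numeric())
  } else {
    ok <- !is.na(rec$consensus) & rec$consensus == rec$true_class
    per_class <- lapply(unique(rec$true_class), function(cl) {
      sel <- rec$true_class == cl
      tibble::tibble(class = cl, n = sum(sel), recovered = mean(ok[sel]))
    })
    rbind(do.call(rbind, per_class),
          tibble::tibble(class = "overall", n = nrow(rec),
                         recovered = mean(ok)))
  }
  # detection probability per group over (object, rater) trials
  anns_by_group <- split(links, ledger$annotators$group[
    match(links$annotator_id, ledger$annotators$annotator_id)])
  n_obj_by_img <- table(ledger$objects$image_id)
  det <- vapply(ANNOTATION_GROUPS, function(g) {
    ann_ids <- ledger$annotators$annotator_id[ledger$annotators$group == g]
    trials <- sum(n_obj_by_img) * length(ann_ids)
    if (trials == 0) return(NA_real_)
    hits <- sum(!links$spurious & links$annotator_id %in% ann_ids)
    hits / trials
  }, 1)
  list(purity = purity, recovery = recovery, detection_prob = det,
       n_true_objects = nrow(ledger$objects),
       n_clusters = length(unique(clustered$cluster_id)))
}
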