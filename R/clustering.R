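#' Intersection-over-union of two axis-aligned boxes
#'
#' Boxes are half-open on their max edges, so area is
#' `(x_max - x_min) * (y_max - y_min)` and touching boxes do not intersect.
#'
#' @param a,b boxes as numeric vectors `c(x_min, y_min, x_max, y_max)` or
#'   one-row data frames with those columns.
#' @return IoU in \[0, 1\]; symmetric in its arguments.
#' @export
iou <- function(a, b) {
  a <- as_box(a); b <- as_box(b)
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

as_box <- function(x) {
  if (is.data.frame(x)) {
    x <- as.numeric(x[1, c("x_min", "y_min", "x_max", "y_max")])
  }
  stopifnot(length(x) == 4, all(is.finite(x)), x[1] < x[3], x[2] < x[4])
  x
}

# Pairwise IoU of all boxes in an annotation table (n x n matrix).
iou_matrix <- function(ann) {
  n <- nrow(ann)
  x1 <- ann$x_min; y1 <- ann$y_min; x2 <- ann$x_max; y2 <- ann$y_max
  area <- (x2 - x1) * (y2 - y1)
  ix <- pmax(0, outer(x2, x2, pmin) - outer(x1, x1, pmax))
  iy <- pmax(0, outer(y2, y2, pmin) - outer(y1, y1, pmax))
  inter <- ix * iy
  inter / (outer(area, area, "+") - inter)
}

#' Clustering parameters
#'
#' @param iou_threshold minimum mean IoU for two clusters to be linked;
#'   in (0, 1\], default 0.5.
#' @return a list with class `clustering_params`.
#' @export
clustering_params <- function(iou_threshold = 0.5) {
  if (!is.numeric(iou_threshold) || length(iou_threshold) != 1 ||
      iou_threshold <= 0 || iou_threshold > 1) {
    stop("iou_threshold must be a single number in (0, 1]", call. = FALSE)
  }
  structure(list(iou_threshold = iou_threshold, link_rule = "greedy-best-pair"),
            class = "clustering_params")
}

#' Cluster one image's annotations into unique objects
#'
#' Groups the bounding boxes that all annotators drew on a single image into
#' clusters, each cluster standing for one unique physical object. The rule is
#' greedy average-linkage agglomeration on IoU: starting from singletons,
#' repeatedly merge the pair of clusters with the highest mean pairwise IoU,
#' provided that mean is at least `iou_threshold` and the merged cluster would
#' not contain two boxes from the same annotator. Ties are broken by the lower
#' (min id, max id) cluster-id pair; initial ids follow a deterministic sort by
#' (annotator_id, x_min, y_min, x_max, y_max), so the output is reproducible
#' regardless of input row order.
#'
#' @param ann annotation table whose rows all share one `image_id`.
#' @param params a [clustering_params()] object.
#' @return the input table with an integer `cluster_id` column appended
#'   (ids are 1..k in order of each cluster's first member under the
#'   deterministic sort).
#' @export
cluster_image <- function(ann, params = clustering_params()) {
  validate_annotations(ann)
  if (length(unique(ann$image_id)) > 1) {
    stop("cluster_image: annotations span multiple image_ids", call. = FALSE)
  }
  n <- nrow(ann)
  if (n == 0) {
    ann$cluster_id <- integer()
    return(ann)
  }
  ord <- order(ann$annotator_id, ann$x_min, ann$y_min, ann$x_max, ann$y_max)
  ann <- ann[ord, , drop = FALSE]
  membership <- greedy_merge(iou_matrix(ann),
                             annotators = ann$annotator_id,
                             threshold = params$iou_threshold)
  # renumber clusters 1..k by first-member position
  first_seen <- unique(membership)
  ann$cluster_id <- match(membership, first_seen)
  ann
}

# Greedy average-linkage agglomeration under a same-annotator exclusion.
# Returns an integer membership vector (cluster id = smallest member index).
greedy_merge <- function(iou_mat, annotators, threshold) {
  n <- nrow(iou_mat)
  membership <- seq_len(n)
  ann_codes <- as.integer(factor(annotators))
  n_ann <- max(ann_codes)
  repeat {
    ids <- sort(unique(membership))
    k <- length(ids)
    if (k == 1) break
    M <- matrix(0, k, n)
    M[cbind(match(membership, ids), seq_len(n))] <- 1
    sizes <- rowSums(M)
    sum_iou <- M %*% iou_mat %*% t(M)
    mean_iou <- sum_iou / outer(sizes, sizes)
    # annotator conflict: clusters sharing any annotator may not merge
    A <- matrix(0, k, n_ann)
    A[cbind(match(membership, ids), ann_codes)] <- 1
    conflict <- tcrossprod(A) > 0
    score <- mean_iou
    score[conflict] <- -Inf
    score[score < threshold] <- -Inf
    diag(score) <- -Inf
    best <- max(score)
    if (!is.finite(best)) break
    hits <- which(score >= best - 1e-12 & is.finite(score), arr.ind = TRUE)
    lo <- pmin(ids[hits[, 1]], ids[hits[, 2]])
    hi <- pmax(ids[hits[, 1]], ids[hits[, 2]])
    pick <- order(lo, hi)[1]
    membership[membership == hi[pick]] <- lo[pick]
  }
  membership
}

#' Cluster annotations across all images
#'
#' Applies [cluster_image()] to each image (in sorted `image_id` order) and
#' returns one long table with globally unique cluster ids of the form
#' `"<image_id>#<k>"`.
#'
#' @inheritParams cluster_image
#' @param annotations annotation table covering any number of images.
#' @return the annotation table with a character `cluster_id` column.
#' @export
cluster_annotations <- function(annotations, params = clustering_params()) {
  validate_annotations(annotations)
  if (nrow(annotations) == 0) {
    annotations$cluster_id <- character()
    return(annotations)
  }
  pieces <- lapply(sort(unique(annotations$image_id)), function(img) {
    out <- cluster_image(annotations[annotations$image_id == img, ,
                                     drop = FALSE], params)
    out$cluster_id <- sprintf("%s#%d", img, out$cluster_id)
    out
  })
  do.call(rbind, pieces)
}

#' Summarize clusters
#'
#' One row per cluster: image, member count, member annotators and labels, the
#' per-label vote counts, and a representative box (coordinate-wise median of
#' the member boxes).
#'
#' @param clustered output of [cluster_annotations()] or [cluster_image()].
#' @return a [tibble::tibble] with one row per cluster.
#' @export
cluster_table <- function(clustered) {
  stopifnot("cluster_id" %in% names(clustered))
  if (nrow(clustered) == 0) {
    return(tibble::tibble(
      cluster_id = character(), image_id = character(), n_members = integer(),
      annotator_ids = character(), labels = character(),
      n_live = integer(), n_dead = integer(), n_unknown = integer(),
      x_min = numeric(), y_min = numeric(), x_max = numeric(), y_max = numeric()
    ))
  }
  split_idx <- split(seq_len(nrow(clustered)), clustered$cluster_id)
  rows <- lapply(split_idx, function(idx) {
    m <- clustered[idx, , drop = FALSE]
    tibble::tibble(
      cluster_id = m$cluster_id[1],
      image_id = m$image_id[1],
      n_members = nrow(m),
      annotator_ids = paste(sort(m$annotator_id), collapse = ";"),
      labels = paste(m$label[order(m$annotator_id)], collapse = ";"),
      n_live = sum(m$label == "live"),
      n_dead = sum(m$label == "dead"),
      n_unknown = sum(m$label == "unknown"),
      x_min = stats::median(m$x_min), y_min = stats::median(m$y_min),
      x_max = stats::median(m$x_max), y_max = stats::median(m$y_max)
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$image_id, out$cluster_id), , drop = FALSE]
}
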