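CONFUSION_CLASSES <- c("live", "dead", "unknown", "0")

#' Build a confusion table of individual responses against consensus truth
#'
#' Cross-tabulates, for every (responder, cluster) pair in a stratum, the
#' responder's label on that cluster against the cluster's consensus truth.
#' The class `"0"` means "not observed": as a response it marks a responder who
#' drew no box in the cluster (a miss), and as a truth column it marks a
#' cluster adjudicated as a false positive. Model responders can only answer
#' `"live"` or `"0"`.
#'
#' @param consensus a consensus table from [consensus_table()]; every cluster
#'   in the stratum must appear here (clusters the live-only rule removed are
#'   simply not evaluated).
#' @param clustered the clustered annotation table the consensus was built
#'   from.
#' @param annotators data frame with columns `annotator_id`, `group` listing
#'   every responder to evaluate (absence from a cluster then counts as `"0"`).
#' @param images image record table, used for quality-score stratification.
#' @param groups responder groups to include (default all three).
#' @param quality_scores quality scores to include (default all).
#' @return a `confusion_table`: a 4x4 integer matrix (rows = response,
#'   columns = truth, classes `live`, `dead`, `unknown`, `0`) with the stratum
#'   stored in attributes. Zero matrix, with a warning, if the stratum selects
#'   no clusters.
#' @export
build_confusion <- function(consensus, clustered, annotators, images,
                            groups = ANNOTATION_GROUPS,
                            quality_scores = 0:4) {
  validate_images(images)
  stopifnot(all(c("annotator_id", "group") %in% names(annotators)))
  tab <- matrix(0L, 4, 4,
                dimnames = list(response = CONFUSION_CLASSES,
                                truth = CONFUSION_CLASSES))
  keep_imgs <- images$image_id[images$quality_score %in% quality_scores]
  cons <- consensus[consensus$image_id %in% keep_imgs, , drop = FALSE]
  resp <- annotators[annotators$group %in% groups, , drop = FALSE]
  if (nrow(cons) == 0 || nrow(resp) == 0) {
    warning("stratum selects no clusters or no responders; returning zeros",
            call. = FALSE)
    return(structure(tab, class = "confusion_table",
                     groups = groups, quality_scores = quality_scores))
  }
  truth_col <- ifelse(cons$truth == "false_positive", "0", cons$truth)
  # member lookup: label of each (cluster, annotator) pair
  key <- paste(clustered$cluster_id, clustered$annotator_id, sep = "\r")
  member_label <- stats::setNames(clustered$label, key)
  for (r in seq_len(nrow(resp))) {
    k <- paste(cons$cluster_id, resp$annotator_id[r], sep = "\r")
    response <- member_label[k]
    response[is.na(response)] <- "0"
    t_counts <- table(factor(response, levels = CONFUSION_CLASSES),
                      factor(truth_col, levels = CONFUSION_CLASSES))
    tab <- tab + as.integer(t_counts)
  }
  structure(matrix(as.integer(tab), 4, 4,
                   dimnames = list(response = CONFUSION_CLASSES,
                                   truth = CONFUSION_CLASSES)),
            class = "confusion_table",
            groups = groups, quality_scores = quality_scores)
}

#' Binary classification metrics from a confusion table
#'
#' Reduces the 4-class confusion table to positive class vs rest and computes
#' accuracy, precision, recall (= TPR), FPR, F1 and the single-operating-point
#' AUC. A metric whose denominator is zero is reported as `NA` with a warning,
#' never as 0.
#'
#' @param table a `confusion_table` from [build_confusion()] (or any square
#'   matrix with identical row/column class names).
#' @param positive_class the positive class; default `"live"`.
#' @return a one-row [tibble::tibble]: `positive_class`, `tp`, `fp`, `fn`,
#'   `tn`, `accuracy`, `precision`, `recall`, `f1`, `tpr`, `fpr`, `auc`.
#' @export
binary_metrics <- function(table, positive_class = "live") {
  stopifnot(is.matrix(table), nrow(table) == ncol(table),
            positive_class %in% rownames(table))
  pos <- positive_class
  tp <- table[pos, pos]
  fp <- sum(table[pos, ]) - tp
  fn <- sum(table[, pos]) - tp
  tn <- sum(table) - tp - fp - fn
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  accuracy <- ratio(tp + tn, sum(table), "accuracy")
  precision <- ratio(tp, tp + fp, "precision")
  recall <- ratio(tp, tp + fn, "recall")
  fpr <- ratio(fp, fp + tn, "fpr")
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    warning("f1 undefined", call. = FALSE)
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  auc <- if (is.na(recall) || is.na(fpr)) NA_real_ else
    single_point_auc(recall, fpr)
  tibble::tibble(
    positive_class = pos, tp = tp, fp = fp, fn = fn, tn = tn,
    accuracy = accuracy, precision = precision, recall = recall, f1 = f1,
    tpr = recall, fpr = fpr, auc = auc
  )
}

#' Multiclass agreement accuracy of a confusion table
#'
#' The fraction of (responder, cluster) evaluation pairs whose response equals
#' the consensus truth exactly, over all four classes (including `"0"`):
#' `sum(diag) / total`. This is the accuracy of the full four-class analysis;
#' [binary_metrics()] reports the live-vs-rest accuracy instead.
#'
#' @param table a `confusion_table` from [build_confusion()].
#' @return accuracy in \[0, 1\], or `NA` with a warning on an empty table.
#' @export
multiclass_accuracy <- function(table) {
  stopifnot(is.matrix(table), nrow(table) == ncol(table))
  total <- sum(table)
  if (total == 0) {
    warning("multiclass accuracy undefined (empty table)", call. = FALSE)
    return(NA_real_)
  }
  sum(diag(table)) / total
}

#' Area under the single-operating-point ROC curve
#'
#' With one confusion table per rater group there is a single ROC operating
#' point; the ROC curve is then the polyline (0,0) -> (fpr, tpr) -> (1,1) and
#' its area is the trapezoid value `(1 + tpr - fpr) / 2`.
#'
#' @param tpr,fpr true and false positive rates in \[0, 1\].
#' @return AUC in \[0, 1\]: 1 for a perfect classifier, 0.5 on the chance
#'   diagonal.
#' @export
single_point_auc <- function(tpr, fpr) {
  if (!is.numeric(tpr) || !is.numeric(fpr) ||
      any(tpr < 0 | tpr > 1) || any(fpr < 0 | fpr > 1)) {
    stop("tpr and fpr must lie in [0, 1]", call. = FALSE)
  }
  (1 + tpr - fpr) / 2
}
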