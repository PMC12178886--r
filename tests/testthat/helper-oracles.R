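# Independent oracles and small fixture builders used across the test files.
# These re-derive expected behaviour by direct, unoptimized interpretation of
# the rules, so they stay independent of the package's implementation paths.

# build an annotation table from a compact spec: one row per box
make_ann <- function(annotator_id, x_min, y_min, x_max, y_max,
                     label = "live", image_id = "img01",
                     group = NULL, confidence = NA_real_) {
  n <- max(length(annotator_id), length(x_min))
  if (is.null(group)) {
    group <- ifelse(grepl("^model", annotator_id), "model",
                    ifelse(grepl("^nonexpert", annotator_id), "nonexpert",
                           "expert"))
  }
  conf <- rep_len(confidence, n)
  conf[rep_len(group, n) == "model" & is.na(conf)] <- 0.9
  annotations(
    image_id = rep_len(image_id, n),
    annotator_id = annotator_id, group = group,
    x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
    label = rep_len(label, n), confidence = conf
  )
}

# random annotation table on one image, possibly with repeated annotators
random_ann <- function(n, n_annotators = 4, seed = 1, image_id = "img01") {
  set.seed(seed)
  x <- runif(n, 0, 200)
  y <- runif(n, 0, 200)
  w <- runif(n, 10, 60)
  h <- runif(n, 10, 60)
  make_ann(
    annotator_id = sprintf("expert%d", sample(n_annotators, n, replace = TRUE)),
    x_min = x, y_min = y, x_max = x + w, y_max = y + h,
    label = sample(c("live", "dead", "unknown"), n, replace = TRUE),
    image_id = image_id
  )
}

# plain-loop IoU, written independently of boxconcord::iou
oracle_iou <- function(a, b) {
  ix1 <- max(a[1], b[1]); iy1 <- max(a[2], b[2])
  ix2 <- min(a[3], b[3]); iy2 <- min(a[4], b[4])
  if (ix2 <= ix1 || iy2 <= iy1) return(0)
  inter <- (ix2 - ix1) * (iy2 - iy1)
  area_a <- (a[3] - a[1]) * (a[4] - a[2])
  area_b <- (b[3] - b[1]) * (b[4] - b[2])
  inter / (area_a + area_b - inter)
}

# brute-force simulation of the greedy mean-IoU agglomeration rule:
# clusters are index sets; at each step every feasible cluster pair's mean
# pairwise IoU is recomputed from scratch by double loop; the best pair
# (ties: lowest min-id, then lowest max-id; ids = smallest member index)
# merges if its mean IoU reaches the threshold.
oracle_greedy_cluster <- function(ann, threshold = 0.5) {
  ord <- order(ann$annotator_id, ann$x_min, ann$y_min, ann$x_max, ann$y_max)
  ann <- ann[ord, , drop = FALSE]
  n <- nrow(ann)
  boxes <- lapply(seq_len(n), function(i)
    as.numeric(ann[i, c("x_min", "y_min", "x_max", "y_max")]))
  clusters <- as.list(seq_len(n))
  repeat {
    k <- length(clusters)
    if (k < 2) break
    best <- NULL
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        members_i <- clusters[[i]]; members_j <- clusters[[j]]
        if (length(intersect(ann$annotator_id[members_i],
                             ann$annotator_id[members_j])) > 0) next
        total <- 0
        for (a in members_i) for (b in members_j) {
          total <- total + oracle_iou(boxes[[a]], boxes[[b]])
        }
        m <- total / (length(members_i) * length(members_j))
        if (m < threshold) next
        id_i <- min(members_i); id_j <- min(members_j)
        lo <- min(id_i, id_j); hi <- max(id_i, id_j)
        take <- if (is.null(best)) TRUE
        else if (m > best$m + 1e-12) TRUE
        else if (m < best$m - 1e-12) FALSE
        else if (lo != best$lo) lo < best$lo
        else hi < best$hi
        if (take) best <- list(m = m, lo = lo, hi = hi, i = i, j = j)
      }
    }
    if (is.null(best)) break
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  # membership vector in the sorted order, numbered by first member
  membership <- integer(n)
  firsts <- vapply(clusters, min, 1L)
  clusters <- clusters[order(firsts)]
  for (c_id in seq_along(clusters)) membership[clusters[[c_id]]] <- c_id
  list(ann = ann, membership = membership)
}

# literal interpreter of the published consensus wording, independent of the
# package's implementation
oracle_consensus_all_class <- function(labels) {
  n <- length(labels)
  live <- sum(labels == "live"); dead <- sum(labels == "dead")
  unknown <- sum(labels == "unknown")
  if (n <= 2) {
    truth <- "false_positive"
  } else if (live >= dead && live >= unknown) {
    truth <- "live"   # most frequent, and live wins ties it is part of
  } else if (dead > live && dead >= unknown) {
    truth <- "dead"   # dead wins the dead/unknown tie
  } else {
    truth <- "unknown"
  }
  matching <- if (truth == "live") live else if (truth == "dead") dead
  else if (truth == "unknown") unknown else max(live, dead, unknown)
  list(truth = truth, confidence = matching / n)
}

oracle_consensus_live_only <- function(labels) {
  live <- sum(labels == "live")
  if (live == 0) return(NULL)
  truth <- if (live >= 3) "live" else "false_positive"
  n <- length(labels)
  matching <- if (truth == "live") live else
    max(live, sum(labels == "dead"), sum(labels == "unknown"))
  list(truth = truth, confidence = matching / n)
}

# all label multisets (as label vectors) with n identifiers
all_vote_multisets <- function(n) {
  out <- list()
  for (live in 0:n) for (dead in 0:(n - live)) {
    unknown <- n - live - dead
    out[[length(out) + 1]] <- rep(c("live", "dead", "unknown"),
                                  c(live, dead, unknown))
  }
  out
}

default_groups_for_test <- function() synthetic_config()$groups

# noiseless generator settings: perfect raters on an all-live world
noiseless_config <- function(n_images = 20, seed = 1,
                             objects_per_image = 8) {
  groups <- list(
    model = list(n_annotators = 1, detection_prob = 1, label_confusion = NULL,
                 fp_rate = 0, fp_label_probs = c(live = 1, dead = 0, unknown = 0),
                 jitter_sd = 0),
    expert = list(n_annotators = 5, detection_prob = 1,
                  label_confusion = matrix(c(1, 0, 0, 0, 1, 0), 2, 3,
                                           byrow = TRUE),
                  fp_rate = 0, fp_label_probs = c(live = 1, dead = 0, unknown = 0),
                  jitter_sd = 0),
    nonexpert = list(n_annotators = 5, detection_prob = 1,
                     label_confusion = matrix(c(1, 0, 0, 0, 1, 0), 2, 3,
                                              byrow = TRUE),
                     fp_rate = 0, fp_label_probs = c(live = 1, dead = 0, unknown = 0),
                     jitter_sd = 0)
  )
  synthetic_config(
    n_images = n_images, objects_per_image = objects_per_image,
    class_mix = c(live = 1, dead = 0), groups = groups,
    qs_effect = list(detect = c("2" = 1, "3" = 1, "4" = 1),
                     jitter = c("2" = 1, "3" = 1, "4" = 1)),
    seed = seed
  )
}
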