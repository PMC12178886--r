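annotator_frame <- function() {
  tibble::tibble(
    annotator_id = c("model1", paste0("expert", 1:5), paste0("nonexpert", 1:5)),
    group = c("model", rep("expert", 5), rep("nonexpert", 5))
  )
}

test_that("confusion tabulation counts responses and misses per cluster", {
  # one unanimous-live cluster seen by 5 experts; the other 6 raters miss it
  ann <- make_ann(paste0("expert", 1:5), 10, 10, 50, 50, label = "live")
  cl <- cluster_annotations(ann)
  cons <- consensus_table(cl, "all_class")
  images <- image_records("img01", 3)
  tab <- build_confusion(cons, cl, annotator_frame(), images)
  expect_equal(tab["live", "live"], 5L)
  expect_equal(tab["0", "live"], 6L)
  expect_equal(sum(tab), 11L)
})

test_that("false-positive truth lands in column 0", {
  ann <- make_ann(c("expert1", "expert2"), 10, 10, 50, 50, label = "live")
  cl <- cluster_annotations(ann)
  cons <- consensus_table(cl, "all_class")
  expect_equal(cons$truth, "false_positive")
  tab <- build_confusion(cons, cl, annotator_frame(),
                         image_records("img01", 2))
  expect_equal(tab["live", "0"], 2L)
  expect_equal(tab["0", "0"], 9L)
})

test_that("confusion tables equal a hand tally on mixed clusters", {
  # three clusters on one QS-3 image, adjudicated by hand:
  #   c1: live x3 + dead x1        -> truth live
  #   c2: dead x2 + unknown x2     -> truth dead
  #   c3: unknown x2               -> truth false_positive
  ann <- rbind(
    make_ann(c("expert1", "expert2", "expert3", "nonexpert1"), 0, 0, 40, 40,
             label = c("live", "live", "live", "dead")),
    make_ann(c("expert1", "expert2", "nonexpert1", "nonexpert2"),
             200, 200, 240, 240,
             label = c("dead", "dead", "unknown", "unknown")),
    make_ann(c("expert4", "nonexpert3"), 400, 0, 440, 40, label = "unknown")
  )
  cl <- cluster_annotations(ann)
  cons <- consensus_table(cl, "all_class")
  expect_setequal(cons$truth, c("live", "dead", "false_positive"))
  tab <- build_confusion(cons, cl, annotator_frame(),
                         image_records("img01", 3))
  expected <- matrix(0L, 4, 4, dimnames = dimnames(tab))
  # truth live (c1): 3 live responses, 1 dead, 7 misses
  expected["live", "live"] <- 3; expected["dead", "live"] <- 1
  expected["0", "live"] <- 7
  # truth dead (c2): 2 dead, 2 unknown, 7 misses
  expected["dead", "dead"] <- 2; expected["unknown", "dead"] <- 2
  expected["0", "dead"] <- 7
  # truth 0 (c3): 2 unknown, 9 misses
  expected["unknown", "0"] <- 2; expected["0", "0"] <- 9
  expect_equal(unclass(tab), expected, ignore_attr = TRUE)
  # conservation: each truth column sums to the number of responders
  expect_true(all(colSums(tab)[c("live", "dead", "0")] == 11))
})

test_that("stratum filters select groups and quality scores", {
  ann <- rbind(
    make_ann(paste0("expert", 1:3), 0, 0, 40, 40, image_id = "q2",
             label = "live"),
    make_ann(paste0("expert", 1:3), 0, 0, 40, 40, image_id = "q4",
             label = "live")
  )
  images <- image_records(c("q2", "q4"), c(2, 4))
  cl <- cluster_annotations(ann)
  cons <- consensus_table(cl, "all_class")
  raters <- annotator_frame()
  tab_q2 <- build_confusion(cons, cl, raters, images,
                            groups = "expert", quality_scores = 2)
  expect_equal(sum(tab_q2), 5L)  # 5 experts x 1 cluster
  expect_equal(tab_q2["live", "live"], 3L)
  expect_warning(
    zero <- build_confusion(cons, cl, raters, images, quality_scores = 0),
    "no clusters")
  expect_equal(sum(zero), 0L)
})

test_that("binary metrics reproduce forced arithmetic", {
  tab <- matrix(0L, 4, 4, dimnames = list(response = c("live", "dead",
                                                       "unknown", "0"),
                                          truth = c("live", "dead",
                                                    "unknown", "0")))
  tab["live", "live"] <- 2           # TP
  tab["live", "dead"] <- 1           # FP
  tab["0", "live"] <- 1              # FN
  tab["dead", "dead"] <- 3; tab["unknown", "0"] <- 3  # TN mass
  m <- binary_metrics(tab, "live")
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$fpr, 1 / 7)
  expect_equal(m$auc, (1 + 2 / 3 - 1 / 7) / 2)
  expect_equal(multiclass_accuracy(tab), 5 / 10)
})

test_that("a diagonal table scores perfectly; empty denominators give NA", {
  tab <- diag(c(5L, 4L, 3L, 2L))
  dimnames(tab) <- list(response = c("live", "dead", "unknown", "0"),
                        truth = c("live", "dead", "unknown", "0"))
  m <- binary_metrics(tab, "live")
  expect_equal(m$accuracy, 1); expect_equal(m$precision, 1)
  expect_equal(m$recall, 1); expect_equal(m$f1, 1); expect_equal(m$auc, 1)
  expect_equal(multiclass_accuracy(tab), 1)

  empty_pos <- tab
  empty_pos["live", "live"] <- 0L
  w <- capture_warnings(m2 <- binary_metrics(empty_pos, "live"))
  expect_true(any(grepl("precision", w)))
  expect_true(any(grepl("recall", w)))
  expect_true(is.na(m2$precision))
  expect_true(is.na(m2$recall))
  expect_false(isTRUE(m2$precision == 0))
})

test_that("single-point AUC is the trapezoid under the one-point ROC", {
  expect_equal(single_point_auc(1, 0), 1)
  expect_equal(single_point_auc(0.3, 0.3), 0.5)
  expect_equal(single_point_auc(0, 1), 0)
  # numeric integration oracle over the polyline (0,0)-(fpr,tpr)-(1,1)
  roc_height <- function(x, tpr, fpr) {
    ifelse(x <= fpr,
           if (fpr == 0) tpr else tpr * x / fpr,
           if (fpr == 1) tpr else tpr + (1 - tpr) * (x - fpr) / (1 - fpr))
  }
  for (pt in list(c(0.7, 0.2), c(0.9, 0.05), c(0.4, 0.6))) {
    grid <- seq(0, 1, length.out = 20001)
    heights <- roc_height(grid, pt[1], pt[2])
    numeric_auc <- sum((heights[-1] + heights[-length(heights)]) / 2) *
      diff(grid[1:2])
    expect_equal(single_point_auc(pt[1], pt[2]), numeric_auc,
                 tolerance = 1e-6)
  }
  expect_equal(single_point_auc(0.7, 0.2), 0.75)
  # monotone in tpr, antitone in fpr
  expect_gt(single_point_auc(0.8, 0.2), single_point_auc(0.6, 0.2))
  expect_lt(single_point_auc(0.8, 0.4), single_point_auc(0.8, 0.2))
  expect_error(single_point_auc(1.2, 0), "\\[0, 1\\]")
})
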