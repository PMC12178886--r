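test_that("per-image counts tally exactly, with zeros for absent raters", {
  ann <- rbind(
    make_ann(rep("expert1", 3), c(0, 50, 100), 0, c(40, 90, 140), 40,
             label = "live", image_id = "img01"),
    make_ann("expert2", 0, 0, 40, 40, label = "dead", image_id = "img01"),
    make_ann("expert1", 0, 0, 40, 40, label = "live", image_id = "img02")
  )
  images <- image_records(c("img01", "img02", "img03"), c(3, 3, 2))
  m <- per_image_counts(ann, images, "live",
                        annotators = c("expert1", "expert2"))
  expect_equal(m["img01", "expert1"], 3L)
  expect_equal(m["img01", "expert2"], 0L)
  expect_equal(m["img02", "expert1"], 1L)
  expect_equal(m["img03", "expert1"], 0L)  # no annotations at all
  expect_equal(sum(per_image_counts(ann, images, "dead",
                                    annotators = c("expert1", "expert2"))), 1L)
})

test_that("group means round half away from zero", {
  counts <- matrix(c(2, 3, 3, 2, 3,
                     2, 2, 3, 3, 0), nrow = 2, byrow = TRUE,
                   dimnames = list(c("i1", "i2"), paste0("r", 1:5)))
  m1 <- group_mean_rounded(counts, paste0("r", 1:5))
  expect_equal(m1["i1", 1], 3L)                     # mean 2.6 -> 3
  m2 <- group_mean_rounded(counts[, 1:4, drop = FALSE], paste0("r", 1:4))
  expect_equal(m2["i2", 1], 3L)                     # mean 2.5 -> 3 (half away)
  same <- matrix(4L, 3, 4, dimnames = list(letters[1:3], paste0("r", 1:4)))
  expect_true(all(group_mean_rounded(same, paste0("r", 1:4)) == 4L))
  expect_error(group_mean_rounded(counts, character()), "empty")
  # bounded between the group's min and max per image
  set.seed(2)
  rnd <- matrix(rpois(60, 4), 12, 5,
                dimnames = list(paste0("i", 1:12), paste0("r", 1:5)))
  g <- group_mean_rounded(rnd, paste0("r", 1:5))
  expect_true(all(g >= apply(rnd, 1, min) & g <= apply(rnd, 1, max)))
})

test_that("ICC(2,1) equals the ANOVA mean-squares oracle on a 6x3 table", {
  mat <- matrix(c(9, 2, 5,
                  6, 1, 3,
                  8, 4, 6,
                  7, 1, 2,
                  10, 5, 6,
                  6, 2, 4), nrow = 6, byrow = TRUE)
  res <- icc(mat)
  # independent oracle: mean squares from a two-way aov fit
  df <- data.frame(y = as.vector(mat),
                   target = factor(rep(1:6, 3)),
                   rater = factor(rep(1:3, each = 6)))
  ms <- summary(stats::aov(y ~ target + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 3; n <- 6
  expected <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(res$icc, expected, tolerance = 1e-10)
  expect_equal(res$f_value, msr / mse, tolerance = 1e-10)
  expect_equal(res$p_value,
               pf(msr / mse, n - 1, (n - 1) * (k - 1), lower.tail = FALSE))
})

test_that("ICC hits its boundary and invariance properties", {
  set.seed(4)
  base <- rpois(30, 5)
  dup <- cbind(base, base, base)
  expect_equal(icc(dup)$icc, 1)
  # invariant to adding a constant to every cell
  noisy <- cbind(base + rnorm(30), base + rnorm(30))
  expect_equal(icc(noisy)$icc, icc(noisy + 100)$icc, tolerance = 1e-10)
  # more independent noise on one column lowers agreement (on average)
  mean_icc <- function(sd) {
    mean(vapply(1:30, function(i) {
      set.seed(i)
      icc(cbind(base, base + rnorm(30, 0, sd)))$icc
    }, 1))
  }
  expect_gt(mean_icc(1), mean_icc(4))
  # zero between-target variance is undefined, not a number
  flat <- matrix(3, 10, 3)
  expect_warning(res <- icc(flat), "undefined")
  expect_true(is.na(res$icc))
  expect_error(icc(matrix(1:3, 3, 1)), ">= 2")
})

test_that("ICC is near zero for independent raters", {
  set.seed(11)
  mat <- matrix(rnorm(200 * 3), 200, 3)
  expect_lt(abs(icc(mat)$icc), 0.1)
})

test_that("ICC bands follow the conventional cutoffs", {
  expect_equal(icc_band(0.43), "poor")
  expect_equal(icc_band(0.673), "moderate")
  expect_equal(icc_band(0.89), "good")
  expect_equal(icc_band(0.95), "excellent")
})

test_that("rank tests detect shifts and respect the paired contract", {
  set.seed(21)
  a <- rpois(50, 5); b <- rpois(50, 5) + 6
  res <- rank_tests(list(a = a, b = b), "paired")
  expect_equal(res$test, "wilcoxon_signed_rank")
  expect_lt(res$p_value, 0.001)
  # near-identical paired samples: no signal
  x <- rnorm(40)
  quiet <- rank_tests(list(x = x, y = x + rnorm(40, 0, 1e-3)), "paired")
  expect_gt(quiet$p_value, 0.05)
  expect_error(rank_tests(list(x = x, y = x), "paired"), "degenerate")
  expect_error(rank_tests(list(a = 1:3, b = 1:4), "paired"), "equal-length")
})

test_that("Kruskal-Wallis plus Dunn flags a shifted group in all its pairs", {
  set.seed(31)
  g1 <- rnorm(50); g2 <- rnorm(50); g3 <- rnorm(50) + 3
  res <- rank_tests(list(g1 = g1, g2 = g2, g3 = g3), "multigroup")
  expect_equal(res$test, "kruskal_wallis")
  expect_lt(res$p_value, 0.001)
  pw <- res$pairwise
  expect_equal(nrow(pw), 3)
  hit <- pw$group1 == "g3" | pw$group2 == "g3"
  expect_true(all(pw$p_adjusted[hit] < 0.001))
  expect_gt(pw$p_adjusted[!hit], 0.05)
})

test_that("Dunn z-statistics agree with the rank formula on a worked case", {
  samples <- list(a = c(1, 3, 5, 7), b = c(2, 4, 6, 8), c = c(10, 11, 12, 13))
  pw <- dunn_test(samples, p_adjust_method = "none")
  # hand recomputation (no ties): sigma^2 = N(N+1)/12
  x <- unlist(samples); r <- rank(x)
  mr <- tapply(r, rep(names(samples), each = 4), mean)
  se <- sqrt(length(x) * (length(x) + 1) / 12 * (1 / 4 + 1 / 4))
  expect_equal(pw$z[pw$group1 == "a" & pw$group2 == "b"],
               unname((mr["a"] - mr["b"]) / se))
  expect_equal(pw$z[pw$group1 == "a" & pw$group2 == "c"],
               unname((mr["a"] - mr["c"]) / se))
  expect_equal(pw$p_value, 2 * pnorm(-abs(pw$z)))
})
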