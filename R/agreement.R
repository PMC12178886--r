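#' Per-image annotation counts
#'
#' Tallies how many boxes of one label each rater drew on each image. Every
#' admissible image appears as a row, with zeros for raters who drew nothing.
#'
#' @param annotations annotation table.
#' @param images image record table (defines the row set).
#' @param label the class to count (`live`, `dead` or `unknown`).
#' @param annotators optional character vector fixing the column set and
#'   order; defaults to the raters present in `annotations`.
#' @return an integer matrix, rows = image ids, columns = annotator ids.
#' @export
per_image_counts <- function(annotations, images, label,
                             annotators = NULL) {
  validate_annotations(annotations)
  validate_images(images)
  stopifnot(label %in% ANNOTATION_LABELS)
  if (is.null(annotators)) {
    annotators <- sort(unique(annotations$annotator_id))
  }
  imgs <- sort(images$image_id)
  sub <- annotations[annotations$label == label &
                       annotations$annotator_id %in% annotators &
                       annotations$image_id %in% imgs, , drop = FALSE]
  tab <- table(factor(sub$image_id, levels = imgs),
               factor(sub$annotator_id, levels = annotators))
  matrix(as.integer(tab), nrow = length(imgs),
         dimnames = list(imgs, annotators))
}

# round half away from zero (commercial rounding), unlike base round()'s
# round-half-even
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Average a rater group's per-image counts and round
#'
#' To compare groups with unequal numbers of raters, a group's per-image
#' counts are averaged and rounded to an integer so group columns live on the
#' same scale as single-rater columns. Rounding is half-away-from-zero
#' (2.5 -> 3).
#'
#' @param counts a count matrix from [per_image_counts()].
#' @param columns the column names (rater ids) forming the group.
#' @return a one-column integer matrix of rounded group means.
#' @export
group_mean_rounded <- function(counts, columns) {
  if (length(columns) == 0) stop("empty rater group", call. = FALSE)
  missing_cols <- setdiff(columns, colnames(counts))
  if (length(missing_cols) > 0) {
    stop("unknown rater column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  m <- rowMeans(counts[, columns, drop = FALSE])
  matrix(as.integer(round_half_away(m)), ncol = 1,
         dimnames = list(rownames(counts), paste(columns, collapse = "+")))
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random effects, single rater, absolute agreement: both the images
#' (targets) and the raters are treated as random samples, and systematic
#' rater offsets count against agreement. Computed from the two-way ANOVA mean
#' squares:
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with \eqn{n} targets, \eqn{k} raters, row (target) mean square \eqn{MS_R},
#' column (rater) mean square \eqn{MS_C} and residual \eqn{MS_E}. The p-value
#' is from the F test \eqn{MS_R / MS_E} on \eqn{(n-1, (n-1)(k-1))} degrees of
#' freedom. Qualitative bands follow the conventional cutoffs: poor < 0.5,
#' moderate < 0.75, good < 0.9, excellent otherwise.
#'
#' @param counts numeric matrix, rows = targets (images), columns = raters;
#'   needs at least 2 rows and 2 columns of finite values.
#' @return a list: `icc`, `p_value`, `f_value`, `df1`, `df2`, `band`,
#'   `design = "ICC(2,1)"`, `n`, `k`. If the between-target variance is zero
#'   the ICC is undefined and returned as `NA` with a warning.
#' @export
icc <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2 || !all(is.finite(counts))) {
    stop("icc needs a finite matrix with >= 2 rows and >= 2 columns",
         call. = FALSE)
  }
  n <- nrow(counts); k <- ncol(counts)
  grand <- mean(counts)
  row_means <- rowMeans(counts)
  col_means <- colMeans(counts)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((counts - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr <= 0) {
    warning("zero between-target variance: ICC undefined", call. = FALSE)
    return(list(icc = NA_real_, p_value = NA_real_, f_value = NA_real_,
                df1 = n - 1, df2 = (n - 1) * (k - 1), band = NA_character_,
                design = "ICC(2,1)", n = n, k = k))
  }
  value <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  f_value <- if (mse > 0) msr / mse else Inf
  p_value <- stats::pf(f_value, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  list(icc = value, p_value = p_value, f_value = f_value,
       df1 = n - 1, df2 = (n - 1) * (k - 1), band = icc_band(value),
       design = "ICC(2,1)", n = n, k = k)
}

#' @rdname icc
#' @param value an ICC value.
#' @export
icc_band <- function(value) {
  if (is.na(value)) return(NA_character_)
  if (value < 0.5) "poor"
  else if (value < 0.75) "moderate"
  else if (value < 0.9) "good"
  else "excellent"
}

#' Rank-based group comparisons
#'
#' Thin wrappers over the standard nonparametric tests used to compare
#' per-image counts between rater groups: the Wilcoxon signed-rank test for a
#' paired two-sample design, and the Kruskal-Wallis test with Dunn's post hoc
#' z-tests (all pairs) for three or more independent groups.
#'
#' @param samples a named list of numeric vectors. For `design = "paired"`,
#'   exactly two vectors of equal length (paired by position).
#' @param design `"paired"` or `"multigroup"`.
#' @param p_adjust_method adjustment for Dunn's pairwise p-values
#'   (see [stats::p.adjust]); default `"holm"`.
#' @return a list: `test` (name), `statistic`, `p_value`, and for the
#'   multigroup design a `pairwise` tibble of Dunn results
#'   (`group1`, `group2`, `z`, `p_value`, `p_adjusted`).
#' @export
rank_tests <- function(samples, design = c("paired", "multigroup"),
                       p_adjust_method = "holm") {
  design <- match.arg(design)
  stopifnot(is.list(samples), all(vapply(samples, is.numeric, TRUE)))
  if (design == "paired") {
    if (length(samples) != 2 ||
        length(samples[[1]]) != length(samples[[2]])) {
      stop("paired design needs two equal-length samples", call. = FALSE)
    }
    d <- samples[[1]] - samples[[2]]
    if (all(d == 0)) {
      stop("degenerate paired test: all paired differences are zero",
           call. = FALSE)
    }
    ht <- suppressWarnings(
      stats::wilcox.test(samples[[1]], samples[[2]], paired = TRUE,
                         exact = FALSE))
    return(list(test = "wilcoxon_signed_rank",
                statistic = unname(ht$statistic), p_value = ht$p.value))
  }
  if (length(samples) < 3) {
    stop("multigroup design needs >= 3 groups", call. = FALSE)
  }
  ht <- stats::kruskal.test(samples)
  list(test = "kruskal_wallis",
       statistic = unname(ht$statistic), p_value = ht$p.value,
       pairwise = dunn_test(samples, p_adjust_method = p_adjust_method))
}

#' Dunn's post hoc test for all group pairs
#'
#' Pairwise z-tests on mean ranks after a Kruskal-Wallis test, with the
#' standard tie correction; two-sided p-values, adjusted across all pairs.
#'
#' @inheritParams rank_tests
#' @return a [tibble::tibble]: `group1`, `group2`, `z`, `p_value`,
#'   `p_adjusted`.
#' @export
dunn_test <- function(samples, p_adjust_method = "holm") {
  stopifnot(is.list(samples), length(samples) >= 2)
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    names(samples) <- paste0("group", seq_along(samples))
  }
  g <- rep(names(samples), lengths(samples))
  x <- unlist(samples, use.names = FALSE)
  N <- length(x)
  r <- rank(x)
  mean_ranks <- tapply(r, g, mean)
  n_i <- tapply(r, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  sigma2_base <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(names(samples), 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(sigma2_base * (1 / n_i[[a]] + 1 / n_i[[b]]))
    z[j] <- (mean_ranks[[a]] - mean_ranks[[b]]) / se
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  tibble::tibble(
    group1 = pairs[1, ], group2 = pairs[2, ], z = z, p_value = p,
    p_adjusted = stats::p.adjust(p, method = p_adjust_method)
  )
}
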