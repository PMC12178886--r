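#' Run configuration for the full concordance pipeline
#'
#' Exactly one of `annotation_files` (with `metadata_file`) or `synthetic`
#' must be supplied.
#'
#' @param annotation_files character vector of annotation files to ingest
#'   (all in one `dialect`).
#' @param dialect dialect of `annotation_files` (see [read_annotations()]).
#' @param metadata_file image metadata CSV (required with
#'   `annotation_files`).
#' @param synthetic a [synthetic_config()] to generate data instead of
#'   reading it.
#' @param clustering a [clustering_params()] object.
#' @param model_cutoff strict lower bound on admitted model confidences.
#' @param include_model_in_quorum see [consensus_table()].
#' @param subset_n optional number of images to randomly sub-sample (seeded)
#'   before clustering and all downstream analysis; mirrors evaluating a
#'   random image subset by hand.
#' @param seed integer seed controlling sub-sampling (and, for synthetic
#'   input, overriding the generator's seed so one seed drives the run).
#' @param out_dir optional directory; when given, all report tables are
#'   written there as CSV/JSON along with a run manifest.
#' @return a validated `run_config` list.
#' @export
run_config <- function(annotation_files = NULL, dialect = "csv",
                       metadata_file = NULL, synthetic = NULL,
                       clustering = clustering_params(),
                       model_cutoff = 0.5,
                       include_model_in_quorum = TRUE,
                       subset_n = NULL, seed = 1L, out_dir = NULL) {
  if (is.null(synthetic) == is.null(annotation_files)) {
    stop("supply exactly one of annotation_files or synthetic", call. = FALSE)
  }
  if (!is.null(annotation_files) && is.null(metadata_file)) {
    stop("annotation_files require a metadata_file", call. = FALSE)
  }
  structure(list(
    annotation_files = annotation_files, dialect = dialect,
    metadata_file = metadata_file, synthetic = synthetic,
    clustering = clustering, model_cutoff = model_cutoff,
    include_model_in_quorum = include_model_in_quorum,
    subset_n = subset_n, seed = as.integer(seed), out_dir = out_dir
  ), class = "run_config")
}

#' Run the full multi-annotator concordance pipeline
#'
#' Sequences every stage: ingest (or generate) annotations, apply the
#' admission filters (quality score >= 2; model confidence strictly above the
#' cutoff), optionally sub-sample images, cluster boxes into unique objects,
#' adjudicate consensus truth under both rule sets, tabulate confusion tables
#' and binary metrics per rater group (overall and per quality score), and
#' compute per-image count statistics: ICC between groups (model vs rounded
#' group means), ICC between and within the human groups, and the rank-based
#' group comparisons. Deterministic given the seed.
#'
#' @param config a [run_config()].
#' @return a `run_bundle` list: `annotations`, `images`, `clustered`,
#'   `cluster_summary`, `consensus` (per method), `metrics` (tidy tibble),
#'   `confusion` (named list of tables), `icc` (tidy tibble), `tests`
#'   (rank-test results), `oracle` (recovery report; synthetic input only),
#'   `manifest` (stage log, counts, versions), and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  stages <- list()
  log_stage <- function(name, n_in, n_out) {
    stages[[name]] <<- list(n_in = n_in, n_out = n_out)
  }

  # -- ingest ----------------------------------------------------------------
  ledger <- NULL
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    syn$seed <- config$seed
    gen <- generate_annotations(syn)
    anns <- gen$annotations
    images <- gen$images
    ledger <- gen$ledger
  } else {
    anns <- do.call(rbind, lapply(config$annotation_files, read_annotations,
                                  dialect = config$dialect))
    if (!"annotation_id" %in% names(anns)) {
      anns$annotation_id <- sprintf("a%06d", seq_len(nrow(anns)))
    }
    images <- read_image_metadata(config$metadata_file)
  }
  log_stage("ingest", NA_integer_, nrow(anns))

  # -- admission filters -----------------------------------------------------
  filtered <- filter_admissible(anns, images, config$model_cutoff)
  images_adm <- images[images$quality_score >= 2, , drop = FALSE]
  log_stage("filter_admissible", nrow(anns), nrow(filtered))

  # -- image subset ----------------------------------------------------------
  if (!is.null(config$subset_n)) {
    if (config$subset_n > nrow(images_adm)) {
      stop("subset_n exceeds the number of admissible images", call. = FALSE)
    }
    set.seed(config$seed)
    keep <- sort(sample(images_adm$image_id, config$subset_n))
    images_adm <- images_adm[images_adm$image_id %in% keep, , drop = FALSE]
    filtered <- filtered[filtered$image_id %in% keep, , drop = FALSE]
  }
  log_stage("subset", nrow(images_adm) + 0L, nrow(filtered))

  annotators <- unique(filtered[, c("annotator_id", "group")])
  annotators <- annotators[order(annotators$annotator_id), , drop = FALSE]
  if (!is.null(ledger)) annotators <- ledger$annotators

  # -- clustering ------------------------------------------------------------
  clustered <- cluster_annotations(filtered, config$clustering)
  log_stage("clustering", nrow(filtered),
            length(unique(clustered$cluster_id)))

  # -- consensus -------------------------------------------------------------
  consensus <- list(
    all_class = consensus_table(clustered, "all_class",
                                config$include_model_in_quorum),
    live_only = consensus_table(clustered, "live_only",
                                config$include_model_in_quorum)
  )
  log_stage("consensus", length(unique(clustered$cluster_id)),
            nrow(consensus$all_class))

  # -- confusion tables and metrics -------------------------------------------
  qs_levels <- sort(unique(images_adm$quality_score))
  strata <- c(
    list(list(name = "all", groups = ANNOTATION_GROUPS, qs = 0:4)),
    lapply(ANNOTATION_GROUPS, function(g)
      list(name = g, groups = g, qs = 0:4)),
    lapply(qs_levels, function(q)
      list(name = paste0("human_qs", q), groups = c("expert", "nonexpert"),
           qs = q)),
    unlist(lapply(ANNOTATION_GROUPS, function(g) {
      lapply(qs_levels, function(q)
        list(name = paste0(g, "_qs", q), groups = g, qs = q))
    }), recursive = FALSE)
  )
  confusion <- list()
  metric_rows <- list()
  for (s in strata) {
    tab <- suppressWarnings(
      build_confusion(consensus$all_class, clustered, annotators, images_adm,
                      groups = s$groups, quality_scores = s$qs))
    confusion[[s$name]] <- tab
    if (sum(tab) > 0) {
      m <- suppressWarnings(binary_metrics(tab, "live"))
      m$multiclass_accuracy <- multiclass_accuracy(tab)
      m$stratum <- s$name
      metric_rows[[s$name]] <- m
    }
  }
  metrics <- do.call(rbind, metric_rows)
  log_stage("metrics", length(strata), nrow(metrics))

  # -- agreement statistics ---------------------------------------------------
  icc_tbl <- pipeline_icc(filtered, images_adm, annotators, qs_levels)
  tests <- pipeline_rank_tests(filtered, images_adm, annotators)
  log_stage("agreement", nrow(images_adm), nrow(icc_tbl))

  oracle <- if (!is.null(ledger)) {
    led <- ledger
    led$links <- led$links[led$links$annotation_id %in%
                             clustered$annotation_id, , drop = FALSE]
    led$objects <- led$objects[led$objects$image_id %in%
                                 images_adm$image_id, , drop = FALSE]
    oracle_metrics(led, clustered, consensus$all_class)
  }

  manifest <- list(
    seed = config$seed,
    stages = stages,
    n_images = nrow(images_adm),
    n_annotators = nrow(annotators),
    package_version = as.character(utils::packageVersion("boxconcord")),
    r_version = R.version.string,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    settings = list(
      iou_threshold = config$clustering$iou_threshold,
      model_cutoff = config$model_cutoff,
      include_model_in_quorum = config$include_model_in_quorum,
      subset_n = config$subset_n
    )
  )
  bundle <- structure(list(
    annotations = filtered, images = images_adm, clustered = clustered,
    cluster_summary = cluster_table(clustered), consensus = consensus,
    metrics = metrics, confusion = confusion, icc = icc_tbl, tests = tests,
    oracle = oracle, manifest = manifest, config = config
  ), class = "run_bundle")
  if (!is.null(config$out_dir)) write_run_outputs(bundle, config$out_dir)
  bundle
}

pipeline_icc <- function(anns, images, annotators, qs_levels) {
  experts <- annotators$annotator_id[annotators$group == "expert"]
  nonexp <- annotators$annotator_id[annotators$group == "nonexpert"]
  model <- annotators$annotator_id[annotators$group == "model"]
  all_ids <- annotators$annotator_id
  rows <- list()
  add <- function(grouping, label, mat, imgs = images) {
    res <- tryCatch(suppressWarnings(icc(mat)), error = function(e) NULL)
    if (is.null(res)) return()
    rows[[length(rows) + 1]] <<- tibble::tibble(
      grouping = grouping, label = label, icc = res$icc,
      p_value = res$p_value, band = if (is.na(res$icc)) NA_character_ else
        icc_band(res$icc),
      n_images = res$n, n_raters = res$k
    )
  }
  mat_for <- function(label, imgs) {
    per_image_counts(anns[anns$image_id %in% imgs$image_id, , drop = FALSE],
                     imgs, label, annotators = all_ids)
  }
  group_cols <- function(m) {
    cols <- list()
    if (length(model) > 0) cols$model <- m[, model, drop = FALSE]
    if (length(experts) > 0) cols$expert <- group_mean_rounded(m, experts)
    if (length(nonexp) > 0) cols$nonexpert <- group_mean_rounded(m, nonexp)
    do.call(cbind, cols)
  }
  m_live <- mat_for("live", images)
  if (length(model) && length(experts) && length(nonexp)) {
    add("between_all_groups", "live", group_cols(m_live))
  }
  if (length(experts) && length(nonexp)) {
    gm <- cbind(group_mean_rounded(m_live, experts),
                group_mean_rounded(m_live, nonexp))
    add("expert_vs_nonexpert", "live", gm)
    for (lab in c("dead", "unknown")) {
      m <- mat_for(lab, images)
      add("expert_vs_nonexpert", lab,
          cbind(group_mean_rounded(m, experts), group_mean_rounded(m, nonexp)))
    }
  }
  if (length(experts) > 1) add("within_expert", "live",
                               m_live[, experts, drop = FALSE])
  if (length(nonexp) > 1) add("within_nonexpert", "live",
                              m_live[, nonexp, drop = FALSE])
  for (q in qs_levels) {
    imgs_q <- images[images$quality_score == q, , drop = FALSE]
    if (nrow(imgs_q) < 3) next
    mq <- mat_for("live", imgs_q)
    if (length(model) && length(experts) && length(nonexp)) {
      add(paste0("between_all_groups_qs", q), "live",
          cbind(mq[, model, drop = FALSE],
                group_mean_rounded(mq, experts),
                group_mean_rounded(mq, nonexp)))
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- tibble::tibble(grouping = character(), label = character(),
                          icc = numeric(), p_value = numeric(),
                          band = character(), n_images = integer(),
                          n_raters = integer())
  }
  out
}

pipeline_rank_tests <- function(anns, images, annotators) {
  experts <- annotators$annotator_id[annotators$group == "expert"]
  nonexp <- annotators$annotator_id[annotators$group == "nonexpert"]
  model <- annotators$annotator_id[annotators$group == "model"]
  rows <- list()
  m_live <- per_image_counts(anns, images, "live",
                             annotators = annotators$annotator_id)
  if (length(model) && length(experts) && length(nonexp) &&
      nrow(m_live) >= 3) {
    groups <- list(
      model = as.numeric(m_live[, model[1]]),
      expert = as.numeric(group_mean_rounded(m_live, experts)),
      nonexpert = as.numeric(group_mean_rounded(m_live, nonexp))
    )
    kt <- tryCatch(rank_tests(groups, "multigroup"), error = function(e) NULL)
    if (!is.null(kt)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        comparison = "live_counts_by_group", test = kt$test,
        statistic = kt$statistic, p_value = kt$p_value
      )
      pw <- kt$pairwise
      rows[[length(rows) + 1]] <- tibble::tibble(
        comparison = paste("dunn", pw$group1, pw$group2, sep = "_"),
        test = "dunn", statistic = pw$z, p_value = pw$p_adjusted
      )
    }
  }
  if (length(experts) && length(nonexp)) {
    for (lab in c("dead", "unknown")) {
      m <- per_image_counts(anns, images, lab,
                            annotators = annotators$annotator_id)
      wt <- tryCatch(
        rank_tests(list(expert = as.numeric(group_mean_rounded(m, experts)),
                        nonexpert = as.numeric(group_mean_rounded(m, nonexp))),
                   "paired"),
        error = function(e) NULL)
      if (!is.null(wt)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          comparison = paste0(lab, "_counts_expert_vs_nonexpert"),
          test = wt$test, statistic = wt$statistic, p_value = wt$p_value
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- tibble::tibble(comparison = character(), test = character(),
                          statistic = numeric(), p_value = numeric())
  }
  out
}

#' Write the pipeline report bundle to disk
#'
#' Emits the consensus tables, cluster summary, tidy metrics, confusion
#' tables (one labelled CSV each), ICC table, rank-test table and a JSON run
#' manifest into `out_dir`.
#'
#' @param bundle a `run_bundle` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_outputs <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  w(bundle$cluster_summary, "clusters.csv")
  w(bundle$consensus$all_class, "consensus_all_class.csv")
  w(bundle$consensus$live_only, "consensus_live_only.csv")
  w(bundle$metrics, "metrics.csv")
  w(bundle$icc, "icc.csv")
  w(bundle$tests, "tests.csv")
  for (name in names(bundle$confusion)) {
    utils::write.csv(as.data.frame(unclass(bundle$confusion[[name]])),
                     file.path(out_dir, paste0("confusion_", name, ".csv")))
  }
  jsonlite::write_json(bundle$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' One-page human-readable summary of a pipeline run
#'
#' @param bundle a `run_bundle` from [run_pipeline()].
#' @return a character vector of markdown lines (also usable with `cat`).
#' @export
summarize_run <- function(bundle) {
  stopifnot(inherits(bundle, "run_bundle"))
  fmt <- function(x, d = 2) ifelse(is.na(x), "NA", sprintf(paste0("%.", d, "f"), x))
  lines <- c(
    "# Multi-annotator concordance run summary",
    "",
    sprintf("- images analysed: %d (seed %d)", bundle$manifest$n_images,
            bundle$manifest$seed),
    sprintf("- annotations after admission filters: %d",
            nrow(bundle$annotations)),
    sprintf("- unique objects (clusters): %d", nrow(bundle$cluster_summary)),
    sprintf("- consensus objects, all-class rule: %d; live-only rule: %d",
            nrow(bundle$consensus$all_class), nrow(bundle$consensus$live_only)),
    "",
    "## Live-vs-not-observed metrics by group"
  )
  for (g in ANNOTATION_GROUPS) {
    m <- bundle$metrics[bundle$metrics$stratum == g, , drop = FALSE]
    if (nrow(m) == 0) {
      lines <- c(lines, sprintf("- %s: no data", g))
    } else {
      lines <- c(lines, sprintf(
        "- %s: accuracy %s, precision %s, recall %s, F1 %s, AUC %s",
        g, fmt(m$accuracy), fmt(m$precision), fmt(m$recall), fmt(m$f1),
        fmt(m$auc)))
    }
  }
  lines <- c(lines, "", "## Agreement of per-image live counts (ICC)")
  if (nrow(bundle$icc) == 0) {
    lines <- c(lines, "- no data")
  } else {
    for (i in seq_len(nrow(bundle$icc))) {
      r <- bundle$icc[i, ]
      lines <- c(lines, sprintf("- %s (%s): ICC = %s (%s), p = %s",
                                r$grouping, r$label, fmt(r$icc, 3),
                                ifelse(is.na(r$band), "NA", r$band),
                                fmt(r$p_value, 4)))
    }
  }
  if (!is.null(bundle$oracle)) {
    ov <- bundle$oracle$recovery
    overall <- ov$recovered[ov$class == "overall"]
    lines <- c(lines, "", "## Ground-truth recovery (synthetic input)",
               sprintf("- clustering purity: %s", fmt(bundle$oracle$purity, 3)),
               sprintf("- consensus recovery (overall): %s",
                       fmt(if (length(overall)) overall else NA_real_, 3)))
  }
  lines
}
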