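CONSENSUS_TRUTHS <- c("live", "dead", "unknown", "false_positive")

count_votes <- function(labels) {
  c(live = sum(labels == "live"),
    dead = sum(labels == "dead"),
    unknown = sum(labels == "unknown"))
}

#' All-class consensus rule
#'
#' Adjudicates a cluster's true label from the labels its members carry.
#' An object identified by two or fewer annotators is a false positive.
#' Otherwise the truth is the most frequent label, with a fixed tie hierarchy:
#' live beats any tie it is part of, and dead beats unknown. The per-object
#' confidence is the number of votes matching the adjudicated truth divided by
#' the number of identifiers (for a false positive, the modal label's count is
#' used as the matching count — a package convention, since no vote can be
#' "false_positive").
#'
#' @param labels character vector of member labels (`live`/`dead`/`unknown`),
#'   one per annotator that identified the object.
#' @return a list: `truth`, `confidence`, `n_identifiers`, `votes`
#'   (named count vector), `method`.
#' @seealso [consensus_live_only()], [confidence_score()]
#' @export
consensus_all_class <- function(labels) {
  if (length(labels) == 0) stop("empty cluster", call. = FALSE)
  stopifnot(all(labels %in% ANNOTATION_LABELS))
  votes <- count_votes(labels)
  n <- length(labels)
  truth <- if (n <= 2) {
    "false_positive"
  } else {
    mx <- max(votes)
    if (votes[["live"]] == mx) "live"
    else if (votes[["dead"]] == mx) "dead"
    else "unknown"
  }
  list(truth = truth,
       confidence = confidence_score(votes, truth, n),
       n_identifiers = n, votes = votes, method = "all_class")
}

#' Live-only consensus rule
#'
#' The second adjudication rule considers only live votes: a cluster with no
#' live identifications is removed from the dataset (returns `NULL`); one or
#' two live identifications make a false positive; three or more make the
#' object live. Confidence is computed exactly as in [consensus_all_class()],
#' over all identifiers of the object.
#'
#' @inheritParams consensus_all_class
#' @return a list as in [consensus_all_class()], or `NULL` if the cluster is
#'   removed (zero live votes).
#' @export
consensus_live_only <- function(labels) {
  if (length(labels) == 0) stop("empty cluster", call. = FALSE)
  stopifnot(all(labels %in% ANNOTATION_LABELS))
  votes <- count_votes(labels)
  n <- length(labels)
  n_live <- votes[["live"]]
  if (n_live == 0) return(NULL)
  truth <- if (n_live >= 3) "live" else "false_positive"
  list(truth = truth,
       confidence = confidence_score(votes, truth, n),
       n_identifiers = n, votes = votes, method = "live_only")
}

#' Per-object confidence score
#'
#' The fraction of an object's identifications that match its adjudicated
#' truth: matching votes / total identifications. For `truth =
#' "false_positive"` the modal label's count is taken as the matching count.
#'
#' @param vote_counts named integer vector with entries `live`, `dead`,
#'   `unknown`.
#' @param truth one of `live`, `dead`, `unknown`, `false_positive`.
#' @param n_identifiers total identifications of the object (>= 1).
#' @return a number in (0, 1\]; 1 exactly when the votes are unanimous.
#' @export
confidence_score <- function(vote_counts, truth, n_identifiers) {
  if (n_identifiers < 1) stop("n_identifiers must be >= 1", call. = FALSE)
  stopifnot(truth %in% CONSENSUS_TRUTHS)
  matching <- if (truth == "false_positive") {
    max(vote_counts)
  } else {
    vote_counts[[truth]]
  }
  matching / n_identifiers
}

#' Consensus table for all clusters
#'
#' Runs one consensus rule over every cluster of a clustered annotation table.
#' Clusters removed by the live-only rule (no live votes) are absent from the
#' output.
#'
#' @param clustered output of [cluster_annotations()].
#' @param method `"all_class"` or `"live_only"`.
#' @param include_model_in_quorum if `FALSE`, the model's member is excluded
#'   from vote counting (and from the identifier quorum) before adjudication;
#'   default `TRUE` counts the model as one annotator.
#' @return a [tibble::tibble]: `cluster_id`, `image_id`, `method`, `truth`,
#'   `confidence`, `n_identifiers`, `n_live`, `n_dead`, `n_unknown`.
#' @export
consensus_table <- function(clustered, method = c("all_class", "live_only"),
                            include_model_in_quorum = TRUE) {
  method <- match.arg(method)
  stopifnot("cluster_id" %in% names(clustered))
  fn <- if (method == "all_class") consensus_all_class else consensus_live_only
  split_idx <- split(seq_len(nrow(clustered)), clustered$cluster_id)
  rows <- lapply(split_idx, function(idx) {
    m <- clustered[idx, , drop = FALSE]
    if (!include_model_in_quorum) {
      m <- m[m$group != "model", , drop = FALSE]
      if (nrow(m) == 0) return(NULL)
    }
    res <- fn(m$label)
    if (is.null(res)) return(NULL)
    tibble::tibble(
      cluster_id = m$cluster_id[1], image_id = m$image_id[1],
      method = method, truth = res$truth, confidence = res$confidence,
      n_identifiers = res$n_identifiers,
      n_live = res$votes[["live"]], n_dead = res$votes[["dead"]],
      n_unknown = res$votes[["unknown"]]
    )
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) {
    return(tibble::tibble(
      cluster_id = character(), image_id = character(), method = character(),
      truth = character(), confidence = numeric(), n_identifiers = integer(),
      n_live = integer(), n_dead = integer(), n_unknown = integer()
    ))
  }
  out <- do.call(rbind, rows)
  out[order(out$image_id, out$cluster_id), , drop = FALSE]
}
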