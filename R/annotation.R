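## Aggregating per-annotator survey responses into utterance-level and
## cluster-level moral labels.  The thresholds implement the survey
## aggregation rules exactly: >= 75% moral votes -> moral with the majority
## foundation; < 50% -> nonmoral; the 50-75% band -> moral only when the
## majority foundation confirms the utterance's initial (seed-derived)
## foundation; listed one-word utterances are always nonmoral.

#' Default one-word blacklist
#'
#' Single-word utterances that convey no moral context on their own and are
#' always labelled nonmoral: kinship and role nouns plus bare dictionary
#' words whose isolated mention is uninformative.
#'
#' @return character vector of lowercase word types.
#' @export
mfd_blacklist <- function() {
  c("mommy", "mother", "cried", "together", "monarch", "food", "blood",
    "mucky", "trash", "garbage", "nurse", "queen", "refused", "country",
    "wife", "daddy", "dad")
}

#' Construct a moral label
#'
#' @param relevance `"moral"` or `"nonmoral"`.
#' @param foundation a foundation-polarity category (or foundation name)
#'   when moral, `NA` when nonmoral.
#' @param provenance one of `"unanimous_rule"`, `"band_rule"`,
#'   `"blacklist"`, `"propagated"`.
#' @param tie logical, whether a vote tie was resolved.
#' @return a list of class `moral_label`.
#' @export
moral_label <- function(relevance, foundation = NA_character_,
                        provenance = "unanimous_rule", tie = FALSE) {
  stopifnot(relevance %in% c("moral", "nonmoral"))
  if (relevance == "nonmoral") foundation <- NA_character_
  if (relevance == "moral" && is.na(foundation)) {
    stop("a moral label requires a foundation")
  }
  structure(list(relevance = relevance, foundation = foundation,
                 provenance = provenance, tie = tie),
            class = "moral_label")
}

#' @export
print.moral_label <- function(x, ...) {
  cat(sprintf("moral_label: %s%s [%s]%s\n", x$relevance,
              if (x$relevance == "moral") paste0(" / ", x$foundation) else "",
              x$provenance, if (isTRUE(x$tie)) " (tie resolved)" else ""))
  invisible(x)
}

check_annotation_records <- function(records) {
  needed <- c("utterance_id", "annotator_id", "says_moral", "foundations",
              "passed_attention")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0L) {
    stop("annotation records lack column(s): ", paste(missing, collapse = ", "))
  }
  bad <- vapply(seq_len(nrow(records)), function(i) {
    f <- records$foundations[[i]]
    length(f[!is.na(f) & nzchar(f)]) > 0L && !records$says_moral[i]
  }, TRUE)
  if (any(bad)) stop("records with foundations but says_moral = FALSE")
  invisible(records)
}

#' Remove annotators who failed the attention check
#'
#' @param records annotation data.frame with columns `utterance_id`,
#'   `annotator_id`, `says_moral`, `foundations` (list column of category
#'   vectors), `passed_attention`.
#' @return the records of passing annotators only.
#' @export
filter_annotators <- function(records) {
  check_annotation_records(records)
  failed <- unique(records$annotator_id[!records$passed_attention])
  out <- records[!records$annotator_id %in% failed, , drop = FALSE]
  rownames(out) <- NULL
  out
}

foundation_votes <- function(records) {
  unlist(records$foundations[records$says_moral], use.names = FALSE)
}

#' Aggregate survey responses for one utterance
#'
#' Applies, in order: (a) a single-token utterance whose token is
#' blacklisted is nonmoral regardless of votes; (b) moral-vote share >= 0.75
#' gives a moral label with the majority foundation among chosen categories
#' (each selected category counts one vote; ties prefer the initial
#' foundation, then lexicographic order); (c) share < 0.5 gives nonmoral;
#' (d) 0.5 <= share < 0.75 gives moral only when the majority foundation
#' equals the utterance's initial foundation, else nonmoral.
#'
#' @param records annotation rows for one utterance (post
#'   [filter_annotators()]; at least one row).
#' @param initial_foundation the seed-derived category of the utterance.
#' @param tokens the utterance's tokens (used for the one-word blacklist);
#'   may be omitted when blacklisting is not wanted.
#' @param blacklist lowercase word types, default [mfd_blacklist()].
#' @return a [moral_label()].
#' @export
aggregate_utterance <- function(records, initial_foundation, tokens = NULL,
                                blacklist = mfd_blacklist()) {
  if (nrow(records) == 0L) stop("no annotation records for utterance")
  if (!is.null(tokens) && length(tokens) == 1L && tolower(tokens) %in% blacklist) {
    return(moral_label("nonmoral", provenance = "blacklist"))
  }
  share <- mean(records$says_moral)
  votes <- foundation_votes(records)
  maj <- majority_vote(votes, prefer = initial_foundation)
  if (share >= 0.75) {
    if (is.na(maj$winner)) return(moral_label("nonmoral", provenance = "unanimous_rule"))
    return(moral_label("moral", maj$winner, "unanimous_rule", tie = maj$tie))
  }
  if (share < 0.5) {
    return(moral_label("nonmoral", provenance = "unanimous_rule"))
  }
  if (!is.na(maj$winner) && identical(maj$winner, initial_foundation)) {
    return(moral_label("moral", maj$winner, "band_rule", tie = maj$tie))
  }
  moral_label("nonmoral", provenance = "band_rule")
}

#' Aggregate survey responses for one cluster
#'
#' Pools all records for all surveyed utterances in the cluster: relevance
#' is the pooled majority of moral votes (an exact tie gives nonmoral,
#' logged); the foundation is the majority over all chosen categories (ties
#' broken lexicographically, logged).
#'
#' @param records pooled annotation rows for the cluster's surveyed
#'   utterances.
#' @return a [moral_label()].
#' @export
aggregate_cluster <- function(records) {
  if (nrow(records) == 0L) stop("no annotation records for cluster")
  n_moral <- sum(records$says_moral)
  n_non <- nrow(records) - n_moral
  if (n_moral <= n_non) {
    return(moral_label("nonmoral", provenance = "unanimous_rule",
                       tie = n_moral == n_non))
  }
  maj <- majority_vote(foundation_votes(records))
  moral_label("moral", maj$winner, "unanimous_rule", tie = maj$tie)
}

#' Agreement ratio between surveyed utterances and their cluster label
#'
#' The fraction of a cluster's surveyed utterances whose aggregated label
#' agrees with the cluster-level label, computed separately for the
#' relevance field and the foundation field (foundation `NA` matches `NA`,
#' i.e. two nonmoral labels agree).
#'
#' @param utterance_labels list of [moral_label()]s for the surveyed
#'   utterances of one cluster.
#' @param cluster_label the cluster's [moral_label()].
#' @return named numeric vector `c(relevance = ..., foundation = ...)`.
#' @export
agreement_ratio <- function(utterance_labels, cluster_label) {
  if (length(utterance_labels) == 0L) stop("no labelled surveyed utterances")
  rel <- vapply(utterance_labels, function(l) l$relevance == cluster_label$relevance, TRUE)
  fnd <- vapply(utterance_labels, function(l) {
    identical(l$foundation, cluster_label$foundation) ||
      (is.na(l$foundation) && is.na(cluster_label$foundation))
  }, TRUE)
  c(relevance = mean(rel), foundation = mean(fnd))
}
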