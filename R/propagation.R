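## Extending survey labels to the rest of the corpus.  Seed-matched
## utterances get a majority vote over {cluster label, 2 nearest surveyed
## neighbours}; utterances without seed words (never clustered) get a
## majority vote over their 3 nearest surveyed neighbours.

#' Nearest surveyed neighbours by cosine similarity
#'
#' @param query numeric vector (non-zero).
#' @param surveyed numeric matrix of surveyed-utterance vectors in the same
#'   space, rownames = utterance ids.
#' @param k number of neighbours.
#' @return data.frame with `neighbor_id`, `cosine`, `rank`; exact cosine
#'   ties are broken by utterance id (stable).
#' @export
nearest_surveyed <- function(query, surveyed, k) {
  if (k > nrow(surveyed)) {
    stop("k = ", k, " exceeds the surveyed pool of ", nrow(surveyed))
  }
  cos <- cosine_rows(query, surveyed)
  ord <- order(-cos, rownames(surveyed), na.last = TRUE)
  top <- ord[seq_len(k)]
  data.frame(neighbor_id = rownames(surveyed)[top], cosine = cos[top],
             rank = seq_len(k), stringsAsFactors = FALSE)
}

vote_over_labels <- function(labels, initial_foundation = NULL,
                             fallback_foundation = NULL) {
  rel_votes <- vapply(labels, `[[`, "", "relevance")
  n_moral <- sum(rel_votes == "moral")
  relevance <- if (n_moral > length(labels) / 2) "moral" else "nonmoral"
  if (relevance == "nonmoral") {
    return(moral_label("nonmoral", provenance = "propagated"))
  }
  fvotes <- vapply(labels, `[[`, "", "foundation")
  fvotes <- fvotes[!is.na(fvotes)]
  tab <- table(fvotes)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) {
    return(moral_label("moral", top, "propagated"))
  }
  # tied foundations: the initial (seed-derived) foundation wins when it is
  # among the votes; otherwise the designated fallback (cluster label or
  # rank-1 neighbour) decides
  if (!is.null(initial_foundation) && initial_foundation %in% fvotes) {
    return(moral_label("moral", initial_foundation, "propagated", tie = TRUE))
  }
  if (!is.null(fallback_foundation) && !is.na(fallback_foundation)) {
    return(moral_label("moral", fallback_foundation, "propagated", tie = TRUE))
  }
  moral_label("moral", sort(top)[1L], "propagated", tie = TRUE)
}

#' Propagate a label to a seed-matched utterance
#'
#' Majority vote over three labels: the utterance's cluster label and the
#' labels of its two nearest surveyed neighbours.  Relevance is the
#' majority of the three relevance votes.  The foundation is the majority
#' of the three foundation votes; when all differ (a 3-way tie) the
#' utterance's initial seed-derived foundation wins if it is among the
#' votes, else the cluster's foundation is used.
#'
#' @param cluster_label the [moral_label()] of the utterance's cluster.
#' @param neighbor_labels list of exactly 2 neighbour [moral_label()]s.
#' @param initial_foundation the utterance's seed-derived category.
#' @return a [moral_label()] with provenance `"propagated"`.
#' @export
propagate_seeded <- function(cluster_label, neighbor_labels, initial_foundation) {
  if (is.null(cluster_label) || length(neighbor_labels) != 2L ||
      any(vapply(neighbor_labels, is.null, TRUE))) {
    stop("propagation needs a cluster label and exactly 2 neighbour labels")
  }
  vote_over_labels(c(list(cluster_label), neighbor_labels),
                   initial_foundation = initial_foundation,
                   fallback_foundation = cluster_label$foundation)
}

#' Propagate a label to an utterance without seed words
#'
#' Majority vote over the labels of the 3 nearest surveyed neighbours in
#' the contextual space.  A 3-way foundation tie falls back to the rank-1
#' neighbour's foundation (flagged in the label).
#'
#' @param neighbor_labels list of exactly 3 neighbour [moral_label()]s,
#'   ordered by rank.
#' @return a [moral_label()] with provenance `"propagated"`.
#' @export
propagate_unseeded <- function(neighbor_labels) {
  if (length(neighbor_labels) != 3L) stop("exactly 3 neighbour labels required")
  vote_over_labels(neighbor_labels,
                   fallback_foundation = neighbor_labels[[1L]]$foundation)
}

#' Run the seed-matched labelling pipeline end to end
#'
#' Convenience driver for the full "further annotation" stage: matches the
#' lexicon against the corpus, encodes the seed-matched utterances, runs
#' the per-cell clustering stage, and propagates the supplied survey labels
#' to every unsurveyed seed-matched utterance via [propagate_cell()].  An
#' utterance matched into several cells keeps the label from the first cell
#' (in category x role order) that labels it.
#'
#' @param utterances utterance data.frame.
#' @param lexicon lexicon data.frame.
#' @param encoder sentence encoder, e.g. [hash_encoder()].
#' @param surveyed_labels named list of [moral_label()]s for the surveyed
#'   utterances.
#' @param variance_target,k_range,seed passed to [run_clustering_stage()].
#' @param min_age_years,max_age_years passed to [match_seeds()].
#' @return list with `labels` (named list: surveyed labels plus propagated
#'   labels), `stage` (the `clustering_stage`), `matches`, and
#'   `initial` (seed-derived categories).
#' @export
run_seed_pipeline <- function(utterances, lexicon, encoder, surveyed_labels,
                              variance_target = 0.95, k_range = 2:10,
                              seed = 1L, min_age_years = 1, max_age_years = 6) {
  matches <- match_seeds(utterances, lexicon, min_age_years, max_age_years)
  seeded <- unique(matches$utterance_id)
  V <- encode_contextual(utterances[utterances$utterance_id %in% seeded, ,
                                    drop = FALSE], encoder)
  stage <- run_clustering_stage(V, matches, utterances, variance_target,
                                k_range, seed)
  init <- initial_categories(matches)
  labels <- surveyed_labels
  for (cell in stage$cells) {
    got <- propagate_cell(cell$model, cell$reduced, surveyed_labels, init)
    new <- setdiff(names(got), names(labels))
    labels[new] <- got[new]
  }
  list(labels = labels, stage = stage, matches = matches, initial = init)
}

#' Propagate survey labels across one clustering cell
#'
#' Convenience wrapper tying the pieces together for a fitted cell: cluster
#' labels are the pooled majority over the surveyed members of each cluster,
#' and every unsurveyed member receives [propagate_seeded()] with its two
#' nearest surveyed neighbours in the cell's reduced space.
#'
#' @param model a `cluster_model` for the cell.
#' @param vectors the cell's reduced vectors.
#' @param surveyed_labels named list of [moral_label()]s for the surveyed
#'   utterances (names are utterance ids; any subset of the cell).
#' @param initial_foundations named character vector utterance_id -> seed
#'   category.
#' @return named list of [moral_label()]s for the unsurveyed members.
#'   Clusters containing no surveyed member yield no labels and are listed
#'   in attribute `unlabelled_clusters`.
#' @export
propagate_cell <- function(model, vectors, surveyed_labels, initial_foundations) {
  surveyed_ids <- intersect(names(surveyed_labels), names(model$assignments))
  out <- list()
  unlabelled <- integer(0)
  cluster_labels <- list()
  for (cl in sort(unique(model$assignments))) {
    members <- names(model$assignments)[model$assignments == cl]
    s <- intersect(members, surveyed_ids)
    if (length(s) == 0L) {
      unlabelled <- c(unlabelled, cl)
      next
    }
    labs <- surveyed_labels[s]
    n_moral <- sum(vapply(labs, function(l) l$relevance == "moral", TRUE))
    if (n_moral > length(labs) / 2) {
      f <- majority_vote(unlist(lapply(labs, `[[`, "foundation")))
      cluster_labels[[as.character(cl)]] <- moral_label("moral", f$winner,
                                                        "propagated", f$tie)
    } else {
      cluster_labels[[as.character(cl)]] <- moral_label("nonmoral",
                                                        provenance = "propagated")
    }
  }
  if (length(surveyed_ids) >= 2L) {
    S <- vectors[surveyed_ids, , drop = FALSE]
    for (id in setdiff(names(model$assignments), surveyed_ids)) {
      cl <- as.character(model$assignments[[id]])
      clab <- cluster_labels[[cl]]
      if (is.null(clab)) next
      nn <- nearest_surveyed(vectors[id, ], S, 2L)
      out[[id]] <- propagate_seeded(clab, surveyed_labels[nn$neighbor_id],
                                    initial_foundations[[id]])
    }
  }
  attr(out, "unlabelled_clusters") <- unlabelled
  attr(out, "cluster_labels") <- cluster_labels
  out
}
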