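## Moral word-sense disambiguation: per foundation-polarity x speaker-role
## cell, embedded seed-matched utterances are clustered with a Gaussian
## mixture; k in 2..10 is chosen to maximize the mean silhouette width.
## Survey sentences are selected per cluster by proximity to the cluster
## mean (cosine), taking the closest ("prototypical") and furthest
## ("peripheral") members.

fit_gmm_k <- function(X, k, seed) {
  fit <- with_seed(seed, tryCatch(
    suppressWarnings(Mclust(
      X, G = k, modelNames = "VVV", verbose = FALSE,
      prior = priorControl(functionName = "defaultPrior"))),
    error = function(e) NULL))
  if (is.null(fit)) {
    # degenerate cells (tiny n, collinear points): spherical fallback
    fit <- with_seed(seed, tryCatch(
      suppressWarnings(Mclust(
        X, G = k, modelNames = "EII", verbose = FALSE,
        prior = priorControl(functionName = "defaultPrior"))),
      error = function(e) NULL))
  }
  fit
}

mean_silhouette <- function(assignments, X) {
  if (length(unique(assignments)) < 2L) return(NA_real_)
  sil <- cluster::silhouette(assignments, stats::dist(X))
  mean(sil[, "sil_width"])
}

#' Fit a mixture model to one clustering cell
#'
#' Fits a full-covariance Gaussian mixture (with a conjugate-prior
#' regularization of the covariances) for every `k` in `k_range`, scores
#' each clustering by mean silhouette width (Euclidean distance on the
#' given vectors) and returns the fit with the highest silhouette; ties are
#' broken toward the smallest `k`.  `k_range` is truncated to `n - 1` when
#' the cell has fewer than `max(k_range) + 1` members.  Cells with fewer
#' than 3 members fall back to a single cluster with undefined silhouette.
#'
#' @param vectors numeric matrix of (reduced) sentence vectors, rownames =
#'   utterance ids.
#' @param k_range integer candidate cluster counts (default `2:10`).
#' @param seed RNG seed for the mixture fits.
#' @param cell optional cell label `(category, role)` carried in the result.
#' @return an object of class `cluster_model`: list with `cell`, `k` (the
#'   realized number of non-empty clusters), `k_requested` (the mixture
#'   order selected), `assignments` (named integer vector), `silhouette`,
#'   `seed`, `silhouette_by_k`, `fallback`.
#' @export
fit_cell <- function(vectors, k_range = 2:10, seed = 1L, cell = NULL) {
  n <- nrow(vectors)
  ids <- rownames(vectors)
  if (n < 3L) {
    return(structure(list(cell = cell, k = 1L,
                          assignments = stats::setNames(rep(1L, n), ids),
                          silhouette = NA_real_, seed = seed,
                          silhouette_by_k = numeric(0), fallback = TRUE),
                     class = "cluster_model"))
  }
  kr <- k_range[k_range <= n - 1L & k_range >= 2L]
  if (length(kr) < length(k_range)) {
    message("k_range truncated to 2..", n - 1L, " for a cell of ", n, " members")
  }
  if (length(kr) == 0L) kr <- 2L
  sils <- stats::setNames(rep(NA_real_, length(kr)), kr)
  fits <- vector("list", length(kr))
  for (i in seq_along(kr)) {
    fit <- fit_gmm_k(vectors, kr[i], seed)
    if (is.null(fit)) next
    fits[[i]] <- as.integer(fit$classification)
    sils[i] <- mean_silhouette(fits[[i]], vectors)
  }
  ok <- which(!is.na(sils))
  if (length(ok) == 0L) {
    return(structure(list(cell = cell, k = 1L,
                          assignments = stats::setNames(rep(1L, n), ids),
                          silhouette = NA_real_, seed = seed,
                          silhouette_by_k = sils, fallback = TRUE),
                     class = "cluster_model"))
  }
  best <- ok[which.max(sils[ok])]            # which.max takes the first (smallest k) tie
  assignments <- stats::setNames(fits[[best]], ids)
  # mixture components can come out empty; k is the realized cluster count
  structure(list(cell = cell, k = length(unique(assignments)),
                 k_requested = kr[best],
                 assignments = assignments,
                 silhouette = unname(sils[best]), seed = seed,
                 silhouette_by_k = sils, fallback = FALSE),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: k = %d over %d utterances, silhouette = %s%s\n",
              x$k, length(x$assignments),
              if (is.na(x$silhouette)) "NA" else sprintf("%.3f", x$silhouette),
              if (isTRUE(x$fallback)) " (fallback)" else ""))
  if (!is.null(x$cell)) cat("  cell:", paste(unlist(x$cell), collapse = " / "), "\n")
  invisible(x)
}

#' Proximity of a sentence vector to a cluster
#'
#' Cosine similarity between a sentence vector and the cluster center,
#' where the center is the arithmetic mean of the member vectors.
#'
#' @param v numeric sentence vector.
#' @param center numeric cluster-mean vector (non-zero, same length).
#' @param id optional utterance id used in error messages.
#' @return cosine similarity in `[-1, 1]`.
#' @export
proximity <- function(v, center, id = NULL) {
  if (length(v) != length(center)) stop("vector and center lengths differ")
  if (sqrt(sum(v * v)) == 0) {
    stop("zero vector for utterance ", id %||% "<unnamed>")
  }
  if (sqrt(sum(center * center)) == 0) stop("cluster center is the zero vector")
  cosine(v, center)
}

#' Summarize the clusters of a fitted cell
#'
#' @param model a `cluster_model`.
#' @param vectors the matrix the model was fitted on.
#' @return a list, one element per cluster index: `center`, `member_ids`,
#'   `proximity` (named, sorted decreasing).
#' @export
cluster_summaries <- function(model, vectors) {
  lapply(sort(unique(model$assignments)), function(cl) {
    ids <- names(model$assignments)[model$assignments == cl]
    M <- vectors[ids, , drop = FALSE]
    center <- colMeans(M)
    nc <- sqrt(sum(center * center))
    nv <- sqrt(rowSums(M * M))
    degenerate <- nc < 1e-12
    if (degenerate) {
      # a cluster centered exactly at the origin of the (centered) reduced
      # space, or identical member texts: cosine is undefined, use a flat
      # proximity with deterministic id order
      prox <- stats::setNames(rep(0, length(ids)), ids)
    } else {
      prox <- as.vector(M %*% center) / (nv * nc)
      prox[nv < 1e-12] <- 0
      names(prox) <- ids
    }
    prox <- prox[order(-prox, ids)]
    list(cluster = cl, center = center, member_ids = ids, proximity = prox,
         degenerate = degenerate)
  })
}

#' Select prototypical and peripheral survey sentences
#'
#' For each cluster, takes up to `n_proto` members with the highest
#' proximity to the cluster mean (prototypical) and up to `n_proto` with the
#' lowest (peripheral).  Sentences are de-duplicated globally by utterance
#' text across both lists and across clusters: the first occurrence (in
#' cluster order, prototypes before peripherals) is kept.
#'
#' @param summaries result of [cluster_summaries()].
#' @param texts named character vector utterance_id -> raw text.
#' @param n_proto maximum per list per cluster (default 10).
#' @return list per cluster with `prototypes` and `peripherals` id vectors.
#' @export
select_survey_sentences <- function(summaries, texts, n_proto = 10L) {
  seen <- new.env(parent = emptyenv())
  claim <- function(ids) {
    kept <- character(0)
    for (i in ids) {
      key <- tolower(trimws(texts[[i]] %||% i))
      if (is.null(seen[[key]])) {
        assign(key, TRUE, envir = seen)
        kept <- c(kept, i)
      }
    }
    kept
  }
  lapply(summaries, function(s) {
    ordered <- names(s$proximity)          # decreasing proximity
    protos <- utils::head(ordered, n_proto)
    periph <- utils::head(rev(ordered), n_proto)
    list(cluster = s$cluster,
         prototypes = claim(protos),
         peripherals = claim(periph))
  })
}

#' Run the full clustering stage over all cells
#'
#' Partitions seed-matched utterances into (foundation-polarity category x
#' speaker role) cells — 10 categories x 2 roles = 20 cells when all are
#' populated — reduces each cell's contextual vectors by PCA to the variance
#' target, and fits one mixture per cell.  An utterance with seed matches in
#' several categories joins every matching cell.  Empty or singleton cells
#' are skipped with a warning and listed in the result.
#'
#' @param vectors contextual sentence vectors (rownames = utterance ids).
#' @param matches seed matches from [match_seeds()].
#' @param utterances utterance data.frame (for speaker roles and texts).
#' @param variance_target PCA variance target (default 0.95).
#' @param k_range candidate cluster counts (default `2:10`).
#' @param seed RNG seed.
#' @param n_proto survey sentences per list per cluster (default 10).
#' @return an object of class `clustering_stage`: list with `cells` (per
#'   populated cell: `model`, `summaries`, `survey`, `reduced`, `reduction`),
#'   and `skipped` (cell names with too few members).
#' @export
run_clustering_stage <- function(vectors, matches, utterances,
                                 variance_target = 0.95, k_range = 2:10,
                                 seed = 1L, n_proto = 10L) {
  role <- stats::setNames(utterances$speaker_role, utterances$utterance_id)
  texts <- stats::setNames(utterances$text, utterances$utterance_id)
  pairs <- unique(matches[, c("utterance_id", "category")])
  pairs$role <- role[pairs$utterance_id]
  cells <- list()
  skipped <- character(0)
  for (cat in mf_categories()) {
    for (r in c("child", "caretaker")) {
      name <- paste(cat, r, sep = "|")
      ids <- pairs$utterance_id[pairs$category == cat & pairs$role == r]
      ids <- intersect(ids, rownames(vectors))
      if (length(ids) < 2L) {
        skipped <- c(skipped, name)
        warning("cell ", name, " has ", length(ids), " utterance(s); skipped")
        next
      }
      red <- reduce_vectors(vectors[ids, , drop = FALSE], variance_target)
      model <- fit_cell(red$scores, k_range, seed = seed,
                        cell = list(category = cat, role = r))
      summaries <- cluster_summaries(model, red$scores)
      survey <- select_survey_sentences(summaries, texts, n_proto)
      cells[[name]] <- list(model = model, summaries = summaries,
                            survey = survey, reduced = red$scores,
                            reduction = red[c("rotation", "center",
                                              "explained_variance_ratio",
                                              "source_dim", "target_dim")])
    }
  }
  structure(list(cells = cells, skipped = skipped, seed = seed),
            class = "clustering_stage")
}

#' @export
print.clustering_stage <- function(x, ...) {
  nclust <- sum(vapply(x$cells, function(c) c$model$k, 1L))
  cat(sprintf("clustering_stage: %d cell fit(s), %d cluster(s), %d cell(s) skipped\n",
              length(x$cells), nclust, length(x$skipped)))
  invisible(x)
}
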