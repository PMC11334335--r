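## Blank-slate moral inference: regularized multinomial logistic models on
## mean static word embeddings of labelled conversational utterances,
## evaluated by micro-F1 on balanced out-of-domain test sets, over a grid of
## age cutoffs x embedding variants x speaker roles, with size-matched
## random-label controls.

#' Collapse fine-grained moral labels
#'
#' `"fairness_merge"` maps Equality and Proportionality to Fairness (the
#' six-foundation scheme back to five).  `"drop_polarity"` maps a
#' foundation-polarity category to its foundation (`Care.virtue` ->
#' `Care`).  `"both"` applies both, giving the 5-class scheme.  `"none"` is
#' the identity.  Unknown labels are an error.
#'
#' @param labels character vector of labels.
#' @param mode one of `"none"`, `"fairness_merge"`, `"drop_polarity"`,
#'   `"both"`.
#' @return character vector of collapsed labels.
#' @export
collapse_labels <- function(labels, mode = c("both", "fairness_merge",
                                             "drop_polarity", "none")) {
  mode <- match.arg(mode)
  known <- c(mf_categories(), mf_foundations(), "Equality", "Proportionality",
             "moral", "nonmoral")
  bad <- setdiff(unique(labels), known)
  if (length(bad) > 0L) stop("unknown label(s): ", paste(bad, collapse = ", "))
  out <- labels
  if (mode %in% c("drop_polarity", "both")) {
    is_cat <- out %in% mf_categories()
    out[is_cat] <- split_category(out[is_cat])$foundation
  }
  if (mode %in% c("fairness_merge", "both")) {
    out[out %in% c("Equality", "Proportionality")] <- "Fairness"
  }
  out
}

featurize_tokens <- function(token_list, table) {
  M <- t(vapply(token_list, function(t) mean_embedding(t, table),
                numeric(table$dim)))
  zero <- rowSums(abs(M)) == 0
  attr(M, "zero_rows") <- which(zero)
  M
}

#' Assemble a training matrix for one model configuration
#'
#' Selects labelled utterances of the requested speaker role with integer
#' age (`floor(months/12)`) at or below the cumulative cutoff, featurizes
#' them as mean static embeddings, and builds targets for the task:
#' `binary_relevance` uses moral vs nonmoral labels; `fine_10class` keeps
#' moral utterances with their 10 foundation-polarity categories;
#' `fine_5class` collapses polarity (and Equality/Proportionality into
#' Fairness).  All-out-of-vocabulary (zero-vector) utterances are excluded
#' from the matrix but counted in attribute `n_zero_dropped`.
#'
#' @param utterances utterance data.frame.
#' @param labels label data.frame (`utterance_id`, `relevance`,
#'   `foundation`) or named list of [moral_label()]s.
#' @param table an `embedding_table`.
#' @param task `"binary_relevance"`, `"fine_10class"` or `"fine_5class"`.
#' @param age_cutoff_years cumulative upper age in years (1..6).
#' @param speaker_role `"child"` or `"caretaker"`.
#' @return list with `features` (matrix) and `targets` (factor).  Fewer
#'   than two target classes is an error naming the classes present.
#' @export
build_training_matrix <- function(utterances, labels, table,
                                  task = c("binary_relevance", "fine_10class",
                                           "fine_5class"),
                                  age_cutoff_years = 6L,
                                  speaker_role = "child") {
  task <- match.arg(task)
  lab <- if (is.data.frame(labels)) labels else labels_to_frame(labels)
  u <- merge(utterances, lab, by = "utterance_id")
  u <- u[u$speaker_role == speaker_role &
           floor(u$child_age_months / 12) <= age_cutoff_years, , drop = FALSE]
  if (task == "binary_relevance") {
    y <- u$relevance
  } else {
    u <- u[u$relevance == "moral" & !is.na(u$foundation), , drop = FALSE]
    y <- if (task == "fine_10class") u$foundation else collapse_labels(u$foundation, "both")
  }
  classes <- unique(y)
  if (length(classes) < 2L) {
    stop("training data has ", length(classes), " class(es): ",
         paste(classes, collapse = ", "))
  }
  X <- featurize_tokens(u$tokens, table)
  rownames(X) <- u$utterance_id
  zero <- attr(X, "zero_rows")
  if (length(zero) > 0L) {
    X <- X[-zero, , drop = FALSE]
    y <- y[-zero]
  }
  structure(list(features = X, targets = factor(y)),
            n_zero_dropped = length(zero))
}

#' Train a regularized multinomial logistic classifier
#'
#' Multinomial logistic regression fitted by penalized maximum likelihood
#' (quadratic weight decay); deterministic given the data and seed.
#'
#' @param features numeric matrix.
#' @param targets factor (>= 2 levels present).
#' @param seed RNG seed.
#' @param decay L2 penalty (default 1e-3).
#' @param maxit maximum iterations (default 200).
#' @return object of class `moral_classifier`.
#' @export
train_linear <- function(features, targets, seed = 1L, decay = 1e-3,
                         maxit = 200L) {
  targets <- droplevels(as.factor(targets))
  if (nlevels(targets) < 2L) {
    stop("degenerate training set: single class ", levels(targets))
  }
  df <- data.frame(features)
  df$.y <- targets
  fit <- with_seed(seed, nnet::multinom(
    .y ~ ., data = df, decay = decay, maxit = maxit, trace = FALSE,
    MaxNWts = 10000L))
  structure(list(fit = fit, levels = levels(targets), dim = ncol(features),
                 decay = decay, seed = seed),
            class = "moral_classifier")
}

#' @export
print.moral_classifier <- function(x, ...) {
  cat(sprintf("moral_classifier: %d classes (%s), %d features, decay = %g\n",
              length(x$levels), paste(x$levels, collapse = ", "), x$dim, x$decay))
  invisible(x)
}

#' Predict classes and probabilities
#'
#' @param object a `moral_classifier`.
#' @param newdata numeric feature matrix.
#' @param ... unused.
#' @return list with `class` (character) and `probs` (matrix, one column
#'   per class).
#' @export
predict.moral_classifier <- function(object, newdata, ...) {
  df <- data.frame(newdata)
  colnames(df) <- object$fit$coefnames[-1L]
  p <- stats::predict(object$fit, newdata = df, type = "probs")
  if (is.null(dim(p))) {   # 2-class: vector of P(second level)
    p <- cbind(1 - p, p)
    colnames(p) <- object$levels
  }
  p <- as.matrix(p)
  list(class = object$levels[max.col(p, ties.method = "first")], probs = p)
}

#' Micro-averaged F1
#'
#' Pooled over all decisions; for single-label multi-class prediction this
#' equals accuracy (pooled false positives equal pooled false negatives).
#'
#' @param predictions,golds character vectors of equal positive length.
#' @return micro-F1 in `[0, 1]`.
#' @export
micro_f1 <- function(predictions, golds) {
  if (length(predictions) != length(golds)) stop("length mismatch")
  if (length(golds) == 0L) stop("empty evaluation")
  mean(predictions == golds)
}

#' Classify a multi-sentence document
#'
#' Splits the document into sentences with the corpus preprocessing
#' splitter, classifies each sentence, and labels the document with the
#' majority of sentence labels; ties are broken toward the label with the
#' highest summed predicted probability (flagged via attribute `tie`).
#'
#' @param text document text.
#' @param classifier a `moral_classifier`.
#' @param table the `embedding_table` used for features.
#' @param lemmatizer passed to [preprocess()].
#' @return the document label (character scalar).
#' @export
predict_long_text <- function(text, classifier, table, lemmatizer = lemmatize_en) {
  sents <- preprocess(text, lemmatizer)
  if (length(sents) == 0L) stop("document is empty after sentence splitting")
  X <- featurize_tokens(sents, table)
  pred <- predict(classifier, X)
  tab <- table(pred$class)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) return(top)
  sums <- colSums(pred$probs[, top, drop = FALSE])
  structure(top[which.max(sums)], tie = TRUE)
}

#' Sample balanced test sets from a labelled pool
#'
#' Each of `n_sets` sets draws, without replacement within the set, an
#' equal number of documents per class — the size of the smallest class
#' (optionally capped).  Sampling is seeded.
#'
#' @param pool data.frame with columns `text`, `label`.
#' @param n_sets number of balanced sets (default 10).
#' @param seed RNG seed.
#' @param cap optional per-class cap.
#' @return list of `n_sets` data.frames.
#' @export
balanced_eval <- function(pool, n_sets = 10L, seed = 1L, cap = Inf) {
  sizes <- table(pool$label)
  if (any(sizes == 0L) || length(sizes) < 2L) {
    stop("every class needs at least one pool member; got ",
         paste(names(sizes), sizes, sep = "=", collapse = ", "))
  }
  n_per <- min(min(sizes), cap)
  by_class <- split(seq_len(nrow(pool)), pool$label)
  with_seed(seed, lapply(seq_len(n_sets), function(s) {
    idx <- unlist(lapply(by_class, function(i) sample(i, n_per)))
    out <- pool[idx, , drop = FALSE]
    rownames(out) <- NULL
    out
  }))
}

evaluate_on_sets <- function(classifier, table, test_sets, long = FALSE,
                             lemmatizer = lemmatize_en) {
  vapply(test_sets, function(ts) {
    pred <- if (long) {
      vapply(ts$text, function(d)
        as.character(predict_long_text(d, classifier, table, lemmatizer)), "")
    } else {
      X <- featurize_tokens(lapply(ts$text, function(t) {
        s <- preprocess(t, lemmatizer); unlist(s)
      }), table)
      predict(classifier, X)$class
    }
    micro_f1(pred, ts$label)
  }, 0)
}

ci95 <- function(scores) {
  m <- mean(scores)
  half <- 1.96 * stats::sd(scores) / sqrt(length(scores))
  c(mean = m, lo = m - half, hi = m + half)
}

#' Run the full model grid
#'
#' Trains one classifier per (cumulative age cutoff x embedding variant x
#' speaker role) cell — 6 x 4 x 2 = 48 configurations with the defaults —
#' and evaluates each on every balanced test set, reporting mean micro-F1
#' with a 95% confidence interval (mean +/- 1.96 sd/sqrt(n) over the sets).
#' With `train_source = "random_control"`, each configuration instead
#' trains on `n_control` size-matched samples from `control_pool`
#' (utterances without seed words) with uniformly random class labels, and
#' reports the score averaged over the control repeats.
#'
#' @param utterances utterance data.frame.
#' @param labels labels as in [build_training_matrix()].
#' @param tables named list of `embedding_table`s, one per embedding
#'   variant (the names become the grid's `embedding_variant` values).
#' @param test_sets list of balanced test data.frames (`text`, `label`).
#' @param task passed to [build_training_matrix()].
#' @param roles speaker roles to cover (default both).
#' @param cutoffs cumulative age cutoffs (default `1:6`).
#' @param train_source `"moral_labels"` or `"random_control"`.
#' @param control_pool utterance data.frame without seed matches (required
#'   for the control).
#' @param n_control control resamples per configuration (default 20).
#' @param long treat test documents as multi-sentence (majority vote over
#'   sentences).
#' @param seed RNG seed.
#' @return data.frame with one row per configuration: `task`,
#'   `age_cutoff_years`, `embedding_variant`, `speaker_role`,
#'   `train_source`, `n_train`, `micro_f1`, `ci_lo`, `ci_hi`,
#'   `n_test_sets`.
#' @export
run_grid <- function(utterances, labels, tables, test_sets,
                     task = "binary_relevance",
                     roles = c("child", "caretaker"), cutoffs = 1:6,
                     train_source = c("moral_labels", "random_control"),
                     control_pool = NULL, n_control = 20L, long = FALSE,
                     seed = 1L) {
  train_source <- match.arg(train_source)
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stop("tables must be a named list of embedding variants")
  }
  if (train_source == "random_control" && is.null(control_pool)) {
    stop("random_control requires a control_pool")
  }
  classes <- sort(unique(unlist(lapply(test_sets, function(ts) ts$label))))
  rows <- list()
  cfg <- 0L
  for (role in roles) for (variant in names(tables)) for (cut in cutoffs) {
    cfg <- cfg + 1L
    table <- tables[[variant]]
    tm <- build_training_matrix(utterances, labels, table, task, cut, role)
    if (train_source == "moral_labels") {
      clf <- train_linear(tm$features, tm$targets, seed = seed + cfg)
      scores <- evaluate_on_sets(clf, table, test_sets, long)
    } else {
      n_train <- nrow(tm$features)
      per_rep <- with_seed(seed + cfg, {
        vapply(seq_len(n_control), function(r) {
          idx <- sample(nrow(control_pool), min(n_train, nrow(control_pool)),
                        replace = nrow(control_pool) < n_train)
          Xc <- featurize_tokens(control_pool$tokens[idx], table)
          yc <- factor(sample(classes, length(idx), replace = TRUE),
                       levels = classes)
          clf <- train_linear(Xc, yc, seed = seed + cfg + r)
          mean(evaluate_on_sets(clf, table, test_sets, long))
        }, 0)
      })
      scores <- per_rep
    }
    ci <- ci95(scores)
    rows[[cfg]] <- data.frame(
      task = task, age_cutoff_years = cut, embedding_variant = variant,
      speaker_role = role, train_source = train_source,
      n_train = nrow(tm$features), micro_f1 = ci[["mean"]],
      ci_lo = ci[["lo"]], ci_hi = ci[["hi"]],
      n_test_sets = length(test_sets), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
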