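## Developmental analyses: frequency time-courses of moral categories per
## age and speaker role, bootstrap significance of individual word
## frequencies, negation split, mean length of utterance, lexical-subset
## (property word / modal verb) courses, and CS-vs-CDS rate comparison.

labels_to_frame <- function(labels) {
  data.frame(utterance_id = names(labels),
             relevance = vapply(labels, `[[`, "", "relevance"),
             foundation = vapply(labels, function(l) l$foundation %||% NA_character_, ""),
             stringsAsFactors = FALSE)
}

age_years_of <- function(months, pool_above = NULL) {
  yr <- floor(months / 12)
  if (!is.null(pool_above)) {
    lab <- ifelse(yr > pool_above, paste0(pool_above + 1, "+"), as.character(yr))
  } else {
    lab <- as.character(yr)
  }
  lab
}

#' Frequency time-course of moral categories
#'
#' Counts morally labelled utterances per (age year, speaker role,
#' foundation-polarity category) cell and normalizes either as the share of
#' all moral utterances at that (age, role) (`"share_of_moral"`), or per
#' total utterances at that (age, role) (`"per_total_sentences"`).  Integer
#' age is `floor(months / 12)`; ages above `pool_above` (if given) are
#' pooled into one open bin, e.g. `pool_above = 6` pools ages 7+.
#'
#' @param utterances utterance data.frame.
#' @param labels either a named list of [moral_label()]s or a data.frame
#'   with columns `utterance_id`, `relevance`, `foundation` (category).
#' @param normalization `"share_of_moral"` or `"per_total_sentences"`.
#' @param by_gender stratify by `child_gender` (default FALSE).
#' @param pool_above optional integer age above which ages are pooled.
#' @return data.frame with one row per populated cell: `age_year`,
#'   `speaker_role` (plus `child_gender` when stratified), `category`,
#'   `foundation`, `polarity`, `count`, `denominator`, `freq`,
#'   `normalization`.
#' @export
time_course <- function(utterances, labels,
                        normalization = c("share_of_moral", "per_total_sentences"),
                        by_gender = FALSE, pool_above = NULL) {
  normalization <- match.arg(normalization)
  lab <- if (is.data.frame(labels)) labels else labels_to_frame(labels)
  u <- utterances
  u$age_year <- age_years_of(u$child_age_months, pool_above)
  u <- merge(u[, c("utterance_id", "age_year", "speaker_role", "child_gender")],
             lab, by = "utterance_id", all.x = TRUE)
  strata <- c("age_year", "speaker_role", if (by_gender) "child_gender")
  key <- interaction(u[strata], drop = TRUE, sep = "\r")
  totals <- table(key)
  moral <- u[!is.na(u$relevance) & u$relevance == "moral" & !is.na(u$foundation), ]
  if (nrow(moral) == 0L) {
    return(data.frame(age_year = character(0), speaker_role = character(0),
                      category = character(0), foundation = character(0),
                      polarity = character(0), count = integer(0),
                      denominator = integer(0), freq = numeric(0),
                      normalization = character(0), stringsAsFactors = FALSE))
  }
  mkey <- interaction(moral[strata], drop = FALSE, sep = "\r")
  counts <- as.data.frame(table(key = mkey, category = moral$foundation),
                          stringsAsFactors = FALSE)
  counts <- counts[counts$Freq > 0, , drop = FALSE]
  moral_totals <- table(mkey)
  parts <- strsplit(counts$key, "\r", fixed = TRUE)
  out <- data.frame(age_year = vapply(parts, `[`, "", 1L),
                    speaker_role = vapply(parts, `[`, "", 2L),
                    stringsAsFactors = FALSE)
  if (by_gender) out$child_gender <- vapply(parts, `[`, "", 3L)
  out$category <- counts$category
  fp <- split_category(counts$category)
  out$foundation <- fp$foundation
  out$polarity <- fp$polarity
  out$count <- counts$Freq
  out$denominator <- if (normalization == "share_of_moral") {
    as.integer(moral_totals[counts$key])
  } else {
    as.integer(totals[counts$key])
  }
  out$freq <- out$count / out$denominator
  out$normalization <- normalization
  ord <- order(out$age_year, out$speaker_role, out$category)
  rownames(out) <- NULL
  out[ord, , drop = FALSE]
}

## per-sentence counts of each seed word type; sentences = list of token
## vectors, words = seed lemma types
seed_count_matrix <- function(sentences, words) {
  W <- length(words)
  n <- length(sentences)
  toks <- unlist(sentences, use.names = FALSE)
  sid <- rep.int(seq_len(n), lengths(sentences))
  wid <- match(toks, words)
  keep <- !is.na(wid)
  counts <- tabulate((sid[keep] - 1L) * W + wid[keep], nbins = W * n)
  matrix(counts, W, n, dimnames = list(words, NULL))
}

#' Bootstrap significance of a moral word's frequency
#'
#' For the moral utterances at one age and speaker role, draws `n_perm`
#' bootstrap resamples of the utterances (with replacement, same size) and
#' in each compares the word's seed-token frequency with the mean frequency
#' over all moral seed words present.  The p-value is the add-one estimate
#' `(1 + #\{resamples where word frequency >= mean\}) / (n_perm + 1)`; a word
#' is flagged as insignificant (usage below the moral-vocabulary average)
#' when `p < alpha`.
#'
#' @param sentences list of token vectors for the moral utterances of one
#'   (age, role) cell.
#' @param seed_words the moral seed lemma types present in the cell.
#' @param word the word under test (must be one of `seed_words`).
#' @param n_perm number of bootstrap resamples (default 2000).
#' @param alpha significance level (default 0.01).
#' @param seed RNG seed.
#' @return list of class `permutation_result`: `word`, `p_value`,
#'   `flagged_insignificant`, `n_perm`, `alpha`, `seed`.
#' @export
word_significance <- function(sentences, seed_words, word, n_perm = 2000L,
                              alpha = 0.01, seed = 1L) {
  if (length(sentences) == 0L) stop("no moral utterances supplied")
  if (!word %in% seed_words) stop("word ", word, " is not among the seed words")
  res <- word_significance_all(sentences, seed_words, n_perm, alpha, seed)
  row <- res[res$word == word, ]
  structure(list(word = word, p_value = row$p_value,
                 flagged_insignificant = row$flagged_insignificant,
                 n_perm = n_perm, alpha = alpha, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result: '%s' p = %.4f (alpha = %g)%s\n",
              x$word, x$p_value, x$alpha,
              if (x$flagged_insignificant) " [below-average usage]" else ""))
  invisible(x)
}

#' @describeIn word_significance vectorized version over all seed words;
#'   returns a data.frame with one row per word.
#' @export
word_significance_all <- function(sentences, seed_words, n_perm = 2000L,
                                  alpha = 0.01, seed = 1L) {
  if (length(sentences) == 0L) stop("no moral utterances supplied")
  C <- seed_count_matrix(sentences, seed_words)          # words x sentences
  n <- length(sentences)
  W <- length(seed_words)
  with_seed(seed, {
    # a bootstrap resample of sentences == multinomial multiplicities;
    # resamples are drawn in chunks to bound memory on large corpora
    ge_total <- numeric(W)
    done <- 0L
    chunk <- max(1L, min(n_perm, as.integer(2e7 / n)))
    while (done < n_perm) {
      b <- min(chunk, n_perm - done)
      mult <- stats::rmultinom(b, n, rep(1 / n, n))      # sentences x b
      freq <- (C %*% mult) / n                           # words x b
      mean_freq <- colSums(freq) / W
      ge_total <- ge_total + rowSums(freq >= rep(mean_freq, each = W))
      done <- done + b
    }
    p <- (1 + ge_total) / (n_perm + 1)
    data.frame(word = seed_words, p_value = p,
               flagged_insignificant = p < alpha,
               n_perm = n_perm, alpha = alpha, seed = seed,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Split utterances into positive and negative forms
#'
#' An utterance is negative iff its lowercased text contains the standalone
#' words `no` or `not`, or the contraction `n't` (curly apostrophes are
#' normalized first).  `nobody`, `nothing` etc. do not count.
#'
#' @param text character vector of raw utterance texts.
#' @return character vector, `"positive"` or `"negative"`.
#' @export
negation_split <- function(text) {
  x <- tolower(normalize_apostrophes(text))
  neg <- grepl("\\bno\\b|\\bnot\\b", x) | grepl("n't", x, fixed = TRUE)
  ifelse(neg, "negative", "positive")
}

#' Mean length of utterance
#'
#' Arithmetic mean of word-level token counts, the standard MLU proxy for
#' language complexity.
#'
#' @param utterances utterance data.frame with a `tokens` list column, or a
#'   list of token vectors.
#' @return mean tokens per utterance.
#' @export
mlu <- function(utterances) {
  toks <- if (is.data.frame(utterances)) utterances$tokens else utterances
  if (length(toks) == 0L) stop("no utterances supplied")
  mean(lengths(toks))
}

match_lexical_pattern <- function(text, patterns) {
  x <- tolower(normalize_apostrophes(text))
  hits <- rep(FALSE, length(x))
  for (p in patterns) {
    p <- tolower(normalize_apostrophes(p))
    esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", p)
    # patterns starting with the clitic n't attach to the preceding word,
    # so no leading word boundary there
    re <- if (startsWith(p, "n't")) paste0(esc, "\\b") else paste0("\\b", esc, "\\b")
    hits <- hits | grepl(re, x)
  }
  hits
}

#' Frequency course of a fixed word set
#'
#' Counts, per (age year, speaker role), the utterances whose raw lowercased
#' text contains at least one of the listed patterns (multi-word patterns
#' are matched literally with word boundaries; patterns beginning with
#' `n't` match the clitic).  With `mode = "moral_only"` only morally
#' labelled utterances are counted.  Frequencies are normalized per total
#' utterances at the (age, role); a foundation breakdown of the matching
#' moral utterances is attached as attribute `"foundations"`.
#'
#' @param utterances utterance data.frame.
#' @param labels labels as in [time_course()] (needed for `moral_only` and
#'   the foundation breakdown; may be `NULL` with `mode = "all"`).
#' @param word_set character vector of patterns, e.g.
#'   `c("mine", "yours", "not mine", "not yours", "n't mine", "n't yours")`.
#' @param mode `"moral_only"` or `"all"`.
#' @param pool_above optional age pooling as in [time_course()].
#' @return data.frame with `age_year`, `speaker_role`, `count`,
#'   `denominator`, `freq`.
#' @export
lexical_subset_course <- function(utterances, labels = NULL, word_set,
                                  mode = c("moral_only", "all"),
                                  pool_above = NULL) {
  mode <- match.arg(mode)
  if (length(word_set) == 0L) stop("word_set is empty")
  u <- utterances
  u$age_year <- age_years_of(u$child_age_months, pool_above)
  u$hit <- match_lexical_pattern(u$text, word_set)
  lab <- NULL
  if (!is.null(labels)) {
    lab <- if (is.data.frame(labels)) labels else labels_to_frame(labels)
    u <- merge(u, lab, by = "utterance_id", all.x = TRUE)
  }
  if (mode == "moral_only") {
    if (is.null(lab)) stop("mode = 'moral_only' requires labels")
    counted <- u$hit & !is.na(u$relevance) & u$relevance == "moral"
  } else {
    counted <- u$hit
  }
  key <- interaction(u$age_year, u$speaker_role, drop = TRUE, sep = "\r")
  totals <- table(key)
  hits <- table(key[counted])
  parts <- strsplit(names(totals), "\r", fixed = TRUE)
  out <- data.frame(age_year = vapply(parts, `[`, "", 1L),
                    speaker_role = vapply(parts, `[`, "", 2L),
                    count = as.integer(hits[names(totals)]),
                    denominator = as.integer(totals),
                    stringsAsFactors = FALSE)
  out$count[is.na(out$count)] <- 0L
  out$freq <- out$count / out$denominator
  if (!is.null(lab)) {
    br <- u[counted & !is.na(u$foundation), c("age_year", "speaker_role", "foundation")]
    attr(out, "foundations") <- if (nrow(br) > 0L) {
      as.data.frame(table(br), stringsAsFactors = FALSE)
    } else NULL
  }
  rownames(out) <- NULL
  out[order(out$age_year, out$speaker_role), , drop = FALSE]
}

#' Compare per-age moral rates between child and caretaker speech
#'
#' One-way analysis of variance on the per-age rates of each foundation with
#' speaker role as the factor, testing whether children and caretakers talk
#' about a foundation at different rates across ages.
#'
#' @param rates data.frame with columns `foundation`, `age_year`,
#'   `speaker_role`, `freq` (e.g. a [time_course()] result aggregated to
#'   foundations).
#' @return data.frame with one row per foundation: `foundation`,
#'   `f_statistic`, `p_value`, `df1`, `df2`.
#' @export
compare_roles <- function(rates) {
  out <- lapply(split(rates, rates$foundation), function(d) {
    if (length(unique(d$speaker_role)) < 2L || nrow(d) < 3L) {
      stop("need per-age rates for both roles (foundation ",
           d$foundation[1L], ")")
    }
    fit <- stats::aov(freq ~ speaker_role, data = d)
    s <- summary(fit)[[1L]]
    data.frame(foundation = d$foundation[1L],
               f_statistic = s[["F value"]][1L],
               p_value = s[["Pr(>F)"]][1L],
               df1 = s[["Df"]][1L], df2 = s[["Df"]][2L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
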