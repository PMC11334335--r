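## Synthetic study inputs with known ground truth: an age-structured
## child/caretaker corpus with planted foundation-polarity usage curves,
## ambiguous (nonmoral) senses of a polysemous seed word, negation, a toy
## moral dictionary, simulated survey annotators, and out-of-domain labelled
## test documents.  Every output is a pure function of (config, seed).

#' Built-in synthetic vocabulary
#'
#' Seed words and category-typical frame words per foundation-polarity
#' category, plus filler vocabulary for nonmoral sentences.  Frame
#' vocabularies are disjoint across categories so that the hashing sentence
#' encoder separates categories geometrically, mirroring the real contrast
#' between, say, fair-allocation talk and fairground talk.  The word
#' `fair` is the designated polysemous seed: its nonmoral sense appears in
#' fairground sentences.
#'
#' @return list with `categories` (per category: `seeds` as `.dic`
#'   patterns, `frames`), `filler`, `polysemous`.
#' @export
sim_vocabulary <- function() {
  list(
    categories = list(
      "Care.virtue" = list(seeds = c("help*", "care*", "protect*"),
                           frames = c("gently", "kind", "baby", "bandage")),
      "Care.vice" = list(seeds = c("hurt*", "fight*", "kick*"),
                         frames = c("ouch", "cry", "mean", "bruise")),
      "Fairness.virtue" = list(seeds = c("fair", "share*", "equal*"),
                               frames = c("toys", "everyone", "halves", "game")),
      "Fairness.vice" = list(seeds = c("cheat*", "steal*", "unfair"),
                             frames = c("trick", "sneaky", "dice", "prize")),
      "Loyalty.virtue" = list(seeds = c("together", "loyal", "team"),
                              frames = c("friends", "family", "club", "stick")),
      "Loyalty.vice" = list(seeds = c("betray*", "enemy", "traitor"),
                            frames = c("secret", "side", "against", "told")),
      "Authority.virtue" = list(seeds = c("obey*", "permission", "respect*"),
                                frames = c("teacher", "listen", "ask", "please")),
      "Authority.vice" = list(seeds = c("disobey*", "naughty", "rebel*"),
                              frames = c("rules", "broke", "timeout", "corner")),
      "Purity.virtue" = list(seeds = c("clean*", "pure", "holy"),
                             frames = c("wash", "hands", "bath", "soap")),
      "Purity.vice" = list(seeds = c("dirty", "germ*", "gross"),
                           frames = c("yuck", "floor", "touch", "icky"))
    ),
    filler = c("look", "ball", "red", "big", "outside", "dog", "car", "book",
               "play", "lunch", "tree", "run", "jump", "sun", "shoe", "hat",
               "window", "door", "milk", "banana"),
    polysemous = list("Fairness.virtue" = "fair"),
    nonmoral_frames = c("ride", "carnival", "balloon", "today", "went")
  )
}

#' Toy moral lexicon for the synthetic vocabulary
#'
#' @param vocabulary a [sim_vocabulary()] list.
#' @return a lexicon data.frame in the [load_lexicon()] layout.
#' @export
sim_lexicon <- function(vocabulary = sim_vocabulary()) {
  rows <- list()
  for (cat in names(vocabulary$categories)) {
    for (s in vocabulary$categories[[cat]]$seeds) {
      is_stem <- endsWith(s, "*")
      rows[[length(rows) + 1L]] <- list(
        pattern = if (is_stem) substr(s, 1, nchar(s) - 1L) else s,
        is_stem = is_stem, category = cat)
    }
  }
  out <- data.frame(pattern = vapply(rows, `[[`, "", "pattern"),
                    is_stem = vapply(rows, `[[`, TRUE, "is_stem"),
                    category = vapply(rows, `[[`, "", "category"),
                    stringsAsFactors = FALSE)
  fp <- split_category(out$category)
  out$foundation <- fp$foundation
  out$polarity <- fp$polarity
  out[, c("pattern", "is_stem", "foundation", "polarity", "category")]
}

#' Write a lexicon as a LIWC-style .dic file
#'
#' @param lexicon lexicon data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_mfd_dic <- function(lexicon, path) {
  cats <- sort(unique(lexicon$category))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("%", con)
  for (i in seq_along(cats)) {
    writeLines(sprintf("%d\t%s", i, tolower(cats[i])), con)
  }
  writeLines("%", con)
  for (j in seq_len(nrow(lexicon))) {
    pat <- paste0(lexicon$pattern[j], if (lexicon$is_stem[j]) "*" else "")
    writeLines(sprintf("%s\t%d", pat, match(lexicon$category[j], cats)), con)
  }
  invisible(path)
}

#' Default planted emergence curves
#'
#' Category weights per age year 1..6, mirroring the developmental shape
#' the analyses are designed to detect: Care (both polarities) present from
#' age 1 and dominant throughout, Fairness and Purity from age 2, Authority
#' from age 3, Loyalty from age 4, with gradually rising shares for the
#' later foundations.  Rows are normalized at sampling time.
#'
#' @return 10 x 6 matrix, rownames = categories, colnames = ages.
#' @export
default_emergence_curves <- function() {
  m <- rbind(
    "Care.virtue"      = c(.55, .45, .40, .35, .33, .30),
    "Care.vice"        = c(.45, .34, .30, .27, .24, .22),
    "Fairness.virtue"  = c(0,   .05, .07, .09, .11, .12),
    "Fairness.vice"    = c(0,   .03, .05, .06, .07, .08),
    "Loyalty.virtue"   = c(0,    0,   0,  .03, .03, .04),
    "Loyalty.vice"     = c(0,    0,   0,  .02, .02, .02),
    "Authority.virtue" = c(0,    0,  .03, .05, .06, .07),
    "Authority.vice"   = c(0,    0,  .02, .03, .04, .05),
    "Purity.virtue"    = c(0,   .03, .04, .04, .04, .04),
    "Purity.vice"      = c(0,   .05, .06, .06, .06, .06))
  colnames(m) <- as.character(1:6)
  m[mf_categories(), , drop = FALSE]
}

#' Synthetic-corpus generator configuration
#'
#' Defaults define the simulated study conditions: ages 1-6, both speaker
#' roles, a moral-content rate of 0.30 (child) / 0.35 (caretaker) per
#' sentence, planted emergence curves per [default_emergence_curves()], a
#' 10% ambiguous (nonmoral) sense rate on the polysemous seed, higher
#' negation on vice than virtue categories, and a survey of 300 annotators
#' with 40 items each, individual accuracy 0.9 and a 1/6 attention-failure
#' rate (so roughly 50 of 300 fail).
#'
#' @param seed base RNG seed.
#' @param n_per_age_role sentences generated per (age, role) cell.
#' @param ... overrides for any config field.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_per_age_role = 150L, ...) {
  neg <- stats::setNames(rep(c(0.1, 0.25), 5L), mf_categories())
  cfg <- list(
    seed = seed,
    n_children = 20L,
    ages = 1:6,
    n_per_age_role = n_per_age_role,
    p_moral = c(child = 0.30, caretaker = 0.35),
    emergence_curves = default_emergence_curves(),
    ambiguity_rate = 0.10,
    negation_rate = neg,
    annotator_accuracy = 0.9,
    n_annotators = 300L,
    utterances_per_annotator = 40L,
    attention_fail_rate = 1 / 6,
    vocabulary = sim_vocabulary(),
    corpus_name = "SimCorpus")
  dots <- list(...)
  cfg[names(dots)] <- dots
  probs <- c(cfg$p_moral, cfg$ambiguity_rate, cfg$negation_rate,
             cfg$annotator_accuracy, cfg$attention_fail_rate,
             as.vector(cfg$emergence_curves))
  if (any(probs < 0 | probs > 1)) stop("config probabilities must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

seed_surface <- function(pattern, is_stem) {
  if (!is_stem) return(pattern)
  suffix <- sample(c("", "ing", "s"), 1L, prob = c(.6, .2, .2))
  paste0(pattern, suffix)
}

moral_sentence <- function(category, vocabulary, negated) {
  info <- vocabulary$categories[[category]]
  s <- sample(info$seeds, 1L)
  is_stem <- endsWith(s, "*")
  seed_tok <- seed_surface(if (is_stem) substr(s, 1, nchar(s) - 1L) else s, is_stem)
  subj <- sample(c("you", "we", "i", "she", "he"), 1L)
  frames <- sample(info$frames, 2L)
  toks <- c(subj, if (negated) "not", seed_tok, "the", frames)
  paste0(paste(toks, collapse = " "), ".")
}

ambiguous_sentence <- function(word, vocabulary) {
  frames <- sample(vocabulary$nonmoral_frames, 2L)
  paste0(paste(c("did", "you", "like", "the", word, frames), collapse = " "), ".")
}

filler_sentence <- function(vocabulary) {
  n <- sample(3:6, 1L)
  paste0(paste(sample(vocabulary$filler, n), collapse = " "), ".")
}

#' Generate a synthetic child-caretaker corpus with ground truth
#'
#' Sentences are templated from the synthetic vocabulary.  Each sentence is
#' moral with the role's `p_moral`; moral sentences draw a
#' foundation-polarity category from the emergence-curve column of the
#' child's age and embed one of that category's seed words in a
#' category-typical frame, negated at the category's negation rate.  When
#' the drawn category owns a polysemous seed, the sentence instead uses the
#' seed in its nonmoral sense with probability `ambiguity_rate`.  Remaining
#' sentences are filler built from seed-free vocabulary.  Children (and
#' hence genders) are assigned round-robin; exact month ages are drawn
#' within the year.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_corpus`: `utterances` (utterance data.frame),
#'   `manifest` (ground truth: `utterance_id`, `true_relevance`,
#'   `true_category`, `true_foundation`, `true_polarity`,
#'   `is_ambiguous_sense`, `age_year`, `speaker_role`, `child_id`),
#'   `lexicon`, `config`.
#' @export
generate_corpus <- function(config = sim_config()) {
  vocab <- config$vocabulary
  cats <- rownames(config$emergence_curves)
  with_seed(config$seed, {
    rows <- list(); man <- list()
    counter <- 0L
    child_gender <- rep(c("female", "male"), length.out = config$n_children)
    for (role in c("child", "caretaker")) {
      for (age in config$ages) {
        curve <- config$emergence_curves[, as.character(min(age, ncol(config$emergence_curves)))]
        for (i in seq_len(config$n_per_age_role)) {
          counter <- counter + 1L
          id <- sprintf("sim-%s-%05d", substr(role, 1, 2), counter)
          child <- sample.int(config$n_children, 1L)
          months <- age * 12L + sample(0:11, 1L)
          is_moral <- stats::runif(1) < config$p_moral[[role]]
          if (is_moral && sum(curve) > 0) {
            category <- sample(cats, 1L, prob = curve)
            poly <- vocab$polysemous[[category]]
            if (!is.null(poly) && stats::runif(1) < config$ambiguity_rate) {
              text <- ambiguous_sentence(poly, vocab)
              man[[counter]] <- list(id = id, rel = "nonmoral", cat = NA_character_,
                                     amb = TRUE)
            } else {
              negated <- stats::runif(1) < config$negation_rate[[category]]
              text <- moral_sentence(category, vocab, negated)
              man[[counter]] <- list(id = id, rel = "moral", cat = category,
                                     amb = FALSE)
            }
          } else {
            text <- filler_sentence(vocab)
            man[[counter]] <- list(id = id, rel = "nonmoral", cat = NA_character_,
                                   amb = FALSE)
          }
          toks <- preprocess(text)
          rows[[counter]] <- list(
            utterance_id = id, text = sub("\\.$", "", text),
            tokens = if (length(toks) > 0L) toks[[1L]] else character(0),
            speaker_role = role, child_age_months = months,
            child_gender = child_gender[child],
            corpus_name = config$corpus_name, child_id = child,
            age_year = age)
        }
      }
    }
    utterances <- utterance_frame(rows)
    utterances$child_id <- vapply(rows, function(r) as.integer(r$child_id), 1L)
    manifest <- data.frame(
      utterance_id = vapply(man, `[[`, "", "id"),
      true_relevance = vapply(man, `[[`, "", "rel"),
      true_category = vapply(man, `[[`, "", "cat"),
      is_ambiguous_sense = vapply(man, `[[`, TRUE, "amb"),
      stringsAsFactors = FALSE)
    fp <- split_category(manifest$true_category)
    manifest$true_foundation <- fp$foundation
    manifest$true_polarity <- fp$polarity
    manifest$age_year <- vapply(rows, function(r) as.integer(r$age_year), 1L)
    manifest$speaker_role <- utterances$speaker_role
    manifest$child_id <- utterances$child_id
    structure(list(utterances = utterances, manifest = manifest,
                   lexicon = sim_lexicon(vocab), config = config),
              class = "sim_corpus")
  })
}

#' @export
print.sim_corpus <- function(x, ...) {
  cat(sprintf("sim_corpus: %d utterances (%d moral), ages %s, seed %d\n",
              nrow(x$utterances), sum(x$manifest$true_relevance == "moral"),
              paste(range(x$config$ages), collapse = "-"), x$config$seed))
  invisible(x)
}

#' Write a synthetic corpus as CHAT files
#'
#' One `.cha` file per (child, age year) with `CHI` and `MOT` tiers, child
#' age recorded in the `@ID` header.  Readable by [read_chat_corpus()].
#'
#' @param corpus a `sim_corpus`.
#' @param dir output directory (created if needed).
#' @return character vector of file paths.
#' @export
write_chat_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  u <- corpus$utterances
  u$age_year <- floor(u$child_age_months / 12)
  paths <- character(0)
  for (key in unique(paste(u$child_id, u$age_year, sep = "-"))) {
    parts <- as.integer(strsplit(key, "-")[[1L]])
    sel <- u[u$child_id == parts[1L] & u$age_year == parts[2L], ]
    months <- sel$child_age_months[1L]
    age_str <- sprintf("%d;%d.", months %/% 12L, months %% 12L)
    sex <- sel$child_gender[1L]
    path <- file.path(dir, sprintf("child%02d-age%d.cha", parts[1L], parts[2L]))
    con <- file(path, "w", encoding = "UTF-8")
    writeLines(c("@UTF8", "@Begin", "@Languages:\teng",
                 "@Participants:\tCHI Target_Child, MOT Mother",
                 sprintf("@ID:\teng|%s|CHI|%s|%s|||Target_Child||",
                         corpus$config$corpus_name, age_str, sex),
                 sprintf("@ID:\teng|%s|MOT|||||Mother||",
                         corpus$config$corpus_name)), con)
    for (i in seq_len(nrow(sel))) {
      tier <- if (sel$speaker_role[i] == "child") "*CHI" else "*MOT"
      writeLines(sprintf("%s:\t%s .", tier, sel$text[i]), con)
    }
    writeLines("@End", con)
    close(con)
    paths <- c(paths, path)
  }
  paths
}

#' Simulate survey annotators
#'
#' Each annotator is assigned `utterances_per_annotator` items drawn
#' uniformly from the surveyed pool and fails the attention check with
#' probability `attention_fail_rate`.  On each item the annotator reports
#' the exact ground truth with probability `annotator_accuracy`; otherwise,
#' for a truly moral item, half the errors report nonmoral and half keep
#' moral with a uniformly random wrong category, and for a truly nonmoral
#' item the error reports moral with a uniformly random category.
#'
#' @param surveyed_ids utterance ids included in the survey.
#' @param manifest ground-truth manifest from [generate_corpus()].
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to `config$seed + 1`).
#' @return annotation data.frame (`utterance_id`, `annotator_id`,
#'   `says_moral`, `foundations` list column, `passed_attention`).
#' @export
simulate_survey <- function(surveyed_ids, manifest, config = sim_config(),
                            seed = config$seed + 1L) {
  truth <- manifest[match(surveyed_ids, manifest$utterance_id), ]
  if (any(is.na(truth$utterance_id))) stop("manifest does not cover all surveyed ids")
  cats <- mf_categories()
  with_seed(seed, {
    rows <- list()
    for (a in seq_len(config$n_annotators)) {
      aid <- sprintf("A%03d", a)
      passed <- stats::runif(1) >= config$attention_fail_rate
      n_items <- min(config$utterances_per_annotator, length(surveyed_ids))
      items <- sample(seq_along(surveyed_ids), n_items)
      for (i in items) {
        is_moral <- truth$true_relevance[i] == "moral"
        cat_true <- truth$true_category[i]
        if (stats::runif(1) < config$annotator_accuracy) {
          says <- is_moral
          fnd <- if (is_moral) cat_true else NULL
        } else if (is_moral) {
          if (stats::runif(1) < 0.5) {
            says <- FALSE; fnd <- NULL
          } else {
            says <- TRUE; fnd <- sample(setdiff(cats, cat_true), 1L)
          }
        } else {
          says <- TRUE; fnd <- sample(cats, 1L)
        }
        rows[[length(rows) + 1L]] <- list(
          utterance_id = surveyed_ids[i], annotator_id = aid,
          says_moral = says, foundations = fnd %||% character(0),
          passed_attention = passed)
      }
    }
    out <- data.frame(
      utterance_id = vapply(rows, `[[`, "", "utterance_id"),
      annotator_id = vapply(rows, `[[`, "", "annotator_id"),
      says_moral = vapply(rows, `[[`, TRUE, "says_moral"),
      passed_attention = vapply(rows, `[[`, TRUE, "passed_attention"),
      stringsAsFactors = FALSE)
    out$foundations <- lapply(rows, `[[`, "foundations")
    out[, c("utterance_id", "annotator_id", "says_moral", "foundations",
            "passed_attention")]
  })
}

#' Generate out-of-domain labelled test documents
#'
#' Emulates short single-sentence moral documents (tweet-like, labelled
#' with one of the 10 categories, plus seed-free nonmoral documents for the
#' binary task) and longer multi-sentence comments (2-6 sentences, labelled
#' with one of the 5 foundations, where a configurable majority of
#' sentences express the document's foundation).
#'
#' @param config a [sim_config()].
#' @param n_short documents per category in the short set (default 30).
#' @param n_long documents per foundation in the long set (default 20).
#' @param majority_frac minimum fraction of a long document's sentences
#'   expressing its label (default 0.8).
#' @param seed RNG seed (defaults to `config$seed + 2`).
#' @return list with `short` (`text`, `label` over the 10 categories plus
#'   `"nonmoral"`), `short_binary` (`text`, `label` moral/nonmoral), and
#'   `long` (`text`, `label` over the 5 foundations).
#' @export
generate_external_tests <- function(config = sim_config(), n_short = 30L,
                                    n_long = 20L, majority_frac = 0.8,
                                    seed = config$seed + 2L) {
  vocab <- config$vocabulary
  cats <- names(vocab$categories)
  with_seed(seed, {
    short_rows <- list()
    for (cat in cats) {
      for (i in seq_len(n_short)) {
        short_rows[[length(short_rows) + 1L]] <-
          list(text = moral_sentence(cat, vocab, negated = FALSE), label = cat)
      }
    }
    for (i in seq_len(n_short)) {
      short_rows[[length(short_rows) + 1L]] <-
        list(text = filler_sentence(vocab), label = "nonmoral")
    }
    short <- data.frame(text = vapply(short_rows, `[[`, "", "text"),
                        label = vapply(short_rows, `[[`, "", "label"),
                        stringsAsFactors = FALSE)
    short_binary <- data.frame(
      text = short$text,
      label = ifelse(short$label == "nonmoral", "nonmoral", "moral"),
      stringsAsFactors = FALSE)
    long_rows <- list()
    for (f in mf_foundations()) {
      own <- cats[startsWith(cats, paste0(f, "."))]
      for (i in seq_len(n_long)) {
        n_sent <- sample(2:6, 1L)
        n_own <- max(ceiling(majority_frac * n_sent), floor(n_sent / 2) + 1L)
        src <- c(sample(own, n_own, replace = TRUE),
                 sample(setdiff(cats, own), n_sent - n_own, replace = TRUE))
        sents <- vapply(sample(src), function(cat)
          moral_sentence(cat, vocab, negated = FALSE), "")
        long_rows[[length(long_rows) + 1L]] <-
          list(text = paste(sents, collapse = " "), label = f)
      }
    }
    long <- data.frame(text = vapply(long_rows, `[[`, "", "text"),
                       label = vapply(long_rows, `[[`, "", "label"),
                       stringsAsFactors = FALSE)
    list(short = short, short_binary = short_binary, long = long)
  })
}

#' Train the four static embedding variants for the model grid
#'
#' The two "pretrained" variants are trained on a large synthetic
#' background corpus drawn uniformly over all categories and filler (a
#' synthetic stand-in for embeddings pretrained on rich external text); the
#' two "corpus" variants are trained only on the supplied conversational
#' corpus, so their vocabulary is limited to what children and caretakers
#' said.
#'
#' @param corpus a `sim_corpus`.
#' @param dim embedding dimension (default 16).
#' @param n_background background-corpus size (default 3000 sentences).
#' @param seed RNG seed.
#' @return named list of four `embedding_table`s: `w2v_pretrained`,
#'   `glove_pretrained`, `w2v_corpus`, `glove_corpus`.
#' @export
sim_embedding_tables <- function(corpus, dim = 16L, n_background = 3000L,
                                 seed = corpus$config$seed + 3L) {
  vocab <- corpus$config$vocabulary
  cats <- names(vocab$categories)
  background <- with_seed(seed, lapply(seq_len(n_background), function(i) {
    if (stats::runif(1) < 0.6) {
      preprocess(moral_sentence(sample(cats, 1L), vocab,
                                negated = stats::runif(1) < 0.15))[[1L]]
    } else {
      preprocess(filler_sentence(vocab))[[1L]]
    }
  }))
  own <- corpus$utterances$tokens
  list(
    w2v_pretrained = train_static(background, "skipgram", dim, seed = seed + 1L),
    glove_pretrained = train_static(background, "glove_style", dim, seed = seed + 2L),
    w2v_corpus = train_static(own, "skipgram", dim, seed = seed + 3L),
    glove_corpus = train_static(own, "glove_style", dim, seed = seed + 4L))
}
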