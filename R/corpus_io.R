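## Reading conversational corpora (CHAT and a JSONL dialect), preprocessing
## text into lemmatized tokens, loading a LIWC-style moral dictionary and
## matching its seed words against utterances.

## small irregular-form table; the rule engine handles regular inflection
.lemma_table <- c(
  children = "child", men = "man", women = "woman", feet = "foot",
  teeth = "tooth", mice = "mouse", geese = "goose",
  making = "make", taking = "take", coming = "come", giving = "give",
  having = "have", gave = "give", took = "take", broke = "break",
  stole = "steal", went = "go", ran = "run", said = "say", got = "get",
  lying = "lie", lied = "lie", better = "good", best = "good"
)

#' Lemmatize English tokens
#'
#' A small deterministic rule-based lemmatizer: an irregular-form table plus
#' suffix rules for plural \code{-s}, \code{-es}, \code{-ies}, progressive
#' \code{-ing} and past \code{-ed} (with consonant undoubling).  Tokens
#' containing an apostrophe (contractions such as \code{don't}) are left
#' intact so that negation analysis can still see \code{n't}.  Any function
#' with the same token-vector-in, token-vector-out contract can be plugged
#' into [preprocess()] in its place.
#'
#' @param tokens character vector of lowercase tokens.
#' @return character vector of lemmas, same length.
#' @export
lemmatize_en <- function(tokens) {
  vapply(tokens, function(tok) {
    if (!is.na(.lemma_table[tok])) return(unname(.lemma_table[tok]))
    if (grepl("'", tok, fixed = TRUE)) return(tok)
    n <- nchar(tok)
    if (n > 4 && endsWith(tok, "ies")) return(paste0(substr(tok, 1, n - 3), "y"))
    if (n > 4 && grepl("(s|x|z|ch|sh)es$", tok)) return(substr(tok, 1, n - 2))
    if (n > 3 && endsWith(tok, "s") && !endsWith(tok, "ss") && !endsWith(tok, "us")) {
      return(substr(tok, 1, n - 1))
    }
    undouble <- function(s) {
      m <- nchar(s)
      if (m >= 3 && substr(s, m, m) == substr(s, m - 1, m - 1) &&
          grepl("[^aeiou]", substr(s, m, m))) substr(s, 1, m - 1) else s
    }
    if (n > 5 && endsWith(tok, "ing")) return(undouble(substr(tok, 1, n - 3)))
    if (n > 4 && endsWith(tok, "ed"))  return(undouble(substr(tok, 1, n - 2)))
    tok
  }, "", USE.NAMES = FALSE)
}

#' Preprocess raw text into sentences of lemmatized tokens
#'
#' Lower-cases the text, splits it into sentences on terminal punctuation,
#' removes remaining punctuation (apostrophes are kept so contractions
#' survive), tokenizes on whitespace and lemmatizes each token.  Empty
#' sentences are dropped.
#'
#' @param text character scalar (may contain several sentences).
#' @param lemmatizer a function mapping a character vector of tokens to a
#'   character vector of lemmas; defaults to [lemmatize_en()].
#' @return a list of character vectors, one per non-empty sentence.
#' @examples
#' preprocess("Help me! Let me help you up.")
#' @export
preprocess <- function(text, lemmatizer = lemmatize_en) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(list())
  x <- tolower(normalize_apostrophes(text))
  sentences <- strsplit(x, "[.!?;]+")[[1L]]
  out <- lapply(sentences, function(s) {
    s <- gsub("[^a-z0-9' ]", " ", s)
    s <- gsub("'+\\s", " ", paste0(s, " "))          # strip dangling quotes
    toks <- strsplit(trimws(s), "\\s+")[[1L]]
    toks <- toks[nzchar(toks) & toks != "'"]
    if (length(toks) == 0L) return(NULL)
    lemmatizer(toks)
  })
  out[!vapply(out, is.null, TRUE)]
}

## ---------------------------------------------------------------------------
## CHAT (.cha) parsing

chat_age_to_months <- function(age) {
  # CHAT ages are "y;m.d" (day optional)
  m <- regmatches(age, regexec("^([0-9]+);([0-9]+)?", age))[[1L]]
  if (length(m) == 0L) return(NA_integer_)
  years <- as.integer(m[2L])
  months <- if (is.na(m[3L]) || !nzchar(m[3L])) 0L else as.integer(m[3L])
  years * 12L + months
}

strip_chat_markup <- function(x) {
  x <- gsub("\\[[^]]*\\]", " ", x)       # [x 2], [% comment], [: corrections]
  x <- gsub("&=?[a-zA-Z]+", " ", x)      # &=laughs, &uh
  x <- gsub("<|>|\\+\\.*|/+", " ", x)    # retracing and pause codes
  x <- gsub("\\(|\\)", "", x)            # (be)cause -> because
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

parse_chat_file <- function(path, lemmatizer = lemmatize_en) {
  lines <- tryCatch(readLines(path, warn = FALSE, encoding = "UTF-8"),
                    error = function(e) stop("cannot read CHAT file ", path, ": ",
                                             conditionMessage(e)))
  # fold continuation lines (starting with a tab) into the previous line
  folded <- character(0)
  for (l in lines) {
    if (grepl("^\\t", l) && length(folded) > 0L && !grepl("^@", l)) {
      folded[length(folded)] <- paste(folded[length(folded)], trimws(l))
    } else {
      folded <- c(folded, l)
    }
  }
  participants <- character(0)   # code -> role name from @Participants
  corpus <- NA_character_
  age_months <- NA_integer_
  gender <- "unknown"
  records <- list()
  for (i in seq_along(folded)) {
    l <- folded[i]
    if (grepl("^@Participants:", l)) {
      body <- sub("^@Participants:\\s*", "", l)
      for (p in strsplit(body, ",")[[1L]]) {
        fields <- strsplit(trimws(p), "\\s+")[[1L]]
        if (length(fields) >= 1L) participants[fields[1L]] <- fields[length(fields)]
      }
    } else if (grepl("^@ID:", l)) {
      fields <- strsplit(sub("^@ID:\\s*", "", l), "|", fixed = TRUE)[[1L]]
      if (length(fields) >= 3L && fields[3L] == "CHI") {
        corpus <- fields[2L]
        if (length(fields) >= 4L && nzchar(fields[4L])) {
          age_months <- chat_age_to_months(fields[4L])
        }
        if (length(fields) >= 5L) {
          gender <- switch(tolower(fields[5L]), female = "female", male = "male",
                           "unknown")
        }
      } else if (length(fields) >= 2L && is.na(corpus)) {
        corpus <- fields[2L]
      }
    } else if (grepl("^\\*", l)) {
      m <- regmatches(l, regexec("^\\*([A-Za-z0-9]+):\\s*(.*)$", l))[[1L]]
      if (length(m) == 0L) stop("unparseable main tier at ", path, " line ", i)
      records[[length(records) + 1L]] <- list(tier = m[2L], text = m[3L], line = i)
    }
    # @ headers other than the above and %-dependent tiers are ignored
  }
  list(records = records, participants = participants, corpus = corpus,
       age_months = age_months, gender = gender, path = path)
}

#' Read a CHAT corpus into an utterance table
#'
#' Parses one `.cha` file or a directory of them.  Only main speaker tiers
#' are read; dependent tiers (`%mor`, `%gra`, ...) are ignored.  Each main
#' line is split into sentences by [preprocess()], and every non-empty
#' sentence becomes one utterance row.  The `CHI` tier becomes the child;
#' every other participant tier listed in `role_map` becomes a caretaker.
#' Files whose child participant has no recorded age contribute no
#' utterances (the drop count is attached as attribute `n_dropped_no_age`),
#' and tiers absent from `role_map` are skipped with a warning.
#'
#' @param path a `.cha` file or a directory containing them.
#' @param role_map named character vector mapping tier codes to
#'   `"child"`/`"caretaker"`.  `NULL` (default) maps `CHI` to child and every
#'   other participant declared in the file to caretaker.
#' @param exclude_corpora corpus names to drop entirely (e.g. `"Hall"`).
#' @param lemmatizer passed to [preprocess()].
#' @return a data.frame of utterances with columns `utterance_id`, `text`,
#'   `tokens` (list column of lemma vectors), `speaker_role`,
#'   `child_age_months`, `child_gender`, `corpus_name`.
#' @export
read_chat_corpus <- function(path, role_map = NULL, exclude_corpora = character(0),
                             lemmatizer = lemmatize_en) {
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.cha$", full.names = TRUE, recursive = TRUE)
  } else path
  rows <- list()
  dropped_no_age <- 0L
  for (f in sort(files)) {
    parsed <- parse_chat_file(f, lemmatizer)
    corpus <- parsed$corpus %||% NA_character_
    if (is.na(corpus)) corpus <- sub("\\.cha$", "", basename(f))
    if (corpus %in% exclude_corpora) next
    rmap <- role_map
    if (is.null(rmap)) {
      codes <- names(parsed$participants)
      if (length(codes) == 0L) codes <- unique(vapply(parsed$records, `[[`, "", "tier"))
      rmap <- stats::setNames(ifelse(codes == "CHI", "child", "caretaker"), codes)
    }
    if (is.na(parsed$age_months)) {
      dropped_no_age <- dropped_no_age + length(parsed$records)
      next
    }
    stem <- sub("\\.cha$", "", basename(f))
    for (rec in parsed$records) {
      role <- rmap[rec$tier]
      if (is.na(role)) {
        warning("unknown tier ", rec$tier, " in ", f, "; utterance skipped")
        next
      }
      clean <- strip_chat_markup(rec$text)
      sents <- preprocess(clean, lemmatizer)
      raw_sents <- strsplit(normalize_apostrophes(clean), "[.!?;]+")[[1L]]
      raw_sents <- trimws(raw_sents)
      raw_sents <- raw_sents[nzchar(raw_sents)]
      for (si in seq_along(sents)) {
        raw <- if (si <= length(raw_sents)) raw_sents[si] else paste(sents[[si]], collapse = " ")
        rows[[length(rows) + 1L]] <- list(
          utterance_id = sprintf("%s:%d:%d", stem, rec$line, si),
          text = raw, tokens = sents[[si]], speaker_role = unname(role),
          child_age_months = parsed$age_months, child_gender = parsed$gender,
          corpus_name = corpus)
      }
    }
  }
  out <- utterance_frame(rows)
  attr(out, "n_dropped_no_age") <- dropped_no_age
  out
}

utterance_frame <- function(rows) {
  if (length(rows) == 0L) {
    out <- data.frame(utterance_id = character(0), text = character(0),
                      speaker_role = character(0),
                      child_age_months = integer(0), child_gender = character(0),
                      corpus_name = character(0), stringsAsFactors = FALSE)
    out$tokens <- list()
    return(out[, c("utterance_id", "text", "tokens", "speaker_role",
                   "child_age_months", "child_gender", "corpus_name")])
  }
  out <- data.frame(
    utterance_id = vapply(rows, `[[`, "", "utterance_id"),
    text = vapply(rows, `[[`, "", "text"),
    speaker_role = vapply(rows, `[[`, "", "speaker_role"),
    child_age_months = vapply(rows, function(r) as.integer(r$child_age_months), 1L),
    child_gender = vapply(rows, `[[`, "", "child_gender"),
    corpus_name = vapply(rows, `[[`, "", "corpus_name"),
    stringsAsFactors = FALSE)
  out$tokens <- lapply(rows, `[[`, "tokens")
  out[, c("utterance_id", "text", "tokens", "speaker_role",
          "child_age_months", "child_gender", "corpus_name")]
}

#' Write and read utterances in the JSONL dialect
#'
#' One object per line with fields `id`, `text`, `role`, `age_months`,
#' `gender`, `corpus`.  Tokens are not stored: they are re-derived
#' deterministically by [preprocess()] on read, so a write/read round trip
#' reproduces every field.
#'
#' @param utterances an utterance data.frame as returned by
#'   [read_chat_corpus()].
#' @param path file path.
#' @param lemmatizer passed to [preprocess()] on read.
#' @return `read_utterances_jsonl()` returns an utterance data.frame.
#' @export
write_utterances_jsonl <- function(utterances, path) {
  recs <- lapply(seq_len(nrow(utterances)), function(i) {
    list(id = utterances$utterance_id[i], text = utterances$text[i],
         role = utterances$speaker_role[i],
         age_months = utterances$child_age_months[i],
         gender = utterances$child_gender[i],
         corpus = utterances$corpus_name[i])
  })
  write_jsonl(recs, path)
}

#' @rdname write_utterances_jsonl
#' @export
read_utterances_jsonl <- function(path, lemmatizer = lemmatize_en) {
  recs <- read_jsonl(path)
  rows <- lapply(recs, function(r) {
    sents <- preprocess(r$text, lemmatizer)
    toks <- if (length(sents) > 0L) unlist(sents) else character(0)
    list(utterance_id = r$id, text = r$text, tokens = toks,
         speaker_role = r$role, child_age_months = as.integer(r$age_months),
         child_gender = r$gender %||% "unknown", corpus_name = r$corpus %||% NA_character_)
  })
  utterance_frame(rows)
}

## ---------------------------------------------------------------------------
## LIWC-style .dic lexicon

#' Load a LIWC-style moral dictionary
#'
#' The `.dic` layout is a category block delimited by `%` lines (numeric id,
#' whitespace, category name such as `care.virtue`), followed by word lines
#' (`pattern id [id ...]`).  A trailing `*` on a pattern marks a stem with
#' prefix-match semantics.  Category names must be one of the ten
#' foundation-polarity categories (case-insensitive).
#'
#' @param path path to the `.dic` file.
#' @return a data.frame of lexicon entries with columns `pattern`,
#'   `is_stem`, `foundation`, `polarity`, `category`.  Duplicate
#'   pattern-category lines are collapsed with a warning.
#' @export
load_lexicon <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  pct <- which(lines == "%")
  if (length(pct) < 2L) stop("malformed .dic file (missing % category block): ", path)
  if (pct[2L] == pct[1L] + 1L) stop("empty category block in ", path)
  header <- lines[(pct[1L] + 1L):(pct[2L] - 1L)]
  header <- header[nzchar(header)]
  if (length(header) == 0L) stop("empty category block in ", path)
  cats <- new.env(parent = emptyenv())
  valid <- tolower(mf_categories())
  for (h in header) {
    fields <- strsplit(h, "\\s+")[[1L]]
    if (length(fields) < 2L) stop("malformed category line in ", path, ": ", h)
    name <- tolower(fields[2L])
    if (!name %in% valid) stop("unknown category name in ", path, ": ", fields[2L])
    assign(fields[1L], mf_categories()[match(name, valid)], envir = cats)
  }
  body <- lines[(pct[2L] + 1L):length(lines)]
  body <- body[nzchar(body)]
  rows <- list()
  for (b in body) {
    fields <- strsplit(b, "\\s+")[[1L]]
    pat <- tolower(fields[1L])
    ids <- fields[-1L]
    if (length(ids) == 0L) stop("word line without category id in ", path, ": ", b)
    for (id in ids) {
      if (!exists(id, envir = cats, inherits = FALSE)) {
        stop("unknown category id ", id, " in ", path, ": ", b)
      }
      category <- get(id, envir = cats)
      is_stem <- endsWith(pat, "*")
      rows[[length(rows) + 1L]] <- list(
        pattern = if (is_stem) substr(pat, 1, nchar(pat) - 1L) else pat,
        is_stem = is_stem, category = category)
    }
  }
  out <- data.frame(
    pattern = vapply(rows, `[[`, "", "pattern"),
    is_stem = vapply(rows, `[[`, TRUE, "is_stem"),
    category = vapply(rows, `[[`, "", "category"),
    stringsAsFactors = FALSE)
  if (any(!nzchar(out$pattern))) stop("empty pattern in ", path)
  dup <- duplicated(out[, c("pattern", "category")])
  if (any(dup)) {
    warning(sum(dup), " duplicate pattern line(s) collapsed in ", path)
    out <- out[!dup, , drop = FALSE]
  }
  fp <- split_category(out$category)
  out$foundation <- fp$foundation
  out$polarity <- fp$polarity
  rownames(out) <- NULL
  out[, c("pattern", "is_stem", "foundation", "polarity", "category")]
}

## ---------------------------------------------------------------------------
## Seed matching

#' Match moral seed words against utterances
#'
#' Matches lexicon patterns against the lemmatized tokens of each utterance:
#' exact lemma equality for plain patterns, prefix match for stem
#' (trailing-`*`) patterns.  Utterances are restricted to the configured
#' child-age window, with integer age = `floor(months / 12)`.
#'
#' @param utterances utterance data.frame with a `tokens` list column.
#' @param lexicon lexicon data.frame from [load_lexicon()].
#' @param min_age_years,max_age_years inclusive age window in whole years
#'   (defaults 1 and 6).
#' @return a data.frame of seed matches, one row per (utterance, token,
#'   entry) triple: `utterance_id`, `matched_token`, `pattern`, `is_stem`,
#'   `foundation`, `polarity`, `category`.
#' @export
match_seeds <- function(utterances, lexicon, min_age_years = 1, max_age_years = 6) {
  age <- floor(utterances$child_age_months / 12)
  keep <- which(age >= min_age_years & age <= max_age_years)
  exact <- lexicon[!lexicon$is_stem, , drop = FALSE]
  stems <- lexicon[lexicon$is_stem, , drop = FALSE]
  rows <- list()
  for (i in keep) {
    toks <- unique(utterances$tokens[[i]])
    for (tok in toks) {
      hit_e <- which(exact$pattern == tok)
      hit_s <- which(startsWith(tok, stems$pattern))
      for (j in hit_e) {
        rows[[length(rows) + 1L]] <- list(
          utterance_id = utterances$utterance_id[i], matched_token = tok,
          pattern = exact$pattern[j], is_stem = FALSE,
          category = exact$category[j])
      }
      for (j in hit_s) {
        rows[[length(rows) + 1L]] <- list(
          utterance_id = utterances$utterance_id[i], matched_token = tok,
          pattern = stems$pattern[j], is_stem = TRUE,
          category = stems$category[j])
      }
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(utterance_id = character(0), matched_token = character(0),
                      pattern = character(0), is_stem = logical(0),
                      foundation = character(0), polarity = character(0),
                      category = character(0), stringsAsFactors = FALSE)
    return(out)
  }
  out <- data.frame(
    utterance_id = vapply(rows, `[[`, "", "utterance_id"),
    matched_token = vapply(rows, `[[`, "", "matched_token"),
    pattern = vapply(rows, `[[`, "", "pattern"),
    is_stem = vapply(rows, `[[`, TRUE, "is_stem"),
    category = vapply(rows, `[[`, "", "category"),
    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[, c("utterance_id", "matched_token", "pattern", "category")]), ]
  fp <- split_category(out$category)
  out$foundation <- fp$foundation
  out$polarity <- fp$polarity
  rownames(out) <- NULL
  out[, c("utterance_id", "matched_token", "pattern", "is_stem",
          "foundation", "polarity", "category")]
}

#' Initial foundation-polarity category per seed-matched utterance
#'
#' The "initial" category of an utterance is the lexicographically first
#' category among its seed matches (deterministic regardless of match
#' order).  This is the label an utterance carries before any human or
#' propagated annotation, and the tie-break anchor for the aggregation and
#' propagation rules.
#'
#' @param matches a seed-match data.frame from [match_seeds()].
#' @return named character vector: utterance_id -> category.
#' @export
initial_categories <- function(matches) {
  if (nrow(matches) == 0L) return(stats::setNames(character(0), character(0)))
  ord <- order(matches$utterance_id, matches$category)
  m <- matches[ord, ]
  first <- !duplicated(m$utterance_id)
  stats::setNames(m$category[first], m$utterance_id[first])
}
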