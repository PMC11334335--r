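# Shared fixtures built in code.

# a minimal .dic file with two categories and stem/non-stem patterns
write_tiny_dic <- function(path = tempfile(fileext = ".dic")) {
  writeLines(c(
    "%",
    "1\tcare.virtue",
    "2\tfairness.virtue",
    "%",
    "help*\t1",
    "fair\t2",
    "share*\t2"
  ), path)
  path
}

# a hand-built CHAT file: 2 child lines, 3 mother lines, child age 2;6
write_tiny_cha <- function(path = tempfile(fileext = ".cha"),
                           corpus = "Demo") {
  writeLines(c(
    "@UTF8",
    "@Begin",
    "@Languages:\teng",
    "@Participants:\tCHI Target_Child, MOT Mother",
    sprintf("@ID:\teng|%s|CHI|2;6.|female|||Target_Child||", corpus),
    sprintf("@ID:\teng|%s|MOT|||||Mother||", corpus),
    "*CHI:\thelp me .",
    "*MOT:\tlet me help you up .",
    "*CHI:\tthat is not fair .",
    "%mor:\tignored tier .",
    "*MOT:\tyou have to share the toys .",
    "*MOT:\tis that fair enough ?",
    "@End"
  ), path)
  path
}

# utterance frame builder for small in-code fixtures
make_utterances <- function(texts, roles, ages_months,
                            genders = rep("unknown", length(texts)),
                            corpus = "Fixture") {
  rows <- lapply(seq_along(texts), function(i) {
    sents <- preprocess(texts[i])
    list(utterance_id = sprintf("u%03d", i), text = texts[i],
         tokens = if (length(sents) > 0) unlist(sents) else character(0),
         speaker_role = roles[i], child_age_months = ages_months[i],
         child_gender = genders[i], corpus_name = corpus)
  })
  df <- data.frame(
    utterance_id = vapply(rows, `[[`, "", "utterance_id"),
    text = vapply(rows, `[[`, "", "text"),
    speaker_role = vapply(rows, `[[`, "", "speaker_role"),
    child_age_months = vapply(rows, function(r) as.integer(r$child_age_months), 1L),
    child_gender = vapply(rows, `[[`, "", "child_gender"),
    corpus_name = corpus, stringsAsFactors = FALSE)
  df$tokens <- lapply(rows, `[[`, "tokens")
  df[, c("utterance_id", "text", "tokens", "speaker_role",
         "child_age_months", "child_gender", "corpus_name")]
}

# annotation records builder: votes is a list of per-annotator
# list(moral = TRUE/FALSE, f = category or NULL)
make_records <- function(utterance_id, votes, passed = TRUE) {
  df <- data.frame(
    utterance_id = utterance_id,
    annotator_id = sprintf("a%02d", seq_along(votes)),
    says_moral = vapply(votes, `[[`, TRUE, "moral"),
    passed_attention = rep(passed, length.out = length(votes)),
    stringsAsFactors = FALSE)
  df$foundations <- lapply(votes, function(v) {
    if (isTRUE(v$moral) && !is.null(v$f)) v$f else character(0)
  })
  df
}

label_moral <- function(f) moral_label("moral", f, "unanimous_rule")
label_nonmoral <- function() moral_label("nonmoral")
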