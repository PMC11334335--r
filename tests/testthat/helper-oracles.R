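# Independent brute-force recodings of the labelling rules, written directly
# from their stated thresholds.  Used by the unit suites and the acceptance
# suite as the comparison oracles.

# utterance-level survey aggregation
oracle_aggregate <- function(says_moral, foundations, initial, tokens = NULL,
                             blacklist = mfd_blacklist()) {
  if (!is.null(tokens) && length(tokens) == 1 && tolower(tokens) %in% blacklist) {
    return(list(relevance = "nonmoral", foundation = NA_character_))
  }
  share <- sum(says_moral) / length(says_moral)
  votes <- unlist(foundations[says_moral])
  maj <- NA_character_
  if (length(votes) > 0) {
    tab <- table(votes)
    top <- sort(names(tab)[tab == max(tab)])
    maj <- if (length(top) > 1 && initial %in% top) initial else top[1]
  }
  if (share >= 0.75) {
    if (is.na(maj)) return(list(relevance = "nonmoral", foundation = NA_character_))
    return(list(relevance = "moral", foundation = maj))
  }
  if (share < 0.5) return(list(relevance = "nonmoral", foundation = NA_character_))
  if (!is.na(maj) && maj == initial) {
    return(list(relevance = "moral", foundation = maj))
  }
  list(relevance = "nonmoral", foundation = NA_character_)
}

# 3-vote propagation (seeded: fallback = cluster foundation; unseeded:
# fallback = rank-1 neighbour foundation)
oracle_vote <- function(rels, fnds, initial = NULL, fallback = NULL) {
  if (sum(rels == "moral") <= length(rels) / 2) {
    return(list(relevance = "nonmoral", foundation = NA_character_))
  }
  v <- fnds[!is.na(fnds)]
  tab <- table(v)
  top <- sort(names(tab)[tab == max(tab)])
  if (length(top) == 1) return(list(relevance = "moral", foundation = top))
  if (!is.null(initial) && initial %in% v) {
    return(list(relevance = "moral", foundation = initial))
  }
  if (!is.null(fallback) && !is.na(fallback)) {
    return(list(relevance = "moral", foundation = fallback))
  }
  list(relevance = "moral", foundation = top[1])
}

# run the implementation against both oracles on random vote configurations
# and count disagreements
rule_oracle_mismatches <- function(n_agg, n_prop, seed) {
  cats <- mf_categories()
  same <- function(got, want) {
    identical(got$relevance, want$relevance) &&
      identical(got$foundation %||% NA_character_, want$foundation)
  }
  `%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
  with_seed(seed, {
    bad_agg <- 0L
    for (rep in seq_len(n_agg)) {
      n <- sample(3:9, 1)
      says <- runif(n) < runif(1)
      fnds <- lapply(seq_len(n), function(i) {
        if (says[i]) sample(cats, sample(1:2, 1)) else character(0)
      })
      initial <- sample(cats, 1)
      rec <- make_records("u", lapply(seq_len(n), function(i) {
        list(moral = says[i], f = if (says[i]) fnds[[i]] else NULL)
      }))
      rec$foundations <- fnds
      if (!same(aggregate_utterance(rec, initial),
                oracle_aggregate(says, fnds, initial))) bad_agg <- bad_agg + 1L
    }
    bad_seeded <- 0L
    bad_unseeded <- 0L
    lab_of <- function(rel, f) {
      if (rel == "moral") moral_label("moral", f) else moral_label("nonmoral")
    }
    for (rep in seq_len(n_prop)) {
      rels <- sample(c("moral", "nonmoral"), 3, replace = TRUE)
      fnds <- ifelse(rels == "moral", sample(cats, 3, replace = TRUE), NA)
      labs <- lapply(1:3, function(i) lab_of(rels[i], fnds[i]))
      initial <- sample(cats, 1)
      if (!same(propagate_seeded(labs[[1]], labs[2:3], initial),
                oracle_vote(rels, fnds, initial = initial, fallback = fnds[1]))) {
        bad_seeded <- bad_seeded + 1L
      }
      if (!same(propagate_unseeded(labs),
                oracle_vote(rels, fnds, fallback = fnds[1]))) {
        bad_unseeded <- bad_unseeded + 1L
      }
    }
    c(n_cases = n_agg + 2L * n_prop,
      aggregate = bad_agg, seeded = bad_seeded, unseeded = bad_unseeded)
  })
}
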