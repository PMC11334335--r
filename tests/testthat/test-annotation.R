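test_that("attention-check failures remove all of an annotator's records", {
  votes <- list(list(moral = TRUE, f = "Care.virtue"),
                list(moral = FALSE), list(moral = TRUE, f = "Care.vice"))
  rec <- make_records("u1", votes)
  expect_identical(filter_annotators(rec), rec)

  rec$passed_attention[2] <- FALSE
  out <- filter_annotators(rec)
  expect_equal(nrow(out), 2L)
  expect_false("a02" %in% out$annotator_id)
})

test_that("a planted failure rate removes exactly the planted annotators", {
  cfg <- sim_config(seed = 30, n_per_age_role = 40L)
  gen <- generate_corpus(cfg)
  ids <- gen$manifest$utterance_id[1:200]
  rec <- simulate_survey(ids, gen$manifest, cfg, seed = 77)
  failed <- unique(rec$annotator_id[!rec$passed_attention])
  out <- filter_annotators(rec)
  expect_equal(sort(unique(out$annotator_id)),
               sort(setdiff(unique(rec$annotator_id), failed)))
  expect_true(all(out$passed_attention))
})

test_that("the 75%/50% aggregation rules and the one-word blacklist are enforced", {
  # 6 of 7 say moral, plurality chooses Loyalty although the seed said Fairness
  votes <- c(lapply(1:4, function(i) list(moral = TRUE, f = "Loyalty.vice")),
             lapply(1:2, function(i) list(moral = TRUE, f = "Fairness.vice")),
             list(list(moral = FALSE)))
  lab <- aggregate_utterance(make_records("u1", votes), "Fairness.vice")
  expect_equal(lab$relevance, "moral")
  expect_equal(lab$foundation, "Loyalty.vice")

  # nobody says moral
  lab0 <- aggregate_utterance(make_records("u2", lapply(1:8, function(i)
    list(moral = FALSE))), "Care.virtue")
  expect_equal(lab0$relevance, "nonmoral")
  expect_true(is.na(lab0$foundation))

  # 5 of 8 (62.5%): moral only when the majority matches the initial foundation
  band <- c(lapply(1:5, function(i) list(moral = TRUE, f = "Care.virtue")),
            lapply(1:3, function(i) list(moral = FALSE)))
  lab_match <- aggregate_utterance(make_records("u3", band), "Care.virtue")
  expect_equal(lab_match$relevance, "moral")
  expect_equal(lab_match$foundation, "Care.virtue")
  expect_equal(lab_match$provenance, "band_rule")
  band2 <- c(lapply(1:5, function(i) list(moral = TRUE, f = "Authority.virtue")),
             lapply(1:3, function(i) list(moral = FALSE)))
  lab_mis <- aggregate_utterance(make_records("u4", band2), "Care.virtue")
  expect_equal(lab_mis$relevance, "nonmoral")

  # a blacklisted one-word utterance is nonmoral regardless of votes
  all_moral <- lapply(1:7, function(i) list(moral = TRUE, f = "Authority.virtue"))
  lab_bl <- aggregate_utterance(make_records("u5", all_moral), "Authority.virtue",
                                tokens = "daddy")
  expect_equal(lab_bl$relevance, "nonmoral")
  expect_equal(lab_bl$provenance, "blacklist")
  # ... but only one-word utterances are blacklisted
  lab_two <- aggregate_utterance(make_records("u6", all_moral), "Authority.virtue",
                                 tokens = c("daddy", "said"))
  expect_equal(lab_two$relevance, "moral")

  empty <- make_records("u7", list(list(moral = FALSE)))[0, ]
  expect_error(aggregate_utterance(empty, "Care.virtue"), "no annotation records")
})

test_that("utterance aggregation matches the brute-force rule oracle on random votes", {
  cats <- mf_categories()
  with_seed(99, {
    for (rep in 1:500) {
      n <- sample(3:9, 1)
      says <- runif(n) < runif(1)
      fnds <- lapply(seq_len(n), function(i) {
        if (says[i]) sample(cats, sample(1:2, 1)) else character(0)
      })
      initial <- sample(cats, 1)
      votes <- lapply(seq_len(n), function(i) {
        list(moral = says[i], f = if (says[i]) fnds[[i]] else NULL)
      })
      rec <- make_records("u", votes)
      rec$foundations <- fnds
      got <- aggregate_utterance(rec, initial)
      want <- oracle_aggregate(says, fnds, initial)
      expect_equal(got$relevance, want$relevance)
      expect_equal(got$foundation, want$foundation)
    }
  })
})

test_that("aggregation is invariant to record order and annotator relabeling", {
  votes <- c(lapply(1:5, function(i) list(moral = TRUE, f = "Purity.vice")),
             lapply(1:2, function(i) list(moral = FALSE)))
  rec <- make_records("u1", votes)
  base <- aggregate_utterance(rec, "Purity.vice")
  with_seed(3, {
    for (i in 1:10) {
      perm <- sample(nrow(rec))
      shuffled <- rec[perm, ]
      shuffled$annotator_id <- sprintf("z%02d", seq_len(nrow(rec)))
      got <- aggregate_utterance(shuffled, "Purity.vice")
      expect_equal(got$relevance, base$relevance)
      expect_equal(got$foundation, base$foundation)
    }
  })
})

test_that("adding a moral vote never flips a moral verdict to nonmoral", {
  cats <- mf_categories()
  with_seed(17, {
    for (rep in 1:200) {
      n <- sample(3:8, 1)
      says <- runif(n) < 0.6
      f <- sample(cats, 1)
      fnds <- lapply(says, function(s) if (s) f else character(0))
      votes <- lapply(seq_len(n), function(i)
        list(moral = says[i], f = if (says[i]) f else NULL))
      rec <- make_records("u", votes)
      before <- aggregate_utterance(rec, f)
      rec2 <- rbind(rec, make_records("u", list(list(moral = TRUE, f = f))))
      rec2$annotator_id <- sprintf("a%02d", seq_len(nrow(rec2)))
      after <- aggregate_utterance(rec2, f)
      if (before$relevance == "moral") expect_equal(after$relevance, "moral")
    }
  })
})

test_that("cluster aggregation pools records with documented tie handling", {
  all_care <- make_records("u1", lapply(1:6, function(i)
    list(moral = TRUE, f = "Care.virtue")))
  lab <- aggregate_cluster(all_care)
  expect_equal(lab$relevance, "moral")
  expect_equal(lab$foundation, "Care.virtue")

  pooled <- rbind(
    make_records("u1", lapply(1:10, function(i) list(moral = TRUE, f = "Care.virtue"))),
    make_records("u2", lapply(1:30, function(i) list(moral = FALSE))))
  expect_equal(aggregate_cluster(pooled)$relevance, "nonmoral")

  even <- rbind(
    make_records("u1", lapply(1:5, function(i) list(moral = TRUE, f = "Care.virtue"))),
    make_records("u2", lapply(1:5, function(i) list(moral = FALSE))))
  tie <- aggregate_cluster(even)
  expect_equal(tie$relevance, "nonmoral")
  expect_true(tie$tie)
})

test_that("agreement ratios count matching relevance and foundation fields", {
  cl <- label_moral("Care.virtue")
  labs <- list(label_moral("Care.virtue"), label_moral("Care.virtue"),
               label_moral("Fairness.virtue"), label_nonmoral())
  r <- agreement_ratio(labs, cl)
  expect_equal(unname(r["relevance"]), 0.75)
  expect_equal(unname(r["foundation"]), 0.5)
  expect_equal(unname(agreement_ratio(list(label_moral("Care.virtue")), cl)["relevance"]), 1.0)
  none <- agreement_ratio(lapply(1:5, function(i) label_moral("Purity.vice")),
                          label_nonmoral())
  expect_equal(unname(none["relevance"]), 0.0)
})

test_that("accurate simulated annotators let aggregation recover ground truth", {
  cfg <- sim_config(seed = 8, n_per_age_role = 120L,
                    annotator_accuracy = 0.95, attention_fail_rate = 0,
                    n_annotators = 450L, utterances_per_annotator = 8L)
  gen <- generate_corpus(cfg)
  man <- gen$manifest
  pool <- man[!man$is_ambiguous_sense, ]
  ids <- with_seed(5, sample(pool$utterance_id, 500))
  rec <- filter_annotators(simulate_survey(ids, man, cfg, seed = 6))
  init <- setNames(ifelse(is.na(pool$true_category[match(ids, pool$utterance_id)]),
                          "Care.virtue",
                          pool$true_category[match(ids, pool$utterance_id)]), ids)
  hits <- vapply(ids, function(id) {
    r <- rec[rec$utterance_id == id, ]
    if (nrow(r) == 0) return(NA)
    lab <- aggregate_utterance(r, init[[id]])
    truth <- pool[pool$utterance_id == id, ]
    lab$relevance == truth$true_relevance &&
      (lab$relevance == "nonmoral" || identical(lab$foundation, truth$true_category))
  }, TRUE)
  hits <- hits[!is.na(hits)]
  expect_gte(mean(hits), 0.99)
})
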