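fixture_table <- function() {
  # tiny deterministic embedding table over the synthetic vocabulary core
  words <- c("help", "hurt", "fair", "cheat", "clean", "dirty", "ball", "dog",
             "the", "you")
  with_seed(55, {
    W <- matrix(rnorm(length(words) * 6), length(words), 6)
    rownames(W) <- words
    structure(list(vectors = W, algorithm = "fixture", dim = 6L),
              class = "embedding_table")
  })
}

test_that("label collapsing merges fairness partitions and drops polarity", {
  expect_equal(collapse_labels("Equality", "fairness_merge"), "Fairness")
  expect_equal(collapse_labels("Proportionality", "both"), "Fairness")
  expect_equal(collapse_labels("Care.virtue", "both"), "Care")
  expect_equal(collapse_labels("Care", "none"), "Care")
  expect_equal(collapse_labels(c("Care.vice", "Purity.virtue"), "drop_polarity"),
               c("Care", "Purity"))
  expect_error(collapse_labels("NotALabel"), "unknown label")
})

test_that("micro-F1 equals accuracy for single-label prediction", {
  expect_equal(micro_f1(c("a", "b"), c("a", "b")), 1.0)
  expect_equal(micro_f1(c("a", "b", "a", "a"), c("a", "b", "b", "a")), 0.75)
  expect_error(micro_f1("a", c("a", "b")), "length mismatch")

  # confusion-matrix oracle: pooled TP / (TP + (FP + FN) / 2)
  with_seed(40, {
    for (i in 1:20) {
      k <- sample(2:6, 1)
      n <- 50
      pred <- sample(letters[1:k], n, replace = TRUE)
      gold <- sample(letters[1:k], n, replace = TRUE)
      tp <- sum(pred == gold)
      fp <- sum(pred != gold)   # every wrong single-label call is one FP...
      fn <- sum(pred != gold)   # ...and one FN, pooled over classes
      expect_equal(micro_f1(pred, gold), tp / (tp + (fp + fn) / 2))
    }
  })
})

test_that("balanced test sets equalize class counts by the smallest class", {
  pool <- data.frame(text = sprintf("t%03d", 1:150),
                     label = rep(c("x", "y"), c(100, 50)),
                     stringsAsFactors = FALSE)
  sets <- balanced_eval(pool, n_sets = 10, seed = 4)
  expect_length(sets, 10L)
  for (s in sets) {
    expect_equal(as.vector(table(s$label)), c(50L, 50L))
    expect_false(any(duplicated(paste(s$text, s$label))))
  }
  # sampling is seeded: same seed, same draw
  sets2 <- balanced_eval(pool, n_sets = 10, seed = 4)
  expect_identical(sets, sets2)
  expect_error(balanced_eval(data.frame(text = "a", label = "x")), "class")
})

test_that("training matrices grow cumulatively with the age cutoff", {
  gen <- generate_corpus(sim_config(seed = 61, n_per_age_role = 60L))
  man <- gen$manifest
  labs <- data.frame(utterance_id = man$utterance_id,
                     relevance = man$true_relevance,
                     foundation = man$true_category,
                     stringsAsFactors = FALSE)
  tab <- train_static(gen$utterances$tokens, "glove_style", dim = 12, seed = 1)
  sizes <- vapply(1:6, function(cut) {
    nrow(build_training_matrix(gen$utterances, labs, tab, "binary_relevance",
                               cut, "child")$features)
  }, 0)
  expect_true(all(diff(sizes) >= 0))
})

test_that("feature assembly matches hand-built mean embeddings", {
  tab <- fixture_table()
  u <- make_utterances(
    c("help the dog", "you hurt", "fair ball", "cheat", "clean the ball",
      "dirty dog"),
    rep("child", 6), rep(40L, 6))
  labs <- data.frame(
    utterance_id = u$utterance_id,
    relevance = c("moral", "moral", "moral", "moral", "moral", "moral"),
    foundation = c("Care.virtue", "Care.vice", "Fairness.virtue",
                   "Fairness.vice", "Purity.virtue", "Purity.vice"),
    stringsAsFactors = FALSE)
  tm <- build_training_matrix(u, labs, tab, "fine_10class", 6, "child")
  W <- tab$vectors
  expect_equal(unname(tm$features["u001", ]),
               unname(colMeans(W[c("help", "the", "dog"), ])))
  expect_equal(unname(tm$features["u004", ]), unname(W["cheat", ]))
  expect_equal(as.character(tm$targets[rownames(tm$features) == "u006"]),
               "Purity.vice")

  # degenerate 5-class collapse: Care.virtue + Care.vice alone is one class
  labs2 <- labs[1:2, ]
  expect_error(build_training_matrix(u[1:2, ], labs2, tab, "fine_5class", 6, "child"),
               "class")
})

test_that("the linear model separates separable blobs deterministically", {
  with_seed(9, {
    X <- rbind(matrix(rnorm(100, 0, 0.3), 50, 2),
               matrix(rnorm(100, 4, 0.3), 50, 2))
    y <- factor(rep(c("p", "q"), each = 50))
  })
  clf <- train_linear(X, y, seed = 2)
  pred <- predict(clf, X)
  expect_equal(micro_f1(pred$class, as.character(y)), 1.0)
  clf2 <- train_linear(X, y, seed = 2)
  expect_identical(predict(clf2, X)$class, pred$class)
  expect_error(train_linear(X, factor(rep("p", 100))), "single class")
})

test_that("random-label training scores at chance on balanced evaluation", {
  with_seed(33, {
    X <- matrix(rnorm(400 * 4), 400, 4)
    y <- factor(sample(c("a", "b", "c", "d"), 400, replace = TRUE))
    Xt <- matrix(rnorm(200 * 4), 200, 4)
    yt <- rep(c("a", "b", "c", "d"), each = 50)
  })
  clf <- train_linear(X, y, seed = 5)
  f1 <- micro_f1(predict(clf, Xt)$class, yt)
  # Monte-Carlo chance oracle for K = 4 balanced classes
  expect_lt(abs(f1 - 0.25), 0.1)
})

test_that("long documents take the sentence-majority label with probability tie-break", {
  tab <- fixture_table()
  u <- make_utterances(
    c("help the dog", "you hurt the dog", "help you", "hurt you"),
    rep("child", 4), rep(40L, 4))
  labs <- data.frame(utterance_id = u$utterance_id, relevance = "moral",
                     foundation = c("Care", "Harm", "Care", "Harm"),
                     stringsAsFactors = FALSE)
  labs$foundation <- c("Care.virtue", "Care.vice", "Care.virtue", "Care.vice")
  tm <- build_training_matrix(u, labs, tab, "fine_10class", 6, "child")
  clf <- train_linear(tm$features, tm$targets, seed = 1)

  expect_equal(predict_long_text("help the dog.", clf, tab), "Care.virtue")
  maj <- predict_long_text("help the dog. help you. you hurt the dog.", clf, tab)
  expect_equal(as.character(maj), "Care.virtue")
  tied <- predict_long_text("help the dog. you hurt the dog.", clf, tab)
  # 1-1 tie: winner must carry the higher summed probability
  p <- predict(clf, rbind(
    mean_embedding(c("help", "the", "dog"), tab),
    mean_embedding(c("you", "hurt", "the", "dog"), tab)))$probs
  expect_equal(as.character(tied), colnames(p)[which.max(colSums(p))])
  expect_true(isTRUE(attr(tied, "tie")))
  expect_error(predict_long_text("", clf, tab), "empty")
})

test_that("the model grid covers 48 configurations and beats its own random control", {
  gen <- generate_corpus(sim_config(seed = 71, n_per_age_role = 50L))
  man <- gen$manifest
  labs <- data.frame(utterance_id = man$utterance_id,
                     relevance = man$true_relevance,
                     foundation = man$true_category,
                     stringsAsFactors = FALSE)
  tabs <- sim_embedding_tables(gen, dim = 12L, n_background = 600L)
  tests <- generate_external_tests(gen$config, n_short = 12L, n_long = 0L)
  sets <- balanced_eval(tests$short_binary, n_sets = 3, seed = 5)

  grid <- run_grid(gen$utterances, labs, tabs, sets, task = "binary_relevance",
                   cutoffs = c(2L, 6L), seed = 9)
  expect_equal(nrow(grid), 2L * 4L * 2L)   # cutoffs x variants x roles
  expect_true(all(grid$ci_lo <= grid$micro_f1 & grid$micro_f1 <= grid$ci_hi))

  # control on a narrowed grid: chance-level scores, moral models above them
  pool <- gen$utterances[!gen$utterances$utterance_id %in%
                           match_seeds(gen$utterances, gen$lexicon)$utterance_id, ]
  ctrl <- run_grid(gen$utterances, labs, tabs["w2v_pretrained"], sets,
                   task = "binary_relevance", roles = "child", cutoffs = 6L,
                   train_source = "random_control", control_pool = pool,
                   n_control = 5L, seed = 9)
  expect_lt(abs(ctrl$micro_f1 - 0.5), 0.1)
  moral_row <- grid[grid$embedding_variant == "w2v_pretrained" &
                      grid$speaker_role == "child" & grid$age_cutoff_years == 6L, ]
  expect_gt(moral_row$micro_f1, ctrl$micro_f1)

  # determinism of the full path
  grid2 <- run_grid(gen$utterances, labs, tabs, sets, task = "binary_relevance",
                    cutoffs = c(2L, 6L), seed = 9)
  expect_equal(grid$micro_f1, grid2$micro_f1, tolerance = 1e-12)

  expect_error(run_grid(gen$utterances, labs, unname(tabs), sets), "named list")
})
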