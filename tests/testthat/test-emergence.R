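test_that("time courses count moral utterances per cell under both normalizations", {
  u <- make_utterances(
    c("you help the baby", "look at the ball", "that is fair",
      "big red ball", "dog outside"),
    c("child", "child", "child", "caretaker", "child"),
    c(30L, 30L, 30L, 30L, 30L))
  labs <- data.frame(
    utterance_id = c("u001", "u003"),
    relevance = "moral",
    foundation = c("Care.virtue", "Fairness.virtue"),
    stringsAsFactors = FALSE)

  tc <- time_course(u, labs, "share_of_moral")
  expect_equal(tc$freq[tc$category == "Care.virtue"], 0.5)
  expect_equal(tc$freq[tc$category == "Fairness.virtue"], 0.5)

  # a single moral utterance takes the whole share of its cell
  tc1 <- time_course(u[1:2, ], labs[1, ], "share_of_moral")
  expect_equal(tc1$freq, 1.0)

  # per-total normalization divides by all utterances at the (age, role)
  tt <- time_course(u, labs, "per_total_sentences")
  expect_equal(tt$denominator[tt$speaker_role == "child"], c(4L, 4L))
  expect_equal(tt$freq[tt$category == "Care.virtue"], 0.25)
})

test_that("share-of-moral normalization sums to 1 per (age, role) cell", {
  gen <- generate_corpus(sim_config(seed = 12, n_per_age_role = 80L))
  man <- gen$manifest
  labs <- data.frame(utterance_id = man$utterance_id,
                     relevance = man$true_relevance,
                     foundation = man$true_category,
                     stringsAsFactors = FALSE)
  tc <- time_course(gen$utterances, labs, "share_of_moral")
  sums <- tapply(tc$freq, paste(tc$age_year, tc$speaker_role), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("planted category shares are recovered within binomial error", {
  curves <- default_emergence_curves() * 0
  curves["Care.virtue", ] <- 0.6
  curves["Fairness.virtue", ] <- 0.4
  gen <- generate_corpus(sim_config(seed = 44, n_per_age_role = 600L,
                                    ages = 3L, emergence_curves = curves))
  man <- gen$manifest
  labs <- data.frame(utterance_id = man$utterance_id,
                     relevance = man$true_relevance,
                     foundation = man$true_category,
                     stringsAsFactors = FALSE)
  tc <- time_course(gen$utterances, labs, "share_of_moral")
  care <- tc$freq[tc$category == "Care.virtue" & tc$speaker_role == "child"]
  n_moral <- tc$denominator[tc$category == "Care.virtue" & tc$speaker_role == "child"]
  expect_lt(abs(care - 0.6), 3 * sqrt(0.6 * 0.4 / n_moral))
})

test_that("ages above the window pool into one open bin", {
  u <- make_utterances(rep("you help the baby", 4), rep("child", 4),
                       c(36L, 90L, 102L, 130L))
  labs <- data.frame(utterance_id = u$utterance_id, relevance = "moral",
                     foundation = "Care.virtue", stringsAsFactors = FALSE)
  tc <- time_course(u, labs, "share_of_moral", pool_above = 6)
  expect_setequal(tc$age_year, c("3", "7+"))
  expect_equal(tc$count[tc$age_year == "7+"], 3L)
})

test_that("gender stratification splits counts without changing totals", {
  u <- make_utterances(rep("you help the baby", 4), rep("child", 4),
                       rep(30L, 4), genders = c("female", "female", "male", "male"))
  labs <- data.frame(utterance_id = u$utterance_id, relevance = "moral",
                     foundation = "Care.virtue", stringsAsFactors = FALSE)
  tc <- time_course(u, labs, "share_of_moral", by_gender = TRUE)
  expect_equal(nrow(tc), 2L)
  expect_equal(sum(tc$count), 4L)
  expect_true(all(tc$freq == 1.0))
})

test_that("the bootstrap word test flags only below-average words", {
  # word carrying 100% of seed usage can never fall below the average
  sents <- lapply(1:50, function(i) c("help", "me"))
  r <- word_significance(sents, "help", "help", n_perm = 500, seed = 2)
  expect_gt(r$p_value, 0.99)
  expect_false(r$flagged_insignificant)

  # rare word among many seed tokens is flagged
  sents2 <- c(lapply(1:999, function(i) sample(c("help", "share", "hug", "hurt"), 1)),
              list("belong"))
  sents2 <- lapply(sents2, function(s) c(s, "filler"))
  words <- c("help", "share", "hug", "hurt", "belong")
  r2 <- word_significance(sents2, words, "belong", n_perm = 2000, seed = 3)
  expect_true(r2$flagged_insignificant)
  expect_lt(r2$p_value, 0.01)

  expect_error(word_significance(list(), "x", "x"), "no moral utterances")
  expect_error(word_significance(sents, "help", "absent"), "not among")
})

test_that("the bootstrap p-value matches an independent small-n recomputation", {
  sents <- list(c("a", "x"), c("a", "x"), c("b", "x"), c("a", "b"))
  words <- c("a", "b")
  n_perm <- 400
  got <- word_significance_all(sents, words, n_perm = n_perm, seed = 9)

  # oracle: replay the documented procedure directly with the same RNG
  counts <- rbind(a = c(1, 1, 0, 1), b = c(0, 0, 1, 1))
  oracle <- with_seed(9, {
    mult <- stats::rmultinom(n_perm, 4, rep(0.25, 4))
    freq <- (counts %*% mult) / 4
    meanf <- colSums(freq) / 2
    (1 + rowSums(freq >= rep(meanf, each = 2))) / (n_perm + 1)
  })
  expect_equal(got$p_value, unname(oracle), tolerance = 1e-12)
  # word exactly at the mean in every resample -> p = 1 under ">="
  same <- list(c("a", "b"), c("a", "b"))
  r_same <- word_significance_all(same, c("a", "b"), n_perm = 200, seed = 1)
  expect_true(all(r_same$p_value == 1))
})

test_that("negation detection requires standalone no/not or the n't clitic", {
  expect_equal(negation_split("it's not fair"), "negative")
  expect_equal(negation_split("help me"), "positive")
  expect_equal(negation_split("nobody wiped the germ off"), "positive")
  expect_equal(negation_split("no, that's mine"), "negative")
  expect_equal(negation_split("I can’t do it"), "negative")  # curly apostrophe
  expect_equal(negation_split(c("notable effort", "do not")),
               c("positive", "negative"))
})

test_that("MLU is the mean word count per utterance", {
  expect_equal(mlu(list(c("help", "me"))), 2.0)
  expect_equal(mlu(list(c("a", "b"), c("a", "b", "c", "d"))), 3.0)
  expect_error(mlu(list()), "no utterances")

  # age-graded synthetic corpus: older children produce the longer templates
  gen <- generate_corpus(sim_config(seed = 3, n_per_age_role = 150L))
  u <- gen$utterances
  m <- tapply(lengths(u$tokens), floor(u$child_age_months / 12), mean)
  expect_true(all(m > 3) && all(m < 8))
})

test_that("lexical subset courses match listed patterns literally", {
  u <- make_utterances(
    c("no, that's mine", "you should go", "that mustn’t happen",
      "it isn't mine", "the dog is mining coal", "must we"),
    rep("child", 6), rep(30L, 6))
  labs <- data.frame(utterance_id = u$utterance_id,
                     relevance = c("moral", "moral", "moral", "moral",
                                   "nonmoral", "nonmoral"),
                     foundation = c("Fairness.virtue", "Authority.virtue",
                                    "Authority.virtue", "Fairness.virtue", NA, NA),
                     stringsAsFactors = FALSE)
  property <- c("mine", "yours", "not mine", "not yours", "n't mine", "n't yours")
  all_mode <- lexical_subset_course(u, labs, property, mode = "all")
  # "no, that's mine" and "it isn't mine" match; "mining" must not match "mine"
  expect_equal(all_mode$count, 2L)
  moral_mode <- lexical_subset_course(u, labs, property, mode = "moral_only")
  expect_equal(moral_mode$count, 2L)
  expect_equal(moral_mode$denominator, 6L)
  expect_equal(moral_mode$freq, 2 / 6)

  modals <- c("should", "must", "shouldn't", "mustn't", "should not", "must not")
  mod <- lexical_subset_course(u, labs, modals, mode = "all")
  # "you should go", "that mustn’t happen" (curly normalized), "must we"
  expect_equal(mod$count, 3L)

  fb <- attr(moral_mode, "foundations")
  expect_true(!is.null(fb))
  expect_setequal(unique(fb$foundation[fb$Freq > 0]), "Fairness.virtue")
  expect_error(lexical_subset_course(u, labs, character(0)), "empty")
})

test_that("role comparison reproduces the closed-form two-group F statistic", {
  rates <- data.frame(
    foundation = "Care",
    age_year = rep(1:6, 2),
    speaker_role = rep(c("child", "caretaker"), each = 6),
    freq = c(0.10, 0.12, 0.14, 0.11, 0.13, 0.12,
             0.50, 0.52, 0.48, 0.51, 0.49, 0.50))
  got <- compare_roles(rates)
  # closed form: F = MSB / MSW for two groups of 6
  g1 <- rates$freq[1:6]; g2 <- rates$freq[7:12]
  msb <- 6 * ((mean(g1) - mean(c(g1, g2)))^2 + (mean(g2) - mean(c(g1, g2)))^2)
  msw <- (sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)) / 10
  expect_equal(got$f_statistic, msb / msw, tolerance = 1e-10)
  expect_lt(got$p_value, 0.05)
  expect_equal(got$df1, 1L)
  expect_equal(got$df2, 10L)

  # identical rate vectors across roles: zero between-group variance
  same <- rates
  same$freq <- rep(c(0.1, 0.2, 0.3, 0.25, 0.15, 0.2), 2)
  expect_equal(compare_roles(same)$f_statistic, 0, tolerance = 1e-12)

  one_role <- rates[rates$speaker_role == "child", ]
  expect_error(compare_roles(one_role), "both roles")
})

test_that("a planted role effect in the generator is detected", {
  cfg <- sim_config(seed = 19, n_per_age_role = 300L,
                    p_moral = c(child = 0.15, caretaker = 0.45))
  gen <- generate_corpus(cfg)
  man <- gen$manifest
  labs <- data.frame(utterance_id = man$utterance_id,
                     relevance = man$true_relevance,
                     foundation = man$true_category,
                     stringsAsFactors = FALSE)
  tc <- time_course(gen$utterances, labs, "per_total_sentences")
  care <- tc[tc$foundation == "Care", ]
  agg <- aggregate(freq ~ age_year + speaker_role, data = care, FUN = sum)
  agg$foundation <- "Care"
  got <- compare_roles(agg)
  expect_lt(got$p_value, 0.05)
})
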