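---
title: "Tracking the emergence of moral-foundations vocabulary in child-caretaker speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking the emergence of moral-foundations vocabulary in child-caretaker speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question and the pipeline

Moral Foundations Theory describes morality as a small set of modular
foundations — Care, Fairness, Loyalty, Authority and Purity — each with a
virtue and a vice polarity.  A natural developmental question is *when*
children begin to talk about each foundation.  `morallex` implements a
corpus-based answer: track the frequency of foundation vocabulary in
transcribed child speech (CS) and child-directed speech (CDS) across ages
1–6, after separating genuinely moral word uses from nonmoral senses of the
same words ("is that fair enough?" versus "did you like the fair?").

The pipeline has five stages, each a module of the package:

1. **Ingestion** (`read_chat_corpus()`, `load_lexicon()`, `match_seeds()`).
   CHAT transcripts are split into sentences, lower-cased, stripped of
   punctuation and lemmatized; a LIWC-style dictionary maps word and stem
   patterns to the ten foundation-polarity categories.  A sentence
   containing a dictionary "seed" word becomes a candidate moral utterance
   with an *initial* category derived from its seed.
2. **Embedding and clustering** (`encode_contextual()`, `reduce_vectors()`,
   `fit_cell()`, `run_clustering_stage()`).  Within each of the 20 cells
   (10 categories × 2 speaker roles), sentence vectors are reduced by PCA
   to retain 95% of variance and clustered with a full-covariance Gaussian
   mixture; the number of clusters k ∈ 2..10 is chosen to maximize the mean
   silhouette width.  Clusters separate word senses, so a nonmoral sense
   lands in its own cluster.
3. **Survey annotation** (`select_survey_sentences()`,
   `aggregate_utterance()`, `aggregate_cluster()`).  Up to 10 prototypical
   and 10 peripheral sentences per cluster — ranked by the proximity
   Proximity(s, C) = cos(v_s, mean of member vectors of C) — are annotated
   by (simulated or human) raters.  Votes aggregate under fixed rules:
   at least 75% moral votes gives a moral label with the majority
   foundation; under 50% gives nonmoral; between 50% and 75% gives moral
   only when the majority foundation confirms the initial category; listed
   one-word utterances are always nonmoral.
4. **Propagation** (`propagate_seeded()`, `propagate_unseeded()`,
   `run_seed_pipeline()`).  Every unsurveyed seed-matched utterance takes
   the majority of three votes — its cluster's label and its two nearest
   surveyed neighbours by cosine; utterances with no seed word at all take
   the majority of their three nearest surveyed neighbours.
5. **Analyses** (`time_course()`, `word_significance()`, `negation_split()`,
   `mlu()`, `lexical_subset_course()`, `compare_roles()`, `run_grid()`).
   Frequency time-courses by age and role, bootstrap significance of
   individual words, negation and utterance-length measures, and a
   "blank-slate" generalization grid: logistic classifiers on mean static
   word embeddings, trained on labelled conversational utterances and
   evaluated by micro-F1 on balanced out-of-domain test sets.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `variance_target` | 0.95 | PCA variance retained per clustering cell |
| `k_range` | 2..10 | candidate mixture orders, silhouette-selected |
| `n_proto` | 10 | prototypical / peripheral sentences per cluster |
| aggregation thresholds | 0.75 / 0.50 | moral-vote shares for the unanimity and band rules |
| neighbours | 2 (seeded) / 3 (unseeded) | nearest surveyed utterances in the vote |
| `n_perm` | 2000 | bootstrap resamples per word test |
| `alpha` | 0.01 | flagging level for below-average word usage |
| age window | 1–6 years | `floor(months/12)`, inclusive |

Boundary conventions follow the rules literally: a share of exactly 0.75
triggers the unanimity rule, exactly 0.50 falls into the band rule.  Vote
ties prefer the utterance's initial category when it is among the tied
values and otherwise fall back lexicographically (aggregation), to the
cluster's foundation (seeded propagation) or to the rank-1 neighbour
(unseeded propagation); every resolved tie is flagged on the label.

## The synthetic-data generator

No conversational corpus, dictionary or survey ships with the package, so
`generate_corpus()` fabricates all of them with known ground truth.  Its
defaults define the simulated study conditions:

* ages 1–6, both roles, with a per-sentence moral-content rate of 0.30 in
  child speech and 0.35 in caretaker speech — caretakers moralize slightly
  more, and roughly a third of sentences carrying moral content at all
  keeps the seed-matched subset a realistic minority of the corpus;
* planted emergence curves (`default_emergence_curves()`): Care present
  from age 1 and dominant throughout, Fairness and Purity from age 2,
  Authority from age 3, Loyalty from age 4, with gradually rising shares —
  the onset ordering the emergence analyses are designed to detect;
* a polysemous seed (`fair`) used in a nonmoral fairground sense at rate
  0.10, mirroring the real moral/nonmoral sense ambiguity;
* negation rates of 0.10 (virtue) and 0.25 (vice) per category;
* a survey of 300 annotators × 40 items, individual accuracy 0.9,
  attention-failure rate 1/6 (so about 50 of 300 fail, and utterances
  average about 7 raters).  On an error, a rater of a truly moral item
  says nonmoral half the time and otherwise picks a uniformly random wrong
  category; a rater of a nonmoral item says moral with a uniform random
  category.  The simulator reports the exact truth otherwise.

Sentence templates are deliberately simple subject–verb–object frames with
category-specific frame vocabulary, so that the deterministic
feature-hashing encoder (`hash_encoder()`) separates categories
geometrically.  That is the point of the generator: downstream clustering,
propagation and classification must have recoverable signal without any
pretrained model.  Consequently, passing tests demonstrate that the
*machinery* is correct — rules, votes, selection, normalization,
calibration — not that a hash encoder resolves real English polysemy.  On
real transcripts one would plug a transformer sentence encoder into the
same `encode_contextual()` contract and pretrained word2vec/GloVe tables
into the grid; the package's "pretrained" embedding variants are trained
on a larger synthetic background corpus and are labelled synthetic
stand-ins.

## Numerical choices and degenerate inputs

* **Mixtures.**  Full-covariance Gaussian mixtures with a conjugate-prior
  regularization of the covariances; when a cell is too small or collinear
  the fit falls back to a spherical model, and below 3 members to a single
  cluster with undefined silhouette.  Mixture components can come out
  empty, so a model's `k` reports the realized number of non-empty
  clusters (the selected mixture order is kept alongside).  Silhouettes
  use Euclidean distance on the reduced vectors; cosine is available for
  the proximity ranking, which is scale-invariant by construction.
* **PCA.**  Fitted per cell, separately for CS and CDS, because clustering
  is per cell.  Scores are centred, so a cluster spanning a whole cell has
  its mean at the origin; summaries then fall back to a flat proximity
  with deterministic id order instead of an undefined cosine.
* **Word test.**  The p-value is the add-one estimator
  (1 + #{resamples with word frequency ≥ mean}) / (n_perm + 1), one-sided:
  a small p means the word's usage is significantly *below* the average
  moral word, and such words are flagged.  Words exactly at the mean get
  p = 1 under the "≥" convention.  Calibration under exchangeable planted
  frequencies is asymptotic in the corpus size: the bootstrap plugs in the
  realized word count, whose square-root variance slightly inflates the
  one-sided rate in small corpora.  The calibration experiment therefore
  uses 8,000-sentence replicate corpora, where the realized rate sits
  within two binomial standard deviations of the nominal 0.01.
* **Text matching.**  Negation is detected from standalone `no`/`not` or
  the clitic `n't` (so "nobody" is not negated); curly apostrophes are
  normalized before any matching; fixed word-set patterns ("mine",
  "n't mine", "should not", ...) are matched literally with word
  boundaries, a leading `n't` attaching to the preceding word.
* **MLU** counts words, not morphemes.
* **Classifiers.**  Multinomial logistic regression by penalized maximum
  likelihood (decay 1e-3), deterministic given data and seed.  The 95%
  interval over balanced test sets is mean ± 1.96·sd/√n.  All-out-of-
  vocabulary sentences are excluded from training matrices but counted.
  Negative examples for the binary task are the utterances labelled
  nonmoral by aggregation/propagation.

## Design decisions that were genuinely open

* Which tiers count as caretakers is configurable (`role_map`); the
  default maps every non-child participant to the caretaker role.
* Integer age is `floor(months/12)`, since CHAT records exact `y;m.d`
  ages.
* An utterance whose seeds span several categories joins every matching
  cell; its single *initial* category is the lexicographically first,
  which keeps tie-breaking deterministic.
* Seeded propagation runs in the cell's reduced space (the space the
  clusters live in); unseeded propagation runs in the full contextual
  space, because those sentences were never part of any cell's PCA.
* Clusters containing no surveyed member yield no propagated labels and
  are reported, rather than silently inheriting a neighbouring cluster's
  label.
* Static embeddings: skip-gram with negative sampling, plus a positive-PMI
  + truncated-SVD factorization as the count-based variant; minimum token
  count 1 by default because synthetic vocabularies are tiny.

## Problem sizes used by the packaged experiments

The acceptance experiments run on: 100,000 Monte-Carlo draws per chance
baseline; a 6,000-sentence corpus (500 per age × role) for the 20-cell
clustering stage; a 600-sentence corpus for the 48-configuration grid;
10,000 random vote configurations against the rule oracles; 50 words ×
100 replicates × 2,000 resamples (8,000-sentence corpora) for calibration;
500 surveyed utterances for annotation recovery; a ~2,000-utterance corpus
with 10% surveyed for propagation recovery; and a 5,400-utterance corpus
for the onset-order analysis.

## Known limitations

* The rule-based lemmatizer covers regular English inflection plus a small
  irregular table; it is a pluggable contract, not a full morphological
  analyser.
* The CHAT parser reads main tiers and participant metadata only; `%mor`
  and other dependent tiers are ignored by design.
* The generator does not model individual children longitudinally, child
  grammar, or multi-foundation sentences; document labels in the long test
  set are majority-constructed by design.
* Real-corpus figures (cluster counts, agreement ratios, cross-domain F1
  on public moral-text datasets) depend on external data the package does
  not download; nothing here claims to reproduce them.
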