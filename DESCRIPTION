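Package: morallex
Title: Emergence of Moral Foundations Vocabulary in Child-Caretaker Speech
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for tracking when the vocabulary of the five moral
    foundations (Care, Fairness, Loyalty, Authority, Purity, each with a
    virtue and a vice polarity) appears in transcribed conversations between
    young children and their caretakers.  The package reads CHAT transcripts
    and LIWC-style moral dictionaries, disambiguates moral from nonmoral
    word senses by clustering sentence embeddings per foundation-polarity
    cell with Gaussian mixtures and silhouette model selection, aggregates
    survey annotations under explicit majority-vote rules, propagates labels
    to unannotated utterances by cluster plus nearest-neighbour votes,
    computes developmental frequency time-courses with permutation
    significance tests, and trains blank-slate logistic classifiers to test
    whether moral information in childhood speech generalizes to
    out-of-domain moral text.  A synthetic-corpus generator with known
    ground truth makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    mclust,
    cluster,
    nnet
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
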