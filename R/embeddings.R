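## Sentence vectors: a pluggable contextual encoder (with a deterministic
## feature-hashing default), PCA reduction to a variance target, and static
## token embeddings (skip-gram with negative sampling, or PPMI+SVD) averaged
## into sentence features.

## deterministic 31-bit string hash (polynomial, seed-mixed)
str_hash <- function(s, seed = 0L) {
  h <- (17L + seed) %% 2147483647
  for (c in utf8ToInt(s)) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}

#' Deterministic feature-hashing sentence encoder
#'
#' Returns an encoder function mapping token vectors to fixed-length
#' vectors: each token and each adjacent token bigram is hashed to a
#' coordinate (with a hashed sign), accumulated and L2-normalized.  The
#' encoder is a pure function of its inputs and the seed, so identical
#' sentences always receive bitwise-identical vectors.  It satisfies the
#' sentence-encoder contract of [encode_contextual()]; a pretrained
#' transformer encoder can be plugged in through the same contract when one
#' is available.
#'
#' @param dim embedding dimension (default 64).
#' @param seed integer mixed into the hash.
#' @return a function `f(tokens)` returning a numeric vector of length `dim`.
#' @export
hash_encoder <- function(dim = 64, seed = 1L) {
  force(dim); force(seed)
  cache <- new.env(parent = emptyenv())
  feat <- function(s) {
    hit <- cache[[s]]
    if (!is.null(hit)) return(hit)
    h <- str_hash(s, seed)
    idx <- h %% dim + 1L
    sgn <- if ((h %/% dim) %% 2L == 0L) 1 else -1
    val <- c(idx, sgn)
    assign(s, val, envir = cache)
    val
  }
  function(tokens) {
    v <- numeric(dim)
    if (length(tokens) > 0L) {
      grams <- c(tokens, if (length(tokens) > 1L)
        paste(tokens[-length(tokens)], tokens[-1L], sep = "_"))
      for (g in grams) {
        f <- feat(g)
        v[f[1L]] <- v[f[1L]] + f[2L]
      }
    }
    nrm <- sqrt(sum(v * v))
    if (nrm > 0) v <- v / nrm
    v
  }
}

#' Encode utterances into contextual sentence vectors
#'
#' Applies a sentence encoder to the lemmatized tokens of each utterance.
#' The encoder must map any token vector to a fixed-length finite numeric
#' vector deterministically.
#'
#' @param utterances utterance data.frame with `utterance_id` and `tokens`.
#' @param encoder an encoder function, e.g. from [hash_encoder()].
#' @return numeric matrix, one row per utterance, rownames = utterance ids,
#'   with attribute `space_tag = "contextual"`.
#' @export
encode_contextual <- function(utterances, encoder) {
  vecs <- lapply(seq_len(nrow(utterances)), function(i) {
    v <- tryCatch(encoder(utterances$tokens[[i]]),
                  error = function(e) stop("encoder failed on utterance ",
                                           utterances$utterance_id[i], ": ",
                                           conditionMessage(e)))
    if (!is.numeric(v) || any(!is.finite(v))) {
      stop("encoder returned a non-finite vector for utterance ",
           utterances$utterance_id[i])
    }
    v
  })
  lens <- lengths(vecs)
  if (length(unique(lens)) > 1L) stop("encoder returned vectors of differing length")
  M <- do.call(rbind, vecs)
  rownames(M) <- utterances$utterance_id
  attr(M, "space_tag") <- "contextual"
  M
}

#' Reduce sentence vectors by PCA to a variance target
#'
#' Fits principal components on the rows of `vectors` and keeps the minimal
#' number of leading components whose cumulative explained variance reaches
#' `variance_target` (default 0.95).
#'
#' @param vectors numeric matrix (>= 2 rows).
#' @param variance_target fraction of variance to retain, in (0, 1].
#' @return list with `scores` (reduced vectors, rownames preserved,
#'   `space_tag = "contextual_reduced"`), `rotation`, `center`,
#'   `explained_variance_ratio`, `source_dim`, `target_dim`.
#' @export
reduce_vectors <- function(vectors, variance_target = 0.95) {
  if (nrow(vectors) < 2L) stop("PCA reduction needs at least 2 vectors")
  if (!(variance_target > 0 && variance_target <= 1)) {
    stop("variance_target must be in (0, 1]")
  }
  p <- stats::prcomp(vectors, center = TRUE, scale. = FALSE)
  v <- p$sdev^2
  rank <- sum(v > max(v[1L], .Machine$double.eps) * 1e-10)
  rank <- max(rank, 1L)
  ratio <- cumsum(v[seq_len(rank)]) / sum(v)
  target_dim <- if (variance_target >= 1) rank else which(ratio >= variance_target)[1L]
  if (is.na(target_dim)) target_dim <- rank
  scores <- p$x[, seq_len(target_dim), drop = FALSE]
  attr(scores, "space_tag") <- "contextual_reduced"
  list(scores = scores,
       rotation = p$rotation[, seq_len(target_dim), drop = FALSE],
       center = p$center,
       explained_variance_ratio = ratio[target_dim],
       source_dim = ncol(vectors), target_dim = target_dim)
}

## ---------------------------------------------------------------------------
## Static token embeddings

build_vocab <- function(sentences, min_count = 1L) {
  counts <- table(unlist(sentences))
  counts <- counts[counts >= min_count]
  sort(names(counts))
}

cooccurrence_matrix <- function(sentences, vocab, window = 2L) {
  V <- length(vocab)
  M <- matrix(0, V, V, dimnames = list(vocab, vocab))
  for (s in sentences) {
    ids <- match(s, vocab)
    n <- length(ids)
    for (i in seq_len(n)) {
      if (is.na(ids[i])) next
      for (d in seq_len(window)) {
        j <- i + d
        if (j > n || is.na(ids[j])) next
        w <- 1 / d
        M[ids[i], ids[j]] <- M[ids[i], ids[j]] + w
        M[ids[j], ids[i]] <- M[ids[j], ids[i]] + w
      }
    }
  }
  M
}

train_ppmi_svd <- function(sentences, vocab, dim, window) {
  M <- cooccurrence_matrix(sentences, vocab, window)
  total <- sum(M)
  if (total == 0) stop("no co-occurrences in corpus")
  pr <- rowSums(M) / total
  pc <- colSums(M) / total
  P <- M / total
  expected <- outer(pr, pc)
  ppmi <- log(pmax(P, .Machine$double.xmin) / pmax(expected, .Machine$double.xmin))
  ppmi[P == 0] <- 0
  ppmi[ppmi < 0] <- 0
  d <- min(dim, ncol(ppmi))
  sv <- svd(ppmi, nu = d, nv = 0)
  W <- sv$u %*% diag(sqrt(sv$d[seq_len(d)]), d)
  if (d < dim) W <- cbind(W, matrix(0, nrow(W), dim - d))
  rownames(W) <- vocab
  W
}

sigmoid <- function(x) 1 / (1 + exp(-x))

train_sgns <- function(sentences, vocab, dim, window, epochs, negative, lr) {
  V <- length(vocab)
  centers <- integer(0); contexts <- integer(0)
  for (s in sentences) {
    ids <- match(s, vocab)
    n <- length(ids)
    for (d in seq_len(window)) {
      if (n <= d) next
      a <- ids[seq_len(n - d)]; b <- ids[seq_len(n - d) + d]
      ok <- !is.na(a) & !is.na(b)
      centers <- c(centers, a[ok], b[ok])
      contexts <- c(contexts, b[ok], a[ok])
    }
  }
  if (length(centers) == 0L) stop("corpus too small to form skip-gram pairs")
  counts <- tabulate(contexts, V)
  neg_prob <- counts^0.75
  neg_prob <- neg_prob / sum(neg_prob)
  W <- matrix(stats::runif(V * dim, -0.5, 0.5) / dim, V, dim)
  C <- matrix(0, V, dim)
  npairs <- length(centers)
  batch <- 2048L
  for (ep in seq_len(epochs)) {
    perm <- sample.int(npairs)
    for (start in seq(1L, npairs, by = batch)) {
      idx <- perm[start:min(start + batch - 1L, npairs)]
      ci <- centers[idx]; oi <- contexts[idx]
      wb <- W[ci, , drop = FALSE]; cb <- C[oi, , drop = FALSE]
      # positive pairs
      g <- 1 - sigmoid(rowSums(wb * cb))
      dW <- g * cb
      dC <- g * wb
      # negative samples (shared draw per batch element x `negative`)
      for (k in seq_len(negative)) {
        ni <- sample.int(length(neg_prob), length(idx), replace = TRUE, prob = neg_prob)
        nb <- C[ni, , drop = FALSE]
        gn <- -sigmoid(rowSums(wb * nb))
        dW <- dW + gn * nb
        dCn <- gn * wb
        agg <- rowsum(dCn, ni)
        ui <- as.integer(rownames(agg))
        C[ui, ] <- C[ui, ] + lr * agg
      }
      aggW <- rowsum(dW, ci)
      uw <- as.integer(rownames(aggW))
      W[uw, ] <- W[uw, ] + lr * aggW
      aggC <- rowsum(dC, oi)
      uc <- as.integer(rownames(aggC))
      C[uc, ] <- C[uc, ] + lr * aggC
    }
  }
  rownames(W) <- vocab
  W
}

#' Train static token embeddings on a corpus
#'
#' Two in-package backends: `"skipgram"` is word2vec-style skip-gram with
#' negative sampling (vectorized mini-batch SGD); `"glove_style"` is a
#' count-based factorization (positive PMI of the distance-weighted
#' co-occurrence matrix, truncated SVD), the classic count-based member of
#' the same embedding family.  Both are reproducible under a fixed seed.
#'
#' @param sentences list of token vectors.
#' @param algorithm `"skipgram"` or `"glove_style"`.
#' @param dim embedding dimension.
#' @param window symmetric context window (default 2).
#' @param min_count minimum token count to enter the vocabulary (default 1,
#'   suited to small synthetic vocabularies).
#' @param seed RNG seed.
#' @param epochs,negative,lr skip-gram training hyperparameters.
#' @return an object of class `embedding_table`: list with `vectors`
#'   (vocabulary x dim matrix), `algorithm`, `dim`.
#' @export
train_static <- function(sentences, algorithm = c("skipgram", "glove_style"),
                         dim = 16, window = 2L, min_count = 1L, seed = 1L,
                         epochs = 5L, negative = 5L, lr = 0.05) {
  algorithm <- match.arg(algorithm)
  sentences <- sentences[lengths(sentences) > 0L]
  if (length(sentences) == 0L) stop("empty corpus")
  vocab <- build_vocab(sentences, min_count)
  if (length(vocab) == 0L) stop("no vocabulary after min_count filtering")
  W <- with_seed(seed, {
    if (algorithm == "skipgram") {
      train_sgns(sentences, vocab, dim, window, epochs, negative, lr)
    } else {
      train_ppmi_svd(sentences, vocab, dim, window)
    }
  })
  structure(list(vectors = W, algorithm = algorithm, dim = dim),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("embedding_table: %d words x %d dims (%s)\n",
              nrow(x$vectors), x$dim, x$algorithm))
  invisible(x)
}

#' Mean static embedding of a token sequence
#'
#' Arithmetic mean of the embeddings of in-vocabulary tokens;
#' out-of-vocabulary tokens are skipped.  A sentence with no in-vocabulary
#' token yields the zero vector with attribute `oov = TRUE` so that callers
#' can exclude (but count) it.
#'
#' @param tokens character vector.
#' @param table an `embedding_table`.
#' @return numeric vector of length `table$dim`.
#' @export
mean_embedding <- function(tokens, table) {
  idx <- match(tokens, rownames(table$vectors))
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) {
    return(structure(numeric(table$dim), oov = TRUE))
  }
  colMeans(table$vectors[idx, , drop = FALSE])
}

#' Serialize an embedding table in word2vec text format
#'
#' First line `"<vocab> <dim>"`, then one `word v1 ... vd` line per word.
#'
#' @param table an `embedding_table`.
#' @param path file path.
#' @param algorithm algorithm tag recorded when reading back.
#' @return `read_word2vec()` returns an `embedding_table`.
#' @export
write_word2vec <- function(table, path) {
  W <- table$vectors
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(W), ncol(W)), con)
  for (i in seq_len(nrow(W))) {
    writeLines(paste(rownames(W)[i],
                     paste(format(W[i, ], digits = 17, scientific = TRUE,
                                  trim = TRUE), collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_word2vec
#' @export
read_word2vec <- function(path, algorithm = "unknown") {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  hdr <- as.integer(strsplit(lines[1L], "\\s+")[[1L]])
  body <- strsplit(lines[-1L], "\\s+")
  W <- t(vapply(body, function(f) as.numeric(f[-1L]), numeric(hdr[2L])))
  rownames(W) <- vapply(body, `[`, "", 1L)
  structure(list(vectors = W, algorithm = algorithm, dim = hdr[2L]),
            class = "embedding_table")
}
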