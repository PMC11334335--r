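#' Moral foundation constants
#'
#' The five moral foundations and their two polarities give ten
#' foundation-polarity categories, written as \code{"Care.virtue"},
#' \code{"Care.vice"}, and so on.  These are the label alphabet used by the
#' lexicon, the annotation rules and the classifiers.
#'
#' @return `mf_foundations()` returns the five foundation names;
#'   `mf_polarities()` the two polarity names; `mf_categories()` the ten
#'   foundation-polarity category strings.
#' @export
mf_foundations <- function() c("Care", "Fairness", "Loyalty", "Authority", "Purity")

#' @rdname mf_foundations
#' @export
mf_polarities <- function() c("virtue", "vice")

#' @rdname mf_foundations
#' @export
mf_categories <- function() {
  as.vector(t(outer(mf_foundations(), mf_polarities(), paste, sep = ".")))
}

#' Split a foundation-polarity category string
#'
#' @param category character vector of categories such as `"Care.virtue"`.
#' @return data.frame with columns `foundation` and `polarity`.
#' @export
split_category <- function(category) {
  parts <- strsplit(as.character(category), ".", fixed = TRUE)
  data.frame(
    foundation = vapply(parts, `[`, "", 1L),
    polarity   = vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_, ""),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's random-number state afterwards, so that seeded
#' generator and model-fitting calls do not disturb surrounding code.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Cosine similarity between two vectors
#'
#' @param a,b numeric vectors of equal length; both must be non-zero.
#' @return cosine similarity in `[-1, 1]`.
#' @export
cosine <- function(a, b) {
  na <- sqrt(sum(a * a))
  nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) stop("cosine undefined for a zero vector")
  sum(a * b) / (na * nb)
}

## cosine of one query against the rows of a matrix; rows with zero norm -> NA
cosine_rows <- function(q, M) {
  nq <- sqrt(sum(q * q))
  if (nq == 0) stop("cosine undefined for a zero query vector")
  norms <- sqrt(rowSums(M * M))
  out <- as.vector(M %*% q) / (nq * norms)
  out[norms == 0] <- NA_real_
  out
}

normalize_apostrophes <- function(x) gsub("’", "'", x)

#' Read and write JSON-lines files
#'
#' One JSON object per line.  Used for the utterance and label streams.
#'
#' @param path file path.
#' @param records a list of named lists (one per line).
#' @return `read_jsonl()` returns a list of named lists.
#' @export
read_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
}

#' @rdname read_jsonl
#' @export
write_jsonl <- function(records, path) {
  lines <- vapply(records, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, null = "null"))
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

## majority over a character vector; ties resolved by `prefer` if it is among
## the tied values, else lexicographically first tied value.  Returns the
## winner plus whether a tie occurred.
majority_vote <- function(votes, prefer = NULL) {
  votes <- votes[!is.na(votes)]
  if (length(votes) == 0L) return(list(winner = NA_character_, tie = FALSE))
  tab <- table(votes)
  top <- names(tab)[tab == max(tab)]
  tie <- length(top) > 1L
  winner <- if (tie && !is.null(prefer) && prefer %in% top) prefer else sort(top)[1L]
  list(winner = winner, tie = tie)
}
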