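# Character-count vector space: one coordinate per letter a-z then digit 0-9.
CHAR_ALPHABET <- c(letters, as.character(0:9))

#' Normalize a name string for character-count matching
#'
#' Lowercases the input and removes every character outside `[a-z0-9]`
#' (whitespace, punctuation, Greek letters, accents and any other non-ASCII
#' are dropped, not transliterated). The 36-dimensional vector space has no
#' room for anything else.
#'
#' @param s A character vector.
#' @return A character vector of the same length containing only `[a-z0-9]`.
#' @export
#' @examples
#' normalize_string("D(+)-glucose")  # "dglucose"
normalize_string <- function(s) {
  gsub("[^a-z0-9]", "", tolower(s))
}

#' Character-count vector of a string
#'
#' Maps a string to its 36-dimensional count vector: one dimension per letter
#' of the alphabet and per numeral 0-9, in the fixed order a..z, 0..9. The
#' coordinate for a character is the number of times it occurs in the
#' normalized string. The encoding is lossy (anagrams coincide).
#'
#' @param s A single string.
#' @param normalize Normalize with [normalize_string()] first (default TRUE).
#'   Set to FALSE only if `s` is already normalized.
#' @return A named integer vector of length 36.
#' @export
#' @examples
#' v <- char_vector("PPi")
#' v[c("p", "i")]  # 2, 1
char_vector <- function(s, normalize = TRUE) {
  stopifnot(is.character(s), length(s) == 1L)
  if (normalize) s <- normalize_string(s)
  v <- integer(36L)
  names(v) <- CHAR_ALPHABET
  if (nzchar(s)) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    idx <- match(chars, CHAR_ALPHABET)
    v <- v + tabulate(idx, nbins = 36L)
    names(v) <- CHAR_ALPHABET
  }
  v
}

#' Cosine similarity of two character-count vectors
#'
#' `dot(u, v) / (|u| |v|)`. Because every coordinate is nonnegative, the
#' result lies in \[0, 1\]; 1 means the vectors are parallel (same character
#' multiset up to scaling). If either vector is zero the score is defined as
#' 0 (such queries are normally rejected by the element filter anyway).
#'
#' @param u,v Numeric vectors of equal length (typically from
#'   [char_vector()]).
#' @return A number in \[0, 1\].
#' @export
cosine_sim <- function(u, v) {
  stopifnot(length(u) == length(v))
  a <- sum(u * u)
  b <- sum(v * v)
  if (a == 0 || b == 0) return(0)
  d <- sum(u * v)
  # counts are small integers, so d^2 and a*b are exact in doubles: parallel
  # vectors score exactly 1 instead of 1 - epsilon
  if (d * d == a * b) return(1)
  min(1, d / sqrt(a * b))
}

#' Species match score (cScore)
#'
#' The match score between a query name and a reference species term is the
#' maximum cosine similarity between the query's character-count vector and
#' the vectors of the term's synonyms.
#'
#' @param query A raw query string (normalized internally).
#' @param term A species term: a list with a nonempty character vector
#'   `$synonyms` (e.g. an entry of `db$species`).
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' term <- list(synonyms = c("ATP", "adenosine triphosphate"))
#' cscore("atp", term)  # 1
cscore <- function(query, term) {
  syns <- term$synonyms
  stopifnot(length(syns) >= 1L)
  qv <- char_vector(query)
  max(vapply(syns, function(s) cosine_sim(qv, char_vector(s)), numeric(1)))
}

# Batch cScore of one query against every species term in a database, using
# the synonym vectors cached at load time. Returns a named numeric vector
# over term ids. Identical results to calling cscore() term by term.
cscore_all <- function(query, db) {
  qv <- char_vector(query)
  qn2 <- sum(qv * qv)
  term_ids <- names(db$species)
  if (qn2 == 0 || length(db$syn_term) == 0L) {
    return(stats::setNames(numeric(length(term_ids)), term_ids))
  }
  dots <- as.numeric(crossprod(db$syn_matrix, qv))
  n2 <- db$syn_norms2
  sims <- ifelse(n2 == 0, 0,
                 ifelse(dots * dots == n2 * qn2, 1,
                        pmin(1, dots / sqrt(n2 * qn2))))
  per_term <- vapply(split(sims, db$syn_term), max, numeric(1))
  out <- stats::setNames(numeric(length(term_ids)), term_ids)
  out[names(per_term)] <- per_term
  out
}
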