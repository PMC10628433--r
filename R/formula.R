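#' Parse a chemical formula string
#'
#' Tokenizes a molecular formula such as `"C6H12O6"` into element counts.
#' Element symbols are a capital letter optionally followed by one lowercase
#' letter; an optional count follows each symbol (default 1). Repeated symbols
#' are summed, so `"CHHH"` parses to `{C:1, H:3}`. A trailing charge token
#' (`+`, `-`, `2-`, `3+`, and the unicode minus) is tolerated and discarded:
#' protonation-state differences are handled downstream by hydrogen removal,
#' so charges carry no information here. Parenthesized repeat groups and
#' isotope notations are rejected rather than guessed.
#'
#' @param raw A single nonempty formula string.
#' @return An object of class `chem_formula`: a list with `elements`
#'   (named integer vector, all counts >= 1) and `raw` (the input).
#' @seealso [simplify_formula()]
#' @export
#' @examples
#' parse_formula("C6H12O6")$elements
#' parse_formula("HPO4")$elements   # charge-free hydrogenphosphate
#' parse_formula("H+")$elements     # trailing charge discarded
parse_formula <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  s <- trimws(raw)
  if (!nzchar(s)) stop("empty formula string")
  # strip one trailing charge token: at most one digit then +/- (ascii or
  # unicode minus); a single digit keeps "PO43-" parsing as P,O4 charge 3-
  s_body <- sub("[0-9]?[+−–-]$", "", s)
  if (!nzchar(s_body)) {
    stop(sprintf("formula '%s' has no element tokens", raw))
  }
  chars <- strsplit(s_body, "", fixed = TRUE)[[1]]
  elements <- integer(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (!grepl("^[A-Z]$", ch)) {
      stop(sprintf("malformed formula '%s': unexpected character '%s' at position %d",
                   raw, ch, i))
    }
    sym <- ch
    i <- i + 1L
    if (i <= n && grepl("^[a-z]$", chars[i])) {
      sym <- paste0(sym, chars[i])
      i <- i + 1L
    }
    j <- i
    while (j <= n && grepl("^[0-9]$", chars[j])) j <- j + 1L
    count <- if (j > i) as.integer(paste(chars[i:(j - 1L)], collapse = "")) else 1L
    if (is.na(count) || count < 1L) {
      stop(sprintf("malformed formula '%s': invalid count at position %d", raw, i))
    }
    i <- j
    elements[sym] <- (if (sym %in% names(elements)) elements[[sym]] else 0L) + count
  }
  structure(list(elements = elements, raw = raw), class = "chem_formula")
}

#' Simplify a chemical formula by removing hydrogen
#'
#' Produces the canonical hydrogen-free form used as the coordinate alphabet
#' of reaction vectors: all hydrogen atoms are omitted, except that a formula
#' containing only hydrogen (Hn) simplifies to `"H"`. The remaining elements
#' are serialized in strict alphabetical order with the count suffix omitted
#' when it is 1 (e.g. glucose `C6H12O6` becomes `"C6O6"`, water becomes
#' `"O"`). Dropping hydrogen absorbs protonation/deprotonation variants of
#' the same species into one coordinate.
#'
#' @param f A `chem_formula` (from [parse_formula()]) or a formula string.
#' @return A single string: the canonical simplified formula.
#' @export
#' @examples
#' simplify_formula("H2O")     # "O"
#' simplify_formula("H2")      # "H"
#' simplify_formula("C6H12O6") # "C6O6"
simplify_formula <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "chem_formula"))
  el <- f$elements
  keep <- el[setdiff(names(el), "H")]
  if (length(keep) == 0L) return("H")
  keep <- keep[order(names(keep))]
  paste0(names(keep), ifelse(keep == 1L, "", as.character(keep)), collapse = "")
}
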