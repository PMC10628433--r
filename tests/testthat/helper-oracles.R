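# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit loops, dense vectors, regex tokenization) so
# they cannot share a defect with the implementation paths they check.

ALPHA36 <- c(letters, as.character(0:9))

# Regex-based formula tokenizer, independent of parse_formula's scanner.
oracle_parse_formula <- function(raw) {
  s <- sub("[0-9]?[+−–-]$", "", trimws(raw))
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  toks <- regmatches(s, gregexpr("[A-Z][a-z]?[0-9]*", s))[[1]]
  if (paste(toks, collapse = "") != s) stop("oracle: malformed formula ", raw)
  out <- integer(0)
  for (t in toks) {
    sym <- gsub("[0-9]", "", t)
    num <- gsub("[^0-9]", "", t)
    cnt <- if (nzchar(num)) as.integer(num) else 1L
    out[sym] <- (if (sym %in% names(out)) out[[sym]] else 0L) + cnt
  }
  out
}

# Cosine similarity by explicit character counting loops.
oracle_cosine <- function(s1, s2) {
  count36 <- function(s) {
    s <- tolower(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    v <- numeric(36)
    for (i in seq_along(ALPHA36)) {
      for (ch in chars) if (ch == ALPHA36[i]) v[i] <- v[i] + 1
    }
    v
  }
  u <- count36(s1); v <- count36(s2)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  s <- sum(u * v) / (nu * nv)
  if (abs(s - 1) < 1e-12) 1 else s
}

rand_string <- function(len, alphabet = c(letters, as.character(0:9), " ", "-", "(", ")")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Dense-vector normalizer: dot products with every reference reaction done
# on full 0/1 vectors.
oracle_normalizer <- function(qcoords, db) {
  n <- length(db$formula_index)
  dense <- function(coords) { v <- numeric(n); v[coords] <- 1; v }
  qv <- dense(qcoords)
  dots <- integer(0)
  selfs <- integer(0)
  for (id in names(db$reactions)) {
    rv <- dense(reference_reaction_vector(id, db))
    dots[id] <- sum(qv * rv)
    selfs[id] <- sum(rv * rv)
  }
  M <- max(dots)
  if (M == 0) return(list(M_q = 0L, D = 0L, dots = dots))
  L <- names(dots)[dots == M]
  list(M_q = as.integer(M), L_q = L, D = as.integer(min(selfs[L])), dots = dots)
}

# Brute-force MSSC selector: enumerate every subset of the candidate list
# and keep the unique subset satisfying the selection definition.
oracle_select <- function(ids, scores, mssc, cutoff) {
  n <- length(ids)
  valid <- NULL
  for (mask in 0:(2^n - 1)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    ok <- if (mssc == "top") {
      m <- if (n > 0) max(scores) else -Inf
      if (n > 0 && m >= cutoff) all(inset == (scores == m)) else !any(inset)
    } else {
      all(inset == (scores >= cutoff))
    }
    if (ok) { valid <- sort(ids[inset]); break }
  }
  valid
}

# Write a species/reaction table pair to tempfiles and load it.
make_db <- function(species_rows, reaction_rows = NULL) {
  sp <- tempfile(fileext = ".tsv")
  writeLines(c("term_id\tname\tsynonyms\tformula", species_rows), sp)
  rx <- NULL
  if (!is.null(reaction_rows)) {
    rx <- tempfile(fileext = ".tsv")
    writeLines(c("reaction_id\tparticipants", reaction_rows), rx)
  }
  load_reference_db(sp, rx)
}

# A one-species-per-reaction toy model over a generated database, exercised
# through the public model_view constructor.
toy_model_from_db <- function(db, n_species = length(db$species)) {
  ids <- names(db$species)[seq_len(n_species)]
  species <- lapply(seq_along(ids), function(i) {
    list(element_id = sprintf("X%02d", i),
         display_name = db$species[[ids[i]]]$synonyms[1])
  })
  model_view("toy", species)
}
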