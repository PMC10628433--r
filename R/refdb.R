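# Reference database: species terms (ChEBI-style), reference reactions
# (Rhea-style), the simplified-formula coordinate index shared by both, and
# cached synonym character-count vectors for fast species scoring.

split_pipe <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, "|", fixed = TRUE)[[1]]
}

# Assemble a ref_db from parsed species/reaction lists. Internal: loaders and
# the synthetic generator both funnel through here so invariants are enforced
# in one place.
build_ref_db <- function(species, reactions = list()) {
  stopifnot(length(species) >= 1L)
  ids <- vapply(species, `[[`, character(1), "term_id")
  if (anyDuplicated(ids)) {
    stop("duplicate species term ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(species) <- ids

  if (length(reactions)) {
    rids <- vapply(reactions, `[[`, character(1), "reaction_id")
    if (anyDuplicated(rids)) {
      stop("duplicate reaction ids: ", paste(unique(rids[duplicated(rids)]), collapse = ", "))
    }
    names(reactions) <- rids
    unknown <- lapply(reactions, function(r) setdiff(r$participants, ids))
    bad <- unknown[lengths(unknown) > 0L]
    if (length(bad)) {
      stop("reaction participants not in species table: ",
           paste(sprintf("%s -> {%s}", names(bad),
                         vapply(bad, paste, character(1), collapse = ",")),
                 collapse = "; "))
    }
    reactions <- lapply(reactions, function(r) {
      r$formula_set <- sort(unique(unlist(
        lapply(species[r$participants], `[[`, "formulas"), use.names = FALSE)))
      r
    })
  }

  all_formulas <- sort(unique(c(
    unlist(lapply(species, `[[`, "formulas"), use.names = FALSE),
    unlist(lapply(reactions, `[[`, "formula_set"), use.names = FALSE))))
  formula_index <- stats::setNames(seq_along(all_formulas), all_formulas)

  # cache each reaction's coordinate support for fast normalizer scans
  reactions <- lapply(reactions, function(r) {
    r$coords <- sort(unique(as.integer(formula_index[r$formula_set])))
    r
  })

  # synonym vector cache
  syn_term <- rep(ids, times = vapply(species, function(s) length(s$synonyms), integer(1)))
  syn_strings <- unlist(lapply(species, `[[`, "synonyms"), use.names = FALSE)
  syn_matrix <- vapply(syn_strings, function(s) as.numeric(char_vector(s)),
                       numeric(36L))
  if (length(syn_strings) == 0L) syn_matrix <- matrix(0, nrow = 36L, ncol = 0L)
  syn_matrix <- matrix(as.numeric(syn_matrix), nrow = 36L)
  syn_norms2 <- colSums(syn_matrix^2)

  structure(list(
    species = species,
    reactions = reactions,
    formula_index = formula_index,
    syn_term = syn_term,
    syn_matrix = syn_matrix,
    syn_norms2 = syn_norms2
  ), class = "ref_db")
}

#' @export
print.ref_db <- function(x, ...) {
  cat(sprintf("Reference database: %d species terms, %d reactions, %d simplified formulas\n",
              length(x$species), length(x$reactions), length(x$formula_index)))
  invisible(x)
}

#' Load a reference database from TSV tables
#'
#' Reads the species dictionary and (optionally) the reference reaction table
#' and builds the indexed database used for all scoring.
#'
#' File dialect (UTF-8, tab-separated, header row):
#' * species table: columns `term_id`, `name`, `synonyms` (pipe-separated),
#'   `formula` (semicolon-separated list of molecular formulas);
#' * reaction table: columns `reaction_id`, `participants` (pipe-separated
#'   term ids).
#'
#' Only species terms with at least one parsable chemical formula are
#' admitted; terms without one are dropped with a warning (the reaction
#' match score is defined over simplified formulas, so formula-less terms
#' cannot participate). Formulas are simplified at load time
#' ([simplify_formula()]); a term may retain several distinct simplified
#' formulas. A reaction referencing an unknown term id is a load error.
#'
#' @param species_path Path to the species TSV.
#' @param reactions_path Path to the reaction TSV, or `NULL` for a
#'   species-only database.
#' @return A `ref_db` object: list with `species` (term id -> term),
#'   `reactions` (reaction id -> reaction, each with its `formula_set`), and
#'   `formula_index`, a bijection from every distinct simplified formula to a
#'   coordinate in the reaction vector space.
#' @export
load_reference_db <- function(species_path, reactions_path = NULL) {
  if (!file.exists(species_path)) stop("species table not found: ", species_path)
  sp <- utils::read.delim(species_path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("term_id", "name", "synonyms", "formula")
  if (!all(need %in% names(sp))) {
    stop("species table must have columns: ", paste(need, collapse = ", "))
  }
  species <- list()
  dropped <- character(0)
  for (i in seq_len(nrow(sp))) {
    syns <- unique(c(sp$name[i], split_pipe(sp$synonyms[i])))
    syns <- syns[nzchar(syns)]
    raw_forms <- trimws(strsplit(sp$formula[i], ";", fixed = TRUE)[[1]])
    raw_forms <- raw_forms[nzchar(raw_forms)]
    simplified <- character(0)
    for (f in raw_forms) {
      simplified <- c(simplified,
                      tryCatch(simplify_formula(f), error = function(e) NA_character_))
    }
    simplified <- sort(unique(simplified[!is.na(simplified)]))
    if (length(simplified) == 0L || length(syns) == 0L) {
      dropped <- c(dropped, sp$term_id[i])
      next
    }
    species[[length(species) + 1L]] <- list(
      term_id = sp$term_id[i],
      synonyms = syns,
      formulas = simplified,
      raw_formulas = raw_forms
    )
  }
  if (length(dropped)) {
    warning("dropped ", length(dropped),
            " species term(s) without a parsable formula or synonym: ",
            paste(dropped, collapse = ", "))
  }
  if (length(species) == 0L) stop("no admissible species terms in ", species_path)

  reactions <- list()
  if (!is.null(reactions_path)) {
    if (!file.exists(reactions_path)) stop("reaction table not found: ", reactions_path)
    rx <- utils::read.delim(reactions_path, sep = "\t", quote = "", comment.char = "",
                            stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    if (!all(c("reaction_id", "participants") %in% names(rx))) {
      stop("reaction table must have columns: reaction_id, participants")
    }
    reactions <- lapply(seq_len(nrow(rx)), function(i) {
      parts <- split_pipe(rx$participants[i])
      if (length(parts) == 0L) {
        stop(sprintf("reaction %s (line %d) has no participants", rx$reaction_id[i], i + 1L))
      }
      list(reaction_id = rx$reaction_id[i], participants = sort(unique(parts)))
    })
  }
  build_ref_db(species, reactions)
}

#' Write a reference database back to the TSV dialect
#'
#' Inverse of [load_reference_db()] up to formula simplification (simplified
#' formulas are written, which re-simplify to themselves).
#'
#' @param db A `ref_db`.
#' @param species_path,reactions_path Output paths (`reactions_path` may be
#'   `NULL` to skip reactions).
#' @return Invisibly, the paths written.
#' @export
write_reference_db <- function(db, species_path, reactions_path = NULL) {
  stopifnot(inherits(db, "ref_db"))
  sp <- data.frame(
    term_id = names(db$species),
    name = vapply(db$species, function(s) s$synonyms[1], character(1)),
    synonyms = vapply(db$species, function(s) paste(s$synonyms, collapse = "|"), character(1)),
    formula = vapply(db$species, function(s) {
      paste(if (!is.null(s$raw_formulas)) s$raw_formulas else s$formulas, collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(sp, species_path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(reactions_path) && length(db$reactions)) {
    rx <- data.frame(
      reaction_id = names(db$reactions),
      participants = vapply(db$reactions, function(r) paste(r$participants, collapse = "|"),
                            character(1)),
      stringsAsFactors = FALSE
    )
    utils::write.table(rx, reactions_path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  invisible(c(species_path, reactions_path))
}

#' Load a cross-reference map (KEGG reaction / EC number to reaction ids)
#'
#' Two-column TSV with header `foreign_id`, `reaction_ids` (pipe-separated).
#' Duplicate `foreign_id` rows are unioned. Targets that do not resolve in
#' `db` (when given) are retained but flagged with a warning, so evaluation
#' code can decide to exclude them.
#'
#' @param path Path to the TSV.
#' @param db Optional `ref_db` used to check that targets resolve.
#' @return A named list `foreign_id -> character vector of reaction ids`,
#'   with attribute `"unresolved"` listing foreign ids whose targets were not
#'   all found in `db`.
#' @export
load_crossref_map <- function(path, db = NULL) {
  if (!file.exists(path)) stop("cross-reference map not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  map <- list()
  if (length(lines)) {
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    body <- if (identical(header[1:2], c("foreign_id", "reaction_ids"))) lines[-1] else lines
    for (k in seq_along(body)) {
      fields <- strsplit(body[k], "\t", fixed = TRUE)[[1]]
      if (length(fields) < 2L || !nzchar(fields[1])) {
        stop(sprintf("malformed cross-reference row at line %d: '%s'", k + 1L, body[k]))
      }
      targets <- split_pipe(fields[2])
      map[[fields[1]]] <- sort(unique(c(map[[fields[1]]], targets)))
    }
  }
  unresolved <- character(0)
  if (!is.null(db) && length(map)) {
    known <- names(db$reactions)
    unresolved <- names(map)[vapply(map, function(t) any(!t %in% known), logical(1))]
    if (length(unresolved)) {
      warning("cross-reference targets not in reaction table for: ",
              paste(unresolved, collapse = ", "))
    }
  }
  attr(map, "unresolved") <- unresolved
  map
}
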