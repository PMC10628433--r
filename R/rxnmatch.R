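# Reaction match scoring. Reactions are binary vectors over the simplified-
# formula coordinates of the reference database; scores are normalized dot
# products. Vectors are carried as sparse support sets (sorted integer
# coordinates); dot products are support intersections, identical in result
# to dense arithmetic.

# Coordinates for a set of simplified formula strings.
formula_coords <- function(formulas, db) {
  if (length(formulas) == 0L) return(integer(0))
  idx <- db$formula_index[formulas]
  if (anyNA(idx)) {
    stop("formula(s) not in database index: ",
         paste(formulas[is.na(idx)], collapse = ", "))
  }
  sort(unique(as.integer(idx)))
}

#' Binary reaction vector of a reference reaction
#'
#' The support is the set of coordinates of the union of the participants'
#' simplified formulas; reactants and products are pooled, without direction
#' or stoichiometry. Two participants sharing a simplified formula set a
#' single coordinate.
#'
#' @param term A reaction entry of a `ref_db` (or its id).
#' @param db The `ref_db`.
#' @return An integer vector of coordinates (class `reaction_vector`).
#' @export
reference_reaction_vector <- function(term, db) {
  stopifnot(inherits(db, "ref_db"))
  if (is.character(term)) {
    if (!term %in% names(db$reactions)) stop("unknown reaction id: ", term)
    term <- db$reactions[[term]]
  }
  unknown <- setdiff(term$participants, names(db$species))
  if (length(unknown)) {
    stop("unresolved participants: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(term$coords)) {
    return(structure(term$coords, class = "reaction_vector"))
  }
  fs <- term$formula_set
  if (is.null(fs)) {
    fs <- sort(unique(unlist(lapply(db$species[term$participants], `[[`, "formulas"),
                             use.names = FALSE)))
  }
  structure(formula_coords(fs, db), class = "reaction_vector")
}

#' Binary reaction vector of a query reaction
#'
#' Built from the current species predictions: the support is the union,
#' over all participants of the query reaction, of the simplified formulas
#' of every candidate term in that participant's prediction set. A species
#' whose candidates carry several formulas sets several coordinates;
#' participants with empty prediction sets contribute nothing.
#'
#' @param rxn A query reaction: list with `$participants` (species element
#'   ids).
#' @param species_preds Named list of species prediction sets (see
#'   [predict_species_annotations()]); names are species element ids.
#' @param db The `ref_db`.
#' @return An integer coordinate vector (class `reaction_vector`).
#' @export
query_reaction_vector <- function(rxn, species_preds, db) {
  stopifnot(inherits(db, "ref_db"))
  formulas <- character(0)
  for (sp in rxn$participants) {
    ps <- species_preds[[sp]]
    if (is.null(ps)) next
    ids <- ps$candidates$annotation_id
    ids <- ids[ids %in% names(db$species)]
    if (length(ids)) {
      formulas <- c(formulas, unlist(lapply(db$species[ids], `[[`, "formulas"),
                                     use.names = FALSE))
    }
  }
  structure(formula_coords(sort(unique(formulas)), db), class = "reaction_vector")
}

#' Normalization context for a query reaction vector
#'
#' Scans every reference reaction, computing its dot product with the query.
#' `M_q` is the largest dot product, `L_q` the reference reactions achieving
#' it, and the normalization constant `D` is the smallest self-dot-product
#' (support size, i.e. number of distinct simplified participant formulas)
#' among reactions in `L_q`. When the query vector is empty or overlaps no
#' reference reaction (`M_q = 0`), `D` is set to 0 and every score is 0.
#'
#' @param qvec Query `reaction_vector`.
#' @param db The `ref_db` (must contain at least one reaction).
#' @return A list with `M_q`, `L_q` (character ids), `D`, and `dots`
#'   (named integer vector of dot products for every reference reaction).
#' @export
compute_normalizer <- function(qvec, db) {
  stopifnot(inherits(db, "ref_db"))
  if (length(db$reactions) == 0L) stop("reference database has no reactions")
  rvecs <- lapply(names(db$reactions), function(id) reference_reaction_vector(id, db))
  names(rvecs) <- names(db$reactions)
  dots <- vapply(rvecs, function(rv) length(intersect(qvec, rv)), integer(1))
  M_q <- max(dots)
  if (M_q == 0L) {
    return(list(M_q = 0L, L_q = names(dots), D = 0L, dots = dots))
  }
  L_q <- names(dots)[dots == M_q]
  self_dots <- vapply(rvecs[L_q], length, integer(1))
  list(M_q = M_q, L_q = L_q, D = min(self_dots), dots = dots)
}

#' Reaction match score (rScore)
#'
#' `rScore = (Rq . Rr) / D`, the dot product of the query and reference
#' binary vectors divided by the normalization constant from
#' [compute_normalizer()]. Always in \[0, 1\]: the dot product is at most
#' `M_q`, and `M_q <= D` because any reference achieving it has at least
#' `M_q` coordinates of its own. `D` rescales the value without changing the
#' ranking. `D = 0` yields 0 by convention.
#'
#' @param qvec,rvec Query and reference `reaction_vector`s.
#' @param ctx Normalizer context from [compute_normalizer()] for `qvec`
#'   against the database containing `rvec`.
#' @return A number in \[0, 1\].
#' @export
rscore <- function(qvec, rvec, ctx) {
  if (ctx$D == 0L) return(0)
  length(intersect(qvec, rvec)) / ctx$D
}

# Score every reference reaction for one query vector: named numeric vector.
rscore_all <- function(qvec, db) {
  ctx <- compute_normalizer(qvec, db)
  if (ctx$D == 0L) {
    return(stats::setNames(numeric(length(ctx$dots)), names(ctx$dots)))
  }
  ctx$dots / ctx$D
}
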