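# Iterative cross-refinement of species and reaction predictions. Once a
# reaction has a mapped reference reaction (its top-scoring candidate), its
# participants are paired with the reference participants; species whose
# current annotation disagrees with their paired reference term are proposed
# for revision, and affected reactions are re-scored concurrently.

#' Pair query reaction participants with a mapped reference reaction
#'
#' Builds a deterministic pairing between the participants of a query
#' reaction and the participants of its mapped (top-scoring) reference
#' reaction. Exact annotation matches are fixed first (a query species whose
#' current predicted annotation set contains a reference participant term is
#' paired with it); remaining participants are paired greedily by descending
#' cosine match score between the query species' name and the reference
#' participant's synonyms. Ties break lexicographically by
#' (element_id, term_id). Each side of the pairing is used at most once;
#' the number of pairs is the smaller participant count.
#'
#' @param model The `model_view`.
#' @param reaction_id Element id of the query reaction.
#' @param mapped_id Reaction id of the mapped reference reaction.
#' @param species_preds Current species prediction sets.
#' @param db The `ref_db`.
#' @return A data.frame with columns `element_id`, `term_id`, `matched`
#'   (TRUE iff the species' prediction set contains the paired term), plus
#'   attributes `reaction_id` and `mapped_id`.
#' @export
pair_participants <- function(model, reaction_id, mapped_id, species_preds, db) {
  rxn <- model$reactions[[reaction_id]]
  if (is.null(rxn)) stop("unknown reaction element: ", reaction_id)
  ref <- db$reactions[[mapped_id]]
  if (is.null(ref)) stop("unknown reference reaction: ", mapped_id)

  q_left <- sort(rxn$participants)
  r_left <- sort(ref$participants)
  pairs <- list()
  current_ids <- function(el) {
    ps <- species_preds[[el]]
    if (is.null(ps)) character(0) else ps$candidates$annotation_id
  }

  # phase 1: exact annotation matches, query participants in lexicographic order
  for (el in q_left) {
    hit <- sort(intersect(current_ids(el), r_left))
    if (length(hit)) {
      pairs[[length(pairs) + 1L]] <- list(element_id = el, term_id = hit[1], matched = TRUE)
      r_left <- setdiff(r_left, hit[1])
    }
  }
  q_left <- setdiff(q_left, vapply(pairs, `[[`, character(1), "element_id"))

  # phase 2: greedy by descending name-vs-synonym cScore
  while (length(q_left) && length(r_left)) {
    grid <- expand.grid(element_id = q_left, term_id = r_left,
                        stringsAsFactors = FALSE)
    grid$score <- mapply(function(el, tid) {
      cscore(species_query_string(model$species[[el]]), db$species[[tid]])
    }, grid$element_id, grid$term_id)
    grid <- grid[order(-grid$score, grid$element_id, grid$term_id), , drop = FALSE]
    best <- grid[1, ]
    pairs[[length(pairs) + 1L]] <- list(
      element_id = best$element_id, term_id = best$term_id,
      matched = best$term_id %in% current_ids(best$element_id))
    q_left <- setdiff(q_left, best$element_id)
    r_left <- setdiff(r_left, best$term_id)
  }

  out <- data.frame(
    element_id = vapply(pairs, `[[`, character(1), "element_id"),
    term_id = vapply(pairs, `[[`, character(1), "term_id"),
    matched = vapply(pairs, `[[`, logical(1), "matched"),
    stringsAsFactors = FALSE)
  attr(out, "reaction_id") <- reaction_id
  attr(out, "mapped_id") <- mapped_id
  out
}

#' Species revision proposals from a pairing
#'
#' Every unmatched pair proposes changing the query species' annotation to
#' the paired reference participant term; matched pairs propose nothing.
#'
#' @param pairing Output of [pair_participants()].
#' @param species_preds Current species prediction sets (used to drop
#'   no-op proposals).
#' @return A data.frame with columns `element_id`, `term_id` (deduplicated).
#' @export
revise_species <- function(pairing, species_preds) {
  un <- pairing[!pairing$matched, c("element_id", "term_id"), drop = FALSE]
  un <- unique(un)
  rownames(un) <- NULL
  un
}

# Sum of top rScores over all reactions in `reaction_ids`, under species
# predictions `sp`. Used for conflict resolution.
summed_top_rscore <- function(model, db, sp, reaction_ids, params) {
  total <- 0
  for (rid in reaction_ids) {
    qvec <- query_reaction_vector(model$reactions[[rid]], sp, db)
    if (length(qvec) == 0L) next
    scores <- rscore_all(qvec, db)
    total <- total + max(scores)
  }
  total
}

single_term_prediction <- function(element_id, term_id, score, params) {
  list(element_id = element_id,
       candidates = data.frame(annotation_id = term_id, score = score,
                               stringsAsFactors = FALSE),
       filtered = FALSE,
       source = "revised-by-reaction",
       params = params)
}

#' Iteratively refine species and reaction predictions
#'
#' Repeats up to `max_iter` rounds of: (a) pair participants of every
#' reaction with a nonempty prediction set against its mapped reference
#' reaction(s) (all ties at the top score contribute); (b) collect species
#' revision proposals from unmatched pairs; (c) resolve conflicting
#' proposals for the same species by choosing the term that maximizes the
#' summed top rScore over all reactions containing that species (ties break
#' lexicographically by term id); (d) replace each revised species'
#' candidate set with the single proposed term, scored with the proposing
#' reaction's top rScore and flagged `"revised-by-reaction"`; (e) re-score
#' and re-select candidates for every reaction touching a revised species.
#' Stops early at a fixed point (no proposal accepted).
#'
#' @param model The `model_view`.
#' @param db The `ref_db`.
#' @param species_preds,reaction_preds Initial prediction sets from
#'   [predict_species_annotations()] / [predict_reaction_annotations()].
#' @param params The [prediction_params()] used for re-selection.
#' @param max_iter Maximum refinement rounds (default 3; fixed points are
#'   typically reached in 1-2).
#' @return A list with `species_preds`, `reaction_preds`, `iterations`
#'   (rounds actually run), `changed` (TRUE iff any revision was applied),
#'   and `audit`, a data.frame logging every accepted revision (`iteration`,
#'   `reaction_element_id`, `mapped_reaction_id`, `species_element_id`,
#'   `old_annotations`, `new_annotation`, `score_before`, `score_after`).
#' @export
iterate_refinement <- function(model, db, species_preds, reaction_preds,
                               params = prediction_params(), max_iter = 3L) {
  sp <- species_preds
  rp <- reaction_preds
  audit <- list()
  changed_any <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # (a)-(b) collect proposals: element_id -> proposals with provenance
    proposals <- list()
    for (rid in names(rp)) {
      cand <- rp[[rid]]$candidates
      if (nrow(cand) == 0L) next
      top_score <- max(cand$score)
      mapped_ids <- sort(cand$annotation_id[cand$score == top_score])
      for (mid in mapped_ids) {
        if (!mid %in% names(db$reactions)) next
        pairing <- pair_participants(model, rid, mid, sp, db)
        props <- revise_species(pairing, sp)
        if (nrow(props) == 0L) next
        for (k in seq_len(nrow(props))) {
          proposals[[length(proposals) + 1L]] <- list(
            element_id = props$element_id[k], term_id = props$term_id[k],
            reaction_id = rid, mapped_id = mid, score = top_score)
        }
      }
    }
    if (length(proposals) == 0L) break

    # (c) conflict resolution per species
    by_species <- split(proposals,
                        vapply(proposals, `[[`, character(1), "element_id"))
    accepted <- list()
    for (el in sort(names(by_species))) {
      terms <- sort(unique(vapply(by_species[[el]], `[[`, character(1), "term_id")))
      touching <- names(model$reactions)[vapply(model$reactions, function(r)
        el %in% r$participants, logical(1))]
      if (length(terms) > 1L) {
        gains <- vapply(terms, function(t) {
          sp_try <- sp
          sp_try[[el]] <- single_term_prediction(el, t, 0, params)
          summed_top_rscore(model, db, sp_try, touching, params)
        }, numeric(1))
        best <- terms[gains == max(gains)][1]  # lexicographic tie-break (sorted)
      } else {
        best <- terms
      }
      proposers <- Filter(function(p) p$term_id == best, by_species[[el]])
      accepted[[el]] <- list(term_id = best,
                             score = max(vapply(proposers, `[[`, numeric(1), "score")),
                             proposers = proposers)
    }
    if (length(accepted) == 0L) break

    # (d) apply
    touched_rxns <- character(0)
    before_scores <- vapply(rp, function(p)
      if (nrow(p$candidates)) max(p$candidates$score) else 0, numeric(1))
    for (el in names(accepted)) {
      acc <- accepted[[el]]
      old <- sp[[el]]$candidates$annotation_id
      sp[[el]] <- single_term_prediction(el, acc$term_id, acc$score, params)
      touching <- names(model$reactions)[vapply(model$reactions, function(r)
        el %in% r$participants, logical(1))]
      touched_rxns <- union(touched_rxns, touching)
      for (p in acc$proposers) {
        audit[[length(audit) + 1L]] <- data.frame(
          iteration = iter,
          reaction_element_id = p$reaction_id,
          mapped_reaction_id = p$mapped_id,
          species_element_id = el,
          old_annotations = paste(old, collapse = ";"),
          new_annotation = acc$term_id,
          score_before = before_scores[[p$reaction_id]],
          score_after = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    changed_any <- TRUE

    # (e) re-score touched reactions and re-select
    for (rid in touched_rxns) {
      rxn <- model$reactions[[rid]]
      if (!filter_reaction(length(rxn$participants), params$min_participants)) next
      qvec <- query_reaction_vector(rxn, sp, db)
      ps <- empty_prediction(rid, params)
      if (length(qvec) > 0L) {
        scores <- rscore_all(qvec, db)
        ps$candidates <- select_candidates(names(scores), scores, params$mssc,
                                           params$cutoff)
      }
      ps$source <- if (nrow(ps$candidates)) "participants" else "none"
      rp[[rid]] <- ps
    }
    for (k in seq_along(audit)) {
      if (is.na(audit[[k]]$score_after) && audit[[k]]$iteration == iter) {
        rid <- audit[[k]]$reaction_element_id
        cand <- rp[[rid]]$candidates
        audit[[k]]$score_after <- if (nrow(cand)) max(cand$score) else 0
      }
    }
  }
  audit_df <- if (length(audit)) do.call(rbind, audit) else
    data.frame(iteration = integer(0), reaction_element_id = character(0),
               mapped_reaction_id = character(0), species_element_id = character(0),
               old_annotations = character(0), new_annotation = character(0),
               score_before = numeric(0), score_after = numeric(0),
               stringsAsFactors = FALSE)
  rownames(audit_df) <- NULL
  list(species_preds = sp, reaction_preds = rp, iterations = iter,
       changed = changed_any, audit = audit_df)
}
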