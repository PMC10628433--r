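# End-to-end annotation prediction: element filters, scoring against the
# reference database, and match-score-selection-criteria (MSSC) candidate
# selection.

#' Prediction parameters
#'
#' Bundles the knobs of the prediction pipeline.
#'
#' @param mssc Match score selection criterion: `"top"` keeps the
#'   annotations of the reference element(s) tied at the largest match score,
#'   provided that score is at least `cutoff`; `"above"` keeps every
#'   reference element whose score is at least `cutoff`.
#' @param cutoff Match score cutoff in \[0, 1\]; comparison is inclusive
#'   (score >= cutoff), so the default 0 recommends for every scorable
#'   element while 1 still admits exact matches.
#' @param min_len Element filter for species: minimum length of the
#'   normalized query string (default 3; names like "S1" carry no signal).
#' @param min_participants Element filter for reactions: minimum number of
#'   participant species (default 0, i.e. score everything; the evaluation
#'   preset in published benchmarks uses 3).
#' @return A list of class `prediction_params`.
#' @export
prediction_params <- function(mssc = c("top", "above"), cutoff = 0,
                              min_len = 3L, min_participants = 0L) {
  mssc <- match.arg(mssc)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff >= 0, cutoff <= 1,
            min_len >= 0, min_participants >= 0)
  structure(list(mssc = mssc, cutoff = cutoff,
                 min_len = as.integer(min_len),
                 min_participants = as.integer(min_participants)),
            class = "prediction_params")
}

#' Element filter for species
#'
#' A species passes iff its normalized query string (display name if
#' nonempty, else element id) has at least `min_len` characters.
#'
#' @param query_string The raw query string.
#' @param min_len Minimum normalized length.
#' @return TRUE (pass) or FALSE (reject).
#' @export
filter_species <- function(query_string, min_len = 3L) {
  nchar(normalize_string(query_string)) >= min_len
}

#' Element filter for reactions
#'
#' A reaction passes iff it has at least `min_participants` participant
#' species (reactants and products pooled).
#'
#' @param n_participants Number of participants (or a query reaction list).
#' @param min_participants Minimum count.
#' @return TRUE (pass) or FALSE (reject).
#' @export
filter_reaction <- function(n_participants, min_participants = 0L) {
  if (is.list(n_participants)) n_participants <- length(n_participants$participants)
  n_participants >= min_participants
}

# Query string for a species: display name if present and nonempty after
# trimming, else the element id.
species_query_string <- function(sp) {
  nm <- sp$display_name
  if (!is.null(nm) && length(nm) == 1L && !is.na(nm) && nzchar(trimws(nm))) {
    trimws(nm)
  } else {
    sp$element_id
  }
}

#' Select candidates under an MSSC and cutoff
#'
#' Applies the match score selection criterion to a scored candidate list.
#' Under `"top"`, the result is every candidate tied at the maximal score if
#' that score is at least the cutoff, otherwise empty; under `"above"`, every
#' candidate scoring at least the cutoff. Selection is deterministic and
#' independent of input order; ties are returned in lexicographic
#' annotation-id order.
#'
#' @param ids Character vector of annotation ids.
#' @param scores Numeric scores in \[0, 1\], parallel to `ids`.
#' @param mssc `"top"` or `"above"`.
#' @param cutoff Cutoff in \[0, 1\] (inclusive comparison).
#' @return A data.frame with columns `annotation_id`, `score`, sorted by
#'   decreasing score then id.
#' @export
select_candidates <- function(ids, scores, mssc = c("top", "above"), cutoff = 0) {
  mssc <- match.arg(mssc)
  stopifnot(length(ids) == length(scores))
  keep <- if (length(scores) == 0L) {
    logical(0)
  } else if (mssc == "top") {
    m <- max(scores)
    if (m >= cutoff) scores == m else rep(FALSE, length(scores))
  } else {
    scores >= cutoff
  }
  out <- data.frame(annotation_id = as.character(ids[keep]),
                    score = as.numeric(scores[keep]),
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$annotation_id), , drop = FALSE]
}

empty_prediction <- function(element_id, params, filtered = FALSE) {
  list(element_id = element_id,
       candidates = data.frame(annotation_id = character(0), score = numeric(0),
                               stringsAsFactors = FALSE),
       filtered = filtered,
       source = "none",
       params = params)
}

#' Predict species annotations for a model
#'
#' For every species in the model: choose the query string (display name,
#' falling back to the element id), apply the length filter, compute the
#' cosine match score against every reference species term, and select
#' candidates under the MSSC/cutoff. Filtered-out species get an empty
#' prediction set.
#'
#' @param model A `model_view` (see [read_sbml_model()]).
#' @param db A `ref_db`.
#' @param params A [prediction_params()].
#' @return A named list (by species element id) of prediction sets; each is a
#'   list with `element_id`, `candidates` (data.frame `annotation_id`,
#'   `score`), `filtered`, `source` and `params`.
#' @export
predict_species_annotations <- function(model, db, params = prediction_params()) {
  stopifnot(inherits(db, "ref_db"))
  out <- list()
  for (sp in model$species) {
    q <- species_query_string(sp)
    if (!filter_species(q, params$min_len)) {
      out[[sp$element_id]] <- empty_prediction(sp$element_id, params, filtered = TRUE)
      next
    }
    scores <- cscore_all(q, db)
    ps <- empty_prediction(sp$element_id, params)
    ps$candidates <- select_candidates(names(scores), scores, params$mssc, params$cutoff)
    ps$source <- if (nrow(ps$candidates)) "string" else "none"
    out[[sp$element_id]] <- ps
  }
  out
}

#' Predict reaction annotations for a model
#'
#' For every reaction passing the participant-count filter: build the query
#' reaction vector from the participants' current species predictions
#' ([query_reaction_vector()]), compute the normalization context over the
#' reference reactions, score every reference reaction with [rscore()], and
#' select candidates under the MSSC/cutoff. Reactions whose participants all
#' lack species predictions have an empty query vector and therefore an
#' empty prediction set.
#'
#' @param model A `model_view`.
#' @param db A `ref_db` containing reactions.
#' @param species_preds Species prediction sets for the same model.
#' @param params A [prediction_params()].
#' @return A named list (by reaction element id) of prediction sets.
#' @export
predict_reaction_annotations <- function(model, db, species_preds,
                                         params = prediction_params()) {
  stopifnot(inherits(db, "ref_db"))
  out <- list()
  for (rx in model$reactions) {
    if (!filter_reaction(length(rx$participants), params$min_participants)) {
      out[[rx$element_id]] <- empty_prediction(rx$element_id, params, filtered = TRUE)
      next
    }
    qvec <- query_reaction_vector(rx, species_preds, db)
    scores <- rscore_all(qvec, db)
    ps <- empty_prediction(rx$element_id, params)
    if (length(qvec) > 0L) {
      ps$candidates <- select_candidates(names(scores), scores, params$mssc, params$cutoff)
    }
    ps$source <- if (nrow(ps$candidates)) "participants" else "none"
    out[[rx$element_id]] <- ps
  }
  out
}

#' Tabulate predictions as a recommendation report
#'
#' Flattens species and reaction prediction sets into the TSV report schema:
#' one row per recommended annotation, columns `element_id`, `element_type`,
#' `annotation_id`, `match_score` (6 decimal places), `selected_by`,
#' `existing_annotation` (whether the element already carries any
#' recognized annotation in the model).
#'
#' @param model The `model_view` the predictions were computed on.
#' @param species_preds,reaction_preds Prediction-set lists (either may be
#'   `NULL`).
#' @param path Optional path; when given the report is written as TSV.
#' @return The report data.frame (invisibly when `path` is given).
#' @export
recommendation_report <- function(model, species_preds = NULL,
                                  reaction_preds = NULL, path = NULL) {
  rows <- list()
  add <- function(preds, type, elements) {
    existing <- stats::setNames(
      vapply(elements, function(e) length(e$annotations) > 0L, logical(1)),
      vapply(elements, `[[`, character(1), "element_id"))
    for (ps in preds) {
      if (nrow(ps$candidates) == 0L) next
      rows[[length(rows) + 1L]] <<- data.frame(
        element_id = ps$element_id,
        element_type = type,
        annotation_id = ps$candidates$annotation_id,
        match_score = sprintf("%.6f", ps$candidates$score),
        selected_by = ps$params$mssc,
        existing_annotation = if (isTRUE(existing[[ps$element_id]])) "yes" else "no",
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(species_preds)) add(species_preds, "species", model$species)
  if (!is.null(reaction_preds)) add(reaction_preds, "reaction", model$reactions)
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(element_id = character(0), element_type = character(0),
               annotation_id = character(0), match_score = character(0),
               selected_by = character(0), existing_annotation = character(0),
               stringsAsFactors = FALSE)
  rownames(report) <- NULL
  if (!is.null(path)) {
    utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    return(invisible(report))
  }
  report
}
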