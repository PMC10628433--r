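# Prediction-quality metrics. For one element with prediction set P and
# expected (ground-truth) set E: nonempty = [P != {}]; when nonempty,
# accuracy = min(1, |P & E|) (did at least one correct annotation make it
# into P) and exactness = 1/|P| (how specific the recommendation is);
# accuracy and exactness are undefined (NA) for empty prediction sets.
# Corpus-level figures are element-pooled means with the corresponding
# denominators.

#' Evaluate one prediction set against its ground truth
#'
#' @param P Character vector of predicted annotation ids (may be empty).
#' @param E Nonempty character vector of expected annotation ids.
#' @return A list with `nonempty` (0/1), `accuracy` (0/1 or NA), and
#'   `exactness` (1/|P| or NA).
#' @export
evaluate_element <- function(P, E) {
  stopifnot(length(E) >= 1L)
  P <- unique(as.character(P))
  E <- unique(as.character(E))
  if (length(P) == 0L) {
    return(list(nonempty = 0L, accuracy = NA_real_, exactness = NA_real_))
  }
  list(nonempty = 1L,
       accuracy = min(1, length(intersect(P, E))),
       exactness = 1 / length(P))
}

#' Aggregate element evaluations to corpus-level means
#'
#' `mean_nonempty` averages over all evaluated elements; `mean_accuracy` and
#' `mean_exactness` average only over elements with a nonempty prediction
#' set (their defining denominator). Empty denominators yield NA means.
#'
#' @param evals A list of [evaluate_element()] results.
#' @return A list with `n_elements`, `n_nonempty`, `mean_nonempty`,
#'   `mean_accuracy`, `mean_exactness`.
#' @export
summarize_evaluations <- function(evals) {
  n <- length(evals)
  if (n == 0L) {
    return(list(n_elements = 0L, n_nonempty = 0L, mean_nonempty = NA_real_,
                mean_accuracy = NA_real_, mean_exactness = NA_real_))
  }
  nonempty <- vapply(evals, `[[`, numeric(1), "nonempty")
  acc <- vapply(evals, `[[`, numeric(1), "accuracy")
  exa <- vapply(evals, `[[`, numeric(1), "exactness")
  k <- sum(nonempty)
  list(n_elements = n,
       n_nonempty = as.integer(k),
       mean_nonempty = mean(nonempty),
       mean_accuracy = if (k > 0) mean(acc[nonempty == 1]) else NA_real_,
       mean_exactness = if (k > 0) mean(exa[nonempty == 1]) else NA_real_)
}

# Evaluate one model's predictions against ground truth for one element
# type; elements absent from the truth are skipped.
evaluate_predictions <- function(preds, truth) {
  evals <- list()
  for (el in names(truth)) {
    E <- truth[[el]]
    if (length(E) == 0L) next
    ps <- preds[[el]]
    P <- if (is.null(ps)) character(0) else ps$candidates$annotation_id
    evals[[el]] <- evaluate_element(P, E)
  }
  evals
}

#' Sweep quality metrics over match score cutoffs
#'
#' Runs the full prediction pipeline at each cutoff (and optionally each
#' element-filter setting) and tabulates corpus-level metrics, one row per
#' (cutoff, filter, element type). Elements are pooled across all supplied
#' models (repository-level averaging); set `per_model = TRUE` to average
#' model means instead.
#'
#' @param models A `model_view` or list of them.
#' @param db A `ref_db`.
#' @param ground_truth A list with `species` and `reactions` maps
#'   (element id -> expected annotation ids), or a list of such lists
#'   parallel to `models`.
#' @param cutoffs Numeric vector of cutoffs in \[0, 1\].
#' @param mssc `"top"` or `"above"`.
#' @param min_len,min_participants Element-filter settings (vectors allowed;
#'   the sweep crosses them pairwise with `cutoffs` kept inner).
#' @param per_model Average per-model means instead of pooling elements.
#' @return A data.frame with columns `cutoff`, `min_len`,
#'   `min_participants`, `mssc`, `element_type`, `n_elements`, `n_nonempty`,
#'   `mean_nonempty`, `mean_accuracy`, `mean_exactness`.
#' @export
sweep_metrics <- function(models, db, ground_truth, cutoffs = seq(0, 1, by = 0.1),
                          mssc = "top", min_len = 3L, min_participants = 0L,
                          per_model = FALSE) {
  if (inherits(models, "model_view")) {
    models <- list(models)
    ground_truth <- list(ground_truth)
  }
  stopifnot(length(models) == length(ground_truth))
  grid <- expand.grid(min_len = min_len, min_participants = min_participants,
                      cutoff = cutoffs)
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    params <- prediction_params(mssc = mssc, cutoff = grid$cutoff[g],
                                min_len = grid$min_len[g],
                                min_participants = grid$min_participants[g])
    sp_evals <- list(); rx_evals <- list()
    for (m in seq_along(models)) {
      sp <- predict_species_annotations(models[[m]], db, params)
      se <- evaluate_predictions(sp, ground_truth[[m]]$species)
      re <- list()
      if (length(db$reactions) && length(models[[m]]$reactions)) {
        rx <- predict_reaction_annotations(models[[m]], db, sp, params)
        re <- evaluate_predictions(rx, ground_truth[[m]]$reactions)
      }
      if (per_model) {
        sp_evals[[m]] <- se; rx_evals[[m]] <- re
      } else {
        sp_evals <- c(sp_evals, se); rx_evals <- c(rx_evals, re)
      }
    }
    mk <- function(evals, type) {
      s <- if (per_model) {
        per <- lapply(evals, summarize_evaluations)
        per <- Filter(function(x) x$n_elements > 0L, per)
        if (!length(per)) return(NULL)
        list(n_elements = sum(vapply(per, `[[`, integer(1), "n_elements")),
             n_nonempty = sum(vapply(per, `[[`, integer(1), "n_nonempty")),
             mean_nonempty = mean(vapply(per, `[[`, numeric(1), "mean_nonempty")),
             mean_accuracy = mean(vapply(per, `[[`, numeric(1), "mean_accuracy"),
                                  na.rm = TRUE),
             mean_exactness = mean(vapply(per, `[[`, numeric(1), "mean_exactness"),
                                   na.rm = TRUE))
      } else {
        if (!length(evals)) return(NULL)
        summarize_evaluations(evals)
      }
      data.frame(cutoff = grid$cutoff[g], min_len = grid$min_len[g],
                 min_participants = grid$min_participants[g], mssc = mssc,
                 element_type = type, n_elements = s$n_elements,
                 n_nonempty = s$n_nonempty, mean_nonempty = s$mean_nonempty,
                 mean_accuracy = s$mean_accuracy, mean_exactness = s$mean_exactness,
                 stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- mk(sp_evals, "species")
    rows[[length(rows) + 1L]] <- mk(rx_evals, "reaction")
  }
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cutoff = numeric(0), min_len = integer(0),
               min_participants = integer(0), mssc = character(0),
               element_type = character(0), n_elements = integer(0),
               n_nonempty = integer(0), mean_nonempty = numeric(0),
               mean_accuracy = numeric(0), mean_exactness = numeric(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Strip existing annotations from a model, keeping them as ground truth
#'
#' Removes recognized annotations from a `model_view` and returns them as an
#' evaluation ground truth. Species keep their ChEBI ids; reactions keep
#' Rhea ids directly, while KEGG-reaction and EC annotations are mapped
#' through the cross-reference map when one is supplied. Elements whose
#' annotations cannot be resolved against the reference database (when
#' given) are excluded from the ground truth with a warning rather than
#' counted as failures.
#'
#' @param model A `model_view` with at least one recognized annotation.
#' @param db Optional `ref_db`; when given, truth ids are restricted to ids
#'   present in it.
#' @param crossref Optional map from [load_crossref_map()].
#' @return A list with `model` (annotations emptied) and `ground_truth`
#'   (list with `species` and `reactions` maps).
#' @export
strip_annotations <- function(model, db = NULL, crossref = NULL) {
  truth_sp <- list(); truth_rx <- list()
  excluded <- character(0)
  resolve_sp <- function(ids) {
    ids <- ids[grepl("^CHEBI:", ids)]
    if (!is.null(db)) ids <- ids[ids %in% names(db$species)]
    ids
  }
  resolve_rx <- function(ids) {
    out <- ids[grepl("^RHEA:", ids)]
    for (id in ids[grepl("^(KEGG|EC):", ids)]) {
      if (!is.null(crossref) && !is.null(crossref[[id]])) {
        out <- c(out, crossref[[id]])
      }
    }
    out <- unique(out)
    if (!is.null(db) && length(db$reactions)) out <- out[out %in% names(db$reactions)]
    out
  }
  n_annotated <- 0L
  for (el in names(model$species)) {
    ann <- model$species[[el]]$annotations
    if (length(ann) == 0L) next
    n_annotated <- n_annotated + 1L
    ids <- resolve_sp(ann)
    if (length(ids)) truth_sp[[el]] <- ids else excluded <- c(excluded, el)
    model$species[[el]]$annotations <- character(0)
  }
  for (el in names(model$reactions)) {
    ann <- model$reactions[[el]]$annotations
    if (length(ann) == 0L) next
    n_annotated <- n_annotated + 1L
    ids <- resolve_rx(ann)
    if (length(ids)) truth_rx[[el]] <- ids else excluded <- c(excluded, el)
    model$reactions[[el]]$annotations <- character(0)
  }
  if (n_annotated == 0L) {
    stop("model has no recognized annotations to strip")
  }
  if (length(excluded)) {
    warning("annotation(s) not resolvable, element(s) excluded from ground truth: ",
            paste(excluded, collapse = ", "))
  }
  list(model = model,
       ground_truth = list(species = truth_sp, reactions = truth_rx))
}
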