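# Deterministic synthetic-data generator: reference databases, SBML models
# whose element names are noisy variants of reference synonyms, and ground
# truth, so the whole pipeline is testable without downloading ChEBI/Rhea.

# Run code under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic generator
#'
#' All ranges are inclusive `c(lo, hi)` pairs. Defaults give a corpus of 50
#' species terms and 20 reactions with clean (noise-free) names — the
#' regime in which prediction must recover the ground truth exactly — and
#' formulas drawn over a small element alphabet that includes hydrogen so
#' the simplification rule is exercised.
#'
#' @param n_species_terms Number of reference species terms.
#' @param synonyms_per_term Range of synonym counts per term.
#' @param name_length Range of base-name lengths (characters).
#' @param n_formula_elements Range of distinct non-hydrogen elements per
#'   formula.
#' @param n_reactions Number of reference reactions.
#' @param participants_per_reaction Range of participant counts.
#' @param name_noise_rate Per-character probability of perturbing a model
#'   species display name (substitution or deletion), in \[0, 1\].
#' @param participant_dropout_rate Per-participant probability of omitting a
#'   reference participant from the model reaction, in \[0, 1\].
#' @param seed Integer seed; every generator operation is reproducible from
#'   it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_species_terms = 50L, synonyms_per_term = c(2L, 4L),
                         name_length = c(5L, 10L), n_formula_elements = c(1L, 4L),
                         n_reactions = 20L, participants_per_reaction = c(2L, 6L),
                         name_noise_rate = 0, participant_dropout_rate = 0,
                         seed = 1L) {
  stopifnot(n_species_terms >= 1L, n_reactions >= 0L,
            length(synonyms_per_term) == 2L, synonyms_per_term[1] >= 1L,
            length(name_length) == 2L, name_length[1] >= 1L,
            length(n_formula_elements) == 2L, n_formula_elements[1] >= 0L,
            length(participants_per_reaction) == 2L,
            participants_per_reaction[1] >= 1L,
            name_noise_rate >= 0, name_noise_rate <= 1,
            participant_dropout_rate >= 0, participant_dropout_rate <= 1)
  structure(list(n_species_terms = as.integer(n_species_terms),
                 synonyms_per_term = as.integer(synonyms_per_term),
                 name_length = as.integer(name_length),
                 n_formula_elements = as.integer(n_formula_elements),
                 n_reactions = as.integer(n_reactions),
                 participants_per_reaction = as.integer(participants_per_reaction),
                 name_noise_rate = name_noise_rate,
                 participant_dropout_rate = participant_dropout_rate,
                 seed = as.integer(seed)),
            class = "synth_config")
}

rint <- function(range) if (range[1] >= range[2]) range[1] else
  sample(range[1]:range[2], 1L)

# Character-multiset signature used to keep synonyms of different terms from
# accidentally matching with cosine similarity 1.
char_signature <- function(s) {
  paste(sort(strsplit(normalize_string(s), "", fixed = TRUE)[[1]]), collapse = "")
}

random_name <- function(len) paste(sample(letters, len, replace = TRUE), collapse = "")

synonym_variants <- function(base, n) {
  pool <- c(base,
            paste0(base, "ate"), paste0(base, "ine"), paste0(base, "ol"),
            paste0(base, "s"),
            { pos <- sample(nchar(base), 1L)
              paste0(substr(base, 1, pos), sample(0:9, 1L), substr(base, pos + 1L, nchar(base))) },
            paste0(sample(0:9, 1L), "-", base))
  unique(pool)[seq_len(min(n, length(unique(pool))))]
}

#' Generate a synthetic reference database
#'
#' Species terms get random alphanumeric base names with synonym variants
#' (suffixes, pluralization, digit insertion) and random chemical formulas
#' over the alphabet C/N/O/P/S plus hydrogen; the first term is pure
#' hydrogen (`H2`) so the hydrogen-only simplification rule is always
#' exercised. Synonyms are rejection-sampled so that no two terms share a
#' character multiset, making noiseless recovery exact by construction.
#' Reactions are random participant subsets. Fully reproducible from
#' `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @return A `ref_db`.
#' @export
generate_reference_db <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    used_sigs <- character(0)
    species <- vector("list", cfg$n_species_terms)
    for (i in seq_len(cfg$n_species_terms)) {
      syns <- NULL
      for (try in 1:200) {
        base <- random_name(rint(cfg$name_length))
        cand <- synonym_variants(base, rint(cfg$synonyms_per_term))
        sigs <- vapply(cand, char_signature, character(1))
        if (!any(sigs %in% used_sigs)) { syns <- cand; used_sigs <- c(used_sigs, sigs); break }
      }
      if (is.null(syns)) stop("could not generate collision-free synonyms; enlarge name_length")
      if (i == 1L) {
        formula <- "H2"
      } else {
        n_el <- rint(cfg$n_formula_elements)
        els <- if (n_el > 0) sample(c("C", "N", "O", "P", "S"), n_el) else character(0)
        counts <- if (n_el > 0) sample(1:12, n_el, replace = TRUE) else integer(0)
        h <- sample(0:12, 1L)
        parts <- c(if (h > 0) paste0("H", h) else NULL,
                   if (n_el > 0) paste0(els, counts) else NULL)
        if (length(parts) == 0L) parts <- "H"
        formula <- paste(parts, collapse = "")
      }
      species[[i]] <- list(term_id = sprintf("CHEBI:%d", 10000L + i),
                           synonyms = syns,
                           formulas = simplify_formula(formula),
                           raw_formulas = formula)
    }
    reactions <- vector("list", cfg$n_reactions)
    term_ids <- vapply(species, `[[`, character(1), "term_id")
    for (j in seq_len(cfg$n_reactions)) {
      k <- min(rint(cfg$participants_per_reaction), length(term_ids))
      reactions[[j]] <- list(reaction_id = sprintf("RHEA:%d", 20000L + j),
                             participants = sort(sample(term_ids, k)))
    }
    build_ref_db(species, reactions)
  })
}

perturb_name <- function(name, rate) {
  if (rate <= 0) return(name)
  chars <- strsplit(name, "", fixed = TRUE)[[1]]
  out <- character(0)
  for (ch in chars) {
    if (stats::runif(1) < rate) {
      if (stats::runif(1) < 0.5) next  # deletion
      ch <- sample(c(letters, as.character(0:9)), 1L)  # substitution
    }
    out <- c(out, ch)
  }
  paste(out, collapse = "")
}

#' Generate a synthetic model with ground truth
#'
#' Builds a `model_view` from a generated reference database: one model
#' reaction per reference reaction (participants dropped independently at
#' `participant_dropout_rate`, always keeping at least one) and one model
#' species per reference term used, whose display name is a randomly chosen
#' synonym of its source term perturbed per character at `name_noise_rate`.
#' The ground truth records the source ids. Reproducible from `cfg$seed`
#' (offset so the database and model draws are independent).
#'
#' @param db A `ref_db` from [generate_reference_db()].
#' @param cfg The same [synth_config()].
#' @return A list with `model` (a `model_view`) and `ground_truth` (list
#'   with `species` and `reactions` maps to expected id sets).
#' @export
generate_model <- function(db, cfg) {
  stopifnot(inherits(db, "ref_db"), inherits(cfg, "synth_config"))
  with_seed(cfg$seed + 1000003L, {
    rx_list <- list(); truth_rx <- list()
    used_terms <- character(0)
    for (j in seq_along(db$reactions)) {
      src <- db$reactions[[j]]
      keep <- src$participants[stats::runif(length(src$participants)) >=
                                 cfg$participant_dropout_rate]
      if (length(keep) == 0L) keep <- sample(src$participants, 1L)
      used_terms <- union(used_terms, keep)
      rx_list[[j]] <- list(term_participants = keep, src_id = src$reaction_id)
    }
    used_terms <- sort(used_terms)
    sp_el <- stats::setNames(sprintf("M_sp%03d", seq_along(used_terms)), used_terms)
    species <- list(); truth_sp <- list()
    for (t in used_terms) {
      syn <- sample(db$species[[t]]$synonyms, 1L)
      species[[length(species) + 1L]] <- list(
        element_id = sp_el[[t]],
        display_name = perturb_name(syn, cfg$name_noise_rate))
      truth_sp[[sp_el[[t]]]] <- t
    }
    reactions <- list()
    for (j in seq_along(rx_list)) {
      el <- sprintf("R%03d", j)
      reactions[[j]] <- list(element_id = el,
                             participants = unname(sp_el[rx_list[[j]]$term_participants]))
      truth_rx[[el]] <- rx_list[[j]]$src_id
    }
    list(model = model_view(sprintf("synthetic_seed%d", cfg$seed), species, reactions),
         ground_truth = list(species = truth_sp, reactions = truth_rx))
  })
}

#' Hand-built demonstration fixture (synthetic ATP-hydrolysis analogue)
#'
#' Loads the small reference database and SBML model packaged under
#' `inst/extdata/`: nine ChEBI-style species terms (ATP, ADP, AMP, water,
#' hydron, hydrogenphosphate, acetate, acetyl phosphate, glucose analogues),
#' three Rhea-style reactions, a cross-reference map, and a model containing
#' an ATP -> ADP query reaction plus an acetate-kinase-style reaction whose
#' ATP species is deliberately named so that string matching mispredicts it
#' (exercising refinement). The database is constructed so that the
#' ATP -> ADP query has dot product 2 with the ATP-hydrolysis reference,
#' `M_q = 2`, `D = 5`, and rScore exactly 0.4. All contents are synthetic
#' stand-ins styled after real ChEBI/Rhea identifiers.
#'
#' @return A list with `db` (a `ref_db`), `model` (a `model_view`),
#'   `crossref` (from [load_crossref_map()]), and `paths` (the packaged
#'   files).
#' @export
demo_fixture <- function() {
  ext <- function(f) system.file("extdata", f, package = "sbmlannot", mustWork = TRUE)
  db <- load_reference_db(ext("demo_species.tsv"), ext("demo_reactions.tsv"))
  crossref <- load_crossref_map(ext("demo_crossref.tsv"), db)
  model <- read_sbml_model(ext("demo_model.xml"))
  list(db = db, model = model, crossref = crossref,
       paths = list(species = ext("demo_species.tsv"),
                    reactions = ext("demo_reactions.tsv"),
                    crossref = ext("demo_crossref.tsv"),
                    model = ext("demo_model.xml")))
}
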