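# SBML read/write. Only the element skeleton needed for annotation work is
# modelled: species (id, display name, annotations) and reactions (id,
# reactant+product species, annotations). Annotations are MIRIAM-style RDF
# controlled-vocabulary terms with identifiers.org resource URIs.

RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
BQBIOL_NS <- "http://biomodels.net/biology-qualifiers/"

#' Construct a model view
#'
#' In-memory view of an SBML model: just ids, display names, reaction
#' participant sets (reactants and products pooled; modifiers are not
#' participants) and existing annotation ids.
#'
#' @param model_id Model identifier string.
#' @param species List of lists with `element_id`, optional `display_name`,
#'   optional `annotations` (character vector of ids like `"CHEBI:15377"`).
#' @param reactions List of lists with `element_id`, `participants`
#'   (character vector of species element ids), optional `annotations`.
#' @return An object of class `model_view`.
#' @export
model_view <- function(model_id, species = list(), reactions = list()) {
  fix <- function(e, with_participants) {
    stopifnot(!is.null(e$element_id))
    if (is.null(e$display_name)) e$display_name <- NA_character_
    if (is.null(e$annotations)) e$annotations <- character(0)
    if (with_participants) e$participants <- sort(unique(as.character(e$participants)))
    e
  }
  species <- lapply(species, fix, with_participants = FALSE)
  reactions <- lapply(reactions, fix, with_participants = TRUE)
  sids <- vapply(species, `[[`, character(1), "element_id")
  rids <- vapply(reactions, `[[`, character(1), "element_id")
  if (anyDuplicated(c(sids, rids))) stop("duplicate element ids in model")
  names(species) <- sids
  names(reactions) <- rids
  for (r in reactions) {
    missing <- setdiff(r$participants, sids)
    if (length(missing)) {
      stop(sprintf("reaction %s references unknown species: %s",
                   r$element_id, paste(missing, collapse = ", ")))
    }
  }
  structure(list(model_id = model_id, species = species, reactions = reactions),
            class = "model_view")
}

#' @export
print.model_view <- function(x, ...) {
  cat(sprintf("SBML model view '%s': %d species, %d reactions\n",
              x$model_id, length(x$species), length(x$reactions)))
  invisible(x)
}

# Parse one annotation resource URI into a normalized id ("CHEBI:...",
# "RHEA:...", "KEGG:R...", "EC:...") or NA if not recognized. Accepts both
# identifiers.org dialects (path-style lowercase prefix and compact
# id-style) plus legacy urn:miriam forms.
parse_annotation_uri <- function(uri) {
  u <- utils::URLdecode(trimws(uri))
  u <- sub("^https?://(www\\.)?identifiers\\.org/", "", u)
  u <- sub("^urn:miriam:", "", u)
  if (grepl("^CHEBI:\\d+$", u)) return(u)
  m <- regmatches(u, regexec("^chebi[:/](CHEBI:\\d+)$", u))[[1]]
  if (length(m)) return(m[2])
  if (grepl("^RHEA:\\d+$", u)) return(u)
  m <- regmatches(u, regexec("^rhea[:/](RHEA:)?(\\d+)$", u))[[1]]
  if (length(m)) return(paste0("RHEA:", m[3]))
  m <- regmatches(u, regexec("^kegg\\.reaction[:/](R\\d+)$", u))[[1]]
  if (length(m)) return(paste0("KEGG:", m[2]))
  m <- regmatches(u, regexec("^ec-code[:/]([0-9.]+)$", u))[[1]]
  if (length(m)) return(paste0("EC:", m[2]))
  NA_character_
}

# Normalized id -> identifiers.org URI (modern dialect).
annotation_uri <- function(id) {
  if (grepl("^CHEBI:\\d+$", id)) return(paste0("https://identifiers.org/", id))
  m <- regmatches(id, regexec("^RHEA:(\\d+)$", id))[[1]]
  if (length(m)) return(paste0("https://identifiers.org/rhea/", m[2]))
  m <- regmatches(id, regexec("^KEGG:(R\\d+)$", id))[[1]]
  if (length(m)) return(paste0("https://identifiers.org/kegg.reaction:", m[2]))
  m <- regmatches(id, regexec("^EC:([0-9.]+)$", id))[[1]]
  if (length(m)) return(paste0("https://identifiers.org/ec-code/", m[2]))
  stop("cannot build a resource URI for id: ", id)
}

annotation_class <- function(id) sub(":.*$", "", id)

# All recognized annotation ids under one element node.
node_annotation_ids <- function(node) {
  lis <- xml2::xml_find_all(node, ".//*[local-name()='li']")
  uris <- vapply(lis, function(li) {
    at <- xml2::xml_attrs(li)
    hit <- grep("(^|:)resource$", names(at))
    if (length(hit)) at[[hit[1]]] else NA_character_
  }, character(1))
  ids <- vapply(uris[!is.na(uris)], parse_annotation_uri, character(1))
  sort(unique(ids[!is.na(ids)]))
}

#' Read an SBML model
#'
#' Parses an SBML Level 2 or 3 file into a [model_view()]: species ids and
#' display names, reaction participant sets (reactants and products pooled;
#' modifiers excluded), and existing ChEBI/Rhea/KEGG-reaction/EC annotations
#' from RDF controlled-vocabulary resource URIs (both identifiers.org
#' dialects and urn:miriam are recognized).
#'
#' @param path Path to an SBML XML file.
#' @return A `model_view`.
#' @export
read_sbml_model <- function(path) {
  if (!file.exists(path)) stop("SBML file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML file ", path, ": ",
                                           conditionMessage(e)))
  model_node <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (inherits(model_node, "xml_missing")) stop("no <model> element in ", path)
  model_id <- xml2::xml_attr(model_node, "id")
  if (is.na(model_id)) model_id <- tools::file_path_sans_ext(basename(path))

  sp_nodes <- xml2::xml_find_all(
    model_node, "./*[local-name()='listOfSpecies']/*[local-name()='species']")
  species <- lapply(sp_nodes, function(n) {
    list(element_id = xml2::xml_attr(n, "id"),
         display_name = xml2::xml_attr(n, "name"),
         annotations = node_annotation_ids(n))
  })

  rx_nodes <- xml2::xml_find_all(
    model_node, "./*[local-name()='listOfReactions']/*[local-name()='reaction']")
  reactions <- lapply(rx_nodes, function(n) {
    refs <- xml2::xml_find_all(
      n, paste0("./*[local-name()='listOfReactants' or local-name()='listOfProducts']",
                "/*[local-name()='speciesReference']"))
    list(element_id = xml2::xml_attr(n, "id"),
         display_name = xml2::xml_attr(n, "name"),
         participants = unique(xml2::xml_attr(refs, "species")),
         annotations = node_annotation_ids(n))
  })
  model_view(model_id, species, reactions)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

# Find the element node (species or reaction) with a given SBML id.
find_element_node <- function(doc, element_id) {
  xml2::xml_find_first(doc, sprintf(
    ".//*[(local-name()='species' or local-name()='reaction') and @id='%s']",
    element_id))
}

# Add CV-term resource URIs under one element node (creating the
# annotation/RDF skeleton and a metaid as needed).
add_cv_terms <- function(doc, element_id, ids, qualifier = "is") {
  node <- find_element_node(doc, element_id)
  if (inherits(node, "xml_missing")) stop("unknown element id: ", element_id)
  metaid <- xml2::xml_attr(node, "metaid")
  if (is.na(metaid)) {
    metaid <- paste0("meta_", element_id)
    xml2::xml_attr(node, "metaid") <- metaid
  }
  uris <- vapply(ids, annotation_uri, character(1))

  bag <- xml2::xml_find_first(node, sprintf(
    "./*[local-name()='annotation']//*[local-name()='%s' and namespace-uri()='%s']/*[local-name()='Bag']",
    qualifier, BQBIOL_NS))
  if (!inherits(bag, "xml_missing")) {
    existing <- node_annotation_ids(bag)
    for (u in uris[!(ids %in% existing)]) {
      xml2::xml_add_child(bag, "rdf:li", "rdf:resource" = u)
    }
    return(invisible(node))
  }

  frag <- paste0(
    '<annotation><rdf:RDF xmlns:rdf="', RDF_NS, '" xmlns:bqbiol="', BQBIOL_NS, '">',
    '<rdf:Description rdf:about="#', xml_escape(metaid), '">',
    '<bqbiol:', qualifier, '><rdf:Bag>',
    paste0('<rdf:li rdf:resource="', xml_escape(uris), '"/>', collapse = ""),
    '</rdf:Bag></bqbiol:', qualifier, '>',
    '</rdf:Description></rdf:RDF></annotation>')
  ann <- xml2::xml_find_first(node, "./*[local-name()='annotation']")
  new_node <- xml2::read_xml(frag)
  if (inherits(ann, "xml_missing")) {
    xml2::xml_add_child(node, new_node, .where = 0)
  } else {
    # merge: move our RDF into the existing annotation container
    xml2::xml_add_child(ann, xml2::xml_child(new_node, 1))
  }
  invisible(node)
}

# Remove existing CV li entries under an element whose parsed id belongs to
# one of the given namespace classes (e.g. "CHEBI", "RHEA").
remove_cv_terms <- function(doc, element_id, classes) {
  node <- find_element_node(doc, element_id)
  lis <- xml2::xml_find_all(node, "./*[local-name()='annotation']//*[local-name()='li']")
  for (li in lis) {
    at <- xml2::xml_attrs(li)
    hit <- grep("(^|:)resource$", names(at))
    if (!length(hit)) next
    id <- parse_annotation_uri(at[[hit[1]]])
    if (!is.na(id) && annotation_class(id) %in% classes) xml2::xml_remove(li)
  }
  invisible(node)
}

#' Write recommended annotations into an SBML file
#'
#' Adds controlled-vocabulary terms (default qualifier `bqbiol:is`) with
#' identifiers.org resource URIs to the named elements. In `"append"` mode
#' existing annotations are kept; in `"replace"` mode existing annotations in
#' the same namespace(s) as the new ids (e.g. old ChEBI terms on a species
#' being given new ChEBI terms) are removed first, while annotations in
#' other namespaces are untouched. All other model content is preserved up
#' to canonical XML serialization. Unknown element ids abort before anything
#' is written.
#'
#' @param path_in Input SBML path.
#' @param records Data.frame with columns `element_id`, `annotation_id`
#'   (one row per recommended annotation; several rows per element allowed).
#' @param mode `"append"` (default) or `"replace"`.
#' @param path_out Output SBML path.
#' @param qualifier Biology qualifier local name (default `"is"`).
#' @return `path_out`, invisibly.
#' @export
write_annotations <- function(path_in, records, mode = c("append", "replace"),
                              path_out, qualifier = "is") {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(records),
            all(c("element_id", "annotation_id") %in% names(records)))
  doc <- xml2::read_xml(path_in)
  els <- unique(records$element_id)
  missing <- els[vapply(els, function(e) inherits(find_element_node(doc, e), "xml_missing"),
                        logical(1))]
  if (length(missing)) {
    stop("element id(s) not found in model: ", paste(missing, collapse = ", "))
  }
  for (e in els) {
    ids <- sort(unique(records$annotation_id[records$element_id == e]))
    if (mode == "replace") {
      remove_cv_terms(doc, e, unique(vapply(ids, annotation_class, character(1))))
    }
    add_cv_terms(doc, e, ids, qualifier = qualifier)
  }
  xml2::write_xml(doc, path_out)
  invisible(path_out)
}

#' Serialize a model view to SBML
#'
#' Writes a minimal SBML Level 3 Version 1 document containing the model's
#' species (with display names), reactions (participants written as
#' reactants for the first half and products for the rest, which is
#' immaterial to annotation work since participants are pooled on reading),
#' and any annotation ids carried by the view as CV terms.
#'
#' @param model A `model_view`.
#' @param path Output path.
#' @param qualifier Biology qualifier for written annotations.
#' @return `path`, invisibly.
#' @export
model_to_sbml <- function(model, path, qualifier = "is") {
  stopifnot(inherits(model, "model_view"))
  sp_xml <- vapply(model$species, function(s) {
    nm <- if (!is.na(s$display_name))
      sprintf(' name="%s"', xml_escape(s$display_name)) else ""
    sprintf(paste0('      <species id="%s"%s compartment="c" hasOnlySubstanceUnits="false"',
                   ' boundaryCondition="false" constant="false"/>'),
            xml_escape(s$element_id), nm)
  }, character(1))
  rx_xml <- vapply(model$reactions, function(r) {
    n <- length(r$participants)
    half <- max(1L, n %/% 2L)
    reac <- r$participants[seq_len(half)]
    prod <- if (n > half) r$participants[(half + 1L):n] else character(0)
    sref <- function(ids) paste0(
      sprintf('          <speciesReference species="%s" stoichiometry="1" constant="true"/>',
              xml_escape(ids)), collapse = "\n")
    body <- sprintf('        <listOfReactants>\n%s\n        </listOfReactants>', sref(reac))
    if (length(prod)) {
      body <- paste0(body, sprintf(
        '\n        <listOfProducts>\n%s\n        </listOfProducts>', sref(prod)))
    }
    sprintf('      <reaction id="%s" reversible="false" fast="false">\n%s\n      </reaction>',
            xml_escape(r$element_id), body)
  }, character(1))
  txt <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">\n',
    sprintf('  <model id="%s">\n', xml_escape(model$model_id)),
    '    <listOfCompartments>\n',
    '      <compartment id="c" constant="true"/>\n',
    '    </listOfCompartments>\n',
    if (length(sp_xml)) paste0('    <listOfSpecies>\n',
                               paste(sp_xml, collapse = "\n"),
                               '\n    </listOfSpecies>\n') else "",
    if (length(rx_xml)) paste0('    <listOfReactions>\n',
                               paste(rx_xml, collapse = "\n"),
                               '\n    </listOfReactions>\n') else "",
    '  </model>\n</sbml>\n')
  writeLines(txt, path, useBytes = TRUE)
  records <- do.call(rbind, lapply(c(model$species, model$reactions), function(e) {
    if (length(e$annotations) == 0L) return(NULL)
    data.frame(element_id = e$element_id, annotation_id = e$annotations,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(records) && nrow(records)) {
    write_annotations(path, records, mode = "append", path_out = path,
                      qualifier = qualifier)
  }
  invisible(path)
}
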