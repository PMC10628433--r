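test_that("reading the packaged model extracts elements, names and annotations", {
  fx <- demo_fixture()
  m <- fx$model
  expect_s3_class(m, "model_view")
  expect_length(m$species, 7L)
  expect_length(m$reactions, 2L)
  expect_identical(m$species[["S_atp"]]$display_name, "ATP")
  # species without a name attribute falls back to its id as query string
  expect_true(is.na(m$species[["S1"]]$display_name))
  # participants pool reactants and products
  expect_setequal(m$reactions[["R_ACKr"]]$participants,
                  c("M_ac_c", "M_atp_c", "M_actp_c", "M_adp_c"))
  # all three URI dialects in the file are recognized
  expect_identical(m$species[["S_atp"]]$annotations, "CHEBI:30616")    # modern compact
  expect_identical(m$species[["S_adp"]]$annotations, "CHEBI:456216")   # legacy path
  expect_identical(m$species[["M_adp_c"]]$annotations, "CHEBI:456216") # urn:miriam
  expect_identical(m$reactions[["R_hyd"]]$annotations, "KEGG:R00086")
  expect_identical(m$reactions[["R_ACKr"]]$annotations, "RHEA:11352")
})

test_that("modifier species are read but not counted as reaction participants", {
  p <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '  <model id="mod"><listOfSpecies>',
    '    <species id="a" name="alpha"/><species id="b"/><species id="e"/>',
    '  </listOfSpecies><listOfReactions>',
    '    <reaction id="r1">',
    '      <listOfReactants><speciesReference species="a"/></listOfReactants>',
    '      <listOfProducts><speciesReference species="b"/></listOfProducts>',
    '      <listOfModifiers><modifierSpeciesReference species="e"/></listOfModifiers>',
    '    </reaction>',
    '  </listOfReactions></model></sbml>'), p)
  m <- read_sbml_model(p)
  expect_length(m$species, 3L)
  expect_setequal(m$reactions[["r1"]]$participants, c("a", "b"))
})

test_that("models with zero reactions and unparsable files behave as documented", {
  p <- tempfile(fileext = ".xml")
  writeLines(c('<?xml version="1.0"?>',
               '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core">',
               '<model id="empty"><listOfSpecies><species id="x" name="water"/>',
               '</listOfSpecies></model></sbml>'), p)
  m <- read_sbml_model(p)
  expect_length(m$reactions, 0L)

  bad <- tempfile(fileext = ".xml")
  writeLines("not xml at all <", bad)
  expect_error(read_sbml_model(bad), "cannot parse")
  expect_error(read_sbml_model(tempfile()), "not found")
})

test_that("append mode adds CV terms and round-trips, preserving prior content", {
  fx <- demo_fixture()
  out <- tempfile(fileext = ".xml")
  recs <- data.frame(element_id = c("M_ac_c", "M_ac_c", "R_hyd"),
                     annotation_id = c("CHEBI:30089", "CHEBI:15377", "RHEA:13065"),
                     stringsAsFactors = FALSE)
  write_annotations(fx$paths$model, recs, mode = "append", path_out = out)
  m2 <- read_sbml_model(out)
  # two resource URIs under one qualifier for the species
  expect_setequal(m2$species[["M_ac_c"]]$annotations, c("CHEBI:30089", "CHEBI:15377"))
  # prior annotation kept alongside the new one
  expect_setequal(m2$reactions[["R_hyd"]]$annotations, c("KEGG:R00086", "RHEA:13065"))
  # untouched elements unchanged
  expect_identical(m2$species[["S_atp"]]$annotations, "CHEBI:30616")
  expect_length(m2$species, 7L)
  expect_identical(lapply(m2$reactions, `[[`, "participants"),
                   lapply(fx$model$reactions, `[[`, "participants"))
})

test_that("replace mode supersedes same-namespace annotations only", {
  fx <- demo_fixture()
  out <- tempfile(fileext = ".xml")
  write_annotations(fx$paths$model,
                    data.frame(element_id = "S_atp", annotation_id = "CHEBI:16027"),
                    mode = "replace", path_out = out)
  m2 <- read_sbml_model(out)
  expect_identical(m2$species[["S_atp"]]$annotations, "CHEBI:16027")

  # a reaction's KEGG annotation survives a RHEA replacement
  out2 <- tempfile(fileext = ".xml")
  write_annotations(fx$paths$model,
                    data.frame(element_id = "R_hyd", annotation_id = "RHEA:13065"),
                    mode = "replace", path_out = out2)
  m3 <- read_sbml_model(out2)
  expect_setequal(m3$reactions[["R_hyd"]]$annotations, c("KEGG:R00086", "RHEA:13065"))
})

test_that("unknown element ids abort before any write", {
  fx <- demo_fixture()
  out <- tempfile(fileext = ".xml")
  expect_error(
    write_annotations(fx$paths$model,
                      data.frame(element_id = c("S_atp", "nope"),
                                 annotation_id = c("CHEBI:30616", "CHEBI:1")),
                      path_out = out),
    "nope")
  expect_false(file.exists(out))
})

test_that("model_view serialization to SBML round-trips elements and annotations", {
  cfg <- synth_config(n_species_terms = 12L, n_reactions = 5L, seed = 3)
  db <- generate_reference_db(cfg)
  gm <- generate_model(db, cfg)
  m <- gm$model
  # attach ground-truth annotations to the view before writing
  for (el in names(gm$ground_truth$species))
    m$species[[el]]$annotations <- gm$ground_truth$species[[el]]
  p <- tempfile(fileext = ".xml")
  model_to_sbml(m, p)
  back <- read_sbml_model(p)
  expect_identical(names(back$species), names(m$species))
  expect_identical(lapply(back$reactions, `[[`, "participants"),
                   lapply(m$reactions, `[[`, "participants"))
  expect_identical(lapply(back$species, `[[`, "annotations"),
                   lapply(m$species, `[[`, "annotations"))
  expect_identical(lapply(back$species, `[[`, "display_name"),
                   lapply(m$species, `[[`, "display_name"))
})

test_that("URI parsing inverts URI writing for database identifiers", {
  fx <- demo_fixture()
  ids <- c(names(fx$db$species), names(fx$db$reactions), "KEGG:R00086", "EC:2.7.2.1")
  for (id in ids) {
    expect_identical(sbmlannot:::parse_annotation_uri(sbmlannot:::annotation_uri(id)), id)
  }
})
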