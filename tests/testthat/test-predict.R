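test_that("element filters gate on normalized name length and participant count", {
  expect_false(filter_species("S1", 3L))
  expect_true(filter_species("atp", 3L))
  expect_false(filter_species("", 1L))
  expect_true(filter_species("D-(+)x", 2L))  # normalized "dx"

  expect_false(filter_reaction(2L, 3L))
  expect_true(filter_reaction(3L, 3L))
  expect_true(filter_reaction(0L, 0L))
})

test_that("MSSC selection: tie inclusion under top, threshold under above", {
  ids <- c("A", "B", "C"); sc <- c(0.9, 0.9, 0.5)
  expect_setequal(select_candidates(ids, sc, "top", 0.8)$annotation_id, c("A", "B"))
  expect_setequal(select_candidates(ids, sc, "above", 0.4)$annotation_id,
                  c("A", "B", "C"))
  expect_identical(nrow(select_candidates("A", 0.9, "top", 0.95)), 0L)
  # inclusive comparison: an exact match survives cutoff 1
  expect_identical(select_candidates("A", 1.0, "top", 1.0)$annotation_id, "A")
  # order independence and lexicographic tie order
  out <- select_candidates(rev(ids), rev(sc), "top", 0)
  expect_identical(out$annotation_id, c("A", "B"))
})

test_that("MSSC selection agrees with a brute-force subset selector", {
  set.seed(23)
  for (i in 1:200) {
    n <- sample(1:6, 1)
    ids <- paste0("T", sample(100:999, n))
    scores <- round(runif(n), 2)
    cutoff <- sample(c(0, 0.25, 0.5, 0.9, 1), 1)
    for (mssc in c("top", "above")) {
      got <- sort(select_candidates(ids, scores, mssc, cutoff)$annotation_id)
      expect_identical(got, oracle_select(ids, scores, mssc, cutoff))
    }
  }
})

test_that("species prediction recovers ground truth on a noiseless corpus", {
  cfg <- synth_config(n_species_terms = 30L, n_reactions = 10L, seed = 21)
  db <- generate_reference_db(cfg)
  gm <- generate_model(db, cfg)
  preds <- predict_species_annotations(gm$model, db,
                                       prediction_params(mssc = "top", cutoff = 0.99))
  for (el in names(gm$ground_truth$species)) {
    expect_true(gm$ground_truth$species[[el]] %in% preds[[el]]$candidates$annotation_id)
  }
})

test_that("uninformative names are filtered; empty models yield empty maps", {
  fx <- demo_fixture()
  m <- model_view("short", list(list(element_id = "S1", display_name = "S1"),
                                list(element_id = "S2", display_name = "S2")))
  preds <- predict_species_annotations(m, fx$db, prediction_params(min_len = 3L))
  expect_true(all(vapply(preds, function(p) nrow(p$candidates) == 0L, logical(1))))
  expect_true(all(vapply(preds, `[[`, logical(1), "filtered")))

  empty <- model_view("empty")
  expect_length(predict_species_annotations(empty, fx$db, prediction_params()), 0L)
})

test_that("display name is preferred; element id is the fallback", {
  fx <- demo_fixture()
  m <- model_view("fallback", list(
    list(element_id = "glucose"),                       # no display name
    list(element_id = "X1", display_name = "  "),       # blank -> fallback to id, filtered
    list(element_id = "X2", display_name = "water")))
  preds <- predict_species_annotations(m, fx$db, prediction_params(cutoff = 0.9))
  expect_identical(preds[["glucose"]]$candidates$annotation_id[1], "CHEBI:17634")
  expect_identical(nrow(preds[["X1"]]$candidates), 0L)
  expect_identical(preds[["X2"]]$candidates$annotation_id[1], "CHEBI:15377")
})

test_that("reaction prediction reproduces the worked example through the pipeline", {
  fx <- demo_fixture()
  sp <- predict_species_annotations(fx$model, fx$db, prediction_params())
  above <- predict_reaction_annotations(fx$model, fx$db, sp,
                                        prediction_params(mssc = "above", cutoff = 0.3))
  hit <- above[["R_hyd"]]$candidates
  expect_true("RHEA:13065" %in% hit$annotation_id)
  expect_equal(hit$score[hit$annotation_id == "RHEA:13065"], 0.4)

  higher <- predict_reaction_annotations(fx$model, fx$db, sp,
                                         prediction_params(mssc = "above", cutoff = 0.5))
  expect_false("RHEA:13065" %in% higher[["R_hyd"]]$candidates$annotation_id)

  # participants without species predictions -> empty set
  none <- lapply(sp, function(p) { p$candidates <- p$candidates[0, ]; p })
  rx <- predict_reaction_annotations(fx$model, fx$db, none, prediction_params())
  expect_true(all(vapply(rx, function(p) nrow(p$candidates) == 0L, logical(1))))
})

test_that("top is a subset of above, and prediction sets shrink as the cutoff rises", {
  cfg <- synth_config(n_species_terms = 25L, n_reactions = 10L,
                      name_noise_rate = 0.2, seed = 31)
  db <- generate_reference_db(cfg)
  gm <- generate_model(db, cfg)
  cutoffs <- seq(0, 1, by = 0.25)
  # species predictions feeding reaction query vectors are held fixed so the
  # cutoff sweep varies only the selection threshold
  sp_base <- predict_species_annotations(gm$model, db, prediction_params("top", 0))
  prev_sp <- NULL; prev_rx <- NULL
  for (cut in cutoffs) {
    top_sp <- predict_species_annotations(gm$model, db,
                                          prediction_params("top", cut))
    abv_sp <- predict_species_annotations(gm$model, db,
                                          prediction_params("above", cut))
    for (el in names(top_sp)) {
      expect_true(all(top_sp[[el]]$candidates$annotation_id %in%
                        abv_sp[[el]]$candidates$annotation_id))
    }
    rx <- predict_reaction_annotations(gm$model, db, sp_base,
                                       prediction_params("top", cut))
    if (!is.null(prev_sp)) {
      for (el in names(top_sp)) {
        expect_true(all(top_sp[[el]]$candidates$annotation_id %in% prev_sp[[el]]))
      }
      for (el in names(rx)) {
        expect_true(all(rx[[el]]$candidates$annotation_id %in% prev_rx[[el]]))
      }
    }
    prev_sp <- lapply(top_sp, function(p) p$candidates$annotation_id)
    prev_rx <- lapply(rx, function(p) p$candidates$annotation_id)
  }
})

test_that("prediction is deterministic across repeated runs", {
  fx <- demo_fixture()
  p <- prediction_params("above", 0.2)
  a <- predict_species_annotations(fx$model, fx$db, p)
  b <- predict_species_annotations(fx$model, fx$db, p)
  expect_identical(a, b)
  ra <- predict_reaction_annotations(fx$model, fx$db, a, p)
  rb <- predict_reaction_annotations(fx$model, fx$db, b, p)
  expect_identical(ra, rb)
})

test_that("the recommendation report has the documented schema", {
  fx <- demo_fixture()
  sp <- predict_species_annotations(fx$model, fx$db, prediction_params())
  rx <- predict_reaction_annotations(fx$model, fx$db, sp, prediction_params())
  path <- tempfile(fileext = ".tsv")
  rep <- recommendation_report(fx$model, sp, rx, path = path)
  expect_identical(names(rep), c("element_id", "element_type", "annotation_id",
                                 "match_score", "selected_by", "existing_annotation"))
  expect_true(all(grepl("^\\d\\.\\d{6}$", rep$match_score)))
  expect_identical(rep$existing_annotation[rep$element_id == "S_atp"][1], "yes")
  expect_identical(rep$existing_annotation[rep$element_id == "M_ac_c"][1], "no")
  back <- read.delim(path, stringsAsFactors = FALSE)
  expect_identical(nrow(back), nrow(rep))
})
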