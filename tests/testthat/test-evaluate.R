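test_that("element metrics: nonempty, accuracy = min(1,|P&E|), exactness = 1/|P|", {
  e <- evaluate_element("a", "a")
  expect_identical(e$nonempty, 1L); expect_equal(e$accuracy, 1); expect_equal(e$exactness, 1)

  e2 <- evaluate_element(c("a", "b", "c"), c("c", "d"))
  expect_equal(e2$accuracy, 1)
  expect_equal(e2$exactness, 1 / 3)

  e3 <- evaluate_element(character(0), "a")
  expect_identical(e3$nonempty, 0L)
  expect_true(is.na(e3$accuracy)); expect_true(is.na(e3$exactness))

  expect_error(evaluate_element("a", character(0)))
})

test_that("element metrics match brute-force set computation on random pairs", {
  set.seed(77)
  universe <- paste0("CHEBI:", 1:30)
  for (i in 1:1000) {
    P <- sample(universe, sample(0:6, 1))
    E <- sample(universe, sample(1:4, 1))
    got <- evaluate_element(P, E)
    inter <- 0L
    for (p in unique(P)) for (q in unique(E)) if (p == q) inter <- inter + 1L
    if (length(P) == 0) {
      expect_identical(got$nonempty, 0L)
    } else {
      expect_equal(got$accuracy, min(1, inter))
      expect_equal(got$exactness, 1 / length(unique(P)))
      expect_identical(got$exactness == 1, length(unique(P)) == 1L)
      expect_true(got$accuracy %in% c(0, 1))
      expect_true(got$exactness > 0 && got$exactness <= 1)
    }
  }
})

test_that("summaries use the stated denominators and are permutation-invariant", {
  evals <- list(evaluate_element(character(0), "a"),
                evaluate_element("a", "a"))
  s <- summarize_evaluations(evals)
  expect_equal(s$mean_nonempty, 0.5)
  expect_equal(s$mean_accuracy, 1)
  expect_identical(s$n_elements, 2L); expect_identical(s$n_nonempty, 1L)

  all_empty <- summarize_evaluations(list(evaluate_element(character(0), "a")))
  expect_equal(all_empty$mean_nonempty, 0)
  expect_true(is.na(all_empty$mean_accuracy))

  one <- summarize_evaluations(list(evaluate_element("a", "a")))
  expect_equal(one$mean_nonempty, 1); expect_equal(one$mean_accuracy, 1)
  expect_equal(one$mean_exactness, 1)

  set.seed(9)
  evals <- lapply(1:20, function(i)
    evaluate_element(sample(letters, sample(0:3, 1)), sample(letters, 2)))
  expect_identical(summarize_evaluations(evals),
                   summarize_evaluations(rev(evals)))

  expect_identical(summarize_evaluations(list())$n_elements, 0L)
})

test_that("cutoff sweeps: perfect recovery on noiseless corpora, monotone nonempty", {
  cfg <- synth_config(n_species_terms = 25L, n_reactions = 10L, seed = 4)
  db <- generate_reference_db(cfg)
  gm <- generate_model(db, cfg)
  tab <- sweep_metrics(gm$model, db, gm$ground_truth, cutoffs = c(0, 0.5, 1.0))
  expect_true(all(tab$mean_accuracy == 1))
  for (ty in unique(tab$element_type)) {
    ne <- tab$mean_nonempty[tab$element_type == ty][order(tab$cutoff[tab$element_type == ty])]
    expect_true(all(diff(ne) <= 0))
  }
  # empty corpus -> empty table
  expect_identical(nrow(sweep_metrics(list(), db, list(), cutoffs = c(0, 1))), 0L)
})

test_that("nonempty declines with cutoff on a noisy corpus", {
  cfg <- synth_config(n_species_terms = 25L, n_reactions = 10L,
                      name_noise_rate = 0.3, seed = 6)
  db <- generate_reference_db(cfg)
  gm <- generate_model(db, cfg)
  tab <- sweep_metrics(gm$model, db, gm$ground_truth, cutoffs = seq(0, 1, 0.25))
  sp <- tab[tab$element_type == "species", ]
  sp <- sp[order(sp$cutoff), ]
  expect_true(all(diff(sp$mean_nonempty) <= 0))
  expect_lt(sp$mean_nonempty[nrow(sp)], sp$mean_nonempty[1])
})

test_that("strip_annotations extracts ground truth and maps foreign reaction ids", {
  fx <- demo_fixture()
  out <- strip_annotations(fx$model, fx$db, fx$crossref)
  expect_identical(out$ground_truth$species[["S_atp"]], "CHEBI:30616")
  expect_identical(out$ground_truth$species[["S_adp"]], "CHEBI:456216")
  # KEGG annotation mapped through the cross-reference map
  expect_identical(out$ground_truth$reactions[["R_hyd"]], "RHEA:13065")
  expect_identical(out$ground_truth$reactions[["R_ACKr"]], "RHEA:11352")
  # annotations removed from the returned model
  anns <- unlist(lapply(c(out$model$species, out$model$reactions), `[[`, "annotations"))
  expect_length(anns, 0L)

  # unmappable foreign annotation -> element excluded with a warning
  m <- fx$model
  m$reactions[["R_hyd"]]$annotations <- "EC:9.9.9.9"
  expect_warning(out2 <- strip_annotations(m, fx$db, fx$crossref), "R_hyd")
  expect_false("R_hyd" %in% names(out2$ground_truth$reactions))

  # stripped model + recovered truth close the evaluation loop
  sp <- predict_species_annotations(out$model, fx$db, prediction_params("top", 0.9))
  evals <- lapply(names(out$ground_truth$species), function(el)
    evaluate_element(sp[[el]]$candidates$annotation_id, out$ground_truth$species[[el]]))
  expect_equal(summarize_evaluations(evals)$mean_accuracy, 1)
})
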