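# small hand-built corpus: a transcription-factor product that only this
# model produces, plus an upstream species shared with a second model
hox_corpus <- function(tf_seen_elsewhere = FALSE) {
  uri <- function(id) paste0("https://identifiers.org/uniprot/", id)
  m1 <- pathway_model(
    "model-tf",
    species = list(
      species_node("a1", annotation_uris = uri("Q00001")),
      species_node("tf1", display_name = "HOXD4", annotation_uris = uri("P09016"))
    ),
    reactions = list(reaction_node(
      "r1", reactants = list(participant_ref("a1", "reactant")),
      products = list(participant_ref("tf1", "product"))
    ))
  )
  mods <- if (tf_seen_elsewhere) {
    list(participant_ref("m2x", "modifier"))
  } else list()
  sp2 <- list(
    species_node("a2", annotation_uris = uri("Q00001")),
    species_node("b2", annotation_uris = uri("Q00002"))
  )
  if (tf_seen_elsewhere) {
    sp2 <- c(sp2, list(species_node("m2x", annotation_uris = uri("P09016"))))
  }
  # b2 feeds a2 so neither is product-only with a corpus-unique identifier
  # (a2 shares Q00001 with the first model)
  m2 <- pathway_model(
    "model-other",
    species = sp2,
    reactions = list(reaction_node(
      "r2", reactants = list(participant_ref("b2", "reactant")),
      products = list(participant_ref("a2", "product")),
      modifiers = mods
    ))
  )
  list(m1, m2)
}

test_that("the corpus index keys shared identifiers to all their models", {
  idx <- build_corpus_index(hox_corpus())
  expect_setequal(models_for_species(idx, "Q00001"), c("model-other", "model-tf"))
  expect_equal(models_for_species(idx, "q00001"),
               models_for_species(idx, "Q00001"))
  expect_length(models_for_species(idx, "NOPE"), 0L)
})

test_that("species without annotations contribute nothing to the index", {
  ms <- hox_corpus()
  ms[[1]]$species$bare <- species_node("bare")
  idx <- build_corpus_index(ms)
  expect_length(idx$identifiers, 3L)  # Q00001, P09016, Q00002; nothing for bare
  expect_equal(attr(idx, "unannotated"), 1L)
})

test_that("an HGNC table adds gene symbols as index keys", {
  idx <- build_corpus_index(hox_corpus(), hgnc = load_hgnc(toy_hgnc_csv))
  expect_equal(models_for_species(idx, "HOXD4"), "model-tf")
})

test_that("overlap statistics follow set arithmetic", {
  chain_model <- function(id, ids) {
    n <- length(ids)
    pathway_model(
      id,
      species = lapply(seq_len(n), function(i) {
        species_node(paste0(id, "_s", i),
                     annotation_uris = paste0("https://identifiers.org/uniprot/", ids[i]))
      }),
      reactions = lapply(seq_len(n - 1L), function(i) {
        reaction_node(paste0(id, "_r", i),
          reactants = list(participant_ref(paste0(id, "_s", i), "reactant")),
          products = list(participant_ref(paste0(id, "_s", i + 1L), "product")))
      })
    )
  }
  ma <- chain_model("ma", paste0("I", 1:6))
  mb <- chain_model("mb", paste0("I", 5:10))
  idx <- build_corpus_index(list(ma, mb))
  ov <- species_overlap(idx, "ma", "mb")
  expect_setequal(ov$shared_identifiers, c("I5", "I6"))
  expect_equal(ov$jaccard, 2 / 10)
  # symmetry and self-identity
  expect_equal(species_overlap(idx, "mb", "ma")$jaccard, ov$jaccard)
  expect_equal(species_overlap(idx, "ma", "ma")$jaccard, 1)
  expect_error(species_overlap(idx, "ma", "nope"), "unknown model")
})

test_that("disjoint models have zero overlap", {
  idx <- build_corpus_index(hox_corpus())
  ms <- idx$models
  # rebuild second model with disjoint ids
  m3 <- pathway_model(
    "model-disjoint",
    species = list(
      species_node("x", annotation_uris = "https://identifiers.org/uniprot/Z00001"),
      species_node("y", annotation_uris = "https://identifiers.org/uniprot/Z00002")
    ),
    reactions = list(reaction_node("r",
      reactants = list(participant_ref("x", "reactant")),
      products = list(participant_ref("y", "product"))))
  )
  idx <- build_corpus_index(c(unname(ms), list(m3)))
  expect_equal(species_overlap(idx, "model-tf", "model-disjoint")$jaccard, 0)
})

test_that("a product-only species unseen elsewhere is reported as a gap", {
  gaps <- find_gap_species(build_corpus_index(hox_corpus()))
  expect_equal(nrow(gaps), 1L)
  expect_equal(gaps$model_id, "model-tf")
  expect_equal(gaps$species_id, "tf1")
  expect_equal(gaps$identifiers[[1]], "P09016")
  expect_equal(gaps$reason, "product-only, no external appearances")
})

test_that("a modifier appearance in another model disqualifies the gap", {
  gaps <- find_gap_species(build_corpus_index(hox_corpus(tf_seen_elsewhere = TRUE)))
  expect_false("tf1" %in% gaps$species_id)
})

test_that("planted gaps in the synthetic corpus are recovered exactly", {
  corpus <- simulate_sbml_corpus(n_models = 5L, species_per_model = 13L,
                                 n_gap_models = 3L, seed = 9L)
  idx <- build_corpus_index(corpus$models)
  gaps <- find_gap_species(idx)
  want <- do.call(rbind, lapply(corpus$manifest$gaps, as.data.frame))
  expect_equal(nrow(gaps), nrow(want))
  expect_setequal(paste(gaps$model_id, gaps$species_id),
                  paste(want$model_id, want$species_id))

  # soundness: every report re-verified against the raw models by an
  # independent brute-force scan, and no qualifying pair is missed
  brute <- list()
  all_ids_by_model <- lapply(corpus$models, function(m) {
    toupper(extract_link_id(unlist(lapply(m$species, `[[`, "annotation_uris"),
                                   use.names = FALSE)))
  })
  for (mid in names(corpus$models)) {
    m <- corpus$models[[mid]]
    consumed <- character(); produced <- character()
    for (r in m$reactions) {
      for (p in r$reactants) consumed <- c(consumed, p$species_id)
      for (p in r$modifiers) consumed <- c(consumed, p$species_id)
      for (p in r$products) produced <- c(produced, p$species_id)
    }
    for (sp in names(m$species)) {
      if (!(sp %in% produced) || sp %in% consumed) next
      ids <- toupper(extract_link_id(m$species[[sp]]$annotation_uris))
      if (!length(ids)) next
      seen_elsewhere <- any(vapply(setdiff(names(corpus$models), mid),
                                   function(o) any(ids %in% all_ids_by_model[[o]]),
                                   logical(1)))
      if (!seen_elsewhere) brute[[length(brute) + 1L]] <- paste(mid, sp)
    }
  }
  expect_setequal(paste(gaps$model_id, gaps$species_id), unlist(brute))
})

test_that("gap reports serialize to JSON with stable keys", {
  gaps <- find_gap_species(build_corpus_index(hox_corpus()))
  path <- tempfile(fileext = ".json")
  write_gap_report(gaps, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(names(parsed), c("gaps", "unannotated_species"))
  expect_equal(parsed$gaps[[1]]$species_id, "tf1")
})
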