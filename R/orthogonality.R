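#' Index a model corpus by extracted species identifiers
#'
#' Species identity across Reactome-style models cannot rely on species ids
#' (they are model-scoped), so the corpus index keys on identifiers
#' harvested from annotation URIs via [extract_link_id()], optionally
#' augmented with gene symbols resolved through an HGNC table (UniProt or
#' Ensembl hits). Identifier matching is case-normalized (upper case).
#' Species without any annotation URI contribute nothing to cross-model
#' claims; their count is recorded in attribute `"unannotated"`.
#'
#' @param models List of [pathway_model()] objects with unique model ids.
#' @param hgnc Optional `"hgnc_table"` from [load_hgnc()] used to add gene
#'   symbols for resolvable protein/gene identifiers.
#' @return An object of class `"corpus_index"`: a list with `identifiers`
#'   (named list identifier -> character vector of model ids), `models`
#'   (named list of models) and `species_ids` (per model per species, the
#'   extracted identifiers).
#' @export
build_corpus_index <- function(models, hgnc = NULL) {
  stopifnot(length(models) >= 1L)
  model_ids <- vapply(models, `[[`, character(1), "model_id")
  if (anyDuplicated(model_ids)) stop("duplicate model ids in corpus", call. = FALSE)
  names(models) <- model_ids

  unannotated <- 0L
  species_ids <- lapply(models, function(m) {
    per_species <- lapply(m$species, function(s) {
      if (!length(s$annotation_uris)) return(character())
      ids <- extract_link_id(s$annotation_uris)
      if (!is.null(hgnc)) {
        syms <- unlist(lapply(ids, function(i) {
          c(map_identifier(hgnc, i, "uniprot", "symbol"),
            map_identifier(hgnc, i, "ensembl", "symbol"))
        }), use.names = FALSE)
        ids <- c(ids, syms)
      }
      unique(toupper(ids))
    })
    unannotated <<- unannotated + sum(lengths(per_species) == 0L)
    per_species
  })

  identifiers <- list()
  for (mid in model_ids) {
    ids <- unique(unlist(species_ids[[mid]], use.names = FALSE))
    for (i in ids) identifiers[[i]] <- c(identifiers[[i]], mid)
  }
  structure(
    list(identifiers = identifiers, models = models, species_ids = species_ids),
    unannotated = unannotated,
    class = "corpus_index"
  )
}

#' @export
print.corpus_index <- function(x, ...) {
  cat("<corpus_index> ", length(x$models), " model(s), ",
      length(x$identifiers), " distinct identifier(s)\n", sep = "")
  invisible(x)
}

#' Models containing a species identifier
#'
#' @param index A `"corpus_index"`.
#' @param identifier UniProt accession, Ensembl id or gene symbol; matching
#'   is exact after case normalization.
#' @return Sorted character vector of model ids (empty when absent).
#' @export
models_for_species <- function(index, identifier) {
  stopifnot(inherits(index, "corpus_index"))
  hit <- index$identifiers[[toupper(identifier)]]
  if (is.null(hit)) character() else sort(unique(hit))
}

#' Species overlap between two models
#'
#' Models in a pathway corpus are biochemical network fragments; overlap in
#' their species identifier sets is the basis for associating them.
#'
#' @param index A `"corpus_index"`.
#' @param model_a,model_b Model ids present in the index.
#' @return List with `shared_identifiers` (sorted) and `jaccard`
#'   (`|intersection| / |union|`; 0 when both sets are empty).
#' @export
species_overlap <- function(index, model_a, model_b) {
  stopifnot(inherits(index, "corpus_index"))
  for (m in c(model_a, model_b)) {
    if (!m %in% names(index$models)) {
      stop("unknown model id '", m, "'", call. = FALSE)
    }
  }
  ids_a <- unique(unlist(index$species_ids[[model_a]], use.names = FALSE))
  ids_b <- unique(unlist(index$species_ids[[model_b]], use.names = FALSE))
  shared <- sort(intersect(ids_a, ids_b))
  un <- union(ids_a, ids_b)
  list(
    shared_identifiers = shared,
    jaccard = if (!length(un)) 0 else length(shared) / length(un)
  )
}

#' Detect candidate knowledge-gap species across a corpus
#'
#' A gap species is produced by its model but never consumed or modified
#' there (a system output per [species_roles()]), and none of its extracted
#' identifiers appear in any other model of the corpus: the downstream
#' actions of the species are absent from the corpus. Modifier appearances
#' elsewhere disqualify a gap, since a regulatory role is exactly the kind
#' of "vital action" the flag is after. Species without identifiers are
#' excluded from reports (no cross-model claim is possible); their count is
#' carried in attribute `"unannotated"`.
#'
#' @param index A `"corpus_index"`.
#' @return A data frame with columns `model_id`, `species_id`,
#'   `identifiers` (list column) and `reason` (fixed string
#'   `"product-only, no external appearances"`).
#' @export
find_gap_species <- function(index) {
  stopifnot(inherits(index, "corpus_index"))
  rows <- list()
  for (mid in names(index$models)) {
    roles <- species_roles(index$models[[mid]])
    outputs <- roles$species_id[roles$role == "output"]
    for (sp in outputs) {
      ids <- index$species_ids[[mid]][[sp]]
      if (!length(ids)) next
      elsewhere <- unlist(lapply(ids, function(i) {
        setdiff(index$identifiers[[i]], mid)
      }), use.names = FALSE)
      if (!length(elsewhere)) {
        rows[[length(rows) + 1L]] <- list(model_id = mid, species_id = sp,
                                          identifiers = ids)
      }
    }
  }
  out <- data.frame(
    model_id = vapply(rows, `[[`, character(1), "model_id"),
    species_id = vapply(rows, `[[`, character(1), "species_id"),
    reason = rep("product-only, no external appearances", length(rows)),
    stringsAsFactors = FALSE
  )
  out$identifiers <- lapply(rows, `[[`, "identifiers")
  attr(out, "unannotated") <- attr(index, "unannotated")
  out
}

#' Write a gap report as JSON
#'
#' Stable key order (model_id, species_id, identifiers, reason) so reports
#' are diffable.
#'
#' @param gaps Data frame from [find_gap_species()].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_gap_report <- function(gaps, file) {
  entries <- lapply(seq_len(nrow(gaps)), function(i) {
    list(model_id = gaps$model_id[i], species_id = gaps$species_id[i],
         identifiers = as.list(gaps$identifiers[[i]]), reason = gaps$reason[i])
  })
  payload <- list(gaps = entries,
                  unannotated_species = as.integer(attr(gaps, "unannotated") %||% 0L))
  jsonlite::write_json(payload, file, auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
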