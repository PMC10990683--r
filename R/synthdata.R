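#' Simulate an HPA-style expression table with planted lineage markers
#'
#' Generates long-format nTPM records emulating the structure of
#' single-cell tissue expression exports: lineages (tissue + cell type)
#' with several phenotypic clusters each, and a hierarchical expression
#' model. Each gene has a log-normal baseline; every cell type modulates
#' every gene by a shared log-normal effect (`celltype_sdlog`), every
#' lineage adds its own private effect (`lineage_sdlog`) -- real cell
#' lineages differ genome-wide, and cell type explains more of that
#' variance than tissue of origin, so lineages of the same cell type sit
#' close together (e.g. smooth muscle across tissues), the behaviour the
#' classifier is expected to expose. On top of that, planted marker genes
#' are expressed at `marker_multiplier` times their level inside the
#' marked lineage (private markers) or cell type (shared markers).
#' Cluster replicates add multiplicative log-normal noise of scale
#' `noise_sigma`.
#'
#' Everything is driven by one integer seed through an isolated RNG stream;
#' regeneration with the same parameters is deterministic (byte-identical
#' TSV), and the caller's RNG state is left untouched.
#'
#' @param n_lineages Number of lineages (default 8, laid out as
#'   `n_lineages / 2` tissues times 2 cell types when divisible, else one
#'   cell type per tissue).
#' @param n_clusters Cluster replicates per lineage (default 3).
#' @param n_genes Total genes (default 300).
#' @param markers_per_lineage Private marker genes per lineage (default 5).
#' @param markers_per_celltype Shared marker genes per cell type (default 5;
#'   0 disables the shared tier).
#' @param marker_multiplier Marker effect size as a fold change over
#'   baseline (default 8).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline nTPM
#'   parameters (defaults 1 and 1).
#' @param celltype_sdlog Log-scale sd of the genome-wide cell-type effect
#'   (default 0.4).
#' @param lineage_sdlog Log-scale sd of the genome-wide private lineage
#'   effect (default 0.3).
#' @param noise_sigma Multiplicative log-scale noise between cluster
#'   replicates (default 0.2).
#' @param seed Integer seed (default 0).
#' @return A list with `records` (data frame in [read_expression_table()]
#'   layout), `tsv` (the 7-column TSV text), and `manifest` (ground truth:
#'   per-lineage markers, per-cell-type markers, matrix of true lineage
#'   means, parameters, seed).
#' @export
simulate_expression_table <- function(n_lineages = 8L, n_clusters = 3L,
                                      n_genes = 300L,
                                      markers_per_lineage = 5L,
                                      markers_per_celltype = 5L,
                                      marker_multiplier = 8,
                                      baseline_meanlog = 1,
                                      baseline_sdlog = 1,
                                      celltype_sdlog = 0.4,
                                      lineage_sdlog = 0.3,
                                      noise_sigma = 0.2,
                                      seed = 0L) {
  if (n_lineages < 2L) stop("config error: need at least 2 lineages", call. = FALSE)
  n_markers <- n_lineages * markers_per_lineage
  tissues_ct <- .lineage_layout(n_lineages)
  n_ct_markers <- length(unique(tissues_ct$cell_type)) * markers_per_celltype
  if (n_genes < n_markers + n_ct_markers) {
    stop("config error: n_genes too small for the requested markers", call. = FALSE)
  }
  old <- .rng_save()
  on.exit(.rng_restore(old), add = TRUE)
  set.seed(seed)

  genes <- sprintf("GENE%04d", seq_len(n_genes))
  ensembl <- sprintf("ENSGS%010d", seq_len(n_genes))
  names(ensembl) <- genes

  # disjoint marker assignment: first the private tiers, then the shared
  pool <- genes
  lineage_markers <- list()
  for (i in seq_len(n_lineages)) {
    lineage_markers[[i]] <- pool[seq_len(markers_per_lineage)]
    pool <- pool[-seq_len(markers_per_lineage)]
  }
  cell_types <- unique(tissues_ct$cell_type)
  celltype_markers <- stats::setNames(vector("list", length(cell_types)), cell_types)
  for (ct in cell_types) {
    if (markers_per_celltype > 0L) {
      celltype_markers[[ct]] <- pool[seq_len(markers_per_celltype)]
      pool <- pool[-seq_len(markers_per_celltype)]
    } else celltype_markers[[ct]] <- character()
  }

  baseline <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
  names(baseline) <- genes

  keys <- lineage_key(tissues_ct$tissue, tissues_ct$cell_type)
  names(lineage_markers) <- keys
  ct_effect <- matrix(stats::rnorm(length(cell_types) * n_genes, 0, celltype_sdlog),
                      nrow = length(cell_types),
                      dimnames = list(cell_types, genes))
  lin_effect <- matrix(stats::rnorm(n_lineages * n_genes, 0, lineage_sdlog),
                       nrow = n_lineages, dimnames = list(keys, genes))
  true_means <- matrix(rep(baseline, each = n_lineages), nrow = n_lineages,
                       dimnames = list(keys, genes))
  true_means <- true_means * exp(ct_effect[tissues_ct$cell_type, , drop = FALSE]) *
    exp(lin_effect)
  for (i in seq_len(n_lineages)) {
    true_means[i, lineage_markers[[i]]] <- true_means[i, lineage_markers[[i]]] * marker_multiplier
    ctm <- celltype_markers[[tissues_ct$cell_type[i]]]
    if (length(ctm)) true_means[i, ctm] <- true_means[i, ctm] * marker_multiplier
  }

  rows <- vector("list", n_lineages * n_clusters)
  k <- 0L
  for (i in seq_len(n_lineages)) {
    for (cl in seq_len(n_clusters)) {
      noise <- if (noise_sigma > 0) exp(stats::rnorm(n_genes, 0, noise_sigma)) else rep(1, n_genes)
      vals <- round(true_means[i, ] * noise, 4)
      k <- k + 1L
      rows[[k]] <- data.frame(
        ensembl_id = unname(ensembl),
        gene_symbol = genes,
        tissue = tissues_ct$tissue[i],
        cluster = paste0("c-", cl),
        cell_type = tissues_ct$cell_type[i],
        read_count = round(vals * 50),
        ntpm = vals,
        stringsAsFactors = FALSE
      )
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL

  tsv <- paste(
    c(paste(c("Gene", "Gene.name", "Tissue", "Cluster", "Cell.type",
              "Read.count", "nTPM"), collapse = "\t"),
      paste(records$ensembl_id, records$gene_symbol, records$tissue,
            records$cluster, records$cell_type,
            vapply(records$read_count, .fmt_num, character(1)),
            vapply(records$ntpm, .fmt_num, character(1)),
            sep = "\t"),
      ""),
    collapse = "\n"
  )

  list(
    records = records,
    tsv = tsv,
    manifest = list(
      lineages = keys,
      lineage_markers = lineage_markers,
      celltype_markers = celltype_markers,
      true_means = true_means,
      params = list(n_lineages = n_lineages, n_clusters = n_clusters,
                    n_genes = n_genes,
                    markers_per_lineage = markers_per_lineage,
                    markers_per_celltype = markers_per_celltype,
                    marker_multiplier = marker_multiplier,
                    baseline_meanlog = baseline_meanlog,
                    baseline_sdlog = baseline_sdlog,
                    celltype_sdlog = celltype_sdlog,
                    lineage_sdlog = lineage_sdlog,
                    noise_sigma = noise_sigma),
      seed = seed
    )
  )
}

.lineage_layout <- function(n_lineages) {
  tissue_pool <- c("Adipose", "Heart", "Placenta", "Lung", "Liver", "Kidney",
                   "Spleen", "Colon", "Skin", "Brain", "Testis", "Tongue")
  ct_pool <- c("smooth muscle cells", "fibroblasts")
  if (n_lineages %% 2L == 0L) {
    n_t <- n_lineages %/% 2L
    tissues <- rep(tissue_pool[seq_len(n_t)], each = 2L)
    cts <- rep(ct_pool, n_t)
  } else {
    tissues <- tissue_pool[seq_len(n_lineages)]
    cts <- rep(ct_pool[1L], n_lineages)
  }
  if (anyNA(tissues)) {
    tissues[is.na(tissues)] <- sprintf("Tissue%02d", which(is.na(tissues)))
  }
  data.frame(tissue = tissues, cell_type = cts, stringsAsFactors = FALSE)
}

#' Simulate a Reactome-like SBML corpus with planted ground truth
#'
#' Builds `n_models` connected bipartite reaction networks with known
#' species roles: each model is a linear conversion chain with occasional
#' modifier attachments, so the chain head is a system input, the tail a
#' system output and every interior species a mediator. Species carry
#' identifiers.org-style annotation URIs ending in planted UniProt-like
#' accessions. Each consecutive model pair shares exactly `n_shared`
#' identifiers (model `i` donates `n_shared` freshly minted accessions
#' that model `i + 1` reuses). The first `n_gap_models` models carry one
#' planted gap species each: the chain tail, product-only, with a
#' corpus-unique identifier. Tails of the remaining models reuse an
#' identifier that also occurs in a neighbouring model, so they are
#' product-only but not gaps.
#'
#' @param n_models Number of models (default 6, minimum 2).
#' @param species_per_model Chain length per model (default 25; must be at
#'   least `2 * n_shared + 3`).
#' @param n_gap_models How many models carry a planted gap species
#'   (default 2).
#' @param n_shared Identifiers shared between consecutive model pairs
#'   (default 4, minimum 1).
#' @param seed Integer seed (default 0).
#' @return A list with `models` (named list of [pathway_model()]), `xml`
#'   (named character vector of SBML documents) and `manifest` (planted
#'   roles per model, gap species, shared-identifier map, seed).
#' @export
simulate_sbml_corpus <- function(n_models = 6L, species_per_model = 25L,
                                 n_gap_models = 2L, n_shared = 4L, seed = 0L) {
  if (n_models < 2L) stop("config error: need >= 2 models", call. = FALSE)
  if (n_shared < 1L) stop("config error: n_shared must be >= 1", call. = FALSE)
  if (species_per_model < 2L * n_shared + 3L) {
    stop("config error: species_per_model must be >= 2 * n_shared + 3", call. = FALSE)
  }
  if (n_gap_models > n_models) {
    stop("config error: more gap models than models", call. = FALSE)
  }
  old <- .rng_save()
  on.exit(.rng_restore(old), add = TRUE)
  set.seed(seed)

  next_uid <- 1L
  mint <- function() {
    id <- sprintf("Q%06d", next_uid)
    next_uid <<- next_uid + 1L
    id
  }

  n_sp <- species_per_model
  reuse_pos <- seq(2L, 1L + n_shared)            # reused from previous model
  donate_pos <- seq(2L + n_shared, 1L + 2L * n_shared)  # reused by next model

  models <- vector("list", n_models)
  roles_manifest <- list()
  gap_manifest <- list()
  donate_prev <- NULL

  for (mi in seq_len(n_models)) {
    model_id <- sprintf("R-SYN-%07d", mi)
    sp_ids <- sprintf("species_%d_%d", mi, seq_len(n_sp))
    is_gap_model <- mi <= n_gap_models

    ids <- vapply(seq_len(n_sp), function(si) mint(), character(1))
    if (mi > 1L) ids[reuse_pos] <- donate_prev
    if (!is_gap_model) {
      # tail must appear in another model: reuse an identifier donated to or
      # received from a neighbour
      ids[n_sp] <- if (mi > 1L) donate_prev[1L] else ids[donate_pos[1L]]
    }
    donate_prev <- ids[donate_pos]

    species <- lapply(seq_len(n_sp), function(si) {
      species_node(
        sp_ids[si],
        display_name = paste0("Protein ", ids[si]),
        compartment = "cytosol",
        sbo_term = if (si %% 5L == 0L) "SBO:0000297" else "SBO:0000252",
        annotation_uris = paste0("https://identifiers.org/uniprot/", ids[si]),
        initial_amount = 1
      )
    })

    reactions <- lapply(seq_len(n_sp - 1L), function(ri) {
      mods <- if (ri %% 4L == 0L && ri + 2L < n_sp) {
        list(participant_ref(sp_ids[ri + 2L], "modifier"))
      } else list()
      reaction_node(
        sprintf("reaction_%d_%d", mi, ri),
        display_name = sprintf("step %d", ri),
        reactants = list(participant_ref(sp_ids[ri], "reactant")),
        products = list(participant_ref(sp_ids[ri + 1L], "product")),
        modifiers = mods
      )
    })

    models[[mi]] <- pathway_model(
      model_id = model_id, model_name = sprintf("Synthetic pathway %d", mi),
      species = species, reactions = reactions, compartments = "cytosol"
    )

    # roles follow from the chain construction, independent of the analytics:
    # head consumed only, tail produced only, interior both (modifier use of
    # an interior species leaves it a mediator)
    roles_manifest[[model_id]] <- stats::setNames(
      c("input", rep("mediator", n_sp - 2L), "output"), sp_ids
    )
    if (is_gap_model) {
      gap_manifest[[length(gap_manifest) + 1L]] <- list(
        model_id = model_id, species_id = sp_ids[n_sp],
        identifier = toupper(ids[n_sp])
      )
    }
  }

  names(models) <- vapply(models, `[[`, character(1), "model_id")
  xml <- vapply(models, write_sbml, character(1))
  shared <- lapply(seq_len(n_models - 1L), function(i) {
    m <- models[[i + 1L]]
    reused <- toupper(extract_link_id(unlist(lapply(
      m$species[reuse_pos], `[[`, "annotation_uris"
    ), use.names = FALSE)))
    list(models = c(names(models)[i], names(models)[i + 1L]),
         identifiers = reused)
  })
  list(
    models = models,
    xml = xml,
    manifest = list(roles = roles_manifest, gaps = gap_manifest,
                    shared = shared, seed = seed)
  )
}

# save/restore the global RNG state so generators do not disturb callers
.rng_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

.rng_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
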