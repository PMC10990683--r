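# Shared in-code fixtures: toy networks, tiny tables, and independent
# oracles used to cross-check the package implementations.

# Chain of three reactions R1 -> R2 -> R3 linked through shared species:
# S1 -R1-> S2 -R2-> S3 -R3-> S4
toy_chain_model <- function() {
  pathway_model(
    model_id = "toy-chain",
    species = list(
      species_node("S1"), species_node("S2"),
      species_node("S3"), species_node("S4")
    ),
    reactions = list(
      reaction_node("R1", reactants = list(participant_ref("S1", "reactant")),
                    products = list(participant_ref("S2", "product"))),
      reaction_node("R2", reactants = list(participant_ref("S2", "reactant")),
                    products = list(participant_ref("S3", "product"))),
      reaction_node("R3", reactants = list(participant_ref("S3", "reactant")),
                    products = list(participant_ref("S4", "product")))
    )
  )
}

toy_hgnc_csv <- paste(
  "symbol,ensembl_gene_id,uniprot_ids,name,locus_type",
  "HOXD4,ENSG00000170166,P09016,homeobox D4,gene with protein product",
  "DEFA5,ENSG00000164816,Q01523,defensin alpha 5,gene with protein product",
  "NOENS,,A00001|A00002 A00003,multi uniprot example,gene with protein product",
  sep = "\n"
)

toy_pathway_index <- paste(
  "R-HSA-70171\tGlycolysis\tHomo sapiens",
  "R-MMU-70171\tGlycolysis\tMus musculus",
  "R-HSA-109582\tHemostasis\tHomo sapiens",
  sep = "\n"
)

# Table of six placenta rows; the two smooth-muscle rows carry distinct
# clusters of the same lineage.
placenta_records <- function() {
  data.frame(
    ensembl_id = "ENSG00000000003",
    gene_symbol = "TSPAN6",
    tissue = "Placenta",
    cluster = paste0("c-", 1:6),
    cell_type = c("smooth muscle cells", "t-cells", "smooth muscle cells",
                  "endothelial cells", "fibroblasts", "mixed immune cells"),
    read_count = 0,
    ntpm = c(62.3, 3.3, 19.3, 50.1, 44.9, 11.7),
    stringsAsFactors = FALSE
  )
}

defa5_records <- function() {
  data.frame(
    ensembl_id = "ENSG00000164816",
    gene_symbol = "DEFA5",
    tissue = "Small intestine",
    cluster = paste0("c-", 1:3),
    cell_type = "undifferentiated cells",
    read_count = 0,
    ntpm = c(882, 5116.4, 941045),
    stringsAsFactors = FALSE
  )
}

# Independent BFS oracle on the reaction-adjacency projection: plain
# frontier expansion over an explicitly materialized adjacency list.
oracle_reaction_distances <- function(model, focus) {
  parts <- netprofiler:::model_participants(model)
  rx <- vapply(model$reactions, `[[`, character(1), "reaction_id")
  sp_of <- split(parts$species_id, parts$reaction_id)
  adj <- lapply(rx, function(a) {
    rx[vapply(rx, function(b) {
      a != b && length(intersect(sp_of[[a]], sp_of[[b]])) > 0
    }, logical(1))]
  })
  names(adj) <- rx
  d <- stats::setNames(rep(Inf, length(rx)), rx)
  d[focus] <- 0
  queue <- focus
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in adj[[cur]]) {
      if (is.infinite(d[[nb]])) {
        d[nb] <- d[[cur]] + 1
        queue <- c(queue, nb)
      }
    }
  }
  d
}

# Brute-force pairwise distances, the double-loop oracle.
oracle_distances <- function(m, metric = "L1") {
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    diff <- m[i, ] - m[j, ]
    out[i, j] <- if (metric == "L1") sum(abs(diff)) else sqrt(sum(diff^2))
  }
  out
}

# Multiset of participant edges as sorted "src|role|dst" strings.
edge_multiset <- function(model) {
  parts <- netprofiler:::model_participants(model)
  sort(ifelse(parts$role == "product",
              paste(parts$reaction_id, parts$role, parts$species_id, sep = "|"),
              paste(parts$species_id, parts$role, parts$reaction_id, sep = "|")))
}
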