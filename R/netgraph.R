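#' Classify species by their systemic role
#'
#' Every species of a model is assigned exactly one role from its pattern of
#' participation: a system *input* is consumed (reactant or modifier) but
#' never produced, an *output* is produced but never consumed, a *mediator*
#' appears on both sides, and an *isolated* species is listed in the model
#' but referenced by no reaction.
#'
#' @param model A [pathway_model()].
#' @return A data frame with columns `species_id` and `role`
#'   (`input`/`output`/`mediator`/`isolated`), one row per species in model
#'   order.
#' @export
#' @examples
#' species_roles(toy_conversion_model())
species_roles <- function(model) {
  stopifnot(inherits(model, "pathway_model"))
  parts <- model_participants(model)
  consumed <- unique(parts$species_id[parts$role %in% c("reactant", "modifier")])
  produced <- unique(parts$species_id[parts$role == "product"])
  ids <- names(model$species)
  role <- ifelse(
    ids %in% consumed & ids %in% produced, "mediator",
    ifelse(ids %in% consumed, "input",
           ifelse(ids %in% produced, "output", "isolated"))
  )
  data.frame(species_id = ids, role = role, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Prune a model to the neighbourhood of a focus reaction
#'
#' Reaction distance is the BFS hop count on the reaction-adjacency
#' projection: two reactions are adjacent when they share at least one
#' participant species, in any role (modifiers included). The pruned model
#' keeps every reaction within `depth` hops of the focus, plus all
#' participant species of the retained reactions. `depth = 0` keeps the
#' focus reaction alone.
#'
#' @param model A [pathway_model()].
#' @param focus_reaction_id Reaction to centre on; must exist in the model.
#' @param depth Non-negative integer reaction distance.
#' @return A [pathway_model()] submodel.
#' @export
prune_subgraph <- function(model, focus_reaction_id, depth) {
  stopifnot(inherits(model, "pathway_model"), depth >= 0)
  rx_ids <- vapply(model$reactions, `[[`, character(1), "reaction_id")
  if (!focus_reaction_id %in% rx_ids) {
    stop("unknown focus reaction id '", focus_reaction_id, "'", call. = FALSE)
  }
  parts <- model_participants(model)
  sp_of <- split(parts$species_id, parts$reaction_id)

  dist <- stats::setNames(rep(Inf, length(rx_ids)), rx_ids)
  dist[focus_reaction_id] <- 0
  frontier <- focus_reaction_id
  d <- 0
  while (length(frontier) && d < depth) {
    frontier_species <- unique(unlist(sp_of[frontier], use.names = FALSE))
    nxt <- rx_ids[vapply(rx_ids, function(r) {
      is.infinite(dist[[r]]) && length(intersect(sp_of[[r]], frontier_species)) > 0
    }, logical(1))]
    dist[nxt] <- d + 1
    frontier <- nxt
    d <- d + 1
  }
  keep_rx <- rx_ids[is.finite(dist)]
  keep_reactions <- Filter(function(r) r$reaction_id %in% keep_rx, model$reactions)
  keep_sp <- unique(unlist(sp_of[keep_rx], use.names = FALSE))
  pathway_model(
    model_id = model$model_id,
    model_name = model$model_name,
    species = unname(model$species[names(model$species) %in% keep_sp]),
    reactions = keep_reactions,
    compartments = intersect(
      model$compartments,
      vapply(model$species[keep_sp], `[[`, character(1), "compartment")
    ),
    annotation_xml = model$annotation_xml
  )
}

# One style table keeps DOT output stable across the package.
.dot_style <- list(
  reaction = "shape=box, style=filled, fillcolor=orange",
  species = "shape=ellipse"
)

.dot_quote <- function(x) {
  paste0("\"", gsub("\"", "\\\\\"", gsub("\\\\", "\\\\\\\\", x)), "\"")
}

# Node labels use display names; duplicates are disambiguated with the id,
# since Reactome reuses display names across compartments.
.node_labels <- function(model) {
  ids <- names(model$species)
  labels <- vapply(model$species, `[[`, character(1), "display_name")
  dup <- labels %in% labels[duplicated(labels)]
  labels[dup] <- paste0(labels[dup], " [", ids[dup], "]")
  stats::setNames(labels, ids)
}

#' Export a model as a GraphViz DOT digraph
#'
#' One node per species (ellipse) and per reaction (orange filled box);
#' directed edges run species to reaction for reactants and modifiers, and
#' reaction to species for products, each labelled with its role.
#'
#' @param model A [pathway_model()].
#' @return DOT source as a single string.
#' @export
#' @examples
#' cat(to_dot(toy_conversion_model()))
to_dot <- function(model) {
  stopifnot(inherits(model, "pathway_model"))
  labels <- .node_labels(model)
  lines <- c("digraph pathway {", "  rankdir=LR;")
  for (id in names(model$species)) {
    lines <- c(lines, sprintf("  %s [label=%s, %s];", .dot_quote(id),
                              .dot_quote(labels[[id]]), .dot_style$species))
  }
  for (r in model$reactions) {
    lines <- c(lines, sprintf("  %s [label=%s, %s];", .dot_quote(r$reaction_id),
                              .dot_quote(r$display_name), .dot_style$reaction))
  }
  parts <- model_participants(model)
  for (i in seq_len(nrow(parts))) {
    p <- parts[i, ]
    edge <- if (p$role == "product") {
      sprintf("  %s -> %s [label=%s];", .dot_quote(p$reaction_id),
              .dot_quote(p$species_id), .dot_quote(p$role))
    } else {
      sprintf("  %s -> %s [label=%s];", .dot_quote(p$species_id),
              .dot_quote(p$reaction_id), .dot_quote(p$role))
    }
    lines <- c(lines, edge)
  }
  paste(c(lines, "}", ""), collapse = "\n")
}

#' Export a model in simple interaction format (SIF)
#'
#' One tab-separated line per participant edge, `source<TAB>relation<TAB>target`,
#' oriented as in [to_dot()]: reactants and modifiers point at the reaction,
#' the reaction points at its products. Names may contain spaces; fields are
#' tab-delimited.
#'
#' @param model A [pathway_model()].
#' @return SIF text as a single string (one line per participant).
#' @export
to_sif <- function(model) {
  stopifnot(inherits(model, "pathway_model"))
  parts <- model_participants(model)
  lines <- vapply(seq_len(nrow(parts)), function(i) {
    p <- parts[i, ]
    if (p$role == "product") {
      paste(p$reaction_id, p$role, p$species_id, sep = "\t")
    } else {
      paste(p$species_id, p$role, p$reaction_id, sep = "\t")
    }
  }, character(1))
  paste(c(lines, ""), collapse = "\n")
}
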