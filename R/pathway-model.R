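#' In-memory pathway network containers
#'
#' A `pathway_model` is the in-memory form of a Reactome-style SBML model: a
#' named list of species nodes and an ordered list of reaction nodes, each
#' reaction holding participant references (reactant / product / modifier)
#' that must resolve against the species map. These constructors validate the
#' structural invariants once, so downstream graph analytics can assume a
#' closed, well-formed bipartite network.
#'
#' @param species_id,reaction_id Unique identifier within the model.
#' @param display_name Human-readable name; falls back to the id when empty.
#' @param compartment Compartment identifier (may be `""`).
#' @param sbo_term Optional Systems Biology Ontology term, `"SBO:0000NNN"`.
#' @param annotation_uris Character vector of annotation URIs, order kept.
#' @param initial_amount Optional non-negative initial amount/concentration.
#' @return `species_node()` returns an object of class `"species_node"`.
#' @export
species_node <- function(species_id, display_name = species_id,
                         compartment = "", sbo_term = NA_character_,
                         annotation_uris = character(), initial_amount = NA_real_) {
  stopifnot(is.character(species_id), length(species_id) == 1L, nzchar(species_id))
  if (!is.na(sbo_term) && !grepl("^SBO:[0-9]{7}$", sbo_term)) {
    stop("invalid SBO term '", sbo_term, "': expected form SBO:0000NNN", call. = FALSE)
  }
  if (!is.na(initial_amount) && initial_amount < 0) {
    stop("initial_amount must be non-negative", call. = FALSE)
  }
  if (is.null(display_name) || is.na(display_name) || !nzchar(display_name)) {
    display_name <- species_id
  }
  structure(
    list(species_id = species_id, display_name = display_name,
         compartment = compartment, sbo_term = sbo_term,
         annotation_uris = as.character(annotation_uris),
         initial_amount = initial_amount),
    class = "species_node"
  )
}

#' @rdname species_node
#' @param role Participant role: `"reactant"`, `"product"` or `"modifier"`.
#' @param stoichiometry Positive stoichiometric coefficient (default 1;
#'   modifiers are always carried with stoichiometry 1).
#' @export
participant_ref <- function(species_id, role, stoichiometry = 1) {
  role <- match.arg(role, c("reactant", "product", "modifier"))
  if (role == "modifier") stoichiometry <- 1
  stopifnot(is.numeric(stoichiometry), stoichiometry > 0)
  structure(
    list(species_id = species_id, stoichiometry = as.numeric(stoichiometry),
         role = role),
    class = "participant_ref"
  )
}

#' @rdname species_node
#' @param reactants,products,modifiers Lists of `participant_ref` objects.
#' @param reversible Logical; defaults to `FALSE` as in Reactome exports that
#'   omit the attribute.
#' @param kinetic_law Optional `kinetic_law` object.
#' @export
reaction_node <- function(reaction_id, display_name = reaction_id,
                          reactants = list(), products = list(),
                          modifiers = list(), reversible = FALSE,
                          kinetic_law = NULL) {
  stopifnot(is.character(reaction_id), length(reaction_id) == 1L, nzchar(reaction_id))
  if (length(reactants) + length(products) + length(modifiers) < 1L) {
    stop("reaction '", reaction_id, "' has no participants", call. = FALSE)
  }
  if (is.null(display_name) || is.na(display_name) || !nzchar(display_name)) {
    display_name <- reaction_id
  }
  structure(
    list(reaction_id = reaction_id, display_name = display_name,
         reactants = reactants, products = products, modifiers = modifiers,
         reversible = isTRUE(reversible), kinetic_law = kinetic_law),
    class = "reaction_node"
  )
}

#' @rdname species_node
#' @param law_type One of `"mass_action"`, `"michaelis_menten"`, `"custom"`.
#' @param expression Infix rate expression referencing reaction species and
#'   declared parameters, e.g. `"k_f * A^2 * B"`.
#' @param parameters Named numeric vector/list of local parameters.
#' @export
kinetic_law <- function(law_type, expression, parameters = list()) {
  law_type <- match.arg(law_type, c("mass_action", "michaelis_menten", "custom"))
  stopifnot(is.character(expression), length(expression) == 1L, nzchar(expression))
  expression <- rate_expr_canonical(expression)
  parameters <- as.list(parameters)
  if (length(parameters) && is.null(names(parameters))) {
    stop("kinetic law parameters must be named", call. = FALSE)
  }
  structure(
    list(law_type = law_type, expression = expression,
         parameters = lapply(parameters, as.numeric)),
    class = "kinetic_law"
  )
}

#' @rdname species_node
#' @param model_id,model_name Model identifier and display name.
#' @param species List of `species_node` objects (names taken from ids).
#' @param reactions Ordered list of `reaction_node` objects.
#' @param compartments Character vector of compartment ids.
#' @param annotation_xml Opaque model-level `<annotation>` text preserved
#'   through read/write round trips, or `NA`.
#' @export
pathway_model <- function(model_id, model_name = model_id, species = list(),
                          reactions = list(), compartments = character(),
                          annotation_xml = NA_character_) {
  sp_ids <- vapply(species, function(s) s$species_id, character(1))
  if (anyDuplicated(sp_ids)) {
    stop("duplicate species id: ", sp_ids[duplicated(sp_ids)][1L], call. = FALSE)
  }
  names(species) <- sp_ids
  rx_ids <- vapply(reactions, function(r) r$reaction_id, character(1))
  if (anyDuplicated(rx_ids)) {
    stop("duplicate reaction id: ", rx_ids[duplicated(rx_ids)][1L], call. = FALSE)
  }
  m <- structure(
    list(model_id = model_id, model_name = model_name, species = species,
         reactions = reactions, compartments = compartments,
         annotation_xml = annotation_xml),
    class = "pathway_model"
  )
  dangling <- setdiff(model_participants(m)$species_id, sp_ids)
  if (length(dangling)) {
    stop("dangling species reference: ", paste(dangling, collapse = ", "),
         call. = FALSE)
  }
  m
}

# Flat participant table: one row per (reaction, species, role) occurrence.
model_participants <- function(model) {
  rows <- lapply(model$reactions, function(r) {
    ps <- c(r$reactants, r$products, r$modifiers)
    if (!length(ps)) return(NULL)
    data.frame(
      reaction_id = r$reaction_id,
      species_id = vapply(ps, `[[`, character(1), "species_id"),
      role = vapply(ps, `[[`, character(1), "role"),
      stoichiometry = vapply(ps, `[[`, numeric(1), "stoichiometry"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(reaction_id = character(), species_id = character(),
                      role = character(), stoichiometry = numeric(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' @export
print.pathway_model <- function(x, ...) {
  cat("<pathway_model> ", x$model_id,
      if (!identical(x$model_name, x$model_id)) paste0(" (", x$model_name, ")"),
      "\n", sep = "")
  cat("  species:   ", length(x$species), "\n", sep = "")
  cat("  reactions: ", length(x$reactions), "\n", sep = "")
  n_laws <- sum(vapply(x$reactions, function(r) !is.null(r$kinetic_law), logical(1)))
  if (n_laws) cat("  kinetic laws: ", n_laws, "\n", sep = "")
  invisible(x)
}

#' @export
print.species_node <- function(x, ...) {
  cat("<species_node> ", x$species_id, " '", x$display_name, "'",
      if (!is.na(x$sbo_term)) paste0(" [", x$sbo_term, "]"), "\n", sep = "")
  invisible(x)
}

#' @export
print.reaction_node <- function(x, ...) {
  cat("<reaction_node> ", x$reaction_id, ": ",
      length(x$reactants), " reactant(s) -> ", length(x$products),
      " product(s), ", length(x$modifiers), " modifier(s)",
      if (x$reversible) " (reversible)", "\n", sep = "")
  invisible(x)
}

# Equality on the network structure (ids, names, roles, stoichiometries, SBO
# terms, annotation URIs, kinetic laws); used by round-trip tests.
model_identical <- function(a, b) {
  strip <- function(m) {
    m$annotation_xml <- NULL
    m$species <- m$species[order(names(m$species))]
    m
  }
  identical(strip(a), strip(b))
}
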