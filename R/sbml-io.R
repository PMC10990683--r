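#' Read Reactome-dialect SBML into a pathway model
#'
#' Parses an SBML document (any level/version; element matching is
#' namespace-agnostic, so Reactome's level 2 and level 3 exports both load)
#' into a [pathway_model()]. Species annotation URIs are harvested from
#' `rdf:li` resource attributes in document order; `sboTerm` attributes are
#' kept verbatim; kinetic laws, when present, are decoded from their MathML
#' into an infix rate expression with local parameters.
#'
#' @param x SBML as a single string, a character vector of lines, or a path
#'   to an existing file.
#' @return A [pathway_model()].
#' @seealso [write_sbml()] for the inverse; round trips are identities on the
#'   network structure.
#' @export
#' @examples
#' m <- read_sbml(write_sbml(toy_conversion_model()))
#' length(m$species)
read_sbml <- function(x) {
  txt <- if (length(x) == 1L && !grepl("<", x, fixed = TRUE) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else {
    paste(x, collapse = "\n")
  }
  doc <- tryCatch(
    xml2::read_xml(txt),
    error = function(e) stop("SBML parse error: ", conditionMessage(e), call. = FALSE)
  )
  model <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (inherits(model, "xml_missing")) {
    stop("structural error: no <model> element found", call. = FALSE)
  }
  los <- xml2::xml_find_first(model, "./*[local-name()='listOfSpecies']")
  if (inherits(los, "xml_missing")) {
    stop("structural error: missing listOfSpecies block", call. = FALSE)
  }
  lor <- xml2::xml_find_first(model, "./*[local-name()='listOfReactions']")
  if (inherits(lor, "xml_missing")) {
    stop("structural error: missing listOfReactions block", call. = FALSE)
  }

  compartments <- xml2::xml_attr(
    xml2::xml_find_all(model, "./*[local-name()='listOfCompartments']/*[local-name()='compartment']"),
    "id"
  )

  species <- lapply(
    xml2::xml_find_all(los, "./*[local-name()='species']"),
    function(node) {
      amt <- xml2::xml_attr(node, "initialAmount")
      if (is.na(amt)) amt <- xml2::xml_attr(node, "initialConcentration")
      uris <- .sbml_resource_uris(node)
      species_node(
        species_id = xml2::xml_attr(node, "id"),
        display_name = xml2::xml_attr(node, "name"),
        compartment = .attr_or(node, "compartment", ""),
        sbo_term = xml2::xml_attr(node, "sboTerm"),
        annotation_uris = uris,
        initial_amount = if (is.na(amt)) NA_real_ else as.numeric(amt)
      )
    }
  )

  reactions <- lapply(
    xml2::xml_find_all(lor, "./*[local-name()='reaction']"),
    .sbml_parse_reaction
  )

  ann_node <- xml2::xml_find_first(model, "./*[local-name()='annotation']")
  ann <- if (inherits(ann_node, "xml_missing")) NA_character_ else as.character(ann_node)

  m <- tryCatch(
    pathway_model(
      model_id = .attr_or(model, "id", "model"),
      model_name = .attr_or(model, "name", .attr_or(model, "id", "model")),
      species = species, reactions = reactions,
      compartments = compartments, annotation_xml = ann
    ),
    error = function(e) stop("species reference resolution failed: ",
                             conditionMessage(e), call. = FALSE)
  )
  m
}

.attr_or <- function(node, attr, default) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v)) default else v
}

# rdf:resource attributes under any nested annotation, in document order;
# matched on the attribute local name to tolerate namespace prefix drift.
.sbml_resource_uris <- function(node) {
  lis <- xml2::xml_find_all(node, ".//*[local-name()='li']")
  uris <- vapply(lis, function(li) {
    at <- xml2::xml_attrs(li)
    hit <- grepl("(^|:)resource$", names(at))
    if (any(hit)) at[hit][[1]] else NA_character_
  }, character(1))
  uris[!is.na(uris)]
}

.sbml_parse_reaction <- function(node) {
  refs <- function(list_name, role) {
    el <- if (role == "modifier") "modifierSpeciesReference" else "speciesReference"
    nodes <- xml2::xml_find_all(
      node, sprintf("./*[local-name()='%s']/*[local-name()='%s']", list_name, el)
    )
    lapply(nodes, function(r) {
      st <- xml2::xml_attr(r, "stoichiometry")
      participant_ref(
        species_id = xml2::xml_attr(r, "species"),
        role = role,
        stoichiometry = if (is.na(st)) 1 else as.numeric(st)
      )
    })
  }
  kl_node <- xml2::xml_find_first(node, "./*[local-name()='kineticLaw']")
  kl <- if (inherits(kl_node, "xml_missing")) NULL else .sbml_parse_kinetic_law(kl_node)
  reaction_node(
    reaction_id = xml2::xml_attr(node, "id"),
    display_name = xml2::xml_attr(node, "name"),
    reactants = refs("listOfReactants", "reactant"),
    products = refs("listOfProducts", "product"),
    modifiers = refs("listOfModifiers", "modifier"),
    reversible = identical(xml2::xml_attr(node, "reversible"), "true"),
    kinetic_law = kl
  )
}

.sbml_law_sbo <- c(mass_action = "SBO:0000012", michaelis_menten = "SBO:0000028")

.sbml_parse_kinetic_law <- function(node) {
  sbo <- xml2::xml_attr(node, "sboTerm")
  law_type <- names(.sbml_law_sbo)[match(sbo, .sbml_law_sbo)]
  if (is.na(law_type)) law_type <- "custom"
  math <- xml2::xml_find_first(node, "./*[local-name()='math']")
  if (inherits(math, "xml_missing")) {
    stop("kineticLaw without math element", call. = FALSE)
  }
  pars <- xml2::xml_find_all(
    node,
    "./*[local-name()='listOfLocalParameters' or local-name()='listOfParameters']/*[local-name()='localParameter' or local-name()='parameter']"
  )
  params <- stats::setNames(
    lapply(pars, function(p) as.numeric(xml2::xml_attr(p, "value"))),
    vapply(pars, function(p) xml2::xml_attr(p, "id"), character(1))
  )
  kinetic_law(law_type, mathml_to_rate_expr(math), params)
}

#' Serialize a pathway model to SBML
#'
#' Emits an SBML Level 3 document. Kinetic laws are written as `kineticLaw`
#' blocks with a MathML rate expression, local parameters, and the standard
#' rate-law ontology term (`SBO:0000012` mass action, `SBO:0000028`
#' Michaelis-Menten) so the law type survives a round trip. A preserved
#' model-level annotation block is re-emitted verbatim.
#'
#' @param model A [pathway_model()].
#' @param file Optional path; when given the XML is also written there.
#' @return The SBML document as a single string (invisibly when `file` is
#'   given).
#' @export
write_sbml <- function(model, file = NULL) {
  stopifnot(inherits(model, "pathway_model"))
  if (!length(model$reactions)) {
    stop("cannot serialize a model with an empty reaction list", call. = FALSE)
  }
  dangling <- setdiff(model_participants(model)$species_id, names(model$species))
  if (length(dangling)) {
    stop("refusing to serialize: unresolved species reference ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }

  esc <- xml_escape
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" level=\"3\" version=\"1\">",
    sprintf("  <model id=\"%s\" name=\"%s\">", esc(model$model_id), esc(model$model_name))
  )
  if (!is.na(model$annotation_xml)) {
    out <- c(out, paste0("    ", model$annotation_xml))
  }

  comps <- unique(c(model$compartments,
                    Filter(nzchar, vapply(model$species, `[[`, character(1), "compartment"))))
  if (length(comps)) {
    out <- c(out, "    <listOfCompartments>",
             sprintf("      <compartment id=\"%s\" constant=\"true\"/>", esc(comps)),
             "    </listOfCompartments>")
  }

  out <- c(out, "    <listOfSpecies>")
  for (s in model$species) {
    attrs <- sprintf(" id=\"%s\" name=\"%s\"", esc(s$species_id), esc(s$display_name))
    if (nzchar(s$compartment)) attrs <- paste0(attrs, sprintf(" compartment=\"%s\"", esc(s$compartment)))
    if (!is.na(s$sbo_term)) attrs <- paste0(attrs, sprintf(" sboTerm=\"%s\"", s$sbo_term))
    if (!is.na(s$initial_amount)) {
      attrs <- paste0(attrs, sprintf(" initialAmount=\"%.17g\"", s$initial_amount))
    }
    attrs <- paste0(attrs, " hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\" constant=\"false\"")
    if (length(s$annotation_uris)) {
      out <- c(out,
        sprintf("      <species%s>", attrs),
        "        <annotation>",
        "          <rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\" xmlns:bqbiol=\"http://biomodels.net/biology-qualifiers/\">",
        sprintf("            <rdf:Description rdf:about=\"#%s\">", esc(s$species_id)),
        "              <bqbiol:is>",
        "                <rdf:Bag>",
        sprintf("                  <rdf:li rdf:resource=\"%s\"/>", esc(s$annotation_uris)),
        "                </rdf:Bag>",
        "              </bqbiol:is>",
        "            </rdf:Description>",
        "          </rdf:RDF>",
        "        </annotation>",
        "      </species>")
    } else {
      out <- c(out, sprintf("      <species%s/>", attrs))
    }
  }
  out <- c(out, "    </listOfSpecies>", "    <listOfReactions>")

  for (r in model$reactions) {
    out <- c(out, sprintf("      <reaction id=\"%s\" name=\"%s\" reversible=\"%s\" fast=\"false\">",
                          esc(r$reaction_id), esc(r$display_name),
                          if (r$reversible) "true" else "false"))
    wr_refs <- function(list_name, refs, el) {
      if (!length(refs)) return(character())
      c(sprintf("        <%s>", list_name),
        vapply(refs, function(p) {
          if (el == "speciesReference") {
            sprintf("          <speciesReference species=\"%s\" stoichiometry=\"%.17g\" constant=\"true\"/>",
                    esc(p$species_id), p$stoichiometry)
          } else {
            sprintf("          <modifierSpeciesReference species=\"%s\"/>", esc(p$species_id))
          }
        }, character(1)),
        sprintf("        </%s>", list_name))
    }
    out <- c(out,
             wr_refs("listOfReactants", r$reactants, "speciesReference"),
             wr_refs("listOfProducts", r$products, "speciesReference"),
             wr_refs("listOfModifiers", r$modifiers, "modifierSpeciesReference"))
    if (!is.null(r$kinetic_law)) {
      kl <- r$kinetic_law
      sbo_attr <- if (kl$law_type %in% names(.sbml_law_sbo)) {
        sprintf(" sboTerm=\"%s\"", .sbml_law_sbo[[kl$law_type]])
      } else ""
      out <- c(out,
        sprintf("        <kineticLaw%s>", sbo_attr),
        "          <math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
        rate_expr_to_mathml(kl$expression, indent = "            "),
        "          </math>")
      if (length(kl$parameters)) {
        out <- c(out, "          <listOfLocalParameters>",
          sprintf("            <localParameter id=\"%s\" value=\"%.17g\"/>",
                  esc(names(kl$parameters)), unlist(kl$parameters)),
          "          </listOfLocalParameters>")
      }
      out <- c(out, "        </kineticLaw>")
    }
    out <- c(out, "      </reaction>")
  }
  out <- c(out, "    </listOfReactions>", "  </model>", "</sbml>", "")
  xml <- paste(out, collapse = "\n")
  if (!is.null(file)) {
    writeLines(xml, file, useBytes = TRUE)
    return(invisible(xml))
  }
  xml
}

#' Minimal two-species conversion model
#'
#' The smallest valid network (`A -> B`), used throughout the examples and
#' tests as the canonical toy model.
#'
#' @param reversible Should the single reaction be flagged reversible?
#' @return A [pathway_model()].
#' @export
toy_conversion_model <- function(reversible = FALSE) {
  pathway_model(
    model_id = "toy-ab", model_name = "A to B conversion",
    species = list(
      species_node("A", "A", compartment = "cytosol", initial_amount = 1),
      species_node("B", "B", compartment = "cytosol", initial_amount = 0)
    ),
    reactions = list(
      reaction_node("R1", "A becomes B",
                    reactants = list(participant_ref("A", "reactant")),
                    products = list(participant_ref("B", "product")),
                    reversible = reversible)
    ),
    compartments = "cytosol"
  )
}
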