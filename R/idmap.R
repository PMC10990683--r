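#' Load an HGNC-format gene identifier table
#'
#' Reads the HGNC "complete set" CSV dialect (comma-separated, quoted
#' fields) into a lookup table connecting gene symbols, Ensembl gene ids and
#' UniProt accessions. The `uniprot_ids` cell may hold several accessions
#' separated by `|` or whitespace; both are split. Rows with a blank Ensembl
#' id stay reachable by symbol.
#'
#' @param x CSV text (single string or lines) or a path to a CSV file.
#' @return An object of class `"hgnc_table"`: a data frame with columns
#'   `symbol`, `ensembl_gene_id`, `uniprot_ids` (list column), `gene_name`,
#'   `locus_type`.
#' @export
load_hgnc <- function(x) {
  txt <- if (length(x) == 1L && !grepl("[,\n]", x) && file.exists(x)) x else textConnection(paste(x, collapse = "\n"))
  df <- utils::read.csv(txt, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("symbol", "ensembl_gene_id", "uniprot_ids", "name")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("HGNC format error: missing required column '", missing[1L], "'",
         call. = FALSE)
  }
  if (any(!nzchar(df$symbol) | is.na(df$symbol))) {
    stop("HGNC format error: empty gene symbol", call. = FALSE)
  }
  if (anyDuplicated(df$symbol)) {
    stop("HGNC load error: duplicate symbol '",
         df$symbol[duplicated(df$symbol)][1L], "'", call. = FALSE)
  }
  out <- data.frame(
    symbol = df$symbol,
    ensembl_gene_id = ifelse(is.na(df$ensembl_gene_id), "", df$ensembl_gene_id),
    gene_name = if (is.null(df$name)) "" else df$name,
    locus_type = if ("locus_type" %in% names(df)) df$locus_type else "",
    stringsAsFactors = FALSE
  )
  out$uniprot_ids <- lapply(df$uniprot_ids, function(cell) {
    if (is.na(cell) || !nzchar(cell)) return(character())
    ids <- unlist(strsplit(cell, "[|[:space:]]+"))
    ids[nzchar(ids)]
  })
  class(out) <- c("hgnc_table", "data.frame")
  out
}

#' Map a gene identifier between namespaces
#'
#' Case-insensitive lookup across the three namespaces of a loaded HGNC
#' table. Returns every mapped identifier (a symbol can carry several
#' UniProt accessions); an absent identifier maps to an empty vector.
#'
#' @param table An `"hgnc_table"` from [load_hgnc()].
#' @param query Identifier to map.
#' @param from,to Namespace names: `"symbol"`, `"ensembl"` or `"uniprot"`.
#' @return Character vector of mapped identifiers (possibly empty).
#' @export
map_identifier <- function(table, query, from, to) {
  stopifnot(inherits(table, "hgnc_table"))
  ns <- c("symbol", "ensembl", "uniprot")
  if (!from %in% ns || !to %in% ns) {
    stop("unknown namespace; use one of: ", paste(ns, collapse = ", "),
         call. = FALSE)
  }
  q <- toupper(query)
  hit <- switch(from,
    symbol = toupper(table$symbol) == q,
    ensembl = toupper(table$ensembl_gene_id) == q & nzchar(table$ensembl_gene_id),
    uniprot = vapply(table$uniprot_ids, function(u) q %in% toupper(u), logical(1))
  )
  rows <- which(hit)
  if (!length(rows)) return(character())
  out <- switch(to,
    symbol = table$symbol[rows],
    ensembl = table$ensembl_gene_id[rows],
    uniprot = unlist(table$uniprot_ids[rows], use.names = FALSE)
  )
  unique(out[nzchar(out)])
}

#' Extract the trailing identifier from an annotation URI
#'
#' Returns the final path segment of a URI (the text after the last `/`),
#' the convention used by identifiers.org and UniProt annotation links.
#' A trailing slash is stripped first; a string without any slash is
#' returned unchanged. Idempotent.
#'
#' @param uri Character vector of URIs.
#' @return Character vector of extracted identifiers.
#' @export
#' @examples
#' extract_link_id("https://identifiers.org/uniprot/P09016")
extract_link_id <- function(uri) {
  x <- sub("/+$", "", uri)
  sub("^.*/", "", x)
}

#' Load a Systems Biology Ontology label table
#'
#' Either a two-column tab-separated table (`term<TAB>label`) or a minimal
#' OWL/XML document from which `rdfs:label` values are harvested per class
#' (the class IRI fragment `SBO_0000NNN` is converted to `SBO:0000NNN`).
#'
#' @param x TSV/OWL text or a file path.
#' @param format `"tsv"` or `"owl"`.
#' @return A named character vector, labels keyed by SBO term.
#' @export
load_sbo <- function(x, format = c("tsv", "owl")) {
  format <- match.arg(format)
  txt <- if (length(x) == 1L && !grepl("[\t\n<]", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else {
    paste(x, collapse = "\n")
  }
  if (format == "owl") {
    doc <- xml2::read_xml(txt)
    classes <- xml2::xml_find_all(doc, ".//*[local-name()='Class']")
    terms <- character(); labels <- character()
    for (cl in classes) {
      at <- xml2::xml_attrs(cl)
      iri <- at[grepl("(^|:)about$", names(at))]
      lab <- xml2::xml_find_first(cl, "./*[local-name()='label']")
      if (!length(iri) || inherits(lab, "xml_missing")) next
      frag <- sub("^.*[/#]", "", iri[[1]])
      if (!grepl("^SBO_[0-9]{7}$", frag)) next
      terms <- c(terms, sub("^SBO_", "SBO:", frag))
      labels <- c(labels, xml2::xml_text(lab))
    }
    return(stats::setNames(labels, terms))
  }
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 2L
  stats::setNames(
    vapply(fields[ok], `[[`, character(1), 2L),
    vapply(fields[ok], `[[`, character(1), 1L)
  )
}

#' Human-readable label for an SBO term
#'
#' @param term A term of the form `"SBO:0000NNN"`.
#' @param ontology Named label vector from [load_sbo()].
#' @return The label, or the sentinel `"unknown SBO term"` when absent.
#' @export
#' @examples
#' sbo <- load_sbo(system.file("extdata", "sbo_terms.tsv", package = "netprofiler"))
#' sbo_label("SBO:0000297", sbo)
sbo_label <- function(term, ontology) {
  if (!grepl("^SBO:[0-9]{7}$", term)) {
    stop("malformed SBO term '", term, "': expected SBO:0000NNN", call. = FALSE)
  }
  if (term %in% names(ontology)) unname(ontology[[term]]) else "unknown SBO term"
}
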