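#' Load a local pathway index
#'
#' Reads the three-column tab-separated pathway index dialect
#' (`model id<TAB>name<TAB>organism`, the `ReactomePathways.txt` layout).
#' Malformed lines (not exactly three fields) are skipped; the skip count is
#' attached as attribute `"skipped"` and reported via a message.
#'
#' @param x TSV text or a file path.
#' @return A data frame with columns `model_id`, `name`, `organism`.
#' @export
load_pathway_index <- function(x) {
  lines <- .read_lines_arg(x)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) == 3L
  skipped <- sum(!ok)
  if (skipped) message("pathway index: skipped ", skipped, " malformed line(s)")
  if (!any(ok)) stop("pathway index format error: no parseable lines", call. = FALSE)
  out <- data.frame(
    model_id = vapply(fields[ok], `[[`, character(1), 1L),
    name = vapply(fields[ok], `[[`, character(1), 2L),
    organism = vapply(fields[ok], `[[`, character(1), 3L),
    stringsAsFactors = FALSE
  )
  attr(out, "skipped") <- skipped
  out
}

#' Search a pathway index
#'
#' The query is lowercased and split on whitespace; an entry matches when
#' every token occurs as a substring of the concatenation of its three
#' fields. Matches are ranked by (1) the number of distinct fields that
#' contain at least one token, descending -- so multi-word queries like
#' `"glycolysis homo sapiens"` push entries matched on both name and
#' organism ahead of name-only hits -- then (2) name length ascending, then
#' (3) `model_id`. The ordering is a deterministic total order.
#'
#' @param index Data frame from [load_pathway_index()].
#' @param query Non-empty query string.
#' @return The matching rows of `index`, ranked.
#' @export
search_pathways <- function(index, query) {
  if (!is.character(query) || length(query) != 1L || !nzchar(trimws(query))) {
    stop("usage error: query must be a non-empty string", call. = FALSE)
  }
  tokens <- strsplit(tolower(trimws(query)), "[[:space:]]+")[[1]]
  f1 <- tolower(index$model_id); f2 <- tolower(index$name); f3 <- tolower(index$organism)
  all_text <- paste(f1, f2, f3)
  match_all <- vapply(seq_len(nrow(index)), function(i) {
    all(vapply(tokens, function(t) grepl(t, all_text[i], fixed = TRUE), logical(1)))
  }, logical(1))
  hits <- which(match_all)
  if (!length(hits)) return(index[integer(), , drop = FALSE])
  n_fields <- vapply(hits, function(i) {
    sum(vapply(list(f1[i], f2[i], f3[i]), function(f) {
      any(vapply(tokens, function(t) grepl(t, f, fixed = TRUE), logical(1)))
    }, logical(1)))
  }, integer(1))
  ord <- order(-n_fields, nchar(index$name[hits]), index$model_id[hits])
  out <- index[hits[ord], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load a pathway parent/child relations table
#'
#' Two-column tab-separated `parent_id<TAB>child_id` lines (the
#' `ReactomePathwaysRelation.txt` layout). Self-loops are rejected;
#' duplicate edges collapse to one.
#'
#' @param x TSV text or a file path.
#' @return A data frame with columns `parent_id`, `child_id`.
#' @export
load_pathway_relations <- function(x) {
  lines <- .read_lines_arg(x)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 2L
  out <- unique(data.frame(
    parent_id = vapply(fields[ok], `[[`, character(1), 1L),
    child_id = vapply(fields[ok], `[[`, character(1), 2L),
    stringsAsFactors = FALSE
  ))
  out <- out[out$parent_id != out$child_id, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find pathways associated with a model
#'
#' Looks up the direct parents and children of a pathway in a relations
#' table. Unknown ids yield two empty lists rather than an error.
#'
#' @param relations Data frame from [load_pathway_relations()].
#' @param model_id Pathway id to look up.
#' @return A list with sorted, deduplicated character vectors `parents` and
#'   `children`.
#' @export
find_associated <- function(relations, model_id) {
  list(
    parents = sort(unique(relations$parent_id[relations$child_id == model_id])),
    children = sort(unique(relations$child_id[relations$parent_id == model_id]))
  )
}

.read_lines_arg <- function(x) {
  if (length(x) == 1L && !grepl("[\t\n]", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(paste(x, collapse = "\n"), "\n", fixed = TRUE))
  }
}
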