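# Minimal infix <-> MathML bridge for kinetic-law rate expressions.
#
# The grammar covers exactly what the rate-law injectors emit and what sane
# hand-written laws look like: + - * / ^, parentheses, identifiers, numeric
# literals, unary minus. Expressions are canonicalized (one space around
# binary operators, minimal parentheses) so write -> read round trips are
# identities on the stored text.

rate_expr_parse <- function(text) {
  toks <- rate_expr_tokens(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  node <- .rx_expr(st)
  if (st$pos <= length(st$toks)) {
    stop("trailing input in rate expression at token '",
         st$toks[st$pos], "'", call. = FALSE)
  }
  node
}

rate_expr_tokens <- function(text) {
  pat <- "[A-Za-z_][A-Za-z0-9_]*|[0-9]+\\.?[0-9]*([eE][-+]?[0-9]+)?|\\.[0-9]+|[-+*/^()]"
  m <- gregexpr(pat, text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  covered <- sum(attr(m, "match.length"))
  residue <- gsub("[[:space:]]", "", text)
  if (nchar(residue) != sum(nchar(toks))) {
    stop("cannot tokenize rate expression: '", text, "'", call. = FALSE)
  }
  toks
}

.rx_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_
.rx_take <- function(st) { t <- .rx_peek(st); st$pos <- st$pos + 1L; t }

.rx_expr <- function(st) {
  node <- .rx_term(st)
  while (!is.na(.rx_peek(st)) && .rx_peek(st) %in% c("+", "-")) {
    op <- .rx_take(st)
    rhs <- .rx_term(st)
    node <- list(op = if (op == "+") "plus" else "minus", args = list(node, rhs))
  }
  node
}

.rx_term <- function(st) {
  node <- .rx_factor(st)
  while (!is.na(.rx_peek(st)) && .rx_peek(st) %in% c("*", "/")) {
    op <- .rx_take(st)
    rhs <- .rx_factor(st)
    node <- list(op = if (op == "*") "times" else "divide", args = list(node, rhs))
  }
  node
}

.rx_factor <- function(st) {
  base <- .rx_base(st)
  if (!is.na(.rx_peek(st)) && .rx_peek(st) == "^") {
    .rx_take(st)
    list(op = "power", args = list(base, .rx_factor(st)))  # right-assoc
  } else base
}

.rx_base <- function(st) {
  t <- .rx_take(st)
  if (is.na(t)) stop("unexpected end of rate expression", call. = FALSE)
  if (t == "(") {
    node <- .rx_expr(st)
    if (!identical(.rx_take(st), ")")) {
      stop("unbalanced parenthesis in rate expression", call. = FALSE)
    }
    return(node)
  }
  if (t == "-") return(list(op = "minus", args = list(list(cn = 0), .rx_base(st))))
  if (grepl("^[0-9.]", t)) return(list(cn = as.numeric(t)))
  if (grepl("^[A-Za-z_]", t)) return(list(ci = t))
  stop("unexpected token '", t, "' in rate expression", call. = FALSE)
}

# precedence: plus/minus 1, times/divide 2, power 3
.rx_prec <- c(plus = 1L, minus = 1L, times = 2L, divide = 2L, power = 3L)

rate_expr_render <- function(node) .rx_render(node, 0L)

.rx_render <- function(node, parent_prec) {
  if (!is.null(node$ci)) return(node$ci)
  if (!is.null(node$cn)) return(format(node$cn, scientific = FALSE, trim = TRUE))
  op <- node$op
  prec <- .rx_prec[[op]]
  sym <- c(plus = "+", minus = "-", times = "*", divide = "/", power = "^")[[op]]
  lhs <- .rx_render(node$args[[1]], prec)
  # right operand of a non-commutative op needs strictly higher precedence
  rhs_min <- if (op %in% c("minus", "divide")) prec + 1L else prec
  rhs <- .rx_render(node$args[[2]], rhs_min)
  out <- if (op == "power") paste0(lhs, sym, rhs) else paste(lhs, sym, rhs)
  if (prec < parent_prec) paste0("(", out, ")") else out
}

rate_expr_canonical <- function(text) rate_expr_render(rate_expr_parse(text))

rate_expr_to_mathml <- function(text, indent = "") {
  .rx_mathml(rate_expr_parse(text), indent)
}

.rx_mathml <- function(node, indent) {
  if (!is.null(node$ci)) return(paste0(indent, "<ci> ", xml_escape(node$ci), " </ci>"))
  if (!is.null(node$cn)) {
    return(paste0(indent, "<cn> ", format(node$cn, scientific = FALSE, trim = TRUE), " </cn>"))
  }
  inner <- vapply(node$args, .rx_mathml, character(1), indent = paste0(indent, "  "))
  paste0(indent, "<apply>\n", indent, "  <", node$op, "/>\n",
         paste(inner, collapse = "\n"), "\n", indent, "</apply>")
}

mathml_to_rate_expr <- function(math_node) {
  rate_expr_render(.rx_from_mathml(math_node))
}

.rx_from_mathml <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "math") {
    kids <- xml2::xml_children(node)
    if (!length(kids)) stop("empty MathML math element", call. = FALSE)
    return(.rx_from_mathml(kids[[1]]))
  }
  if (nm == "ci") return(list(ci = trimws(xml2::xml_text(node))))
  if (nm == "cn") return(list(cn = as.numeric(trimws(xml2::xml_text(node)))))
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    args <- lapply(kids[-1], .rx_from_mathml)
    if (!op %in% names(.rx_prec)) {
      stop("unsupported MathML operator '", op, "'", call. = FALSE)
    }
    if (length(args) == 1L && op == "minus") {
      return(list(op = "minus", args = list(list(cn = 0), args[[1]])))
    }
    # n-ary plus/times fold left
    node <- args[[1]]
    for (a in args[-1]) node <- list(op = op, args = list(node, a))
    return(node)
  }
  stop("unsupported MathML element '", nm, "'", call. = FALSE)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}
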