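#' Gene-protein-reaction (GPR) rule trees
#'
#' A GPR rule is a boolean expression over genes stating which gene
#' combinations enable a reaction: `AND` nodes model enzyme complexes
#' (all subunits required), `OR` nodes model isozymes (any suffices).
#' Trees are plain recursive lists with fields `kind` (`"GENE"`, `"AND"`,
#' `"OR"`), `gene_id` (GENE leaves only) and `children` (AND/OR only).
#'
#' @param gene_id gene identifier (single non-empty string).
#' @param ... child GPR nodes (at least one).
#' @return a GPR node.
#' @examples
#' g <- gprOr(gprAnd(gprGene("b0001"), gprGene("b0002")), gprGene("b0003"))
#' gprToString(g)
#' @export
gprGene <- function(gene_id) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))
  structure(list(kind = "GENE", gene_id = gene_id), class = "GprNode")
}

#' @rdname gprGene
#' @export
gprAnd <- function(...) {
  children <- list(...)
  stopifnot(length(children) >= 1L)
  structure(list(kind = "AND", children = children), class = "GprNode")
}

#' @rdname gprGene
#' @export
gprOr <- function(...) {
  children <- list(...)
  stopifnot(length(children) >= 1L)
  structure(list(kind = "OR", children = children), class = "GprNode")
}

#' Flatten a GPR tree to its gene set
#'
#' @param node a GPR node or `NULL`.
#' @return character vector of distinct gene ids (empty for `NULL`).
#' @export
gprGenes <- function(node) {
  if (is.null(node)) return(character())
  if (node$kind == "GENE") return(node$gene_id)
  unique(unlist(lapply(node$children, gprGenes)))
}

#' Render a GPR tree as a boolean rule string
#'
#' Produces the conventional `"(a and b) or c"` notation used in COBRA-style
#' model notes.
#'
#' @param node a GPR node or `NULL`.
#' @return character scalar (`""` for `NULL`).
#' @export
gprToString <- function(node) {
  if (is.null(node)) return("")
  if (node$kind == "GENE") return(node$gene_id)
  op <- if (node$kind == "AND") " and " else " or "
  parts <- vapply(node$children, function(ch) {
    s <- gprToString(ch)
    if (ch$kind != "GENE") paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = op)
}

# Tokenizer for textual GPR rules: parentheses, and/or (case-insensitive,
# also &&/& and ||/|), everything else is a gene token.
gprTokenize <- function(x) {
  x <- gsub("&&|&", " and ", x)
  x <- gsub("\\|\\||\\|", " or ", x)
  x <- gsub("([()])", " \\1 ", x)
  toks <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

#' Parse a textual GPR rule
#'
#' Parses COBRA-style boolean gene association strings such as
#' `"(b0001 and b0002) or b0003"`. `and` binds tighter than `or`;
#' parentheses are honored; `&`/`|` spellings are accepted.
#'
#' @param text rule string; empty or whitespace-only yields `NULL`.
#' @return a GPR node or `NULL`.
#' @export
parseGpr <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- gprTokenize(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() {
    tok <- toks[pos]
    pos <<- pos + 1L
    tok
  }
  parse_primary <- function() {
    tok <- peek()
    if (is.na(tok)) stop("GPR parse error: unexpected end of rule: ", text, call. = FALSE)
    if (tok == "(") {
      advance()
      node <- parse_or()
      if (!identical(peek(), ")")) {
        stop("GPR parse error: missing ')' in rule: ", text, call. = FALSE)
      }
      advance()
      return(node)
    }
    if (tok %in% c(")", "and", "AND", "And", "or", "OR", "Or")) {
      stop("GPR parse error: unexpected token '", tok, "' in rule: ", text, call. = FALSE)
    }
    advance()
    gprGene(tok)
  }
  parse_and <- function() {
    kids <- list(parse_primary())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      kids <- c(kids, list(parse_primary()))
    }
    if (length(kids) == 1L) kids[[1]] else do.call(gprAnd, kids)
  }
  parse_or <- function() {
    kids <- list(parse_and())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      kids <- c(kids, list(parse_and()))
    }
    if (length(kids) == 1L) kids[[1]] else do.call(gprOr, kids)
  }
  node <- parse_or()
  if (!is.na(peek())) {
    stop("GPR parse error: trailing token '", peek(), "' in rule: ", text, call. = FALSE)
  }
  node
}

# Recursive GPR evaluation against a per-gene record table.
# `records` is a data.frame with rownames = gene ids and columns
# p_value, log2_fc, rank (the ordering key). Returns a one-row record
# (with source_gene) or NULL when no gene in the subtree has data.
# AND picks the child record with minimum rank (limiting subunit),
# OR the one with maximum rank (dominant isozyme); children without
# data are ignored at both node kinds.
gprEvaluate <- function(node, records) {
  if (is.null(node)) return(NULL)
  if (node$kind == "GENE") {
    if (!node$gene_id %in% rownames(records)) return(NULL)
    rec <- records[node$gene_id, , drop = FALSE]
    rec$source_gene <- node$gene_id
    return(rec)
  }
  kids <- Filter(Negate(is.null), lapply(node$children, gprEvaluate, records = records))
  if (!length(kids)) return(NULL)
  ranks <- vapply(kids, function(r) r$rank, numeric(1))
  pick <- if (node$kind == "AND") which.min(ranks) else which.max(ranks)
  kids[[pick]]
}
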