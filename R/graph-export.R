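#' Build an annotated network from a (sub)model
#'
#' Constructs the bipartite metabolite-reaction network of a model, one node
#' per metabolite and reaction (plus one per gene when `includeGenes`), with
#' edges derived from stoichiometry signs: consumed metabolites send
#' `substrate` edges into the reaction node, produced metabolites receive
#' `product` edges from it, and genes send `catalysis` edges to the
#' reactions whose GPR mentions them. Reversible reactions stay a single
#' node with a `reversible` attribute. A reaction is flagged `is_exchange`
#' when it touches a boundary species or has at most one participant —
#' these demarcate the uptake and release points visualization styles
#' highlight.
#'
#' @param sub a [MetabolicModel-class] (typically from [extractSubmodel()]).
#' @param includeGenes add gene nodes and catalysis edges (default `TRUE`).
#' @return an [AnnotatedGraph-class].
#' @export
buildGraph <- function(sub, includeGenes = TRUE) {
  validObject(sub)
  rxn <- sub@reactions
  met <- sub@metabolites
  boundary_ids <- met$id[met$boundary]
  orig_index <- if ("orig_index" %in% names(rxn)) rxn$orig_index else seq_len(nrow(rxn))

  node <- function(id, type, label, compartment = NA_character_,
                   subsystem = NA_character_, index = NA_integer_,
                   is_exchange = NA, reversible = NA) {
    data.frame(id = id, type = type, label = label, compartment = compartment,
               subsystem = subsystem, index = index, is_exchange = is_exchange,
               reversible = reversible, occurrence_pct = NA_real_,
               log2_fc = NA_real_, p_value = NA_real_, no_data = NA,
               stringsAsFactors = FALSE)
  }

  nodes <- list()
  if (nrow(met)) {
    nodes[[length(nodes) + 1L]] <- node(paste0("m:", met$id), "metabolite",
                                        met$name, compartment = met$compartment)
  }
  edges <- list()
  for (j in seq_len(nrow(rxn))) {
    sj <- reactionStoichiometry(sub, j)
    n_part <- length(sj)
    sub_lab <- paste(rxn$subsystem[[j]], collapse = "; ")
    nodes[[length(nodes) + 1L]] <- node(
      paste0("r:", rxn$id[j]), "reaction", rxn$name[j],
      subsystem = if (nzchar(sub_lab)) sub_lab else NA_character_,
      index = orig_index[j],
      is_exchange = n_part <= 1L || any(names(sj) %in% boundary_ids),
      reversible = rxn$reversible[j])
    if (n_part) {
      subs <- names(sj)[sj < 0]; prods <- names(sj)[sj > 0]
      if (length(subs)) {
        edges[[length(edges) + 1L]] <- data.frame(
          source = paste0("m:", subs), target = paste0("r:", rxn$id[j]),
          type = "substrate", stoichiometry = abs(unname(sj[subs])),
          flux = NA_real_, stringsAsFactors = FALSE)
      }
      if (length(prods)) {
        edges[[length(edges) + 1L]] <- data.frame(
          source = paste0("r:", rxn$id[j]), target = paste0("m:", prods),
          type = "product", stoichiometry = abs(unname(sj[prods])),
          flux = NA_real_, stringsAsFactors = FALSE)
      }
    }
    if (includeGenes && !is.null(sub@gpr[[j]])) {
      gg <- gprGenes(sub@gpr[[j]])
      edges[[length(edges) + 1L]] <- data.frame(
        source = paste0("g:", gg), target = paste0("r:", rxn$id[j]),
        type = "catalysis", stoichiometry = NA_real_, flux = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (includeGenes && length(sub@genes)) {
    used <- unique(unlist(lapply(sub@gpr, gprGenes)))
    if (length(used)) {
      gn <- node(paste0("g:", used), "gene", used)
      gn$no_data <- NA
      nodes[[length(nodes) + 1L]] <- gn
    }
  }
  nodes <- if (length(nodes)) do.call(rbind, nodes) else emptyNodes()
  edges <- if (length(edges)) do.call(rbind, edges) else emptyEdges()
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  new("AnnotatedGraph", nodes = nodes, edges = edges)
}

emptyNodes <- function() {
  data.frame(id = character(), type = character(), label = character(),
             compartment = character(), subsystem = character(),
             index = integer(), is_exchange = logical(), reversible = logical(),
             occurrence_pct = numeric(), log2_fc = numeric(),
             p_value = numeric(), no_data = logical(),
             stringsAsFactors = FALSE)
}

emptyEdges <- function() {
  data.frame(source = character(), target = character(), type = character(),
             stoichiometry = numeric(), flux = numeric(),
             stringsAsFactors = FALSE)
}

#' Graph accessors
#'
#' @param object an [AnnotatedGraph-class].
#' @return `graphNodes`, `graphEdges`: the node and edge attribute tables.
#' @name graph-accessors
NULL

#' @rdname graph-accessors
#' @export
setGeneric("graphNodes", function(object) standardGeneric("graphNodes"))
#' @rdname graph-accessors
#' @export
setGeneric("graphEdges", function(object) standardGeneric("graphEdges"))
#' @rdname graph-accessors
setMethod("graphNodes", "AnnotatedGraph", function(object) object@nodes)
#' @rdname graph-accessors
setMethod("graphEdges", "AnnotatedGraph", function(object) object@edges)

setMethod("show", "AnnotatedGraph", function(object) {
  tt <- table(object@nodes$type)
  cat(sprintf("AnnotatedGraph: %d nodes (%s), %d edges\n",
              nrow(object@nodes),
              paste(sprintf("%d %s", as.integer(tt), names(tt)), collapse = ", "),
              nrow(object@edges)))
  invisible(object)
})

#' Map an EFM's relative fluxes onto graph edges
#'
#' Every substrate and product edge incident to a reaction node receives the
#' magnitude of that reaction's relative flux, so edge thickness can encode
#' flux in downstream styles. All edges of one reaction carry the same value
#' (one relative flux per reaction).
#'
#' @param g an [AnnotatedGraph-class] whose reaction nodes carry `index`
#'   attributes addressing `efm`'s model index space.
#' @param efm either an [EfmSet-class] plus `id`, or a named numeric vector
#'   of fluxes keyed by reaction index.
#' @param id EFM id, when `efm` is an `EfmSet`.
#' @return the graph with `flux` set on substrate/product edges.
#' @export
mapFluxes <- function(g, efm, id = NULL) {
  fl <- if (is(efm, "EfmSet")) efmRelativeFluxes(efm, id) else efm
  if (is.null(fl)) stop("EFM carries no relative fluxes", call. = FALSE)
  nd <- g@nodes
  rnodes <- nd[nd$type == "reaction", , drop = FALSE]
  missing_fl <- rnodes$id[!as.character(rnodes$index) %in% names(fl)]
  if (length(missing_fl)) {
    stop("no flux for reaction node(s): ", paste(missing_fl, collapse = ", "),
         call. = FALSE)
  }
  flux_of <- stats::setNames(abs(fl[as.character(rnodes$index)]), rnodes$id)
  ed <- g@edges
  touch <- ed$type %in% c("substrate", "product")
  rid <- ifelse(ed$type == "substrate", ed$target, ed$source)
  ed$flux[touch] <- flux_of[rid[touch]]
  new("AnnotatedGraph", nodes = nd, edges = ed)
}

#' Map gene-level statistics onto gene nodes
#'
#' Gene nodes matched by id receive `log2_fc` and `p_value`; unmatched gene
#' nodes are flagged `no_data`.
#'
#' @param g an [AnnotatedGraph-class] with gene nodes.
#' @param stats gene statistics table (see [readGeneStats()]).
#' @return the annotated graph.
#' @export
mapGeneData <- function(g, stats) {
  stats <- validateGeneStats(stats)
  nd <- g@nodes
  is_gene <- nd$type == "gene"
  pos <- match(nd$label[is_gene], stats$gene_id)
  nd$log2_fc[is_gene] <- stats$log2_fc[pos]
  nd$p_value[is_gene] <- stats$p_value[pos]
  nd$no_data[is_gene] <- is.na(pos)
  new("AnnotatedGraph", nodes = nd, edges = g@edges)
}

#' Attach backbone occurrence percentages to reaction nodes
#'
#' @param g an [AnnotatedGraph-class].
#' @param backbone result of [extractBackbone()].
#' @return the graph with `occurrence_pct` (0-100) on reaction nodes.
#' @export
mapOccurrence <- function(g, backbone) {
  nd <- g@nodes
  is_rxn <- nd$type == "reaction"
  nd$occurrence_pct[is_rxn] <-
    100 * unname(backbone$occurrence[as.character(nd$index[is_rxn])])
  new("AnnotatedGraph", nodes = nd, edges = g@edges)
}

#' Serialize an annotated graph
#'
#' Writes the network with all node and edge attributes in one of three
#' formats: `"graphml"` (typed attributes, via igraph), `"sif"` (a Cytoscape
#' simple-interaction file using the edge type as the interaction token,
#' plus `<base>_nodes.tsv` and `<base>_edges.tsv` attribute tables) or
#' `"json"` (a node-link JSON document).
#'
#' @param g an [AnnotatedGraph-class].
#' @param path output path (for SIF, the `.sif` path; companion TSVs are
#'   derived from it).
#' @param format one of `"graphml"`, `"sif"`, `"json"`.
#' @return character vector of the files written, invisibly.
#' @export
writeGraph <- function(g, path, format = c("graphml", "sif", "json")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown graph format: ",
                                              format[1], call. = FALSE))
  validObject(g)
  switch(format,
    graphml = writeGraphML(g, path),
    sif = writeSif(g, path),
    json = writeJsonGraph(g, path))
}

asIgraph <- function(g) {
  nd <- g@nodes
  ed <- g@edges
  # igraph's GraphML writer has no NA notion for strings; use "" for absent
  for (col in c("compartment", "subsystem")) nd[[col]][is.na(nd[[col]])] <- ""
  # graph_from_data_frame takes vertex names from the first column
  nd <- cbind(name = nd$id, nd[setdiff(names(nd), "id")])
  igraph::graph_from_data_frame(ed, directed = TRUE, vertices = nd)
}

writeGraphML <- function(g, path) {
  ig <- asIgraph(g)
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".graphml")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  igraph::write_graph(ig, tmp, format = "graphml")
  file.rename(tmp, path)
  invisible(path)
}

writeSif <- function(g, path) {
  ed <- g@edges
  sif_lines <- if (nrow(ed)) sprintf("%s\t%s\t%s", ed$source, ed$type, ed$target)
               else character()
  # isolated nodes still appear in SIF as bare node lines
  isolated <- setdiff(g@nodes$id, c(ed$source, ed$target))
  writeLinesAtomic(c(sif_lines, isolated), path)
  base <- sub("\\.sif$", "", path)
  node_path <- paste0(base, "_nodes.tsv")
  edge_path <- paste0(base, "_edges.tsv")
  writeTsvAtomic(g@nodes, node_path)
  writeTsvAtomic(g@edges, edge_path)
  invisible(c(path, node_path, edge_path))
}

writeJsonGraph <- function(g, path) {
  doc <- list(directed = TRUE, nodes = g@nodes, edges = g@edges)
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".json")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

writeTsvAtomic <- function(df, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tsv")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  file.rename(tmp, path)
  invisible(path)
}
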