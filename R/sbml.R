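#' Read a genome-scale metabolic model from SBML
#'
#' Reads SBML Level 2 and Level 3 documents in the COBRA style. GPR rules are
#' taken from fbc (version 2) gene-product associations when present, else
#' from legacy `GENE_ASSOCIATION:` note strings. Subsystems are taken from
#' the groups package when present, else from `SUBSYSTEM:` note strings.
#' Reaction order equals document order and defines the index space used by
#' EFM files. Identifiers are preserved verbatim.
#'
#' @param path path to an SBML file.
#' @return a [MetabolicModel-class].
#' @seealso [writeModelSBML()]
#' @export
readModelSBML <- function(path) {
  if (!file.exists(path)) stop("SBML file not found: ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed SBML in ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  if (xml2::xml_name(doc) != "sbml") {
    stop("malformed SBML in ", path, ": root element is <",
         xml2::xml_name(doc), ">, expected <sbml>", call. = FALSE)
  }
  model_node <- childByName(doc, "model")
  if (is.null(model_node)) {
    stop("malformed SBML in ", path, ": no <model> element", call. = FALSE)
  }
  model_id <- firstNonEmpty(xml2::xml_attr(model_node, "id"),
                            xml2::xml_attr(model_node, "name"), "model")

  ## compartments
  comp_nodes <- listChildren(model_node, "listOfCompartments", "compartment")
  comp_ids <- vapply(comp_nodes, function(n) xml2::xml_attr(n, "id"), character(1))
  comp_names <- vapply(comp_nodes, function(n) {
    firstNonEmpty(xml2::xml_attr(n, "name"), xml2::xml_attr(n, "id"))
  }, character(1))
  compartments <- stats::setNames(comp_names, comp_ids)

  ## species
  sp_nodes <- listChildren(model_node, "listOfSpecies", "species")
  metabolites <- data.frame(
    id = vapply(sp_nodes, function(n) xml2::xml_attr(n, "id"), character(1)),
    name = vapply(sp_nodes, function(n) {
      firstNonEmpty(xml2::xml_attr(n, "name"), xml2::xml_attr(n, "id"))
    }, character(1)),
    compartment = vapply(sp_nodes, function(n) xml2::xml_attr(n, "compartment"),
                         character(1)),
    boundary = vapply(sp_nodes, function(n) {
      identical(xml2::xml_attr(n, "boundaryCondition"), "true")
    }, logical(1)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(metabolites$id)) {
    stop("invalid SBML in ", path, ": duplicate species id: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "),
         call. = FALSE)
  }

  ## fbc gene products: fbc:id -> label (gene identifier used by the model)
  gp_nodes <- listChildren(model_node, "listOfGeneProducts", "geneProduct")
  gp_map <- character()
  if (length(gp_nodes)) {
    gp_id <- vapply(gp_nodes, function(n) xml2::xml_attr(n, "id"), character(1))
    gp_label <- vapply(gp_nodes, function(n) {
      firstNonEmpty(xml2::xml_attr(n, "label"), xml2::xml_attr(n, "id"))
    }, character(1))
    gp_map <- stats::setNames(gp_label, gp_id)
  }

  ## reactions
  rxn_nodes <- listChildren(model_node, "listOfReactions", "reaction")
  nr <- length(rxn_nodes)
  rxn_id <- character(nr); rxn_name <- character(nr); rxn_rev <- logical(nr)
  stoich <- vector("list", nr)
  gpr <- vector("list", nr)
  note_subsystem <- vector("list", nr)
  for (j in seq_len(nr)) {
    n <- rxn_nodes[[j]]
    rxn_id[j] <- xml2::xml_attr(n, "id")
    rxn_name[j] <- firstNonEmpty(xml2::xml_attr(n, "name"), rxn_id[j])
    # L2 default for 'reversible' is true; L3 requires the attribute
    rev <- xml2::xml_attr(n, "reversible")
    rxn_rev[j] <- if (is.na(rev)) TRUE else identical(rev, "true")
    sj <- numeric()
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      for (sr in listChildren(n, side, "speciesReference")) {
        sp <- xml2::xml_attr(sr, "species")
        coef <- xml2::xml_attr(sr, "stoichiometry")
        coef <- if (is.na(coef)) 1 else as.numeric(coef)
        if (is.na(coef)) {
          stop("malformed SBML in ", path, ": non-numeric stoichiometry in reaction ",
               rxn_id[j], call. = FALSE)
        }
        sj[sp] <- (if (sp %in% names(sj)) sj[[sp]] else 0) + sgn * coef
      }
    }
    stoich[[j]] <- sj[sj != 0]
    gpa <- childByName(n, "geneProductAssociation")
    if (!is.null(gpa)) {
      assoc <- xml2::xml_children(gpa)
      if (length(assoc)) gpr[[j]] <- parseFbcAssociation(assoc[[1]], gp_map)
    }
    notes <- notesFields(n)
    if (is.null(gpr[[j]]) && !is.null(notes$gene_association)) {
      gpr[[j]] <- parseGpr(notes$gene_association)
    }
    note_subsystem[[j]] <- if (is.null(notes$subsystem)) character() else notes$subsystem
  }
  if (anyDuplicated(rxn_id)) {
    stop("invalid SBML in ", path, ": duplicate reaction id: ",
         paste(unique(rxn_id[duplicated(rxn_id)]), collapse = ", "), call. = FALSE)
  }

  ## subsystems: groups package wins over notes
  subsystem <- rep(list(character()), nr)
  grp_nodes <- listChildren(model_node, "listOfGroups", "group")
  if (length(grp_nodes)) {
    for (g in grp_nodes) {
      label <- firstNonEmpty(xml2::xml_attr(g, "name"), xml2::xml_attr(g, "id"))
      for (m in listChildren(g, "listOfMembers", "member")) {
        ref <- firstNonEmpty(xml2::xml_attr(m, "idRef"), xml2::xml_attr(m, "metaIdRef"))
        k <- match(ref, rxn_id)
        if (!is.na(k)) subsystem[[k]] <- union(subsystem[[k]], label)
      }
    }
  } else {
    subsystem <- note_subsystem
  }

  reactions <- data.frame(id = rxn_id, name = rxn_name, reversible = rxn_rev,
                          stringsAsFactors = FALSE)
  reactions$subsystem <- I(subsystem)
  genes <- unique(c(unname(gp_map), unlist(lapply(gpr, gprGenes))))
  MetabolicModel(id = model_id, reactions = reactions, metabolites = metabolites,
                 stoichiometry = stoich, gpr = gpr, genes = genes,
                 compartments = compartments)
}

# first child (any namespace) with a given local name, or NULL
childByName <- function(node, name) {
  kids <- xml2::xml_children(node)
  nm <- xml2::xml_name(kids)
  hit <- which(nm == name)
  if (length(hit)) kids[[hit[1]]] else NULL
}

# children of <container> with a given local name (empty list when absent)
listChildren <- function(node, container, name) {
  box <- childByName(node, container)
  if (is.null(box)) return(list())
  kids <- xml2::xml_children(box)
  kids[xml2::xml_name(kids) == name]
}

firstNonEmpty <- function(...) {
  for (x in list(...)) if (!is.na(x) && nzchar(x)) return(x)
  NA_character_
}

# fbc association subtree -> GPR node
parseFbcAssociation <- function(node, gp_map) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    gene <- if (ref %in% names(gp_map)) gp_map[[ref]] else ref
    return(gprGene(gene))
  }
  kids <- lapply(xml2::xml_children(node), parseFbcAssociation, gp_map = gp_map)
  if (nm == "and") return(do.call(gprAnd, kids))
  if (nm == "or") return(do.call(gprOr, kids))
  stop("unsupported fbc association element <", nm, ">", call. = FALSE)
}

# Extract GENE_ASSOCIATION / SUBSYSTEM fields from COBRA-style notes
notesFields <- function(rxn_node) {
  out <- list(gene_association = NULL, subsystem = NULL)
  notes <- childByName(rxn_node, "notes")
  if (is.null(notes)) return(out)
  txt <- xml2::xml_text(xml2::xml_find_all(notes, ".//text()"))
  for (line in txt) {
    line <- trimws(line)
    m <- regmatches(line, regexec("^GENE[_ ]ASSOCIATION:\\s*(.*)$", line))[[1]]
    if (length(m) == 2 && nzchar(m[2])) out$gene_association <- m[2]
    m <- regmatches(line, regexec("^SUBSYSTEM:\\s*(.*)$", line))[[1]]
    if (length(m) == 2 && nzchar(m[2])) out$subsystem <- m[2]
  }
  out
}

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

# deterministic SId-safe alias for a gene identifier
geneSId <- function(gene_ids) {
  sid <- paste0("G_", gsub("[^A-Za-z0-9_]", "_", gene_ids))
  make.unique(sid, sep = "_")
}

fmtNum <- function(x) {
  # shortest representation that round-trips a double
  vapply(x, function(v) format(v, digits = 15, scientific = FALSE, trim = TRUE),
         character(1))
}

gprToFbcXml <- function(node, sid_of, indent) {
  pad <- strrep(" ", indent)
  if (node$kind == "GENE") {
    return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="%s"/>',
                   pad, xmlEscape(sid_of[[node$gene_id]])))
  }
  tag <- if (node$kind == "AND") "fbc:and" else "fbc:or"
  inner <- vapply(node$children, gprToFbcXml, character(1),
                  sid_of = sid_of, indent = indent + 2)
  paste0(pad, "<", tag, ">\n", paste(inner, collapse = "\n"),
         "\n", pad, "</", tag, ">")
}

#' Write a model as SBML Level 3 Version 1
#'
#' Serializes a [MetabolicModel-class] as an SBML L3V1 document with the fbc
#' version-2 package carrying GPR associations and flux bounds, and the
#' groups version-1 package carrying subsystem labels. Reaction, metabolite,
#' compartment and subsystem identifiers are written verbatim; gene
#' identifiers are written verbatim as fbc labels with SId-safe aliases as
#' fbc ids. Flux bounds are wide-open defaults (the document describes
#' network structure, not a calibrated simulation).
#'
#' Reading the file back with [readModelSBML()] reproduces id sets, GPR tree
#' structure and subsystem labels.
#'
#' @param model a [MetabolicModel-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeModelSBML <- function(model, path) {
  validObject(model)
  rxn <- model@reactions
  met <- model@metabolites
  genes <- model@genes
  sid_of <- stats::setNames(geneSId(genes), genes)

  L <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'xmlns:groups="http://www.sbml.org/sbml/level3/version1/groups/version1" ',
           'level="3" version="1" fbc:required="false" groups:required="false">'),
    sprintf('  <model id="%s" fbc:strict="false">', xmlEscape(model@id)),
    '    <listOfParameters>',
    '      <parameter id="default_lb" value="-1000" constant="true"/>',
    '      <parameter id="default_ub" value="1000" constant="true"/>',
    '      <parameter id="zero_bound" value="0" constant="true"/>',
    '    </listOfParameters>'
  )

  if (length(model@compartments)) {
    L <- c(L, '    <listOfCompartments>',
           sprintf('      <compartment id="%s" name="%s" constant="true"/>',
                   xmlEscape(names(model@compartments)),
                   xmlEscape(unname(model@compartments))),
           '    </listOfCompartments>')
  }
  if (nrow(met)) {
    L <- c(L, '    <listOfSpecies>',
           sprintf(paste0('      <species id="%s" name="%s" compartment="%s" ',
                          'boundaryCondition="%s" hasOnlySubstanceUnits="false" constant="false"/>'),
                   xmlEscape(met$id), xmlEscape(met$name), xmlEscape(met$compartment),
                   ifelse(met$boundary, "true", "false")),
           '    </listOfSpecies>')
  }
  if (length(genes)) {
    L <- c(L, '    <fbc:listOfGeneProducts>',
           sprintf('      <fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
                   xmlEscape(unname(sid_of)), xmlEscape(genes)),
           '    </fbc:listOfGeneProducts>')
  }

  L <- c(L, '    <listOfReactions>')
  for (j in seq_len(nrow(rxn))) {
    sj <- reactionStoichiometry(model, j)
    lb <- if (rxn$reversible[j]) "default_lb" else "zero_bound"
    L <- c(L, sprintf(paste0('      <reaction id="%s" name="%s" reversible="%s" ',
                             'fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="default_ub">'),
                      xmlEscape(rxn$id[j]), xmlEscape(rxn$name[j]),
                      ifelse(rxn$reversible[j], "true", "false"), lb))
    subs <- names(sj)[sj < 0]; prods <- names(sj)[sj > 0]
    if (length(subs)) {
      L <- c(L, '        <listOfReactants>',
             sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                     xmlEscape(subs), fmtNum(-unname(sj[subs]))),
             '        </listOfReactants>')
    }
    if (length(prods)) {
      L <- c(L, '        <listOfProducts>',
             sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                     xmlEscape(prods), fmtNum(unname(sj[prods]))),
             '        </listOfProducts>')
    }
    if (!is.null(model@gpr[[j]])) {
      L <- c(L, '        <fbc:geneProductAssociation>',
             gprToFbcXml(model@gpr[[j]], sid_of, 10),
             '        </fbc:geneProductAssociation>')
    }
    L <- c(L, '      </reaction>')
  }
  L <- c(L, '    </listOfReactions>')

  labels <- unique(unlist(rxn$subsystem))
  if (length(labels)) {
    L <- c(L, '    <groups:listOfGroups>')
    for (k in seq_along(labels)) {
      members <- rxn$id[vapply(rxn$subsystem, function(s) labels[k] %in% s, logical(1))]
      L <- c(L, sprintf('      <groups:group groups:id="subsystem_%d" groups:kind="partonomy" groups:name="%s">',
                        k, xmlEscape(labels[k])),
             '        <groups:listOfMembers>',
             sprintf('          <groups:member groups:idRef="%s"/>', xmlEscape(members)),
             '        </groups:listOfMembers>',
             '      </groups:group>')
    }
    L <- c(L, '    </groups:listOfGroups>')
  }
  L <- c(L, '  </model>', '</sbml>')
  writeLinesAtomic(L, path)
  invisible(path)
}

# write lines to a temp file in the destination directory, then rename
writeLinesAtomic <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) stop("cannot write ", path, call. = FALSE)
  invisible(path)
}
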