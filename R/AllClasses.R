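#' @import methods
#' @importFrom Matrix sparseMatrix Matrix
NULL

#' MetabolicModel: a genome-scale metabolic model
#'
#' Container for a constraint-based metabolic reconstruction: reactions,
#' metabolites, genes, compartments, the stoichiometric matrix, and per-reaction
#' gene-protein-reaction (GPR) rules and subsystem labels. Reaction order is
#' stable and defines the index space addressed by EFM files.
#'
#' @slot id model identifier.
#' @slot reactions `data.frame` with columns `id`, `name`, `reversible`
#'   (logical), `subsystem` (list column: zero or more labels per reaction),
#'   and optionally `orig_index` (set on submodels: the reaction's index in
#'   the parent model).
#' @slot metabolites `data.frame` with columns `id`, `name`, `compartment`,
#'   `boundary` (logical; boundary species are excluded from steady-state
#'   balance checks).
#' @slot genes character vector of gene identifiers; a superset of all genes
#'   referenced in GPR rules.
#' @slot compartments named character vector (id -> display name).
#' @slot stoichiometry sparse metabolites x reactions matrix of signed
#'   coefficients (negative = consumed, positive = produced).
#' @slot gpr list, one entry per reaction: a GPR tree (see [gprGene()]) or
#'   `NULL` when the reaction has no gene association.
#'
#' @seealso [readModelSBML()], [stoichiometricMatrix()], [extractSubmodel()]
#' @export
setClass("MetabolicModel",
  representation(
    id = "character",
    reactions = "data.frame",
    metabolites = "data.frame",
    genes = "character",
    compartments = "character",
    stoichiometry = "Matrix",
    gpr = "list"
  )
)

setValidity("MetabolicModel", function(object) {
  msgs <- character()
  rxn <- object@reactions
  met <- object@metabolites
  need_r <- c("id", "name", "reversible", "subsystem")
  need_m <- c("id", "name", "compartment", "boundary")
  if (!all(need_r %in% names(rxn))) {
    return(sprintf("reactions must have columns %s", paste(need_r, collapse = ", ")))
  }
  if (!all(need_m %in% names(met))) {
    return(sprintf("metabolites must have columns %s", paste(need_m, collapse = ", ")))
  }
  if (anyDuplicated(rxn$id)) {
    msgs <- c(msgs, sprintf("duplicate reaction id: %s",
                            paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", ")))
  }
  if (anyDuplicated(met$id)) {
    msgs <- c(msgs, sprintf("duplicate metabolite id: %s",
                            paste(unique(met$id[duplicated(met$id)]), collapse = ", ")))
  }
  if (any(!nzchar(rxn$id)) || any(!nzchar(met$id))) {
    msgs <- c(msgs, "empty identifier")
  }
  bad_comp <- setdiff(met$compartment, names(object@compartments))
  if (length(bad_comp)) {
    msgs <- c(msgs, sprintf("metabolite compartment not declared: %s",
                            paste(bad_comp, collapse = ", ")))
  }
  if (length(object@gpr) != nrow(rxn)) {
    msgs <- c(msgs, "gpr list length must equal reaction count")
  } else {
    gpr_genes <- unique(unlist(lapply(object@gpr, gprGenes)))
    missing_g <- setdiff(gpr_genes, object@genes)
    if (length(missing_g)) {
      msgs <- c(msgs, sprintf("GPR references undeclared gene: %s",
                              paste(missing_g, collapse = ", ")))
    }
  }
  S <- object@stoichiometry
  if (!all(dim(S) == c(nrow(met), nrow(rxn)))) {
    msgs <- c(msgs, "stoichiometry dimensions must be metabolites x reactions")
  }
  if (length(msgs)) msgs else TRUE
})

#' EfmSet: an ordered collection of elementary flux modes
#'
#' Each EFM is a set of 1-based reaction indices into a model's reaction list,
#' optionally carrying the relative flux of each active reaction. EFM ids are
#' the row numbers of the source file and survive filtering, so a selected
#' mode can always be traced back to its original row.
#'
#' @slot efms list of sorted integer vectors (active reaction indices).
#' @slot fluxes list parallel to `efms`: named numeric vector per EFM
#'   (names = reaction indices) or `NULL` when fluxes were not supplied.
#' @slot efmIds integer vector of original EFM ids (1-based row numbers).
#' @slot nReactions size of the model index space the indices address.
#' @slot modelRef identifier of the model the indices refer to.
#'
#' @seealso [parseEfmFile()], [filterEfmsByReaction()], [computeYields()]
#' @export
setClass("EfmSet",
  representation(
    efms = "list",
    fluxes = "list",
    efmIds = "integer",
    nReactions = "integer",
    modelRef = "character"
  )
)

setValidity("EfmSet", function(object) {
  n <- length(object@efms)
  if (length(object@fluxes) != n || length(object@efmIds) != n) {
    return("efms, fluxes and efmIds must have equal length")
  }
  if (anyDuplicated(object@efmIds)) return("efm ids must be unique")
  nr <- object@nReactions
  for (i in seq_len(n)) {
    idx <- object@efms[[i]]
    if (length(idx) == 0L) {
      return(sprintf("EFM %d is empty", object@efmIds[i]))
    }
    if (any(idx < 1L | idx > nr)) {
      return(sprintf("EFM %d has reaction index outside 1..%d", object@efmIds[i], nr))
    }
    if (anyDuplicated(idx)) {
      return(sprintf("EFM %d has duplicate reaction indices", object@efmIds[i]))
    }
    fl <- object@fluxes[[i]]
    if (!is.null(fl)) {
      if (!setequal(as.integer(names(fl)), idx)) {
        return(sprintf("EFM %d: flux keys do not match active reactions", object@efmIds[i]))
      }
      if (any(fl == 0) || any(!is.finite(fl))) {
        return(sprintf("EFM %d: fluxes must be finite and nonzero", object@efmIds[i]))
      }
    }
  }
  TRUE
})

#' AnnotatedGraph: a typed metabolic network ready for export
#'
#' Bipartite metabolite-reaction network, optionally extended with gene nodes,
#' carrying the attributes visualization styles bind to (compartment,
#' subsystem, occurrence percentage, differential-expression statistics,
#' per-edge stoichiometry and flux).
#'
#' Node types are `metabolite`, `reaction`, `gene`; node ids are namespaced
#' with `m:`, `r:`, `g:` prefixes so a gene and a metabolite sharing an SBML
#' id cannot collide in flat graph formats. Edge types are `substrate`
#' (metabolite -> reaction), `product` (reaction -> metabolite) and
#' `catalysis` (gene -> reaction).
#'
#' @slot nodes `data.frame`: `id`, `type`, `label`, `compartment`,
#'   `subsystem`, `index` (reaction nodes: model reaction index),
#'   `is_exchange`, `reversible`, `occurrence_pct`, `log2_fc`, `p_value`,
#'   `no_data`.
#' @slot edges `data.frame`: `source`, `target`, `type`, `stoichiometry`,
#'   `flux`.
#'
#' @seealso [buildGraph()], [writeGraph()]
#' @export
setClass("AnnotatedGraph",
  representation(nodes = "data.frame", edges = "data.frame")
)

setValidity("AnnotatedGraph", function(object) {
  nd <- object@nodes
  ed <- object@edges
  if (nrow(ed)) {
    missing_ref <- setdiff(c(ed$source, ed$target), nd$id)
    if (length(missing_ref)) {
      return(sprintf("edge references missing node: %s",
                     paste(utils::head(missing_ref, 3), collapse = ", ")))
    }
    type_of <- stats::setNames(nd$type, nd$id)
    bad <- !((ed$type == "substrate" & type_of[ed$source] == "metabolite" &
                type_of[ed$target] == "reaction") |
             (ed$type == "product" & type_of[ed$source] == "reaction" &
                type_of[ed$target] == "metabolite") |
             (ed$type == "catalysis" & type_of[ed$source] == "gene" &
                type_of[ed$target] == "reaction"))
    if (any(bad)) return("edge endpoint types inconsistent with edge type")
  }
  if (anyDuplicated(nd$id)) return("duplicate node id")
  TRUE
})
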