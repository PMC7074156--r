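#' Construct a MetabolicModel
#'
#' Low-level constructor assembling a model from per-reaction descriptions.
#' Most users will read models from SBML with [readModelSBML()]; this
#' constructor is the programmatic route used by the fixture generator and
#' by tests.
#'
#' @param id model identifier.
#' @param reactions `data.frame` with columns `id`, and optionally `name`,
#'   `reversible`, `subsystem` (character or list column).
#' @param metabolites `data.frame` with columns `id`, and optionally `name`,
#'   `compartment`, `boundary`.
#' @param stoichiometry list parallel to `reactions`: named numeric vectors
#'   (metabolite id -> signed coefficient), or a metabolites x reactions
#'   matrix.
#' @param gpr list parallel to `reactions`: GPR nodes (or rule strings,
#'   parsed with [parseGpr()]) or `NULL`.
#' @param genes character vector of gene ids; defaults to the union of genes
#'   referenced by `gpr`.
#' @param compartments named character vector of compartment names; defaults
#'   to the compartments used by `metabolites`.
#' @return a [MetabolicModel-class] object.
#' @export
MetabolicModel <- function(id, reactions, metabolites, stoichiometry,
                           gpr = NULL, genes = NULL, compartments = NULL) {
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  nr <- nrow(reactions)
  nm <- nrow(metabolites)
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$reversible)) reactions$reversible <- rep(FALSE, nr)
  if (is.null(reactions$subsystem)) {
    reactions$subsystem <- I(rep(list(character()), nr))
  } else if (!is.list(reactions$subsystem)) {
    reactions$subsystem <- I(lapply(reactions$subsystem, function(s) {
      if (is.na(s) || !nzchar(s)) character() else s
    }))
  }
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment)) metabolites$compartment <- rep("c", nm)
  if (is.null(metabolites$boundary)) metabolites$boundary <- rep(FALSE, nm)

  if (is.null(gpr)) gpr <- rep(list(NULL), nr)
  gpr <- lapply(gpr, function(g) if (is.character(g)) parseGpr(g) else g)
  if (length(gpr) != nr) stop("gpr must have one entry per reaction")

  if (is.list(stoichiometry) && !is.data.frame(stoichiometry)) {
    if (length(stoichiometry) != nr) {
      stop("stoichiometry list must have one entry per reaction")
    }
    ii <- integer(); jj <- integer(); xx <- numeric()
    for (j in seq_len(nr)) {
      sj <- stoichiometry[[j]]
      if (length(sj) == 0L) next
      pos <- match(names(sj), metabolites$id)
      if (anyNA(pos)) {
        stop("reaction ", reactions$id[j], " references unknown metabolite: ",
             paste(names(sj)[is.na(pos)], collapse = ", "))
      }
      if (any(!is.finite(sj)) || any(sj == 0)) {
        stop("reaction ", reactions$id[j], " has non-finite or zero coefficient")
      }
      ii <- c(ii, pos); jj <- c(jj, rep(j, length(sj))); xx <- c(xx, unname(sj))
    }
    S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nm, nr),
                              dimnames = list(metabolites$id, reactions$id))
  } else {
    S <- Matrix::Matrix(stoichiometry, sparse = TRUE)
    dimnames(S) <- list(metabolites$id, reactions$id)
  }

  if (is.null(genes)) genes <- unique(unlist(lapply(gpr, gprGenes)))
  if (is.null(genes)) genes <- character()
  if (is.null(compartments)) {
    cc <- unique(metabolites$compartment)
    compartments <- stats::setNames(cc, cc)
  }
  new("MetabolicModel", id = id, reactions = reactions,
      metabolites = metabolites, genes = as.character(genes),
      compartments = compartments, stoichiometry = S, gpr = gpr)
}

#' Model accessors
#'
#' Accessor generics for [MetabolicModel-class]: reaction/metabolite/gene
#' identifiers and counts, GPR rules, subsystem labels and the reaction and
#' metabolite annotation tables.
#'
#' @param object a `MetabolicModel`.
#' @return `reactionIds`, `metaboliteIds`, `geneIds`: character vectors;
#'   `nReactions`, `nMetabolites`, `nGenes`: integer counts; `gprRules`:
#'   list of GPR nodes (or `NULL`s); `subsystems`: list of character vectors,
#'   one per reaction; `reactionTable`, `metaboliteTable`: `data.frame`s.
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))
#' @rdname model-accessors
#' @export
setGeneric("metaboliteIds", function(object) standardGeneric("metaboliteIds"))
#' @rdname model-accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))
#' @rdname model-accessors
#' @export
setGeneric("nReactions", function(object) standardGeneric("nReactions"))
#' @rdname model-accessors
#' @export
setGeneric("nMetabolites", function(object) standardGeneric("nMetabolites"))
#' @rdname model-accessors
#' @export
setGeneric("nGenes", function(object) standardGeneric("nGenes"))
#' @rdname model-accessors
#' @export
setGeneric("gprRules", function(object) standardGeneric("gprRules"))
#' @rdname model-accessors
#' @export
setGeneric("subsystems", function(object) standardGeneric("subsystems"))
#' @rdname model-accessors
#' @export
setGeneric("reactionTable", function(object) standardGeneric("reactionTable"))
#' @rdname model-accessors
#' @export
setGeneric("metaboliteTable", function(object) standardGeneric("metaboliteTable"))

#' @rdname model-accessors
setMethod("reactionIds", "MetabolicModel", function(object) object@reactions$id)
#' @rdname model-accessors
setMethod("metaboliteIds", "MetabolicModel", function(object) object@metabolites$id)
#' @rdname model-accessors
setMethod("geneIds", "MetabolicModel", function(object) object@genes)
#' @rdname model-accessors
setMethod("nReactions", "MetabolicModel", function(object) nrow(object@reactions))
#' @rdname model-accessors
setMethod("nMetabolites", "MetabolicModel", function(object) nrow(object@metabolites))
#' @rdname model-accessors
setMethod("nGenes", "MetabolicModel", function(object) length(object@genes))
#' @rdname model-accessors
setMethod("gprRules", "MetabolicModel", function(object) object@gpr)
#' @rdname model-accessors
setMethod("subsystems", "MetabolicModel", function(object) {
  stats::setNames(as.list(object@reactions$subsystem), object@reactions$id)
})
#' @rdname model-accessors
setMethod("reactionTable", "MetabolicModel", function(object) object@reactions)
#' @rdname model-accessors
setMethod("metaboliteTable", "MetabolicModel", function(object) object@metabolites)

#' Stoichiometric matrix of a model
#'
#' Returns the sparse metabolites x reactions matrix S of signed
#' coefficients: entry (i, j) is the coefficient of metabolite i in reaction
#' j (negative = consumed, positive = produced), zero elsewhere. Row and
#' column order match the model's metabolite and reaction order, so `S %*% v`
#' for a full-length flux vector v gives the net production rate of every
#' species.
#'
#' @param object a [MetabolicModel-class].
#' @return a `dgCMatrix` with dimnames (metabolite ids, reaction ids).
#' @export
setGeneric("stoichiometricMatrix", function(object) standardGeneric("stoichiometricMatrix"))

#' @rdname stoichiometricMatrix
setMethod("stoichiometricMatrix", "MetabolicModel", function(object) {
  object@stoichiometry
})

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel:", object@id, "\n")
  cat(sprintf("  %d reactions, %d metabolites, %d genes, %d compartments\n",
              nReactions(object), nMetabolites(object), nGenes(object),
              length(object@compartments)))
  n_gpr <- sum(!vapply(object@gpr, is.null, logical(1)))
  n_sub <- sum(lengths(object@reactions$subsystem) > 0)
  cat(sprintf("  GPR rules on %d reactions; subsystem labels on %d\n",
              n_gpr, n_sub))
  invisible(object)
})

# Named stoichiometry of one reaction (metabolite id -> coefficient).
reactionStoichiometry <- function(model, j) {
  col <- model@stoichiometry[, j]
  col[col != 0]
}
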