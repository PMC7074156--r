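#' Default ubiquitous (currency) metabolites
#'
#' Highly connected currency species clutter network views: ATP/ADP/AMP,
#' phosphate, protons, water, CO2, O2, the NAD(P)(H) couples and CoA
#' participate in so many reactions that their edges obscure the pathway
#' structure. The package ships a default base-name list
#' (`inst/extdata/ubiquitous_metabolites.txt`, one base id per line, `#`
#' comments); `defaultUbiquitousIds()` expands it per compartment with the
#' common `<base>_<compartment>` id convention and intersects with the
#' model's metabolites. Fully overridable: pass any id vector to
#' [extractSubmodel()] instead.
#'
#' @param model a [MetabolicModel-class].
#' @param path optional path to an alternative base-name list.
#' @return character vector of metabolite ids present in the model.
#' @export
defaultUbiquitousIds <- function(model, path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ubiquitous_metabolites.txt",
                        package = "efmtools", mustWork = TRUE)
  }
  base <- readUbiquitousList(path)
  comps <- names(model@compartments)
  cand <- c(outer(base, comps, function(b, co) paste0(b, "_", co)))
  intersect(metaboliteIds(model), cand)
}

#' @rdname defaultUbiquitousIds
#' @export
readUbiquitousList <- function(path) {
  if (!file.exists(path)) stop("ubiquitous list not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- sub("#.*$", "", lines)
  trimws(lines[nzchar(trimws(lines))])
}

#' Extract one EFM as a standalone submodel
#'
#' Restricts a model to exactly the reactions of one EFM: the remaining
#' reactions are removed, along with any metabolites and genes left
#' unconnected, giving a standalone model of that mode's pathway. Metabolites
#' on the ubiquitous list are additionally removed from the retained
#' reactions' participant sets (their stoichiometric entries are dropped)
#' to declutter downstream visualization; reactions are never removed by
#' ubiquitous stripping, even when left with no participants, because the
#' reaction nodes carry the flux annotations mapped later. GPR trees are
#' kept whole.
#'
#' The submodel's reaction table carries an `orig_index` column recording
#' each reaction's index in the parent model, so fluxes keyed by model index
#' can still be mapped after extraction.
#'
#' @param model a [MetabolicModel-class].
#' @param efms an [EfmSet-class] over `model`'s index space.
#' @param id the EFM id to extract.
#' @param ubiquitous character vector of metabolite ids to strip (empty
#'   default; see [defaultUbiquitousIds()]).
#' @param protected metabolite ids that must never be stripped (e.g. the
#'   mode's designated substrate and product); requesting their removal is
#'   an error.
#' @return a [MetabolicModel-class] with id `<model_id>_EFM<id>`.
#' @export
extractSubmodel <- function(model, efms, id, ubiquitous = character(),
                            protected = character()) {
  idx <- efmReactionIndices(efms, id)
  if (!length(idx)) stop("empty EFM", call. = FALSE)
  if (any(idx > nReactions(model))) {
    stop("EFM indices exceed model reaction count", call. = FALSE)
  }
  clash <- intersect(ubiquitous, protected)
  if (length(clash)) {
    stop("protected metabolite(s) on the ubiquitous removal list: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  rxn <- model@reactions[idx, , drop = FALSE]
  rxn$orig_index <- idx
  rownames(rxn) <- NULL
  gpr <- model@gpr[idx]
  stoich <- lapply(idx, function(j) {
    sj <- reactionStoichiometry(model, j)
    sj[setdiff(names(sj), ubiquitous)]
  })
  used_mets <- unique(unlist(lapply(stoich, names)))
  met <- model@metabolites[model@metabolites$id %in% used_mets, , drop = FALSE]
  rownames(met) <- NULL
  genes <- unique(unlist(lapply(gpr, gprGenes)))
  comps <- model@compartments[names(model@compartments) %in% met$compartment]
  MetabolicModel(id = sprintf("%s_EFM%d", model@id, as.integer(id)),
                 reactions = rxn, metabolites = met, stoichiometry = stoich,
                 gpr = gpr, genes = genes, compartments = comps)
}

#' @rdname writeModelSBML
#' @export
writeSubmodelSBML <- writeModelSBML
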