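#' Construct an EfmSet
#'
#' @param efms list of integer vectors of active reaction indices (1-based).
#' @param nReactions size of the model's reaction index space.
#' @param fluxes optional list parallel to `efms`: numeric vectors named by
#'   reaction index, or `NULL` per EFM.
#' @param efmIds original EFM ids; defaults to `seq_along(efms)`.
#' @param modelRef identifier of the model the indices address.
#' @return an [EfmSet-class].
#' @export
EfmSet <- function(efms, nReactions, fluxes = NULL, efmIds = NULL,
                   modelRef = NA_character_) {
  efms <- lapply(efms, function(x) sort(as.integer(x)))
  if (is.null(fluxes)) fluxes <- rep(list(NULL), length(efms))
  if (is.null(efmIds)) efmIds <- seq_along(efms)
  new("EfmSet", efms = efms, fluxes = fluxes, efmIds = as.integer(efmIds),
      nReactions = as.integer(nReactions), modelRef = modelRef)
}

#' EfmSet accessors
#'
#' @param object,x an `EfmSet`.
#' @param id an EFM id (as assigned at parse time, i.e. source-file row).
#' @param i index vector for subsetting (positional, logical, or negative).
#' @param j,drop,... ignored (matrix-style subsetting is not supported).
#' @return `efmCount`: number of EFMs; `efmIds`: their ids;
#'   `efmReactionIndices`: sorted integer vector of the EFM's active
#'   reactions; `efmRelativeFluxes`: named numeric vector (names = reaction
#'   indices) or `NULL`; `hasFluxes`: logical, TRUE when every EFM carries
#'   fluxes. `[` returns a subset `EfmSet` preserving ids and order.
#' @name efmset-accessors
NULL

#' @rdname efmset-accessors
#' @export
setGeneric("efmCount", function(object) standardGeneric("efmCount"))
#' @rdname efmset-accessors
#' @export
setGeneric("efmIds", function(object) standardGeneric("efmIds"))
#' @rdname efmset-accessors
#' @export
setGeneric("efmReactionIndices", function(object, id) standardGeneric("efmReactionIndices"))
#' @rdname efmset-accessors
#' @export
setGeneric("efmRelativeFluxes", function(object, id) standardGeneric("efmRelativeFluxes"))
#' @rdname efmset-accessors
#' @export
setGeneric("hasFluxes", function(object) standardGeneric("hasFluxes"))

#' @rdname efmset-accessors
setMethod("efmCount", "EfmSet", function(object) length(object@efms))
#' @rdname efmset-accessors
setMethod("efmIds", "EfmSet", function(object) object@efmIds)
#' @rdname efmset-accessors
setMethod("efmReactionIndices", "EfmSet", function(object, id) {
  object@efms[[efmPosition(object, id)]]
})
#' @rdname efmset-accessors
setMethod("efmRelativeFluxes", "EfmSet", function(object, id) {
  object@fluxes[[efmPosition(object, id)]]
})
#' @rdname efmset-accessors
setMethod("hasFluxes", "EfmSet", function(object) {
  length(object@fluxes) > 0 && !any(vapply(object@fluxes, is.null, logical(1)))
})

#' @rdname efmset-accessors
setMethod("length", "EfmSet", function(x) length(x@efms))

#' @rdname efmset-accessors
setMethod("[", "EfmSet", function(x, i, j, ..., drop = TRUE) {
  pos <- seq_along(x@efms)[i]
  new("EfmSet", efms = x@efms[pos], fluxes = x@fluxes[pos],
      efmIds = x@efmIds[pos], nReactions = x@nReactions, modelRef = x@modelRef)
})

setMethod("show", "EfmSet", function(object) {
  cat(sprintf("EfmSet: %d EFMs over %d reactions", length(object), object@nReactions))
  if (!is.na(object@modelRef)) cat(" (model ", object@modelRef, ")", sep = "")
  cat("\n")
  if (length(object)) {
    len <- lengths(object@efms)
    cat(sprintf("  EFM length: min %d, median %g, max %d\n",
                min(len), stats::median(len), max(len)))
    cat(sprintf("  relative fluxes: %s\n",
                if (hasFluxes(object)) "present" else "absent"))
  }
  invisible(object)
})

efmPosition <- function(efms, id) {
  pos <- match(as.integer(id), efms@efmIds)
  if (is.na(pos)) stop("no EFM with id ", id, call. = FALSE)
  pos
}

#' Parse an EFM file
#'
#' Reads the conventional exchange format for computed elementary flux modes:
#' plain text, one EFM per line, whitespace-separated integer indices of the
#' reactions active in that mode. Blank lines are skipped; any run of spaces
#' or tabs is one delimiter. Indices are normalized to the package's 1-based
#' internal convention; duplicated indices within a row are collapsed with a
#' warning.
#'
#' @param path path to the EFM file.
#' @param nReactions number of reactions in the model (index space bound).
#' @param indexBase base of the indices in the file: `1` (MATLAB/COBRA
#'   heritage, default) or `0`.
#' @param modelRef optional model identifier recorded on the result.
#' @return an [EfmSet-class] (without fluxes; see [parseFluxFile()]).
#' @export
parseEfmFile <- function(path, nReactions, indexBase = 1, modelRef = NA_character_) {
  stopifnot(nReactions >= 1, indexBase %in% c(0, 1))
  if (!file.exists(path)) stop("EFM file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  rows <- which(keep)
  efms <- vector("list", length(rows))
  for (k in seq_along(rows)) {
    toks <- strsplit(trimws(lines[rows[k]]), "[ \t]+")[[1]]
    bad <- !grepl("^[0-9]+$", toks)
    if (any(bad)) {
      stop(sprintf("EFM parse error at row %d, column %d: token '%s' is not a nonnegative integer",
                   rows[k], which(bad)[1], toks[which(bad)[1]]), call. = FALSE)
    }
    idx <- as.integer(toks) + (1L - as.integer(indexBase))
    if (anyDuplicated(idx)) {
      warning(sprintf("EFM row %d: duplicate reaction indices collapsed", rows[k]),
              call. = FALSE)
      idx <- unique(idx)
    }
    if (any(idx < 1L | idx > nReactions)) {
      off <- idx[idx < 1L | idx > nReactions][1]
      stop(sprintf("EFM validation error at row %d: reaction index %d outside 1..%d",
                   rows[k], off, nReactions), call. = FALSE)
    }
    efms[[k]] <- idx
  }
  EfmSet(efms, nReactions = nReactions, modelRef = modelRef)
}

#' Parse a relative-flux file aligned to an EFM set
#'
#' Flux files mirror the EFM file: one row per EFM. The compact form carries
#' one value per active reaction, in the same token order as the EFM file
#' row; a full-length row (one value per model reaction) is detected by its
#' width and accepted, requiring zeros exactly off the active set.
#'
#' @param path path to the flux file.
#' @param efms the [EfmSet-class] the rows align to.
#' @return the `EfmSet` with relative fluxes populated.
#' @export
parseFluxFile <- function(path, efms) {
  if (!file.exists(path)) stop("flux file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != length(efms)) {
    stop(sprintf("flux alignment error: %d flux rows for %d EFMs",
                 length(lines), length(efms)), call. = FALSE)
  }
  fluxes <- vector("list", length(efms))
  nr <- efms@nReactions
  for (k in seq_along(lines)) {
    id <- efms@efmIds[k]
    toks <- strsplit(trimws(lines[k]), "[ \t]+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) {
      stop(sprintf("flux parse error for EFM %d: token '%s' is not a number",
                   id, toks[which(is.na(vals))[1]]), call. = FALSE)
    }
    # EFM files list indices in arbitrary order but the EfmSet stores them
    # sorted; flux rows written by the same tool follow ascending index order.
    idx <- efms@efms[[k]]
    if (length(vals) == length(idx)) {
      fl <- stats::setNames(vals, idx)
    } else if (length(vals) == nr) {
      fl <- stats::setNames(vals[idx], idx)
      off <- setdiff(seq_len(nr), idx)
      if (any(vals[off] != 0)) {
        stop(sprintf("flux alignment error for EFM %d: nonzero flux on inactive reaction %d",
                     id, off[which(vals[off] != 0)[1]]), call. = FALSE)
      }
    } else {
      stop(sprintf("flux alignment error for EFM %d: %d values for %d active reactions",
                   id, length(vals), length(idx)), call. = FALSE)
    }
    if (any(fl == 0)) {
      stop(sprintf("flux validation error for EFM %d: zero flux for active reaction %s",
                   id, names(fl)[which(fl == 0)[1]]), call. = FALSE)
    }
    fluxes[[k]] <- fl
  }
  new("EfmSet", efms = efms@efms, fluxes = fluxes, efmIds = efms@efmIds,
      nReactions = efms@nReactions, modelRef = efms@modelRef)
}

#' Write EFM and flux files
#'
#' Serializes an [EfmSet-class] back to the plain-text exchange formats read
#' by [parseEfmFile()] and [parseFluxFile()]: active reaction indices in
#' ascending order, and (for `writeFluxFile`) the matching relative fluxes
#' in the same token order.
#'
#' @param efms an [EfmSet-class].
#' @param path output file path.
#' @param indexBase base to write indices in (default 1).
#' @return the path, invisibly.
#' @export
writeEfmFile <- function(efms, path, indexBase = 1) {
  stopifnot(indexBase %in% c(0, 1))
  shift <- as.integer(indexBase) - 1L
  lines <- vapply(efms@efms, function(idx) paste(idx + shift, collapse = " "),
                  character(1))
  writeLinesAtomic(lines, path)
}

#' @rdname writeEfmFile
#' @export
writeFluxFile <- function(efms, path) {
  if (!hasFluxes(efms)) stop("EfmSet carries no relative fluxes", call. = FALSE)
  lines <- mapply(function(idx, fl) {
    paste(fmtNum(unname(fl[as.character(idx)])), collapse = " ")
  }, efms@efms, efms@fluxes)
  writeLinesAtomic(as.character(lines), path)
}
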