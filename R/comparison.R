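#' Subsystem occurrence across EFMs
#'
#' For each EFM, the distribution of its reactions across the model's
#' subsystem (pathway) labels: entry (e, s) is the fraction of EFM e's
#' reactions assigned to subsystem s. Reactions without a label are pooled
#' under the reserved label `"(unassigned)"`; a reaction carrying m labels
#' contributes 1/m to each, so every row sums to 1 exactly.
#'
#' @param model a [MetabolicModel-class] with subsystem annotations.
#' @param efms a non-empty [EfmSet-class].
#' @return list with `occurrence` (matrix, rows = EFM ids as
#'   `"EFM<id>"`, columns = the union of subsystems occurring in any EFM)
#'   and `reaction_count` (named integer vector per EFM).
#' @export
subsystemOccurrence <- function(model, efms) {
  if (length(efms) == 0L) stop("empty EfmSet", call. = FALSE)
  labels_of <- lapply(model@reactions$subsystem, function(s) {
    if (length(s)) s else "(unassigned)"
  })
  cols <- unique(unlist(labels_of[sort(unique(unlist(efms@efms)))]))
  occ <- matrix(0, nrow = length(efms), ncol = length(cols),
                dimnames = list(paste0("EFM", efms@efmIds), cols))
  counts <- stats::setNames(lengths(efms@efms), paste0("EFM", efms@efmIds))
  for (i in seq_along(efms@efms)) {
    idx <- efms@efms[[i]]
    for (j in idx) {
      lab <- labels_of[[j]]
      occ[i, lab] <- occ[i, lab] + 1 / (length(lab) * length(idx))
    }
  }
  list(occurrence = occ, reaction_count = counts)
}

#' Backbone reactions of an EFM collection
#'
#' The backbone of a set of EFMs is the reactions present in more than a
#' chosen fraction of them — the conserved core structure. For every
#' reaction appearing in at least one EFM, the occurrence fraction
#' f_r = (#EFMs containing r) / (#EFMs) is computed; the backbone at cutoff
#' tau is `{r : f_r > tau}` (strict by default, mirroring "present in more
#' than" phrasing; set `strict = FALSE` for `>=`). Lowering tau can only
#' grow the backbone.
#'
#' @param efms a non-empty [EfmSet-class].
#' @param tau occurrence cutoff in `[0, 1)` (for `strict = FALSE`, `(0, 1]`
#'   is also allowed).
#' @param strict logical: `TRUE` selects `f_r > tau`, `FALSE` selects
#'   `f_r >= tau`.
#' @param bins histogram break points over (0, 1] for the occurrence
#'   distribution (right-closed bins).
#' @return list with `occurrence` (named numeric: f_r per reaction index,
#'   descending), `cutoff`, `strict`, `selected` (sorted integer vector of
#'   backbone reaction indices) and `histogram` (named integer: reactions
#'   per occurrence bin; sums to the size of the reaction union).
#' @export
extractBackbone <- function(efms, tau, strict = TRUE,
                            bins = seq(0, 1, by = 0.1)) {
  if (length(efms) == 0L) stop("empty EfmSet", call. = FALSE)
  if (strict && tau >= 1) {
    stop("tau must be < 1: no reaction can be present in more than 100% of EFMs",
         call. = FALSE)
  }
  if (tau < 0 || tau > 1) stop("tau must be in [0, 1]", call. = FALSE)
  tab <- table(unlist(efms@efms))
  f <- as.numeric(tab) / length(efms)
  names(f) <- names(tab)
  selected <- as.integer(names(f)[if (strict) f > tau else f >= tau])
  cut_bins <- cut(f, breaks = bins, right = TRUE)
  hist <- stats::setNames(as.integer(table(cut_bins)), levels(cut_bins))
  list(occurrence = sort(f, decreasing = TRUE), cutoff = tau, strict = strict,
       selected = sort(selected), histogram = hist)
}

#' Overlap between two EFMs
#'
#' Partitions the union of two EFMs' reaction sets into the shared reactions
#' and those exclusive to either mode.
#'
#' @param efms an [EfmSet-class].
#' @param a,b EFM ids (both addressing the same model index space).
#' @return list with sorted integer vectors `common`, `only_a`, `only_b`.
#' @export
efmOverlap <- function(efms, a, b) {
  ra <- efmReactionIndices(efms, a)
  rb <- efmReactionIndices(efms, b)
  list(common = sort(intersect(ra, rb)),
       only_a = sort(setdiff(ra, rb)),
       only_b = sort(setdiff(rb, ra)))
}
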