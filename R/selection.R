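#' Read a gene-statistics table
#'
#' Reads per-gene differential-expression summary statistics from a
#' delimited table with header columns `gene_id`, `p_value`, `log2_fc` and
#' (optionally) `expression`. The delimiter is taken from the file extension
#' (`.csv` = comma, else tab). `expression` is the nonnegative ranking value
#' used by min/max selection in GPR mapping; when absent, mapping can fall
#' back to `|log2_fc|` (see [mapGeneStatsToReactions()]).
#'
#' @param path path to a TSV/CSV file.
#' @return `data.frame` with columns `gene_id`, `p_value`, `log2_fc`,
#'   `expression` (`NA` when not supplied).
#' @export
readGeneStats <- function(path) {
  if (!file.exists(path)) stop("gene statistics file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "p_value", "log2_fc")
  if (!all(need %in% names(tab))) {
    stop("gene statistics table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"expression" %in% names(tab)) tab$expression <- NA_real_
  validateGeneStats(tab[, c("gene_id", "p_value", "log2_fc", "expression")])
}

validateGeneStats <- function(stats) {
  if (anyDuplicated(stats$gene_id)) {
    stop("duplicate gene_id in gene statistics: ",
         paste(unique(stats$gene_id[duplicated(stats$gene_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(stats$p_value < 0 | stats$p_value > 1, na.rm = TRUE)) {
    stop("gene statistics p_value outside [0, 1]", call. = FALSE)
  }
  stats
}

#' Filter EFMs by presence or absence of a reaction
#'
#' Retains the EFMs that contain (or exclude) a reaction of interest — e.g.
#' keep the glucose-uptake modes that also release a product. Original EFM
#' ids and order are preserved.
#'
#' @param efms an [EfmSet-class].
#' @param reactionIndex 1-based model reaction index.
#' @param mode `"contains"` (default) or `"excludes"`.
#' @return the filtered [EfmSet-class].
#' @export
filterEfmsByReaction <- function(efms, reactionIndex, mode = c("contains", "excludes")) {
  mode <- match.arg(mode)
  reactionIndex <- as.integer(reactionIndex)
  if (length(reactionIndex) != 1L || is.na(reactionIndex) ||
      reactionIndex < 1L || reactionIndex > efms@nReactions) {
    stop("reaction index outside 1..", efms@nReactions, call. = FALSE)
  }
  has <- vapply(efms@efms, function(idx) reactionIndex %in% idx, logical(1))
  efms[if (mode == "contains") has else !has]
}

#' Per-EFM product yield on a substrate
#'
#' For every EFM, the yield is the relative flux of the output (product
#' release) reaction divided by the relative flux of the input (substrate
#' uptake) reaction. Flux magnitudes are used, so the result is independent
#' of the sign convention of split forward/backward exchange reactions.
#' Yield is dimensionless when both fluxes share units
#' (e.g. mmol gDW^-1 h^-1).
#'
#' @param efms an [EfmSet-class] with relative fluxes; every EFM must
#'   contain both reactions.
#' @param inputRxn,outputRxn 1-based model reaction indices of the uptake
#'   and release reactions.
#' @return `data.frame` with columns `efm_id`, `input_flux`, `output_flux`,
#'   `yield`.
#' @export
computeYields <- function(efms, inputRxn, outputRxn) {
  inputRxn <- as.integer(inputRxn); outputRxn <- as.integer(outputRxn)
  missing_rxn <- efms@efmIds[!vapply(efms@efms, function(idx) {
    inputRxn %in% idx && outputRxn %in% idx
  }, logical(1))]
  if (length(missing_rxn)) {
    stop("EFM(s) missing input or output reaction: ",
         paste(missing_rxn, collapse = ", "), call. = FALSE)
  }
  if (!hasFluxes(efms)) {
    stop("EFMs carry no relative fluxes; parse a flux file first", call. = FALSE)
  }
  vin <- vapply(efms@fluxes, function(fl) abs(fl[[as.character(inputRxn)]]), numeric(1))
  vout <- vapply(efms@fluxes, function(fl) abs(fl[[as.character(outputRxn)]]), numeric(1))
  if (any(vin == 0)) {
    stop("zero input flux for EFM(s): ",
         paste(efms@efmIds[vin == 0], collapse = ", "), call. = FALSE)
  }
  data.frame(efm_id = efms@efmIds, input_flux = vin, output_flux = vout,
             yield = vout / vin)
}

#' Select the EFMs with extreme yield
#'
#' Returns all EFM ids attaining the minimum (or maximum) yield, within a
#' relative tolerance, ordered by ascending EFM length (number of active
#' reactions) and then ascending EFM id — so the first element is the
#' shortest EFM at that extreme.
#'
#' @param yields result of [computeYields()].
#' @param which `"min"` or `"max"`.
#' @param efms the [EfmSet-class] the yields came from (supplies lengths).
#' @param tol relative tolerance for tie detection at the extreme.
#' @return integer vector of EFM ids.
#' @export
selectExtremeYield <- function(yields, which = c("min", "max"), efms, tol = 1e-9) {
  which <- match.arg(which)
  if (!nrow(yields)) stop("empty yield table", call. = FALSE)
  y <- yields$yield
  ext <- if (which == "min") min(y) else max(y)
  hit <- abs(y - ext) <= tol * max(1, abs(ext))
  ids <- yields$efm_id[hit]
  len <- vapply(ids, function(id) length(efmReactionIndices(efms, id)), integer(1))
  ids[order(len, ids)]
}

#' Map gene-level statistics onto reactions through GPR rules
#'
#' Propagates per-gene differential-expression statistics to the reaction
#' level using each reaction's gene-protein-reaction rule: at an AND node
#' (enzyme complex) the record of the child with minimum ranking value is
#' taken (the limiting subunit); at an OR node (isozymes) the child with
#' maximum ranking value (the dominant isozyme). Genes without data are
#' ignored at both node kinds; a reaction whose whole tree lacks data is
#' flagged `coverage = FALSE`. Ties are broken by the first child in rule
#' order.
#'
#' @param model a [MetabolicModel-class].
#' @param stats gene statistics table (see [readGeneStats()]).
#' @param rankBy ranking value used for min/max selection: `"expression"`
#'   (default) or `"abs_log2_fc"` for tables without an expression column.
#' @return `data.frame` with one row per model reaction: `reaction_index`,
#'   `reaction_id`, `p_value`, `log2_fc`, `source_gene`, `coverage`.
#' @export
mapGeneStatsToReactions <- function(model, stats,
                                    rankBy = c("expression", "abs_log2_fc")) {
  rankBy <- match.arg(rankBy)
  stats <- validateGeneStats(stats)
  rank_val <- if (rankBy == "expression") stats$expression else abs(stats$log2_fc)
  if (rankBy == "expression" && all(is.na(rank_val))) {
    stop("gene statistics carry no expression values; use rankBy = \"abs_log2_fc\"",
         call. = FALSE)
  }
  keep <- !is.na(rank_val)
  records <- data.frame(p_value = stats$p_value[keep],
                        log2_fc = stats$log2_fc[keep],
                        rank = rank_val[keep],
                        row.names = stats$gene_id[keep])
  nr <- nReactions(model)
  out <- data.frame(reaction_index = seq_len(nr),
                    reaction_id = reactionIds(model),
                    p_value = NA_real_, log2_fc = NA_real_,
                    source_gene = NA_character_, coverage = FALSE)
  for (j in seq_len(nr)) {
    rec <- gprEvaluate(model@gpr[[j]], records)
    if (!is.null(rec)) {
      out$p_value[j] <- rec$p_value
      out$log2_fc[j] <- rec$log2_fc
      out$source_gene[j] <- rec$source_gene
      out$coverage[j] <- TRUE
    }
  }
  out
}

#' Over-representation of regulated reactions in each EFM
#'
#' Treats each EFM as a set of reactions and tests whether it contains more
#' significantly up- (or down-) regulated reactions than expected by chance.
#' A reaction is significant-up when it has mapped data, `p_value < sigP`
#' and `log2_fc > 0` (down: `< 0`). The test is the one-sided hypergeometric
#' upper tail P(X >= k) over mapped reactions only, with k = significant
#' reactions of the tested direction inside the EFM, n = mapped reactions
#' inside the EFM, K and N the corresponding background counts. Raw p-values
#' are Benjamini-Hochberg adjusted across all tested EFMs. EFMs with no
#' mapped reactions get p = 1.
#'
#' @param efms an [EfmSet-class] (non-empty).
#' @param rstats reaction statistics from [mapGeneStatsToReactions()].
#' @param direction `"up"` or `"down"`.
#' @param sigP reaction-level significance cutoff in (0, 1); default 0.05.
#' @param background integer vector of reaction indices to use as the
#'   background universe; defaults to all reactions with mapped data.
#' @return `data.frame` with one row per EFM: `efm_id`, `direction`, `k`,
#'   `n`, `K`, `N`, `p_raw`, `p_adjusted`.
#' @export
enrichEfms <- function(efms, rstats, direction = c("up", "down"),
                       sigP = 0.05, background = NULL) {
  direction <- match.arg(direction)
  stopifnot(sigP > 0, sigP < 1)
  if (length(efms) == 0L) stop("empty EfmSet", call. = FALSE)
  mapped <- rstats$reaction_index[rstats$coverage]
  if (is.null(background)) background <- mapped
  background <- unique(as.integer(background))
  if (length(setdiff(mapped[mapped %in% unlist(efms@efms)], background))) {
    stop("background must contain every mapped reaction under test", call. = FALSE)
  }
  sig <- rstats$coverage & !is.na(rstats$p_value) & rstats$p_value < sigP &
    (if (direction == "up") rstats$log2_fc > 0 else rstats$log2_fc < 0)
  sig_idx <- intersect(rstats$reaction_index[sig], background)
  mapped_bg <- intersect(mapped, background)
  N <- length(mapped_bg)
  K <- length(intersect(sig_idx, mapped_bg))
  if (K == 0L) {
    warning("no significant ", direction, "-regulated reactions in the background",
            call. = FALSE)
  }
  k <- integer(length(efms)); n <- integer(length(efms))
  for (i in seq_along(efms@efms)) {
    inside <- intersect(efms@efms[[i]], mapped_bg)
    n[i] <- length(inside)
    k[i] <- length(intersect(inside, sig_idx))
  }
  # one-sided over-representation: P(X >= k), X ~ Hypergeometric(N, K, n)
  p_raw <- ifelse(n == 0L, 1,
                  stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE))
  p_raw <- pmin(pmax(p_raw, 0), 1)
  data.frame(efm_id = efms@efmIds, direction = direction, k = k, n = n,
             K = K, N = N, p_raw = p_raw,
             p_adjusted = stats::p.adjust(p_raw, method = "BH"))
}

#' Enrichment in both directions with per-EFM direction labels
#'
#' Runs [enrichEfms()] for up- and down-regulation and labels each EFM with
#' the direction that attains the smaller adjusted p-value (ties go to
#' `"up"`).
#'
#' @inheritParams enrichEfms
#' @return `data.frame` as [enrichEfms()], one row per EFM, with the winning
#'   direction.
#' @export
enrichEfmsBothDirections <- function(efms, rstats, sigP = 0.05, background = NULL) {
  up <- enrichEfms(efms, rstats, "up", sigP, background)
  down <- enrichEfms(efms, rstats, "down", sigP, background)
  take_up <- up$p_adjusted <= down$p_adjusted
  out <- up
  out[!take_up, ] <- down[!take_up, ]
  out
}
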