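#' Deterministic synthetic fixture bundle
#'
#' Builds a toy genome-scale model together with a planted EFM collection,
#' relative fluxes, a gene-statistics table and a ground-truth record, so
#' every stage of the workflow can be exercised and checked without any
#' external data.
#'
#' The model is a substrate-to-product factory with `nRoutes` parallel
#' conversion routes plus an internal futile cycle:
#' a boundary substrate enters through an exchange reaction, is transported
#' into the cytosol, converted by route i (`sub_c + atp_c -> c_i prod_c +
#' adp_c`, with route-specific product stoichiometry c_i spanning 0.5 to
#' 2.0), the spent ATP is regenerated, and the product is transported out
#' and released through a second exchange reaction. Each route defines one
#' EFM (id i = route i); one extra EFM is the two-reaction internal cycle.
#' Every planted EFM balances all non-boundary species exactly (S v = 0),
#' and the product yield of route i is exactly c_i, so the extreme-yield
#' modes are known by construction.
#'
#' Gene statistics are planted so that exactly one route (`sigRoute`) has
#' significantly upregulated genes: its EFM is the unique most-enriched
#' mode. All other genes draw p-values from `[0.2, 0.9]` and cannot reach
#' the significance cutoff. One gene of the last route is withheld from the
#' table to exercise missing-data handling, and the model declares one
#' orphan gene appearing in no GPR.
#'
#' @param dir output directory; when given, `model.xml` (SBML), `efms.txt`,
#'   `fluxes.txt`, `gene_stats.tsv` and `ground_truth.json` are written
#'   there. `NULL` keeps the bundle in memory.
#' @param nRoutes number of parallel conversion routes (>= 2; default 24).
#' @param sigRoute index of the route with planted upregulation (default 2).
#' @param seed integer seed; the bundle is a deterministic function of
#'   `(nRoutes, sigRoute, seed)` — identical calls give byte-identical files.
#' @return (invisibly, when `dir` is given) a list with `model`
#'   ([MetabolicModel-class]), `efms` ([EfmSet-class] with fluxes),
#'   `geneStats` (`data.frame`), `groundTruth` (list: `yields`,
#'   `backbone_occurrence`, `contingency`, `most_enriched_efm`,
#'   `min_yield_efm`, `max_yield_efm`) and `files` (named paths or `NULL`).
#' @export
generateFixture <- function(dir = NULL, nRoutes = 24, sigRoute = 2, seed = 1) {
  if (nRoutes < 2) stop("nRoutes must be >= 2", call. = FALSE)
  if (sigRoute < 1 || sigRoute > nRoutes) {
    stop("sigRoute must be in 1..nRoutes", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  R <- as.integer(nRoutes)
  c_i <- round(0.5 + 1.5 * (seq_len(R) - 1) / (R - 1), 4)

  metabolites <- data.frame(
    id = c("sub_b", "sub_e", "sub_c", "prod_c", "prod_e", "prod_b",
           "atp_c", "adp_c", "x_c", "y_c"),
    name = c("substrate (boundary)", "substrate (extracellular)",
             "substrate (cytosol)", "product (cytosol)",
             "product (extracellular)", "product (boundary)",
             "atp", "adp", "cycle carrier X", "cycle carrier Y"),
    compartment = c("e", "e", "c", "c", "e", "e", "c", "c", "c", "c"),
    boundary = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
                 FALSE, FALSE),
    stringsAsFactors = FALSE
  )

  conv_ids <- sprintf("CONV%02d", seq_len(R))
  rxn_id <- c("EX_sub", "T_sub", conv_ids, "REGEN_ATP", "T_prod", "EX_prod",
              "CYC_FWD", "CYC_REV")
  subsystem <- c("exchange/demand", "transport",
                 ifelse(seq_len(R) %% 2 == 1, "conversion pathway A",
                        "conversion pathway B"),
                 "energy metabolism", "transport", "exchange/demand",
                 "futile cycle", "futile cycle")
  reactions <- data.frame(id = rxn_id, name = rxn_id, reversible = FALSE,
                          subsystem = subsystem, stringsAsFactors = FALSE)

  stoich <- c(
    list(c(sub_b = -1, sub_e = 1), c(sub_e = -1, sub_c = 1)),
    lapply(seq_len(R), function(i) {
      c(sub_c = -1, atp_c = -1, prod_c = unname(c_i[i]), adp_c = 1)
    }),
    list(c(adp_c = -1, atp_c = 1),
         c(prod_c = -1, prod_e = 1),
         c(prod_e = -1, prod_b = 1),
         c(x_c = -1, y_c = 1),
         c(y_c = -1, x_c = 1))
  )

  route_gpr <- vapply(seq_len(R), function(i) {
    op <- if (i %% 2 == 1) "and" else "or"
    sprintf("gA%02d %s gB%02d", i, op, i)
  }, character(1))
  # order: EX_sub (no GPR), T_sub, CONV_i, REGEN, T_prod, EX_prod, CYC x2
  gpr <- c(list(NULL, parseGpr("gT1 or gT2")), lapply(route_gpr, parseGpr),
           list(parseGpr("gR1"), parseGpr("gT3"), NULL, NULL, NULL))

  genes <- c("gT1", "gT2", "gT3", "gR1",
             as.vector(rbind(sprintf("gA%02d", seq_len(R)),
                             sprintf("gB%02d", seq_len(R)))),
             "gOrphan")
  model <- MetabolicModel(
    id = sprintf("toyFactory%d", R), reactions = reactions,
    metabolites = metabolites, stoichiometry = stoich, gpr = gpr,
    genes = genes,
    compartments = c(e = "extracellular space", c = "cytosol"))

  ## planted EFMs: one per route, plus the futile cycle
  conv_idx <- 2L + seq_len(R)
  i_regen <- R + 3L; i_tprod <- R + 4L; i_exprod <- R + 5L
  i_cyc <- c(R + 6L, R + 7L)
  # powers of two: scaling by u is exact in binary floating point, so the
  # yield (c_i * u) / u recovered from the serialized files equals c_i bit
  # for bit
  u <- sample(c(2, 4, 8, 16, 32), R, replace = TRUE)
  w <- sample(c(2, 4, 8), 1)
  efm_list <- c(lapply(seq_len(R), function(i) {
    c(1L, 2L, conv_idx[i], i_regen, i_tprod, i_exprod)
  }), list(i_cyc))
  flux_list <- c(lapply(seq_len(R), function(i) {
    stats::setNames(c(u[i], u[i], u[i], u[i], c_i[i] * u[i], c_i[i] * u[i]),
                    c(1L, 2L, conv_idx[i], i_regen, i_tprod, i_exprod))
  }), list(stats::setNames(c(w, w), i_cyc)))
  efms <- EfmSet(efm_list, nReactions = nReactions(model), fluxes = flux_list,
                 modelRef = model@id)

  ## planted gene statistics
  hot <- c(sprintf("gA%02d", sigRoute), sprintf("gB%02d", sigRoute))
  tabulated <- setdiff(setdiff(genes, "gOrphan"), sprintf("gB%02d", R))
  n_tab <- length(tabulated)
  gene_stats <- data.frame(
    gene_id = tabulated,
    p_value = round(stats::runif(n_tab, 0.2, 0.9), 4),
    log2_fc = round(stats::rnorm(n_tab, 0, 0.4), 4),
    expression = round(stats::runif(n_tab, 1, 50), 3),
    stringsAsFactors = FALSE
  )
  gene_stats$log2_fc[gene_stats$log2_fc == 0] <- 0.1
  hot_rows <- match(hot, gene_stats$gene_id)
  gene_stats$p_value[hot_rows] <- c(2e-4, 5e-4)
  gene_stats$log2_fc[hot_rows] <- c(2.5, 3.1)
  gene_stats$expression[hot_rows] <- c(95, 80)

  ## ground truth, recomputable from the serialized files
  N_bg <- R + 3L  # reactions with GPR and >= 1 tabulated gene
  contingency <- data.frame(
    efm_id = seq_len(R + 1L),
    k = c(as.integer(seq_len(R) == sigRoute), 0L),
    n = c(rep(4L, R), 0L),
    K = 1L, N = N_bg)
  ground_truth <- list(
    n_efms = R + 1L,
    yields = data.frame(efm_id = seq_len(R), yield = c_i),
    backbone_occurrence = stats::setNames(
      c(rep(R / (R + 1), 2), rep(1 / (R + 1), R), rep(R / (R + 1), 3),
        rep(1 / (R + 1), 2)),
      as.character(seq_len(R + 7L))),
    contingency = contingency,
    most_enriched_efm = as.integer(sigRoute),
    min_yield_efm = 1L,
    max_yield_efm = R,
    input_reaction = 1L,
    output_reaction = i_exprod
  )

  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- c(model = file.path(dir, "model.xml"),
               efms = file.path(dir, "efms.txt"),
               fluxes = file.path(dir, "fluxes.txt"),
               gene_stats = file.path(dir, "gene_stats.tsv"),
               ground_truth = file.path(dir, "ground_truth.json"))
    writeModelSBML(model, files[["model"]])
    writeEfmFile(efms, files[["efms"]])
    writeFluxFile(efms, files[["fluxes"]])
    writeTsvAtomic(gene_stats, files[["gene_stats"]])
    gt_json <- ground_truth
    gt_json$backbone_occurrence <- as.list(gt_json$backbone_occurrence)
    jsonlite::write_json(gt_json, files[["ground_truth"]], auto_unbox = TRUE,
                         digits = NA, dataframe = "columns", pretty = TRUE)
  }
  invisible(list(model = model, efms = efms, geneStats = gene_stats,
                 groundTruth = ground_truth, files = files))
}

#' Check an EFM against the steady-state condition
#'
#' An elementary flux mode must balance every internal species: with v the
#' full-length flux vector that is zero off the EFM and equal to the mode's
#' relative fluxes on it, the net production rate S v of every non-boundary
#' metabolite must vanish. Boundary species (SBML `boundaryCondition`) are
#' excluded — exchange reactions are allowed net flux across the system
#' boundary.
#'
#' @param model a [MetabolicModel-class].
#' @param efms an [EfmSet-class] with relative fluxes.
#' @param id the EFM id to check.
#' @param tol residual tolerance (default `1e-9`).
#' @return list with `valid` (logical: max residual <= tol) and
#'   `max_residual` (numeric: max over non-boundary species of |S v|).
#' @export
validateEfmSteadyState <- function(model, efms, id, tol = 1e-9) {
  fl <- efmRelativeFluxes(efms, id)
  if (is.null(fl)) stop("EFM ", id, " carries no relative fluxes", call. = FALSE)
  v <- numeric(nReactions(model))
  v[as.integer(names(fl))] <- fl
  resid <- as.numeric(model@stoichiometry %*% v)
  internal <- !model@metabolites$boundary
  max_resid <- if (any(internal)) max(abs(resid[internal])) else 0
  list(valid = max_resid <= tol, max_residual = max_resid)
}
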