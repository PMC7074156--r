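# Shared fixtures and independent oracles.

# Small hand-built model: 7 reactions, 6 metabolites, 4 genes, 2 compartments.
# Linear uptake -> branch -> condensation -> release topology with one
# boundary species, mixed GPR forms and three subsystems.
tinyModel <- function() {
  metabolites <- data.frame(
    id = c("a_e", "a_c", "b_c", "c_c", "d_e", "d_b"),
    name = c("A ext", "A cyt", "B", "C", "D ext", "D boundary"),
    compartment = c("e", "c", "c", "c", "e", "e"),
    boundary = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  reactions <- data.frame(
    id = c("EX_a", "T_a", "R1", "R2", "R3", "T_d", "DM_d"),
    name = c("A exchange", "A transport", "branch 1", "branch 2",
             "condensation", "D transport", "D demand"),
    reversible = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    subsystem = c("exchange", "transport", "glycolysis", "glycolysis",
                  "synthesis", "transport", "exchange"),
    stringsAsFactors = FALSE
  )
  stoich <- list(
    c(a_e = 1),
    c(a_e = -1, a_c = 1),
    c(a_c = -1, b_c = 1),
    c(a_c = -1, c_c = 1),
    c(b_c = -1, c_c = -1, d_e = 2),
    c(d_e = -1, d_b = 1),
    c(d_b = -1)
  )
  gpr <- list(NULL, "g1", "g2 and g3", "g2 or g3", "(g2 and g3) or g4",
              NULL, NULL)
  MetabolicModel(id = "tiny", reactions = reactions, metabolites = metabolites,
                 stoichiometry = stoich, gpr = gpr,
                 compartments = c(e = "extracellular", c = "cytosol"))
}

# Hypergeometric upper tail by direct combinatorial summation:
# P(X >= k) for X ~ Hypergeometric(N items, K marked, n drawn).
oracleHyperTail <- function(N, K, n, k) {
  hi <- min(n, K)
  if (k > hi) return(0)
  x <- max(k, max(0L, n + K - N)):hi
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

# The same probability by literally enumerating every n-subset of an N-set
# with the first K elements marked (feasible only for small N).
oracleHyperEnumerate <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  mean(apply(subsets, 2, function(s) sum(s <= K) >= k))
}

# Random GPR tree over a gene pool; leaves at depth 0.
randomGprTree <- function(genes, depth) {
  if (depth == 0L || stats::runif(1) < 0.3) {
    return(gprGene(sample(genes, 1)))
  }
  n_child <- sample(2:3, 1)
  kids <- lapply(seq_len(n_child), function(i) randomGprTree(genes, depth - 1L))
  if (stats::runif(1) < 0.5) do.call(gprAnd, kids) else do.call(gprOr, kids)
}

# Independent bottom-up GPR evaluator: collects each subtree's chosen
# (gene, rank) pair using explicit sorting rather than which.min/which.max.
# `lookup` is a data.frame with rownames = gene ids and column `rank`;
# genes absent from it have no data.
oracleGprEval <- function(node, lookup) {
  if (is.null(node)) return(NULL)
  if (node$kind == "GENE") {
    if (!node$gene_id %in% rownames(lookup)) return(NULL)
    return(list(gene = node$gene_id, rank = lookup[node$gene_id, "rank"]))
  }
  kids <- Filter(Negate(is.null), lapply(node$children, oracleGprEval, lookup = lookup))
  if (!length(kids)) return(NULL)
  ranks <- vapply(kids, `[[`, numeric(1), "rank")
  ord <- if (node$kind == "AND") order(ranks) else order(-ranks)
  kids[[ord[1]]]
}

# Random EfmSet: nEfms subsets of 1..nReactions with random sizes.
randomEfmSet <- function(nReactions, nEfms) {
  efms <- lapply(seq_len(nEfms), function(i) {
    sample(nReactions, sample(seq_len(max(1, nReactions - 1)), 1))
  })
  EfmSet(efms, nReactions = nReactions)
}

# Canonical rendering of a GPR tree for structural comparison up to
# child order at a node: sorts children recursively.
gprCanonical <- function(node) {
  if (is.null(node)) return("")
  if (node$kind == "GENE") return(node$gene_id)
  parts <- sort(vapply(node$children, gprCanonical, character(1)))
  paste0(tolower(node$kind), "(", paste(parts, collapse = ","), ")")
}
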