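singleReactionModel <- function() {
  MetabolicModel(
    id = "one", reactions = data.frame(id = "R"),
    metabolites = data.frame(id = c("A", "B"), compartment = "c"),
    stoichiometry = list(c(A = -1, B = 1)), gpr = list("G"))
}

test_that("a single gene-catalyzed conversion gives 4 nodes and 3 typed edges", {
  g <- buildGraph(singleReactionModel(), includeGenes = TRUE)
  nd <- graphNodes(g); ed <- graphEdges(g)
  expect_equal(nrow(nd), 4L)
  expect_equal(nrow(ed), 3L)
  expect_setequal(nd$id, c("m:A", "m:B", "r:R", "g:G"))
  expect_equal(ed$type[ed$source == "m:A"], "substrate")
  expect_equal(ed$target[ed$source == "m:A"], "r:R")
  expect_equal(ed$type[ed$target == "m:B"], "product")
  expect_equal(ed$type[ed$source == "g:G"], "catalysis")
})

test_that("an empty submodel gives an empty graph; genes can be omitted", {
  empty <- MetabolicModel(id = "e", reactions = data.frame(id = character()),
                          metabolites = data.frame(id = character(),
                                                   compartment = character()),
                          stoichiometry = list())
  g <- buildGraph(empty)
  expect_equal(nrow(graphNodes(g)), 0L)
  expect_equal(nrow(graphEdges(g)), 0L)
  g2 <- buildGraph(singleReactionModel(), includeGenes = FALSE)
  expect_false(any(graphNodes(g2)$type == "gene"))
  expect_equal(nrow(graphEdges(g2)), 2L)
})

test_that("node and edge counts equal an independent participant tally", {
  b <- generateFixture(nRoutes = 5, seed = 7)
  sub <- extractSubmodel(b$model, b$efms, 3)
  g <- buildGraph(sub, includeGenes = TRUE)
  nd <- graphNodes(g); ed <- graphEdges(g)
  n_genes <- length(unique(unlist(lapply(gprRules(sub), gprGenes))))
  expect_equal(nrow(nd), nMetabolites(sub) + nReactions(sub) + n_genes)
  S <- stoichiometricMatrix(sub)
  expect_equal(sum(ed$type %in% c("substrate", "product")), sum(S != 0))
  expect_equal(sum(ed$type == "catalysis"),
               sum(lengths(lapply(gprRules(sub), gprGenes))))
  # degree identity per reaction node
  for (rid in nd$id[nd$type == "reaction"]) {
    deg <- sum(ed$target == rid & ed$type == "substrate") +
      sum(ed$source == rid & ed$type == "product")
    j <- match(sub("^r:", "", rid), reactionIds(sub))
    expect_equal(deg, sum(S[, j] != 0))
  }
})

test_that("exchange reactions are flagged via boundary species or arity", {
  b <- generateFixture(nRoutes = 4, seed = 7)
  sub <- extractSubmodel(b$model, b$efms, 1)
  nd <- graphNodes(buildGraph(sub))
  ex <- sub("^r:", "", nd$id[nd$type == "reaction" & nd$is_exchange])
  expect_setequal(ex, c("EX_sub", "EX_prod"))
})

test_that("flux mapping puts one constant magnitude on all edges of a reaction", {
  b <- generateFixture(nRoutes = 4, seed = 11)
  sub <- extractSubmodel(b$model, b$efms, 2)
  g <- mapFluxes(buildGraph(sub), b$efms, id = 2)
  ed <- graphEdges(g)
  fl <- efmRelativeFluxes(b$efms, 2)
  for (rid in graphNodes(g)$id[graphNodes(g)$type == "reaction"]) {
    touching <- ed$flux[(ed$source == rid | ed$target == rid) &
                          ed$type != "catalysis"]
    expect_equal(length(unique(touching)), 1L)
    j <- graphNodes(g)$index[graphNodes(g)$id == rid]
    expect_equal(unique(touching), abs(fl[[as.character(j)]]))
  }
  expect_true(all(is.na(ed$flux[ed$type == "catalysis"])))
  # mapping twice with the same EFM is the identity
  expect_identical(mapFluxes(g, b$efms, id = 2)@edges, g@edges)
  # a reaction without flux is an error naming the node
  short <- b$efms
  short@fluxes[[2]] <- short@fluxes[[2]][-1]
  short@efms[[2]] <- short@efms[[2]][-1]
  expect_error(mapFluxes(buildGraph(sub), short, id = 2), "r:EX_sub")
})

test_that("gene data lands on matched gene nodes and flags the rest", {
  b <- generateFixture(nRoutes = 4, seed = 11)
  sub <- extractSubmodel(b$model, b$efms, 1)
  g <- mapGeneData(buildGraph(sub), b$geneStats)
  nd <- graphNodes(g)
  gn <- nd[nd$type == "gene", ]
  matched <- gn$label %in% b$geneStats$gene_id
  expect_true(all(!gn$no_data[matched]))
  expect_equal(gn$log2_fc[matched],
               b$geneStats$log2_fc[match(gn$label[matched], b$geneStats$gene_id)])
  # stats covering no graph gene leave everything flagged, values NA
  alien <- data.frame(gene_id = "zzz", p_value = 0.5, log2_fc = 1,
                      expression = 1)
  g2 <- mapGeneData(buildGraph(sub), alien)
  gn2 <- graphNodes(g2)[graphNodes(g2)$type == "gene", ]
  expect_true(all(gn2$no_data))
  expect_true(all(is.na(gn2$log2_fc)))
  dup <- rbind(alien, alien)
  expect_error(mapGeneData(buildGraph(sub), dup), "duplicate gene_id")
})

test_that("GraphML round-trips ids, types and mapped attributes", {
  b <- generateFixture(nRoutes = 4, seed = 13)
  sub <- extractSubmodel(b$model, b$efms, 1)
  g <- mapGeneData(mapFluxes(buildGraph(sub), b$efms, id = 1), b$geneStats)
  path <- withr::local_tempfile(fileext = ".graphml")
  writeGraph(g, path, "graphml")
  ig <- igraph::read_graph(path, format = "graphml")
  expect_setequal(igraph::V(ig)$name, graphNodes(g)$id)
  expect_equal(igraph::ecount(ig), nrow(graphEdges(g)))
  got_types <- setNames(igraph::V(ig)$type, igraph::V(ig)$name)
  expect_equal(unname(got_types[graphNodes(g)$id]), graphNodes(g)$type)
  # edge attribute multiset survives
  got_flux <- sort(igraph::E(ig)$flux[!is.nan(igraph::E(ig)$flux)])
  want_flux <- sort(graphEdges(g)$flux[!is.na(graphEdges(g)$flux)])
  expect_equal(got_flux, want_flux)
})

test_that("SIF export uses the edge type as interaction token plus TSV tables", {
  g <- buildGraph(singleReactionModel())
  dir <- withr::local_tempdir()
  path <- file.path(dir, "net.sif")
  files <- writeGraph(g, path, "sif")
  lines <- readLines(path)
  expect_true("m:A\tsubstrate\tr:R" %in% lines)
  expect_true("g:G\tcatalysis\tr:R" %in% lines)
  nodes <- read.delim(file.path(dir, "net_nodes.tsv"))
  expect_equal(nrow(nodes), 4L)
  edges <- read.delim(file.path(dir, "net_edges.tsv"))
  expect_equal(nrow(edges), 3L)
})

test_that("JSON export serializes an empty graph as a valid document", {
  empty <- MetabolicModel(id = "e", reactions = data.frame(id = character()),
                          metabolites = data.frame(id = character(),
                                                   compartment = character()),
                          stoichiometry = list())
  path <- withr::local_tempfile(fileext = ".json")
  writeGraph(buildGraph(empty), path, "json")
  doc <- jsonlite::read_json(path)
  expect_true(doc$directed)
  expect_equal(length(doc$nodes), 0L)
  expect_error(writeGraph(buildGraph(empty), path, "dot"), "unknown graph format")
})

test_that("backbone occurrence percentages decorate reaction nodes", {
  b <- generateFixture(nRoutes = 4, seed = 13)
  bb <- extractBackbone(b$efms, 0.5)
  g <- mapOccurrence(buildGraph(b$model), bb)
  nd <- graphNodes(g)
  shared <- nd$occurrence_pct[nd$id == "r:EX_sub"]
  expect_equal(shared, 100 * 4 / 5)
})
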