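mkEfms <- function(sets, nReactions = 10, fluxes = NULL) {
  EfmSet(sets, nReactions = nReactions, fluxes = fluxes)
}

test_that("reaction-presence filtering keeps ids and order", {
  efms <- mkEfms(list(c(1, 2), c(2, 3), c(1, 3)))
  kept <- filterEfmsByReaction(efms, 2)
  expect_equal(efmIds(kept), c(1L, 2L))
  expect_equal(length(filterEfmsByReaction(efms, 9)), 0L)
  # a reaction present everywhere filters nothing
  all3 <- filterEfmsByReaction(efms, 3, "excludes")
  expect_equal(efmIds(all3), 1L)
  expect_error(filterEfmsByReaction(efms, 99), "outside 1..10")
})

test_that("yields divide output flux magnitude by input flux magnitude", {
  efms <- mkEfms(list(c(1, 2), c(1, 2)),
                 fluxes = list(c("1" = 3.43, "2" = 10), c("1" = -20, "2" = 10)))
  y <- computeYields(efms, 1, 2)
  expect_equal(y$yield, c(10 / 3.43, 0.5))
  # input = output reaction: yield identically 1
  expect_equal(computeYields(efms, 1, 1)$yield, c(1, 1))
})

test_that("yield is invariant under per-EFM flux rescaling", {
  set.seed(9)
  base <- runif(3, 0.5, 5)
  efms1 <- mkEfms(list(c(1, 2, 3)), fluxes = list(setNames(base, 1:3)))
  efms2 <- mkEfms(list(c(1, 2, 3)), fluxes = list(setNames(7.3 * base, 1:3)))
  expect_equal(computeYields(efms1, 1, 3)$yield, computeYields(efms2, 1, 3)$yield)
})

test_that("yield preconditions are enforced", {
  efms <- mkEfms(list(c(1, 2), c(2, 3)),
                 fluxes = list(c("1" = 1, "2" = 2), c("2" = 1, "3" = 1)))
  expect_error(computeYields(efms, 1, 2), "missing input or output reaction: 2")
  no_flux <- mkEfms(list(c(1, 2)))
  expect_error(computeYields(no_flux, 1, 2), "no relative fluxes")
})

test_that("extreme-yield selection returns ties ordered shortest-first", {
  efms <- mkEfms(list(c(1, 2, 3, 4, 9), c(1, 4), c(1, 4, 5)))
  y <- data.frame(efm_id = 1:3, input_flux = 1, output_flux = c(0.5, 0.5, 2.9),
                  yield = c(0.5, 0.5, 2.9))
  expect_equal(selectExtremeYield(y, "min", efms), c(2L, 1L))
  expect_equal(selectExtremeYield(y, "max", efms), 3L)
  one <- mkEfms(list(c(1, 2)))
  y1 <- data.frame(efm_id = 1, input_flux = 1, output_flux = 2, yield = 2)
  expect_equal(selectExtremeYield(y1, "min", one), 1L)
  expect_equal(selectExtremeYield(y1, "max", one), 1L)
})

test_that("extreme selection matches an exhaustive scan on fixture yields", {
  b <- generateFixture(nRoutes = 8, seed = 13)
  routes <- filterEfmsByReaction(b$efms, b$groundTruth$output_reaction)
  y <- computeYields(routes, b$groundTruth$input_reaction,
                     b$groundTruth$output_reaction)
  # brute force over all records
  expect_equal(selectExtremeYield(y, "min", routes)[1],
               y$efm_id[order(y$yield, lengths(routes@efms))[1]])
  expect_equal(selectExtremeYield(y, "max", routes)[1],
               y$efm_id[order(-y$yield, lengths(routes@efms))[1]])
})

sigStats <- function(N, K) {
  # N mapped reactions, the last K significant-up
  data.frame(reaction_index = seq_len(N), reaction_id = paste0("R", seq_len(N)),
             p_value = c(rep(0.5, N - K), rep(0.01, K)),
             log2_fc = c(rep(-1, N - K), rep(2, K)),
             source_gene = "g", coverage = TRUE)
}

test_that("enrichment p-values equal combinatorial enumeration on small cases", {
  rstats <- sigStats(8, 3)
  # EFMs drawing k = 0..3 significant of n = 4 mapped reactions
  efms <- mkEfms(list(c(1, 2, 3, 4), c(1, 2, 3, 6), c(1, 2, 6, 7),
                      c(1, 6, 7, 8)), nReactions = 8)
  res <- suppressWarnings(enrichEfms(efms, rstats, "up", sigP = 0.05))
  expect_equal(res$k, 0:3)
  for (i in 1:4) {
    expect_equal(res$p_raw[i], oracleHyperEnumerate(8, 3, 4, res$k[i]),
                 tolerance = 1e-12)
  }
  # k = 0: upper tail includes X >= 0, so exactly 1
  expect_identical(res$p_raw[1], 1)
})

test_that("enrichment distinguishes directions and respects the cutoff", {
  rstats <- sigStats(8, 3)
  efms <- mkEfms(list(c(6, 7, 8, 1)), nReactions = 8)
  up <- enrichEfms(efms, rstats, "up")
  down <- suppressWarnings(enrichEfms(efms, rstats, "down"))
  expect_equal(up$k, 3L)
  expect_equal(down$k, 0L)
  expect_warning(enrichEfms(efms, rstats, "down"), "no significant down")
  # with a cutoff below every p-value nothing is significant
  strict <- suppressWarnings(enrichEfms(efms, rstats, "up", sigP = 0.001))
  expect_equal(strict$K, 0L)
  expect_equal(strict$p_raw, 1)
})

test_that("EFMs outside the mapped universe get p = 1", {
  rstats <- sigStats(8, 3)
  rstats$coverage[1:2] <- FALSE
  efms <- mkEfms(list(c(1, 2)), nReactions = 8)
  res <- enrichEfms(efms, rstats, "up")
  expect_equal(res$n, 0L)
  expect_equal(res$p_raw, 1)
})

test_that("p_raw is monotone nonincreasing in k at fixed N, K, n", {
  for (N in c(10, 20)) for (K in c(3, 7)) for (n in c(4, 9)) {
    p <- vapply(0:min(n, K), function(k)
      phyper(k - 1, K, N - K, n, lower.tail = FALSE), numeric(1))
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("BH adjustment is nondecreasing when sorted and bounds raw p", {
  rstats <- sigStats(12, 4)
  set.seed(17)
  efms <- randomEfmSet(12, 15)
  res <- suppressWarnings(enrichEfms(efms, rstats, "up"))
  expect_true(all(res$p_adjusted >= res$p_raw - 1e-15))
  expect_true(all(res$p_adjusted >= 0 & res$p_adjusted <= 1))
  ord <- order(res$p_raw)
  expect_true(all(diff(res$p_adjusted[ord]) >= -1e-15))
  expect_equal(res$p_adjusted, p.adjust(res$p_raw, "BH"))
})

test_that("direction labeling picks the smaller adjusted p per EFM", {
  rstats <- sigStats(8, 3)
  rstats$log2_fc[1:2] <- -2
  rstats$p_value[1:2] <- 0.01  # reactions 1,2 significant-down
  efms <- mkEfms(list(c(6, 7, 8), c(1, 2, 5)), nReactions = 8)
  both <- enrichEfmsBothDirections(efms, rstats)
  expect_equal(both$direction, c("up", "down"))
})

test_that("gene statistics tables are validated on read", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tp_value\tlog2_fc\texpression",
               "g1\t0.01\t1.5\t10", "g2\t0.90\t-0.3\t5"), path)
  tab <- readGeneStats(path)
  expect_equal(tab$gene_id, c("g1", "g2"))
  writeLines(c("gene_id\tp_value\tlog2_fc", "g1\t0.01\t1.5", "g1\t0.2\t0.1"),
             path)
  expect_error(readGeneStats(path), "duplicate gene_id")
  writeLines(c("gene_id\tp_value\tlog2_fc", "g1\t1.4\t1.5"), path)
  expect_error(readGeneStats(path), "outside \\[0, 1\\]")
})
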