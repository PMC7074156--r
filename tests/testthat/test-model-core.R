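test_that("SBML write + read round-trips the toy model", {
  m <- tinyModel()
  path <- withr::local_tempfile(fileext = ".xml")
  writeModelSBML(m, path)
  m2 <- readModelSBML(path)

  expect_equal(nReactions(m2), 7L)
  expect_equal(nMetabolites(m2), 6L)
  expect_equal(nGenes(m2), 4L)
  expect_identical(reactionIds(m2), reactionIds(m))
  expect_identical(metaboliteIds(m2), metaboliteIds(m))
  expect_setequal(geneIds(m2), geneIds(m))
  expect_identical(m2@reactions$reversible, m@reactions$reversible)
  expect_identical(as.list(m2@reactions$subsystem), as.list(m@reactions$subsystem))
  expect_identical(m2@metabolites$boundary, m@metabolites$boundary)
  expect_identical(lapply(gprRules(m2), gprCanonical),
                   lapply(gprRules(m), gprCanonical))
  expect_equal(as.matrix(stoichiometricMatrix(m2)),
               as.matrix(stoichiometricMatrix(m)))
})

test_that("stoichiometric matrix matches per-reaction assembly oracle", {
  m <- tinyModel()
  S <- as.matrix(stoichiometricMatrix(m))
  oracle <- matrix(0, nMetabolites(m), nReactions(m),
                   dimnames = list(metaboliteIds(m), reactionIds(m)))
  stoich <- list(
    c(a_e = 1), c(a_e = -1, a_c = 1), c(a_c = -1, b_c = 1),
    c(a_c = -1, c_c = 1), c(b_c = -1, c_c = -1, d_e = 2),
    c(d_e = -1, d_b = 1), c(d_b = -1))
  for (j in seq_along(stoich)) oracle[names(stoich[[j]]), j] <- stoich[[j]]
  expect_equal(S, oracle)
  # column support = the reaction's participant set, nowhere else
  for (j in seq_len(ncol(S))) {
    expect_setequal(names(which(S[, j] != 0)), names(stoich[[j]]))
  }
})

test_that("single conversion reaction yields the signed column (-1, +1)", {
  m <- MetabolicModel(
    id = "one", reactions = data.frame(id = "R"),
    metabolites = data.frame(id = c("A", "B"), compartment = "c"),
    stoichiometry = list(c(A = -1, B = 1)))
  expect_equal(as.numeric(stoichiometricMatrix(m)), c(-1, 1))
})

test_that("SBML without gene associations reads with all-empty GPRs", {
  m <- tinyModel()
  m@gpr <- rep(list(NULL), nReactions(m))
  m@genes <- character()
  path <- withr::local_tempfile(fileext = ".xml")
  writeModelSBML(m, path)
  doc <- readLines(path)
  expect_false(any(grepl("geneProduct", doc)))
  m2 <- readModelSBML(path)
  expect_true(all(vapply(gprRules(m2), is.null, logical(1))))
  expect_equal(nGenes(m2), 0L)
})

test_that("duplicate reaction ids are rejected with a validation error", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="dup"><listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    '<listOfSpecies><species id="A" compartment="c"/></listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="R1" reversible="false"><listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants></reaction>',
    '<reaction id="R1" reversible="false"><listOfProducts><speciesReference species="A" stoichiometry="1"/></listOfProducts></reaction>',
    '</listOfReactions></model></sbml>'), path)
  expect_error(readModelSBML(path), "duplicate reaction id.*R1")
})

test_that("malformed XML errors name the file", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model>", path)
  expect_error(readModelSBML(path), "malformed SBML")
})

test_that("legacy Level 2 notes supply GPRs and subsystems", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="legacy">',
    '<listOfCompartments><compartment id="c"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="A" compartment="c"/>',
    '<species id="B" compartment="c" boundaryCondition="true"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="R1">',
    '<notes><body xmlns="http://www.w3.org/1999/xhtml">',
    '<p>GENE_ASSOCIATION: (g1 and g2) or g3</p>',
    '<p>SUBSYSTEM: Glycolysis</p>',
    '</body></notes>',
    '<listOfReactants><speciesReference species="A"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B" stoichiometry="2"/></listOfProducts>',
    '</reaction>',
    '</listOfReactions></model></sbml>'), path)
  m <- readModelSBML(path)
  expect_equal(gprCanonical(gprRules(m)[[1]]), "or(and(g1,g2),g3)")
  expect_equal(m@reactions$subsystem[[1]], "Glycolysis")
  # Level 2 defaults: reversible = true, stoichiometry = 1
  expect_true(m@reactions$reversible[1])
  expect_equal(as.numeric(stoichiometricMatrix(m)["A", 1]), -1)
  expect_equal(as.numeric(stoichiometricMatrix(m)["B", 1]), 2)
  expect_true(m@metabolites$boundary[m@metabolites$id == "B"])
})

test_that("model validity catches undeclared references", {
  expect_error(
    MetabolicModel(id = "bad", reactions = data.frame(id = "R"),
                   metabolites = data.frame(id = "A", compartment = "c"),
                   stoichiometry = list(c(Z = -1))),
    "unknown metabolite")
  m <- tinyModel()
  m@genes <- character()  # GPRs now reference undeclared genes
  expect_error(validObject(m), "undeclared gene")
})
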