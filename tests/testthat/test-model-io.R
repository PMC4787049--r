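test_that("GPR parsing builds the expected trees and rejects bad input", {
  ast <- parseGpr("(b0001 and b0002) or b0003")
  expect_identical(ast$kind, "OR")
  expect_length(ast$children, 2L)
  expect_identical(ast$children[[1L]]$kind, "AND")
  expect_identical(parseGpr("b0001"),
                   list(kind = "GENE", gene = "b0001"))
  expect_error(parseGpr("(a and b"), "parenthes")
  expect_error(parseGpr("a ^ b"), "unknown token")
  expect_error(parseGpr("a and"), "unexpected end")
  expect_error(parseGpr("and a"), "keyword")
})

test_that("DNF expansion is truth-table equivalent to the source rule", {
  rules <- c("(a or b) and c",
             "a and (b or c)",
             "(a and b) or (a and c) or d",
             "((a or b) and (c or d)) or (e and f)",
             "a and a",
             "x1 or (x2 and x3 and x2)")
  for (r in rules) expectGprDnfEquivalent(r)
})

test_that("complex expansion merges duplicates, counts copies and is idempotent", {
  cx <- expandComplexes(parseGpr("(g1 and g2) or g3"))
  expect_length(cx, 2L)
  expect_identical(cx[[1L]]$subunits, c(g1 = 1L, g2 = 1L))
  expect_identical(cx[[2L]]$subunits, c(g3 = 1L))
  homo <- expandComplexes(parseGpr("g1 and g1 and g1"))
  expect_identical(homo[[1L]]$subunits, c(g1 = 3L))
  # DNF input expands to itself
  dnf <- "(a and b) or c"
  expect_identical(expandComplexes(parseGpr(dnf)),
                   expandComplexes(parseGpr(dnf)))
  # duplicated disjuncts merge
  expect_length(expandComplexes(parseGpr("(a and b) or (b and a)")), 1L)
})

test_that("curated stoichiometry table overrides copy numbers", {
  cx <- expandComplexes(parseGpr("atpB or (atpA and atpB)"))
  tab <- data.frame(enzyme_id = "atp_synthase",
                    gene_id = c("atpA", "atpB"),
                    copies = c(3L, 1L))
  out <- applyStoichiometryTable(cx, tab)
  het <- out[[which(vapply(out, function(c) length(c$subunits) == 2L,
                           logical(1)))]]
  expect_identical(het$subunits[["atpA"]], 3L)
  expect_identical(applyStoichiometryTable(cx, NULL), cx)
  bad <- data.frame(enzyme_id = "nope", gene_id = "zz", copies = 2L)
  expect_warning(out2 <- applyStoichiometryTable(cx, bad), "no complex")
  expect_identical(out2, cx)
})

test_that("model statistics match hand enumeration and planted truth", {
  toy <- MetabolicModel(
    "toy", genes = c("a", "b", "c"), metabolites = c("M1", "M2"),
    reactions = list(
      Reaction("R1", c(M1 = -1, M2 = 1), 0, 10, gpr = "(a and b) or c"),
      Reaction("R2", c(M2 = -1), 0, 10, gpr = "a")),
    objective = "R2")
  st <- modelStats(toy)
  expect_equal(st$isozyme_reaction_fraction, 1 / 2)
  expect_identical(st$multi_complex_genes, "a")
  expect_equal(st$multi_complex_gene_fraction, 1 / 3)

  noGpr <- MetabolicModel("empty", genes = character(),
                          metabolites = "M1",
                          reactions = list(Reaction("R1", c(M1 = 1), 0, 1)),
                          objective = "R1")
  st0 <- modelStats(noGpr)
  expect_equal(st0$isozyme_reaction_fraction, 0)
  expect_equal(st0$multi_complex_gene_count, 0L)

  for (seed in c(1L, 7L, 23L)) {
    fx <- makeToyModel(20L, seed = seed)
    st <- modelStats(fx$model)
    expect_equal(st$isozyme_reaction_fraction,
                 fx$truth$isozyme_reaction_fraction)
    expect_equal(st$multi_complex_gene_count,
                 fx$truth$multi_complex_gene_count)
    expect_identical(st$multi_complex_genes, fx$truth$multi_complex_genes)
  }
})

test_that("model statistics are invariant to reaction order and whitespace", {
  fx <- makeToyModel(12L, seed = 5L)
  m <- fx$model
  ref <- modelStats(m)
  perm <- rev(seq_along(m@reactions))
  m2 <- MetabolicModel(m@modelId, m@genes, m@metabolites,
                       m@reactions[perm], m@objective)
  st2 <- modelStats(m2)
  expect_equal(st2$isozyme_reaction_fraction, ref$isozyme_reaction_fraction)
  expect_identical(st2$multi_complex_genes, ref$multi_complex_genes)
  m3 <- m
  m3@reactions <- lapply(m@reactions, function(r) {
    r@gpr <- gsub(" ", "   ", r@gpr)
    r
  })
  expect_equal(modelStats(m3)$isozyme_reaction_fraction,
               ref$isozyme_reaction_fraction)
})

test_that("JSON model round-trips and SBML subset reads", {
  fx <- makeToyModel(8L, seed = 2L)
  path <- withr::local_tempfile(fileext = ".json")
  writeModelJson(fx$model, path)
  m2 <- readModelJson(path)
  expect_identical(reactionIds(m2), reactionIds(fx$model))
  expect_identical(modelGenes(m2), modelGenes(fx$model))
  expect_equal(fba(m2)$objective, fba(fx$model)$objective)

  sbml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="mini">',
    '<listOfSpecies><species id="M1"/><species id="M2"/></listOfSpecies>',
    '<listOfParameters>',
    '<parameter id="lb0" value="0"/><parameter id="ub10" value="10"/>',
    '</listOfParameters>',
    '<listOfReactions>',
    '<reaction id="R1" lowerFluxBound="lb0" upperFluxBound="ub10">',
    '<listOfReactants><speciesReference species="M1" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="M2" stoichiometry="1"/></listOfProducts>',
    '<notes>GENE_ASSOCIATION: (b1 and b2) or b3</notes>',
    '</reaction>',
    '</listOfReactions>',
    '</model></sbml>')
  sp <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, sp)
  ms <- readModelSbml(sp)
  expect_identical(reactionIds(ms), "R1")
  r1 <- reactions(ms)[[1L]]
  expect_equal(r1@lowerBound, 0)
  expect_equal(r1@upperBound, 10)
  expect_setequal(gprGenes(parseGpr(r1@gpr)), c("b1", "b2", "b3"))
})

test_that("FASTA sequences round-trip", {
  seqs <- c(gA = "MKTAYIAK", gB = "AAAA")
  p <- withr::local_tempfile(fileext = ".fasta")
  writeFastaSeqs(seqs, p)
  expect_identical(readFastaSeqs(p), seqs)
})
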