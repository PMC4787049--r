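test_that("PDB parsing extracts resolution, method and sequences", {
  hl <- makeHelixPdb(10L)
  s <- parsePdb(hl, "helix")
  expect_identical(s@method, "XRAY")
  expect_equal(s@resolution, 2.0)
  expect_identical(chainSequence(s), strrep("A", 10L))
  expect_identical(s@chains[["A"]]$reportedSequence, strrep("A", 10L))

  nmr <- hl[!grepl("^REMARK   2|^EXPDTA", hl)]
  sn <- parsePdb(c("EXPDTA    SOLUTION NMR", nmr), "nmr")
  expect_identical(sn@method, "NMR")
  expect_true(is.na(sn@resolution))

  expect_error(parsePdb(c("HEADER    NOTHING", "END")), "no ATOM records")
  bad <- hl
  atomLine <- grep("^ATOM", bad)[1L]
  substr(bad[atomLine], 31, 38) <- "  xx.yyy"
  expect_error(parsePdb(bad), "malformed coordinate")
})

test_that("SEQRES longer than the resolved residues is detectable downstream", {
  fx <- makeMutantPdb(wtSeq = "AGSTAGSTAG", mutations = character(),
                      gaps = 5L)
  s <- parsePdb(fx$pdb, "gapped")
  # SEQRES carries 9 resolved residues; alignment to the 10-residue wild
  # type shows one interior gap
  aln <- alignStructureToWT(fx$wtSeq, chainSequence(s))
  expect_equal(aln@completeness, 9 / 10)
  expect_identical(nrow(aln@interiorGaps), 1L)
})

test_that("alignment computes identity, completeness, gaps and mutations", {
  a1 <- alignStructureToWT("MKTAYIAK", "MKTAYIAK")
  expect_equal(a1@identity, 1)
  expect_equal(a1@completeness, 1)
  expect_identical(nrow(a1@mutations), 0L)

  a2 <- alignStructureToWT("MKTAYIAK", "MKTYIAK")
  expect_equal(a2@identity, 7 / 8)
  expect_equal(a2@completeness, 7 / 8)
  expect_equal(a2@interiorGaps$start, 4L)
  expect_equal(a2@interiorGaps$length, 1L)

  a3 <- alignStructureToWT("MKTAYIAK", "MKTVYIAK")
  expect_equal(a3@identity, 0.875)
  expect_equal(a3@completeness, 1)
  expect_identical(a3@mutations$wtPos, 4L)

  # terminal truncation: completeness drops, no interior gap
  a4 <- alignStructureToWT("MKTAYIAK", "TAYIAK")
  expect_equal(a4@completeness, 6 / 8)
  expect_identical(nrow(a4@interiorGaps), 0L)
  expect_identical(a4@terminalGaps, c(2L, 0L))

  expect_error(alignStructureToWT("", "AAA"), "non-empty")
})

test_that("identity never exceeds completeness on random mutated fixtures", {
  set.seed(31)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  for (rep in 1:25) {
    wt <- paste(sample(aas, 30, replace = TRUE), collapse = "")
    obs <- strsplit(wt, "")[[1L]]
    nm <- sample(0:4, 1L)
    if (nm > 0) {
      pos <- sample(30, nm)
      obs[pos] <- sample(aas, nm, replace = TRUE)
    }
    drop <- sample(30, sample(0:3, 1L))
    if (length(drop)) obs <- obs[-drop]
    aln <- alignStructureToWT(wt, paste(obs, collapse = ""))
    expect_lte(aln@identity, aln@completeness + 1e-12)
  }
})

test_that("quality scores follow the stated combination", {
  s20 <- parsePdb(makeHelixPdb(8L), "x")
  aln <- alignStructureToWT(strrep("A", 8L), chainSequence(s20))
  s20@resolution <- 1.0
  q <- scoreStructure(aln, s20)
  expect_equal(q@combined, 1.0)
  expect_identical(q@group, "I")

  # identity 0.7, completeness 0.8, resolution 3.0 A (s_res 0.5)
  fake <- new("AlignmentResult", wtLength = 10L,
              pairs = matrix(integer(), ncol = 2,
                             dimnames = list(NULL, c("wtPos", "structResno"))),
              identity = 0.7, completeness = 0.8,
              mutations = data.frame(wtPos = 1L, wtAa = "A", obsAa = "V"),
              interiorGaps = data.frame(start = 5L, length = 1L),
              terminalGaps = c(0L, 1L))
  s20@resolution <- 3.0
  q2 <- scoreStructure(fake, s20)
  expect_equal(q2@sRes, 0.5)
  expect_equal(q2@combined, 0.5 * 0.7 + 0.3 * 0.8 + 0.2 * 0.5)

  # homology model: TM 0.8 with identical composition -> 0.9
  mdl <- parsePdb(makeHelixPdb(8L), "m")
  mdl@method <- "MODEL"
  mdl@resolution <- NA_real_
  mdl@tmScore <- 0.8
  ssc <- secondaryStructureComposition(mdl)
  q3 <- scoreStructure(aln, mdl, ssRef = ssc)
  expect_equal(q3@combined, 0.5 * 0.8 + 0.5 * 1.0)
  mdl@tmScore <- NA_real_
  expect_error(scoreStructure(aln, mdl, ssRef = ssc), "TM-score")
})

test_that("combined score stays in (0, 1] for extreme inputs", {
  s <- parsePdb(makeHelixPdb(8L), "x")
  s@resolution <- 9.0   # resolution score floor
  bad <- new("AlignmentResult", wtLength = 10L,
             pairs = matrix(integer(), ncol = 2,
                            dimnames = list(NULL, c("wtPos", "structResno"))),
             identity = 0, completeness = 0,
             mutations = data.frame(wtPos = integer(), wtAa = character(),
                                    obsAa = character()),
             interiorGaps = data.frame(start = integer(), length = integer()),
             terminalGaps = c(10L, 0L))
  q <- scoreStructure(bad, s)
  expect_gt(q@combined, 0)
  expect_lte(q@combined, 1)
})

test_that("group classification applies the stated bounds", {
  # non-periodic wild type so deletions cannot re-align as terminal gaps
  wt30 <- "ACDEFGHIKLMNPQRSTVWYACDEFGHIKL"
  mk <- function(mutations = character(), gaps = integer(), res = 2.0) {
    fx <- makeMutantPdb(wtSeq = wt30, mutations = mutations,
                        gaps = gaps, resolution = res)
    aln <- alignStructureToWT(fx$wtSeq, chainSequence(fx$structure))
    classifyGroup(aln, fx$structure)
  }
  expect_identical(mk(), "I")
  expect_identical(mk(c("7" = "V"), res = 2.2), "II")
  expect_identical(mk(gaps = 10:19), "III")
  # three sequential mutations exceed the run bound
  expect_identical(mk(c("7" = "V", "8" = "V", "9" = "V")), "III")
  # six scattered mutations exceed the total bound
  expect_identical(
    mk(c("3" = "V", "7" = "V", "11" = "V", "15" = "V", "19" = "V",
         "23" = "V")), "III")
  # resolution above 3 A blocks groups I and II
  expect_identical(mk(res = 3.5), "III")
})

test_that("ranking orders by combined score with the stated tie-breaks", {
  wt <- strrep("A", 10L)
  mkCand <- function(id, res) {
    s <- parsePdb(makeHelixPdb(10L), id)
    s@resolution <- res
    aln <- alignStructureToWT(wt, chainSequence(s))
    list(structure = s, alignment = aln, score = scoreStructure(aln, s))
  }
  # equal identity/completeness; resolution drives both score and tie-breaks
  rk <- rankStructures(list(mkCand("s_a", 2.5), mkCand("s_b", 1.2),
                            mkCand("s_c", 2.5)))
  expect_identical(rk$structure_id, c("s_b", "s_a", "s_c"))
  expect_identical(rk$representative, c(TRUE, FALSE, FALSE))
  expect_error(rankStructures(list()), "no candidate")
})

test_that("ranking matches an independent sort on many candidates", {
  wt <- strrep("A", 10L)
  set.seed(17)
  cands <- lapply(1:50, function(i) {
    s <- parsePdb(makeHelixPdb(10L), sprintf("s%02d", i))
    s@resolution <- round(runif(1, 1, 4), 1)
    aln <- alignStructureToWT(wt, chainSequence(s))
    list(structure = s, alignment = aln, score = scoreStructure(aln, s))
  })
  rk <- rankStructures(cands)
  df <- data.frame(
    id = vapply(cands, function(c) c$structure@structureId, character(1)),
    comb = vapply(cands, function(c) c$score@combined, numeric(1)),
    si = vapply(cands, function(c) c$score@sSi, numeric(1)),
    res = vapply(cands, function(c) c$structure@resolution, numeric(1)))
  ord <- order(-df$comb, -df$si, df$res, df$id)
  expect_identical(rk$structure_id, df$id[ord])
  # determinism across permutations of the input
  rk2 <- rankStructures(cands[sample(50)])
  expect_identical(rk2$structure_id, rk$structure_id)
})

test_that("multi-chain entries resolve to the best-matching chain", {
  hp <- attr(makeHairpinPdb(), "structure")
  # chain sequences identical; best chain is deterministic (first)
  bc <- bestChainFor(hp, strrep("G", 6L))
  expect_identical(bc$chain, "A")
  expect_equal(bc$alignment@identity, 1)
})

test_that("mapQc produces one representative per gene", {
  fx <- makeMutantPdb()
  seqs <- c(gA = fx$wtSeq, gB = strrep("A", 12L))
  structs <- list(gA = list(fx$structure),
                  gB = list(parsePdb(makeHelixPdb(12L), "hx")))
  rk <- mapQc(seqs, structs)
  expect_identical(sort(unique(rk$gene)), c("gA", "gB"))
  expect_equal(sum(rk$representative), 2L)
  expect_identical(rk$group[rk$gene == "gA"], "II")
  expect_identical(rk$group[rk$gene == "gB"], "I")
})
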