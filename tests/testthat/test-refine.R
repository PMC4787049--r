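test_that("mutation detection recovers the planted ground truth", {
  fx <- makeMutantPdb()
  aln <- alignStructureToWT(fx$wtSeq, chainSequence(fx$structure))
  muts <- detectMutations(aln)
  expect_equal(muts$wtPos, fx$truth$mutations$wtPos)
  expect_identical(muts$wtAa, fx$truth$mutations$wtAa)
  expect_identical(muts$obsAa, fx$truth$mutations$obsAa)

  clean <- makeMutantPdb(mutations = character())
  aln0 <- alignStructureToWT(clean$wtSeq, chainSequence(clean$structure))
  expect_identical(nrow(detectMutations(aln0)), 0L)

  scattered <- makeMutantPdb(wtSeq = "ACDEFGHIKLMNPQRSTVWY",
                             mutations = c("3" = "A", "9" = "W", "17" = "A"))
  alnS <- alignStructureToWT(scattered$wtSeq,
                             chainSequence(scattered$structure))
  expect_equal(detectMutations(alnS)$wtPos,
               scattered$truth$mutations$wtPos)
})

test_that("side-chain stripping keeps exactly the backbone", {
  fx <- makeMutantPdb(wtSeq = "AGSEAGSA", mutations = character())
  s <- fx$structure
  before <- s@chains[["A"]]$atoms
  expect_equal(sum(before$resno == 4L), 9L)   # Glu: 9 heavy atoms
  s2 <- stripSidechain(s, "A", 4L)
  after <- s2@chains[["A"]]$atoms
  expect_identical(sort(after$name[after$resno == 4L]),
                   sort(c("N", "CA", "C", "O")))
  # all other residues bit-identical
  keepA <- after[after$resno != 4L, ]
  keepB <- before[before$resno != 4L, ]
  rownames(keepA) <- rownames(keepB) <- NULL
  expect_identical(keepA, keepB)
  # Gly has no R-group to strip
  s3 <- stripSidechain(s, "A", 2L)
  expect_identical(s3@chains[["A"]]$atoms, before)
})

test_that("grafted side chains respect the ideal-geometry table", {
  fx <- makeMutantPdb(wtSeq = "AGSTAGST", mutations = character())
  s <- stripSidechain(fx$structure, "A", 5L)
  getxyz <- function(st, r, n) {
    a <- st@chains[["A"]]$atoms
    i <- which(a$resno == r & a$name == n)
    c(a$x[i], a$y[i], a$z[i])
  }
  sA <- graftSidechain(s, "A", 5L, "A")
  expect_equal(sqrt(sum((getxyz(sA, 5, "CB") - getxyz(sA, 5, "CA"))^2)),
               1.521, tolerance = 1e-6)
  ang <- gemprokit:::angle3(getxyz(sA, 5, "N"), getxyz(sA, 5, "CA"),
                            getxyz(sA, 5, "CB"))
  expect_equal(ang, 110.5, tolerance = 0.1)

  sG <- graftSidechain(stripSidechain(sA, "A", 5L), "A", 5L, "G")
  expect_identical(sum(sG@chains[["A"]]$atoms$resno == 5L), 4L)

  # every template builds without error and with the right atom count
  for (aa in strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]) {
    st <- graftSidechain(stripSidechain(sA, "A", 5L), "A", 5L, aa)
    expect_identical(sum(st@chains[["A"]]$atoms$resno == 5L),
                     4L + nrow(sidechainTemplate(aa)))
  }
  expect_error(graftSidechain(stripSidechain(sA, "A", 5L), "A", 5L, "Z"),
               "template|unknown")
})

test_that("steric minimisation relieves clashes monotonically", {
  twoAtoms <- new("StructureRecord", structureId = "two", method = "XRAY",
                  resolution = 2,
                  chains = list(A = list(
                    reportedSequence = "GG",
                    atoms = data.frame(resno = c(1L, 5L), resname = "GLY",
                                       name = "CA", element = "C",
                                       x = c(0, 2.0), y = 0, z = 0))))
  out <- minimizeSteric(twoAtoms,
                        data.frame(chain = "A", resno = 5L, name = "CA"))
  sep <- abs(diff(out$structure@chains[["A"]]$atoms$x))
  expect_gte(sep, 0.8 * (1.7 + 1.7) * (1 - 1e-3))
  expect_true(all(diff(out$energies) <= 1e-12))
  # fixed atom never moves
  expect_equal(out$structure@chains[["A"]]$atoms$x[1L], 0)

  # clash-free input: zero gradient, coordinates unchanged
  farAtoms <- twoAtoms
  farAtoms@chains[["A"]]$atoms$x <- c(0, 50)
  out2 <- minimizeSteric(farAtoms,
                         data.frame(chain = "A", resno = 5L, name = "CA"))
  expect_identical(out2$structure@chains[["A"]]$atoms$x, c(0, 50))
})

test_that("wild-type reversion fixes mutations without touching the backbone", {
  fx <- makeMutantPdb()   # Glu->His and Glu->Gln planted
  res <- revertToWildtype(fx$structure, fx$wtSeq)
  expect_identical(chainSequence(res$structure), fx$wtSeq)
  expect_identical(nrow(res$report), 2L)
  expect_identical(res$clashesAfter, 0L)
  expect_length(res$remarks, 2L)

  bb <- c("N", "CA", "C", "O")
  a0 <- fx$structure@chains[["A"]]$atoms
  a1 <- res$structure@chains[["A"]]$atoms
  b0 <- a0[a0$name %in% bb, c("x", "y", "z")]
  b1 <- a1[a1$name %in% bb, c("x", "y", "z")]
  expect_equal(nrow(b0), nrow(b1))
  expect_equal(sqrt(mean(as.matrix(b0 - b1)^2)), 0)

  aln <- alignStructureToWT(fx$wtSeq, chainSequence(res$structure))
  expect_equal(aln@identity, 1)
  expect_identical(classifyGroup(aln, res$structure), "I")

  # already wild type: no-op
  clean <- makeMutantPdb(mutations = character())
  res0 <- revertToWildtype(clean$structure, clean$wtSeq)
  expect_identical(nrow(res0$report), 0L)
  expect_identical(res0$structure@chains[["A"]]$atoms,
                   clean$structure@chains[["A"]]$atoms)

  # group III input is refused
  g3 <- makeGappedPdb()
  expect_error(revertToWildtype(g3$structure, g3$wtSeq), "group III")
})

test_that("reversion restores group I across random mutation fixtures", {
  set.seed(41)
  wt <- "ACDEFGHIKLMNPQRSTVWYLAMKTAYIAK"
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  for (rep in 1:5) {
    pos <- sort(sample(3:28, 2L))
    if (diff(pos) < 2L) next
    wtv <- strsplit(wt, "")[[1L]]
    muts <- vapply(pos, function(p)
      sample(setdiff(aas, wtv[p]), 1L), character(1))
    fx <- makeMutantPdb(wtSeq = wt,
                        mutations = stats::setNames(muts, pos))
    res <- revertToWildtype(fx$structure, fx$wtSeq)
    expect_identical(chainSequence(res$structure), wt)
    expect_identical(res$clashesAfter, 0L)
    aln <- alignStructureToWT(wt, chainSequence(res$structure))
    expect_identical(classifyGroup(aln, res$structure), "I")
  }
})
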