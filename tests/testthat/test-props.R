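isoAtom <- function(element = "C") {
  new("StructureRecord", structureId = "iso", method = "XRAY",
      resolution = 2,
      chains = list(A = list(
        reportedSequence = "G",
        atoms = data.frame(resno = 1L, resname = "GLY", name = "CA",
                           element = element, x = 0, y = 0, z = 0))))
}

test_that("SASA recovers the closed-form sphere area for isolated atoms", {
  for (el in c("C", "N", "O", "S")) {
    s <- isoAtom(el)
    r <- gemprokit:::vdwRadius(el) + 1.4
    got <- computeSasa(s)$total
    expect_lt(abs(got - 4 * pi * r^2) / (4 * pi * r^2), 0.02)
  }
  expect_error(computeSasa(isoAtom(), nPoints = 30L), "accuracy floor")
})

test_that("SASA of well-separated atoms is additive and converges", {
  s <- isoAtom()
  s@chains[["A"]]$atoms <- rbind(
    s@chains[["A"]]$atoms,
    data.frame(resno = 2L, resname = "GLY", name = "CA", element = "C",
               x = 100, y = 0, z = 0))
  s@chains[["A"]]$reportedSequence <- "GG"
  one <- computeSasa(isoAtom())$total
  expect_equal(computeSasa(s)$total, 2 * one, tolerance = 1e-9)

  helix <- attr(makeHelixPdb(8L), "structure")
  a <- computeSasa(helix, nPoints = 960L)$total
  b <- computeSasa(helix, nPoints = 3840L)$total
  expect_lt(abs(a - b) / b, 0.01)
})

test_that("surface/buried assignment is strict at 3 A^2", {
  x <- c(r1 = 3.01, r2 = 3.00, r3 = 0, r4 = 50)
  sb <- assignSurfaceBuried(x)
  expect_identical(unname(sb), c("SURFACE", "BURIED", "BURIED", "SURFACE"))
  # small extended peptide: everything exposed
  fx <- makeMutantPdb(wtSeq = "AGS", mutations = character())
  sasa <- computeSasa(fx$structure)
  expect_true(all(assignSurfaceBuried(sasa$perResidue) == "SURFACE"))
})

test_that("helix assignment matches the independent hydrogen-bond oracle", {
  s <- attr(makeHelixPdb(12L), "structure")
  ss <- assignSecondaryStructure(s)
  oracle <- oracleHelixLabels(s@chains[["A"]]$atoms)
  expect_identical(unname(ss == "H"), oracle == "H")
  expect_true(all(ss[3:10] == "H"))

  # dipeptide: no i,i+3 bond possible
  s2 <- attr(makeHelixPdb(2L), "structure")
  expect_true(all(assignSecondaryStructure(s2) == "-"))
})

test_that("antiparallel hairpin strand cores label as E", {
  hp <- attr(makeHairpinPdb(), "structure")
  ss <- assignSecondaryStructure(hp)
  expect_true(all(ss[c("A:2", "A:3", "A:4", "B:2", "B:3", "B:4")] == "E"))
})

test_that("disulfide counting flips at the 5 A cutoff", {
  near <- attr(makeDimerSsbondPdb(4.9), "structure")
  far <- attr(makeDimerSsbondPdb(5.1), "structure")
  expect_identical(as.integer(countSsBonds(near)), 1L)
  expect_identical(as.integer(countSsBonds(far)), 0L)
  noCys <- attr(makeHelixPdb(6L), "structure")
  expect_identical(as.integer(countSsBonds(noCys)), 0L)
  # each SG pairs at most once: three chains in a row -> one bond plus the
  # next nearest pair
  d <- attr(makeDimerSsbondPdb(4.0), "structure")
  expect_equal(attr(countSsBonds(d), "distances"), 4.0, tolerance = 1e-9)
})

test_that("contact counts match the brute-force recount and are isometric", {
  fx <- makeMutantPdb()
  s <- fx$structure
  flat <- gemprokit:::flattenAtoms(s)
  expect_identical(as.integer(countContacts(s)),
                   oracleContactCount(flat))
  # distant residues contribute nothing
  far <- isoAtom()
  far@chains[["A"]]$atoms <- rbind(
    far@chains[["A"]]$atoms,
    data.frame(resno = 9L, resname = "GLY", name = "CA", element = "C",
               x = 50, y = 0, z = 0))
  expect_identical(as.integer(countContacts(far)), 0L)
  # rigid rotation leaves the count unchanged
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  rot <- s
  xyz <- as.matrix(rot@chains[["A"]]$atoms[, c("x", "y", "z")]) %*% R
  rot@chains[["A"]]$atoms$x <- xyz[, 1L]
  rot@chains[["A"]]$atoms$y <- xyz[, 2L]
  rot@chains[["A"]]$atoms$z <- xyz[, 3L]
  expect_identical(countContacts(rot), countContacts(s))
})

test_that("residue depth behaves like a depth", {
  iso <- isoAtom()
  d <- computeResidueDepth(iso)
  expect_equal(unname(d[1L]), 1.7 + 1.4, tolerance = 0.01)

  # 13-atom cluster: centre plus icosahedral shell at radius ~3.1 A;
  # the central atom must be deeper than every peripheral one
  phi <- (1 + sqrt(5)) / 2
  dirs <- rbind(c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
                c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
                c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
  shell <- 3.1 * dirs / sqrt(sum(dirs[1L, ]^2))
  atoms <- data.frame(resno = 1:13, resname = "GLY", name = "CA",
                      element = "C",
                      x = c(0, shell[, 1L]), y = c(0, shell[, 2L]),
                      z = c(0, shell[, 3L]))
  cl <- new("StructureRecord", structureId = "cluster", method = "XRAY",
            resolution = 2,
            chains = list(A = list(reportedSequence = strrep("G", 13),
                                   atoms = atoms)))
  dep <- computeResidueDepth(cl)
  expect_true(all(dep[1L] > dep[2:13]))

  # translation invariance
  tr <- cl
  tr@chains[["A"]]$atoms$x <- tr@chains[["A"]]$atoms$x + 11.3
  expect_equal(as.numeric(computeResidueDepth(tr)), as.numeric(dep),
               tolerance = 1e-9)
})

test_that("the property vector satisfies its accounting invariants", {
  fx <- makeMutantPdb(wtSeq = "KKKKKK", mutations = character())
  pv <- propertyVector(fx$structure)
  expect_identical(names(pv), propertyFeatureNames())
  expect_equal(pv[["pct_positive"]], 100)
  expect_equal(pv[["pct_nonpolar"]], 0)
  expect_equal(pv[["pct_buried"]] + pv[["pct_surface"]], 100)
  ssSum <- sum(pv[c("pct_helix_H", "pct_strand_E", "pct_310_G", "pct_pi_I",
                    "pct_turn_T", "pct_bend_S", "pct_bridge_B",
                    "pct_disordered")])
  expect_equal(ssSum, 100)
  expect_equal(pv[["ovality"]],
               pv[["sasa_total"]] / pv[["n_res"]]^(2 / 3))
  expect_equal(pv[["mean_residue_sasa"]],
               pv[["sasa_total"]] / pv[["n_res"]])

  # ovality arithmetic: SASA 100 with 8 residues -> 25
  expect_equal(100 / 8^(2 / 3), 25)

  # class quartets sum to 100 where the subset is non-empty
  helix <- attr(makeHelixPdb(10L), "structure")
  pv2 <- propertyVector(helix)
  surf <- pv2[c("pct_surface_nonpolar", "pct_surface_polar",
                "pct_surface_positive", "pct_surface_negative")]
  if (!anyNA(surf)) expect_equal(sum(surf), 100)
})

test_that("property vector is invariant under rigid-body transforms", {
  s <- attr(makeHelixPdb(8L), "structure")
  pv <- propertyVector(s, nPoints = 960L)
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3)
  rot <- s
  xyz <- as.matrix(rot@chains[["A"]]$atoms[, c("x", "y", "z")]) %*% R
  rot@chains[["A"]]$atoms$x <- xyz[, 1L] + 5
  rot@chains[["A"]]$atoms$y <- xyz[, 2L] - 3
  rot@chains[["A"]]$atoms$z <- xyz[, 3L] + 7
  pv2 <- propertyVector(rot, nPoints = 960L)
  # lattice quantities move by less than a percent; counts are exact
  expect_equal(pv2[["sasa_total"]], pv[["sasa_total"]],
               tolerance = 0.01)
  expect_identical(pv2[["n_contacts"]], pv[["n_contacts"]])
  expect_identical(pv2[["pct_helix_H"]], pv[["pct_helix_H"]])
})
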