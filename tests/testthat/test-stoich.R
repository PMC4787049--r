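test_that("the protein stoichiometric matrix is built deterministically", {
  cx <- list(list(enzymeId = "a:2", subunits = c(a = 2L)),
             list(enzymeId = "a:1|b:1", subunits = c(a = 1L, b = 1L)))
  P <- buildStoichMatrix(cx)
  m <- stoichMatrix(P)
  expect_identical(rownames(m), c("a", "b"))
  expect_identical(colnames(m), c("a:1|b:1", "a:2"))
  expect_equal(unname(m), matrix(c(1, 1, 2, 0), 2))
  expect_error(buildStoichMatrix(list()), "empty")
})

test_that("complex lists round-trip through the TSV format", {
  set.seed(12)
  cx <- lapply(1:100, function(i) {
    genes <- sort(sample(sprintf("g%03d", 1:40), sample(1:3, 1L)))
    sub <- stats::setNames(sample(1:4, length(genes), replace = TRUE), genes)
    list(enzymeId = paste(genes, sub, sep = ":", collapse = "|"),
         subunits = sub)
  })
  cx <- cx[!duplicated(vapply(cx, `[[`, character(1), "enzymeId"))]
  p <- withr::local_tempfile(fileext = ".tsv")
  writeComplexTsv(cx, p)
  back <- readComplexTsv(p)
  back <- back[match(vapply(cx, `[[`, character(1), "enzymeId"),
                     vapply(back, `[[`, character(1), "enzymeId"))]
  expect_equal(unname(lapply(back, `[[`, "subunits")),
               unname(lapply(cx, `[[`, "subunits")))
})

test_that("abundance fitting solves the stated LP", {
  P <- matrix(c(2, 1), 2, 1, dimnames = list(c("a", "b"), "E1"))
  fit <- fitAbundances(P, c(a = 4, b = 2))
  expect_equal(unname(fit$e), 2, tolerance = 1e-8)
  expect_equal(fit$fTotalMin, 0, tolerance = 1e-8)

  fit2 <- fitAbundances(P, c(a = 5, b = 2))
  oracle <- oracleSingleEnzymeFit(c(2, 1), c(5, 2))
  expect_equal(unname(fit2$e), oracle$e, tolerance = 1e-3)
  expect_equal(fit2$fTotalMin, oracle$tot, tolerance = 1e-3)

  fit0 <- fitAbundances(P, c(a = 0, b = 0))
  expect_equal(unname(fit0$e), 0)
  expect_equal(unname(fit0$f), c(0, 0))

  expect_error(fitAbundances(P, c(a = -1, b = 0)), "negative")
  expect_error(fitAbundances(P, c(a = 1)), "missing")
})

test_that("noiseless abundances recover the planted enzyme levels", {
  for (seed in c(1L, 2L, 3L)) {
    set.seed(seed)
    m <- matrix(rpois(200, 1.2), 20, 10)
    diag(m[1:10, 1:10]) <- diag(m[1:10, 1:10]) + 1L
    rownames(m) <- sprintf("p%02d", 1:20)
    colnames(m) <- sprintf("e%02d", 1:10)
    eTrue <- runif(10, 0, 5)
    fx <- makeAbundanceSet(m, eTrue, noiseSd = 0, seed = seed)
    fit <- fitAbundances(m, fx$abundances)
    expect_lt(max(abs(fit$e - fx$eTrue)), 1e-6)
    expect_lt(fit$fTotalMin, 1e-6)
    # with noise, total free peptide is bounded by the total perturbation
    fxN <- makeAbundanceSet(m, eTrue, noiseSd = 0.1, seed = seed)
    fitN <- fitAbundances(m, fxN$abundances)
    expect_lte(fitN$fTotalMin, sum(abs(fxN$noise)) + 1e-6)
  }
})

test_that("FVA brackets the point estimate and resolves degeneracy", {
  # one protein shared by two single-copy enzymes: e1 + e2 = 4
  P <- matrix(c(1, 1), 1, 2,
              dimnames = list("a", c("E1", "E2")))
  fit <- fitAbundances(P, c(a = 4))
  fva <- fvaEnzymes(P, c(a = 4), fit$fTotalMin)
  expect_equal(fva$min, c(0, 0), tolerance = 1e-5)
  expect_equal(fva$max, c(4, 4), tolerance = 1e-5)
  expect_true(all(fva$min - 1e-6 <= fit$e & fit$e <= fva$max + 1e-6))

  # full-column-rank system: ranges collapse onto the truth
  set.seed(8)
  m <- diag(3) + matrix(rpois(9, 0.5), 3)
  rownames(m) <- c("a", "b", "c"); colnames(m) <- c("E1", "E2", "E3")
  eT <- c(1, 2, 3)
  p <- stats::setNames(as.numeric(m %*% eT), rownames(m))
  fit2 <- fitAbundances(m, p)
  fva2 <- fvaEnzymes(m, p, fit2$fTotalMin)
  expect_lt(max(abs(fva2$min - eT)), 1e-5)
  expect_lt(max(abs(fva2$max - eT)), 1e-5)
})

test_that("FVA intervals widen with the free-peptide slack", {
  P <- matrix(c(1, 1), 1, 2, dimnames = list("a", c("E1", "E2")))
  p <- c(a = 4)
  tight <- fvaEnzymes(P, p, 1, relTol = 1e-8, absTol = 0)
  loose <- fvaEnzymes(P, p, 1, relTol = 0.5, absTol = 0)
  expect_true(all(loose$max >= tight$max - 1e-9))
  expect_true(all(loose$min <= tight$min + 1e-9))
})

test_that("solutions are invariant to row/column permutations", {
  set.seed(21)
  m <- matrix(rpois(50, 1), 10, 5) + diag(1, 10, 5)
  rownames(m) <- sprintf("p%02d", 1:10)
  colnames(m) <- sprintf("e%02d", 1:5)
  p <- stats::setNames(as.numeric(m %*% runif(5, 1, 3)) + 0.5, rownames(m))
  ref <- fitAbundances(m, p)
  mp <- m[sample(10), sample(5)]
  got <- fitAbundances(mp, p)
  expect_equal(got$fTotalMin, ref$fTotalMin, tolerance = 1e-6)
  expect_equal(got$f[names(ref$f)], ref$f, tolerance = 1e-5)
})

test_that("complex census statistics match hand counts", {
  cx <- list(list(enzymeId = "A:2", subunits = c(A = 2L)),
             list(enzymeId = "B:3", subunits = c(B = 3L)),
             list(enzymeId = "A:1|B:1", subunits = c(A = 1L, B = 1L)))
  st <- stoichStats(cx)
  expect_equal(st$homomer_fraction, 2 / 3)
  expect_equal(st$even_fraction_among_homomers, 1 / 2)
  expect_identical(st$multi_complex_genes, c("A", "B"))

  allHet <- list(list(enzymeId = "x", subunits = c(a = 1L, b = 1L)))
  expect_equal(stoichStats(allHet)$homomer_fraction, 0)

  # 500 random complexes vs a direct recount
  set.seed(99)
  big <- lapply(1:500, function(i) {
    genes <- sort(sample(sprintf("g%03d", 1:120), sample(1:3, 1L)))
    sub <- stats::setNames(sample(1:6, length(genes), replace = TRUE), genes)
    list(enzymeId = paste(genes, sub, sep = ":", collapse = "|"),
         subunits = sub)
  })
  big <- big[!duplicated(vapply(big, `[[`, character(1), "enzymeId"))]
  st2 <- stoichStats(big)
  isHomo <- vapply(big, function(c) length(c$subunits) == 1L, logical(1))
  expect_equal(st2$homomer_fraction, mean(isHomo))
  even <- vapply(big[isHomo], function(c) c$subunits[[1L]] %% 2L == 0L,
                 logical(1))
  expect_equal(st2$even_fraction_among_homomers, mean(even))
  cnt <- table(unlist(lapply(big, function(c) names(c$subunits))))
  expect_identical(st2$multi_complex_genes, sort(names(cnt)[cnt >= 2L]))

  # free-abundance ranking is sorted descending
  P <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("a", "b"), c("E1", "E2")))
  sol <- fitAbundances(P, c(a = 1, b = 5.5))
  solLoose <- list(e = sol$e, f = c(a = 0.2, b = 3))
  rk <- stoichStats(cx, solLoose)$free_abundance_ranking
  expect_identical(rk$gene, c("b", "a"))
})
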