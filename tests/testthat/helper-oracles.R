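# Independent oracles used to cross-check the package's implementations.
# Each oracle takes a deliberately different route from the code it checks.

# Evaluate a GPR rule string directly with R's boolean machinery: gene ids
# are substituted by TRUE/FALSE and and/or by &/| before parsing. Completely
# independent of parseGpr().
oracleEvalGprString <- function(text, availableGenes, allGenes) {
  expr <- text
  for (g in allGenes[order(-nchar(allGenes))]) {
    val <- if (g %in% availableGenes) "TRUE" else "FALSE"
    expr <- gsub(paste0("(?<![A-Za-z0-9_.-])", g, "(?![A-Za-z0-9_.-])"),
                 val, expr, perl = TRUE)
  }
  expr <- gsub("\\band\\b", "&", expr, ignore.case = TRUE)
  expr <- gsub("\\bor\\b", "|", expr, ignore.case = TRUE)
  eval(parse(text = expr))
}

# Evaluate a DNF complex list: true iff some complex has all subunits present.
oracleEvalComplexes <- function(complexes, availableGenes) {
  any(vapply(complexes, function(cx)
    all(names(cx$subunits) %in% availableGenes), logical(1)))
}

# Exhaustive truth-table equivalence of a GPR string and its DNF expansion.
expectGprDnfEquivalent <- function(text) {
  ast <- parseGpr(text)
  genes <- gprGenes(ast)
  stopifnot(length(genes) <= 10L)
  cx <- expandComplexes(ast)
  for (mask in 0:(2^length(genes) - 1L)) {
    avail <- genes[bitwAnd(mask, 2^(seq_along(genes) - 1L)) > 0L]
    expect_identical(oracleEvalComplexes(cx, avail),
                     oracleEvalGprString(text, avail, genes),
                     info = paste("GPR:", text, "avail:",
                                  paste(avail, collapse = ",")))
  }
}

# Minimal independent Kabsch-Sander assignment for helices: reconstructs
# amide hydrogens, computes every i->i+4 hydrogen-bond energy from the raw
# atom table with matrix algebra (not the package's backbone walker), and
# labels a residue H when it lies strictly inside at least two such bonds.
oracleHelixLabels <- function(atoms) {
  getAt <- function(r, n) {
    i <- which(atoms$resno == r & atoms$name == n)
    if (!length(i)) return(NULL)
    c(atoms$x[i], atoms$y[i], atoms$z[i])
  }
  resnos <- sort(unique(atoms$resno))
  n <- length(resnos)
  H <- vector("list", n)
  for (k in 2:n) {
    N <- getAt(resnos[k], "N"); CA <- getAt(resnos[k], "CA")
    Cp <- getAt(resnos[k - 1L], "C")
    d <- (N - Cp) / sqrt(sum((N - Cp)^2)) + (N - CA) / sqrt(sum((N - CA)^2))
    H[[k]] <- N + 1.01 * d / sqrt(sum(d^2))
  }
  nrm <- function(v) sqrt(sum(v * v))
  bonded <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(i - j) < 2L || is.null(H[[j]])) next
    O <- getAt(resnos[i], "O"); C <- getAt(resnos[i], "C")
    N <- getAt(resnos[j], "N")
    e <- 27.888 * (1 / nrm(O - N) + 1 / nrm(C - H[[j]]) -
                   1 / nrm(O - H[[j]]) - 1 / nrm(C - N))
    bonded[i, j] <- e < -0.5
  }
  covered <- integer(n)
  for (i in seq_len(n - 4L)) {
    if (bonded[i, i + 4L]) covered[(i + 1L):(i + 3L)] <-
        covered[(i + 1L):(i + 3L)] + 1L
  }
  ifelse(covered >= 2L, "H", "-")
}

# Brute-force graph isomorphism over all atom permutations (<= 8 atoms).
oracleIsomorphic <- function(g1, g2) {
  n <- nrow(g1$atoms)
  if (n != nrow(g2$atoms) || nrow(g1$bonds) != nrow(g2$bonds)) return(FALSE)
  bondKey <- function(g, perm = seq_len(n)) {
    if (!nrow(g$bonds)) return(character())
    sort(paste(pmin(perm[g$bonds$i], perm[g$bonds$j]),
               pmax(perm[g$bonds$i], perm[g$bonds$j]),
               g$bonds$order))
  }
  atomKey <- function(g, ord = seq_len(n))
    paste(g$atoms$element, g$atoms$charge, g$atoms$chirality)[ord]
  ref <- bondKey(g2)
  refAtoms <- paste(g2$atoms$element, g2$atoms$charge, g2$atoms$chirality)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  for (perm in perms(seq_len(n))) {
    # perm maps g1 atom k to g2 atom perm[k]
    ok <- all(paste(g1$atoms$element, g1$atoms$charge,
                    g1$atoms$chirality) == refAtoms[perm])
    if (ok && identical(bondKey(g1, perm), ref)) return(TRUE)
  }
  FALSE
}

# Grid-search LP oracle for single-enzyme abundance fitting.
oracleSingleEnzymeFit <- function(column, p, step = 1e-3) {
  eMax <- min(p / column)
  grid <- seq(0, eMax, by = step)
  best <- NULL
  for (e in grid) {
    f <- p - column * e
    if (any(f < -1e-12)) next
    tot <- sum(f)
    if (is.null(best) || tot < best$tot) best <- list(e = e, tot = tot)
  }
  best
}

# O(n^2) recount of heavy-atom contacts from a flat atom table.
oracleContactCount <- function(atoms, cutoff = 4.5, minSep = 3L) {
  n <- nrow(atoms)
  cnt <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- sqrt((atoms$x[i] - atoms$x[j])^2 + (atoms$y[i] - atoms$y[j])^2 +
              (atoms$z[i] - atoms$z[j])^2)
    sep <- if (atoms$chain[i] != atoms$chain[j]) Inf else
      abs(atoms$resno[i] - atoms$resno[j])
    if (d <= cutoff && sep >= minSep) cnt <- cnt + 1L
  }
  cnt
}

# Adjusted Rand index (used when mclust is unavailable the helper falls
# back to the closed form).
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  (sij - si * sj / n2) / ((si + sj) / 2 - si * sj / n2)
}
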