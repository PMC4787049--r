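# Reversion of mutated residues to the wild-type sequence: strip the side
# chain, graft an idealised wild-type side chain from internal coordinates,
# and relieve steric clashes with a steepest-descent minimiser.

.backboneAtoms <- c("N", "CA", "C", "O")

# Idealised side-chain internal coordinates. Each atom is placed by NeRF from
# three previously placed atoms (refA-refB-refC): bond refC-atom, angle
# refB-refC-atom, dihedral refA-refB-refC-atom. Chi angles default to the
# extended conformation (180 deg); branches sit at +/-120 offsets, ring
# dihedrals at 0/180 (planar). CB uses the L-configuration improper
# C-N-CA-CB = +122.55 deg.
.tplRow <- function(name, a, b, c, bond, ang, dih) {
  data.frame(name = name, refA = a, refB = b, refC = c,
             bond = bond, angle = ang, dihedral = dih,
             stringsAsFactors = FALSE)
}

.cbRow <- .tplRow("CB", "C", "N", "CA", 1.521, 110.5, 122.55)

.sidechainTemplates <- local({
  t <- list()
  t$G <- .tplRow(character(), character(), character(), character(),
                 numeric(), numeric(), numeric())
  t$A <- .cbRow
  t$S <- rbind(.cbRow, .tplRow("OG", "N", "CA", "CB", 1.417, 110.8, 180))
  t$C <- rbind(.cbRow, .tplRow("SG", "N", "CA", "CB", 1.808, 114.4, 180))
  t$T <- rbind(.cbRow,
               .tplRow("OG1", "N", "CA", "CB", 1.433, 109.5, 180),
               .tplRow("CG2", "N", "CA", "CB", 1.521, 110.5, -60))
  t$V <- rbind(.cbRow,
               .tplRow("CG1", "N", "CA", "CB", 1.521, 110.5, 180),
               .tplRow("CG2", "N", "CA", "CB", 1.521, 110.5, -60))
  t$L <- rbind(.cbRow,
               .tplRow("CG", "N", "CA", "CB", 1.530, 116.3, 180),
               .tplRow("CD1", "CA", "CB", "CG", 1.521, 110.7, 180),
               .tplRow("CD2", "CA", "CB", "CG", 1.521, 110.7, 60))
  t$I <- rbind(.cbRow,
               .tplRow("CG1", "N", "CA", "CB", 1.530, 110.4, 180),
               .tplRow("CG2", "N", "CA", "CB", 1.521, 110.5, -60),
               .tplRow("CD1", "CA", "CB", "CG1", 1.513, 113.8, 180))
  t$M <- rbind(.cbRow,
               .tplRow("CG", "N", "CA", "CB", 1.520, 114.1, 180),
               .tplRow("SD", "CA", "CB", "CG", 1.803, 112.7, 180),
               .tplRow("CE", "CB", "CG", "SD", 1.791, 100.9, 180))
  t$P <- rbind(.cbRow,
               .tplRow("CG", "N", "CA", "CB", 1.492, 104.5, -30),
               .tplRow("CD", "CA", "CB", "CG", 1.503, 106.1, 35))
  t$F <- rbind(.cbRow,
               .tplRow("CG", "N", "CA", "CB", 1.502, 113.8, 180),
               .tplRow("CD1", "CA", "CB", "CG", 1.390, 120.8, 90),
               .tplRow("CD2", "CA", "CB", "CG", 1.390, 120.8, -90),
               .tplRow("CE1", "CB", "CG", "CD1", 1.390, 120.0, 180),
               .tplRow("CE2", "CB", "CG", "CD2", 1.390, 120.0, 180),
               .tplRow("CZ", "CG", "CD1", "CE1", 1.390, 120.0, 0))
  t$Y <- rbind(t$F, .tplRow("OH", "CD1", "CE1", "CZ", 1.376, 120.0, 180))
  t$W <- rbind(.cbRow,
               .tplRow("CG", "N", "CA", "CB", 1.498, 113.6, 180),
               .tplRow("CD1", "CA", "CB", "CG", 1.365, 126.9, 90),
               .tplRow("CD2", "CA", "CB", "CG", 1.433, 126.7, -90),
               .tplRow("NE1", "CB", "CG", "CD1", 1.374, 110.2, 180),
               .tplRow("CE2", "CB", "CG", "CD2", 1.409, 107.2, 180),
               .tplRow("CE3", "CB", "CG", "CD2", 1.398, 133.9, 0),
               .tplRow("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, 180),
               .tplRow("CZ3", "CG", "CD2", "CE3", 1.382, 118.6, 180),
               .tplRow("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, 0))
  t$D <- rbind(.cbRow,
               .tplRow("CG", "N", "CA", "CB", 1.516, 112.6, 180),
               .tplRow("OD1", "CA", "CB", "CG", 1.249, 118.4, 0),
               .tplRow("OD2", "CA", "CB", "CG", 1.249, 118.4, 180))
  t$N <- rbind(.cbRow,
               .tplRow("CG", "N", "CA", "CB", 1.516, 112.6, 180),
               .tplRow("OD1", "CA", "CB", "CG", 1.231, 120.8, 0),
               .tplRow("ND2", "CA", "CB", "CG", 1.328, 116.4, 180))
  t$E <- rbind(.cbRow,
               .tplRow("CG", "N", "CA", "CB", 1.520, 114.1, 180),
               .tplRow("CD", "CA", "CB", "CG", 1.516, 112.6, 180),
               .tplRow("OE1", "CB", "CG", "CD", 1.249, 118.4, 0),
               .tplRow("OE2", "CB", "CG", "CD", 1.249, 118.4, 180))
  t$Q <- rbind(.cbRow,
               .tplRow("CG", "N", "CA", "CB", 1.520, 114.1, 180),
               .tplRow("CD", "CA", "CB", "CG", 1.516, 112.6, 180),
               .tplRow("OE1", "CB", "CG", "CD", 1.231, 120.8, 0),
               .tplRow("NE2", "CB", "CG", "CD", 1.328, 116.4, 180))
  t$K <- rbind(.cbRow,
               .tplRow("CG", "N", "CA", "CB", 1.520, 114.1, 180),
               .tplRow("CD", "CA", "CB", "CG", 1.520, 111.3, 180),
               .tplRow("CE", "CB", "CG", "CD", 1.520, 111.3, 180),
               .tplRow("NZ", "CG", "CD", "CE", 1.489, 111.9, 180))
  t$R <- rbind(.cbRow,
               .tplRow("CG", "N", "CA", "CB", 1.520, 114.1, 180),
               .tplRow("CD", "CA", "CB", "CG", 1.520, 111.3, 180),
               .tplRow("NE", "CB", "CG", "CD", 1.461, 112.0, 180),
               .tplRow("CZ", "CG", "CD", "NE", 1.329, 124.2, 180),
               .tplRow("NH1", "CD", "NE", "CZ", 1.326, 120.0, 0),
               .tplRow("NH2", "CD", "NE", "CZ", 1.326, 120.0, 180))
  t$H <- rbind(.cbRow,
               .tplRow("CG", "N", "CA", "CB", 1.492, 113.8, 180),
               .tplRow("ND1", "CA", "CB", "CG", 1.380, 122.7, 90),
               .tplRow("CD2", "CA", "CB", "CG", 1.354, 131.1, -90),
               .tplRow("CE1", "CB", "CG", "ND1", 1.326, 109.2, 180),
               .tplRow("NE2", "CB", "CG", "CD2", 1.373, 107.2, 180))
  t
})

#' Idealised side-chain template for an amino acid
#' @param aa one-letter amino-acid code
#' @return data.frame of internal-coordinate rows (name, refA, refB, refC,
#'   bond, angle, dihedral)
#' @export
sidechainTemplate <- function(aa) {
  tpl <- .sidechainTemplates[[toupper(aa)]]
  if (is.null(tpl)) stop("no side-chain template for amino acid '", aa, "'")
  tpl
}

#' Default configuration for the steric-clash minimiser
#'
#' The clash potential is purely repulsive harmonic: for every non-excluded
#' atom pair closer than \code{r0 = scale * (vdW_i + vdW_j)} the energy is
#' \code{k * (r0 - r)^2}. Pairs within one residue and 1-2/1-3
#' backbone-bonded pairs are excluded.
#'
#' @param scale clash scale factor on the vdW-sum contact distance
#' @param k force constant (energy / A^2)
#' @param step base step size in Angstrom
#' @param tol gradient-norm convergence tolerance
#' @param maxit maximum iterations
#' @return a list
#' @export
minimizerConfig <- function(scale = 0.8, k = 1.0, step = 0.01,
                            tol = 1e-4, maxit = 5000L) {
  stopifnot(scale > 0, k > 0, step > 0, tol > 0, maxit > 0)
  list(scale = scale, k = k, step = step, tol = tol, maxit = as.integer(maxit))
}

#' Mutations of a structure relative to the wild-type sequence
#' @param aln an [AlignmentResult-class]
#' @return data.frame (wtPos, wtAa, obsAa), ordered by position
#' @export
detectMutations <- function(aln) {
  m <- aln@mutations
  m[order(m$wtPos), , drop = FALSE]
}

#' Strip a residue to its peptide backbone
#'
#' Removes every atom of the residue except N, CA, C, O. All other residues
#' are untouched.
#'
#' @param structure a [StructureRecord-class]
#' @param chain chain id
#' @param resno residue number
#' @return the modified [StructureRecord-class]
#' @export
stripSidechain <- function(structure, chain, resno) {
  atoms <- structure@chains[[chain]]$atoms
  inRes <- atoms$resno == resno
  if (!any(inRes)) stop("no residue ", resno, " in chain ", chain)
  have <- atoms$name[inRes]
  if (!all(.backboneAtoms %in% have))
    stop("residue ", resno, " lacks backbone atom(s): ",
         paste(setdiff(.backboneAtoms, have), collapse = ", "))
  keep <- !inRes | atoms$name %in% .backboneAtoms
  structure@chains[[chain]]$atoms <- atoms[keep, , drop = FALSE]
  rownames(structure@chains[[chain]]$atoms) <- NULL
  structure
}

#' Graft an idealised wild-type side chain onto a stripped residue
#'
#' Side-chain atoms are built by internal-coordinate (NeRF) construction from
#' the shipped ideal-geometry table; the residue name is updated. CB sits
#' 1.521 A from CA in tetrahedral L-configuration; chi angles start extended.
#'
#' @param structure a [StructureRecord-class]
#' @param chain chain id
#' @param resno residue number (must be stripped to backbone)
#' @param targetAa one-letter code of the wild-type amino acid
#' @param chi1Offset rotation (degrees) added to the extended chi1; used to
#'   fall back to alternative rotamers when the extended one jams against
#'   neighbouring side chains
#' @return the modified [StructureRecord-class]
#' @export
graftSidechain <- function(structure, chain, resno, targetAa,
                           chi1Offset = 0) {
  tpl <- sidechainTemplate(targetAa)
  if (chi1Offset != 0 && nrow(tpl)) {
    chi1Rows <- tpl$refA == "N" & tpl$refB == "CA" & tpl$refC == "CB"
    tpl$dihedral[chi1Rows] <- tpl$dihedral[chi1Rows] + chi1Offset
  }
  atoms <- structure@chains[[chain]]$atoms
  inRes <- which(atoms$resno == resno)
  if (!length(inRes)) stop("no residue ", resno, " in chain ", chain)
  have <- atoms$name[inRes]
  if (length(setdiff(have, .backboneAtoms)))
    stop("residue ", resno, " is not stripped to its backbone")
  coords <- list()
  for (i in inRes)
    coords[[atoms$name[i]]] <- c(atoms$x[i], atoms$y[i], atoms$z[i])
  newRows <- list()
  if (nrow(tpl)) {
    for (k in seq_len(nrow(tpl))) {
      row <- tpl[k, ]
      pos <- nerfPlace(coords[[row$refA]], coords[[row$refB]],
                       coords[[row$refC]], row$bond, row$angle, row$dihedral)
      coords[[row$name]] <- pos
      newRows[[k]] <- data.frame(
        resno = resno, resname = aa1to3(targetAa), name = row$name,
        element = substr(gsub("[0-9]", "", row$name), 1, 1),
        x = pos[1L], y = pos[2L], z = pos[3L], stringsAsFactors = FALSE)
    }
  }
  atoms$resname[inRes] <- aa1to3(targetAa)
  if (length(newRows)) {
    insert <- do.call(rbind, newRows)
    before <- atoms[seq_len(max(inRes)), , drop = FALSE]
    after <- if (max(inRes) < nrow(atoms))
      atoms[(max(inRes) + 1L):nrow(atoms), , drop = FALSE] else atoms[0, ]
    atoms <- rbind(before, insert, after)
  }
  rownames(atoms) <- NULL
  structure@chains[[chain]]$atoms <- atoms
  structure
}

# Flatten all chains into one atom table with global indices.
flattenAtoms <- function(structure) {
  out <- list()
  for (ch in names(structure@chains)) {
    a <- structure@chains[[ch]]$atoms
    if (nrow(a)) out[[ch]] <- cbind(chain = ch, a, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# 1-2/1-3 backbone exclusion between adjacent residues: C(i)-N(i+1) plus
# CA(i)/O(i)-N(i+1) and C(i)-CA(i+1).
.isExcludedPair <- function(flat, i, j) {
  if (flat$chain[i] != flat$chain[j]) return(FALSE)
  if (flat$resno[i] == flat$resno[j]) return(TRUE)
  d <- flat$resno[j] - flat$resno[i]
  if (abs(d) != 1L) return(FALSE)
  if (d < 0) { tmp <- i; i <- j; j <- tmp }
  key <- paste(flat$name[i], flat$name[j])
  key %in% c("C N", "CA N", "O N", "C CA")
}

#' Steric clash pairs of a structure
#'
#' Heavy-atom pairs closer than \code{scale * (vdW_i + vdW_j)}, excluding
#' pairs within one residue and 1-2/1-3 backbone-bonded pairs.
#'
#' @param structure a [StructureRecord-class]
#' @param scale clash scale factor (default 0.8)
#' @return data.frame: i, j (row indices into the flattened atom table),
#'   r, r0
#' @export
clashPairs <- function(structure, scale = 0.8) {
  flat <- flattenAtoms(structure)
  xyz <- as.matrix(flat[, c("x", "y", "z")])
  rad <- vdwRadius(flat$element)
  n <- nrow(flat)
  out <- list()
  if (n >= 2L) {
    dm <- as.matrix(stats::dist(xyz))
    r0m <- outer(rad, rad, `+`) * scale
    hits <- which(dm < r0m & upper.tri(dm), arr.ind = TRUE)
    for (k in seq_len(nrow(hits))) {
      i <- hits[k, 1L]; j <- hits[k, 2L]
      if (.isExcludedPair(flat, i, j)) next
      out[[length(out) + 1L]] <- data.frame(i = i, j = j,
                                            r = dm[i, j], r0 = r0m[i, j])
    }
  }
  if (!length(out))
    return(data.frame(i = integer(), j = integer(),
                      r = numeric(), r0 = numeric()))
  do.call(rbind, out)
}

#' Relieve steric clashes by steepest descent
#'
#' Minimises the purely repulsive harmonic clash energy
#' \code{sum over pairs with r < r0 of k (r0 - r)^2} by moving only the
#' designated movable atoms. The energy is non-increasing at every iteration
#' (step halving on uphill proposals); iteration stops at the gradient-norm
#' tolerance or the iteration cap.
#'
#' @param structure a [StructureRecord-class]
#' @param movable data.frame selecting movable atoms (columns chain, resno,
#'   name)
#' @param cfg a [minimizerConfig()] list
#' @return list: \code{structure} (minimised), \code{energies} (per-iteration
#'   energy trace), \code{converged}
#' @export
minimizeSteric <- function(structure, movable, cfg = minimizerConfig()) {
  if (!nrow(movable)) stop("movable atom set is empty")
  flat <- flattenAtoms(structure)
  movKey <- paste(movable$chain, movable$resno, movable$name)
  isMov <- paste(flat$chain, flat$resno, flat$name) %in% movKey
  if (!any(isMov)) stop("no movable atoms found in the structure")
  xyz <- as.matrix(flat[, c("x", "y", "z")])
  rad <- vdwRadius(flat$element)
  n <- nrow(flat)

  pairList <- function() {
    # pairs that can contribute: at least one movable member
    dm <- as.matrix(stats::dist(xyz))
    r0m <- outer(rad, rad, `+`) * cfg$scale
    hits <- which(dm < r0m * 1.2 & upper.tri(dm), arr.ind = TRUE)
    keep <- logical(nrow(hits))
    for (k in seq_len(nrow(hits))) {
      i <- hits[k, 1L]; j <- hits[k, 2L]
      keep[k] <- (isMov[i] || isMov[j]) && !.isExcludedPair(flat, i, j)
    }
    hits[keep, , drop = FALSE]
  }

  energyGrad <- function(pos, prs) {
    e <- 0
    g <- matrix(0, n, 3L)
    for (k in seq_len(nrow(prs))) {
      i <- prs[k, 1L]; j <- prs[k, 2L]
      dvec <- pos[i, ] - pos[j, ]
      r <- sqrt(sum(dvec * dvec))
      r0 <- (rad[i] + rad[j]) * cfg$scale
      if (r >= r0 || r < 1e-9) next
      e <- e + cfg$k * (r0 - r)^2
      gmag <- -2 * cfg$k * (r0 - r) / r
      g[i, ] <- g[i, ] + gmag * dvec
      g[j, ] <- g[j, ] - gmag * dvec
    }
    g[!isMov, ] <- 0
    list(e = e, g = g)
  }

  prs <- pairList()
  eg <- energyGrad(xyz, prs)
  if (!is.finite(eg$e)) stop("non-finite clash energy")
  energies <- eg$e
  converged <- FALSE
  it <- 0L
  while (it < cfg$maxit) {
    it <- it + 1L
    gnorm <- sqrt(sum(eg$g^2))
    if (gnorm < cfg$tol) { converged <- TRUE; break }
    dir <- -eg$g / gnorm
    alpha <- cfg$step
    repeat {
      cand <- xyz + alpha * dir
      egNew <- energyGrad(cand, prs)
      if (egNew$e <= eg$e || alpha < cfg$step * 1e-6) break
      alpha <- alpha / 2
    }
    if (egNew$e > eg$e) { converged <- TRUE; break }  # no downhill move left
    xyz <- cand
    eg <- egNew
    energies <- c(energies, eg$e)
    if (it %% 25L == 0L) prs <- pairList()
    if (eg$e < 1e-12) { converged <- TRUE; break }
  }

  # write coordinates back per chain
  offset <- 0L
  for (ch in names(structure@chains)) {
    na <- nrow(structure@chains[[ch]]$atoms)
    if (!na) next
    idx <- offset + seq_len(na)
    structure@chains[[ch]]$atoms$x <- xyz[idx, 1L]
    structure@chains[[ch]]$atoms$y <- xyz[idx, 2L]
    structure@chains[[ch]]$atoms$z <- xyz[idx, 3L]
    offset <- offset + na
  }
  list(structure = structure, energies = energies, converged = converged)
}

#' Revert a group-II structure to its wild-type sequence
#'
#' Runs the three refinement stages: detect mutations by alignment, strip the
#' mutated side chains to the backbone, graft idealised wild-type side
#' chains, and relieve any resulting bad contacts by steepest descent with
#' only the grafted atoms movable. Backbone coordinates are never displaced.
#'
#' @param structure a [StructureRecord-class]
#' @param wtSeq wild-type amino-acid sequence
#' @param chain chain to refine (default: best-matching chain)
#' @param cfg a [minimizerConfig()] list
#' @return list: \code{structure} (refined), \code{report} (data.frame of
#'   fixed mutations: resno, wtPos, from, to), \code{clashesBefore},
#'   \code{clashesAfter} (residual clash pairs involving grafted atoms),
#'   \code{remarks} (REMARK 99 lines flagging modified residues)
#' @export
revertToWildtype <- function(structure, wtSeq, chain = NULL,
                             cfg = minimizerConfig()) {
  if (is.null(chain)) chain <- bestChainFor(structure, wtSeq)$chain
  atoms <- structure@chains[[chain]]$atoms
  resnos <- atoms$resno[!duplicated(atoms$resno)]
  aln <- alignStructureToWT(wtSeq, chainSequence(structure, chain),
                            structResnos = resnos)
  group <- classifyGroup(aln, structure)
  if (group == "III")
    stop("structure classifies as group III; sequence reversion is only ",
         "defined for group II - route this entry to homology modelling")
  muts <- detectMutations(aln)
  if (!nrow(muts)) {
    return(list(structure = structure,
                report = data.frame(resno = integer(), wtPos = integer(),
                                    from = character(), to = character(),
                                    stringsAsFactors = FALSE),
                clashesBefore = 0L, clashesAfter = 0L,
                remarks = character()))
  }
  pairMap <- stats::setNames(aln@pairs[, "structResno"], aln@pairs[, "wtPos"])
  report <- list()
  grafted <- list()
  residueClashes <- function(s, resno, names) {
    cp <- clashPairs(s, scale = cfg$scale)
    if (!nrow(cp)) return(0L)
    flat <- flattenAtoms(s)
    key <- paste(flat$chain, flat$resno, flat$name)
    target <- paste(chain, resno, names)
    sum(key[cp$i] %in% target | key[cp$j] %in% target)
  }
  for (k in seq_len(nrow(muts))) {
    resno <- pairMap[[as.character(muts$wtPos[k])]]
    structure <- stripSidechain(structure, chain, resno)
    tpl <- sidechainTemplate(muts$wtAa[k])
    # deterministic chi1 multi-start: keep the least-clashing rotamer
    best <- NULL
    for (off in c(0, 120, -120)) {
      cand <- graftSidechain(structure, chain, resno, muts$wtAa[k],
                             chi1Offset = off)
      nc <- if (nrow(tpl)) residueClashes(cand, resno, tpl$name) else 0L
      if (is.null(best) || nc < best$nc) best <- list(s = cand, nc = nc)
      if (nc == 0L) break
    }
    structure <- best$s
    if (nrow(tpl))
      grafted[[k]] <- data.frame(chain = chain, resno = resno,
                                 name = tpl$name, stringsAsFactors = FALSE)
    report[[k]] <- data.frame(resno = resno, wtPos = muts$wtPos[k],
                              from = muts$obsAa[k], to = muts$wtAa[k],
                              stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, report)
  movable <- do.call(rbind, grafted)

  graftClashes <- function(s) {
    cp <- clashPairs(s, scale = cfg$scale)
    if (!nrow(cp) || is.null(movable)) return(0L)
    flat <- flattenAtoms(s)
    key <- paste(flat$chain, flat$resno, flat$name)
    movKey <- paste(movable$chain, movable$resno, movable$name)
    sum(key[cp$i] %in% movKey | key[cp$j] %in% movKey)
  }

  clashesBefore <- graftClashes(structure)
  if (!is.null(movable) && clashesBefore > 0L) {
    structure <- minimizeSteric(structure, movable, cfg)$structure
  }
  clashesAfter <- graftClashes(structure)
  structure@chains[[chain]]$reportedSequence <-
    chainSequence(structure, chain)
  remarks <- sprintf(
    "REMARK  99 REVERTED RESIDUE %s %4d %s -> %s",
    chain, report$resno, report$from, report$to)
  list(structure = structure, report = report,
       clashesBefore = clashesBefore, clashesAfter = clashesAfter,
       remarks = remarks)
}
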