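# Per-protein structural properties: solvent-accessible surface area,
# secondary structure (Kabsch-Sander hydrogen-bond energies), contacts,
# disulfide bonds, residue depth and the assembled 29-feature vector.

#' Canonical names of the 29 structural features
#' @return character vector of length 29
#' @export
propertyFeatureNames <- function() {
  c("sasa_total", "n_contacts", "n_ss_bonds", "pct_buried", "pct_surface",
    "pct_helix_H", "pct_strand_E", "pct_310_G", "pct_pi_I", "pct_turn_T",
    "pct_bend_S", "pct_bridge_B", "pct_disordered", "ovality",
    "mean_residue_depth", "pct_nonpolar", "pct_polar", "pct_positive",
    "pct_negative", "pct_surface_nonpolar", "pct_surface_polar",
    "pct_surface_positive", "pct_surface_negative", "pct_buried_nonpolar",
    "pct_buried_polar", "pct_buried_positive", "pct_buried_negative",
    "n_res", "mean_residue_sasa")
}

#' Residue chemical classes
#'
#' Nonpolar: A V L I M F W P G; polar: S T N Q Y C; positively charged:
#' K R H; negatively charged: D E.
#'
#' @return named character vector, one-letter code -> class
#' @export
residueClassTable <- function() {
  c(A = "NONPOLAR", V = "NONPOLAR", L = "NONPOLAR", I = "NONPOLAR",
    M = "NONPOLAR", F = "NONPOLAR", W = "NONPOLAR", P = "NONPOLAR",
    G = "NONPOLAR",
    S = "POLAR", T = "POLAR", N = "POLAR", Q = "POLAR", Y = "POLAR",
    C = "POLAR",
    K = "POSITIVE", R = "POSITIVE", H = "POSITIVE",
    D = "NEGATIVE", E = "NEGATIVE")
}

#' Solvent-accessible surface area (deterministic point lattice)
#'
#' Numerical SASA with a probe sphere: each heavy atom carries a fixed
#' golden-spiral lattice of \code{nPoints} points on its sphere of radius
#' \code{r_vdW + probe}; a point is accessible when it lies inside no other
#' atom's probe-expanded sphere. Deterministic and seed-free.
#'
#' @param structure a [StructureRecord-class]
#' @param probe probe radius in Angstrom (default 1.4)
#' @param nPoints lattice points per atom (default 960; minimum 60)
#' @return list: \code{perAtom} (numeric, A^2), \code{perResidue} (named
#'   numeric keyed "chain:resno"), \code{total}, \code{surfacePoints}
#'   (matrix of accessible point coordinates, used for residue depth),
#'   \code{flat} (the flattened atom table)
#' @export
computeSasa <- function(structure, probe = 1.4, nPoints = 960L) {
  if (nPoints < 60L) stop("nPoints below the accuracy floor of 60")
  flat <- flattenAtoms(structure)
  flat <- flat[flat$element != "H", , drop = FALSE]
  n <- nrow(flat)
  xyz <- as.matrix(flat[, c("x", "y", "z")])
  rad <- vdwRadius(flat$element) + probe
  unitPts <- goldenSpiralPoints(nPoints)
  perAtom <- numeric(n)
  surfacePts <- list()
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(d < rad[i] + rad & seq_len(n) != i)
    pts <- unitPts * rad[i]
    pts <- sweep(pts, 2L, xyz[i, ], `+`)
    acc <- rep(TRUE, nPoints)
    for (j in nb) {
      if (!any(acc)) break
      dj <- colSums((t(pts[acc, , drop = FALSE]) - xyz[j, ])^2)
      acc[acc] <- dj >= rad[j]^2
    }
    frac <- sum(acc) / nPoints
    perAtom[i] <- 4 * pi * rad[i]^2 * frac
    if (any(acc)) surfacePts[[length(surfacePts) + 1L]] <-
        pts[acc, , drop = FALSE]
  }
  resKey <- paste(flat$chain, flat$resno, sep = ":")
  perResidue <- tapply(perAtom, resKey, sum)
  perResidue <- perResidue[unique(resKey)]
  list(perAtom = perAtom,
       perResidue = perResidue,
       total = sum(perAtom),
       surfacePoints = do.call(rbind, surfacePts),
       flat = flat)
}

#' Classify residues as surface or buried
#'
#' Surface iff the residue SASA is strictly greater than the threshold
#' (default 3 A^2); buried otherwise.
#'
#' @param perResidueSasa named numeric of per-residue SASA values
#' @param threshold SASA threshold in A^2
#' @return named character vector of "SURFACE"/"BURIED"
#' @export
assignSurfaceBuried <- function(perResidueSasa, threshold = 3.0) {
  out <- ifelse(perResidueSasa > threshold, "SURFACE", "BURIED")
  stats::setNames(out, names(perResidueSasa))
}

# Backbone coordinate table of one chain: rows = residues with complete
# N/CA/C/O; reconstructs the amide H when absent (H along the bisector of
# C(i-1)->N and CA->N at 1.01 A; residue 1 and prolines carry none).
.chainBackbone <- function(atoms) {
  resnos <- unique(atoms$resno)
  nres <- length(resnos)
  get <- function(resno, name) {
    hit <- which(atoms$resno == resno & atoms$name == name)
    if (!length(hit)) return(NULL)
    c(atoms$x[hit[1L]], atoms$y[hit[1L]], atoms$z[hit[1L]])
  }
  bb <- vector("list", nres)
  for (k in seq_len(nres)) {
    r <- resnos[k]
    bb[[k]] <- list(resno = r,
                    resname = atoms$resname[atoms$resno == r][1L],
                    N = get(r, "N"), CA = get(r, "CA"),
                    C = get(r, "C"), O = get(r, "O"), H = get(r, "H"))
  }
  for (k in seq_len(nres)) {
    if (is.null(bb[[k]]$H) && k > 1L &&
        !is.null(bb[[k]]$N) && !is.null(bb[[k]]$CA) &&
        !is.null(bb[[k - 1L]]$C) &&
        bb[[k]]$resname != "PRO" &&
        bb[[k]]$resno == bb[[k - 1L]]$resno + 1L) {
      dirv <- unitv(unitv(bb[[k]]$N - bb[[k - 1L]]$C) +
                    unitv(bb[[k]]$N - bb[[k]]$CA))
      bb[[k]]$H <- bb[[k]]$N + 1.01 * dirv
    }
  }
  bb
}

# Kabsch-Sander hydrogen-bond energy matrix for one chain backbone.
# hb[i, j] is TRUE when the CO of residue i accepts the NH of residue j
# (E < -0.5 kcal/mol). E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN);
# the bracket is negative in bonding geometry, so bonds have E < 0.
.kabschSanderBonds <- function(bb, cutoff = -0.5,
                               chainOf = rep("A", length(bb))) {
  nres <- length(bb)
  hb <- matrix(FALSE, nres, nres)
  for (i in seq_len(nres)) {
    if (is.null(bb[[i]]$C) || is.null(bb[[i]]$O)) next
    for (j in seq_len(nres)) {
      if (chainOf[i] == chainOf[j] && abs(i - j) < 2L) next
      if (is.null(bb[[j]]$N) || is.null(bb[[j]]$H)) next
      rON <- vnorm(bb[[i]]$O - bb[[j]]$N)
      rCH <- vnorm(bb[[i]]$C - bb[[j]]$H)
      rOH <- vnorm(bb[[i]]$O - bb[[j]]$H)
      rCN <- vnorm(bb[[i]]$C - bb[[j]]$N)
      if (min(rON, rCH, rOH, rCN) < 0.5) { hb[i, j] <- TRUE; next }
      e <- 27.888 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      hb[i, j] <- e < cutoff
    }
  }
  hb
}

#' Assign per-residue secondary structure
#'
#' Backbone hydrogen bonds are detected with the Kabsch-Sander electrostatic
#' energy (bond iff E < -0.5 kcal/mol; the amide H is reconstructed when
#' absent). Helices are assigned where a residue lies strictly between donor
#' and acceptor of at least two distinct n-turn hydrogen bonds (n = 4: H,
#' n = 3: G, n = 5: I); bridges follow the parallel/antiparallel bridge
#' patterns (ladders: E, isolated: B); remaining turn residues: T; a CA-trace
#' kink above 70 degrees: S (bend); everything else "-". Chains of fewer
#' than three residues are entirely "-".
#'
#' @param structure a [StructureRecord-class]
#' @return named character vector over residues ("chain:resno" keys) with
#'   classes in H, G, I, E, B, T, S, -
#' @export
assignSecondaryStructure <- function(structure) {
  # Chains are assessed jointly: hydrogen bonds (and hence bridges) may span
  # chains, while helical turns and bends require residues of one chain with
  # consecutive numbering.
  bb <- list()
  chainOf <- character()
  for (ch in names(structure@chains)) {
    cbb <- .chainBackbone(structure@chains[[ch]]$atoms)
    bb <- c(bb, cbb)
    chainOf <- c(chainOf, rep(ch, length(cbb)))
  }
  nres <- length(bb)
  keys <- paste(chainOf, vapply(bb, `[[`, numeric(1), "resno"), sep = ":")
  if (nres < 3L) return(stats::setNames(rep("-", nres), keys))
  hb <- .kabschSanderBonds(bb, chainOf = chainOf)
  sameRun <- function(i, j) {
    chainOf[i] == chainOf[j] && bb[[j]]$resno - bb[[i]]$resno == j - i
  }
  cov <- list(`3` = integer(nres), `4` = integer(nres), `5` = integer(nres))
  turnAny <- logical(nres)
  for (n in c(3L, 4L, 5L)) {
    for (i in seq_len(max(0L, nres - n))) {
      if (hb[i, i + n] && sameRun(i, i + n)) {
        idx <- (i + 1L):(i + n - 1L)
        cov[[as.character(n)]][idx] <- cov[[as.character(n)]][idx] + 1L
        turnAny[idx] <- TRUE
      }
    }
  }
  bridge <- logical(nres)
  for (i in seq_len(nres)) {
    for (j in seq_len(nres)) {
      if (chainOf[i] == chainOf[j] &&
          abs(bb[[i]]$resno - bb[[j]]$resno) < 3L) next
      par <- (i > 1L && j < nres && hb[i - 1L, j] && hb[j, i + 1L]) ||
             (j > 1L && i < nres && hb[j - 1L, i] && hb[i, j + 1L])
      anti <- (hb[i, j] && hb[j, i]) ||
              (i > 1L && j < nres && i < nres && j > 1L &&
               hb[i - 1L, j + 1L] && hb[j - 1L, i + 1L])
      if (par || anti) { bridge[i] <- TRUE; break }
    }
  }
  ladder <- bridge & (c(FALSE, bridge[-nres]) | c(bridge[-1L], FALSE))
  bend <- logical(nres)
  for (i in if (nres >= 5L) 3:(nres - 2L) else integer()) {
    if (!sameRun(i - 2L, i + 2L)) next
    if (is.null(bb[[i - 2L]]$CA) || is.null(bb[[i]]$CA) ||
        is.null(bb[[i + 2L]]$CA)) next
    u <- bb[[i]]$CA - bb[[i - 2L]]$CA
    v <- bb[[i + 2L]]$CA - bb[[i]]$CA
    kink <- acos(max(-1, min(1, sum(unitv(u) * unitv(v))))) * 180 / pi
    bend[i] <- kink > 70
  }
  ss <- rep("-", nres)
  ss[bend] <- "S"
  ss[turnAny] <- "T"
  ss[cov[["5"]] >= 2L] <- "I"
  ss[cov[["3"]] >= 2L] <- "G"
  ss[bridge & !ladder] <- "B"
  ss[ladder] <- "E"
  ss[cov[["4"]] >= 2L] <- "H"
  stats::setNames(ss, keys)
}

#' Secondary-structure composition of a structure
#' @param structure a [StructureRecord-class]
#' @return named numeric fractions over the classes H, G, I, E, B, T, S, -
#' @export
secondaryStructureComposition <- function(structure) {
  ss <- assignSecondaryStructure(structure)
  classes <- c("H", "G", "I", "E", "B", "T", "S", "-")
  counts <- vapply(classes, function(cl) sum(ss == cl), numeric(1))
  counts / max(1L, length(ss))
}

#' Count disulfide bonds
#'
#' Cysteine SG-SG pairs within the bonding distance cutoff (default 5 A),
#' each SG used at most once (greedy nearest pairing).
#'
#' @param structure a [StructureRecord-class]
#' @param cutoff bonding distance cutoff in Angstrom
#' @return integer bond count; the paired distances are attached as the
#'   \code{"distances"} attribute
#' @export
countSsBonds <- function(structure, cutoff = 5.0) {
  flat <- flattenAtoms(structure)
  sg <- flat[flat$name == "SG" & toupper(flat$resname) == "CYS", ,
             drop = FALSE]
  n <- nrow(sg)
  if (n < 2L) return(base::structure(0L, distances = numeric()))
  xyz <- as.matrix(sg[, c("x", "y", "z")])
  dm <- as.matrix(stats::dist(xyz))
  diag(dm) <- Inf
  used <- logical(n)
  dists <- numeric()
  repeat {
    dm[used, ] <- Inf
    dm[, used] <- Inf
    m <- min(dm)
    if (!is.finite(m) || m > cutoff) break
    idx <- which(dm == m, arr.ind = TRUE)[1L, ]
    used[idx] <- TRUE
    dists <- c(dists, m)
  }
  base::structure(length(dists), distances = dists)
}

#' Count heavy-atom contacts
#'
#' Heavy-atom pairs within \code{cutoff} between residues separated by at
#' least \code{minSep} in sequence (pairs across different chains always
#' qualify).
#'
#' @param structure a [StructureRecord-class]
#' @param cutoff contact distance in Angstrom (default 4.5)
#' @param minSep minimum sequence separation (default 3)
#' @return integer contact count
#' @export
countContacts <- function(structure, cutoff = 4.5, minSep = 3L) {
  flat <- flattenAtoms(structure)
  flat <- flat[flat$element != "H", , drop = FALSE]
  n <- nrow(flat)
  if (n < 2L) return(0L)
  dm <- as.matrix(stats::dist(as.matrix(flat[, c("x", "y", "z")])))
  hits <- which(dm <= cutoff & upper.tri(dm), arr.ind = TRUE)
  if (!nrow(hits)) return(0L)
  i <- hits[, 1L]; j <- hits[, 2L]
  ok <- flat$chain[i] != flat$chain[j] |
    abs(flat$resno[i] - flat$resno[j]) >= minSep
  sum(ok)
}

#' Per-residue depth from the accessible surface
#'
#' Depth of a residue is the mean over its heavy atoms of the minimum
#' distance to any accessible surface sample point (an isolated atom's depth
#' is its own probe-expanded radius).
#'
#' @param structure a [StructureRecord-class]
#' @param sasa result of [computeSasa()] (computed if NULL)
#' @return named numeric of residue depths; mean over residues attached as
#'   attribute \code{"mean"}
#' @export
computeResidueDepth <- function(structure, sasa = NULL) {
  if (is.null(sasa)) sasa <- computeSasa(structure)
  flat <- sasa$flat
  sp <- sasa$surfacePoints
  if (is.null(sp) || !nrow(sp))
    stop("no accessible surface points; cannot compute depth")
  xyz <- as.matrix(flat[, c("x", "y", "z")])
  perAtom <- vapply(seq_len(nrow(flat)), function(i) {
    sqrt(min(colSums((t(sp) - xyz[i, ])^2)))
  }, numeric(1))
  resKey <- paste(flat$chain, flat$resno, sep = ":")
  perRes <- tapply(perAtom, resKey, mean)
  perRes <- perRes[unique(resKey)]
  base::structure(perRes, mean = mean(perRes))
}

#' Assemble the 29-feature structural property vector
#'
#' Computes SASA, surface/buried assignment, secondary-structure
#' composition, disulfide bonds, contacts, residue depth, ovality
#' (SASA / N_res^(2/3)) and the residue-class percentages over all, surface
#' and buried residues. Class percentages over an empty subset are NA (the
#' comparison stage imputes them).
#'
#' @param structure a [StructureRecord-class]
#' @param probe SASA probe radius (A)
#' @param nPoints SASA lattice points per atom
#' @param classTable residue class table (see [residueClassTable()])
#' @return named numeric vector with the [propertyFeatureNames()] entries
#' @export
propertyVector <- function(structure, probe = 1.4, nPoints = 960L,
                           classTable = residueClassTable()) {
  sasa <- computeSasa(structure, probe = probe, nPoints = nPoints)
  flat <- sasa$flat
  resKey <- unique(paste(flat$chain, flat$resno, sep = ":"))
  nRes <- length(resKey)
  resAa <- aa3to1(flat$resname[!duplicated(paste(flat$chain, flat$resno))])
  sb <- assignSurfaceBuried(sasa$perResidue)
  ss <- assignSecondaryStructure(structure)
  ssOf <- ss[resKey]
  depth <- computeResidueDepth(structure, sasa)

  pct <- function(x) 100 * x
  classOf <- classTable[resAa]
  classPct <- function(subset) {
    if (!length(subset) || all(is.na(subset))) {
      return(c(NONPOLAR = NA_real_, POLAR = NA_real_,
               POSITIVE = NA_real_, NEGATIVE = NA_real_))
    }
    vapply(c("NONPOLAR", "POLAR", "POSITIVE", "NEGATIVE"),
           function(cl) pct(sum(subset == cl, na.rm = TRUE) /
                            sum(!is.na(subset))),
           numeric(1))
  }
  allPct <- classPct(classOf)
  surfPct <- classPct(classOf[sb[resKey] == "SURFACE"])
  burPct <- classPct(classOf[sb[resKey] == "BURIED"])
  ssPct <- function(cl) pct(sum(ssOf == cl) / nRes)

  v <- c(
    sasa_total = sasa$total,
    n_contacts = as.numeric(countContacts(structure)),
    n_ss_bonds = as.numeric(countSsBonds(structure)),
    pct_buried = pct(sum(sb == "BURIED") / nRes),
    pct_surface = pct(sum(sb == "SURFACE") / nRes),
    pct_helix_H = ssPct("H"), pct_strand_E = ssPct("E"),
    pct_310_G = ssPct("G"), pct_pi_I = ssPct("I"),
    pct_turn_T = ssPct("T"), pct_bend_S = ssPct("S"),
    pct_bridge_B = ssPct("B"), pct_disordered = ssPct("-"),
    ovality = sasa$total / nRes^(2 / 3),
    mean_residue_depth = attr(depth, "mean"),
    pct_nonpolar = allPct[["NONPOLAR"]], pct_polar = allPct[["POLAR"]],
    pct_positive = allPct[["POSITIVE"]], pct_negative = allPct[["NEGATIVE"]],
    pct_surface_nonpolar = surfPct[["NONPOLAR"]],
    pct_surface_polar = surfPct[["POLAR"]],
    pct_surface_positive = surfPct[["POSITIVE"]],
    pct_surface_negative = surfPct[["NEGATIVE"]],
    pct_buried_nonpolar = burPct[["NONPOLAR"]],
    pct_buried_polar = burPct[["POLAR"]],
    pct_buried_positive = burPct[["POSITIVE"]],
    pct_buried_negative = burPct[["NEGATIVE"]],
    n_res = nRes,
    mean_residue_sasa = sasa$total / nRes)
  v[propertyFeatureNames()]
}
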