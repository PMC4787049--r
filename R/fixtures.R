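# Synthetic fixture generators: every pipeline stage is testable without any
# download. Geometry fixtures are built from ideal internal coordinates
# (N-CA 1.458, CA-C 1.525, C-N 1.329 A, standard angles - the same table the
# grafting code uses); every generator emits its planted ground truth.

# Backbone builder: poly-peptide from phi/psi, ideal bond geometry.
.buildBackbone <- function(seq1, phi, psi, omega = 180) {
  n <- nchar(seq1)
  aa <- strsplit(seq1, "")[[1L]]
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  N <- matrix(NA_real_, n, 3L)
  CA <- matrix(NA_real_, n, 3L)
  C <- matrix(NA_real_, n, 3L)
  O <- matrix(NA_real_, n, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(1.458, 0, 0)
  t1 <- 111.2 * pi / 180
  C[1L, ] <- CA[1L, ] + 1.525 * c(-cos(t1), sin(t1), 0)
  for (i in seq_len(n)) {
    if (i > 1L) {
      N[i, ] <- nerfPlace(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                          1.329, 116.2, psi[i - 1L])
      CA[i, ] <- nerfPlace(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                           1.458, 121.7, omega)
      C[i, ] <- nerfPlace(C[i - 1L, ], N[i, ], CA[i, ],
                          1.525, 111.2, phi[i])
    }
    O[i, ] <- nerfPlace(N[i, ], CA[i, ], C[i, ], 1.231, 120.5, psi[i] + 180)
  }
  rows <- list()
  for (i in seq_len(n)) {
    res3 <- aa1to3(aa[i])
    for (nm in c("N", "CA", "C", "O")) {
      xyz <- switch(nm, N = N[i, ], CA = CA[i, ], C = C[i, ], O = O[i, ])
      rows[[length(rows) + 1L]] <- data.frame(
        resno = i, resname = res3, name = nm,
        element = substr(nm, 1, 1),
        x = xyz[1L], y = xyz[2L], z = xyz[3L], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Assemble a StructureRecord from a sequence and backbone dihedrals,
# optionally grafting idealised side chains residue by residue.
.buildStructure <- function(seq1, phi, psi, structureId, method = "XRAY",
                            resolution = 2.0, chain = "A",
                            sidechains = TRUE, tmScore = NA_real_) {
  atoms <- .buildBackbone(seq1, phi, psi)
  s <- new("StructureRecord", structureId = structureId, method = method,
           resolution = if (method == "XRAY") resolution else NA_real_,
           tmScore = tmScore,
           chains = stats::setNames(
             list(list(reportedSequence = seq1, atoms = atoms)), chain))
  if (sidechains) {
    aa <- strsplit(seq1, "")[[1L]]
    for (i in seq_along(aa))
      s <- graftSidechain(s, chain, i, aa[i])
  }
  s
}

#' Ideal poly-alanine alpha-helix fixture
#'
#' Poly-Ala backbone built from ideal internal coordinates at the given
#' phi/psi; valid PDB ATOM records. Deterministic (no randomness).
#'
#' @param nRes number of residues (>= 2; >= 4 for any helical H-bond)
#' @param phi,psi backbone dihedrals in degrees (defaults: ideal alpha helix)
#' @return character vector of PDB lines; the built
#'   [StructureRecord-class] is attached as attribute \code{"structure"}
#' @export
makeHelixPdb <- function(nRes = 12L, phi = -57, psi = -47) {
  if (nRes < 2L) stop("nRes must be >= 2")
  seq1 <- strrep("A", nRes)
  s <- .buildStructure(seq1, phi, psi, structureId = "helix_fixture")
  base::structure(writeStructurePdb(s), structure = s)
}

# Rigid transform placing a copy of an extended six-residue strand into
# antiparallel hydrogen-bonding register with the original: 180-degree
# rotation about z (reversing the strand direction), then an offset fitted
# once against the Kabsch-Sander energy and frozen. The register constants
# are specific to the six-residue strand.
.hairpinOffsets <- c(dx = 12.5, dy = 6.7, dz = 0.0)

#' Antiparallel two-strand beta-sheet fixture
#'
#' Two extended six-residue strands (phi = -139, psi = 135) in antiparallel
#' register: the second strand is the first rotated 180 degrees about z and
#' offset into hydrogen-bonding distance. Strand-core residues (2-4 of each
#' strand) assign as E.
#'
#' @return character vector of PDB lines with the built
#'   [StructureRecord-class] attached as attribute \code{"structure"}
#' @export
makeHairpinPdb <- function() {
  seq1 <- strrep("G", 6L)
  atomsA <- .buildBackbone(seq1, -139, 135)
  xyzA <- as.matrix(atomsA[, c("x", "y", "z")])
  xyzB <- xyzA %*% diag(c(-1, -1, 1))
  xyzB <- sweep(xyzB, 2L, .hairpinOffsets, `+`)
  atomsB <- atomsA
  atomsB$x <- xyzB[, 1L]; atomsB$y <- xyzB[, 2L]; atomsB$z <- xyzB[, 3L]
  s <- new("StructureRecord", structureId = "hairpin_fixture",
           method = "XRAY", resolution = 1.8,
           chains = list(A = list(reportedSequence = seq1, atoms = atomsA),
                         B = list(reportedSequence = seq1, atoms = atomsB)))
  base::structure(writeStructurePdb(s), structure = s)
}

#' Mutant/gapped structure fixture with planted ground truth
#'
#' Builds an extended-conformation structure whose sequence differs from the
#' wild type by the given point mutations, with optional interior deletions
#' (unresolved residues); residue numbering keeps the wild-type positions so
#' gaps are visible. The planted truth records exactly the applied
#' modifications.
#'
#' @param wtSeq wild-type sequence (default: a 20-residue mixed sequence
#'   with glutamates at positions 8 and 15)
#' @param mutations named character vector, wild-type position -> observed
#'   amino acid; the default plants Glu->His and Glu->Gln point mutations
#' @param gaps integer vector of wild-type positions deleted from the
#'   structure (interior gaps)
#' @param resolution X-ray resolution of the fixture
#' @return list: \code{pdb} (lines), \code{structure}
#'   ([StructureRecord-class]), \code{wtSeq}, \code{truth} (list with
#'   \code{mutations} data.frame and \code{gaps})
#' @export
makeMutantPdb <- function(wtSeq = "AGSTAGSEAGSTAGSEAGST",
                          mutations = c("8" = "H", "16" = "Q"),
                          gaps = integer(),
                          resolution = 2.0) {
  wt <- strsplit(wtSeq, "")[[1L]]
  obs <- wt
  mutPos <- as.integer(names(mutations))
  stopifnot(all(mutPos >= 1L), all(mutPos <= length(wt)))
  obs[mutPos] <- unname(mutations)
  s <- .buildStructure(paste(obs, collapse = ""), -139, 135,
                       structureId = "mutant_fixture",
                       resolution = resolution)
  if (length(gaps)) {
    atoms <- s@chains[["A"]]$atoms
    atoms <- atoms[!atoms$resno %in% gaps, , drop = FALSE]
    rownames(atoms) <- NULL
    s@chains[["A"]]$atoms <- atoms
  }
  s@chains[["A"]]$reportedSequence <- chainSequence(s, "A")
  truth <- list(
    mutations = data.frame(wtPos = mutPos, wtAa = wt[mutPos],
                           obsAa = unname(mutations),
                           stringsAsFactors = FALSE),
    gaps = sort(as.integer(gaps)))
  list(pdb = writeStructurePdb(s), structure = s,
       wtSeq = wtSeq, truth = truth)
}

#' Gapped structure fixture (group III)
#'
#' Convenience wrapper over [makeMutantPdb()] planting one long interior
#' deletion.
#'
#' @param wtSeq wild-type sequence (non-periodic, so the deletion cannot
#'   re-align as a terminal truncation)
#' @param gapStart,gapLength interior deletion placement
#' @return see [makeMutantPdb()]
#' @export
makeGappedPdb <- function(wtSeq = "ACDEFGHIKLMNPQRSTVWYACDEFGHIKL",
                          gapStart = 10L, gapLength = 10L) {
  makeMutantPdb(wtSeq = wtSeq, mutations = character(),
                gaps = seq(gapStart, length.out = gapLength))
}

#' Two-chain fixture with an SG-SG pair at a controlled distance
#'
#' Two copies of a short Gly-Cys-Gly peptide; the second chain is a
#' translate of the first along x so that the SG-SG distance equals
#' \code{sgDistance} exactly.
#'
#' @param sgDistance target SG-SG distance in Angstrom
#' @return character vector of PDB lines with the built
#'   [StructureRecord-class] attached as attribute \code{"structure"}
#' @export
makeDimerSsbondPdb <- function(sgDistance = 4.9) {
  sA <- .buildStructure("GCG", -139, 135, structureId = "ssbond_fixture")
  atomsA <- sA@chains[["A"]]$atoms
  atomsB <- atomsA
  atomsB$x <- atomsB$x + sgDistance
  s <- new("StructureRecord", structureId = "ssbond_fixture",
           method = "XRAY", resolution = 2.0,
           chains = list(A = list(reportedSequence = "GCG", atoms = atomsA),
                         B = list(reportedSequence = "GCG", atoms = atomsB)))
  base::structure(writeStructurePdb(s), structure = s)
}

#' Toy metabolic model with planted GPR ground truth
#'
#' A viable linear pathway (source -> chain of conversions -> biomass) whose
#' conversion reactions carry randomly sampled GPR patterns: single genes,
#' homomers (repeated gene = copy number), heterocomplexes, isozymes and
#' isozymic complexes, with occasional gene reuse across reactions. The
#' planted truth (complex census, isozyme reactions, multi-complex genes) is
#' recorded at construction, independent of the GPR parser.
#'
#' @param nRxn number of conversion reactions (>= 3)
#' @param seed RNG seed (same seed, same model)
#' @return list: \code{model} ([MetabolicModel-class]), \code{truth} (list:
#'   isozyme_reaction_fraction, multi_complex_gene_count,
#'   multi_complex_genes, complexes)
#' @export
makeToyModel <- function(nRxn = 10L, seed = 1L) {
  stopifnot(nRxn >= 3L)
  set.seed(seed)
  mets <- sprintf("M%02d", seq_len(nRxn + 1L))
  genePool <- character()
  newGene <- function() {
    g <- sprintf("g%03d", length(genePool) + 1L)
    genePool <<- c(genePool, g)
    g
  }
  pickGene <- function() {
    # reuse an existing gene 30% of the time to plant multi-complex genes
    if (length(genePool) && stats::runif(1) < 0.3)
      sample(genePool, 1L)
    else newGene()
  }
  reactions <- list(Reaction("R_src",
                             stoichiometry = stats::setNames(1, mets[1L]),
                             lowerBound = 0, upperBound = 10))
  planted <- list()   # per-reaction list of complexes (named int vectors)
  for (i in seq_len(nRxn)) {
    pattern <- sample(c("single", "homomer", "hetero", "iso_pair",
                        "iso_complex"), 1L)
    complexes <- switch(pattern,
      single = list(stats::setNames(1L, pickGene())),
      homomer = list(stats::setNames(sample(2:4, 1L), pickGene())),
      hetero = {
        g1 <- pickGene(); g2 <- newGene()
        list(stats::setNames(c(1L, 1L), c(g1, g2)))
      },
      iso_pair = list(stats::setNames(1L, pickGene()),
                      stats::setNames(1L, newGene())),
      iso_complex = {
        g1 <- pickGene(); g2 <- newGene(); g3 <- newGene()
        list(stats::setNames(c(1L, 1L), c(g1, g2)),
             stats::setNames(1L, g3))
      })
    # drop degenerate duplicates (gene reuse can collide within a reaction)
    keys <- vapply(complexes, complexKey, character(1))
    complexes <- complexes[!duplicated(keys)]
    gprTerms <- vapply(complexes, function(cx) {
      units <- unlist(mapply(function(g, k) rep(g, k), names(cx), cx,
                             SIMPLIFY = FALSE))
      if (length(units) > 1L)
        paste0("(", paste(units, collapse = " and "), ")")
      else units
    }, character(1))
    gpr <- paste(gprTerms, collapse = " or ")
    st <- stats::setNames(c(-1, 1), c(mets[i], mets[i + 1L]))
    reactions[[length(reactions) + 1L]] <-
      Reaction(sprintf("R%02d", i), stoichiometry = st,
               lowerBound = 0, upperBound = 1000, gpr = gpr)
    planted[[sprintf("R%02d", i)]] <- complexes
  }
  reactions[[length(reactions) + 1L]] <-
    Reaction("R_bio",
             stoichiometry = stats::setNames(-1, mets[nRxn + 1L]),
             lowerBound = 0, upperBound = 1000)
  model <- MetabolicModel(sprintf("toy_%d", seed), genes = sort(genePool),
                          metabolites = mets, reactions = reactions,
                          objective = "R_bio")
  allCx <- unlist(planted, recursive = FALSE, use.names = FALSE)
  keys <- vapply(allCx, complexKey, character(1))
  census <- allCx[!duplicated(keys)]
  geneCount <- table(unlist(lapply(census, names)))
  multi <- sort(names(geneCount)[geneCount >= 2L])
  truth <- list(
    isozyme_reaction_fraction =
      sum(vapply(planted, length, integer(1)) >= 2L) / length(planted),
    multi_complex_gene_count = length(multi),
    multi_complex_genes = multi,
    complexes = planted)
  list(model = model, truth = truth)
}

#' Synthetic abundance set from a stoichiometric ground truth
#'
#' \code{p = P e_true + |eps|}, \code{eps ~ N(0, sd)}, seeded.
#'
#' @param P a [ProteinStoichMatrix-class] or plain matrix with dimnames
#' @param eTrue true enzyme abundances (length = number of enzymes)
#' @param noiseSd additive half-normal noise standard deviation
#' @param seed RNG seed
#' @return list: \code{abundances} (named numeric per protein),
#'   \code{eTrue}, \code{noise}
#' @export
makeAbundanceSet <- function(P, eTrue, noiseSd = 0, seed = 1L) {
  m <- if (is(P, "ProteinStoichMatrix")) stoichMatrix(P) else P
  stopifnot(length(eTrue) == ncol(m), all(eTrue >= 0))
  set.seed(seed)
  eps <- abs(stats::rnorm(nrow(m), 0, noiseSd))
  if (noiseSd == 0) eps <- rep(0, nrow(m))
  p <- as.numeric(m %*% eTrue) + eps
  list(abundances = stats::setNames(p, rownames(m)),
       eTrue = stats::setNames(eTrue, colnames(m)), noise = eps)
}

#' Synthetic per-gene melting temperature table
#' @param genes gene ids
#' @param seed RNG seed
#' @param tmRange uniform sampling range in Celsius
#' @param missingFrac fraction of genes left without a value (source MISSING)
#' @return data.frame: gene_id, tm_celsius, source
#' @export
makeTmTable <- function(genes, seed = 1L, tmRange = c(40, 70),
                        missingFrac = 0.2) {
  set.seed(seed)
  tm <- stats::runif(length(genes), tmRange[1L], tmRange[2L])
  src <- sample(c("EXPERIMENTAL", "PREDICTED"), length(genes),
                replace = TRUE, prob = c(0.3, 0.7))
  miss <- stats::runif(length(genes)) < missingFrac
  tm[miss] <- NA_real_
  src[miss] <- "MISSING"
  data.frame(gene_id = genes, tm_celsius = tm, source = src,
             stringsAsFactors = FALSE)
}

#' Gaussian feature blobs with planted cluster labels
#'
#' k isotropic unit-variance Gaussian blobs in the 29-dimensional feature
#' space, centred \code{separation} apart along distinct coordinate axes.
#'
#' @param nPer points per blob
#' @param k number of blobs
#' @param separation centre separation in within-blob standard deviations
#' @param seed RNG seed
#' @param organisms optional vector of organism tags to cycle over rows
#' @return list: \code{matrix} (rows = proteins, 29 named columns),
#'   \code{labels} (planted blob index), \code{organisms}
#' @export
makeClusterBlobs <- function(nPer = 50L, k = 4L, separation = 20,
                             seed = 1L, organisms = c("orgA", "orgB")) {
  stopifnot(k >= 1L)
  set.seed(seed)
  p <- length(propertyFeatureNames())
  # centres sit `separation` from the origin along random orthonormal
  # directions, spreading the signal over all features so that column-wise
  # scaling preserves the separation
  centers <- matrix(0, k, p)
  if (k > 1L) {
    q <- qr.Q(qr(matrix(stats::rnorm(p * (k - 1L)), p, k - 1L)))
    centers[-1L, ] <- separation * t(q)
  }
  rows <- do.call(rbind, lapply(seq_len(k), function(j) {
    matrix(stats::rnorm(nPer * p), nPer, p) +
      matrix(centers[j, ], nPer, p, byrow = TRUE)
  }))
  colnames(rows) <- propertyFeatureNames()
  rownames(rows) <- sprintf("prot%04d", seq_len(nrow(rows)))
  labels <- rep(seq_len(k), each = nPer)
  orgs <- rep_len(organisms, nrow(rows))
  list(matrix = rows, labels = labels, organisms = orgs)
}

# --- ligand graph fixtures --------------------------------------------------

#' Construct a ligand graph
#' @param code ligand component code
#' @param elements character vector of atom elements
#' @param bonds data.frame with columns i, j, order (order in 1, 2, 3, "ar")
#' @param charges,chirality optional per-atom vectors
#' @return a ligand graph (list with code, atoms, bonds)
#' @export
ligandGraph <- function(code, elements, bonds,
                        charges = rep(0L, length(elements)),
                        chirality = rep(0L, length(elements))) {
  bonds$order <- as.character(bonds$order)
  key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
  if (anyDuplicated(key)) stop("duplicate bonds in ligand graph")
  if (any(bonds$i < 1L) || any(bonds$j > length(elements)) ||
      any(bonds$i == bonds$j))
    stop("invalid atom indices in bond list")
  list(code = code,
       atoms = data.frame(element = elements, charge = charges,
                          chirality = chirality, stringsAsFactors = FALSE),
       bonds = bonds)
}

#' Small reference ligand graphs (heavy atoms only)
#' @param which one of "ethanol", "dimethyl_ether", "methane", "ethane",
#'   "benzene", "atp_fragment"
#' @return a ligand graph
#' @export
referenceLigand <- function(which) {
  b <- function(i, j, order = 1) data.frame(i = i, j = j, order = order)
  switch(which,
    ethanol = ligandGraph("EOH", c("C", "C", "O"),
                          rbind(b(1, 2), b(2, 3))),
    dimethyl_ether = ligandGraph("DME", c("C", "O", "C"),
                                 rbind(b(1, 2), b(2, 3))),
    methane = ligandGraph("CH4", "C",
                          data.frame(i = integer(), j = integer(),
                                     order = character())),
    ethane = ligandGraph("ETH", c("C", "C"), b(1, 2)),
    benzene = ligandGraph("BNZ", rep("C", 6),
                          rbind(b(1, 2, "ar"), b(2, 3, "ar"), b(3, 4, "ar"),
                                b(4, 5, "ar"), b(5, 6, "ar"), b(6, 1, "ar"))),
    atp_fragment = ligandGraph("ATP", c("P", "O", "O", "O", "O", "C"),
                               rbind(b(1, 2, 2), b(1, 3), b(1, 4), b(1, 5),
                                     b(5, 6))),
    stop("unknown reference ligand: ", which))
}

#' Random connected ligand graph (tree plus optional extra edge)
#' @param nAtoms number of heavy atoms (>= 1)
#' @param seed RNG seed
#' @return a ligand graph
#' @export
randomLigandGraph <- function(nAtoms, seed = 1L) {
  set.seed(seed)
  elements <- sample(c("C", "N", "O", "S", "P"), nAtoms, replace = TRUE,
                     prob = c(0.6, 0.15, 0.15, 0.05, 0.05))
  bonds <- data.frame(i = integer(), j = integer(), order = character())
  if (nAtoms > 1L) {
    parent <- vapply(2:nAtoms, function(i) sample.int(i - 1L, 1L),
                     integer(1))
    bonds <- data.frame(i = parent, j = 2:nAtoms,
                        order = sample(c("1", "2"), nAtoms - 1L,
                                       replace = TRUE, prob = c(0.8, 0.2)),
                        stringsAsFactors = FALSE)
  }
  ligandGraph(sprintf("RL%03d", seed %% 1000L), elements, bonds)
}

#' Synthetic protein-to-ligand assignment with planted diversity
#'
#' Assigns each synthetic protein a set of ligand graphs of known distinct
#' count (duplicates under atom relabelling are planted deliberately).
#'
#' @param nProteins number of proteins
#' @param seed RNG seed
#' @return list: \code{ligandsByProtein} (named list of ligand-graph lists),
#'   \code{truth} (named integer of distinct ligand counts)
#' @export
makeLigandSet <- function(nProteins = 5L, seed = 1L) {
  set.seed(seed)
  out <- list()
  truth <- integer(nProteins)
  for (i in seq_len(nProteins)) {
    nDistinct <- sample(1:8, 1L)
    gs <- lapply(seq_len(nDistinct), function(j)
      randomLigandGraph(sample(3:8, 1L), seed = seed * 1000L + i * 10L + j))
    # plant a relabelled duplicate of the first ligand
    if (nDistinct >= 1L && nrow(gs[[1L]]$atoms) > 1L) {
      perm <- sample(nrow(gs[[1L]]$atoms))
      g <- gs[[1L]]
      inv <- order(perm)
      g$atoms <- g$atoms[perm, , drop = FALSE]
      rownames(g$atoms) <- NULL
      if (nrow(g$bonds)) {
        g$bonds$i <- inv[g$bonds$i]
        g$bonds$j <- inv[g$bonds$j]
      }
      gs <- c(gs, list(g))
    }
    out[[sprintf("prot%02d", i)]] <- gs
    truth[i] <- nDistinct
  }
  list(ligandsByProtein = out,
       truth = stats::setNames(truth, names(out)))
}
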