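# Ligand classification and diversity: heuristic graph canonicalisation
# (Morgan-style neighbourhood refinement), deterministic path fingerprints
# and Tanimoto similarity, plus the non-metabolic ligand filter.

.bondOrderValue <- function(order) {
  v <- c(`1` = 1, `2` = 2, `3` = 3, ar = 1.5)[as.character(order)]
  if (anyNA(v)) stop("unknown bond order: ",
                     paste(unique(order[is.na(v)]), collapse = ", "))
  unname(v)
}

# adjacency list: for each atom, data.frame(j, order)
.ligandAdjacency <- function(g) {
  n <- nrow(g$atoms)
  adj <- rep(list(data.frame(j = integer(), order = character(),
                             stringsAsFactors = FALSE)), n)
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[k]; j <- g$bonds$j[k]; o <- as.character(g$bonds$order[k])
    adj[[i]] <- rbind(adj[[i]], data.frame(j = j, order = o))
    adj[[j]] <- rbind(adj[[j]], data.frame(j = i, order = o))
  }
  adj
}

.ligandComponents <- function(g) {
  n <- nrow(g$atoms)
  adj <- .ligandAdjacency(g)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      a <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (comp[a]) next
      comp[a] <- cur
      stack <- c(stack, adj[[a]]$j[comp[adj[[a]]$j] == 0L])
    }
  }
  comp
}

.canonicalKeyConnected <- function(g) {
  n <- nrow(g$atoms)
  adj <- .ligandAdjacency(g)
  deg <- vapply(adj, nrow, integer(1))
  val <- vapply(adj, function(a)
    if (nrow(a)) sum(.bondOrderValue(a$order)) else 0, numeric(1))
  inv <- sprintf("%s/%d/%d/%d/%g", g$atoms$element, g$atoms$charge,
                 g$atoms$chirality, deg, val)
  rank <- match(inv, sort(unique(inv)))
  strs <- inv
  # fixed number of refinement rounds (label-invariant stopping rule)
  for (iter in seq_len(n)) {
    strs <- vapply(seq_len(n), function(a) {
      nb <- adj[[a]]
      nbStr <- if (nrow(nb))
        paste(sort(paste(nb$order, rank[nb$j], sep = ":")), collapse = ",")
      else ""
      paste0(rank[a], "{", nbStr, "}")
    }, character(1))
    rank <- match(strs, sort(unique(strs)))
  }
  # label-invariant key: sorted final signature strings (which chain back to
  # the initial element/charge/chirality/degree/valence invariants via the
  # refined ranks) plus the bond-class multiset
  atomPart <- paste(sort(paste(inv, strs, sep = "@")), collapse = ";")
  bondPart <- if (nrow(g$bonds)) {
    paste(sort(sprintf("%s-%s:%s",
                       pmin(rank[g$bonds$i], rank[g$bonds$j]),
                       pmax(rank[g$bonds$i], rank[g$bonds$j]),
                       g$bonds$order)), collapse = ";")
  } else ""
  paste0(atomPart, "#", bondPart)
}

#' Canonical key of a ligand graph
#'
#' Iterative neighbourhood (Morgan-style) refinement: atom invariants start
#' from element, formal charge, chirality flag, degree and valence and are
#' refined by sorted neighbour invariants until the partition stabilises.
#' Isomorphic graphs under atom relabelling map to equal keys; the key is a
#' heuristic certificate, not a complete isomorphism test (rare highly
#' symmetric counterexamples exist). Disconnected graphs yield per-component
#' keys joined by ".".
#'
#' @param g a ligand graph (see [ligandGraph()])
#' @return canonical key string
#' @export
canonicalKey <- function(g) {
  comp <- .ligandComponents(g)
  if (!length(comp)) stop("empty ligand graph")
  if (max(comp) == 1L) return(.canonicalKeyConnected(g))
  keys <- vapply(seq_len(max(comp)), function(cidx) {
    sel <- which(comp == cidx)
    remap <- match(seq_len(nrow(g$atoms)), sel)
    bonds <- g$bonds[g$bonds$i %in% sel & g$bonds$j %in% sel, , drop = FALSE]
    sub <- list(code = g$code,
                atoms = g$atoms[sel, , drop = FALSE],
                bonds = data.frame(i = remap[bonds$i], j = remap[bonds$j],
                                   order = bonds$order,
                                   stringsAsFactors = FALSE))
    rownames(sub$atoms) <- NULL
    .canonicalKeyConnected(sub)
  }, character(1))
  paste(sort(keys), collapse = ".")
}

#' Path fingerprint of a ligand graph
#'
#' Enumerates all simple paths of 0 to \code{maxPath} bonds from every atom;
#' each path's element/bond-order string is hashed with a fixed
#' deterministic polynomial hash and sets one bit of a
#' \code{nBits}-bit set. Invariant under atom relabelling.
#'
#' @param g a ligand graph
#' @param nBits fingerprint length (default 1024)
#' @param maxPath maximum path length in bonds (default 7)
#' @return list of class \code{ligandFingerprint}: \code{bits} (sorted
#'   integer bit indices), \code{nBits}, \code{maxPath}
#' @export
ligandFingerprint <- function(g, nBits = 1024L, maxPath = 7L) {
  adj <- .ligandAdjacency(g)
  n <- nrow(g$atoms)
  paths <- character()
  walk <- function(a, visited, str, depth) {
    paths[[length(paths) + 1L]] <<- str
    if (depth == maxPath) return()
    nb <- adj[[a]]
    for (k in seq_len(nrow(nb))) {
      j <- nb$j[k]
      if (j %in% visited) next
      walk(j, c(visited, j),
           paste0(str, "|", nb$order[k], "|", g$atoms$element[j]),
           depth + 1L)
    }
  }
  for (a in seq_len(n)) walk(a, a, g$atoms$element[a], 0L)
  bits <- sort(unique(as.integer(stableStringHash(paths) %% nBits)))
  base::structure(list(bits = bits, nBits = as.integer(nBits),
                       maxPath = as.integer(maxPath)),
                  class = "ligandFingerprint")
}

#' Tanimoto coefficient between two fingerprints
#'
#' \code{|A & B| / |A | B|}; two empty fingerprints are identical (1), one
#' empty against one non-empty is 0.
#'
#' @param a,b \code{ligandFingerprint} objects with equal parameters
#' @return numeric in [0, 1]
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "ligandFingerprint"),
            inherits(b, "ligandFingerprint"))
  if (a$nBits != b$nBits || a$maxPath != b$maxPath)
    stop("fingerprints computed with different parameters")
  if (!length(a$bits) && !length(b$bits)) return(1)
  inter <- length(intersect(a$bits, b$bits))
  uni <- length(union(a$bits, b$bits))
  if (uni == 0L) return(0)
  inter / uni
}

#' Non-metabolic ligand component codes
#'
#' The shipped exclusion list: water, glycerol and common cryoprotectants,
#' detergents, buffers and precipitant ions seen in crystal structures.
#' Metal cofactors are listed separately and retained by default.
#'
#' @return list: \code{excluded} (character), \code{metals} (character)
#' @export
nonmetabolicLigandCodes <- function() {
  list(
    excluded = c(
      "HOH", "DOD", "WAT",                        # waters
      "GOL", "EDO", "PEG", "PG4", "PGE", "P6G",   # cryoprotectants/PEGs
      "MPD", "BU3", "PDO",
      "BOG", "LDA", "DDM", "SDS", "LMT", "C8E",   # detergents
      "BME", "DTT", "MRD",                        # reductants etc.
      "TRS", "EPE", "MES", "BCT", "CAC",          # buffers
      "ACT", "FMT", "ACY",                        # small acids
      "SO4", "PO4", "NO3", "CL", "BR", "IOD", "F",
      "NA", "K", "CS", "LI", "NH4"),
    metals = c("MG", "ZN", "MN", "FE", "FE2", "CA", "CU", "CU1", "NI",
               "CO", "CD", "MO"))
}

#' Filter non-metabolic ligand codes
#'
#' Removes codes on the shipped exclusion list; metal cofactors are retained
#' unless \code{keepMetals = FALSE}.
#'
#' @param codes character vector of ligand component codes
#' @param keepMetals retain metal cofactor codes (default TRUE)
#' @return retained codes, original order preserved
#' @export
filterNonmetabolic <- function(codes, keepMetals = TRUE) {
  lst <- nonmetabolicLigandCodes()
  drop <- lst$excluded
  if (!keepMetals) drop <- c(drop, lst$metals)
  codes[!toupper(codes) %in% drop]
}

#' Per-protein ligand diversity
#'
#' Deduplicates each protein's (already filtered) ligands by canonical key,
#' counts distinct ligands, computes the maximum pairwise fingerprint
#' distance (1 - minimum Tanimoto) and flags proteins binding more than six
#' different ligands.
#'
#' @param ligandsByProtein named list: protein -> list of ligand graphs
#' @return list: \code{perProtein} (data.frame protein, n_distinct,
#'   max_pairwise_distance, gt6_flag), \code{histogram} (table of
#'   n_distinct), \code{fracGt6}
#' @export
ligandDiversity <- function(ligandsByProtein) {
  rows <- lapply(names(ligandsByProtein), function(pr) {
    gs <- ligandsByProtein[[pr]]
    if (!length(gs))
      return(data.frame(protein = pr, n_distinct = 0L,
                        max_pairwise_distance = 0, gt6_flag = FALSE,
                        stringsAsFactors = FALSE))
    keys <- vapply(gs, canonicalKey, character(1))
    distinct <- gs[!duplicated(keys)]
    maxDist <- 0
    if (length(distinct) >= 2L) {
      fps <- lapply(distinct, ligandFingerprint)
      minTan <- 1
      for (i in seq_len(length(fps) - 1L))
        for (j in (i + 1L):length(fps))
          minTan <- min(minTan, tanimoto(fps[[i]], fps[[j]]))
      maxDist <- 1 - minTan
    }
    data.frame(protein = pr, n_distinct = length(distinct),
               max_pairwise_distance = maxDist,
               gt6_flag = length(distinct) > 6L,
               stringsAsFactors = FALSE)
  })
  perProtein <- do.call(rbind, rows)
  list(perProtein = perProtein,
       histogram = table(perProtein$n_distinct),
       fracGt6 = mean(perProtein$gt6_flag))
}

#' Write ligand graphs to the TSV exchange format
#'
#' One record per ligand: a \code{LIGAND code} line, \code{ATOM idx element
#' charge chirality} lines and \code{BOND i j order} lines.
#'
#' @param ligands list of ligand graphs
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeLigandTsv <- function(ligands, path) {
  lines <- character()
  for (g in ligands) {
    lines <- c(lines, paste("LIGAND", g$code, sep = "\t"))
    for (i in seq_len(nrow(g$atoms)))
      lines <- c(lines, paste("ATOM", i, g$atoms$element[i],
                              g$atoms$charge[i], g$atoms$chirality[i],
                              sep = "\t"))
    for (k in seq_len(nrow(g$bonds)))
      lines <- c(lines, paste("BOND", g$bonds$i[k], g$bonds$j[k],
                              g$bonds$order[k], sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read ligand graphs from the TSV exchange format
#' @param path input path (see [writeLigandTsv()])
#' @return list of ligand graphs
#' @export
readLigandTsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  cur <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    out[[length(out) + 1L]] <<- ligandGraph(
      cur$code, cur$elements,
      data.frame(i = cur$bi, j = cur$bj, order = cur$border,
                 stringsAsFactors = FALSE),
      charges = cur$charges, chirality = cur$chirality)
  }
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (!length(f)) next
    if (f[1L] == "LIGAND") {
      flush()
      cur <- list(code = f[2L], elements = character(),
                  charges = integer(), chirality = integer(),
                  bi = integer(), bj = integer(), border = character())
    } else if (f[1L] == "ATOM") {
      cur$elements <- c(cur$elements, f[3L])
      cur$charges <- c(cur$charges, as.integer(f[4L]))
      cur$chirality <- c(cur$chirality, as.integer(f[5L]))
    } else if (f[1L] == "BOND") {
      cur$bi <- c(cur$bi, as.integer(f[2L]))
      cur$bj <- c(cur$bj, as.integer(f[3L]))
      cur$border <- c(cur$border, f[4L])
    }
  }
  flush()
  out
}
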