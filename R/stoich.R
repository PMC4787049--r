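# Protein complex stoichiometry: the proteins x enzymes matrix, the
# minimum-free-peptide linear program and flux variability analysis over
# enzyme abundances.

#' Build the protein stoichiometric matrix
#'
#' Rows are proteins (genes), columns are enzyme complexes; entries are the
#' copy numbers of each protein within each complex. Rows and columns are
#' sorted by id for determinism.
#'
#' @param complexes deduplicated list of complex definitions
#'   (see [expandComplexes()])
#' @return a [ProteinStoichMatrix-class]
#' @export
buildStoichMatrix <- function(complexes) {
  if (!length(complexes)) stop("empty complex list")
  proteins <- sort(unique(unlist(lapply(complexes,
                                        function(cx) names(cx$subunits)))))
  enzymes <- sort(vapply(complexes, `[[`, character(1), "enzymeId"))
  m <- matrix(0L, length(proteins), length(enzymes),
              dimnames = list(proteins, enzymes))
  for (cx in complexes)
    m[names(cx$subunits), cx$enzymeId] <- as.integer(cx$subunits)
  new("ProteinStoichMatrix", matrix = m)
}

#' Fit enzyme and free-peptide abundances by linear programming
#'
#' Solves \code{min sum(f)} subject to \code{P e + f = p}, \code{e, f >= 0}:
#' measured peptide abundance is fully partitioned into complexed plus free
#' peptide, and total free peptide is minimised. Always feasible (e = 0,
#' f = p). The optimal total free abundance is unique even when individual
#' abundances are degenerate (see [fvaEnzymes()]).
#'
#' @param P a [ProteinStoichMatrix-class] or matrix with dimnames
#' @param p named numeric of measured protein abundances (>= 0); must cover
#'   every protein row of P
#' @param weights optional per-protein objective weights (default: unweighted)
#' @return list: \code{e} (named enzyme abundances), \code{f} (named free
#'   peptide abundances), \code{fTotalMin} (optimal sum of f)
#' @export
fitAbundances <- function(P, p, weights = NULL) {
  m <- if (is(P, "ProteinStoichMatrix")) stoichMatrix(P) else P
  if (!all(rownames(m) %in% names(p)))
    stop("abundances missing for protein(s): ",
         paste(utils::head(setdiff(rownames(m), names(p)), 5),
               collapse = ", "))
  p <- p[rownames(m)]
  if (any(p < 0)) stop("negative measured abundance")
  nP <- nrow(m); nE <- ncol(m)
  w <- if (is.null(weights)) rep(1, nP) else weights[rownames(m)]
  obj <- c(rep(0, nE), w)
  Aeq <- cbind(m, diag(nP))
  res <- solveLp(obj, Aeq = Aeq, beq = as.numeric(p),
                 lb = rep(0, nE + nP), ub = rep(Inf, nE + nP))
  e <- stats::setNames(res$solution[seq_len(nE)], colnames(m))
  f <- stats::setNames(res$solution[nE + seq_len(nP)], rownames(m))
  list(e = e, f = f, fTotalMin = sum(f))
}

#' Flux variability analysis over enzyme abundances
#'
#' For each enzyme, minimises and maximises its abundance subject to the
#' partitioning constraints with total free peptide held at its optimum
#' (within a small relative-plus-absolute slack; strict equality is
#' numerically brittle in LP solvers). Degenerate alternate optima show up
#' as wide ranges rather than an arbitrary vertex choice.
#'
#' @param P a [ProteinStoichMatrix-class] or matrix
#' @param p named numeric measured abundances
#' @param fTotalMin optimal total free peptide from [fitAbundances()]
#' @param relTol,absTol slack on the free-peptide budget
#' @return data.frame: enzyme, min, max
#' @export
fvaEnzymes <- function(P, p, fTotalMin = NULL,
                       relTol = 1e-6, absTol = 1e-9) {
  m <- if (is(P, "ProteinStoichMatrix")) stoichMatrix(P) else P
  if (is.null(fTotalMin)) fTotalMin <- fitAbundances(m, p)$fTotalMin
  p <- p[rownames(m)]
  nP <- nrow(m); nE <- ncol(m)
  Aeq <- cbind(m, diag(nP))
  budget <- c(rep(0, nE), rep(1, nP))
  cap <- fTotalMin * (1 + relTol) + absTol
  out <- data.frame(enzyme = colnames(m),
                    min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(nE)) {
    obj <- numeric(nE + nP); obj[j] <- 1
    for (dir in c(FALSE, TRUE)) {
      res <- solveLp(obj, Aeq = Aeq, beq = as.numeric(p),
                     Aub = matrix(budget, 1L), bub = cap,
                     lb = rep(0, nE + nP), ub = rep(Inf, nE + nP),
                     maximize = dir)
      out[j, if (dir) "max" else "min"] <- res$objective
    }
  }
  out
}

#' Complex census statistics
#'
#' Homomers are complexes with a single distinct subunit gene; their copy
#' numbers are tested for the even-stoichiometry preference. Optionally
#' ranks proteins by free abundance from a fitted solution (high free
#' abundance flags peptides not produced stoichiometrically with their
#' complex, e.g. periplasmic substrate binding proteins).
#'
#' @param complexes deduplicated complex list
#' @param solution optional result of [fitAbundances()]
#' @return list: \code{homomer_fraction},
#'   \code{even_fraction_among_homomers}, \code{multi_complex_genes}
#'   (character), \code{free_abundance_ranking} (data.frame or NULL)
#' @export
stoichStats <- function(complexes, solution = NULL) {
  if (!length(complexes)) stop("empty complex list")
  nSub <- vapply(complexes, function(cx)
    length(cx$subunits), integer(1))
  homomer <- nSub == 1L
  copies <- vapply(complexes, function(cx)
    as.integer(cx$subunits[1L]), integer(1))
  geneCount <- table(unlist(lapply(complexes,
                                   function(cx) names(cx$subunits))))
  ranking <- NULL
  if (!is.null(solution)) {
    ranking <- data.frame(gene = names(solution$f),
                          free = as.numeric(solution$f),
                          stringsAsFactors = FALSE)
    ranking <- ranking[order(-ranking$free, ranking$gene), , drop = FALSE]
    rownames(ranking) <- NULL
  }
  list(homomer_fraction = mean(homomer),
       even_fraction_among_homomers =
         if (any(homomer)) mean(copies[homomer] %% 2L == 0L) else NA_real_,
       multi_complex_genes = sort(names(geneCount)[geneCount >= 2L]),
       free_abundance_ranking = ranking)
}

#' Write a complex list to the stoichiometry TSV format
#' @param complexes complex list
#' @param path output TSV (columns enzyme_id, gene_id, copies)
#' @return \code{path}, invisibly
#' @export
writeComplexTsv <- function(complexes, path) {
  rows <- do.call(rbind, lapply(complexes, function(cx)
    data.frame(enzyme_id = cx$enzymeId, gene_id = names(cx$subunits),
               copies = as.integer(cx$subunits), stringsAsFactors = FALSE)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a complex list from the stoichiometry TSV format
#' @param path TSV with columns enzyme_id, gene_id, copies
#' @return complex list (see [expandComplexes()])
#' @export
readComplexTsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(split(tab, tab$enzyme_id), function(d) {
    sub <- stats::setNames(as.integer(d$copies), d$gene_id)
    list(enzymeId = d$enzyme_id[1L], subunits = sub[order(names(sub))])
  })
}
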