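# Structure-to-wild-type alignment, quality scoring, group classification and
# per-gene ranking of candidate structures.

.alnSubstitutionMatrix <- local({
  letters <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
               "M", "F", "P", "S", "T", "W", "Y", "V", "X")
  m <- matrix(0, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- 1
  m["X", "X"] <- 0  # unknown residues never count as exact matches
  m
})

#' Align a structure-resolved sequence to its wild-type sequence
#'
#' Global (Needleman-Wunsch) alignment scored with match +1, mismatch 0, gap
#' open -2, gap extend -0.5. Identity is the exact-match fraction over the
#' wild-type length; completeness is the fraction of wild-type positions with
#' any aligned (resolved) structure residue, mismatches included, so identity
#' can never exceed completeness.
#'
#' @param wtSeq wild-type amino-acid sequence (one-letter string)
#' @param structSeq structure-derived sequence ("X" allowed)
#' @param structResnos optional residue numbers of the structure sequence
#'   (default 1..nchar)
#' @return an [AlignmentResult-class]
#' @examples
#' aln <- alignStructureToWT("MKTAYIAK", "MKTVYIAK")
#' aln@identity      # 0.875
#' aln@completeness  # 1
#' @export
alignStructureToWT <- function(wtSeq, structSeq,
                               structResnos = seq_len(nchar(structSeq))) {
  if (!nzchar(wtSeq) || !nzchar(structSeq))
    stop("sequences must be non-empty")
  wtSeq <- toupper(wtSeq)
  structSeq <- toupper(structSeq)
  bad <- setdiff(strsplit(paste0(wtSeq, structSeq), "")[[1L]],
                 rownames(.alnSubstitutionMatrix))
  if (length(bad))
    stop("non-standard residue letter(s): ", paste(bad, collapse = ", "))
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(wtSeq),
    subject = Biostrings::AAString(structSeq),
    type = "global",
    substitutionMatrix = .alnSubstitutionMatrix,
    gapOpening = 2, gapExtension = 0.5)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]

  wtLen <- nchar(wtSeq)
  wtPos <- 0L
  sIdx <- 0L
  pairs <- matrix(integer(), ncol = 2L,
                  dimnames = list(NULL, c("wtPos", "structResno")))
  alignedWt <- logical(wtLen)
  matchWt <- logical(wtLen)
  mutations <- list()
  for (k in seq_along(p)) {
    if (p[k] != "-") wtPos <- wtPos + 1L
    if (s[k] != "-") sIdx <- sIdx + 1L
    if (p[k] != "-" && s[k] != "-") {
      pairs <- rbind(pairs, c(wtPos, structResnos[sIdx]))
      alignedWt[wtPos] <- TRUE
      if (p[k] == s[k] && p[k] != "X") {
        matchWt[wtPos] <- TRUE
      } else {
        mutations[[length(mutations) + 1L]] <-
          data.frame(wtPos = wtPos, wtAa = p[k], obsAa = s[k],
                     stringsAsFactors = FALSE)
      }
    }
  }
  alnIdx <- which(alignedWt)
  nTail <- if (length(alnIdx)) alnIdx[1L] - 1L else wtLen
  cTail <- if (length(alnIdx)) wtLen - alnIdx[length(alnIdx)] else 0L
  interior <- data.frame(start = integer(), length = integer())
  if (length(alnIdx) > 1L) {
    inRange <- seq(alnIdx[1L], alnIdx[length(alnIdx)])
    gapRuns <- rle(!alignedWt[inRange])
    posCursor <- alnIdx[1L]
    for (i in seq_along(gapRuns$lengths)) {
      if (gapRuns$values[i])
        interior <- rbind(interior,
                          data.frame(start = posCursor,
                                     length = gapRuns$lengths[i]))
      posCursor <- posCursor + gapRuns$lengths[i]
    }
  }
  muts <- if (length(mutations)) do.call(rbind, mutations) else
    data.frame(wtPos = integer(), wtAa = character(), obsAa = character(),
               stringsAsFactors = FALSE)
  new("AlignmentResult",
      wtLength = wtLen, pairs = pairs,
      identity = sum(matchWt) / wtLen,
      completeness = sum(alignedWt) / wtLen,
      mutations = muts, interiorGaps = interior,
      terminalGaps = c(nTail, cTail))
}

#' Resolution score component
#'
#' X-ray: max(0, 1 - (resolution - 1)/4), i.e. 1.0 A maps to 1 and >= 5.0 A
#' to 0. NMR entries get a fixed 0.7.
#'
#' @param structure a [StructureRecord-class]
#' @return numeric in [0, 1] (NA for MODEL entries)
#' @export
resolutionScore <- function(structure) {
  switch(structure@method,
         XRAY = max(0, 1 - (structure@resolution - 1.0) / 4.0),
         NMR = 0.7,
         MODEL = NA_real_)
}

#' Score a candidate structure against its wild-type alignment
#'
#' Experimental structures combine sequence identity, completeness and
#' resolution as \code{0.5 s_si + 0.3 completeness + 0.2 s_res}, clamped into
#' (0, 1]. Homology models are scored \code{0.5 TM + 0.5 s_comp} where
#' \code{s_comp = 1 - 0.5 * sum |f_model - f_ref|} over the eight
#' secondary-structure class frequencies; with no reference composition the
#' composition term exerts no penalty.
#'
#' @param aln [AlignmentResult-class] against the gene's wild-type sequence
#' @param structure a [StructureRecord-class]
#' @param ssRef optional named numeric reference secondary-structure
#'   composition (fractions over classes H, G, I, E, B, T, S, "-")
#' @param weights experimental score weights (named: si, comp, res)
#' @return a [QualityScore-class]
#' @export
scoreStructure <- function(aln, structure, ssRef = NULL,
                           weights = c(si = 0.5, comp = 0.3, res = 0.2)) {
  sSi <- aln@identity
  sRes <- resolutionScore(structure)
  group <- classifyGroup(aln, structure)
  if (structure@method == "MODEL") {
    if (is.na(structure@tmScore))
      stop("homology model '", structure@structureId,
           "' carries no TM-score annotation")
    sComp <- 1
    if (!is.null(ssRef)) {
      fModel <- secondaryStructureComposition(structure)
      classes <- union(names(fModel), names(ssRef))
      fm <- stats::setNames(numeric(length(classes)), classes)
      fr <- fm
      fm[names(fModel)] <- fModel
      fr[names(ssRef)] <- ssRef
      sComp <- 1 - 0.5 * sum(abs(fm - fr))
    }
    combined <- 0.5 * structure@tmScore + 0.5 * sComp
  } else {
    sComp <- NA_real_
    combined <- weights[["si"]] * sSi +
      weights[["comp"]] * aln@completeness +
      weights[["res"]] * sRes
  }
  combined <- min(1, max(0.01, combined))
  new("QualityScore", sSi = sSi, sRes = if (is.na(sRes)) 0 else sRes,
      sComp = sComp, combined = combined, group = group)
}

#' Classify a structure into quality group I, II or III
#'
#' Group I: no mutations, no interior gaps and resolution <= 3.0 A (NMR and
#' model entries satisfy the resolution criterion vacuously). Group II: every
#' run of consecutive mutated positions is at most \code{maxMutRun} long,
#' mutated positions total at most \code{maxMutTotal}, every interior gap is
#' at most \code{maxGapEach} residues with at most \code{maxGapTotal} in
#' total, and the resolution criterion holds. Everything else is group III
#' and is routed to homology modelling. Terminal gaps never affect the
#' classification.
#'
#' @param aln an [AlignmentResult-class]
#' @param structure a [StructureRecord-class]
#' @param maxMutRun,maxMutTotal,maxGapEach,maxGapTotal,maxResolution group II
#'   bounds
#' @return "I", "II" or "III"
#' @export
classifyGroup <- function(aln, structure, maxMutRun = 2L, maxMutTotal = 5L,
                          maxGapEach = 3L, maxGapTotal = 5L,
                          maxResolution = 3.0) {
  resOk <- structure@method != "XRAY" ||
    (!is.na(structure@resolution) && structure@resolution <= maxResolution)
  nMut <- nrow(aln@mutations)
  nGap <- nrow(aln@interiorGaps)
  if (nMut == 0L && nGap == 0L && resOk) return("I")
  mutRunOk <- TRUE
  if (nMut > 0L) {
    runs <- rle(diff(c(-10L, sort(aln@mutations$wtPos))) == 1L)
    longest <- 1L
    cur <- 1L
    pos <- sort(aln@mutations$wtPos)
    if (length(pos) > 1L) {
      for (i in 2:length(pos)) {
        cur <- if (pos[i] - pos[i - 1L] == 1L) cur + 1L else 1L
        longest <- max(longest, cur)
      }
    }
    mutRunOk <- longest <= maxMutRun
  }
  ok <- resOk && mutRunOk && nMut <= maxMutTotal &&
    (nGap == 0L || (max(aln@interiorGaps$length) <= maxGapEach &&
                    sum(aln@interiorGaps$length) <= maxGapTotal))
  if (ok) "II" else "III"
}

#' Pick the chain of a structure that best matches a wild-type sequence
#'
#' Multi-chain entries are resolved by aligning every chain and keeping the
#' one with the highest identity to the gene's sequence.
#'
#' @param structure a [StructureRecord-class]
#' @param wtSeq wild-type sequence
#' @return list with \code{chain} (chain id) and \code{alignment}
#'   (an [AlignmentResult-class] computed on ATOM-derived residues)
#' @export
bestChainFor <- function(structure, wtSeq) {
  best <- NULL
  for (ch in names(structure@chains)) {
    atoms <- structure@chains[[ch]]$atoms
    resnos <- atoms$resno[!duplicated(atoms$resno)]
    seqs <- chainSequence(structure, ch)
    aln <- alignStructureToWT(wtSeq, seqs, structResnos = resnos)
    if (is.null(best) || aln@identity > best$alignment@identity)
      best <- list(chain = ch, alignment = aln)
  }
  best
}

#' Rank candidate structures for a gene
#'
#' Candidates are sorted by combined score (descending); ties are broken by
#' higher sequence identity, experimental entries before homology models,
#' lower resolution (entries without one last) and finally lexicographic
#' structure id. The first entry is the representative.
#'
#' @param candidates list; each element a list with \code{structure}
#'   (a [StructureRecord-class]) and \code{score} (a [QualityScore-class])
#' @return data.frame ranking with a \code{representative} flag column
#' @export
rankStructures <- function(candidates) {
  if (!length(candidates)) stop("no candidate structures to rank")
  df <- do.call(rbind, lapply(candidates, function(cand) {
    s <- cand$structure
    q <- cand$score
    data.frame(structure_id = s@structureId, method = s@method,
               resolution = s@resolution, s_si = q@sSi,
               completeness = NA_real_, combined = q@combined,
               group = q@group, stringsAsFactors = FALSE)
  }))
  comp <- vapply(candidates, function(cand) {
    a <- cand$alignment
    if (is.null(a)) NA_real_ else a@completeness
  }, numeric(1))
  df$completeness <- comp
  resKey <- ifelse(is.na(df$resolution), Inf, df$resolution)
  methodKey <- ifelse(df$method == "MODEL", 1L, 0L)
  ord <- order(-df$combined, -df$s_si, methodKey, resKey, df$structure_id)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df$representative <- seq_len(nrow(df)) == 1L
  df
}

#' Map model genes to candidate structures and rank them
#'
#' Runs the full QC stage: per gene, each candidate structure's best-matching
#' chain is aligned to the wild-type sequence, scored and classified; the
#' candidates are then ranked and a representative chosen.
#'
#' @param seqs named character vector of wild-type sequences (gene id ->
#'   sequence)
#' @param structuresByGene named list (gene id -> list of
#'   [StructureRecord-class])
#' @return data.frame report: gene, structure_id, method, resolution, s_si,
#'   completeness, combined, group, representative
#' @export
mapQc <- function(seqs, structuresByGene) {
  out <- list()
  for (gene in names(structuresByGene)) {
    wt <- seqs[[gene]]
    if (is.null(wt)) {
      warning("no wild-type sequence for gene ", gene, "; skipped")
      next
    }
    cands <- lapply(structuresByGene[[gene]], function(s) {
      bc <- bestChainFor(s, wt)
      list(structure = s, alignment = bc$alignment,
           score = scoreStructure(bc$alignment, s))
    })
    rk <- rankStructures(cands)
    rk <- cbind(gene = gene, rk, stringsAsFactors = FALSE)
    out[[gene]] <- rk
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
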