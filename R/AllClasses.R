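#' @import methods
NULL

# ---------------------------------------------------------------------------
# Metabolic model containers
# ---------------------------------------------------------------------------

#' Reaction: one reaction of a metabolic model
#'
#' @slot id reaction identifier
#' @slot stoichiometry named numeric vector, metabolite id -> signed
#'   coefficient (negative = consumed)
#' @slot lowerBound,upperBound flux bounds (mmol/gDW/h convention,
#'   dimensionless here)
#' @slot gpr gene-protein-reaction boolean rule ("" when absent)
#' @slot subsystem free-text subsystem annotation
#' @exportClass Reaction
setClass("Reaction",
  representation(id = "character", stoichiometry = "numeric",
                 lowerBound = "numeric", upperBound = "numeric",
                 gpr = "character", subsystem = "character"),
  prototype(gpr = "", subsystem = ""))

setValidity("Reaction", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "reaction id must be a non-empty string")
  if (length(object@lowerBound) != 1L || length(object@upperBound) != 1L ||
      object@lowerBound > object@upperBound)
    msg <- c(msg, "lowerBound must be <= upperBound")
  if (length(object@stoichiometry) &&
      is.null(names(object@stoichiometry)))
    msg <- c(msg, "stoichiometry must be a named vector")
  if (length(msg)) msg else TRUE
})

#' MetabolicModel: a genome-scale metabolic model
#'
#' The systems-level scaffold every other stage attaches to: genes,
#' metabolites, reactions with GPR rules and an objective reaction.
#'
#' @slot modelId model identifier
#' @slot genes character vector of gene locus ids
#' @slot metabolites character vector of metabolite ids
#' @slot reactions list of [Reaction-class] objects
#' @slot objective id of the objective (biomass) reaction
#' @exportClass MetabolicModel
setClass("MetabolicModel",
  representation(modelId = "character", genes = "character",
                 metabolites = "character", reactions = "list",
                 objective = "character"))

setValidity("MetabolicModel", function(object) {
  msg <- character()
  ids <- vapply(object@reactions, function(r) r@id, character(1))
  if (anyDuplicated(ids)) msg <- c(msg, "reaction ids must be unique")
  if (length(object@objective) == 1L && nzchar(object@objective) &&
      !(object@objective %in% ids))
    msg <- c(msg, "objective reaction not present in the model")
  gprGeneSets <- unlist(lapply(object@reactions, function(r) {
    if (nzchar(r@gpr)) gprGenes(parseGpr(r@gpr)) else character()
  }))
  missing <- setdiff(gprGeneSets, object@genes)
  if (length(missing))
    msg <- c(msg, paste0("GPR references unknown genes: ",
                         paste(utils::head(missing, 5), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @describeIn MetabolicModel-class compact display
#' @export
setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel '", object@modelId, "': ",
      length(object@genes), " genes, ",
      length(object@metabolites), " metabolites, ",
      length(object@reactions), " reactions; objective: ",
      object@objective, "\n", sep = "")
})

#' @rdname MetabolicModel-class
#' @param object a \code{MetabolicModel}
#' @export
setGeneric("modelGenes", function(object) standardGeneric("modelGenes"))

#' @rdname MetabolicModel-class
#' @export
setMethod("modelGenes", "MetabolicModel", function(object) object@genes)

#' @rdname MetabolicModel-class
#' @export
setGeneric("reactions", function(object) standardGeneric("reactions"))

#' @rdname MetabolicModel-class
#' @export
setMethod("reactions", "MetabolicModel", function(object) object@reactions)

#' @rdname MetabolicModel-class
#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))

#' @rdname MetabolicModel-class
#' @export
setMethod("reactionIds", "MetabolicModel", function(object)
  vapply(object@reactions, function(r) r@id, character(1)))

# ---------------------------------------------------------------------------
# Structures
# ---------------------------------------------------------------------------

#' StructureRecord: parsed content of one PDB entry
#'
#' @slot structureId entry identifier
#' @slot method one of "XRAY", "NMR", "MODEL"
#' @slot resolution resolution in Angstrom (NA for NMR/model entries)
#' @slot tmScore I-TASSER TM-score annotation for MODEL entries (NA otherwise)
#' @slot chains named list; one element per chain with components
#'   \code{reportedSequence} (one-letter string, SEQRES when present) and
#'   \code{atoms} (data.frame: resno, resname, name, element, x, y, z)
#' @exportClass StructureRecord
setClass("StructureRecord",
  representation(structureId = "character", method = "character",
                 resolution = "numeric", tmScore = "numeric",
                 chains = "list"),
  prototype(resolution = NA_real_, tmScore = NA_real_))

setValidity("StructureRecord", function(object) {
  msg <- character()
  if (!object@method %in% c("XRAY", "NMR", "MODEL"))
    msg <- c(msg, "method must be XRAY, NMR or MODEL")
  if (object@method == "XRAY" &&
      (is.na(object@resolution) || object@resolution <= 0))
    msg <- c(msg, "XRAY entries must carry a positive resolution")
  if (!is.na(object@tmScore) &&
      (object@tmScore < 0 || object@tmScore > 1))
    msg <- c(msg, "tmScore must lie in [0, 1]")
  for (ch in object@chains) {
    rn <- unique(ch$atoms$resno)
    if (is.unsorted(rn, strictly = TRUE))
      msg <- c(msg, "residue numbers must be strictly increasing in a chain")
    if (!all(is.finite(as.matrix(ch$atoms[, c("x", "y", "z")]))))
      msg <- c(msg, "atom coordinates must be finite")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "StructureRecord", function(object) {
  nres <- sum(vapply(object@chains,
                     function(ch) length(unique(ch$atoms$resno)), integer(1)))
  cat("StructureRecord '", object@structureId, "' (", object@method,
      if (!is.na(object@resolution))
        paste0(", ", format(object@resolution), " A") else "",
      "): ", length(object@chains), " chain(s), ", nres, " residues\n",
      sep = "")
})

#' Sequence of one chain of a structure
#'
#' Returns the chain sequence derived from the ATOM residues (the residues
#' actually resolved), as a one-letter string.
#'
#' @param structure a [StructureRecord-class]
#' @param chain chain identifier (default: first chain)
#' @return one-letter amino-acid string
#' @export
chainSequence <- function(structure, chain = names(structure@chains)[1L]) {
  ch <- structure@chains[[chain]]
  if (is.null(ch)) stop("no such chain: ", chain)
  res <- ch$atoms[!duplicated(ch$atoms$resno), c("resno", "resname")]
  paste(aa3to1(res$resname), collapse = "")
}

# ---------------------------------------------------------------------------
# Alignment and quality
# ---------------------------------------------------------------------------

#' AlignmentResult: a structure sequence aligned to its wild-type sequence
#'
#' @slot wtLength length of the wild-type sequence
#' @slot pairs integer matrix, columns \code{wtPos} (1-based wild-type
#'   position) and \code{structResno} (structure residue number)
#' @slot identity exact-match fraction over the wild-type length
#' @slot completeness resolved (aligned) fraction over the wild-type length,
#'   mismatches included
#' @slot mutations data.frame: wtPos, wtAa, obsAa
#' @slot interiorGaps data.frame: start (wt position), length
#' @slot terminalGaps integer length 2: unresolved N- and C-terminal tails
#' @exportClass AlignmentResult
setClass("AlignmentResult",
  representation(wtLength = "integer", pairs = "matrix",
                 identity = "numeric", completeness = "numeric",
                 mutations = "data.frame", interiorGaps = "data.frame",
                 terminalGaps = "integer"))

setValidity("AlignmentResult", function(object) {
  if (object@identity > object@completeness + 1e-12)
    "identity fraction cannot exceed completeness fraction" else TRUE
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf(paste0("AlignmentResult: wt length %d, identity %.3f, ",
                     "completeness %.3f, %d mutation(s), %d interior gap(s)\n"),
              object@wtLength, object@identity, object@completeness,
              nrow(object@mutations), nrow(object@interiorGaps)))
})

#' QualityScore: QC score components for one candidate structure
#'
#' @slot sSi sequence-identity component in [0,1]
#' @slot sRes resolution component in [0,1]
#' @slot sComp secondary-structure composition component (homology models
#'   only; NA otherwise)
#' @slot combined combined score in (0, 1]
#' @slot group quality group "I", "II" or "III"
#' @exportClass QualityScore
setClass("QualityScore",
  representation(sSi = "numeric", sRes = "numeric", sComp = "numeric",
                 combined = "numeric", group = "character"),
  prototype(sComp = NA_real_, group = NA_character_))

setValidity("QualityScore", function(object) {
  msg <- character()
  if (object@combined <= 0 || object@combined > 1)
    msg <- c(msg, "combined score must lie in (0, 1]")
  if (!is.na(object@group) && !object@group %in% c("I", "II", "III"))
    msg <- c(msg, "group must be I, II or III")
  if (length(msg)) msg else TRUE
})

setMethod("show", "QualityScore", function(object) {
  cat(sprintf("QualityScore: combined %.3f (S_SI %.3f, S_res %.3f%s), group %s\n",
              object@combined, object@sSi, object@sRes,
              if (!is.na(object@sComp))
                sprintf(", S_comp %.3f", object@sComp) else "",
              object@group))
})

# ---------------------------------------------------------------------------
# Protein stoichiometric matrix
# ---------------------------------------------------------------------------

#' ProteinStoichMatrix: proteins x enzymes copy-number matrix
#'
#' Rows are peptides (genes), columns are enzyme complexes; entry (i, j) is
#' the number of copies of peptide i in complex j, mirroring the metabolic
#' stoichiometric matrix at the proteome level.
#'
#' @slot matrix non-negative integer matrix with protein row names and enzyme
#'   column names
#' @exportClass ProteinStoichMatrix
setClass("ProteinStoichMatrix", representation(matrix = "matrix"))

setValidity("ProteinStoichMatrix", function(object) {
  m <- object@matrix
  msg <- character()
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "matrix must carry protein row names and enzyme col names")
  if (any(m < 0) || any(m != round(m)))
    msg <- c(msg, "entries must be non-negative integers")
  if (ncol(m) && any(colSums(m) == 0))
    msg <- c(msg, "every enzyme column needs at least one positive entry")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ProteinStoichMatrix", function(object) {
  cat("ProteinStoichMatrix:", nrow(object@matrix), "proteins x",
      ncol(object@matrix), "enzymes\n")
})

#' @rdname ProteinStoichMatrix-class
#' @param object a \code{ProteinStoichMatrix}
#' @export
setGeneric("stoichMatrix", function(object) standardGeneric("stoichMatrix"))

#' @rdname ProteinStoichMatrix-class
#' @export
setMethod("stoichMatrix", "ProteinStoichMatrix",
          function(object) object@matrix)
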