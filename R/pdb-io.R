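# PDB reading and writing. ATOM/SEQRES parsing is delegated to bio3d;
# REMARK 2 resolution, EXPDTA method and the TM-score annotation are scanned
# from the raw text since bio3d does not expose them.

#' Parse PDB file content into a StructureRecord
#'
#' Resolution is read from \code{REMARK   2 RESOLUTION.} when present; the
#' experimental method from \code{EXPDTA} (entries without a resolution and
#' without an EXPDTA record are treated as NMR). Homology models may carry a
#' TM-score on a \code{REMARK  98 TM-SCORE} line. The reported sequence comes
#' from SEQRES when present, otherwise it is derived from the ATOM residues.
#'
#' @param text character vector of PDB lines, or a single string
#' @param structureId identifier for the record
#' @return a [StructureRecord-class]
#' @export
parsePdb <- function(text, structureId = "structure") {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]

  atomLines <- grep("^ATOM  ", text)
  if (!length(atomLines))
    stop("no ATOM records in PDB input '", structureId, "'")
  for (i in atomLines) {
    coords <- substr(text[i], 31, 54)
    vals <- suppressWarnings(as.numeric(c(substr(text[i], 31, 38),
                                          substr(text[i], 39, 46),
                                          substr(text[i], 47, 54))))
    if (anyNA(vals) || !all(is.finite(vals)))
      stop("malformed coordinate field at line ", i, ": '", text[i], "'")
  }

  resolution <- NA_real_
  remark2 <- grep("^REMARK   2 RESOLUTION\\.", text, value = TRUE)
  if (length(remark2)) {
    m <- regmatches(remark2[1L],
                    regexpr("[0-9]+\\.?[0-9]*", sub("RESOLUTION\\.", "",
                                                    remark2[1L])))
    if (length(m)) resolution <- as.numeric(m)
  }
  expdta <- grep("^EXPDTA", text, value = TRUE)
  method <- if (length(expdta) && grepl("NMR", expdta[1L])) "NMR"
            else if (length(expdta) && grepl("THEORETICAL|MODEL", expdta[1L]))
              "MODEL"
            else if (!is.na(resolution)) "XRAY"
            else "NMR"
  tmScore <- NA_real_
  remark98 <- grep("^REMARK  98 TM-SCORE", text, value = TRUE)
  if (length(remark98))
    tmScore <- as.numeric(regmatches(
      remark98[1L], regexpr("[0-9]*\\.?[0-9]+$", trimws(remark98[1L]))))

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(text, tf)
  pdb <- bio3d::read.pdb(tf, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  # keep the first alternate location only
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  at$chain[is.na(at$chain) | at$chain == ""] <- "A"

  seqres <- list()
  if (!is.null(pdb$seqres) && length(pdb$seqres)) {
    for (ch in unique(names(pdb$seqres)))
      seqres[[ch]] <- paste(aa3to1(pdb$seqres[names(pdb$seqres) == ch]),
                            collapse = "")
  }

  chains <- list()
  for (ch in unique(at$chain)) {
    sel <- at[at$chain == ch, , drop = FALSE]
    elem <- sel$elesy
    blank <- is.na(elem) | !nzchar(trimws(elem))
    elem[blank] <- substr(gsub("[0-9]", "", trimws(sel$elety[blank])), 1, 1)
    atoms <- data.frame(resno = sel$resno,
                        resname = sel$resid,
                        name = trimws(sel$elety),
                        element = toupper(trimws(elem)),
                        x = sel$x, y = sel$y, z = sel$z,
                        stringsAsFactors = FALSE)
    atoms <- atoms[order(atoms$resno), , drop = FALSE]
    rownames(atoms) <- NULL
    reported <- seqres[[ch]]
    if (is.null(reported))
      reported <- paste(aa3to1(atoms$resname[!duplicated(atoms$resno)]),
                        collapse = "")
    chains[[ch]] <- list(reportedSequence = reported, atoms = atoms)
  }

  new("StructureRecord", structureId = structureId, method = method,
      resolution = resolution, tmScore = tmScore, chains = chains)
}

#' Read a StructureRecord from a PDB file
#' @param path PDB file path
#' @param structureId identifier (default: file base name)
#' @return a [StructureRecord-class]
#' @export
readPdb <- function(path,
                    structureId = sub("\\.pdb$", "", basename(path))) {
  parsePdb(readLines(path, warn = FALSE), structureId = structureId)
}

#' Write a StructureRecord as PDB text
#'
#' Re-emits ATOM records with the original residue numbering. Additional
#' remarks (e.g. REMARK 99 lines flagging modified residues) are placed in
#' the header.
#'
#' @param structure a [StructureRecord-class]
#' @param path output path (NULL to return the text instead)
#' @param remarks optional character vector of extra full REMARK lines
#' @return the PDB text (invisibly when written to a file)
#' @export
writeStructurePdb <- function(structure, path = NULL, remarks = character()) {
  lines <- character()
  if (structure@method == "NMR") {
    lines <- c(lines, "EXPDTA    SOLUTION NMR")
  } else if (structure@method == "MODEL") {
    lines <- c(lines, "EXPDTA    THEORETICAL MODEL")
    if (!is.na(structure@tmScore))
      lines <- c(lines, sprintf("REMARK  98 TM-SCORE %.3f",
                                structure@tmScore))
  } else {
    lines <- c(lines, "EXPDTA    X-RAY DIFFRACTION")
  }
  if (!is.na(structure@resolution))
    lines <- c(lines, sprintf("REMARK   2 RESOLUTION.  %6.2f ANGSTROMS.",
                              structure@resolution))
  lines <- c(lines, remarks)
  for (ch in names(structure@chains)) {
    seq1 <- structure@chains[[ch]]$reportedSequence
    if (nzchar(seq1)) {
      res3 <- aa1to3(strsplit(seq1, "")[[1L]])
      rows <- split(res3, ceiling(seq_along(res3) / 13))
      for (k in seq_along(rows))
        lines <- c(lines, sprintf("SEQRES %3d %s %4d  %s", k, ch,
                                  length(res3),
                                  paste(rows[[k]], collapse = " ")))
    }
  }
  serial <- 0L
  for (ch in names(structure@chains)) {
    atoms <- structure@chains[[ch]]$atoms
    for (i in seq_len(nrow(atoms))) {
      serial <- serial + 1L
      nm <- atoms$name[i]
      nmFmt <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else nm
      lines <- c(lines, sprintf(
        "ATOM  %5d %4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nmFmt, atoms$resname[i], ch, atoms$resno[i],
        atoms$x[i], atoms$y[i], atoms$z[i], 1.00, 0.00, atoms$element[i]))
    }
    lines <- c(lines, "TER")
  }
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
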