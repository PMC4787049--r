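# Master per-gene table assembly and the end-to-end pipeline driver.

#' Assemble the master per-gene data frame
#'
#' Left-joins the QC ranking (representative rows), the structural property
#' table, complex memberships and melting temperatures onto the model's gene
#' list; genes without data carry NA in the corresponding columns.
#'
#' @param model a [MetabolicModel-class]
#' @param ranking QC report from [mapQc()] (NULL to skip)
#' @param props data.frame of property vectors with a \code{gene} column
#'   (NULL to skip)
#' @param complexes global complex census (see [modelComplexes()]; NULL to
#'   skip)
#' @param tm melting-temperature data.frame (gene_id, tm_celsius; NULL to
#'   skip)
#' @param seqs optional named character vector of wild-type sequences
#' @return data.frame, one row per model gene, deterministic column order
#' @export
assembleMasterTable <- function(model, ranking = NULL, props = NULL,
                                complexes = NULL, tm = NULL, seqs = NULL) {
  out <- data.frame(gene = sort(model@genes), stringsAsFactors = FALSE)
  if (!is.null(seqs))
    out$seq_length <- unname(nchar(seqs[out$gene]))
  if (!is.null(ranking)) {
    rep <- ranking[ranking$representative, , drop = FALSE]
    if (anyDuplicated(rep$gene)) stop("duplicate gene in ranking input")
    cols <- c("gene", "structure_id", "method", "resolution", "s_si",
              "completeness", "combined", "group")
    out <- merge(out, rep[, cols], by = "gene", all.x = TRUE, sort = TRUE)
    nCand <- as.data.frame(table(ranking$gene), stringsAsFactors = FALSE)
    names(nCand) <- c("gene", "n_candidate_structures")
    out <- merge(out, nCand, by = "gene", all.x = TRUE, sort = TRUE)
  }
  if (!is.null(props)) {
    if (anyDuplicated(props$gene)) stop("duplicate gene in property input")
    out <- merge(out, props, by = "gene", all.x = TRUE, sort = TRUE)
  }
  if (!is.null(complexes)) {
    membership <- vapply(out$gene, function(g) {
      hits <- vapply(complexes, function(cx)
        g %in% names(cx$subunits), logical(1))
      paste(vapply(complexes[hits], `[[`, character(1), "enzymeId"),
            collapse = ";")
    }, character(1))
    out$complexes <- unname(membership)
  }
  if (!is.null(tm)) {
    if (anyDuplicated(tm$gene_id)) stop("duplicate gene in Tm input")
    tm2 <- data.frame(gene = tm$gene_id, tm_celsius = tm$tm_celsius,
                      stringsAsFactors = FALSE)
    out <- merge(out, tm2, by = "gene", all.x = TRUE, sort = TRUE)
  }
  rownames(out) <- NULL
  out
}

#' Run the end-to-end pipeline
#'
#' Executes map-qc, refinement of group-II entries, property calculation and
#' the enabled downstream stages, writing TSV outputs plus a MANIFEST with
#' md5 checksums. The configuration is a flat list (or a YAML file path)
#' with entries: \code{model} (JSON path), \code{sequences} (FASTA path),
#' \code{pdb_dir} (directory of .pdb files named like the gene or listed in
#' a \code{structure_map} TSV of gene/file pairs), optional \code{tm_table},
#' \code{abundances}, \code{seed}, and logical switches \code{run_stoich},
#' \code{run_tm_growth}.
#'
#' @param config list or YAML file path
#' @param outDir output directory (created if needed)
#' @return the output directory, invisibly; a MANIFEST file lists every
#'   stage output with its checksum
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  required <- c("model", "sequences", "pdb_dir")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("config is missing key(s): ", paste(missing, collapse = ", "))
  unknown <- setdiff(names(config),
                     c(required, "tm_table", "abundances", "seed",
                       "run_stoich", "run_tm_growth", "structure_map"))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logMsg <- function(...) message("[gemprokit] ", ...)

  model <- readModelJson(config$model)
  seqs <- readFastaSeqs(config$sequences)
  pdbFiles <- list.files(config$pdb_dir, pattern = "\\.pdb$",
                         full.names = TRUE)
  structuresByGene <- list()
  if (!is.null(config$structure_map)) {
    sm <- utils::read.delim(config$structure_map, stringsAsFactors = FALSE)
    for (k in seq_len(nrow(sm))) {
      s <- readPdb(file.path(config$pdb_dir, sm$file[k]))
      structuresByGene[[sm$gene[k]]] <-
        c(structuresByGene[[sm$gene[k]]], list(s))
    }
  } else {
    for (f in pdbFiles) {
      gene <- sub("\\.pdb$", "", basename(f))
      gene <- sub("_[0-9]+$", "", gene)
      structuresByGene[[gene]] <-
        c(structuresByGene[[gene]], list(readPdb(f)))
    }
  }
  outputs <- character()
  emit <- function(df, name) {
    p <- file.path(outDir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, p)
    p
  }

  logMsg("map-qc: ", length(structuresByGene), " gene(s), ",
         length(pdbFiles), " structure file(s)")
  ranking <- mapQc(seqs, structuresByGene)
  emit(ranking, "ranking.tsv")

  refined <- list()
  repRows <- ranking[ranking$representative, , drop = FALSE]
  for (k in seq_len(nrow(repRows))) {
    gene <- repRows$gene[k]
    if (repRows$group[k] != "II") next
    s <- Filter(function(x) x@structureId == repRows$structure_id[k],
                structuresByGene[[gene]])[[1L]]
    res <- revertToWildtype(s, seqs[[gene]])
    refined[[gene]] <- res$structure
    writeLines(writeStructurePdb(res$structure, remarks = res$remarks),
               file.path(outDir, paste0(gene, "_refined.pdb")))
    outputs <- c(outputs, file.path(outDir, paste0(gene, "_refined.pdb")))
  }
  logMsg("refine: ", length(refined), " group-II structure(s) reverted")

  propRows <- list()
  for (k in seq_len(nrow(repRows))) {
    gene <- repRows$gene[k]
    s <- if (!is.null(refined[[gene]])) refined[[gene]] else
      Filter(function(x) x@structureId == repRows$structure_id[k],
             structuresByGene[[gene]])[[1L]]
    pv <- propertyVector(s)
    propRows[[gene]] <- cbind(data.frame(gene = gene,
                                         stringsAsFactors = FALSE),
                              as.data.frame(as.list(pv)))
  }
  props <- do.call(rbind, propRows)
  rownames(props) <- NULL
  emit(props, "props.tsv")
  logMsg("props: ", nrow(props), " property vector(s)")

  cx <- modelComplexes(model)
  tm <- if (!is.null(config$tm_table)) readTmTable(config$tm_table) else NULL

  if (isTRUE(config$run_stoich) && !is.null(config$abundances)) {
    ab <- utils::read.delim(config$abundances, stringsAsFactors = FALSE)
    p <- stats::setNames(ab$abundance, ab$gene_id)
    P <- buildStoichMatrix(cx$census)
    keep <- rownames(stoichMatrix(P)) %in% names(p)
    sol <- fitAbundances(stoichMatrix(P)[keep, , drop = FALSE], p)
    emit(data.frame(enzyme = names(sol$e), abundance = sol$e),
         "enzyme_abundance.tsv")
    logMsg("stoich: total free peptide ", format(sol$fTotalMin))
  }
  if (isTRUE(config$run_tm_growth) && !is.null(tm)) {
    curve <- growthCurve(model, tm, seq(20, 80, by = 5))
    emit(curve, "growth_curve.tsv")
    logMsg("tm-growth: ", nrow(curve), " temperature(s)")
  }

  master <- assembleMasterTable(model, ranking = ranking, props = props,
                                complexes = cx$census, tm = tm, seqs = seqs)
  emit(master, "master_table.tsv")

  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(outDir, "MANIFEST"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logMsg("done: ", length(outputs), " output file(s)")
  invisible(outDir)
}
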