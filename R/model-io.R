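# Metabolic model I/O, GPR boolean rules and enzyme-complex expansion.

#' Construct a Reaction
#'
#' @param id reaction id
#' @param stoichiometry named numeric vector (metabolite -> coefficient)
#' @param lowerBound,upperBound flux bounds
#' @param gpr GPR boolean rule string ("" for none)
#' @param subsystem subsystem annotation
#' @return a [Reaction-class]
#' @export
Reaction <- function(id, stoichiometry = numeric(), lowerBound = -1000,
                     upperBound = 1000, gpr = "", subsystem = "") {
  new("Reaction", id = id, stoichiometry = stoichiometry,
      lowerBound = as.numeric(lowerBound), upperBound = as.numeric(upperBound),
      gpr = gpr, subsystem = subsystem)
}

#' Construct a MetabolicModel
#'
#' @param modelId model id
#' @param genes character vector of gene ids
#' @param metabolites character vector of metabolite ids
#' @param reactions list of [Reaction-class]
#' @param objective id of the objective reaction
#' @return a [MetabolicModel-class]
#' @export
MetabolicModel <- function(modelId, genes, metabolites, reactions,
                           objective = "") {
  new("MetabolicModel", modelId = modelId, genes = genes,
      metabolites = metabolites, reactions = reactions, objective = objective)
}

# --- GPR parsing ------------------------------------------------------------

#' Parse a gene-protein-reaction boolean rule
#'
#' GPR rules are boolean statements over gene ids using \code{and}/\code{or}
#' (case-insensitive) and parentheses; \code{and} binds tighter than
#' \code{or}. Gene ids match \code{[A-Za-z0-9_.-]+}.
#'
#' @param text GPR rule string
#' @return a GPR abstract syntax tree: nested lists with a \code{kind} field
#'   ("GENE", "AND", "OR"), a \code{gene} field at leaves and a
#'   \code{children} list at internal nodes
#' @examples
#' parseGpr("(b0001 and b0002) or b0003")
#' @export
parseGpr <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    stop("GPR rule must be a single string")
  toks <- regmatches(text, gregexpr("\\(|\\)|[A-Za-z0-9_.-]+", text))[[1L]]
  stray <- gsub("\\(|\\)|[A-Za-z0-9_.-]+|\\s+", "", text)
  if (nzchar(stray))
    stop("unknown token(s) in GPR rule: '", stray, "'")
  if (!length(toks)) stop("empty GPR rule")
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() {
    t <- toks[pos]; pos <<- pos + 1L; t
  }
  isKeyword <- function(t) !is.na(t) && tolower(t) %in% c("and", "or")
  parseFactor <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of GPR rule")
    if (t == "(") {
      advance()
      node <- parseOr()
      if (!identical(peek(), ")")) stop("unbalanced parentheses in GPR rule")
      advance()
      return(node)
    }
    if (t == ")") stop("unbalanced parentheses in GPR rule")
    if (isKeyword(t)) stop("unexpected keyword '", t, "' in GPR rule")
    advance()
    list(kind = "GENE", gene = t)
  }
  parseAnd <- function() {
    kids <- list(parseFactor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      kids <- c(kids, list(parseFactor()))
    }
    if (length(kids) == 1L) kids[[1L]] else list(kind = "AND", children = kids)
  }
  parseOr <- function() {
    kids <- list(parseAnd())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      kids <- c(kids, list(parseAnd()))
    }
    if (length(kids) == 1L) kids[[1L]] else list(kind = "OR", children = kids)
  }
  ast <- parseOr()
  if (pos <= length(toks))
    stop("trailing token(s) in GPR rule: '", toks[pos], "'")
  ast
}

#' Genes referenced by a GPR syntax tree
#' @param ast result of [parseGpr()]
#' @return character vector of distinct gene ids
#' @export
gprGenes <- function(ast) {
  if (identical(ast$kind, "GENE")) return(ast$gene)
  unique(unlist(lapply(ast$children, gprGenes)))
}

#' Evaluate a GPR syntax tree under a gene-availability assignment
#' @param ast result of [parseGpr()]
#' @param available named logical vector, or character vector of available
#'   genes; genes not named are treated as unavailable
#' @return logical
#' @export
evalGpr <- function(ast, available) {
  if (is.character(available)) {
    avail <- function(g) g %in% available
  } else {
    avail <- function(g) isTRUE(available[[g]])
  }
  rec <- function(node) {
    switch(node$kind,
           GENE = avail(node$gene),
           AND = all(vapply(node$children, rec, logical(1))),
           OR = any(vapply(node$children, rec, logical(1))),
           stop("bad GPR node kind"))
  }
  rec(ast)
}

# --- complexes --------------------------------------------------------------

complexKey <- function(subunits) {
  subunits <- subunits[order(names(subunits))]
  paste(names(subunits), unname(subunits), sep = ":", collapse = "|")
}

#' Expand a GPR rule into enzyme complexes (disjunctive normal form)
#'
#' Each conjunction of the DNF becomes one candidate complex; a gene repeated
#' within a conjunction contributes its multiplicity as the default copy
#' number. Duplicate complexes (same subunit multiset) are merged; complexes
#' are returned in deterministic order, sorted by canonical subunit string.
#'
#' @param ast result of [parseGpr()]
#' @return list of complex definitions; each is a list with \code{enzymeId}
#'   and \code{subunits} (named integer vector, gene -> copies)
#' @examples
#' expandComplexes(parseGpr("(g1 and g2) or g3"))
#' @export
expandComplexes <- function(ast) {
  rec <- function(node) {
    switch(node$kind,
           GENE = list(stats::setNames(1L, node$gene)),
           OR = unlist(lapply(node$children, rec), recursive = FALSE),
           AND = Reduce(function(acc, kidTerms) {
             out <- list()
             for (a in acc) for (b in kidTerms) {
               genes <- union(names(a), names(b))
               m <- stats::setNames(integer(length(genes)), genes)
               m[names(a)] <- m[names(a)] + a
               m[names(b)] <- m[names(b)] + b
               out <- c(out, list(m))
             }
             out
           }, lapply(node$children, rec)),
           stop("bad GPR node kind"))
  }
  terms <- rec(ast)
  keys <- vapply(terms, complexKey, character(1))
  terms <- terms[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  ord <- order(keys)
  lapply(ord, function(i)
    list(enzymeId = keys[i], subunits = terms[[i]][order(names(terms[[i]]))]))
}

#' Apply a curated complex-stoichiometry table
#'
#' Curated copy numbers override the default of one copy per subunit. A table
#' entry is matched to a complex by its subunit gene set; entries matching no
#' complex are skipped with a warning.
#'
#' @param complexes list of complex definitions (see [expandComplexes()])
#' @param table data.frame with columns \code{enzyme_id}, \code{gene_id},
#'   \code{copies}
#' @return the complex list with curated copy numbers substituted
#' @export
applyStoichiometryTable <- function(complexes, table) {
  if (is.null(table) || !nrow(table)) return(complexes)
  stopifnot(all(c("enzyme_id", "gene_id", "copies") %in% names(table)))
  bySet <- split(table, table$enzyme_id)
  setKeyOf <- function(genes) paste(sort(unique(genes)), collapse = "|")
  cplxSetKeys <- vapply(complexes, function(cx)
    setKeyOf(names(cx$subunits)), character(1))
  for (enz in names(bySet)) {
    entry <- bySet[[enz]]
    hit <- which(cplxSetKeys == setKeyOf(entry$gene_id))
    if (!length(hit)) {
      warning("stoichiometry table entry '", enz,
              "' matches no complex; skipped")
      next
    }
    for (i in hit) {
      sub <- complexes[[i]]$subunits
      sub[entry$gene_id] <- as.integer(entry$copies)
      complexes[[i]]$subunits <- sub
      complexes[[i]]$enzymeId <- complexKey(sub)
    }
  }
  complexes
}

#' Enzyme complexes of every reaction of a model
#'
#' Expands each non-empty GPR into complexes and returns both the per-reaction
#' lists and the global deduplicated complex census (complex identity = the
#' multiset of (gene, copies)).
#'
#' @param model a [MetabolicModel-class]
#' @param table optional curated stoichiometry table
#'   (see [applyStoichiometryTable()])
#' @return list with \code{perReaction} (named list of complex lists) and
#'   \code{census} (deduplicated complex list across the model)
#' @export
modelComplexes <- function(model, table = NULL) {
  perReaction <- list()
  for (r in model@reactions) {
    if (!nzchar(r@gpr)) next
    cx <- expandComplexes(parseGpr(r@gpr))
    if (!is.null(table)) cx <- applyStoichiometryTable(cx, table)
    perReaction[[r@id]] <- cx
  }
  all <- unlist(perReaction, recursive = FALSE, use.names = FALSE)
  keys <- vapply(all, function(cx) complexKey(cx$subunits), character(1))
  census <- all[!duplicated(keys)]
  census <- census[order(vapply(census, `[[`, character(1), "enzymeId"))]
  list(perReaction = perReaction, census = census)
}

#' Model-level GPR statistics
#'
#' An isozyme reaction is a reaction whose GPR expands to two or more
#' complexes; a multi-complex gene is a gene appearing in two or more distinct
#' complexes across the whole model (complexes deduplicated by subunit
#' multiset). The isozyme fraction uses reactions with a non-empty GPR as
#' denominator; the gene fraction uses all model genes.
#'
#' @param model a [MetabolicModel-class]
#' @param table optional curated stoichiometry table
#' @return list with \code{isozyme_reaction_fraction},
#'   \code{multi_complex_gene_count}, \code{multi_complex_gene_fraction}
#' @export
modelStats <- function(model, table = NULL) {
  cx <- modelComplexes(model, table)
  nGpr <- length(cx$perReaction)
  nIso <- sum(vapply(cx$perReaction, length, integer(1)) >= 2L)
  geneCplxCount <- table(unlist(lapply(cx$census,
                                       function(c) names(c$subunits))))
  multi <- names(geneCplxCount)[geneCplxCount >= 2L]
  list(isozyme_reaction_fraction = if (nGpr) nIso / nGpr else 0,
       multi_complex_gene_count = length(multi),
       multi_complex_gene_fraction =
         if (length(model@genes)) length(multi) / length(model@genes) else 0,
       multi_complex_genes = sort(multi))
}

# --- model serialisation ----------------------------------------------------

#' Read a metabolic model from the canonical JSON dialect
#'
#' The dialect is \code{{"id", "genes": [], "metabolites": [], "reactions":
#' [{"id", "stoich": {}, "lb", "ub", "gpr", "subsystem"}], "objective"}}.
#'
#' @param path JSON file path
#' @return a [MetabolicModel-class]
#' @export
readModelJson <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  reactions <- lapply(j$reactions, function(r) {
    st <- unlist(r$stoich)
    Reaction(id = r$id,
             stoichiometry = if (length(st)) st else numeric(),
             lowerBound = r$lb, upperBound = r$ub,
             gpr = if (is.null(r$gpr)) "" else r$gpr,
             subsystem = if (is.null(r$subsystem)) "" else r$subsystem)
  })
  MetabolicModel(modelId = j$id,
                 genes = as.character(unlist(j$genes)),
                 metabolites = as.character(unlist(j$metabolites)),
                 reactions = reactions,
                 objective = if (is.null(j$objective)) "" else j$objective)
}

#' Write a metabolic model to the canonical JSON dialect
#' @param model a [MetabolicModel-class]
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeModelJson <- function(model, path) {
  j <- list(
    id = model@modelId,
    genes = as.list(model@genes),
    metabolites = as.list(model@metabolites),
    reactions = lapply(model@reactions, function(r) {
      list(id = r@id, stoich = as.list(r@stoichiometry),
           lb = r@lowerBound, ub = r@upperBound,
           gpr = r@gpr, subsystem = r@subsystem)
    }),
    objective = model@objective)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a metabolic model from SBML Level 3 (fbc-style subset)
#'
#' Supports the fbc gene-association subset: species, reactions with
#' stoichiometry and bounds (fbc bound parameters or kineticLaw-free default
#' bounds), and gene associations given either as fbc geneProductAssociation
#' trees or as \code{GENE_ASSOCIATION:} note strings.
#'
#' @param path SBML file path
#' @return a [MetabolicModel-class]
#' @export
readModelSbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  modelNode <- xml2::xml_find_first(doc, ".//model")
  modelId <- xml2::xml_attr(modelNode, "id")
  mets <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//listOfSpecies/species"), "id")
  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  paramVal <- stats::setNames(
    as.numeric(xml2::xml_attr(params, "value")),
    xml2::xml_attr(params, "id"))
  geneProducts <- xml2::xml_find_all(doc, ".//listOfGeneProducts/*")
  gpLabel <- stats::setNames(
    xml2::xml_attr(geneProducts, "label"),
    xml2::xml_attr(geneProducts, "id"))
  rxnNodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  reactions <- lapply(rxnNodes, function(rn) {
    id <- xml2::xml_attr(rn, "id")
    st <- numeric()
    for (sr in xml2::xml_find_all(rn, "./listOfReactants/speciesReference")) {
      sp <- xml2::xml_attr(sr, "species")
      k <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      if (is.na(k)) k <- 1
      st[sp] <- -k
    }
    for (sr in xml2::xml_find_all(rn, "./listOfProducts/speciesReference")) {
      sp <- xml2::xml_attr(sr, "species")
      k <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      if (is.na(k)) k <- 1
      st[sp] <- k
    }
    lbRef <- xml2::xml_attr(rn, "lowerFluxBound")
    ubRef <- xml2::xml_attr(rn, "upperFluxBound")
    lb <- if (!is.na(lbRef) && lbRef %in% names(paramVal))
      paramVal[[lbRef]] else -1000
    ub <- if (!is.na(ubRef) && ubRef %in% names(paramVal))
      paramVal[[ubRef]] else 1000
    gpa <- xml2::xml_find_first(rn, "./geneProductAssociation")
    gpr <- ""
    if (!inherits(gpa, "xml_missing")) {
      gpr <- sbmlAssociationToGpr(xml2::xml_child(gpa), gpLabel)
    } else {
      notes <- xml2::xml_text(xml2::xml_find_first(rn, "./notes"))
      m <- regmatches(notes,
                      regexpr("GENE_ASSOCIATION:[^<\n]*", notes))
      if (length(m)) gpr <- trimws(sub("GENE_ASSOCIATION:", "", m))
    }
    Reaction(id = id, stoichiometry = st, lowerBound = lb, upperBound = ub,
             gpr = gpr)
  })
  genes <- unique(unlist(lapply(reactions, function(r)
    if (nzchar(r@gpr)) gprGenes(parseGpr(r@gpr)) else character())))
  obj <- xml2::xml_attr(
    xml2::xml_find_first(doc, ".//listOfObjectives//fluxObjective"),
    "reaction")
  MetabolicModel(modelId = if (is.na(modelId)) "sbml_model" else modelId,
                 genes = genes, metabolites = mets, reactions = reactions,
                 objective = if (is.na(obj)) "" else obj)
}

sbmlAssociationToGpr <- function(node, gpLabel) {
  name <- xml2::xml_name(node)
  if (name == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    lbl <- gpLabel[ref]
    return(if (is.na(lbl)) ref else unname(lbl))
  }
  kids <- vapply(xml2::xml_children(node), sbmlAssociationToGpr,
                 character(1), gpLabel = gpLabel)
  op <- if (name == "and") " and " else " or "
  paste0("(", paste(kids, collapse = op), ")")
}

#' Read per-gene wild-type sequences from FASTA
#' @param path FASTA file path
#' @return named character vector of amino-acid sequences
#' @export
readFastaSeqs <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
}

#' Write per-gene sequences to FASTA
#' @param seqs named character vector of sequences
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeFastaSeqs <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Read a curated complex stoichiometry TSV
#' @param path TSV with columns enzyme_id, gene_id, copies
#' @return data.frame
#' @export
readStoichTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
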