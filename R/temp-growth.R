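# Flux balance analysis and temperature-constrained growth prediction:
# genes whose melting temperature is below the simulated temperature are
# non-functional, their reactions are disabled via the GPR rules, and the
# remaining network is optimised for growth.

#' Flux balance analysis
#'
#' Maximises the objective reaction flux subject to steady-state mass
#' balance \code{S v = 0} and the flux bounds, optionally overridden.
#'
#' @param model a [MetabolicModel-class] with an objective reaction
#' @param boundsOverride optional named list/vector structure:
#'   \code{list(rxn = c(lb, ub))} replacing bounds of selected reactions
#' @return list: \code{objective} (optimal flux through the objective),
#'   \code{fluxes} (named numeric, one optimal vertex)
#' @export
fba <- function(model, boundsOverride = NULL) {
  rxns <- model@reactions
  ids <- vapply(rxns, function(r) r@id, character(1))
  if (!nzchar(model@objective) || !(model@objective %in% ids))
    stop("model has no valid objective reaction")
  mets <- model@metabolites
  S <- matrix(0, length(mets), length(rxns),
              dimnames = list(mets, ids))
  lb <- numeric(length(rxns)); ub <- numeric(length(rxns))
  for (k in seq_along(rxns)) {
    r <- rxns[[k]]
    S[names(r@stoichiometry), k] <- r@stoichiometry
    lb[k] <- r@lowerBound; ub[k] <- r@upperBound
  }
  if (!is.null(boundsOverride)) {
    for (id in names(boundsOverride)) {
      k <- match(id, ids)
      if (is.na(k)) stop("bounds override for unknown reaction: ", id)
      lb[k] <- boundsOverride[[id]][1L]
      ub[k] <- boundsOverride[[id]][2L]
    }
  }
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("fba requires finite flux bounds")
  obj <- numeric(length(rxns))
  obj[match(model@objective, ids)] <- 1
  res <- tryCatch(
    solveLp(obj, Aeq = S, beq = rep(0, nrow(S)), lb = lb, ub = ub,
            maximize = TRUE),
    error = function(e) stop("FBA failed: ", conditionMessage(e),
                             call. = FALSE))
  list(objective = res$objective,
       fluxes = stats::setNames(res$solution, ids))
}

#' Read a melting-temperature table
#' @param path TSV with columns gene_id, tm_celsius, source
#' @return data.frame
#' @export
readTmTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Temperature-derived bounds overrides
#'
#' A gene is functional iff its melting temperature satisfies
#' \code{T_M >= T} (the boundary T = T_M counts as functional); genes
#' without a value default to functional unless \code{strict}. A reaction
#' is disabled (both bounds zero) iff it carries a GPR that evaluates false
#' under the functional-gene assignment; reactions without a GPR are never
#' disabled.
#'
#' @param model a [MetabolicModel-class]
#' @param tm data.frame with columns gene_id, tm_celsius (NA = missing)
#' @param temperature simulated temperature in Celsius
#' @param strict if TRUE, genes without a melting temperature are treated
#'   as non-functional
#' @return list: \code{bounds} (named list of c(0, 0) overrides),
#'   \code{disabled} (character of disabled reaction ids),
#'   \code{functionalGenes}
#' @export
applyTmConstraints <- function(model, tm, temperature, strict = FALSE) {
  tmOf <- stats::setNames(tm$tm_celsius, tm$gene_id)
  functional <- vapply(model@genes, function(g) {
    v <- tmOf[g]
    if (is.null(v) || is.na(v)) return(!strict)
    v >= temperature
  }, logical(1))
  funGenes <- names(functional)[functional]
  bounds <- list()
  disabled <- character()
  for (r in model@reactions) {
    if (!nzchar(r@gpr)) next
    if (!evalGpr(parseGpr(r@gpr), funGenes)) {
      bounds[[r@id]] <- c(0, 0)
      disabled <- c(disabled, r@id)
    }
  }
  list(bounds = bounds, disabled = disabled, functionalGenes = funGenes)
}

#' Predict growth rate across a temperature grid
#'
#' Runs FBA at every temperature with the melting-temperature constraints
#' applied. Because raising the temperature can only shrink the functional
#' gene set, the curve is monotone non-increasing; this is asserted.
#'
#' @param model a [MetabolicModel-class]
#' @param tm melting-temperature data.frame (gene_id, tm_celsius)
#' @param temperatures strictly increasing temperature grid in Celsius
#' @param strict see [applyTmConstraints()]
#' @return data.frame: temperature, growth, n_disabled, disabled_ids
#'   (";"-separated)
#' @export
growthCurve <- function(model, tm, temperatures, strict = FALSE) {
  if (!length(temperatures)) stop("empty temperature grid")
  if (is.unsorted(temperatures, strictly = TRUE))
    stop("temperature grid must be strictly increasing")
  rows <- lapply(temperatures, function(T) {
    cons <- applyTmConstraints(model, tm, T, strict = strict)
    g <- fba(model, cons$bounds)$objective
    data.frame(temperature = T, growth = g,
               n_disabled = length(cons$disabled),
               disabled_ids = paste(cons$disabled, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(diff(out$growth) > 1e-7))
    stop("growth curve is not monotone non-increasing; ",
         "inconsistent model or melting-temperature table")
  out
}
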