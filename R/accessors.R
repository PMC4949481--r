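#' @rdname MetabolicModel-class
#' @aliases reactionIds metaboliteIds geneIds stoichiometry lowerBounds
#'   upperBounds objectiveReaction carbonExchange geneRules reactionTags
#'   isExchange exchangeReactions nReactions nMetabolites
setMethod("reactionIds", "MetabolicModel", function(x) x@reactions$id)

#' @rdname MetabolicModel-class
setMethod("metaboliteIds", "MetabolicModel", function(x) x@metabolites$id)

#' @rdname MetabolicModel-class
setMethod("geneIds", "MetabolicModel", function(x) {
  rules <- x@reactions$geneRule
  sort(unique(unlist(lapply(rules[nzchar(rules)], function(r)
    ruleGenes(parseGeneRule(r))))))
})

#' @rdname MetabolicModel-class
setMethod("stoichiometry", "MetabolicModel", function(x) x@smat)

#' @rdname MetabolicModel-class
setMethod("lowerBounds", "MetabolicModel", function(x)
  stats::setNames(x@reactions$lowerBound, x@reactions$id))

#' @rdname MetabolicModel-class
setMethod("upperBounds", "MetabolicModel", function(x)
  stats::setNames(x@reactions$upperBound, x@reactions$id))

#' @rdname MetabolicModel-class
setMethod("objectiveReaction", "MetabolicModel", function(x) x@objectiveId)

#' @rdname MetabolicModel-class
setMethod("carbonExchange", "MetabolicModel", function(x) x@carbonExchangeId)

#' @rdname MetabolicModel-class
setMethod("geneRules", "MetabolicModel", function(x)
  stats::setNames(x@reactions$geneRule, x@reactions$id))

#' @rdname MetabolicModel-class
setMethod("reactionTags", "MetabolicModel", function(x)
  stats::setNames(strsplit(x@reactions$tags, ";", fixed = TRUE),
                  x@reactions$id))

#' @rdname MetabolicModel-class
setMethod("isExchange", "MetabolicModel", function(x)
  stats::setNames(x@reactions$isExchange, x@reactions$id))

#' @rdname MetabolicModel-class
setMethod("exchangeReactions", "MetabolicModel", function(x)
  x@reactions$id[x@reactions$isExchange])

#' @rdname MetabolicModel-class
setMethod("nReactions", "MetabolicModel", function(x) nrow(x@reactions))

#' @rdname MetabolicModel-class
setMethod("nMetabolites", "MetabolicModel", function(x) nrow(x@metabolites))

#' @rdname FluxDistribution-class
#' @aliases fluxes provenance objectiveValue
setMethod("fluxes", "FluxDistribution", function(x) x@fluxes)

#' @rdname FluxDistribution-class
setMethod("provenance", "FluxDistribution", function(x) x@provenance)

#' @rdname FluxDistribution-class
setMethod("objectiveValue", "FluxDistribution", function(x) x@objectiveValue)

#' @rdname LPOutcome-class
#' @aliases lpStatus
setMethod("lpStatus", "LPOutcome", function(x) x@status)

#' @rdname LPOutcome-class
setMethod("objectiveValue", "LPOutcome", function(x) x@objective)

#' @rdname LPOutcome-class
setMethod("fluxes", "LPOutcome", function(x) {
  if (is.null(x@flux)) stop("no flux distribution: LP status is ", x@status)
  x@flux@fluxes
})

#' @rdname PathwayDefinition-class
#' @aliases productId productExchange
setMethod("productId", "PathwayDefinition", function(x) x@productId)

#' @rdname PathwayDefinition-class
setMethod("productExchange", "PathwayDefinition", function(x) x@exchangeId)

#' Find reactions carrying a given tag
#'
#' @param model a \linkS4class{MetabolicModel}
#' @param tag tag label, e.g. \code{"respiration"} or \code{"heterologous"}
#' @return character vector of reaction ids
#' @export
taggedReactions <- function(model, tag) {
  hit <- vapply(strsplit(model@reactions$tags, ";", fixed = TRUE),
                function(tt) tag %in% tt, logical(1))
  model@reactions$id[hit]
}

#' Verify a flux distribution against a model
#'
#' Checks the steady-state mass balance \eqn{\|S v\|_\infty \le} \code{tol}
#' and that every flux lies within its reaction's bounds (within \code{tol}).
#'
#' @param model a \linkS4class{MetabolicModel}
#' @param flux a \linkS4class{FluxDistribution} or named numeric vector
#' @param tol absolute tolerance (default 1e-6)
#' @return invisibly \code{TRUE}; stops with a message otherwise
#' @export
checkSteadyState <- function(model, flux, tol = 1e-6) {
  v <- if (methods::is(flux, "FluxDistribution")) flux@fluxes else flux
  miss <- setdiff(reactionIds(model), names(v))
  if (length(miss))
    stop("flux distribution missing reaction(s): ", paste(miss, collapse = ", "))
  v <- v[reactionIds(model)]
  imbalance <- max(abs(as.vector(model@smat %*% v)))
  if (imbalance > tol)
    stop("mass-balance violation: max |S v| = ", format(imbalance))
  lo <- model@reactions$lowerBound - tol
  hi <- model@reactions$upperBound + tol
  bad <- which(v < lo | v > hi)
  if (length(bad))
    stop("flux outside bounds for: ",
         paste(reactionIds(model)[bad], collapse = ", "))
  invisible(TRUE)
}
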