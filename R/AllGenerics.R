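#' @include AllClasses.R
NULL

#' @rdname MetabolicModel-class
#' @param object,x a \linkS4class{MetabolicModel} (or, where documented, a
#'   \linkS4class{FluxDistribution} or \linkS4class{LPOutcome})
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("metaboliteIds", function(x) standardGeneric("metaboliteIds"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("stoichiometry", function(x) standardGeneric("stoichiometry"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("lowerBounds", function(x) standardGeneric("lowerBounds"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("upperBounds", function(x) standardGeneric("upperBounds"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("objectiveReaction", function(x) standardGeneric("objectiveReaction"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("carbonExchange", function(x) standardGeneric("carbonExchange"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("geneRules", function(x) standardGeneric("geneRules"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("reactionTags", function(x) standardGeneric("reactionTags"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("isExchange", function(x) standardGeneric("isExchange"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("exchangeReactions", function(x) standardGeneric("exchangeReactions"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("nReactions", function(x) standardGeneric("nReactions"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("nMetabolites", function(x) standardGeneric("nMetabolites"))

#' @rdname FluxDistribution-class
#' @export
setGeneric("fluxes", function(x) standardGeneric("fluxes"))

#' @rdname FluxDistribution-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname FluxDistribution-class
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))

#' @rdname LPOutcome-class
#' @export
setGeneric("lpStatus", function(x) standardGeneric("lpStatus"))

#' @rdname PathwayDefinition-class
#' @export
setGeneric("productId", function(x) standardGeneric("productId"))

#' @rdname PathwayDefinition-class
#' @export
setGeneric("productExchange", function(x) standardGeneric("productExchange"))
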