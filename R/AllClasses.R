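#' Constraint-based metabolic model
#'
#' In-memory representation of a stoichiometric model: a sparse stoichiometric
#' matrix \eqn{S} (metabolites by reactions), per-reaction flux bounds,
#' gene-reaction rules, an objective (biomass) reaction and a designated
#' carbon-source exchange. Fluxes are in mmol/gDW/h; the biomass reaction flux
#' is the specific growth rate in 1/h (the biomass equation is taken to sum to
#' 1 g per gDW), which is what makes growth yields in g biomass per mol
#' substrate well defined.
#'
#' Exchange reactions are single-metabolite boundary reactions written as
#' \code{A <->} with coefficient -1 on \code{A}; uptake is a negative flux,
#' secretion a positive flux. Loaders and generators enforce this convention.
#'
#' @slot smat sparse stoichiometric matrix, metabolites x reactions
#' @slot metabolites data.frame with columns id, name, compartment, formula
#' @slot reactions data.frame with columns id, name, lowerBound, upperBound,
#'   geneRule, isExchange, tags (semicolon-separated labels such as
#'   \code{heterologous}, \code{biomass}, \code{maintenance},
#'   \code{respiration}, \code{g6p_isomerase}, \code{product_exchange})
#' @slot objectiveId id of the objective (biomass) reaction
#' @slot carbonExchangeId id of the carbon-source exchange (may be \code{NA})
#' @slot compartments named character vector, compartment id -> label
#'
#' @seealso [makeModel()], [readModel()], [applyKnockouts()], [fba()]
#' @export
setClass("MetabolicModel",
  representation(
    smat = "Matrix",
    metabolites = "data.frame",
    reactions = "data.frame",
    objectiveId = "character",
    carbonExchangeId = "character",
    compartments = "character"
  )
)

setValidity("MetabolicModel", function(object) {
  msg <- character()
  met <- object@metabolites
  rxn <- object@reactions
  S <- object@smat
  if (any(!nzchar(met$id)) || anyDuplicated(met$id))
    msg <- c(msg, "metabolite ids must be non-empty and unique")
  if (any(!nzchar(rxn$id)) || anyDuplicated(rxn$id))
    msg <- c(msg, "reaction ids must be non-empty and unique")
  if (!identical(dim(S), c(nrow(met), nrow(rxn))))
    msg <- c(msg, "stoichiometric matrix dimensions do not match metabolite/reaction tables")
  if (!identical(rownames(S), met$id) || !identical(colnames(S), rxn$id))
    msg <- c(msg, "stoichiometric matrix dimnames must equal metabolite/reaction ids")
  if (length(msg)) return(msg)
  if (any(!is.finite(S@x)))
    msg <- c(msg, "stoichiometric coefficients must be finite")
  bad <- rxn$id[rxn$lowerBound > rxn$upperBound]
  if (length(bad))
    msg <- c(msg, paste0("lowerBound > upperBound for reaction(s): ",
                         paste(bad, collapse = ", ")))
  ntouch <- Matrix::colSums(S != 0)
  if (any(ntouch == 0))
    msg <- c(msg, paste0("empty stoichiometry for reaction(s): ",
                         paste(rxn$id[ntouch == 0], collapse = ", ")))
  if (any(rxn$isExchange & ntouch != 1))
    msg <- c(msg, paste0("exchange reactions must touch exactly one metabolite: ",
                         paste(rxn$id[rxn$isExchange & ntouch != 1], collapse = ", ")))
  if (!(object@objectiveId %in% rxn$id))
    msg <- c(msg, paste0("objective reaction '", object@objectiveId,
                         "' not in the model"))
  if (!is.na(object@carbonExchangeId) &&
      !(object@carbonExchangeId %in% rxn$id))
    msg <- c(msg, paste0("carbon exchange '", object@carbonExchangeId,
                         "' not in the model"))
  if (length(object@compartments) &&
      !all(met$compartment %in% names(object@compartments)))
    msg <- c(msg, "metabolite compartments must be drawn from the declared compartment set")
  bad <- vapply(rxn$geneRule, function(r) inherits(try(parseGeneRule(r), silent = TRUE), "try-error"),
                logical(1))
  if (any(bad))
    msg <- c(msg, paste0("malformed gene rule for reaction(s): ",
                         paste(rxn$id[bad], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Flux distribution
#'
#' A steady-state flux vector keyed by reaction id, together with the method
#' that produced it and the objective value achieved. See
#' [checkSteadyState()] for verifying mass balance and bounds against a model.
#'
#' @slot fluxes named numeric vector, reaction id -> flux
#' @slot provenance one of \code{"FBA"}, \code{"pFBA"}, \code{"MiMBl"},
#'   \code{"manual"} (free text allowed)
#' @slot objectiveValue objective value of the producing optimization
#' @export
setClass("FluxDistribution",
  representation(fluxes = "numeric", provenance = "character",
                 objectiveValue = "numeric")
)

setValidity("FluxDistribution", function(object) {
  if (is.null(names(object@fluxes)) || anyDuplicated(names(object@fluxes)))
    return("fluxes must be uniquely named by reaction id")
  if (any(!is.finite(object@fluxes)))
    return("fluxes must be finite")
  TRUE
})

setClassUnion("FluxDistributionOrNULL", c("FluxDistribution", "NULL"))

#' Outcome of a linear-programming solve
#'
#' @slot status \code{"optimal"}, \code{"infeasible"}, \code{"unbounded"} or
#'   \code{"maxiter"}; infeasibility and unboundedness are reported as a
#'   status, not as an error
#' @slot objective objective value (\code{NA} unless optimal)
#' @slot flux the optimal \linkS4class{FluxDistribution}, or \code{NULL}
#' @export
setClass("LPOutcome",
  representation(status = "character", objective = "numeric",
                 flux = "FluxDistributionOrNULL")
)

setValidity("LPOutcome", function(object) {
  if (!object@status %in% c("optimal", "infeasible", "unbounded", "maxiter"))
    return("unknown LP status")
  TRUE
})

#' Heterologous pathway definition
#'
#' The reactions to graft onto a host model to make it secrete one product:
#' an ordered list of heterologous reactions plus exactly one product exchange.
#' For an endogenous product the reaction list may consist of the exchange
#' (and, if needed, a transport) alone.
#'
#' @slot productId short product identifier (used as metabolite id stem)
#' @slot productName descriptive name
#' @slot reactions list of reaction entries, each a list with elements
#'   \code{id}, \code{stoich} (named numeric), \code{lb}, \code{ub},
#'   \code{geneRule}, \code{tags}
#' @slot exchangeId id of the product exchange reaction
#' @slot notes free-text molecular identity notes
#' @export
setClass("PathwayDefinition",
  representation(productId = "character", productName = "character",
                 reactions = "list", exchangeId = "character",
                 notes = "character")
)

setValidity("PathwayDefinition", function(object) {
  if (!length(object@reactions)) return("pathway must contain at least one reaction")
  ids <- vapply(object@reactions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) return("duplicate reaction ids in pathway")
  if (sum(ids == object@exchangeId) != 1)
    return("pathway must contain exactly one product exchange reaction")
  ex <- object@reactions[[which(ids == object@exchangeId)]]
  if (length(ex$stoich) != 1)
    return("product exchange must touch exactly one metabolite")
  internal <- object@reactions[ids != object@exchangeId]
  if (length(internal)) {
    # some internal reaction must produce a form of the product (id stem match)
    produced <- any(vapply(internal, function(r) {
      prod <- names(r$stoich)[r$stoich > 0]
      any(startsWith(prod, object@productId))
    }, logical(1)))
    if (!produced)
      return("product metabolite is not produced by any pathway reaction")
  }
  TRUE
})

#' Growth medium definition
#'
#' Exchange-reaction bounds for a defined medium. Uptake and secretion limits
#' are magnitudes (non-negative, mmol/gDW/h); applying a medium sets the
#' exchange lower bound to \code{-maxUptake} and the upper bound to
#' \code{maxSecretion}, and closes uptake through every exchange not listed.
#'
#' @slot exchanges data.frame with columns exchange, maxUptake, maxSecretion
#' @slot carbonSource id of the carbon-source exchange
#' @export
setClass("MediumDefinition",
  representation(exchanges = "data.frame", carbonSource = "character")
)

setValidity("MediumDefinition", function(object) {
  ex <- object@exchanges
  if (!all(c("exchange", "maxUptake", "maxSecretion") %in% names(ex)))
    return("exchanges must have columns exchange, maxUptake, maxSecretion")
  if (any(ex$maxUptake < 0) || any(ex$maxSecretion < 0))
    return("uptake/secretion limits are magnitudes and must be non-negative")
  if (!object@carbonSource %in% ex$exchange)
    return("carbon source must be among the medium exchanges")
  TRUE
})

`%||%` <- function(a, b) if (is.null(a) || !length(a) || is.na(a[1])) b else a

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel:", nrow(object@metabolites), "metabolites x",
      nrow(object@reactions), "reactions\n")
  cat("  compartments:", paste(names(object@compartments), collapse = ", "), "\n")
  cat("  objective:", object@objectiveId,
      "| carbon exchange:", object@carbonExchangeId, "\n")
  nex <- sum(object@reactions$isExchange)
  ngpr <- sum(nzchar(object@reactions$geneRule))
  cat("  ", nex, " exchange reactions, ", ngpr,
      " reactions with gene rules\n", sep = "")
})

setMethod("show", "FluxDistribution", function(object) {
  nz <- sum(abs(object@fluxes) > 1e-9)
  cat("FluxDistribution (", object@provenance, "): ", length(object@fluxes),
      " reactions, ", nz, " carrying flux; objective = ",
      format(object@objectiveValue, digits = 6), "\n", sep = "")
})

setMethod("show", "LPOutcome", function(object) {
  cat("LPOutcome: status =", object@status)
  if (identical(object@status, "optimal"))
    cat(", objective =", format(object@objective, digits = 9))
  cat("\n")
})

setMethod("show", "PathwayDefinition", function(object) {
  cat("PathwayDefinition '", object@productId, "' (", object@productName,
      "): ", length(object@reactions), " reactions, exchange ",
      object@exchangeId, "\n", sep = "")
})

setMethod("show", "MediumDefinition", function(object) {
  cat("MediumDefinition:", nrow(object@exchanges), "exchanges, carbon source",
      object@carbonSource, "\n")
})
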