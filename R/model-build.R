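#' Build a metabolic model from reaction entries
#'
#' Low-level constructor used by the format readers and the synthetic model
#' generators. Each reaction entry is a list with elements \code{id},
#' \code{stoich} (named numeric vector of signed coefficients, negative =
#' consumed), and optionally \code{name}, \code{lb}, \code{ub},
#' \code{geneRule}, \code{tags} and \code{isExchange}. Metabolites are
#' inferred from the stoichiometries; compartments are taken from the trailing
#' \code{_<comp>} suffix of each metabolite id unless a metabolite table is
#' supplied.
#'
#' @param reactions list of reaction entries (see Details)
#' @param objective id of the objective (biomass) reaction
#' @param carbonExchange id of the carbon-source exchange, or \code{NA}
#' @param metabolites optional data.frame with columns id, name, compartment,
#'   formula overriding the inferred metabolite table
#' @param compartments named character vector of compartment labels; defaults
#'   to labels for the compartment ids seen in the metabolites
#' @return a validated \linkS4class{MetabolicModel}
#' @examples
#' m <- makeChainModel(2)
#' nReactions(m)
#' @export
makeModel <- function(reactions, objective, carbonExchange = NA_character_,
                      metabolites = NULL, compartments = NULL) {
  stopifnot(is.list(reactions), length(reactions) >= 1)
  entries <- lapply(reactions, function(r) {
    stopifnot(!is.null(r$id), !is.null(r$stoich))
    list(
      id = as.character(r$id),
      name = as.character(r$name %||% r$id),
      stoich = r$stoich,
      lb = as.numeric(r$lb %||% 0),
      ub = as.numeric(r$ub %||% 1000),
      geneRule = as.character(r$geneRule %||% ""),
      tags = paste(r$tags %||% character(), collapse = ";"),
      isExchange = isTRUE(r$isExchange)
    )
  })
  rids <- vapply(entries, `[[`, character(1), "id")
  if (anyDuplicated(rids))
    stop("duplicate reaction ids: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))

  metIds <- unique(unlist(lapply(entries, function(e) names(e$stoich))))
  if (is.null(metabolites)) {
    comp <- sub("^.*_([A-Za-z0-9]+)$", "\\1", metIds)
    comp[comp == metIds] <- "c"
    metabolites <- data.frame(id = metIds, name = metIds,
                              compartment = comp, formula = NA_character_,
                              stringsAsFactors = FALSE)
  } else {
    missing <- setdiff(metIds, metabolites$id)
    if (length(missing))
      stop("metabolites referenced but not declared: ",
           paste(missing, collapse = ", "))
    metabolites <- metabolites[, c("id", "name", "compartment", "formula")]
  }
  metabolites <- metabolites[order(match(metabolites$id, metIds)), , drop = FALSE]
  rownames(metabolites) <- NULL

  if (is.null(compartments)) {
    cmp <- sort(unique(metabolites$compartment))
    labels <- c(c = "cytosol", e = "extracellular", m = "mitochondrion")
    compartments <- stats::setNames(
      ifelse(cmp %in% names(labels), labels[cmp], cmp), cmp)
  }

  trip <- do.call(rbind, lapply(seq_along(entries), function(j) {
    s <- entries[[j]]$stoich
    cbind(match(names(s), metabolites$id), j, as.numeric(s))
  }))
  smat <- Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = trip[, 3],
                               dims = c(nrow(metabolites), length(entries)),
                               dimnames = list(metabolites$id, rids))

  rxn <- data.frame(
    id = rids,
    name = vapply(entries, `[[`, character(1), "name"),
    lowerBound = vapply(entries, `[[`, numeric(1), "lb"),
    upperBound = vapply(entries, `[[`, numeric(1), "ub"),
    geneRule = vapply(entries, `[[`, character(1), "geneRule"),
    isExchange = vapply(entries, `[[`, logical(1), "isExchange"),
    tags = vapply(entries, `[[`, character(1), "tags"),
    stringsAsFactors = FALSE
  )
  rownames(rxn) <- NULL

  methods::new("MetabolicModel", smat = smat, metabolites = metabolites,
               reactions = rxn, objectiveId = as.character(objective),
               carbonExchangeId = as.character(carbonExchange),
               compartments = compartments)
}

# shorthand used by generators and parsers
.rxn <- function(id, stoich, lb = 0, ub = 1000, gene = "", tags = NULL,
                 exchange = FALSE, name = id) {
  list(id = id, name = name, stoich = stoich, lb = lb, ub = ub,
       geneRule = gene, tags = tags, isExchange = exchange)
}

# exchange shorthand: metabolite <-> nothing, coefficient -1
.exch <- function(id, met, lb = 0, ub = 1000, tags = NULL) {
  .rxn(id, stats::setNames(-1, met), lb = lb, ub = ub, tags = tags,
       exchange = TRUE)
}

# rebuild the per-reaction stoichiometry list from the sparse matrix
.reactionStoich <- function(model, id) {
  col <- model@smat[, id]
  col[col != 0]
}

# internal bound update without re-running full validity on hot paths
.setBoundsFast <- function(model, ids, lb = NULL, ub = NULL) {
  i <- match(ids, model@reactions$id)
  if (anyNA(i)) stop("unknown reaction id(s): ",
                     paste(ids[is.na(i)], collapse = ", "))
  if (!is.null(lb)) model@reactions$lowerBound[i] <- lb
  if (!is.null(ub)) model@reactions$upperBound[i] <- ub
  model
}

#' Set flux bounds on reactions
#'
#' @param model a \linkS4class{MetabolicModel}
#' @param ids reaction ids
#' @param lb,ub new bounds (recycled); \code{NULL} leaves the bound unchanged
#' @return the modified model
#' @export
setBounds <- function(model, ids, lb = NULL, ub = NULL) {
  model <- .setBoundsFast(model, ids, lb, ub)
  methods::validObject(model)
  model
}
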