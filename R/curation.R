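#' Curation actions
#'
#' A curation action is a declarative model edit. Supported kinds:
#' \describe{
#'   \item{merge_duplicates}{merge reactions with exactly identical
#'     stoichiometry into one, uniting their gene rules with \code{or} (the
#'     duplicates are isoenzyme copies); no parameters, detection is exact
#'     stoichiometry match among non-exchange reactions.}
#'   \item{block_secretion}{set the secretion (upper) bound of the named
#'     exchange to 0, leaving uptake untouched; parameter \code{exchange}.}
#'   \item{unconstrain_transport}{open the named transport reaction in both
#'     directions with infinite bounds; parameter \code{reaction}.}
#'   \item{replace_reaction}{replace the stoichiometry (and optionally
#'     bounds/gene rule) of a reaction; parameters \code{reaction},
#'     \code{stoich} (named numeric), optional \code{lb}, \code{ub},
#'     \code{geneRule}.}
#'   \item{remove_reaction}{delete a reaction; parameter \code{reaction}.}
#'   \item{set_bounds}{set bounds; parameters \code{reaction}, \code{lb},
#'     \code{ub}.}
#' }
#' Actions serialize to/from YAML (see [readCurationConfig()]).
#'
#' @param kind action kind, see Details
#' @param ... parameters for the kind
#' @return a curation action (a classed list)
#' @export
curationAction <- function(kind = c("merge_duplicates", "block_secretion",
                                    "unconstrain_transport",
                                    "replace_reaction", "remove_reaction",
                                    "set_bounds"), ...) {
  kind <- match.arg(kind)
  act <- c(list(kind = kind), list(...))
  required <- switch(kind,
    merge_duplicates = character(),
    block_secretion = "exchange",
    unconstrain_transport = "reaction",
    replace_reaction = c("reaction", "stoich"),
    remove_reaction = "reaction",
    set_bounds = c("reaction", "lb", "ub"))
  miss <- setdiff(required, names(act))
  if (length(miss))
    stop("curation action '", kind, "' missing parameter(s): ",
         paste(miss, collapse = ", "))
  structure(act, class = "curationAction")
}

#' Apply curation actions to a model
#'
#' Actions are applied in order; each change is recorded in the returned log.
#' An action referencing a missing reaction fails with the action index and
#' the offending id.
#'
#' @param model a \linkS4class{MetabolicModel}
#' @param actions list of [curationAction()] objects
#' @return list with elements \code{model} and \code{log} (character vector,
#'   one entry per change)
#' @export
applyCuration <- function(model, actions) {
  log <- character()
  for (k in seq_along(actions)) {
    act <- actions[[k]]
    need <- intersect(names(act), c("exchange", "reaction"))
    for (nm in need) {
      if (!act[[nm]] %in% model@reactions$id)
        stop("curation action ", k, " (", act$kind,
             ") references missing reaction '", act[[nm]], "'")
    }
    res <- switch(act$kind,
      merge_duplicates = .curMergeDuplicates(model),
      block_secretion = .curBlockSecretion(model, act$exchange),
      unconstrain_transport = .curUnconstrain(model, act$reaction),
      replace_reaction = .curReplace(model, act),
      remove_reaction = .curRemove(model, act$reaction),
      set_bounds = list(model = setBounds(model, act$reaction,
                                          lb = act$lb, ub = act$ub),
                        log = sprintf("set_bounds: %s -> [%g, %g]",
                                      act$reaction, act$lb, act$ub)),
      stop("unknown curation action kind: ", act$kind))
    model <- res$model
    log <- c(log, res$log)
  }
  list(model = model, log = log)
}

.curMergeDuplicates <- function(model) {
  S <- model@smat
  rxn <- model@reactions
  keyable <- which(!rxn$isExchange)
  keys <- vapply(keyable, function(j) {
    col <- S[, j]
    nz <- which(col != 0)
    paste(rownames(S)[nz], col[nz], sep = ":", collapse = "|")
  }, character(1))
  log <- character()
  drop <- integer()
  for (grp in split(keyable, keys)) {
    if (length(grp) < 2) next
    keep <- grp[1]
    rules <- rxn$geneRule[grp]
    rules <- rules[nzchar(rules)]
    if (length(rules))
      rxn$geneRule[keep] <- paste0("(", paste(unique(rules),
                                              collapse = ") or ("), ")")
    rxn$lowerBound[keep] <- min(rxn$lowerBound[grp])
    rxn$upperBound[keep] <- max(rxn$upperBound[grp])
    drop <- c(drop, grp[-1])
    log <- c(log, sprintf("merge_duplicates: %s absorbed into %s; rule '%s'",
                          paste(rxn$id[grp[-1]], collapse = "+"),
                          rxn$id[keep], rxn$geneRule[keep]))
  }
  if (length(drop)) {
    model@reactions <- rxn[-drop, , drop = FALSE]
    rownames(model@reactions) <- NULL
    model@smat <- S[, -drop, drop = FALSE]
  } else {
    model@reactions <- rxn
  }
  methods::validObject(model)
  list(model = model, log = log)
}

.curBlockSecretion <- function(model, exchange) {
  i <- match(exchange, model@reactions$id)
  if (!model@reactions$isExchange[i])
    stop("block_secretion target '", exchange, "' is not an exchange reaction")
  old <- model@reactions$upperBound[i]
  model@reactions$upperBound[i] <- 0
  if (model@reactions$lowerBound[i] > 0) model@reactions$lowerBound[i] <- 0
  list(model = model,
       log = sprintf("block_secretion: %s upper bound %g -> 0", exchange, old))
}

.curUnconstrain <- function(model, reaction) {
  model <- .setBoundsFast(model, reaction, lb = -Inf, ub = Inf)
  list(model = model,
       log = sprintf("unconstrain_transport: %s bounds set to (-Inf, Inf)",
                     reaction))
}

.curReplace <- function(model, act) {
  j <- match(act$reaction, model@reactions$id)
  stoich <- unlist(act$stoich)
  miss <- setdiff(names(stoich), model@metabolites$id)
  if (length(miss))
    stop("replace_reaction: unknown metabolite(s) ",
         paste(miss, collapse = ", "))
  col <- numeric(nrow(model@smat))
  col[match(names(stoich), model@metabolites$id)] <- stoich
  model@smat[, j] <- col
  if (!is.null(act$lb)) model@reactions$lowerBound[j] <- act$lb
  if (!is.null(act$ub)) model@reactions$upperBound[j] <- act$ub
  if (!is.null(act$geneRule)) model@reactions$geneRule[j] <- act$geneRule
  methods::validObject(model)
  list(model = model,
       log = sprintf("replace_reaction: %s stoichiometry replaced",
                     act$reaction))
}

.curRemove <- function(model, reaction) {
  j <- match(reaction, model@reactions$id)
  model@smat <- model@smat[, -j, drop = FALSE]
  model@reactions <- model@reactions[-j, , drop = FALSE]
  rownames(model@reactions) <- NULL
  methods::validObject(model)
  list(model = model, log = sprintf("remove_reaction: %s", reaction))
}

#' Apply a medium definition to a model
#'
#' Sets exchange bounds from the medium: each listed exchange gets lower
#' bound \code{-maxUptake} and upper bound \code{maxSecretion}; uptake
#' through every exchange not listed is closed (lower bound 0) while its
#' secretion bound is left untouched. Non-exchange reactions are never
#' modified.
#'
#' @param model a \linkS4class{MetabolicModel}
#' @param medium a \linkS4class{MediumDefinition}
#' @return the model with medium bounds applied; the carbon exchange of the
#'   medium becomes the model's carbon exchange
#' @export
applyMedium <- function(model, medium) {
  ex <- medium@exchanges
  unknown <- setdiff(ex$exchange, model@reactions$id)
  if (length(unknown))
    stop("medium references missing exchange(s): ",
         paste(unknown, collapse = ", "))
  isex <- model@reactions$isExchange
  listed <- model@reactions$id %in% ex$exchange
  # close uptake on unlisted exchanges
  i <- which(isex & !listed & model@reactions$lowerBound < 0)
  if (length(i)) model@reactions$lowerBound[i] <- 0
  k <- match(ex$exchange, model@reactions$id)
  model@reactions$lowerBound[k] <- -ex$maxUptake
  model@reactions$upperBound[k] <- ex$maxSecretion
  model@carbonExchangeId <- medium@carbonSource
  methods::validObject(model)
  model
}

#' Remove blocked reactions under a medium
#'
#' Applies the medium, runs a feasibility-anchored flux variability pass (no
#' objective constraint) over all reactions, and removes every reaction that
#' cannot carry flux in either direction (|min| and |max| below \code{tol}).
#' Orphaned metabolites are dropped with their reactions. Reactions that can
#' carry flux are never removed, so no FBA optimum computable in the original
#' model changes.
#'
#' @param model a \linkS4class{MetabolicModel}
#' @param medium a \linkS4class{MediumDefinition}
#' @param tol blocked-flux tolerance (default 1e-9)
#' @return list with elements \code{model} and \code{removed} (ids)
#' @export
removeBlockedReactions <- function(model, medium, tol = 1e-9) {
  model <- applyMedium(model, medium)
  probe <- fba(model)
  if (probe@status != "optimal")
    stop("model infeasible under the medium: status ", probe@status)
  rng <- fva(model, anchor = NULL)
  blocked <- rng$id[abs(rng$min) < tol & abs(rng$max) < tol]
  if (length(blocked)) {
    j <- match(blocked, model@reactions$id)
    model@smat <- model@smat[, -j, drop = FALSE]
    model@reactions <- model@reactions[-j, , drop = FALSE]
    rownames(model@reactions) <- NULL
    orphan <- which(Matrix::rowSums(model@smat != 0) == 0)
    if (length(orphan)) {
      model@smat <- model@smat[-orphan, , drop = FALSE]
      model@metabolites <- model@metabolites[-orphan, , drop = FALSE]
      rownames(model@metabolites) <- NULL
    }
    methods::validObject(model)
  }
  list(model = model, removed = blocked)
}

#' Graft a heterologous pathway onto a host model
#'
#' The producer model is the host plus the pathway reactions and product
#' exchange — nothing else: no additional energetic or precursor requirements
#' are imposed for expressing the heterologous enzymes or secreting the
#' product. Pathway reactions are tagged \code{heterologous}; the product
#' exchange is tagged \code{product_exchange}. Metabolites not present in the
#' host must be produced by the pathway itself (consuming a metabolite absent
#' from the host is an error).
#'
#' @param host a \linkS4class{MetabolicModel}
#' @param pathway a \linkS4class{PathwayDefinition}
#' @return the producer \linkS4class{MetabolicModel}
#' @export
buildProducerModel <- function(host, pathway) {
  ids <- vapply(pathway@reactions, `[[`, character(1), "id")
  clash <- intersect(ids, host@reactions$id)
  if (length(clash))
    stop("pathway reaction id(s) collide with host: ",
         paste(clash, collapse = ", "))
  newMets <- setdiff(unique(unlist(lapply(pathway@reactions,
                                          function(r) names(r$stoich)))),
                     host@metabolites$id)
  producedSomewhere <- unique(unlist(lapply(pathway@reactions, function(r) {
    names(r$stoich)[r$stoich > 0 | r$lb < 0]
  })))
  orphanCons <- setdiff(newMets, c(producedSomewhere,
                                   unlist(lapply(pathway@reactions,
                                                 function(r)
                                                   if (isTRUE(r$isExchange))
                                                     names(r$stoich)))))
  if (length(orphanCons))
    stop("pathway consumes metabolite(s) absent from the host: ",
         paste(orphanCons, collapse = ", "))

  entries <- c(
    lapply(seq_len(nrow(host@reactions)), function(j) {
      r <- host@reactions[j, ]
      list(id = r$id, name = r$name, stoich = .reactionStoich(host, r$id),
           lb = r$lowerBound, ub = r$upperBound, geneRule = r$geneRule,
           tags = strsplit(r$tags, ";", fixed = TRUE)[[1]],
           isExchange = r$isExchange)
    }),
    lapply(pathway@reactions, function(r) {
      tags <- unique(c(r$tags, "heterologous",
                       if (identical(r$id, pathway@exchangeId))
                         "product_exchange"))
      list(id = r$id, name = r$name %||% r$id, stoich = r$stoich,
           lb = r$lb %||% 0, ub = r$ub %||% 1000,
           geneRule = r$geneRule %||% "", tags = tags,
           isExchange = isTRUE(r$isExchange) ||
             identical(r$id, pathway@exchangeId))
    })
  )
  mets <- rbind(host@metabolites,
                data.frame(id = newMets, name = newMets,
                           compartment = sub("^.*_([A-Za-z0-9]+)$", "\\1",
                                             newMets),
                           formula = NA_character_,
                           stringsAsFactors = FALSE))
  cmp <- sort(unique(mets$compartment))
  labels <- c(c = "cytosol", e = "extracellular", m = "mitochondrion")
  compartments <- stats::setNames(
    ifelse(cmp %in% names(labels), labels[cmp], cmp), cmp)
  makeModel(entries, objective = host@objectiveId,
            carbonExchange = host@carbonExchangeId, metabolites = mets,
            compartments = compartments)
}
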