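#' Read and write models
#'
#' Models are exchanged in two formats: COBRA-style JSON (metabolites,
#' reactions with named stoichiometries, bounds, gene rules and an objective
#' coefficient) and an SBML Level 3 subset with flux-bound and objective
#' annotations (see [readSBMLModel()]). Reading validates the model
#' invariants: a missing objective or an unresolvable metabolite reference is
#' an error, and reversed bounds are reported with the offending reaction id.
#' Writing then reading reproduces the model exactly.
#'
#' @param path file path
#' @param format \code{"json"} or \code{"sbml"}; default guessed from the
#'   file extension
#' @return \code{readModel}: a validated \linkS4class{MetabolicModel}
#' @export
readModel <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  switch(format, json = readJSONModel(path), sbml = readSBMLModel(path))
}

#' @rdname readModel
#' @param model a \linkS4class{MetabolicModel}
#' @export
writeModel <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  switch(format, json = writeJSONModel(model, path),
         sbml = writeSBMLModel(model, path))
}

#' @rdname readModel
#' @export
readJSONModel <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stop("not a COBRA-style model JSON: ", path)
  metIds <- vapply(doc$metabolites, function(m) m$id, character(1))
  mets <- data.frame(
    id = metIds,
    name = vapply(doc$metabolites, function(m)
      as.character(m$name %||% m$id), character(1)),
    compartment = vapply(doc$metabolites, function(m)
      as.character(m$compartment %||% "c"), character(1)),
    formula = vapply(doc$metabolites, function(m)
      as.character(m$formula %||% NA_character_), character(1)),
    stringsAsFactors = FALSE)

  objId <- NULL
  entries <- lapply(doc$reactions, function(r) {
    st <- unlist(r$metabolites)
    bad <- setdiff(names(st), metIds)
    if (length(bad))
      stop("reaction '", r$id, "' references unknown metabolite(s): ",
           paste(bad, collapse = ", "))
    if ((r$lower_bound %||% 0) > (r$upper_bound %||% 1000))
      stop("reaction '", r$id, "' has lower bound above upper bound")
    oc <- as.numeric(r$objective_coefficient %||% 0)
    if (!is.na(oc) && oc != 0) objId <<- r$id
    tags <- as.character(unlist(r$notes$tags %||% list()))
    comp1 <- mets$compartment[match(names(st), mets$id)]
    isex <- if (!is.null(r$notes$exchange)) isTRUE(r$notes$exchange) else
      (length(st) == 1 && identical(comp1, "e"))
    list(id = r$id, name = r$name %||% r$id, stoich = st,
         lb = as.numeric(r$lower_bound %||% 0),
         ub = as.numeric(r$upper_bound %||% 1000),
         geneRule = as.character(r$gene_reaction_rule %||% ""),
         tags = tags, isExchange = isex)
  })
  if (is.null(objId))
    stop("model '", path, "' declares no objective reaction ",
         "(no nonzero objective_coefficient)")
  compartments <- unlist(doc$compartments %||% list())
  if (is.null(compartments) || !length(compartments)) compartments <- NULL
  carbon <- as.character(doc$notes$carbon_exchange %||% NA_character_)
  # metabolites may include entries untouched by reactions; keep them all
  touched <- unique(unlist(lapply(entries, function(e) names(e$stoich))))
  mets <- mets[mets$id %in% touched, , drop = FALSE]
  makeModel(entries, objective = objId, carbonExchange = carbon,
            metabolites = mets,
            compartments = if (!is.null(compartments))
              stats::setNames(as.character(compartments),
                              names(compartments)) else NULL)
}

#' @rdname readModel
#' @export
writeJSONModel <- function(model, path) {
  mets <- lapply(seq_len(nMetabolites(model)), function(i) {
    m <- model@metabolites[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment)
    if (!is.na(m$formula)) out$formula <- m$formula
    out
  })
  rxns <- lapply(seq_len(nReactions(model)), function(j) {
    r <- model@reactions[j, ]
    st <- .reactionStoich(model, r$id)
    tags <- strsplit(r$tags, ";", fixed = TRUE)[[1]]
    list(id = r$id, name = r$name,
         metabolites = as.list(st),
         lower_bound = r$lowerBound, upper_bound = r$upperBound,
         gene_reaction_rule = r$geneRule,
         objective_coefficient = if (r$id == model@objectiveId) 1 else 0,
         notes = list(tags = as.list(tags), exchange = r$isExchange))
  })
  genes <- lapply(geneIds(model), function(g) list(id = g, name = g))
  doc <- list(id = "model", version = "1",
              compartments = as.list(model@compartments),
              metabolites = mets, reactions = rxns, genes = genes,
              notes = list(carbon_exchange = model@carbonExchangeId))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}
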