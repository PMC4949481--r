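# SBML Level 3 (core + flux-balance-constraints v2) subset: species,
# compartments, reactions with bound parameters, gene-product associations,
# and the active maximization objective. Reaction tags and the carbon-source
# exchange travel in a small custom annotation namespace so the two formats
# round-trip the same information. Ids gain the conventional M_/R_/G_
# prefixes on write and lose them on read.

.SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
.ANN_NS <- "https://chassisdesign.r/annotations"

#' @rdname readModel
#' @export
writeSBMLModel <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) sprintf("%.12g", x)
  L <- character()
  push <- function(...) L <<- c(L, paste0(...))
  push('<?xml version="1.0" encoding="UTF-8"?>')
  push('<sbml xmlns="', .SBML_NS, '" xmlns:fbc="', .FBC_NS,
       '" xmlns:cd="', .ANN_NS, '" level="3" version="1" ',
       'fbc:required="false">')
  push('  <model id="model" fbc:strict="true">')
  if (!is.na(model@carbonExchangeId))
    push('    <annotation><cd:carbonExchange cd:id="R_',
         esc(model@carbonExchangeId), '"/></annotation>')
  push('    <listOfCompartments>')
  for (i in seq_along(model@compartments))
    push('      <compartment id="', esc(names(model@compartments)[i]),
         '" name="', esc(model@compartments[i]),
         '" constant="true"/>')
  push('    </listOfCompartments>')
  push('    <listOfSpecies>')
  for (i in seq_len(nMetabolites(model))) {
    m <- model@metabolites[i, ]
    push('      <species id="M_', esc(m$id), '" name="', esc(m$name),
         '" compartment="', esc(m$compartment),
         '" hasOnlySubstanceUnits="false" boundaryCondition="false" ',
         'constant="false"',
         if (!is.na(m$formula))
           paste0(' fbc:chemicalFormula="', esc(m$formula), '"') else "",
         '/>')
  }
  push('    </listOfSpecies>')
  # one shared parameter per distinct bound value
  bvals <- sort(unique(c(model@reactions$lowerBound,
                         model@reactions$upperBound)))
  bid <- function(v) paste0("bnd_", match(v, bvals))
  push('    <listOfParameters>')
  for (v in bvals)
    push('      <parameter id="', bid(v), '" value="', num(v),
         '" constant="true"/>')
  push('    </listOfParameters>')
  push('    <listOfReactions>')
  gprXML <- function(ast, indent) {
    pad <- strrep(" ", indent)
    if (!is.null(ast$gene))
      return(paste0(pad, '<fbc:geneProductRef fbc:geneProduct="G_',
                    esc(ast$gene), '"/>'))
    tag <- paste0("fbc:", ast$op)
    c(paste0(pad, "<", tag, ">"),
      unlist(lapply(ast$args, gprXML, indent = indent + 2)),
      paste0(pad, "</", tag, ">"))
  }
  for (j in seq_len(nReactions(model))) {
    r <- model@reactions[j, ]
    st <- .reactionStoich(model, r$id)
    push('      <reaction id="R_', esc(r$id), '" name="', esc(r$name),
         '" reversible="', tolower(r$lowerBound < 0), '" fast="false" ',
         'fbc:lowerFluxBound="', bid(r$lowerBound),
         '" fbc:upperFluxBound="', bid(r$upperBound), '">')
    tags <- strsplit(r$tags, ";", fixed = TRUE)[[1]]
    tags <- tags[nzchar(tags)]
    if (length(tags) || r$isExchange) {
      push('        <annotation><cd:reactionInfo cd:exchange="',
           tolower(r$isExchange), '">',
           paste0('<cd:tag>', esc(tags), '</cd:tag>', collapse = ""),
           '</cd:reactionInfo></annotation>')
    }
    reac <- st[st < 0]; prod <- st[st > 0]
    if (length(reac)) {
      push('        <listOfReactants>')
      for (k in seq_along(reac))
        push('          <speciesReference species="M_',
             esc(names(reac)[k]), '" stoichiometry="', num(-reac[k]),
             '" constant="true"/>')
      push('        </listOfReactants>')
    }
    if (length(prod)) {
      push('        <listOfProducts>')
      for (k in seq_along(prod))
        push('          <speciesReference species="M_',
             esc(names(prod)[k]), '" stoichiometry="', num(prod[k]),
             '" constant="true"/>')
      push('        </listOfProducts>')
    }
    if (nzchar(r$geneRule)) {
      push('        <fbc:geneProductAssociation>')
      ast <- parseGeneRule(r$geneRule)
      L <- c(L, gprXML(ast, 10))
      push('        </fbc:geneProductAssociation>')
    }
    push('      </reaction>')
  }
  push('    </listOfReactions>')
  push('    <fbc:listOfObjectives fbc:activeObjective="obj">')
  push('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
  push('        <fbc:listOfFluxObjectives>')
  push('          <fbc:fluxObjective fbc:reaction="R_',
       esc(model@objectiveId), '" fbc:coefficient="1"/>')
  push('        </fbc:listOfFluxObjectives>')
  push('      </fbc:objective>')
  push('    </fbc:listOfObjectives>')
  genes <- geneIds(model)
  if (length(genes)) {
    push('    <fbc:listOfGeneProducts>')
    for (g in genes)
      push('      <fbc:geneProduct fbc:id="G_', esc(g), '" fbc:label="',
           esc(g), '"/>')
    push('    </fbc:listOfGeneProducts>')
  }
  push('  </model>')
  push('</sbml>')
  writeLines(L, path)
  invisible(path)
}

.unprefix <- function(x, prefix) sub(paste0("^", prefix), "", x)

.attrLocal <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- match(name, sub("^.*:", "", names(at)))
  if (is.na(hit)) NA_character_ else unname(at[hit])
}

#' @rdname readModel
#' @export
readSBMLModel <- function(path) {
  doc <- xml2::read_xml(path)
  find <- function(node, what)
    xml2::xml_find_all(node, paste0(".//*[local-name()='", what, "']"))
  # parameters (flux bounds)
  pars <- find(doc, "parameter")
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                           xml2::xml_attr(pars, "id"))
  comps <- find(doc, "compartment")
  compartments <- stats::setNames(xml2::xml_attr(comps, "name"),
                                  xml2::xml_attr(comps, "id"))
  sp <- find(doc, "species")
  mets <- data.frame(
    id = .unprefix(xml2::xml_attr(sp, "id"), "M_"),
    name = xml2::xml_attr(sp, "name"),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = vapply(sp, function(s) .attrLocal(s, "chemicalFormula"),
                     character(1)),
    stringsAsFactors = FALSE)

  gprString <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef")
      return(.unprefix(.attrLocal(node, "geneProduct"), "G_"))
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, gprString, character(1))
    paste0("(", paste(parts, collapse = paste0(" ", nm, " ")), ")")
  }

  rx <- find(doc, "reaction")
  entries <- lapply(rx, function(r) {
    id <- .unprefix(xml2::xml_attr(r, "id"), "R_")
    reac <- xml2::xml_find_all(r, paste0(
      ".//*[local-name()='listOfReactants']/*[local-name()='speciesReference']"))
    prod <- xml2::xml_find_all(r, paste0(
      ".//*[local-name()='listOfProducts']/*[local-name()='speciesReference']"))
    st <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                      .unprefix(xml2::xml_attr(reac, "species"), "M_")),
      stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
                      .unprefix(xml2::xml_attr(prod, "species"), "M_")))
    bad <- setdiff(names(st), mets$id)
    if (length(bad))
      stop("reaction '", id, "' references unknown species: ",
           paste(bad, collapse = ", "))
    lbid <- .attrLocal(r, "lowerFluxBound")
    ubid <- .attrLocal(r, "upperFluxBound")
    lb <- if (!is.na(lbid)) pvals[[lbid]] else -1000
    ub <- if (!is.na(ubid)) pvals[[ubid]] else 1000
    if (lb > ub)
      stop("reaction '", id, "' has lower bound above upper bound")
    gpa <- xml2::xml_find_first(r, paste0(
      ".//*[local-name()='geneProductAssociation']"))
    rule <- if (inherits(gpa, "xml_missing")) "" else {
      kids <- xml2::xml_children(gpa)
      if (length(kids)) gprString(kids[[1]]) else ""
    }
    info <- xml2::xml_find_first(r, ".//*[local-name()='reactionInfo']")
    tags <- character(); isex <- NULL
    if (!inherits(info, "xml_missing")) {
      tags <- xml2::xml_text(xml2::xml_find_all(info,
        ".//*[local-name()='tag']"))
      isex <- identical(.attrLocal(info, "exchange"), "true")
    }
    if (is.null(isex)) {
      comp1 <- mets$compartment[match(names(st), mets$id)]
      isex <- length(st) == 1 && identical(comp1, "e")
    }
    list(id = id, name = xml2::xml_attr(r, "name") %||% id, stoich = st,
         lb = lb, ub = ub, geneRule = rule, tags = tags, isExchange = isex)
  })

  fo <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
  if (inherits(fo, "xml_missing"))
    stop("model '", path, "' declares no objective")
  objId <- .unprefix(.attrLocal(fo, "reaction"), "R_")
  ce <- xml2::xml_find_first(doc, ".//*[local-name()='carbonExchange']")
  carbon <- if (inherits(ce, "xml_missing")) NA_character_ else
    .unprefix(.attrLocal(ce, "id"), "R_")
  touched <- unique(unlist(lapply(entries, function(e) names(e$stoich))))
  mets <- mets[mets$id %in% touched, , drop = FALSE]
  makeModel(entries, objective = objId, carbonExchange = carbon,
            metabolites = mets, compartments = compartments)
}
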