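#' Parse a text reaction equation
#'
#' Equations use signed-arrow notation with compartment-suffixed metabolite
#' ids: \code{"2 accoa_c + nadph_c -> prdA_c"}; \code{"<->"} (or
#' \code{"<=>"}) marks a reversible reaction. Coefficients default to 1.
#'
#' @param equation equation string
#' @return list with \code{stoich} (named numeric, negative = consumed) and
#'   \code{reversible}
#' @export
parseEquation <- function(equation) {
  arrow <- regmatches(equation, regexpr("<->|<=>|-->|->", equation))
  if (!length(arrow))
    stop("no reaction arrow in equation: \"", equation, "\"")
  sides <- strsplit(equation, "<->|<=>|-->|->")[[1]]
  if (length(sides) > 2)
    stop("multiple arrows in equation: \"", equation, "\"")
  if (length(sides) == 1) sides <- c(sides, "")
  parseSide <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric())
    terms <- trimws(strsplit(side, "\\+")[[1]])
    out <- numeric()
    for (tm in terms) {
      if (!nzchar(tm)) next
      parts <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(parts) == 2) {
        coef <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(coef))
          stop("bad coefficient in term \"", tm, "\" of \"", equation, "\"")
        out[parts[2]] <- sign * coef + (out[parts[2]] %||% 0)
      } else if (length(parts) == 1) {
        out[parts[1]] <- sign * 1 + (out[parts[1]] %||% 0)
      } else {
        stop("cannot parse term \"", tm, "\" in \"", equation, "\"")
      }
    }
    out
  }
  lhs <- parseSide(sides[1], -1)
  rhs <- parseSide(sides[2], 1)
  st <- c(lhs, rhs)
  st <- tapply(st, names(st), sum)
  st <- st[st != 0]
  list(stoich = stats::setNames(as.numeric(st), names(st)),
       reversible = arrow %in% c("<->", "<=>"))
}

#' Read heterologous pathway definitions from TSV
#'
#' The pathway table has one reaction per line with columns \code{product},
#' \code{reaction_id}, \code{equation} (text stoichiometry, compartment
#' suffixes \code{_c}/\code{_e}), \code{lb}, \code{ub} and optionally
#' \code{gene_rule} and \code{notes}. Reactions are grouped by product. A
#' product exchange is synthesized when the table does not provide one: if
#' the extracellular product metabolite \code{<product>_e} appears, only the
#' exchange is added; if the pathway stops at \code{<product>_c}, a transport
#' step and the exchange are both added.
#'
#' @param path TSV file
#' @return named list of \linkS4class{PathwayDefinition}
#' @export
readPathwayTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("product", "reaction_id", "equation", "lb", "ub")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("pathway table missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(tab)) stop("pathway table is empty")
  out <- list()
  for (prod in unique(tab$product)) {
    rows <- which(tab$product == prod)
    entries <- lapply(rows, function(i) {
      eq <- tryCatch(parseEquation(tab$equation[i]), error = function(e)
        stop("line ", i + 1L, ": ", conditionMessage(e), call. = FALSE))
      lb <- tab$lb[i]
      if (is.na(lb)) lb <- if (eq$reversible) -1000 else 0
      ub <- tab$ub[i]
      if (is.na(ub)) ub <- 1000
      isex <- length(eq$stoich) == 1 &&
        grepl("_e$", names(eq$stoich))
      .rxn(tab$reaction_id[i], eq$stoich, lb = lb, ub = ub,
           gene = if ("gene_rule" %in% names(tab))
             tab$gene_rule[i] %||% "" else "",
           tags = "heterologous", exchange = isex)
    })
    mets <- unique(unlist(lapply(entries, function(e) names(e$stoich))))
    exIdx <- which(vapply(entries, function(e)
      isTRUE(e$isExchange) &&
        startsWith(names(e$stoich), prod), logical(1)))
    if (length(exIdx)) {
      exchangeId <- entries[[exIdx[1]]]$id
    } else {
      pe <- paste0(prod, "_e")
      pc <- paste0(prod, "_c")
      if (!(pe %in% mets)) {
        if (!(pc %in% mets))
          stop("product '", prod, "': pathway produces neither ", pc,
               " nor ", pe)
        entries[[length(entries) + 1L]] <-
          .rxn(paste0(toupper(prod), "t"),
               stats::setNames(c(-1, 1), c(pc, pe)), tags = "heterologous")
      }
      exchangeId <- paste0("EX_", prod)
      entries[[length(entries) + 1L]] <-
        .exch(exchangeId, pe, lb = 0, ub = 1000,
              tags = c("heterologous", "product_exchange"))
    }
    notes <- if ("notes" %in% names(tab))
      paste(stats::na.omit(unique(tab$notes[rows])), collapse = "; ") else ""
    out[[prod]] <- methods::new("PathwayDefinition", productId = prod,
                                productName = prod, reactions = entries,
                                exchangeId = exchangeId, notes = notes)
  }
  out
}

#' Read a medium definition from TSV
#'
#' Columns: \code{exchange}, \code{max_uptake}, \code{max_secretion},
#' \code{carbon_source} (0/1, exactly one 1).
#'
#' @param path TSV file
#' @return a \linkS4class{MediumDefinition}
#' @export
readMediumTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("exchange", "max_uptake", "max_secretion", "carbon_source")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("medium table missing column(s): ", paste(miss, collapse = ", "))
  ci <- which(tab$carbon_source == 1)
  if (length(ci) != 1)
    stop("medium table must mark exactly one carbon source")
  methods::new("MediumDefinition",
    exchanges = data.frame(exchange = tab$exchange,
                           maxUptake = tab$max_uptake,
                           maxSecretion = tab$max_secretion,
                           stringsAsFactors = FALSE),
    carbonSource = tab$exchange[ci])
}

#' Write a coupling design report
#'
#' Serializes coupling evaluations to TSV with a fixed column order and a
#' canonical row order (product, then lexicographic knockout set; the
#' knockout set itself is sorted and \code{+}-joined), so equal inputs in
#' any permutation produce byte-identical files. Numbers carry 9 significant
#' digits.
#'
#' @param evaluations data.frame from [screenProduct()] (a \code{product}
#'   column is added from the attribute if absent)
#' @param path output TSV
#' @param product product id used when the evaluations carry none
#' @return invisibly the path
#' @export
writeDesignReport <- function(evaluations, path, product = NULL) {
  ev <- as.data.frame(evaluations)
  if (!"product" %in% names(ev)) {
    label <- product %||% attr(evaluations, "product") %||% "product"
    ev$product <- rep(label, nrow(ev))
  }
  cols <- c("product", "knockout_set", "n_ko", "mu_max", "p_min", "v_glc",
            "growth_yield", "product_yield", "survives")
  cols <- intersect(cols, names(ev))
  ev <- ev[order(ev$product, ev$knockout_set), cols, drop = FALSE]
  num <- vapply(ev, is.numeric, logical(1))
  for (j in which(num))
    ev[[j]] <- formatC(ev[[j]], digits = 9, format = "g")
  con <- file(path, open = "wb")  # fixed eol across platforms
  on.exit(close(con))
  utils::write.table(ev, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Read and write curation configurations
#'
#' Curation actions serialize to YAML as a list of maps, one per action,
#' each with a \code{kind} key plus the kind's parameters.
#'
#' @param path YAML file
#' @return \code{readCurationConfig}: list of [curationAction()] objects
#' @export
readCurationConfig <- function(path) {
  doc <- yaml::read_yaml(path)
  lapply(doc, function(a) {
    kind <- a$kind
    a$kind <- NULL
    if (!is.null(a$stoich)) a$stoich <- unlist(a$stoich)
    do.call(curationAction, c(list(kind = kind), a))
  })
}

#' @rdname readCurationConfig
#' @param actions list of [curationAction()] objects
#' @export
writeCurationConfig <- function(actions, path) {
  doc <- lapply(actions, function(a) {
    out <- unclass(a)
    if (!is.null(out$stoich)) out$stoich <- as.list(out$stoich)
    out
  })
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read background deletion sets (by gene) from YAML
#'
#' The file holds a list of named entries, each with a \code{genes} list;
#' the shipped \code{backgrounds.yaml} carries the two pre-selected deletion
#' sets used for background-constrained screening. Map them to reactions
#' with [mapBackgroundGenes()].
#'
#' @param path YAML file
#' @return named list of character vectors of gene ids
#' @export
readBackgroundsConfig <- function(path) {
  doc <- yaml::read_yaml(path)
  stats::setNames(lapply(doc, function(b) as.character(unlist(b$genes))),
                  vapply(doc, function(b) as.character(b$name),
                         character(1)))
}
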