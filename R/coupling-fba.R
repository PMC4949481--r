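#' Yield-filter configuration
#'
#' Thresholds applied to coupling evaluations: a minimal growth yield (g
#' biomass per mol glucose), an absolute product-yield floor (mol product per
#' mol glucose) below which solutions are never considered, and a relative
#' fraction of the per-product maximum yield that a solution must reach.
#' Defaults are the screening thresholds used throughout: growth yield >=
#' 1e-2 g/mol for FBA-based screening (use 1e-3 for turnover-distance
#' screening), product yield floor 1e-3 mol/mol, relative fraction 0.90. All
#' comparisons are inclusive (\code{>=}).
#'
#' @param minGrowthYield minimal growth yield, g biomass / mol glucose
#' @param minProductYield absolute product-yield floor, mol / mol glucose
#' @param relativeYieldFraction fraction of the per-product maximum product
#'   yield required, in (0, 1]
#' @return a classed list
#' @export
filterConfig <- function(minGrowthYield = 1e-2, minProductYield = 1e-3,
                         relativeYieldFraction = 0.90) {
  stopifnot(minGrowthYield > 0, minProductYield > 0,
            relativeYieldFraction > 0, relativeYieldFraction <= 1)
  structure(list(minGrowthYield = minGrowthYield,
                 minProductYield = minProductYield,
                 relativeYieldFraction = relativeYieldFraction),
            class = "filterConfig")
}

#' Candidate deletion policy
#'
#' Returns the deterministic (lexicographic) list of reactions eligible for
#' knockout enumeration. The default policy excludes exchange reactions, the
#' biomass objective, ATP-maintenance-tagged reactions, heterologous pathway
#' reactions and reactions without a gene association (not implementable
#' genetically). Single-knockout-lethal candidates are retained: they only
#' matter inside multi-knockout sets, and the lethal-subset pruning in
#' [screenProduct()] disposes of them cheaply.
#'
#' @param model a producer \linkS4class{MetabolicModel}
#' @param policy list of logical switches: \code{excludeExchanges},
#'   \code{excludeBiomass}, \code{excludeMaintenance},
#'   \code{excludeHeterologous}, \code{requireGeneRule} (all default TRUE)
#' @return character vector of reaction ids, sorted
#' @export
candidateDeletions <- function(model, policy = list()) {
  p <- utils::modifyList(list(excludeExchanges = TRUE, excludeBiomass = TRUE,
                              excludeMaintenance = TRUE,
                              excludeHeterologous = TRUE,
                              requireGeneRule = TRUE), policy)
  rxn <- model@reactions
  tags <- strsplit(rxn$tags, ";", fixed = TRUE)
  keep <- rep(TRUE, nrow(rxn))
  if (p$excludeExchanges) keep <- keep & !rxn$isExchange
  if (p$excludeBiomass)
    keep <- keep & rxn$id != model@objectiveId &
      !vapply(tags, function(tt) "biomass" %in% tt, logical(1))
  if (p$excludeMaintenance)
    keep <- keep & !vapply(tags, function(tt) "maintenance" %in% tt, logical(1))
  if (p$excludeHeterologous)
    keep <- keep & !vapply(tags, function(tt) "heterologous" %in% tt, logical(1))
  if (p$requireGeneRule) keep <- keep & nzchar(rxn$geneRule)
  sort(rxn$id[keep])
}

#' Enumerate knockout designs
#'
#' Yields every subset of the candidate list of size 1..\code{maxSize} with
#' an empty background, plus, for each background set, every subset of size
#' 0..\code{maxSize} of the candidates not already in that background. Order
#' is deterministic: by background, then size, then lexicographic combination.
#'
#' @param candidates character vector of candidate reaction ids
#' @param maxSize maximal number of free deletions (>= 1)
#' @param backgrounds list of pre-selected deletion sets (character vectors);
#'   candidates overlapping a background are removed from that background's
#'   free enumeration (with a message)
#' @return list of designs, each a list with elements \code{background} and
#'   \code{free}
#' @export
enumerateDesigns <- function(candidates, maxSize, backgrounds = list()) {
  stopifnot(maxSize >= 1)
  candidates <- sort(unique(candidates))
  out <- list()
  add <- function(bg, free) {
    out[[length(out) + 1L]] <<- list(background = bg, free = free)
  }
  for (s in seq_len(min(maxSize, length(candidates)))) {
    cmb <- utils::combn(candidates, s, simplify = FALSE)
    for (cc in cmb) add(character(), cc)
  }
  for (bg in backgrounds) {
    bg <- sort(unique(as.character(bg)))
    pool <- setdiff(candidates, bg)
    if (length(pool) < length(candidates))
      message("background {", paste(bg, collapse = ","),
              "} overlaps candidates; overlap removed from free enumeration")
    for (s in seq_len(min(maxSize, length(pool)))) {
      cmb <- utils::combn(pool, s, simplify = FALSE)
      for (cc in cmb) add(bg, cc)
    }
  }
  keys <- vapply(out, .designKey, character(1))
  out[!duplicated(keys)]
}

.designKey <- function(design) {
  paste(sort(unique(c(design$background, design$free))), collapse = "+")
}

#' Evaluate one knockout design for growth-product coupling
#'
#' Applies the design's knockouts, maximizes growth, then minimizes product
#' secretion with growth held at its maximum (within \code{delta}); computes
#' the growth yield \eqn{Y_x = 1000 \mu / v_{glc}} (g biomass per mol
#' glucose) and product yield \eqn{Y_p = p_{min} / v_{glc}} (mol per mol
#' glucose) from the stage-2 flux distribution. Infeasible or zero-growth
#' mutants come back with \code{muMax = 0} and zero yields.
#'
#' @param model a producer \linkS4class{MetabolicModel}
#' @param design a design from [enumerateDesigns()], or a character vector of
#'   reaction ids
#' @param productExchange id of the product exchange reaction (default: the
#'   reaction tagged \code{product_exchange})
#' @param delta stage-1 slack passed to [twoStageOptimum()]
#' @param backend LP backend
#' @return one-row data.frame with columns knockout_set, n_ko, mu_max,
#'   p_min, v_glc, growth_yield, product_yield
#' @export
evaluateDesign <- function(model, design,
                           productExchange = .productExchangeOf(model),
                           delta = NULL, backend = lpBackend()) {
  if (is.character(design)) design <- list(background = character(),
                                           free = design)
  kos <- unique(c(design$background, design$free))
  key <- paste(sort(kos), collapse = "+")
  mut <- applyKnockouts(model, kos)
  ts <- twoStageOptimum(mut, c(model@objectiveId, "max"),
                        c(productExchange, "min"), delta = delta,
                        backend = backend)
  row <- data.frame(knockout_set = key, n_ko = length(kos), mu_max = 0,
                    p_min = 0, v_glc = 0, growth_yield = 0,
                    product_yield = 0, stringsAsFactors = FALSE)
  if (ts$first@status != "optimal" || ts$second@status != "optimal")
    return(row)
  mu <- ts$first@objective
  if (mu <= 1e-9) return(row)
  v <- fluxes(ts$second)
  vglc <- abs(v[[model@carbonExchangeId]])
  row$mu_max <- mu
  row$p_min <- max(ts$second@objective, 0)
  row$v_glc <- vglc
  if (vglc > 1e-9) {
    row$growth_yield <- 1000 * mu / vglc
    row$product_yield <- row$p_min / vglc
  }
  row
}

.productExchangeOf <- function(model) {
  hits <- taggedReactions(model, "product_exchange")
  if (length(hits) != 1)
    stop("model must carry exactly one reaction tagged 'product_exchange'; ",
         "found: ", paste(hits, collapse = ", "))
  hits
}

#' Apply the yield filters to coupling evaluations
#'
#' Keeps an evaluation iff its growth yield is at least
#' \code{minGrowthYield}, its product yield is at least
#' \code{minProductYield}, and its product yield reaches at least
#' \code{relativeYieldFraction} of the maximum product yield among all
#' supplied evaluations of the product (the maximum is computed over the full
#' input, before any filtering). All comparisons inclusive.
#'
#' @param evaluations data.frame of rows from [evaluateDesign()] (one
#'   product)
#' @param config a [filterConfig()]
#' @return the input data.frame with a logical column \code{survives} added
#' @export
filterDesigns <- function(evaluations, config = filterConfig()) {
  if (!nrow(evaluations)) {
    evaluations$survives <- logical(0)
    return(evaluations)
  }
  ymax <- max(evaluations$product_yield)
  evaluations$survives <-
    evaluations$growth_yield >= config$minGrowthYield &
    evaluations$product_yield >= config$minProductYield &
    evaluations$product_yield >= config$relativeYieldFraction * ymax
  evaluations
}

#' Screen one product for growth-coupling knockout designs
#'
#' Composes enumeration, evaluation and filtering with lethal-subset pruning:
#' any design whose maximal growth falls below the lethality tolerance marks
#' all of its supersets skippable — sound because shrinking bounds can only
#' shrink the feasible flux space, so growth is non-increasing in the
#' knockout set. Pruned (and thus never-evaluated) supersets are recorded
#' with zero growth so the evaluation table still covers the full design
#' space.
#'
#' @param model a producer \linkS4class{MetabolicModel}
#' @param candidates candidate reaction ids (default
#'   [candidateDeletions()] with the default policy)
#' @param maxSize maximal free-knockout set size (default 3)
#' @param backgrounds list of background deletion sets
#' @param config a [filterConfig()]
#' @param prune use lethal-subset pruning (default TRUE; FALSE re-evaluates
#'   every design, used by the equivalence tests)
#' @param delta stage-1 slack, see [twoStageOptimum()]
#' @param backend LP backend
#' @return data.frame of evaluations (one row per design) with columns as in
#'   [evaluateDesign()] plus \code{survives}; the attribute
#'   \code{"summary"} holds the best product yield per design size
#' @export
screenProduct <- function(model, candidates = candidateDeletions(model),
                          maxSize = 3, backgrounds = list(),
                          config = filterConfig(), prune = TRUE,
                          delta = NULL, backend = lpBackend()) {
  designs <- enumerateDesigns(candidates, maxSize, backgrounds)
  pex <- .productExchangeOf(model)
  lethal <- list()
  rows <- vector("list", length(designs))
  for (k in seq_along(designs)) {
    kos <- sort(unique(c(designs[[k]]$background, designs[[k]]$free)))
    key <- paste(kos, collapse = "+")
    if (prune && length(lethal) &&
        any(vapply(lethal, function(ls) all(ls %in% kos), logical(1)))) {
      rows[[k]] <- data.frame(knockout_set = key, n_ko = length(kos),
                              mu_max = 0, p_min = 0, v_glc = 0,
                              growth_yield = 0, product_yield = 0,
                              stringsAsFactors = FALSE)
      next
    }
    row <- evaluateDesign(model, designs[[k]], productExchange = pex,
                          delta = delta, backend = backend)
    if (prune && row$mu_max <= 1e-9) lethal[[length(lethal) + 1L]] <- kos
    rows[[k]] <- row
  }
  ev <- do.call(rbind, rows)
  ev <- ev[!duplicated(ev$knockout_set), , drop = FALSE]
  ev <- ev[order(ev$n_ko, ev$knockout_set), , drop = FALSE]
  rownames(ev) <- NULL
  ev <- filterDesigns(ev, config)
  attr(ev, "product") <- sub("^EX_", "", pex)
  sizes <- sort(unique(ev$n_ko))
  attr(ev, "summary") <- data.frame(
    n_ko = sizes,
    best_product_yield = vapply(sizes, function(s)
      max(c(ev$product_yield[ev$n_ko == s], 0)), numeric(1)))
  ev
}

#' Map background gene sets to reaction knockout sets
#'
#' Pre-selected deletion backgrounds are specified by gene; this maps each
#' gene set through the model's gene-reaction rules to the set of disabled
#' reactions. A gene set that disables no reaction (for instance because an
#' isoenzyme partner remains) yields an empty background, reported as such.
#'
#' @param model a \linkS4class{MetabolicModel}
#' @param geneSets list of character vectors of gene ids
#' @return list of character vectors of reaction ids (possibly empty)
#' @export
mapBackgroundGenes <- function(model, geneSets) {
  lapply(geneSets, function(gs) reactionsDisabledByGenes(model, gs))
}
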