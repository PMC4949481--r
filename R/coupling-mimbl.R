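#' Carbon-catabolite-repressed reference state
#'
#' Builds the high-glucose ("glucose-repressed") reference flux distribution
#' used by the turnover-distance predictor: a parsimonious FBA at maximal
#' growth with (i) all reactions tagged \code{respiration} closed and (ii)
#' the reaction tagged \code{g6p_isomerase} made irreversible towards
#' fructose-6-phosphate. The convention is that the tagged isomerase is
#' written with fructose-6-phosphate on the product side, so the restriction
#' is a zero lower bound. Closing tagged respiration lumps (rather than the
#' oxygen exchange) keeps oxygen-requiring biosyntheses feasible.
#'
#' @param model a \linkS4class{MetabolicModel} carrying \code{respiration}
#'   and \code{g6p_isomerase} reaction tags
#' @param backend LP backend
#' @return a \linkS4class{FluxDistribution} (provenance \code{"pFBA"})
#' @export
ccrReference <- function(model, backend = lpBackend()) {
  resp <- taggedReactions(model, "respiration")
  iso <- taggedReactions(model, "g6p_isomerase")
  missing <- c(if (!length(resp)) "respiration",
               if (!length(iso)) "g6p_isomerase")
  if (length(missing))
    stop("ccrReference requires reaction tag(s): ",
         paste(missing, collapse = ", "))
  m <- .setBoundsFast(model, resp, lb = 0, ub = 0)
  im <- match(iso, m@reactions$id)
  m@reactions$lowerBound[im] <- pmax(m@reactions$lowerBound[im], 0)
  out <- pfba(m, backend = backend)
  if (out@status != "optimal")
    stop("model infeasible under CCR constraints: status ", out@status)
  fl <- out@flux
  fl@provenance <- "pFBA"
  fl
}

#' Metabolite turnovers of a flux distribution
#'
#' The turnover of metabolite \eqn{i} is \eqn{t_i = \frac{1}{2} \sum_j
#' |S_{ij} v_j|}; at steady state this equals both its total production and
#' its total consumption rate. Extracellular boundary metabolites are
#' included.
#'
#' @param model a \linkS4class{MetabolicModel}
#' @param flux a \linkS4class{FluxDistribution} or named numeric vector
#'   covering all reactions
#' @return named numeric vector, metabolite id -> turnover
#' @export
turnovers <- function(model, flux) {
  v <- if (methods::is(flux, "FluxDistribution")) flux@fluxes else flux
  miss <- setdiff(reactionIds(model), names(v))
  if (length(miss))
    stop("flux missing reaction(s): ", paste(miss, collapse = ", "))
  v <- v[reactionIds(model)]
  t <- 0.5 * as.vector(abs(model@smat) %*% abs(v))
  stats::setNames(t, metaboliteIds(model))
}

#' Predict a knockout mutant's fluxes by minimal turnover adjustment
#'
#' Solves for the steady-state flux distribution of the knockout mutant that
#' minimizes the L1 distance between its metabolite turnovers and those of
#' the reference ("wild-type") distribution, with the substrate uptake fixed
#' to the reference uptake so that turnover distances compare like with like.
#' Linearized by splitting each flux into non-negative forward and backward
#' parts and one deviation variable per metabolite. Deviations are
#' unweighted (all metabolites count equally); \code{weights} exposes the
#' weighted variant.
#'
#' @param model a \linkS4class{MetabolicModel} (un-knocked)
#' @param reference a steady-state feasible \linkS4class{FluxDistribution}
#' @param koSet character vector of reactions to knock out (may be empty)
#' @param weights optional named numeric vector of per-metabolite deviation
#'   weights (default: 1 for every metabolite)
#' @param backend LP backend
#' @return list with elements \code{status}, \code{flux} (a
#'   \linkS4class{FluxDistribution} with provenance \code{"MiMBl"}, or
#'   \code{NULL} if infeasible), \code{distance} (the turnover distance D;
#'   \code{NA} if infeasible), \code{turnovers} (predicted) and
#'   \code{referenceTurnovers}
#' @examples
#' rt <- makeRedoxCouplingModel()
#' ref <- fluxes(pfba(rt))  # or a hand-built fermentative reference
#' @export
mimblPredict <- function(model, reference, koSet = character(),
                         weights = NULL, backend = lpBackend()) {
  ids <- model@reactions$id
  n <- length(ids)
  tref <- turnovers(model, reference)
  mI <- length(tref)
  S <- as.matrix(model@smat)
  Ap <- pmax(S, 0)   # production coefficients for forward flux
  Am <- pmax(-S, 0)  # production coefficients for backward flux
  lb <- model@reactions$lowerBound
  ub <- model@reactions$upperBound
  kk <- match(koSet, ids)
  if (anyNA(kk))
    stop("unknown reaction id(s): ",
         paste(koSet[is.na(kk)], collapse = ", "))
  if (length(kk)) { lb[kk] <- 0; ub[kk] <- 0 }
  fl <- pmax(lb, 0); fu <- pmax(ub, 0)
  gl <- pmax(-ub, 0); gu <- pmax(-lb, 0)

  w <- rep(1, mI)
  if (!is.null(weights)) {
    ww <- weights[metaboliteIds(model)]
    w[!is.na(ww)] <- ww[!is.na(ww)]
  }

  glc <- model@carbonExchangeId
  refUptake <- unname(fluxes(reference)[glc])
  ig <- match(glc, ids)
  uptakeRow <- numeric(2 * n + mI)
  uptakeRow[ig] <- 1; uptakeRow[n + ig] <- -1

  Aeq <- rbind(cbind(S, -S, matrix(0, mI, mI)), uptakeRow)
  beq <- c(rep(0, mI), refUptake)
  # e_i >= |prod_i - tref_i| as two one-sided ranged rows
  rows <- rbind(cbind(-Ap, -Am, diag(mI)),   # e - prod >= -tref
                cbind(Ap, Am, diag(mI)))     # e + prod >= tref
  res <- .solveRanged(c(rep(0, 2 * n), w), Aeq, beq,
                      c(fl, gl, rep(0, mI)), c(fu, gu, rep(Inf, mI)),
                      rows = rows, rowLo = c(-tref, tref),
                      rowHi = rep(Inf, 2 * mI), direction = "min",
                      backend = backend)
  if (res$status != "optimal")
    return(list(status = if (res$status == "unbounded") res$status else
                  "infeasible",
                flux = NULL, distance = NA_real_, turnovers = NULL,
                referenceTurnovers = tref, koSet = koSet))
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  tpred <- as.vector(Ap %*% res$x[seq_len(n)] +
                     Am %*% res$x[n + seq_len(n)])
  fd <- methods::new("FluxDistribution",
                     fluxes = stats::setNames(v, ids),
                     provenance = "MiMBl", objectiveValue = res$objective)
  list(status = "optimal", flux = fd, distance = res$objective,
       turnovers = stats::setNames(tpred, names(tref)),
       referenceTurnovers = tref, koSet = koSet)
}

#' Screen a product for regulatory growth-coupling designs
#'
#' Enumerates all single and double knockouts of the candidate reactions,
#' predicts each mutant's flux distribution by minimal turnover adjustment
#' against the carbon-catabolite-repressed reference, reads growth and
#' product yields off the predicted (suboptimal) distribution, and applies
#' the yield filters — with the lower growth-yield threshold (1e-3 g/mol)
#' used for regulatory screening. Mutants that cannot sustain any steady
#' state are reported with zero product flux.
#'
#' @param model a producer \linkS4class{MetabolicModel}
#' @param candidates candidate reaction ids (default
#'   [candidateDeletions()])
#' @param maxKo 1 or 2 (the predictor is not validated beyond double
#'   knockouts)
#' @param config a [filterConfig()]; default uses \code{minGrowthYield =
#'   1e-3}
#' @param reference the CCR reference (default [ccrReference()] computed on
#'   this producer model; it can be shared across producers of one host)
#' @param backend LP backend
#' @return data.frame with one row per design: knockout_set, n_ko, mu,
#'   product_flux, distance, growth_yield, product_yield, survives
#' @export
screenProductMimbl <- function(model,
                               candidates = candidateDeletions(model),
                               maxKo = 2,
                               config = filterConfig(minGrowthYield = 1e-3),
                               reference = ccrReference(model,
                                                        backend = backend),
                               backend = lpBackend()) {
  stopifnot(maxKo %in% 1:2)
  pex <- .productExchangeOf(model)
  glc <- model@carbonExchangeId
  vglc <- abs(unname(fluxes(reference)[glc]))
  candidates <- sort(unique(candidates))
  sets <- list()
  for (s in seq_len(min(maxKo, length(candidates))))
    sets <- c(sets, utils::combn(candidates, s, simplify = FALSE))
  rows <- lapply(sets, function(kos) {
    pr <- mimblPredict(model, reference, kos, backend = backend)
    row <- data.frame(knockout_set = paste(sort(kos), collapse = "+"),
                      n_ko = length(kos), mu = 0, product_flux = 0,
                      distance = NA_real_, growth_yield = 0,
                      product_yield = 0, stringsAsFactors = FALSE)
    if (pr$status != "optimal") return(row)
    v <- fluxes(pr$flux)
    row$mu <- max(unname(v[model@objectiveId]), 0)
    row$product_flux <- max(unname(v[pex]), 0)
    row$distance <- pr$distance
    if (vglc > 1e-9) {
      row$growth_yield <- 1000 * row$mu / vglc
      row$product_yield <- row$product_flux / vglc
    }
    row
  })
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$n_ko, ev$knockout_set), , drop = FALSE]
  rownames(ev) <- NULL
  ymax <- max(c(ev$product_yield, 0))
  ev$survives <- ev$growth_yield >= config$minGrowthYield &
    ev$product_yield >= config$minProductYield &
    ev$product_yield >= config$relativeYieldFraction * ymax
  ev
}
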