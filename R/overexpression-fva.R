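#' Maximal product yield of a producer model
#'
#' Maximizes product secretion with growth not required (the biomass lower
#' bound is dropped to zero if positive), reporting the yield in mol product
#' per mol glucose taken up. The maintenance drain is kept by default;
#' \code{keepMaintenance = FALSE} releases it, and \code{growthFloor} anchors
#' a minimal growth instead of none.
#'
#' @param model a producer \linkS4class{MetabolicModel}
#' @param growthFloor minimal growth rate enforced (default 0)
#' @param keepMaintenance keep maintenance-tagged lower bounds (default TRUE)
#' @param backend LP backend
#' @return list with \code{yield} (mol/mol; 0 if the product is unreachable),
#'   \code{flux} (\linkS4class{FluxDistribution} or \code{NULL}) and
#'   \code{productFlux}, \code{glucoseUptake}
#' @export
maxProductYield <- function(model, growthFloor = 0, keepMaintenance = TRUE,
                            backend = lpBackend()) {
  pex <- .productExchangeOf(model)
  m <- model
  ib <- match(m@objectiveId, m@reactions$id)
  m@reactions$lowerBound[ib] <- growthFloor
  if (!keepMaintenance) {
    mt <- taggedReactions(m, "maintenance")
    if (length(mt)) m <- .setBoundsFast(m, mt, lb = 0)
  }
  out <- fba(m, pex, "max", backend = backend)
  if (out@status != "optimal" || out@objective <= 1e-9)
    return(list(yield = 0, flux = NULL, productFlux = 0, glucoseUptake = NA))
  v <- fluxes(out)
  vglc <- abs(unname(v[m@carbonExchangeId]))
  list(yield = if (vglc > 1e-9) out@objective / vglc else 0,
       flux = out@flux, productFlux = out@objective, glucoseUptake = vglc)
}

#' Product-essential reactions and minimal required fluxes
#'
#' Identifies the reactions essential for converting glucose into the
#' product at (a fraction of) its maximum yield: product secretion is
#' constrained to \code{anchorFraction} of its optimum, glucose uptake is
#' pinned at its limit so fluxes are comparable, and flux variability
#' analysis is run over all reactions. A reaction is essential iff its flux
#' interval excludes zero (entirely positive or entirely negative); its
#' minimal required flux is the interval endpoint closer to zero, reported
#' as magnitude per unit glucose uptake. These are the gene overexpression
#' targets.
#'
#' @inheritParams maxProductYield
#' @param anchorFraction fraction of the maximal product flux enforced
#'   (default \code{1 - 1e-6}; exact equality would be numerically brittle)
#' @param tol zero-exclusion tolerance on the FVA interval
#' @return data.frame with columns product, reaction, direction (+1/-1),
#'   min_flux (per unit glucose), fva_min, fva_max (absolute); zero rows if
#'   the product is unreachable
#' @export
productEssentialReactions <- function(model, anchorFraction = 1 - 1e-6,
                                      growthFloor = 0,
                                      keepMaintenance = TRUE, tol = 1e-6,
                                      backend = lpBackend()) {
  pex <- .productExchangeOf(model)
  product <- sub("^EX_", "", pex)
  top <- maxProductYield(model, growthFloor, keepMaintenance,
                         backend = backend)
  empty <- data.frame(product = character(), reaction = character(),
                      direction = numeric(), min_flux = numeric(),
                      fva_min = numeric(), fva_max = numeric(),
                      stringsAsFactors = FALSE)
  if (top$yield <= 0) return(empty)

  m <- model
  ib <- match(m@objectiveId, m@reactions$id)
  m@reactions$lowerBound[ib] <- growthFloor
  if (!keepMaintenance) {
    mt <- taggedReactions(m, "maintenance")
    if (length(mt)) m <- .setBoundsFast(m, mt, lb = 0)
  }
  # pin glucose uptake and anchor the product optimum
  glc <- m@carbonExchangeId
  ig <- match(glc, m@reactions$id)
  uptake <- abs(m@reactions$lowerBound[ig])
  m@reactions$upperBound[ig] <- m@reactions$lowerBound[ig]
  m <- .setBoundsFast(m, pex, lb = anchorFraction * top$productFlux)
  rng <- fva(m, backend = backend)
  ess <- (rng$min > tol & rng$max > tol) | (rng$min < -tol & rng$max < -tol)
  rng <- rng[ess, , drop = FALSE]
  if (!nrow(rng)) return(empty)
  dirn <- ifelse(rng$min > 0, 1, -1)
  minflux <- pmin(abs(rng$min), abs(rng$max))
  data.frame(product = product, reaction = rng$id, direction = dirn,
             min_flux = minflux / uptake, fva_min = rng$min,
             fva_max = rng$max, stringsAsFactors = FALSE)
}

#' Assemble the products-by-reactions design matrix
#'
#' Stacks essential-reaction reports into a products x reactions matrix:
#' 0/1 incidence, or the minimal required flux (0 where not essential).
#' Reactions essential for every product can be dropped, as is done when
#' only the discriminating, module-forming reactions are of interest.
#'
#' @param reports named list of [productEssentialReactions()] data.frames
#'   (names are the product ids; duplicate product ids are an error)
#' @param mode \code{"incidence"} or \code{"flux"}
#' @param dropShared drop reactions essential for all products (default
#'   FALSE)
#' @return numeric matrix with products as rows, carrying attribute
#'   \code{"mode"}
#' @export
buildDesignMatrix <- function(reports, mode = c("incidence", "flux"),
                              dropShared = FALSE) {
  mode <- match.arg(mode)
  stopifnot(length(reports) >= 1)
  prods <- names(reports)
  if (is.null(prods) || any(!nzchar(prods)))
    prods <- vapply(reports, function(r) r$product[1], character(1))
  if (anyDuplicated(prods))
    stop("duplicate product ids: ",
         paste(unique(prods[duplicated(prods)]), collapse = ", "))
  cols <- sort(unique(unlist(lapply(reports, `[[`, "reaction"))))
  M <- matrix(0, length(reports), length(cols),
              dimnames = list(prods, cols))
  for (k in seq_along(reports)) {
    r <- reports[[k]]
    M[k, r$reaction] <- if (mode == "incidence") 1 else r$min_flux
  }
  if (dropShared && ncol(M)) {
    shared <- colSums(M != 0) == nrow(M)
    M <- M[, !shared, drop = FALSE]
  }
  attr(M, "mode") <- mode
  M
}
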