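#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux through one reaction subject to
#' steady-state mass balance \eqn{S v = 0} and the model's flux bounds.
#' Infeasibility and unboundedness are reported in the returned
#' \linkS4class{LPOutcome} status, not as errors.
#'
#' @param model a \linkS4class{MetabolicModel} with the medium already applied
#' @param objective reaction id to optimize (default: the model's objective)
#' @param direction \code{"max"} or \code{"min"}
#' @param backend LP backend, see [solveLP()]
#' @return an \linkS4class{LPOutcome}
#' @examples
#' m <- makeChainModel(3)
#' objectiveValue(fba(m))   # 10: substrate-uptake limited
#' @export
fba <- function(model, objective = objectiveReaction(model),
                direction = c("max", "min"), backend = lpBackend()) {
  direction <- match.arg(direction)
  if (!objective %in% model@reactions$id)
    stop("objective reaction '", objective, "' not in the model")
  .modelLP(model, stats::setNames(1, objective), direction = direction,
           backend = backend, provenance = "FBA")
}

#' Two-stage (lexicographic) optimization
#'
#' Stage 1 optimizes the first reaction to its optimum \eqn{f^*}; stage 2
#' optimizes the second reaction subject to the first being held at its
#' optimum (within a small slack \eqn{\delta}, mirrored for minimization).
#' This is the robust coupling construction: with first = growth (max) and
#' second = product secretion (min), the stage-2 value is the product flux
#' guaranteed at maximal growth regardless of alternate optima.
#'
#' @param model a \linkS4class{MetabolicModel}
#' @param first,second length-2 character vectors \code{c(reactionId,
#'   direction)} with direction \code{"max"} or \code{"min"}
#' @param delta stage-1 slack; default \code{max(1e-9, 1e-6 |f*|)} — a pure
#'   equality pin would be numerically brittle
#' @param backend LP backend
#' @return list with elements \code{first} and \code{second} (both
#'   \linkS4class{LPOutcome}; stage-1 infeasibility propagates to both) and
#'   \code{delta}
#' @examples
#' rt <- makeRedoxCouplingModel()
#' ko <- applyKnockouts(rt, "Ferm")
#' ts <- twoStageOptimum(ko, c("Biomass", "max"), c("EX_p", "min"))
#' objectiveValue(ts$second)   # 10: product fully coupled
#' @export
twoStageOptimum <- function(model, first, second, delta = NULL,
                            backend = lpBackend()) {
  stopifnot(length(first) == 2, length(second) == 2)
  for (id in c(first[1], second[1]))
    if (!id %in% model@reactions$id)
      stop("reaction '", id, "' not in the model")
  s1 <- fba(model, first[1], first[2], backend = backend)
  if (s1@status != "optimal")
    return(list(first = s1, second = s1, delta = delta))
  fstar <- s1@objective
  if (is.null(delta)) delta <- max(1e-9, 1e-6 * abs(fstar))
  if (identical(first[2], "max")) {
    lbo <- stats::setNames(fstar - delta, first[1])
    s2 <- .modelLP(model, stats::setNames(1, second[1]),
                   direction = second[2], lbOverride = lbo, backend = backend)
  } else {
    ubo <- stats::setNames(fstar + delta, first[1])
    s2 <- .modelLP(model, stats::setNames(1, second[1]),
                   direction = second[2], ubOverride = ubo, backend = backend)
  }
  list(first = s1, second = s2, delta = delta)
}

#' Parsimonious FBA
#'
#' Among flux distributions attaining at least \eqn{(1-\delta)} of the FBA
#' optimum, returns one minimizing the total absolute flux
#' \eqn{\sum_j |v_j|}. Implemented by splitting every flux into non-negative
#' forward and backward parts; the split never leaks out — the returned
#' distribution carries net fluxes. The outcome's objective is the minimal
#' total flux; the growth value is available from the flux vector.
#'
#' @inheritParams fba
#' @param delta anchor slack on the stage-1 optimum. Default 1e-9 (absolute):
#'   the total-flux objective trades one-for-one against the anchor, so a
#'   relative slack would leak into the reported minimal total flux
#' @return an \linkS4class{LPOutcome} with provenance \code{"pFBA"}; the
#'   objective slot holds the minimal total flux
#' @examples
#' m <- makeChainModel(2)
#' objectiveValue(pfba(m))   # 40: uptake plus three unit-flux steps at 10
#' @export
pfba <- function(model, objective = objectiveReaction(model), delta = NULL,
                 backend = lpBackend()) {
  s1 <- fba(model, objective, "max", backend = backend)
  if (s1@status != "optimal") return(s1)
  opt <- s1@objective
  if (is.null(delta)) delta <- 1e-9
  ids <- model@reactions$id
  n <- length(ids)
  lb <- model@reactions$lowerBound
  ub <- model@reactions$upperBound
  S <- as.matrix(model@smat)
  # v = f - g, f,g >= 0; v's own bounds enforced through the split bounds
  fl <- pmax(lb, 0); fu <- pmax(ub, 0)
  gl <- pmax(-ub, 0); gu <- pmax(-lb, 0)
  A <- cbind(S, -S)
  anchor <- numeric(2 * n)
  io <- match(objective, ids)
  anchor[io] <- 1; anchor[n + io] <- -1
  res <- .solveRanged(rep(1, 2 * n), A, rep(0, nrow(S)),
                      c(fl, gl), c(fu, gu),
                      rows = matrix(anchor, 1), rowLo = opt - delta,
                      rowHi = Inf, direction = "min", backend = backend)
  if (res$status != "optimal")
    return(methods::new("LPOutcome", status = res$status,
                        objective = NA_real_, flux = NULL))
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  fl <- methods::new("FluxDistribution",
                     fluxes = stats::setNames(v, ids), provenance = "pFBA",
                     objectiveValue = res$objective)
  methods::new("LPOutcome", status = "optimal", objective = res$objective,
               flux = fl)
}

#' Flux variability analysis
#'
#' For each listed reaction, the minimal and maximal flux subject to the
#' anchor reaction being held at a fraction of its optimum. With
#' \code{anchor = NULL} the variability is computed over the plain feasible
#' space (used for blocked-reaction detection).
#'
#' @inheritParams fba
#' @param reactionIds reactions to scan (default: all)
#' @param anchor either \code{NULL} or a list/vector \code{(reactionId,
#'   fraction)}; the anchor reaction is first maximized, then constrained to
#'   \code{>= fraction * optimum} (sign-aware for negative optima)
#' @return data.frame with columns id, min, max
#' @examples
#' m <- makeChainModel(3)
#' fva(m, anchor = list(objectiveReaction(m), 1))  # all intervals (10, 10)
#' @export
fva <- function(model, reactionIds = NULL, anchor = NULL,
                backend = lpBackend()) {
  ids <- model@reactions$id
  if (is.null(reactionIds)) reactionIds <- ids
  unknown <- setdiff(reactionIds, ids)
  if (length(unknown))
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  lbo <- NULL
  if (!is.null(anchor)) {
    aid <- as.character(anchor[[1]])
    frac <- as.numeric(anchor[[2]])
    s1 <- fba(model, aid, "max", backend = backend)
    if (s1@status != "optimal")
      stop("anchor optimization not optimal: status ", s1@status)
    opt <- s1@objective
    lbo <- stats::setNames(opt - (1 - frac) * abs(opt), aid)
  }
  lo <- hi <- numeric(length(reactionIds))
  for (k in seq_along(reactionIds)) {
    oc <- stats::setNames(1, reactionIds[k])
    rmin <- .modelLP(model, oc, "min", lbOverride = lbo, backend = backend)
    rmax <- .modelLP(model, oc, "max", lbOverride = lbo, backend = backend)
    if (rmin@status != "optimal" || rmax@status != "optimal")
      stop("FVA subproblem not optimal for ", reactionIds[k],
           " (status ", rmin@status, "/", rmax@status, ")")
    lo[k] <- rmin@objective
    hi[k] <- rmax@objective
  }
  data.frame(id = reactionIds, min = lo, max = hi, stringsAsFactors = FALSE)
}
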