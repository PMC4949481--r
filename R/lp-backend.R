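#' Linear-programming backends
#'
#' All optimization in the package goes through a minimal solver contract:
#' minimize (or maximize) \code{c'x} subject to \code{A x = b} and
#' \code{lb <= x <= ub}. Two backends implement it:
#' \describe{
#'   \item{\code{"tableau"}}{the package's compiled bounded-variable two-phase
#'     primal simplex (default); handles infinite bounds and reports
#'     unboundedness.}
#'   \item{\code{"reference"}}{an independent pure-R standard-form tableau
#'     simplex using Bland's rule throughout, on shifted non-negative
#'     variables with explicit slack rows; deliberately different from the
#'     compiled backend in language, formulation and pivoting rule, it is the
#'     cross-check route on small fixtures (infinite bounds are boxed at
#'     1e6, so it is only suitable for problems with a bounded feasible
#'     optimum).}
#' }
#' The active backend is read from \code{option("chassisDesign.lpBackend")}.
#'
#' @param obj objective coefficient vector
#' @param A dense constraint matrix (equality rows)
#' @param b right-hand side
#' @param lb,ub variable bounds (\code{-Inf}/\code{Inf} allowed)
#' @param direction \code{"min"} or \code{"max"}
#' @param backend \code{"tableau"} or \code{"reference"}
#' @return a list with elements \code{status} (\code{"optimal"},
#'   \code{"infeasible"}, \code{"unbounded"} or \code{"maxiter"}),
#'   \code{objective} (on the requested direction's scale; \code{NA} unless
#'   optimal) and \code{x} (primal solution or \code{NULL})
#' @export
solveLP <- function(obj, A, b, lb, ub, direction = c("min", "max"),
                    backend = lpBackend()) {
  direction <- match.arg(direction)
  A <- as.matrix(A)
  stopifnot(length(obj) == ncol(A), length(b) == nrow(A),
            length(lb) == ncol(A), length(ub) == ncol(A))
  cc <- if (direction == "max") -obj else obj
  res <- switch(backend,
    tableau = .solve_tableau(A, b, cc, lb, ub),
    reference = .solve_reference(A, b, cc, lb, ub),
    stop("unknown LP backend: ", backend)
  )
  if (res$status == "optimal" && direction == "max")
    res$objective <- -res$objective
  res
}

#' @rdname solveLP
#' @export
lpBackend <- function() getOption("chassisDesign.lpBackend", "tableau")

.solve_tableau <- function(A, b, cc, lb, ub, tol = 1e-9, maxit = 50000L) {
  out <- .simplex_bounded(A, as.numeric(b), as.numeric(cc),
                          as.numeric(lb), as.numeric(ub), tol, maxit)
  status <- c("optimal", "infeasible", "unbounded", "maxiter")[out$status + 1L]
  list(status = status,
       objective = if (status == "optimal") out$objective else NA_real_,
       x = if (status == "optimal") as.numeric(out$x) else NULL)
}

# Independent reference route, pure R. Standard-form transformation: shift
# x = z + l (infinite bounds boxed at +-big), add one slack row per upper
# bound, artificial variables on the balance rows, and run a two-phase
# tableau simplex with Bland's rule from the first pivot — slower than the
# compiled backend but provably terminating and entirely separate from it.
.solve_reference <- function(A, b, cc, lb, ub, big = 1e6, tol = 1e-9,
                             maxit = 50000L) {
  n <- ncol(A); m <- nrow(A)
  l0 <- ifelse(is.finite(lb), lb, -big)
  u0 <- ifelse(is.finite(ub), ub, big)
  s <- pmax(u0 - l0, 0)
  bp <- as.numeric(b - A %*% l0)
  Af <- A
  flip <- bp < 0
  if (any(flip)) {
    Af[flip, ] <- -Af[flip, , drop = FALSE]
    bp[flip] <- -bp[flip]
  }
  # columns: z (n), w (n slacks for z <= s), a (m artificials)
  Tb <- rbind(cbind(Af, matrix(0, m, n), diag(m)),
              cbind(diag(n), diag(n), matrix(0, n, m)))
  rhs <- c(bp, s)
  nv <- 2L * n
  basis <- c(nv + seq_len(m), n + seq_len(n))
  xB <- rhs

  runPhase <- function(costs, nAllowed) {
    for (it in seq_len(maxit)) {
      yB <- costs[basis]
      red <- costs - as.numeric(yB %*% Tb)
      enter <- 0L
      for (j in seq_len(nAllowed)) {          # Bland: smallest index
        if (j %in% basis) next
        if (red[j] < -tol) { enter <- j; break }
      }
      if (enter == 0L) return("optimal")
      col <- Tb[, enter]
      cand <- which(col > tol)
      if (!length(cand)) return("unbounded")
      ratios <- xB[cand] / col[cand]
      rmin <- min(ratios)
      ties <- cand[ratios <= rmin + 1e-12]
      leave <- ties[which.min(basis[ties])]   # Bland on the leaving side
      piv <- col[leave]
      Tb[leave, ] <<- Tb[leave, ] / piv
      xB[leave] <<- xB[leave] / piv
      for (i in seq_len(m + n)) {
        if (i == leave || abs(Tb[i, enter]) <= 1e-14) next
        f <- Tb[i, enter]
        Tb[i, ] <<- Tb[i, ] - f * Tb[leave, ]
        xB[i] <<- xB[i] - f * xB[leave]
      }
      basis[leave] <<- enter
    }
    "maxiter"
  }

  st <- runPhase(c(rep(0, nv), rep(1, m)), nv + m)
  if (st != "optimal")
    return(list(status = st, objective = NA_real_, x = NULL))
  artVal <- sum(xB[basis > nv])
  if (artVal > 1e-7 * (1 + max(abs(b))))
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  st <- runPhase(c(cc, rep(0, n), rep(0, m)), nv)
  if (st != "optimal")
    return(list(status = st, objective = NA_real_, x = NULL))
  full <- numeric(nv + m)
  full[basis] <- xB
  x <- full[seq_len(n)] + l0
  list(status = "optimal", objective = sum(cc * x), x = x)
}

# Solve with additional ranged rows  rowLo <= R x <= rowHi  by introducing one
# slack variable per row (R x - s = 0, rowLo <= s <= rowHi).
.solveRanged <- function(obj, A, b, lb, ub, rows = NULL, rowLo = NULL,
                         rowHi = NULL, direction = "min",
                         backend = lpBackend()) {
  if (is.null(rows) || nrow(rows) == 0)
    return(solveLP(obj, A, b, lb, ub, direction, backend))
  k <- nrow(rows)
  n <- ncol(A)
  A2 <- rbind(cbind(A, matrix(0, nrow(A), k)),
              cbind(rows, -diag(k)))
  res <- solveLP(c(obj, rep(0, k)), A2, c(b, rep(0, k)),
                 c(lb, rowLo), c(ub, rowHi), direction, backend)
  if (!is.null(res$x)) res$x <- res$x[seq_len(n)]
  res
}

# FBA-style solve on a model: named objective coefficients, optional bound
# overrides (named vectors) and extra ranged rows over reaction fluxes
.modelLP <- function(model, objCoef, direction = "min",
                     lbOverride = NULL, ubOverride = NULL,
                     rows = NULL, rowLo = NULL, rowHi = NULL,
                     backend = lpBackend(), provenance = "FBA") {
  ids <- model@reactions$id
  lb <- model@reactions$lowerBound
  ub <- model@reactions$upperBound
  if (!is.null(lbOverride)) lb[match(names(lbOverride), ids)] <- lbOverride
  if (!is.null(ubOverride)) ub[match(names(ubOverride), ids)] <- ubOverride
  obj <- numeric(length(ids))
  obj[match(names(objCoef), ids)] <- objCoef
  A <- as.matrix(model@smat)
  res <- .solveRanged(obj, A, rep(0, nrow(A)), lb, ub,
                      rows = rows, rowLo = rowLo, rowHi = rowHi,
                      direction = direction, backend = backend)
  if (res$status != "optimal")
    return(methods::new("LPOutcome", status = res$status,
                        objective = NA_real_, flux = NULL))
  fl <- methods::new("FluxDistribution",
                     fluxes = stats::setNames(res$x, ids),
                     provenance = provenance,
                     objectiveValue = res$objective)
  methods::new("LPOutcome", status = "optimal", objective = res$objective,
               flux = fl)
}
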