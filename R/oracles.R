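#' Brute-force growth-coupling oracle
#'
#' Independent re-evaluation of every knockout set up to \code{maxKo}: no
#' pruning, no caching, its own LP assembly (reversed variable ordering,
#' stage-2 growth pin as an explicit constraint row rather than a bound
#' override) and its own inline yield/filter arithmetic. Output is comparable
#' 1:1 with [screenProduct()]; agreement between the two routes is the
#' correctness assertion for the screening stage. A size guard refuses
#' problems beyond exhaustive-desk scale.
#'
#' @param model a producer \linkS4class{MetabolicModel}
#' @param maxKo maximal knockout set size (1..3)
#' @param candidates candidate reaction ids (default
#'   [candidateDeletions()])
#' @param config a [filterConfig()]
#' @param delta stage-1 slack (same default rule as [twoStageOptimum()])
#' @param backend LP backend for the kernel solve
#' @return data.frame with columns knockout_set, n_ko, mu_max, p_min,
#'   v_glc, growth_yield, product_yield, survives
#' @export
bruteForceCouplingOracle <- function(model, maxKo,
                                     candidates = candidateDeletions(model),
                                     config = filterConfig(), delta = NULL,
                                     backend = lpBackend()) {
  stopifnot(maxKo >= 1, maxKo <= 3)
  nDesigns <- sum(choose(length(candidates), seq_len(maxKo)))
  if (nDesigns > 2500)
    stop("oracle size guard: ", nDesigns, " knockout sets (",
         length(candidates), " candidates at maxKo ", maxKo,
         ") exceeds exhaustive-desk scale")
  # deliberately different ordering from the screening path
  cand <- rev(sort(unique(candidates)))
  sets <- list()
  for (s in seq_len(min(maxKo, length(cand))))
    sets <- c(sets, utils::combn(cand, s, simplify = FALSE))

  ids <- model@reactions$id
  perm <- rev(seq_along(ids))          # reversed variable order
  S <- as.matrix(model@smat)[, perm, drop = FALSE]
  lb0 <- model@reactions$lowerBound[perm]
  ub0 <- model@reactions$upperBound[perm]
  pid <- match(.productExchangeOf(model), ids[perm])
  bid <- match(model@objectiveId, ids[perm])
  gid <- match(model@carbonExchangeId, ids[perm])
  m <- nrow(S)

  rows <- lapply(sets, function(kos) {
    lb <- lb0; ub <- ub0
    kk <- match(kos, ids[perm])
    lb[kk] <- 0; ub[kk] <- 0
    key <- paste(sort(kos), collapse = "+")
    row <- data.frame(knockout_set = key, n_ko = length(kos), mu_max = 0,
                      p_min = 0, v_glc = 0, growth_yield = 0,
                      product_yield = 0, stringsAsFactors = FALSE)
    obj1 <- numeric(length(ids)); obj1[bid] <- -1   # maximize growth
    s1 <- switch(backend,
                 tableau = .solve_tableau(S, rep(0, m), obj1, lb, ub),
                 reference = .solve_reference(S, rep(0, m), obj1, lb, ub))
    if (s1$status != "optimal") return(row)
    mu <- -s1$objective
    if (mu <= 1e-9) return(row)
    dlt <- if (is.null(delta)) max(1e-9, 1e-6 * abs(mu)) else delta
    # stage 2: min product with an explicit growth-pin row (slack variable)
    A2 <- rbind(cbind(S, 0), c(as.numeric(seq_along(ids) == bid), -1))
    obj2 <- c(as.numeric(seq_along(ids) == pid), 0)
    s2 <- switch(backend,
                 tableau = .solve_tableau(A2, rep(0, m + 1), obj2,
                                          c(lb, mu - dlt), c(ub, Inf)),
                 reference = .solve_reference(A2, rep(0, m + 1), obj2,
                                    c(lb, mu - dlt), c(ub, Inf)))
    if (s2$status != "optimal") return(row)
    vglc <- abs(s2$x[gid])
    row$mu_max <- mu
    row$p_min <- max(s2$objective, 0)
    row$v_glc <- vglc
    if (vglc > 1e-9) {
      row$growth_yield <- 1000 * mu / vglc
      row$product_yield <- row$p_min / vglc
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

#' Enumerate the vertices of a flux polytope
#'
#' Basic-feasible-solution enumeration for \eqn{\{v : A v = b, l \le v \le
#' u\}}: every choice of basic columns with the nonbasic variables pinned at
#' either bound is solved and kept if feasible. Exponential — intended as an
#' independent oracle for fixtures with at most ~10 variables.
#'
#' @param A equality constraint matrix
#' @param b right-hand side
#' @param lb,ub finite variable bounds
#' @param tol feasibility tolerance
#' @return matrix with one vertex per row (unique within \code{tol})
#' @export
enumerateVertices <- function(A, b, lb, ub, tol = 1e-8) {
  A <- as.matrix(A)
  n <- ncol(A)
  if (n > 12) stop("vertex enumeration guard: ", n, " variables")
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("vertex enumeration needs finite bounds")
  r <- qr(A)$rank
  verts <- list()
  basisSets <- if (r == 0) list(integer()) else
    utils::combn(n, r, simplify = FALSE)
  for (B in basisSets) {
    AB <- A[, B, drop = FALSE]
    if (length(B) && qr(AB)$rank < length(B)) next
    N <- setdiff(seq_len(n), B)
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(N)))
    if (!nrow(grid)) grid <- data.frame(row.names = 1)
    for (g in seq_len(nrow(grid))) {
      x <- numeric(n)
      if (length(N)) {
        atUpper <- as.logical(grid[g, ])
        x[N] <- ifelse(atUpper, ub[N], lb[N])
      }
      rhs <- if (length(N)) b - A[, N, drop = FALSE] %*% x[N] else b
      if (length(B)) {
        xb <- try(qr.solve(AB, rhs), silent = TRUE)
        if (inherits(xb, "try-error")) next
        x[B] <- xb
      }
      if (max(abs(A %*% x - b)) > tol) next
      if (all(x >= lb - tol) && all(x <= ub + tol))
        verts[[length(verts) + 1L]] <- pmin(pmax(x, lb), ub)
    }
  }
  if (!length(verts)) return(matrix(numeric(), 0, n))
  V <- do.call(rbind, verts)
  V[!duplicated(round(V / tol) * tol), , drop = FALSE]
}

#' Vertex-enumeration FBA oracle
#'
#' Maximizes (or minimizes) a reaction flux by evaluating every vertex of the
#' model's flux polytope — an independent check of the simplex route on
#' small, fully bounded fixtures.
#'
#' @param model a small \linkS4class{MetabolicModel} (finite bounds)
#' @param objective reaction id
#' @param direction \code{"max"} or \code{"min"}
#' @return list with \code{objective} (the optimum) and \code{vertices}
#' @export
fbaVertexOracle <- function(model, objective = objectiveReaction(model),
                            direction = c("max", "min")) {
  direction <- match.arg(direction)
  V <- enumerateVertices(as.matrix(model@smat),
                         rep(0, nMetabolites(model)),
                         model@reactions$lowerBound,
                         model@reactions$upperBound)
  if (!nrow(V)) stop("no feasible vertex found")
  j <- match(objective, model@reactions$id)
  vals <- V[, j]
  opt <- if (direction == "max") max(vals) else min(vals)
  list(objective = opt, vertices = V)
}

#' Vertex-enumeration essentiality oracle
#'
#' Flags a reaction as essential for product formation iff its flux is
#' bounded away from zero (same sign) across all vertices of the
#' product-anchored polytope; the minimal required flux is the smallest
#' magnitude over those vertices. Independent of the FVA route.
#'
#' @param model a small producer model with finite bounds
#' @param anchorFraction fraction of the maximal product flux enforced
#' @param tol zero tolerance
#' @return data.frame with columns id, essential, min_flux
#' @export
essentialityVertexOracle <- function(model, anchorFraction = 1 - 1e-6,
                                     tol = 1e-6) {
  pex <- .productExchangeOf(model)
  opt <- fba(model, pex, "max")
  stopifnot(opt@status == "optimal")
  ids <- model@reactions$id
  n <- length(ids)
  # anchored polytope: S v = 0 plus v_p - s = 0, s in [frac*opt, opt]
  A <- rbind(cbind(as.matrix(model@smat), 0),
             c(as.numeric(ids == pex), -1))
  lb <- c(model@reactions$lowerBound, anchorFraction * opt@objective)
  ub <- c(model@reactions$upperBound, opt@objective)
  V <- enumerateVertices(A, rep(0, nrow(A)), lb, ub)
  stopifnot(nrow(V) > 0)
  ess <- logical(n); mf <- numeric(n)
  for (j in seq_len(n)) {
    vals <- V[, j]
    if (all(vals > tol) || all(vals < -tol)) {
      ess[j] <- TRUE
      mf[j] <- min(abs(vals))
    }
  }
  data.frame(id = ids, essential = ess, min_flux = mf,
             stringsAsFactors = FALSE)
}
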