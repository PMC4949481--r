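#' Distances between product profiles
#'
#' \code{binaryDistance} is the asymmetric binary distance: the fraction of
#' discordant positions (exactly one of the two rows nonzero) among the
#' positions where at least one row is nonzero; a pair with an empty union
#' has distance 0 by convention. \code{euclideanDistance} is the standard L2
#' row distance. These are the two metrics used for essential-flux profiles
#' and stoichiometric precursor-requirement profiles respectively; both
#' delegate to \code{stats::dist}.
#'
#' @param matrix numeric matrix with products as rows
#' @return a \code{stats::dist} object
#' @examples
#' m <- rbind(x = c(1, 1, 1, 0), y = c(1, 0, 0, 1))
#' binaryDistance(m)   # 3/4
#' @export
binaryDistance <- function(matrix) {
  d <- stats::dist(matrix, method = "binary")
  d[is.nan(d)] <- 0  # empty-union pairs
  d
}

#' @rdname binaryDistance
#' @export
euclideanDistance <- function(matrix) {
  stats::dist(matrix, method = "euclidean")
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerates the closest pair of clusters at each step, with the distance
#' between clusters defined as the unweighted mean of all member pairwise
#' distances. Ties are broken deterministically by the lexicographically
#' smallest pair of cluster labels (each cluster labelled by its smallest
#' member), so the tree is invariant to row permutation of the input even
#' when distances tie. Returns a standard \code{hclust} object
#' (\code{method = "average"}), directly comparable with
#' \code{stats::hclust}.
#'
#' @param d a \code{stats::dist} object or symmetric distance matrix with at
#'   least two rows
#' @return an object of class \code{hclust}
#' @examples
#' d <- as.dist(rbind(c(0, .2, .6), c(.2, 0, .8), c(.6, .8, 0)))
#' averageLinkage(d)$height   # 0.2, then (0.6 + 0.8) / 2 = 0.7
#' @export
averageLinkage <- function(d) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 2) stop("need at least two items to cluster")
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  # active clusters: leaf members, hclust code, size, smallest label
  cl <- lapply(seq_len(n), function(i)
    list(code = -i, size = 1L, minLabel = labels[i]))
  CD <- D
  diag(CD) <- Inf
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  nodes <- vector("list", n - 1)  # leaf indices per internal node
  leafSets <- as.list(seq_len(n))
  for (step in seq_len(n - 1)) {
    mn <- min(CD)
    cand <- which(CD <= mn + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # lexicographic tie-break on the (sorted) pair of cluster labels
    keys <- apply(cand, 1, function(ij) {
      lab <- sort(c(cl[[ij[1]]]$minLabel, cl[[ij[2]]]$minLabel))
      paste(lab, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    merge[step, ] <- sort(c(cl[[i]]$code, cl[[j]]$code))
    height[step] <- CD[i, j]
    nodes[[step]] <- c(leafSets[[i]], leafSets[[j]])
    # UPGMA update: size-weighted mean reproduces the unweighted mean of
    # all member pairwise distances
    ni <- cl[[i]]$size; nj <- cl[[j]]$size
    newRow <- (ni * CD[i, ] + nj * CD[j, ]) / (ni + nj)
    keep <- setdiff(seq_len(nrow(CD)), c(i, j))
    CD2 <- rbind(cbind(CD[keep, keep, drop = FALSE], newRow[keep]),
                 c(newRow[keep], Inf))
    CD <- CD2
    cl2 <- cl[keep]
    cl2[[length(cl2) + 1L]] <- list(code = step, size = ni + nj,
                                    minLabel = min(cl[[i]]$minLabel,
                                                   cl[[j]]$minLabel))
    cl <- cl2
    leafSets <- c(leafSets[keep], list(nodes[[step]]))
  }
  ord <- .hclustOrder(merge, n)
  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, method = "average",
                 call = match.call(), dist.method = "unspecified"),
            class = "hclust")
}

.hclustOrder <- function(merge, n) {
  expand <- function(code) {
    if (code < 0) return(-code)
    c(expand(merge[code, 1]), expand(merge[code, 2]))
  }
  expand(nrow(merge))
}

#' Write a cluster tree as Newick
#'
#' Converts an \code{hclust} tree to a phylogeny (branch lengths from merge
#' heights) and writes Newick, so dendrograms can move to any tree viewer.
#'
#' @param hc an \code{hclust} object
#' @param path output file
#' @return invisibly the Newick string
#' @export
writeNewick <- function(hc, path) {
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Stoichiometric precursor-requirement matrix
#'
#' For each pathway, computes the net consumption (negative) or production
#' (positive) of every native host metabolite per unit of product secreted:
#' the pathway reactions are solved for the minimal-total-flux distribution
#' that drives one unit of flux through the product exchange, balancing only
#' the pathway's own new metabolites while native metabolites act as free
#' boundary species. Cofactors and byproducts are reported alongside carbon
#' precursors — the interactions of the heterologous pathway with the native
#' network, which is what groups products into precursor/cofactor families.
#'
#' @param pathways list of \linkS4class{PathwayDefinition}
#' @param host the host \linkS4class{MetabolicModel}
#' @param tol entries below this magnitude are set to 0
#' @return matrix with products as rows and native metabolites as columns,
#'   attribute \code{"mode"} = \code{"precursor-stoichiometry"}
#' @export
precursorMatrix <- function(pathways, host, tol = 1e-9) {
  hostMets <- host@metabolites$id
  profiles <- lapply(pathways, function(pw) {
    entries <- pw@reactions
    ids <- vapply(entries, `[[`, character(1), "id")
    mets <- unique(unlist(lapply(entries, function(r) names(r$stoich))))
    S <- matrix(0, length(mets), length(ids),
                dimnames = list(mets, ids))
    for (k in seq_along(entries))
      S[names(entries[[k]]$stoich), k] <- entries[[k]]$stoich
    lb <- vapply(entries, function(r) as.numeric(r$lb %||% 0), numeric(1))
    ub <- vapply(entries, function(r) as.numeric(r$ub %||% 1000), numeric(1))
    iex <- match(pw@exchangeId, ids)
    lb[iex] <- 1; ub[iex] <- 1   # one unit of product secreted
    balance <- setdiff(mets, hostMets)
    Sb <- S[balance, , drop = FALSE]
    # minimal-total-flux routing: split into forward/backward parts
    n <- length(ids)
    A <- cbind(Sb, -Sb)
    res <- solveLP(rep(1, 2 * n), A, rep(0, nrow(Sb)),
                   c(pmax(lb, 0), pmax(-ub, 0)),
                   c(pmax(ub, 0), pmax(-lb, 0)), "min")
    if (res$status != "optimal")
      stop("pathway cannot produce product '", pw@productId,
           "' (status ", res$status, ")")
    v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
    native <- intersect(mets, hostMets)
    net <- as.vector(S[native, , drop = FALSE] %*% v)
    stats::setNames(net, native)
  })
  cols <- sort(unique(unlist(lapply(profiles, names))))
  M <- matrix(0, length(pathways), length(cols),
              dimnames = list(vapply(pathways, function(p) p@productId,
                                     character(1)), cols))
  for (k in seq_along(profiles))
    M[k, names(profiles[[k]])] <- profiles[[k]]
  M[abs(M) < tol] <- 0
  attr(M, "mode") <- "precursor-stoichiometry"
  M
}
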