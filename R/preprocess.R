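#' @include ilp-solve.R distance-oracles.R
NULL

## Greedy resolved matching for one genome pair: marker pairs whose
## adjacency contexts agree close short alternating cycles in the
## comparison graph, so pairs are fixed in decreasing context-agreement
## order (agreement 2 closes the shortest cycles), then remaining copies
## are matched arbitrarily up to maximum cardinality.
greedyMatching <- function(gA, gB) {
  partner <- function(g) {
    a <- g@adjacencies
    c(stats::setNames(a$e2, a$e1), stats::setNames(a$e1, a$e2))
  }
  pA <- partner(gA); pB <- partner(gB)
  famOfA <- stats::setNames(gA@markers$family, gA@markers$id)
  famOfB <- stats::setNames(gB@markers$family, gB@markers$id)
  ctx <- function(p, fam, m, side) {
    e <- p[[extremity(m, side)]]
    if (is.null(e) || isTelomericExtremity(e)) "TEL"
    else paste0(fam[[extremityMarker(e)]], ":", extremitySide(e))
  }
  famsA <- split(gA@markers$id, gA@markers$family)
  famsB <- split(gB@markers$id, gB@markers$family)
  cand <- list()
  for (f in intersect(names(famsA), names(famsB))) {
    for (ma in famsA[[f]]) for (mb in famsB[[f]]) {
      score <- sum(ctx(pA, famOfA, ma, "t") == ctx(pB, famOfB, mb, "t"),
                   ctx(pA, famOfA, ma, "h") == ctx(pB, famOfB, mb, "h"))
      cand[[length(cand) + 1L]] <- list(a = ma, b = mb, s = score)
    }
  }
  if (!length(cand)) return(data.frame(a = character(), b = character()))
  ord <- order(-vapply(cand, `[[`, numeric(1), "s"),
               vapply(cand, `[[`, character(1), "a"),
               vapply(cand, `[[`, character(1), "b"))
  usedA <- character(); usedB <- character()
  a <- character(); bb <- character()
  for (k in ord) {
    p <- cand[[k]]
    if (p$a %in% usedA || p$b %in% usedB) next
    usedA <- c(usedA, p$a); usedB <- c(usedB, p$b)
    a <- c(a, p$a); bb <- c(bb, p$b)
  }
  data.frame(a = a, b = bb, stringsAsFactors = FALSE)
}

#' Compute a feasible initial solution for the small parsimony ILP
#'
#' Two steps mirroring the global and local levels of the ILP: every
#' ancestral degenerate genome is linearized by the weight-aware
#' maximum-weight matching of \code{\link{tryLinearize}}, then a resolved
#' matching per branch is chosen greedily, preferring marker pairings that
#' close short cycles in the comparison graph.  The resulting objective is
#' an upper bound on the optimum.
#'
#' @param phylogeny a \code{\linkS4class{Phylogeny}} with genomes on all
#'   nodes; ancestral genomes must be linearizable (augment first if not).
#' @param weights per-node candidate weights (as in
#'   \code{\link{buildSppModel}}).
#' @param alpha objective trade-off in [0, 1].
#' @return list with \code{linearizations}, \code{matchings} (per branch),
#'   \code{distances} (data.frame parent/child/distance) and
#'   \code{objective}.
#' @export
initialSolution <- function(phylogeny, weights = NULL, alpha = 1) {
  nodes <- phylogeny@nodes
  internal <- setdiff(nodes, phylogeny@leaves)
  getW <- function(nd) {
    w <- if (is.list(weights)) weights[[nd]] else weights
    if (is.null(w)) numeric() else w
  }
  lin <- list()
  for (lf in intersect(phylogeny@leaves, nodes))
    lin[[lf]] <- phylogeny@genomes[[lf]]
  if (length(internal)) {
    res <- tryLinearizeList(lapply(internal, function(nd)
      phylogeny@genomes[[nd]]), lapply(internal, getW))
    for (i in seq_along(internal)) {
      if (!res[[i]]$feasible)
        stop("node '", internal[i], "' is not linearizable; augment it ",
             "first (augmentLocalGuarantees/augmentSafer)")
      lin[[internal[i]]] <- res[[i]]$linearization
    }
  }
  edges <- phylogeny@edges
  matchings <- list(); dist <- integer(nrow(edges)); dTot <- 0
  for (i in seq_len(nrow(edges))) {
    en <- paste0(edges$parent[i], "->", edges$child[i])
    m <- greedyMatching(lin[[edges$parent[i]]], lin[[edges$child[i]]])
    matchings[[en]] <- m
    dist[i] <- dcjIndelDistance(componentCensus(lin[[edges$parent[i]]],
                                                lin[[edges$child[i]]], m))
    dTot <- dTot + dist[i]
  }
  wTot <- 0
  deg <- table(factor(c(edges$parent, edges$child), levels = nodes))
  for (nd in nodes) {
    w <- getW(nd)
    if (!length(w)) next
    a <- lin[[nd]]@adjacencies
    k <- adjKeyAnon(a$e1, a$e2)
    wTot <- wTot + deg[[nd]] * sum(w[intersect(k, names(w))])
  }
  list(linearizations = lin, matchings = matchings,
       distances = data.frame(parent = edges$parent, child = edges$child,
                              distance = dist, stringsAsFactors = FALSE),
       objective = alpha * dTot - (1 - alpha) * wTot)
}

#' Pairwise leaf distance lower bounds
#'
#' For every pair of leaves, computes the pairwise DCJ-indel distance under
#' the maximum matching model (exhaustively for small instances, via the
#' pairwise ILP otherwise).  Any path of intermediate genomes between two
#' leaves must use at least as many operations, so the summed branch
#' distances on the connecting tree path can be bounded from below by these
#' values (the C.opt cuts of \code{\link{buildSppModel}}).
#'
#' @param phylogeny a \code{\linkS4class{Phylogeny}} with genomes on its
#'   leaves.
#' @param enumBudget maximum matchings to enumerate before switching to the
#'   ILP.
#' @param timeLimit per-pair ILP limit in seconds.
#' @return data.frame with columns \code{leaf1}, \code{leaf2},
#'   \code{distance}.
#' @export
leafPairLowerBounds <- function(phylogeny, enumBudget = 2000L,
                                timeLimit = NULL) {
  lv <- phylogeny@leaves
  if (length(lv) < 2L)
    return(data.frame(leaf1 = character(), leaf2 = character(),
                      distance = integer()))
  prs <- utils::combn(lv, 2L)
  d <- integer(ncol(prs))
  for (i in seq_len(ncol(prs))) {
    gA <- phylogeny@genomes[[prs[1, i]]]
    gB <- phylogeny@genomes[[prs[2, i]]]
    d[i] <- tryCatch(distanceMaxMatching(gA, gB, budget = enumBudget),
                     error = function(e)
                       dcjIndelDistanceILP(gA, gB, timeLimit = timeLimit))
  }
  data.frame(leaf1 = prs[1, ], leaf2 = prs[2, ], distance = d,
             stringsAsFactors = FALSE)
}
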