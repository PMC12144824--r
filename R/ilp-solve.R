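#' @include ilp-build.R
NULL

#' Solve a small parsimony ILP and decode the solution
#'
#' @param model an \code{\linkS4class{ILPModel}} from
#'   \code{\link{buildSppModel}}.
#' @param phylogeny the phylogeny the model was built from.
#' @param timeLimit wall-clock limit in seconds (\code{NULL} = none).
#' @param warmStart optional feasible solution from
#'   \code{\link{initialSolution}}; it is validated and used as the
#'   reported incumbent if the solver fails to produce one within the time
#'   limit.
#' @return an \code{\linkS4class{SPPSolution}}.
#' @export
solveSppModel <- function(model, phylogeny, timeLimit = NULL,
                          warmStart = NULL) {
  sol <- solveModel(model, timeLimit = timeLimit)
  if (is.null(sol$x)) {
    if (!is.null(warmStart))
      return(new("SPPSolution",
                 linearizations = warmStart$linearizations,
                 distances = warmStart$distances,
                 matchings = warmStart$matchings,
                 objective = warmStart$objective,
                 recomputedObjective = warmStart$objective,
                 status = "warm-start fallback (solver returned no incumbent)",
                 gap = Inf))
    stop("solver returned no solution: ", sol$message)
  }
  decodeSolution(model, sol, phylogeny)
}

#' Decode a solver assignment into genomes and distances
#'
#' Reconstitutes one linearization per node from the presence and selection
#' variables (validated against the genome definition), reads the per-branch
#' distances and matchings, and independently recomputes the objective from
#' the decoded linearizations via the closed-form distance.  A mismatch
#' between a proven-optimal solver distance and the recomputed distance is
#' an internal consistency failure and raises an error.
#'
#' @param model an \code{\linkS4class{ILPModel}}.
#' @param sol a solution from \code{\link{solveModels}}.
#' @param phylogeny the phylogeny the model was built from.
#' @return an \code{\linkS4class{SPPSolution}}.
#' @export
decodeSolution <- function(model, sol, phylogeny) {
  x <- sol$x
  maps <- model@maps
  alpha <- maps$alpha
  lin <- list()
  wPart <- 0
  for (nd in names(maps$nodes)) {
    nm <- maps$nodes[[nd]]
    D <- phylogeny@genomes[[nd]]
    gv <- x[nm$gIdx] > 0.5
    presentMarkers <- D@markers$id[gv[match(extremity(D@markers$id, "t"),
                                            names(nm$gIdx))]]
    selRows <- x[nm$selIdx] > 0.5
    a <- nm$adjacencies[selRows, , drop = FALSE]
    usedTel <- extremityMarker(
      c(a$e1[isTelomericExtremity(a$e1)], a$e2[isTelomericExtremity(a$e2)]))
    lin[[nd]] <- Genome(nd,
                        D@markers[D@markers$id %in% presentMarkers, ,
                                  drop = FALSE],
                        telomeres = usedTel, adjacencies = a)
    wPart <- wPart + maps$degree[[nd]] * sum(nm$weights[selRows])
  }
  dist <- data.frame(parent = character(), child = character(),
                     distance = integer(), stringsAsFactors = FALSE)
  matchings <- list()
  dPart <- 0
  proven <- isTRUE(sol$status == 0) && isTRUE((sol$gap %||% 0) <= 1e-9)
  for (en in names(maps$edges)) {
    em <- maps$edges[[en]]
    fE <- as.integer(round(x[em$f]))
    sel <- x[em$pairVar] > 0.5
    m <- data.frame(a = em$pairA[sel], b = em$pairB[sel],
                    stringsAsFactors = FALSE)
    matchings[[en]] <- m
    dTrue <- dcjIndelDistance(componentCensus(lin[[em$nodeA]],
                                              lin[[em$nodeB]], m))
    if (proven && alpha > 0 && dTrue != fE)
      stop("internal consistency failure on branch ", en,
           ": ILP distance ", fE, " != recomputed distance ", dTrue)
    dPart <- dPart + dTrue
    dist <- rbind(dist, data.frame(parent = em$nodeA, child = em$nodeB,
                                   distance = fE, stringsAsFactors = FALSE))
  }
  new("SPPSolution", linearizations = lin, distances = dist,
      matchings = matchings,
      objective = sol$objective,
      recomputedObjective = alpha * dPart - (1 - alpha) * wPart,
      status = sol$message, gap = sol$gap %||% 0)
}

setMethod("show", "SPPSolution", function(object) {
  cat("SPPSolution: ", length(object@linearizations), " linearized genomes, ",
      "total tree distance ", sum(object@distances$distance),
      ", objective ", format(object@objective, digits = 6),
      " (gap ", format(object@gap, digits = 3), ")\n", sep = "")
})

#' Total tree distance of a solution
#'
#' @param solution an \code{\linkS4class{SPPSolution}}.
#' @return integer sum of per-branch distances.
#' @export
treeDistance <- function(solution) sum(solution@distances$distance)

#' Solve the weighted small parsimony linearization problem
#'
#' High-level driver: optionally augments the internal nodes' degenerate
#' genomes with telomeres (local-guarantee or safer mode), builds the ILP
#' and solves it.
#'
#' @inheritParams buildSppModel
#' @param augment "none", "local" (telomeres added in components without
#'   local linearizability guarantees) or "safer" (every extremity of every
#'   internal node gains a candidate telomere).
#' @param telomereWeight candidate weight of telomeric adjacencies added by
#'   safer-mode augmentation.
#' @param timeLimit solver wall-clock limit in seconds.
#' @param warmStart optional \code{\link{initialSolution}} result.
#' @return an \code{\linkS4class{SPPSolution}}.
#' @export
solveSpp <- function(phylogeny, weights = NULL, bounds = NULL, alpha = 1,
                     betaEmulation = NULL,
                     augment = c("none", "local", "safer"),
                     telomereWeight = 0,
                     singletonMode = c("auto", "enumerate", "count"),
                     lowerBounds = NULL, timeLimit = NULL, warmStart = NULL) {
  augment <- match.arg(augment)
  singletonMode <- match.arg(singletonMode)
  if (is.null(weights)) weights <- list()
  if (!is.list(weights))
    weights <- stats::setNames(rep(list(weights), length(phylogeny@nodes)),
                               phylogeny@nodes)
  internal <- setdiff(phylogeny@nodes, phylogeny@leaves)
  if (augment != "none") {
    for (nd in internal) {
      D <- phylogeny@genomes[[nd]]
      if (augment == "local") {
        phylogeny@genomes[[nd]] <- augmentLocalGuarantees(D)
      } else {
        res <- augmentSafer(D, telomereWeight)
        phylogeny@genomes[[nd]] <- res$genome
        w <- weights[[nd]] %||% numeric()
        add <- setdiff(names(res$weights), names(w))
        weights[[nd]] <- c(w, res$weights[add])
      }
    }
  }
  model <- buildSppModel(phylogeny, weights = weights, bounds = bounds,
                         alpha = alpha, betaEmulation = betaEmulation,
                         singletonMode = singletonMode,
                         lowerBounds = lowerBounds)
  solveSppModel(model, phylogeny, timeLimit = timeLimit,
                warmStart = warmStart)
}

#' Pairwise DCJ-indel distance via the ILP
#'
#' Builds the two-node small parsimony instance for a genome pair and
#' returns the proven-optimal distance under the maximum matching model.
#'
#' @param genomeA,genomeB two genomes (homology by family labels).
#' @param timeLimit solver limit in seconds.
#' @return non-negative integer distance.
#' @export
dcjIndelDistanceILP <- function(genomeA, genomeB, timeLimit = NULL) {
  phy <- pairPhylogeny(genomeA, genomeB)
  sol <- solveSpp(phy, alpha = 1, timeLimit = timeLimit)
  treeDistance(sol)
}

## Two-node phylogeny A -> B used for pairwise distances.
pairPhylogeny <- function(genomeA, genomeB) {
  ga <- genomeA; gb <- genomeB
  ga@name <- "A."; gb@name <- "B."
  new("Phylogeny", nodes = c("B.", "A."),
      edges = data.frame(parent = "A.", child = "B.",
                         stringsAsFactors = FALSE),
      root = "A.", leaves = c("B."),
      genomes = list("A." = ga, "B." = gb))
}
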