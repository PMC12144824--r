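#' @include milp-backend.R genome.R
NULL

#' Coverage weight of a candidate adjacency
#'
#' The weight used by the linearizability test: the number of non-telomeric
#' extremities incident to the adjacency (2 for extremity-extremity, 1 for
#' extremity-telomere; telomere-telomere adjacencies do not exist).
#'
#' @param e1,e2 extremity encodings.
#' @return integer vector in \{1, 2\}.
#' @export
linearizationWeight <- function(e1, e2) {
  if (any(isTelomericExtremity(e1) & isTelomericExtremity(e2)))
    stop("adjacency joining two telomeres is not allowed")
  2L - isTelomericExtremity(e1) - isTelomericExtremity(e2)
}

## Build the maximum-weight matching MILP for one degenerate genome.
linearizeModel <- function(D, weights = NULL) {
  b <- newModelBuilder()
  a <- D@adjacencies
  n <- nrow(a)
  covw <- if (n) linearizationWeight(a$e1, a$e2) else integer()
  candw <- rep(0, n)
  if (!is.null(weights) && n) {
    k <- adjKeyAnon(a$e1, a$e2)
    hit <- k %in% names(weights)
    candw[hit] <- weights[k[hit]]
  }
  scale <- sum(abs(candw)) + 1
  ## primary objective: coverage (Lemma 1); secondary: candidate weights
  for (i in seq_len(n))
    addVar(b, paste0("sel", i), 0, 1, "B",
           obj = -(scale * covw[i] + candw[i]))
  ends <- c(a$e1, a$e2)
  for (v in unique(ends)) {
    idx <- which(a$e1 == v | a$e2 == v)
    addCon(b, idx, rep(1, length(idx)), NA, 1)
  }
  finalizeModel(b, maps = list(covw = covw, candw = candw, scale = scale))
}

decodeLinearization <- function(D, model, sol) {
  sel <- which(sol$x > 0.5)
  covered <- sum(model@maps$covw[sel])
  nExt <- 2L * nrow(D@markers)
  feasible <- covered == nExt
  lin <- NULL
  if (feasible) {
    a <- D@adjacencies[sel, , drop = FALSE]
    usedTel <- extremityMarker(
      c(a$e1[isTelomericExtremity(a$e1)], a$e2[isTelomericExtremity(a$e2)]))
    lin <- Genome(D@name, D@markers, telomeres = usedTel, adjacencies = a)
  }
  list(feasible = feasible, linearization = lin,
       matchingWeight = as.integer(covered),
       candidateWeight = sum(model@maps$candw[sel]))
}

#' Test linearizability and construct a linearization
#'
#' A degenerate genome is linearizable if and only if a maximum-weight
#' matching on its candidate adjacencies, weighted by incident non-telomeric
#' extremities, covers all marker extremities (total weight |E(D)|).  When
#' candidate adjacency weights are supplied, they break ties among the
#' maximum-coverage matchings (the primary objective is always coverage).
#'
#' @param D a \code{\linkS4class{DegenerateGenome}}.
#' @param weights optional named numeric vector of candidate adjacency
#'   weights keyed by telomere-anonymized adjacency key (see
#'   \code{\link{readAdjacencies}}).
#' @return list with \code{feasible} (logical), \code{linearization}
#'   (a \code{\linkS4class{Genome}} or \code{NULL}), \code{matchingWeight}
#'   (covered extremities) and \code{candidateWeight} (summed candidate
#'   weight of the selected adjacencies).
#' @examples
#' \donttest{
#' gs <- readUnimog(">A\n1 2 |")
#' tryLinearize(as(gs$A, "DegenerateGenome"))$feasible
#' }
#' @export
tryLinearize <- function(D, weights = NULL) {
  tryLinearizeList(list(D), list(weights))[[1]]
}

#' @rdname tryLinearize
#' @param Ds list of degenerate genomes (solved in one backend call).
#' @param weightsList optional list of weight vectors, recycled to
#'   \code{length(Ds)}.
#' @export
tryLinearizeList <- function(Ds, weightsList = NULL) {
  if (is.null(weightsList)) weightsList <- vector("list", length(Ds))
  if (length(weightsList) == 1L && length(Ds) > 1L)
    weightsList <- rep(weightsList, length(Ds))
  models <- mapply(linearizeModel, Ds, weightsList, SIMPLIFY = FALSE)
  sols <- solveModels(models)
  mapply(function(D, m, s) {
    if (is.null(s$x)) stop("linearization solve failed: ", s$message)
    decodeLinearization(D, m, s)
  }, Ds, models, sols, SIMPLIFY = FALSE)
}

## Connected components of the candidate-adjacency graph on extremities and
## telomeres.  (Marker edges play no role here: local linearizability asks
## for a perfect matching among the candidate adjacencies of a component,
## which Lemma-2 style yields a linearization component-wise.)
degenerateComponents <- function(D) {
  verts <- c(extremities(D), extremity(D@telomeres, "o"))
  if (!length(verts)) return(list())
  a <- D@adjacencies
  g <- igraph::graph_from_data_frame(
    data.frame(from = a$e1, to = a$e2, stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = verts))
  comp <- igraph::components(g)
  lapply(seq_len(comp$no), function(ci) {
    vids <- names(comp$membership)[comp$membership == ci]
    igraph::induced_subgraph(g, vids)
  })
}

## Even simple paths, even simple cycles and fully connected components of
## even size all carry perfect matchings, so such components never force
## extra telomeres.
locallyLinearizable <- function(sub) {
  nv <- igraph::vcount(sub)
  if (nv %% 2L != 0L) return(FALSE)
  deg <- igraph::degree(sub)
  ne <- igraph::ecount(sub)
  isPath <- ne == nv - 1L && max(deg) <= 2L
  isCycle <- nv >= 2L && ne == nv && all(deg == 2L)
  if (isPath || isCycle) return(TRUE)
  ends <- igraph::ends(sub, igraph::E(sub))
  keys <- unique(adjKey(ends[, 1], ends[, 2]))
  length(keys) == choose(nv, 2L)
}

telomereIdFor <- function(ext) paste0("t_", gsub(":", ".", ext, fixed = TRUE))

addTelomericAdjacencies <- function(D, exts) {
  if (!length(exts)) return(list(genome = D, added = character()))
  tel <- telomereIdFor(exts)
  keep <- !(tel %in% D@telomeres)
  tel <- tel[keep]; exts <- exts[keep]
  if (!length(exts)) return(list(genome = D, added = character()))
  a2 <- rbind(D@adjacencies,
              data.frame(e1 = exts, e2 = extremity(tel, "o"),
                         stringsAsFactors = FALSE))
  D2 <- DegenerateGenome(D@name, D@markers,
                         telomeres = c(D@telomeres, tel),
                         adjacencies = a2)
  list(genome = D2, added = adjKeyAnon(exts, extremity(tel, "o")))
}

#' Augment a degenerate genome for local linearizability guarantees
#'
#' Decomposes the candidate-adjacency graph into connected components.  A
#' component is locally linearizable when its vertex count is even and it
#' is a simple path, a simple cycle, or fully connected by adjacency
#' edges -- shapes that guarantee a perfect matching among its candidate
#' adjacencies, and perfect matchings per component assemble into a
#' linearization.  In every other component, each marker extremity gains a
#' fresh telomere and telomeric candidate adjacency, making the whole
#' genome linearizable.
#'
#' @param D a \code{\linkS4class{DegenerateGenome}}.
#' @return the augmented \code{\linkS4class{DegenerateGenome}}.
#' @export
augmentLocalGuarantees <- function(D) {
  bad <- character()
  for (sub in degenerateComponents(D)) {
    if (!locallyLinearizable(sub)) {
      vn <- igraph::V(sub)$name
      bad <- c(bad, vn[!isTelomericExtremity(vn)])
    }
  }
  addTelomericAdjacencies(D, bad)$genome
}

#' Augment a degenerate genome in safer linearization mode
#'
#' Connects every marker extremity to an artificially introduced telomere,
#' even in components with local guarantees, reflecting the uncertainty of
#' inferred ancestral adjacencies.  Added telomeric adjacencies carry a
#' configurable candidate weight (default 0).  Idempotent: extremities
#' already carrying their artificial telomere are left untouched.
#'
#' @param D a \code{\linkS4class{DegenerateGenome}}.
#' @param telomereWeight weight assigned to each added telomeric adjacency.
#' @return list with \code{genome} (augmented degenerate genome) and
#'   \code{weights} (named numeric: weight delta for the added telomeric
#'   adjacencies, keyed by anonymized adjacency key).
#' @export
augmentSafer <- function(D, telomereWeight = 0) {
  res <- addTelomericAdjacencies(D, extremities(D))
  w <- stats::setNames(rep(telomereWeight, length(res$added)), res$added)
  list(genome = res$genome, weights = w)
}
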