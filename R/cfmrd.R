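#' @include genome.R
NULL

## Vertex ids inside a CFMRD are "<side>|<extremity>".  Ranks are assigned
## deterministically: telomeres of A, telomeres of B, extremities of A,
## extremities of B, each block sorted lexicographically.  Telomeres rank
## below marker extremities so that path components (which always end in
## telomeres) can never claim a cycle report in the ILP, and A before B so
## that every non-singleton cycle can claim its report on the A side.
cfmrdVertices <- function(genomeA, genomeB) {
  mk <- function(g, side) {
    ext <- sort(extremities(g))
    tel <- sort(extremity(g@telomeres, "o"))
    if (!length(ext) && !length(tel))
      return(data.frame(vid = character(), side = character(),
                        extremity = character(), marker = character(),
                        telomeric = logical(), block = integer(),
                        stringsAsFactors = FALSE))
    data.frame(
      vid = paste0(side, "|", c(tel, ext)),
      side = side,
      extremity = c(tel, ext),
      marker = c(rep(NA_character_, length(tel)), extremityMarker(ext)),
      telomeric = c(rep(TRUE, length(tel)), rep(FALSE, length(ext))),
      block = c(rep(1L, length(tel)), rep(2L, length(ext))),
      stringsAsFactors = FALSE)
  }
  va <- mk(genomeA, "A"); vb <- mk(genomeB, "B")
  v <- rbind(va, vb)
  v <- v[order(v$block, match(v$side, c("A", "B")), v$extremity), ]
  v$rank <- seq_len(nrow(v))
  v$block <- NULL
  rownames(v) <- NULL
  v
}

#' Build the capping-free multi-relational diagram of two genomes
#'
#' Vertices are the extremities and telomeres of both genomes; adjacency
#' edges are the adjacencies of both genomes, self edges the marker edges of
#' singular markers (families present in only one of the genomes), and
#' extremity edges join equivalent extremities across the genomes (tails
#' with tails, heads with heads of homologous markers).  No edge ever joins
#' two telomeres.
#'
#' @param genomeA,genomeB two (possibly degenerate) genomes.
#' @return a \code{\linkS4class{CFMRD}}.
#' @examples
#' gs <- readUnimog(">A\n1 2 |\n>B\n1 -2 |")
#' buildCFMRD(gs$A, gs$B)
#' @export
buildCFMRD <- function(genomeA, genomeB) {
  v <- cfmrdVertices(genomeA, genomeB)
  edges <- list()
  addE <- function(side, e1, e2, type) {
    if (!length(e1)) return()
    edges[[length(edges) + 1L]] <<- data.frame(
      u = paste0(side[1], "|", e1), v = paste0(side[2], "|", e2),
      type = type, stringsAsFactors = FALSE)
  }
  aA <- genomeA@adjacencies; aB <- genomeB@adjacencies
  addE(c("A", "A"), aA$e1, aA$e2, "adj")
  addE(c("B", "B"), aB$e1, aB$e2, "adj")
  famA <- split(genomeA@markers$id, genomeA@markers$family)
  famB <- split(genomeB@markers$id, genomeB@markers$family)
  ## self edges: singular markers only (family absent from the other genome)
  singA <- unlist(famA[setdiff(names(famA), names(famB))], use.names = FALSE)
  singB <- unlist(famB[setdiff(names(famB), names(famA))], use.names = FALSE)
  addE(c("A", "A"), extremity(singA, "t"), extremity(singA, "h"), "self")
  addE(c("B", "B"), extremity(singB, "t"), extremity(singB, "h"), "self")
  ## extremity edges: all pairs of homologous markers across genomes
  for (f in intersect(names(famA), names(famB))) {
    pairs <- expand.grid(a = famA[[f]], b = famB[[f]],
                         stringsAsFactors = FALSE)
    addE(c("A", "B"), extremity(pairs$a, "t"), extremity(pairs$b, "t"), "ext")
    addE(c("A", "B"), extremity(pairs$a, "h"), extremity(pairs$b, "h"), "ext")
  }
  e <- if (length(edges)) do.call(rbind, edges) else
    data.frame(u = character(), v = character(), type = character())
  new("CFMRD", vertices = v, edges = e, genomeA = as(genomeA, "DegenerateGenome"),
      genomeB = as(genomeB, "DegenerateGenome"))
}

setMethod("show", "CFMRD", function(object) {
  tab <- table(factor(object@edges$type, levels = c("adj", "self", "ext")))
  cat("CFMRD of '", object@genomeA@name, "' vs '", object@genomeB@name,
      "': ", nrow(object@vertices), " vertices; ",
      tab[["adj"]], " adjacency, ", tab[["self"]], " self, ",
      tab[["ext"]], " extremity edges\n", sep = "")
})

#' Export a CFMRD as graphviz dot
#'
#' @param cfmrd a \code{\linkS4class{CFMRD}}.
#' @param file optional output path.
#' @return dot text (invisibly when written to \code{file}).
#' @export
cfmrdToDot <- function(cfmrd, file = NULL) {
  esty <- c(adj = "solid", self = "dashed", ext = "dotted")
  lines <- c("graph CFMRD {",
             paste0("  \"", cfmrd@vertices$vid, "\";"),
             paste0("  \"", cfmrd@edges$u, "\" -- \"", cfmrd@edges$v,
                    "\" [style=", esty[cfmrd@edges$type], "];"),
             "}")
  txt <- paste(lines, collapse = "\n")
  if (is.null(txt) || is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

## Normalize a matching argument into a data.frame(a, b) of marker ids.
asMatching <- function(matching) {
  m <- as.data.frame(matching, stringsAsFactors = FALSE)
  if (!nrow(m)) return(data.frame(a = character(), b = character()))
  names(m)[1:2] <- c("a", "b")
  m$a <- as.character(m$a); m$b <- as.character(m$b)
  m
}

#' Census of components under a resolved homology
#'
#' Restricts the comparison graph of two genomes to the extremity edges of a
#' resolved homology (a matching on markers), gives self edges to the
#' unmatched markers, and classifies the connected components: cycles,
#' circular singletons (cycles of alternating adjacency and self edges) and
#' paths by canonical label.  Self edges are ignored for the path/cycle
#' counting; a path ends where the only continuation would be a self edge.
#'
#' @param genomeA,genomeB two non-degenerate genomes.
#' @param matching resolved homology as a two-column object (marker id in A,
#'   marker id in B); matched markers must be homologous.
#' @return a \code{\linkS4class{ComponentCensus}}.
#' @examples
#' ex <- workedExample()
#' componentCensus(ex$A, ex$B, ex$matching)
#' @export
componentCensus <- function(genomeA, genomeB, matching) {
  stopifnot(is(genomeA, "Genome"), is(genomeB, "Genome"))
  matching <- asMatching(matching)
  if (anyDuplicated(matching$a) || anyDuplicated(matching$b))
    stop("homology is not resolved: a marker is matched more than once")
  famA <- stats::setNames(genomeA@markers$family, genomeA@markers$id)
  famB <- stats::setNames(genomeB@markers$family, genomeB@markers$id)
  if (nrow(matching) &&
      !identical(unname(famA[matching$a]), unname(famB[matching$b])))
    stop("matched markers must belong to the same family")

  u <- character(); v <- character(); ty <- character()
  pfx <- function(side, e) if (length(e)) paste0(side, "|", e) else character()
  add <- function(uu, vv, tt) {
    if (!length(uu)) return(invisible())
    u <<- c(u, uu); v <<- c(v, vv); ty <<- c(ty, rep(tt, length(uu)))
  }
  aA <- genomeA@adjacencies; aB <- genomeB@adjacencies
  add(pfx("A", aA$e1), pfx("A", aA$e2), "adj")
  add(pfx("B", aB$e1), pfx("B", aB$e2), "adj")
  if (nrow(matching)) {
    add(pfx("A", extremity(matching$a, "t")),
        pfx("B", extremity(matching$b, "t")), "ext")
    add(pfx("A", extremity(matching$a, "h")),
        pfx("B", extremity(matching$b, "h")), "ext")
  }
  singA <- setdiff(genomeA@markers$id, matching$a)
  singB <- setdiff(genomeB@markers$id, matching$b)
  add(pfx("A", extremity(singA, "t")), pfx("A", extremity(singA, "h")), "self")
  add(pfx("B", extremity(singB, "t")), pfx("B", extremity(singB, "h")), "self")

  allv <- unique(c(
    pfx("A", c(extremities(genomeA), extremity(genomeA@telomeres, "o"))),
    pfx("B", c(extremities(genomeB), extremity(genomeB@telomeres, "o")))))
  g <- igraph::graph_from_data_frame(
    data.frame(from = u, to = v, type = ty, stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = allv))
  comp <- igraph::components(g)

  cN <- 0L; sN <- 0L
  paths <- stats::setNames(integer(length(pathClasses)), pathClasses)
  endLabel <- function(vid) {
    side <- substr(vid, 1L, 1L)
    telo <- endsWith(vid, ":o")
    if (side == "A") (if (telo) "A" else "a") else (if (telo) "B" else "b")
  }
  canonLab <- function(l1, l2) {
    key <- c(l1, l2)
    key <- key[order(match(key, c("A", "a", "B", "b")))]
    paste(key, collapse = "")
  }
  for (ci in seq_len(comp$no)) {
    vids <- names(comp$membership)[comp$membership == ci]
    sub <- igraph::induced_subgraph(g, vids)
    types <- igraph::E(sub)$type
    if (!any(types == "ext") && any(types == "self") &&
        all(igraph::degree(sub) == 2L)) {
      ## cycle of alternating adjacency and self edges: circular singleton
      sN <- sN + 1L
      next
    }
    ## ignore self edges, split into sub-components
    sub2 <- igraph::delete_edges(sub, which(types == "self"))
    comp2 <- igraph::components(sub2)
    for (cj in seq_len(comp2$no)) {
      wids <- names(comp2$membership)[comp2$membership == cj]
      s2 <- igraph::induced_subgraph(sub2, wids)
      deg <- igraph::degree(s2)
      if (length(wids) >= 2L && all(deg == 2L)) {
        cN <- cN + 1L
      } else if (igraph::ecount(s2) >= 1L) {
        endp <- names(deg)[deg == 1L]
        stopifnot(length(endp) == 2L)
        lab <- canonLab(endLabel(endp[1]), endLabel(endp[2]))
        paths[lab] <- paths[lab] + 1L
      }
      ## isolated vertices (possible only for degenerate inputs) count as
      ## no path
    }
  }
  new("ComponentCensus", c = cN, s = sN, n = nrow(matching), paths = paths)
}

setMethod("show", "ComponentCensus", function(object) {
  nz <- object@paths[object@paths > 0L]
  cat("ComponentCensus: n=", object@n, " c=", object@c, " s=", object@s,
      if (length(nz)) paste0(" paths: ",
        paste(names(nz), nz, sep = "=", collapse = " ")) else " (no paths)",
      "\n", sep = "")
})

#' DCJ-indel distance of a resolved homology from its component census
#'
#' Closed form over the component counts of the comparison graph:
#' \deqn{d = n - c + \lceil (p_{ab} + \max(p_{Aa}, p_{aB}) +
#'   \max(p_{Ab}, p_{Bb}) - p_{AB}) / 2 \rceil + s}
#' Path classes entirely within one genome with matching end types
#' (aa, AA, bb, BB) do not enter the formula.
#'
#' @param census a \code{\linkS4class{ComponentCensus}}, or a genome (then
#'   \code{genomeB} and \code{matching} must be given and the census is
#'   computed first).
#' @param genomeB,matching see \code{\link{componentCensus}}.
#' @return non-negative integer distance.
#' @export
dcjIndelDistance <- function(census, genomeB = NULL, matching = NULL) {
  if (is(census, "Genome")) census <- componentCensus(census, genomeB, matching)
  stopifnot(is(census, "ComponentCensus"))
  p <- census@paths
  d <- census@n - census@c +
    ceiling((p[["ab"]] + max(p[["Aa"]], p[["aB"]]) +
             max(p[["Ab"]], p[["Bb"]]) - p[["AB"]]) / 2) + census@s
  as.integer(d)
}
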