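#' @import methods
NULL

#' DegenerateGenome: a set of candidate adjacencies over marker extremities
#'
#' A degenerate genome is a graph on marker extremities and telomeres whose
#' marker edges pair each tail with its head, but whose adjacency set need
#' not be a matching: an extremity may lie in zero, one or many candidate
#' adjacencies.  Degenerate genomes model the uncertainty about adjacencies
#' of ancestral genomes; every proper genome is a degenerate genome with a
#' unique linearization (itself).
#'
#' @slot name genome label (single string).
#' @slot markers \code{data.frame} with columns \code{id} (unique marker
#'   identifier) and \code{family} (homology class label).
#' @slot telomeres character vector of telomere identifiers.
#' @slot adjacencies \code{data.frame} with columns \code{e1}, \code{e2}
#'   holding extremity encodings (\code{"<marker>:t"}, \code{"<marker>:h"},
#'   \code{"<telomere>:o"}).
#' @export
setClass("DegenerateGenome",
  representation(
    name = "character",
    markers = "data.frame",
    telomeres = "character",
    adjacencies = "data.frame"
  )
)

#' Genome: marker extremities and telomeres with a perfect adjacency matching
#'
#' A genome is a degenerate genome whose adjacency edges form a perfect
#' matching on extremities and telomeres, so that every connected component
#' of the genome graph is a simple path (linear chromosome, both ends
#' telomeric) or a simple cycle (circular chromosome).
#'
#' @export
setClass("Genome", contains = "DegenerateGenome")

validDegenerateGenome <- function(object) {
  msg <- character()
  m <- object@markers
  if (!all(c("id", "family") %in% names(m)))
    msg <- c(msg, "markers must have columns 'id' and 'family'")
  else {
    if (anyDuplicated(m$id)) msg <- c(msg, "duplicated marker ids")
    if (any(grepl(":", m$id, fixed = TRUE)))
      msg <- c(msg, "marker ids must not contain ':'")
  }
  if (anyDuplicated(object@telomeres))
    msg <- c(msg, "duplicated telomere ids")
  a <- object@adjacencies
  if (!all(c("e1", "e2") %in% names(a))) {
    msg <- c(msg, "adjacencies must have columns 'e1' and 'e2'")
  } else if (nrow(a)) {
    known <- c(extremity(rep(m$id, 2L), rep(c("t", "h"), each = nrow(m))),
               extremity(object@telomeres, "o"))
    ends <- c(a$e1, a$e2)
    if (!all(ends %in% known))
      msg <- c(msg, paste("adjacency endpoint(s) not in genome:",
                          paste(setdiff(ends, known), collapse = ", ")))
    if (any(isTelomericExtremity(a$e1) & isTelomericExtremity(a$e2)))
      msg <- c(msg, "adjacency joining two telomeres is not allowed")
    if (any(a$e1 == a$e2))
      msg <- c(msg, "self-loop adjacency (same extremity twice)")
    if (anyDuplicated(adjKey(a$e1, a$e2)))
      msg <- c(msg, "duplicated adjacency")
  }
  if (length(msg)) msg else TRUE
}

setValidity("DegenerateGenome", validDegenerateGenome)

setValidity("Genome", function(object) {
  msg <- character()
  base <- validDegenerateGenome(object)
  if (!isTRUE(base)) msg <- base
  a <- object@adjacencies
  ends <- c(a$e1, a$e2)
  need <- c(extremity(rep(object@markers$id, 2L),
                      rep(c("t", "h"), each = nrow(object@markers))),
            extremity(object@telomeres, "o"))
  deg <- table(factor(ends, levels = need))
  if (any(deg != 1L))
    msg <- c(msg, paste("adjacencies are not a perfect matching on",
                        "extremities and telomeres (degree != 1 at:",
                        paste(utils::head(names(deg)[deg != 1L], 5L),
                              collapse = ", "), ")"))
  if (length(msg)) msg else TRUE
})

#' Phylogeny: a rooted tree whose nodes carry (degenerate) genomes
#'
#' @slot nodes character vector of node names (unique; includes the root).
#' @slot edges \code{data.frame} with columns \code{parent}, \code{child}.
#' @slot root name of the root node.
#' @slot leaves character vector of leaf node names.
#' @slot genomes named list binding node names to
#'   \code{\linkS4class{DegenerateGenome}} objects (leaves must carry proper
#'   \code{\linkS4class{Genome}}s).
#' @export
setClass("Phylogeny",
  representation(
    nodes = "character",
    edges = "data.frame",
    root = "character",
    leaves = "character",
    genomes = "list"
  )
)

setValidity("Phylogeny", function(object) {
  msg <- character()
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicated node names")
  if (!all(c(object@edges$parent, object@edges$child) %in% object@nodes))
    msg <- c(msg, "edge endpoint not among nodes")
  bound <- names(object@genomes)
  if (length(bound) && !all(bound %in% object@nodes))
    msg <- c(msg, "genome bound to unknown node")
  for (lf in intersect(object@leaves, bound)) {
    if (!is(object@genomes[[lf]], "Genome"))
      msg <- c(msg, paste0("leaf '", lf, "' must carry a non-degenerate genome"))
  }
  if (length(msg)) msg else TRUE
})

#' CFMRD: capping-free multi-relational diagram of two genomes
#'
#' The comparison graph of two genomes under a homology: vertices are the
#' marker extremities and telomeres of both genomes; adjacency edges are the
#' adjacencies of both genomes, self edges are the marker edges of singular
#' markers (family present in only one of the two genomes), and extremity
#' edges join equivalent extremities across genomes.  No cap edges between
#' telomeres exist.
#'
#' @slot vertices \code{data.frame} with columns \code{vid} (diagram-unique
#'   vertex id), \code{side} ("A"/"B"), \code{extremity} (encoding within its
#'   genome), \code{marker} (id or \code{NA} for telomeres), \code{telomeric}
#'   (logical), \code{rank} (diagram-local rank, a bijection onto 1..n).
#' @slot edges \code{data.frame} with columns \code{u}, \code{v} (vertex
#'   ids) and \code{type} ("adj", "self", "ext").
#' @slot genomeA,genomeB the two genomes compared.
#' @export
setClass("CFMRD",
  representation(
    vertices = "data.frame",
    edges = "data.frame",
    genomeA = "DegenerateGenome",
    genomeB = "DegenerateGenome"
  )
)

#' ComponentCensus: component counts of a resolved comparison graph
#'
#' Counts of cycles, circular singletons and paths by canonical label in the
#' CFMRD of two genomes under a resolved homology, the quantities feeding the
#' closed-form DCJ-indel distance.  Path labels are read from genome A to
#' genome B; uppercase letters denote telomeric ends, lowercase letters ends
#' at singular extremities (where the only continuation would be a self
#' edge).
#'
#' @slot c number of cycles (self edges ignored).
#' @slot s number of circular singletons (cycles of alternating adjacency
#'   and self edges).
#' @slot n number of matched markers.
#' @slot paths named integer vector over the ten path classes
#'   \code{AB, Ab, aB, ab, Aa, aa, AA, Bb, bb, BB}.
#' @export
setClass("ComponentCensus",
  representation(c = "integer", s = "integer", n = "integer",
                 paths = "integer")
)

pathClasses <- c("AB", "Ab", "aB", "ab", "Aa", "aa", "AA", "Bb", "bb", "BB")

#' ILPModel: a solver-neutral mixed integer linear program
#'
#' @slot nvar number of variables.
#' @slot varNames character vector of variable names.
#' @slot lb,ub numeric bounds.
#' @slot vtype "B" (binary), "I" (integer) or "C" (continuous) per variable.
#' @slot obj numeric objective coefficients (always minimized).
#' @slot objConst constant objective offset.
#' @slot ai,aj,ax constraint matrix triplets (row, column, value).
#' @slot lo,hi per-row lower/upper constraint bounds.
#' @slot maps list of decode metadata (variable index maps per node/edge).
#' @export
setClass("ILPModel",
  representation(
    nvar = "integer", varNames = "character",
    lb = "numeric", ub = "numeric", vtype = "character",
    obj = "numeric", objConst = "numeric",
    ai = "integer", aj = "integer", ax = "numeric",
    lo = "numeric", hi = "numeric",
    maps = "list"
  )
)

#' SPPSolution: decoded solution of the small parsimony ILP
#'
#' @slot linearizations named list of \code{\linkS4class{Genome}}s, one per
#'   tree node.
#' @slot distances \code{data.frame} with columns \code{parent}, \code{child},
#'   \code{distance} (the per-branch DCJ-indel distance f_E).
#' @slot matchings named list (per branch "parent->child") of resolved
#'   marker matchings (\code{data.frame} with columns \code{a}, \code{b}).
#' @slot objective solver objective value.
#' @slot recomputedObjective objective recomputed from the decoded
#'   linearizations via the closed-form distance.
#' @slot status solver status string.
#' @slot gap relative MIP gap reported by the solver (0 when proven optimal).
#' @export
setClass("SPPSolution",
  representation(
    linearizations = "list",
    distances = "data.frame",
    matchings = "list",
    objective = "numeric",
    recomputedObjective = "numeric",
    status = "character",
    gap = "numeric"
  )
)

#' GroundTruth: simulated phylogeny with known ancestral genomes
#'
#' @slot phylogeny a \code{\linkS4class{Phylogeny}} whose every node carries
#'   its true simulated genome.
#' @slot trueAdjacencies named list (per internal node) of canonical
#'   adjacency keys of the true genome, telomere-anonymized.
#' @slot opLog \code{data.frame} log of operations applied per branch.
#' @slot config the \code{list} of simulation settings used.
#' @export
setClass("GroundTruth",
  representation(
    phylogeny = "Phylogeny",
    trueAdjacencies = "list",
    opLog = "data.frame",
    config = "list"
  )
)
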