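#' @include ilp-solve.R simulate.R
NULL

#' Score reconstructed ancestral genomes against ground truth
#'
#' Set comparison of recovered vs true adjacencies per internal node on
#' canonical, telomere-anonymized adjacency keys (so keys are invariant
#' under end order and telomere identity).  Precision is
#' |recovered &#8745; true| / |recovered| (defined as 1 on an empty
#' recovered set, flagged in the output), recall is
#' |recovered &#8745; true| / |true|, F1 their harmonic mean.  Aggregates
#' are unweighted means over the internal nodes; pooled counts are also
#' reported.
#'
#' @param solution an \code{\linkS4class{SPPSolution}}.
#' @param truth a \code{\linkS4class{GroundTruth}}.
#' @param telomeric how to treat telomeric adjacencies: "augmented"
#'   (default; recovered telomeric adjacencies that are not in the truth
#'   are excluded from the comparison, so telomeres added purely to ensure
#'   linearizability do not count against precision), "exclude" (drop all
#'   telomeric adjacencies from both sets) or "include" (plain comparison).
#' @return list with \code{perNode} (data.frame: node, nRecovered, nTrue,
#'   nHit, precision, recall, f1, emptyRecovered), \code{precision},
#'   \code{recall}, \code{f1} (unweighted means) and \code{pooled}
#'   (precision/recall/f1 over pooled counts).
#' @export
scoreReconstruction <- function(solution, truth,
                                telomeric = c("augmented", "exclude",
                                              "include")) {
  telomeric <- match.arg(telomeric)
  internal <- names(truth@trueAdjacencies)
  missing <- setdiff(internal, names(solution@linearizations))
  if (length(missing))
    stop("solution lacks node(s): ", paste(missing, collapse = ", "))
  isTelKey <- function(k) grepl("*:o", k, fixed = TRUE)
  rows <- lapply(internal, function(nd) {
    a <- solution@linearizations[[nd]]@adjacencies
    rec <- unique(adjKeyAnon(a$e1, a$e2))
    tru <- unique(truth@trueAdjacencies[[nd]])
    if (telomeric == "exclude") {
      rec <- rec[!isTelKey(rec)]; tru <- tru[!isTelKey(tru)]
    } else if (telomeric == "augmented") {
      rec <- rec[!(isTelKey(rec) & !(rec %in% tru))]
    }
    hit <- length(intersect(rec, tru))
    empty <- length(rec) == 0L
    prec <- if (empty) 1 else hit / length(rec)
    recl <- if (length(tru) == 0L) 1 else hit / length(tru)
    f1 <- if (prec + recl == 0) 0 else 2 * prec * recl / (prec + recl)
    data.frame(node = nd, nRecovered = length(rec), nTrue = length(tru),
               nHit = hit, precision = prec, recall = recl, f1 = f1,
               emptyRecovered = empty, stringsAsFactors = FALSE)
  })
  perNode <- do.call(rbind, rows)
  pooledP <- if (sum(perNode$nRecovered) == 0) 1 else
    sum(perNode$nHit) / sum(perNode$nRecovered)
  pooledR <- if (sum(perNode$nTrue) == 0) 1 else
    sum(perNode$nHit) / sum(perNode$nTrue)
  pooledF <- if (pooledP + pooledR == 0) 0 else
    2 * pooledP * pooledR / (pooledP + pooledR)
  list(perNode = perNode,
       precision = mean(perNode$precision),
       recall = mean(perNode$recall),
       f1 = mean(perNode$f1),
       pooled = c(precision = pooledP, recall = pooledR, f1 = pooledF))
}
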