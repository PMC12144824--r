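#' Two-genome worked example with an unresolved and a resolved homology
#'
#' A pair of five-marker genomes, each a single linear chromosome:
#' A = (1, 1, 2, 4, -3) and B = (1, 1, 2, 5, 3), with in-paralogs in
#' family 1.  Under the unresolved homology the families are
#' \{1_1,1_2,1_3,1_4\}, \{2_1,2_2\}, \{3_1,3_2\}, \{4_1\}, \{5_1\}; the
#' resolved refinement matches 1_1~1_3, 1_2~1_4, 2_1~2_2 and 3_1~3_2,
#' leaving 4_1 and 5_1 singular.  The component census of the comparison
#' graph under the resolved homology is c=2 with one path of each label
#' AB, ab, aB and Ab, giving DCJ-indel distance 3.
#'
#' @return list with elements \code{A}, \code{B} (the two
#'   \code{\linkS4class{Genome}}s) and \code{matching} (the resolved
#'   homology as a data.frame with columns \code{a}, \code{b}).
#' @examples
#' ex <- workedExample()
#' componentCensus(ex$A, ex$B, ex$matching)
#' @export
workedExample <- function() {
  gs <- readUnimog(">A\n1 1 2 4 -3 |\n>B\n1 1 2 5 3 |")
  list(A = gs$A, B = gs$B,
       matching = data.frame(a = c("1_1", "1_2", "2_1", "3_1"),
                             b = c("1_3", "1_4", "2_2", "3_2"),
                             stringsAsFactors = FALSE))
}
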