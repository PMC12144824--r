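## Extremity / adjacency string encoding.
##
## A marker extremity is encoded as "<markerId>:t" (tail) or "<markerId>:h"
## (head); a telomeric extremity as "<telomereId>:o".  Marker ids never
## contain ':' (enforced at parse time), so the encoding is unambiguous.

extremity <- function(marker, side) {
  if (!length(marker)) return(character())
  paste0(marker, ":", side)
}

extremitySide <- function(e) substr(e, nchar(e), nchar(e))

extremityMarker <- function(e) substr(e, 1L, nchar(e) - 2L)

isTelomericExtremity <- function(e) endsWith(e, ":o")

#' Canonical adjacency keys
#'
#' Adjacencies are unordered pairs of extremities (encoded
#' \code{"<marker>:t"}, \code{"<marker>:h"}, \code{"<telomere>:o"}); the
#' key is order-insensitive so that \code{w(f^x g^y) == w(g^y f^x)}.
#' \code{adjKeyAnon} additionally erases telomere identity (all telomeres
#' compare equal); candidate-adjacency weights and reconstruction scoring
#' are keyed this way.
#'
#' @param e1,e2 character vectors of extremity encodings.
#' @return character vector of canonical keys.
#' @export
adjKey <- function(e1, e2) {
  lo <- ifelse(e1 <= e2, e1, e2)
  hi <- ifelse(e1 <= e2, e2, e1)
  paste(lo, hi, sep = "|")
}

#' @rdname adjKey
#' @export
adjKeyAnon <- function(e1, e2) {
  a <- ifelse(isTelomericExtremity(e1), "*:o", e1)
  b <- ifelse(isTelomericExtremity(e2), "*:o", e2)
  adjKey(a, b)
}

splitAdjKey <- function(key) strsplit(key, "|", fixed = TRUE)

## Truncated Zipf sampler on 1..kmax used for duplication/indel lengths.
rzipf <- function(n, exponent, kmax = 20L) {
  p <- (1:kmax)^(-exponent)
  sample.int(kmax, n, replace = TRUE, prob = p / sum(p))
}
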