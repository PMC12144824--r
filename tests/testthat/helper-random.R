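## Shared randomized fixtures, built in code at test time.

## A random tiny genome: <= maxMarkers markers drawn from a family pool in
## which up to two families are duplicated, arranged on 1-2 chromosomes,
## mixed linear/circular, random orientations.
randomTinyGenome <- function(name, famPool, maxMarkers = 5L) {
  n <- sample.int(maxMarkers, 1L)
  fams <- sample(famPool, n, replace = TRUE)
  ## keep at most 2 duplicated families, multiplicity <= 2
  tab <- table(fams)
  while (sum(tab > 1L) > 2L || any(tab > 2L)) {
    worst <- names(tab)[which.max(tab)]
    i <- which(fams == worst)[1]
    fams[i] <- sample(famPool, 1L)
    tab <- table(fams)
  }
  ids <- paste0(name, ".", seq_len(n))
  signs <- sample(c(1L, -1L), n, replace = TRUE)
  nChrom <- sample.int(min(2L, n), 1L)
  cut <- if (nChrom == 2L) sample.int(n - 1L, 1L) else n
  mkCh <- function(idx) list(ids = ids[idx], signs = signs[idx],
                             circular = stats::runif(1) < 0.35)
  chroms <- if (nChrom == 2L) list(mkCh(1:cut), mkCh((cut + 1L):n))
            else list(mkCh(1:n))
  genomeFromChromosomes(name, chroms, stats::setNames(fams, ids))
}

randomTinyPair <- function(seed, maxMarkers = 5L, nFams = 4L) {
  set.seed(seed)
  famPool <- as.character(seq_len(nFams))
  list(A = randomTinyGenome("A", famPool, maxMarkers),
       B = randomTinyGenome("B", famPool, maxMarkers))
}

## A random degenerate genome with <= maxAdj candidate adjacencies over a
## few markers, possibly with candidate telomeres.
randomDegenerateGenome <- function(seed, maxMarkers = 4L, maxAdj = 10L) {
  set.seed(seed)
  n <- sample.int(maxMarkers, 1L)
  ids <- paste0("m", seq_len(n))
  nTel <- sample(0:2, 1L)
  tel <- if (nTel) paste0("t", seq_len(nTel)) else character()
  ext <- c(extremity(ids, "t"), extremity(ids, "h"))
  pool <- c(ext, extremity(tel, "o"))
  cand <- t(utils::combn(pool, 2L))
  keep <- !(isTelomericExtremity(cand[, 1]) & isTelomericExtremity(cand[, 2]))
  cand <- cand[keep, , drop = FALSE]
  k <- sample.int(min(maxAdj, nrow(cand)), 1L)
  sel <- sample.int(nrow(cand), k)
  DegenerateGenome(paste0("D", seed),
                   markers = data.frame(id = ids, family = ids,
                                        stringsAsFactors = FALSE),
                   telomeres = tel,
                   adjacencies = data.frame(e1 = cand[sel, 1],
                                            e2 = cand[sel, 2],
                                            stringsAsFactors = FALSE))
}

## Exhaustive subset-search linearizability oracle: a degenerate genome is
## linearizable iff some subset of its adjacencies is a matching covering
## every marker extremity.
subsetLinearizable <- function(D) {
  a <- D@adjacencies
  ext <- extremities(D)
  if (!length(ext)) return(TRUE)
  n <- nrow(a)
  if (!n) return(FALSE)
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    ends <- c(a$e1[sel], a$e2[sel])
    if (anyDuplicated(ends)) next
    if (all(ext %in% ends)) return(TRUE)
  }
  FALSE
}
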