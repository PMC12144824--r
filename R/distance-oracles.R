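#' @include cfmrd.R
NULL

## Enumerate all maximum matchings between the copies of one family.
## a, b: marker id vectors; returns list of data.frame(a, b).
familyMatchings <- function(a, b) {
  m <- min(length(a), length(b))
  if (m == 0L) return(list(data.frame(a = character(), b = character())))
  swap <- length(a) > length(b)
  small <- if (swap) b else a
  large <- if (swap) a else b
  ## all injections small -> large: ordered selections of |small| from large
  perms <- function(x, k) {
    if (k == 0L) return(list(character()))
    out <- list()
    for (i in seq_along(x)) {
      for (rest in perms(x[-i], k - 1L))
        out[[length(out) + 1L]] <- c(x[i], rest)
    }
    out
  }
  lapply(perms(large, m), function(sel) {
    if (swap) data.frame(a = sel, b = small, stringsAsFactors = FALSE)
    else data.frame(a = small, b = sel, stringsAsFactors = FALSE)
  })
}

#' Enumerate all maximum matchings of the homology between two genomes
#'
#' A maximum matching matches, in every family, as many markers as possible
#' between the two genomes (min of the two copy numbers).
#'
#' @param genomeA,genomeB two genomes (homology given by family labels).
#' @param budget maximum number of matchings to enumerate; exceeding it is
#'   an explicit error, not a silent truncation.
#' @return list of matchings (data.frames with columns \code{a}, \code{b}).
#' @export
maximumMatchings <- function(genomeA, genomeB, budget = 20000L) {
  famA <- split(genomeA@markers$id, genomeA@markers$family)
  famB <- split(genomeB@markers$id, genomeB@markers$family)
  shared <- intersect(names(famA), names(famB))
  perFam <- lapply(shared, function(f) familyMatchings(famA[[f]], famB[[f]]))
  total <- prod(vapply(perFam, length, numeric(1)))
  if (total > budget)
    stop("enumeration budget exceeded: ", total, " maximum matchings (> ",
         budget, ")")
  out <- list(data.frame(a = character(), b = character()))
  for (opts in perFam) {
    out <- unlist(lapply(out, function(acc)
      lapply(opts, function(o) rbind(acc, o))), recursive = FALSE)
  }
  out
}

#' Pairwise DCJ-indel distance under the maximum matching model
#'
#' Exhaustive minimization of the closed-form distance over all maximum
#' matchings of the homology.  This is the reference implementation for
#' small instances; the ILP is the production path.
#'
#' @inheritParams maximumMatchings
#' @return non-negative integer distance.
#' @examples
#' ex <- workedExample()
#' distanceMaxMatching(ex$A, ex$B)
#' @export
distanceMaxMatching <- function(genomeA, genomeB, budget = 20000L) {
  ms <- maximumMatchings(genomeA, genomeB, budget)
  min(vapply(ms, function(m)
    dcjIndelDistance(componentCensus(genomeA, genomeB, m)), integer(1)))
}

## ---------------------------------------------------------------------
## Breadth-first operation-count oracle.
##
## States are genomes up to homology: multisets of chromosomes of signed
## family sequences.  One move is a DCJ (cut two adjacencies - including
## telomeric ones - and rejoin, or cut a single adjacency into two new
## telomeres), a deletion of a contiguous marker block, or an insertion of
## a contiguous block.  The maximum matching model is enforced through
## per-family floors and ceilings: a family may never drop below
## min(count in A, count in B) nor rise above max of the two, so exactly
## the surplus copies are deleted and exactly the deficit inserted.

chromCanon <- function(fams, signs, circular) {
  tok <- function(f, s) paste0(ifelse(s < 0L, "-", "+"), f)
  fwd <- tok(fams, signs)
  rev_ <- tok(rev(fams), -rev(signs))
  n <- length(fams)
  if (!circular) {
    f1 <- paste(fwd, collapse = " "); f2 <- paste(rev_, collapse = " ")
    return(paste0("L:", min(f1, f2)))
  }
  best <- NULL
  for (seqs in list(fwd, rev_)) {
    for (r in seq_len(n)) {
      rot <- paste(c(seqs[r:n], if (r > 1L) seqs[1:(r - 1L)]),
                   collapse = " ")
      if (is.null(best) || rot < best) best <- rot
    }
  }
  paste0("C:", best)
}

stateCanon <- function(state) {
  if (!length(state)) return("<empty>")
  paste(sort(vapply(state, function(ch)
    chromCanon(ch$fams, ch$signs, ch$circular), character(1))),
    collapse = " / ")
}

stateCounts <- function(state) {
  fams <- unlist(lapply(state, `[[`, "fams"))
  if (!length(fams)) return(integer())
  tab <- table(fams)
  stats::setNames(as.integer(tab), names(tab))
}

genomeToState <- function(g) {
  fam <- stats::setNames(g@markers$family, g@markers$id)
  lapply(chromosomes(g), function(ch)
    list(fams = unname(fam[ch$ids]), signs = ch$signs,
         circular = ch$circular))
}

## Chromosomes -> adjacency representation.  Marker instances are numbered;
## extremity tokens are "<i>:t"/"<i>:h"; telomeres are "TEL".
stateToAdj <- function(state) {
  adjs <- list()
  instFam <- character(); instN <- 0L
  for (ch in state) {
    n <- length(ch$fams)
    ids <- instN + seq_len(n)
    instN <- instN + n
    instFam <- c(instFam, ch$fams)
    left <- ifelse(ch$signs > 0L, paste0(ids, ":t"), paste0(ids, ":h"))
    right <- ifelse(ch$signs > 0L, paste0(ids, ":h"), paste0(ids, ":t"))
    if (n > 1L)
      for (i in 1:(n - 1L))
        adjs[[length(adjs) + 1L]] <- c(right[i], left[i + 1L])
    if (ch$circular) adjs[[length(adjs) + 1L]] <- c(right[n], left[1L])
    else {
      adjs[[length(adjs) + 1L]] <- c("TEL", left[1L])
      adjs[[length(adjs) + 1L]] <- c(right[n], "TEL")
    }
  }
  list(adjs = adjs, instFam = instFam)
}

adjToState <- function(adjs, instFam) {
  n <- length(instFam)
  partner <- new.env(parent = emptyenv())
  telAt <- character()
  for (ad in adjs) {
    if (ad[1] == "TEL" && ad[2] == "TEL") next
    if (ad[1] == "TEL") telAt <- c(telAt, ad[2])
    else if (ad[2] == "TEL") telAt <- c(telAt, ad[1])
    else {
      assign(ad[1], ad[2], envir = partner)
      assign(ad[2], ad[1], envir = partner)
    }
  }
  seen <- logical(n)
  state <- list()
  walk <- function(startExt, circular) {
    fams <- character(); signs <- integer()
    e <- startExt
    repeat {
      ii <- as.integer(sub(":[th]$", "", e))
      side <- substr(e, nchar(e), nchar(e))
      fams <- c(fams, instFam[ii])
      signs <- c(signs, if (side == "t") 1L else -1L)
      seen[ii] <<- TRUE
      exit <- paste0(ii, ":", if (side == "t") "h" else "t")
      nxt <- if (exists(exit, envir = partner)) get(exit, envir = partner)
             else NULL
      if (is.null(nxt)) break          # telomeric end
      if (circular && nxt == startExt) break
      e <- nxt
    }
    list(fams = fams, signs = signs, circular = circular)
  }
  for (e in telAt) {
    ii <- as.integer(sub(":[th]$", "", e))
    if (seen[ii]) next
    state[[length(state) + 1L]] <- walk(e, FALSE)
  }
  for (ii in seq_len(n)) {
    if (seen[ii]) next
    state[[length(state) + 1L]] <- walk(paste0(ii, ":t"), TRUE)
  }
  state
}

## All states reachable by one DCJ.
dcjNeighbors <- function(state) {
  sa <- stateToAdj(state)
  adjs <- sa$adjs
  out <- list()
  nA <- length(adjs)
  emit <- function(newAdjs) {
    out[[length(out) + 1L]] <<- adjToState(newAdjs, sa$instFam)
  }
  if (nA >= 2L) {
    for (i in 1:(nA - 1L)) for (j in (i + 1L):nA) {
      p <- adjs[[i]]; q <- adjs[[j]]
      rest <- adjs[-c(i, j)]
      emit(c(rest, list(c(p[1], q[1]), c(p[2], q[2]))))
      emit(c(rest, list(c(p[1], q[2]), c(p[2], q[1]))))
    }
  }
  for (i in seq_len(nA)) {
    p <- adjs[[i]]
    if (p[1] == "TEL" || p[2] == "TEL") next
    emit(c(adjs[-i], list(c(p[1], "TEL"), c(p[2], "TEL"))))
  }
  out
}

## Deletions of contiguous blocks.  A block may be deleted only if every
## family in it stays at or above its count in the target genome, keeping
## copy-number trajectories monotone (maximum matching model: only surplus
## copies are ever deleted).
deletionNeighbors <- function(state, target) {
  cnt <- stateCounts(state)
  out <- list()
  ok <- function(blockFams) {
    tab <- table(blockFams)
    tgt <- target[names(tab)]; tgt[is.na(tgt)] <- 0L
    all(cnt[names(tab)] - as.integer(tab) >= tgt)
  }
  for (ci in seq_along(state)) {
    ch <- state[[ci]]
    n <- length(ch$fams)
    if (ch$circular) {
      if (ok(ch$fams)) out[[length(out) + 1L]] <- state[-ci]   # whole chromosome
      if (n > 1L) {
        for (start in 1:n) for (len in 1:(n - 1L)) {
          idx <- ((start - 1L + 0:(len - 1L)) %% n) + 1L
          if (!ok(ch$fams[idx])) next
          keep <- (((start - 1L + len):(start + n - 2L)) %% n) + 1L
          new <- state
          new[[ci]] <- list(fams = ch$fams[keep], signs = ch$signs[keep],
                            circular = TRUE)
          out[[length(out) + 1L]] <- new
        }
      }
    } else {
      for (i in 1:n) for (j in i:n) {
        if (!ok(ch$fams[i:j])) next
        keep <- setdiff(seq_len(n), i:j)
        new <- state
        if (length(keep))
          new[[ci]] <- list(fams = ch$fams[keep], signs = ch$signs[keep],
                            circular = FALSE)
        else new <- new[-ci]
        out[[length(out) + 1L]] <- new
      }
    }
  }
  out
}

## Candidate insertion blocks: contiguous runs (<= maxLen) of either input
## genome, in both orientations.
insertionBlocks <- function(states, maxLen = 3L) {
  blocks <- list()
  keys <- character()
  addB <- function(f, s) {
    k <- paste(paste0(ifelse(s < 0, "-", "+"), f), collapse = " ")
    if (k %in% keys) return()
    keys <<- c(keys, k)
    blocks[[length(blocks) + 1L]] <<- list(fams = f, signs = s)
  }
  for (st in states) for (ch in st) {
    n <- length(ch$fams)
    lim <- min(maxLen, n)
    for (len in 1:lim) {
      starts <- if (ch$circular) 1:n else 1:(n - len + 1L)
      for (s0 in starts) {
        idx <- if (ch$circular) ((s0 - 1L + 0:(len - 1L)) %% n) + 1L
               else s0:(s0 + len - 1L)
        f <- ch$fams[idx]; s <- ch$signs[idx]
        addB(f, s)
        addB(rev(f), -rev(s))
      }
    }
  }
  blocks
}

## Insertions: a block may be inserted only if every family in it stays at
## or below its count in the target genome (only deficits are ever filled).
insertionNeighbors <- function(state, blocks, target) {
  cnt <- stateCounts(state)
  out <- list()
  for (b in blocks) {
    tab <- table(b$fams)
    cl <- target[names(tab)]; cl[is.na(cl)] <- 0L
    cur <- cnt[names(tab)]; cur[is.na(cur)] <- 0L
    if (any(cur + as.integer(tab) > cl)) next
    ## new linear chromosome
    out[[length(out) + 1L]] <- c(state, list(list(fams = b$fams,
                                                  signs = b$signs,
                                                  circular = FALSE)))
    ## new circular chromosome
    out[[length(out) + 1L]] <- c(state, list(list(fams = b$fams,
                                                  signs = b$signs,
                                                  circular = TRUE)))
    ## into an existing chromosome
    for (ci in seq_along(state)) {
      ch <- state[[ci]]
      n <- length(ch$fams)
      gaps <- if (ch$circular) 1:n else 0:n
      for (gp in gaps) {
        new <- state
        if (ch$circular) {
          ord <- c(seq_len(gp), 0L, if (gp < n) (gp + 1L):n)
        } else {
          ord <- c(seq_len(gp), 0L, if (gp < n) (gp + 1L):n)
        }
        fams <- character(); signs <- integer()
        for (k in ord) {
          if (k == 0L) { fams <- c(fams, b$fams); signs <- c(signs, b$signs) }
          else { fams <- c(fams, ch$fams[k]); signs <- c(signs, ch$signs[k]) }
        }
        new[[ci]] <- list(fams = fams, signs = signs, circular = ch$circular)
        out[[length(out) + 1L]] <- new
      }
    }
  }
  out
}

#' Breadth-first DCJ-indel operation oracle
#'
#' Bidirectional breadth-first search over genome space: one move is a DCJ
#' (cut two adjacencies, or one adjacency and a chromosome end, and rejoin;
#' single cuts create telomeres) or an indel (deletion or insertion of one
#' contiguous marker block).  Indels are constrained to the maximum
#' matching model: per-family copy numbers move monotonically from their
#' value in the source to their value in the target genome, so exactly the
#' surplus copies are deleted and exactly the deficits inserted, and the
#' markers conserved by any found scenario form a maximum matching.
#' Intended for tiny instances only; the search refuses (rather than
#' silently truncates) when its budget is exceeded.
#'
#' @param genomeA,genomeB two genomes.
#' @param maxOps search depth limit (total operations).
#' @param maxStates cap on stored states per side.
#' @return list with \code{distance} (integer or \code{NA}) and
#'   \code{complete} (logical; \code{FALSE} when the budget was exceeded
#'   before the depth limit proved a distance).
#' @export
bfsDistanceOracle <- function(genomeA, genomeB, maxOps = 4L,
                              maxStates = 20000L) {
  sA <- genomeToState(genomeA); sB <- genomeToState(genomeB)
  cA <- stateCounts(sA); cB <- stateCounts(sB)
  blocks <- insertionBlocks(list(sA, sB))

  ## each search direction steers copy numbers toward its own target
  neighborsTo <- function(target) {
    function(state) {
      c(dcjNeighbors(state),
        deletionNeighbors(state, target),
        insertionNeighbors(state, blocks, target))
    }
  }
  neighborsA <- neighborsTo(cB)
  neighborsB <- neighborsTo(cA)

  kA <- stateCanon(sA); kB <- stateCanon(sB)
  if (kA == kB) return(list(distance = 0L, complete = TRUE))
  ## visited maps: canonical state -> first depth on that side
  visA <- new.env(parent = emptyenv()); assign(kA, 0L, envir = visA)
  visB <- new.env(parent = emptyenv()); assign(kB, 0L, envir = visB)
  frontA <- stats::setNames(list(sA), kA)
  frontB <- stats::setNames(list(sB), kB)
  dA <- 0L; dB <- 0L
  nVisited <- 2L
  best <- Inf

  expand <- function(front, vis, depth, neighbors) {
    nxt <- list()
    for (st in front) {
      for (nb in neighbors(st)) {
        k <- stateCanon(nb)
        if (exists(k, envir = vis)) next
        assign(k, depth, envir = vis)
        nxt[[k]] <- nb
        nVisited <<- nVisited + 1L
        if (nVisited > maxStates) return(NULL)
      }
    }
    nxt
  }

  ## Once the two explored balls overlap at combined depth <= dA + dB, the
  ## recorded first-depths give the exact distance (any optimal path has a
  ## midpoint within both balls).
  while (dA + dB < maxOps) {
    growA <- length(frontA) <= length(frontB)
    if (growA) {
      frontA <- expand(frontA, visA, dA + 1L, neighborsA)
      if (is.null(frontA))
        return(list(distance = NA_integer_, complete = FALSE))
      dA <- dA + 1L
      hits <- intersect(names(frontA), ls(visB))
      if (length(hits))
        best <- min(best, dA + min(vapply(hits, get, 0L, envir = visB)))
    } else {
      frontB <- expand(frontB, visB, dB + 1L, neighborsB)
      if (is.null(frontB))
        return(list(distance = NA_integer_, complete = FALSE))
      dB <- dB + 1L
      hits <- intersect(names(frontB), ls(visA))
      if (length(hits))
        best <- min(best, dB + min(vapply(hits, get, 0L, envir = visA)))
    }
    if (best <= dA + dB)
      return(list(distance = as.integer(best), complete = TRUE))
    if (!length(frontA) || !length(frontB))
      return(list(distance = NA_integer_, complete = FALSE))
  }
  if (best <= maxOps)
    return(list(distance = as.integer(best), complete = TRUE))
  list(distance = NA_integer_, complete = FALSE)
}
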