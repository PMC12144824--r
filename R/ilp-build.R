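#' @include milp-backend.R linearize.R cfmrd.R
NULL

## ---------------------------------------------------------------------
## The small parsimony ILP.
##
## Global level: one binary presence variable g_v per extremity/telomere of
## every node's (degenerate) genome, one shared binary selection variable
## per candidate adjacency; head present iff tail present; family
## copy-number bounds; every present vertex in exactly one selected
## adjacency.
##
## Local level, per tree edge: the comparison diagram of the two incident
## genomes.  Adjacency edges inherit their selection variable from the
## global level; extremity edges come in sibling pairs (tail-tail and
## head-head of one marker pairing) sharing one variable; every marker gets
## a self edge on the sides where it may end up unmatched, with one genome
## per family allowed to use self edges (maximum matching model).  Cycle
## and path reports use vertex ranks, a bounded label y constant along
## selected edges, a cycle claim z possible only where y reaches the
## vertex's own rank, and a genome flag l fixed at telomeres and forced at
## selected self edges; crossing label changes charge path reports.
## Circular singletons are counted either by enumerating candidate
## alternating cycles or, past a threshold, by an orientation/potential
## gadget of constant size per edge and vertex.

nodeBounds <- function(node, genome, bounds) {
  cnt <- familyCounts(genome)
  out <- data.frame(family = names(cnt), low = unname(cnt),
                    high = unname(cnt), stringsAsFactors = FALSE)
  if (!is.null(bounds)) {
    bb <- bounds[bounds$genome == node, , drop = FALSE]
    for (i in seq_len(nrow(bb))) {
      j <- match(bb$family[i], out$family)
      if (is.na(j))
        stop("bounds for unknown family '", bb$family[i], "' at node ", node)
      if (bb$high[i] > out$high[j])
        stop("upper bound exceeds candidate copies for family '",
             bb$family[i], "' at node ", node)
      out$low[j] <- bb$low[i]; out$high[j] <- bb$high[i]
    }
  }
  out
}

## Global-level variables and constraints for one node.  Returns decode maps.
emitGlobalNode <- function(b, node, genome, bnd, degree, alpha, w) {
  mk <- genome@markers
  gIdx <- integer(0)
  addG <- function(ext, fixed) {
    i <- addVar(b, paste0("g[", node, "|", ext, "]"),
                if (fixed) 1 else 0, 1, "B")
    gIdx[[ext]] <<- i
    i
  }
  fixedFam <- bnd$family[bnd$low == bnd$high &
                         bnd$high == unname(familyCounts(genome)[bnd$family])]
  for (r in seq_len(nrow(mk))) {
    fx <- mk$family[r] %in% fixedFam
    it <- addG(extremity(mk$id[r], "t"), fx)
    ih <- addG(extremity(mk$id[r], "h"), fx)
    addCon(b, c(it, ih), c(1, -1), 0, 0)                     # C.01 / C.01A
  }
  for (tl in genome@telomeres) addG(extremity(tl, "o"), FALSE)
  ## C.02 for non-default bounds
  for (r in seq_len(nrow(bnd))) {
    if (bnd$family[r] %in% fixedFam) next
    ids <- mk$id[mk$family == bnd$family[r]]
    idx <- gIdx[extremity(ids, "t")]
    addCon(b, idx, rep(1, length(idx)), bnd$low[r], bnd$high[r])
  }
  ## candidate adjacency selection variables (deduped by key)
  a <- genome@adjacencies
  key <- if (nrow(a)) adjKey(a$e1, a$e2) else character()
  keep <- !duplicated(key)
  a <- a[keep, , drop = FALSE]; key <- key[keep]
  akey <- if (nrow(a)) adjKeyAnon(a$e1, a$e2) else character()
  wv <- rep(0, nrow(a))
  hit <- akey %in% names(w); wv[hit] <- w[akey[hit]]
  selIdx <- integer(nrow(a))
  for (i in seq_len(nrow(a)))
    selIdx[i] <- addVar(b, paste0("a[", node, "|", key[i], "]"), 0, 1, "B",
                        obj = -(1 - alpha) * wv[i] * degree)
  ## C.03: every vertex in exactly one selected adjacency iff present
  ends <- c(a$e1, a$e2)
  for (ext in names(gIdx)) {
    inc <- selIdx[which(a$e1 == ext | a$e2 == ext)]
    addCon(b, c(inc, gIdx[[ext]]), c(rep(1, length(inc)), -1), 0, 0)
  }
  list(gIdx = gIdx, adjacencies = a, adjKeys = key, selIdx = selIdx,
       weights = wv)
}

## Enumerate candidate circular-singleton cycles on one genome side.
## capable: marker ids that carry a self edge on this side.  Returns a list
## of cycles (each: list(markers=ids, adjRows=candidate adjacency row idx))
## or NULL when more than `cap` cycles exist.
enumerateSingletonCycles <- function(adj, capable, cap, stepCap = 10000L) {
  if (!length(capable) || !nrow(adj)) return(list())
  ends <- cbind(adj$e1, adj$e2)
  mk1 <- extremityMarker(adj$e1); mk2 <- extremityMarker(adj$e2)
  tel1 <- isTelomericExtremity(adj$e1); tel2 <- isTelomericExtremity(adj$e2)
  ok <- !tel1 & !tel2 & mk1 %in% capable & mk2 %in% capable
  rows <- which(ok)
  if (!length(rows)) return(list())
  incident <- split(rep(rows, 2L),
                    c(adj$e1[rows], adj$e2[rows]))
  cycles <- list(); seenC <- character(); steps <- 0L
  overflow <- FALSE
  startOrder <- sort(capable)
  for (m0 in startOrder) {
    start <- extremity(m0, "t")
    ## DFS: at an extremity just entered via the marker (self) edge,
    ## leave via a candidate adjacency
    dfs <- function(cur, usedMarkers, adjRows) {
      if (overflow) return()
      steps <<- steps + 1L
      if (steps > stepCap) { overflow <<- TRUE; return() }
      m <- extremityMarker(cur)
      other <- extremity(m, if (extremitySide(cur) == "t") "h" else "t")
      for (r in incident[[other]] %||% integer()) {
        nxtE <- if (adj$e1[r] == other) adj$e2[r] else adj$e1[r]
        nm <- extremityMarker(nxtE)
        if (nxtE == start) {
          key <- paste(sort(adjRows <- c(adjRows, r)), collapse = ",")
          if (!(key %in% seenC)) {
            seenC <<- c(seenC, key)
            cycles[[length(cycles) + 1L]] <<-
              list(markers = usedMarkers, adjRows = sort(unique(c(adjRows))))
            if (length(cycles) > cap) { overflow <<- TRUE; return() }
          }
          next
        }
        if (nm %in% usedMarkers) next
        if (nm < m0) next     # canonical: smallest marker is the start
        dfs(nxtE, c(usedMarkers, nm), c(adjRows, r))
      }
    }
    dfs(start, m0, integer())
    if (overflow) return(NULL)
  }
  cycles
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Local-level emission for one tree edge.  nodeA/nodeB: node names;
## gm: per-node decode maps from emitGlobalNode; genomes: list by node.
emitLocalEdge <- function(b, edgeName, nodeA, nodeB, genomes, gm, bndAll,
                          alpha, singletonMode, capFactor = 2) {
  gA <- genomes[[nodeA]]; gB <- genomes[[nodeB]]
  vA <- gm[[nodeA]]; vB <- gm[[nodeB]]
  verts <- cfmrdVertices(gA, gB)
  rank <- stats::setNames(verts$rank, verts$vid)
  nV <- nrow(verts)
  en <- function(tag) paste0(tag, "[", edgeName, "]")

  ## per-vertex variables ------------------------------------------------
  yIdx <- integer(nV); zIdx <- integer(nV); lIdx <- integer(nV)
  gOf <- integer(nV)        # global presence var per vertex
  for (i in seq_len(nV)) {
    vid <- verts$vid[i]
    side <- verts$side[i]
    ext <- verts$extremity[i]
    gOf[i] <- if (side == "A") vA$gIdx[[ext]] else vB$gIdx[[ext]]
    yIdx[i] <- addVar(b, en(paste0("y|", vid)), 0, rank[[vid]], "I")
    zIdx[i] <- addVar(b, en(paste0("z|", vid)), 0, 1, "B")
    telo <- verts$telomeric[i]
    lfix <- if (telo && side == "A") 0 else if (telo && side == "B") 1 else NA
    lIdx[i] <- if (is.na(lfix))
      addVar(b, en(paste0("l|", vid)), 0, 1, "B")
    else addVar(b, en(paste0("l|", vid)), lfix, lfix, "B")     # C.34
    addCon(b, c(zIdx[i], gOf[i]), c(1, -1), NA, 0)             # C.22
    addCon(b, c(zIdx[i], yIdx[i]), c(rank[[vid]], -1), NA, 0)  # C.29
  }
  vi <- stats::setNames(seq_len(nV), verts$vid)

  ## edge bookkeeping ----------------------------------------------------
  bndA <- bndAll[[nodeA]]; bndB <- bndAll[[nodeB]]
  cntBnd <- function(bnd, fam) {
    j <- match(fam, bnd$family)
    if (is.na(j)) c(0L, 0L) else c(bnd$low[j], bnd$high[j])
  }
  famsA <- split(gA@markers$id, gA@markers$family)
  famsB <- split(gB@markers$id, gB@markers$family)
  fams <- union(names(famsA), names(famsB))
  capableA <- character(); capableB <- character()
  selfA <- integer(0); selfB <- integer(0)    # marker id -> x_self var
  for (f in fams) {
    rA <- cntBnd(bndA, f); rB <- cntBnd(bndB, f)
    capA <- rA[2] > rB[1]   # side A may hold unmatched copies of f
    capB <- rB[2] > rA[1]
    if (capA) {
      capableA <- c(capableA, famsA[[f]])
      for (m in famsA[[f]])
        selfA[[m]] <- addVar(b, en(paste0("xsA|", m)), 0, 1, "B")
    }
    if (capB) {
      capableB <- c(capableB, famsB[[f]])
      for (m in famsB[[f]])
        selfB[[m]] <- addVar(b, en(paste0("xsB|", m)), 0, 1, "B")
    }
    if (capA && capB && length(famsA[[f]]) && length(famsB[[f]])) {
      bf <- addVar(b, en(paste0("b|", f)), 0, 1, "B")          # C.23
      for (m in famsA[[f]]) addCon(b, c(selfA[[m]], bf), c(1, -1), NA, 0)
      for (m in famsB[[f]]) addCon(b, c(selfB[[m]], bf), c(1, 1), NA, 1)
    }
  }

  ## extremity-edge sibling pairs (one shared variable per marker pairing)
  pairs <- list()
  for (f in intersect(names(famsA), names(famsB))) {
    for (ma in famsA[[f]]) for (mb in famsB[[f]]) {
      x <- addVar(b, en(paste0("xp|", ma, "~", mb)), 0, 1, "B")  # C.27
      pairs[[length(pairs) + 1L]] <- list(a = ma, b = mb, var = x)
    }
  }
  pairVar <- vapply(pairs, `[[`, integer(1), "var")
  pairA <- vapply(pairs, `[[`, character(1), "a")
  pairB <- vapply(pairs, `[[`, character(1), "b")

  ## degree: each present marker extremity takes one extremity or self edge
  for (m in gA@markers$id) {
    idx <- c(pairVar[pairA == m], if (m %in% names(selfA)) selfA[[m]])
    gv <- vA$gIdx[[extremity(m, "t")]]
    addCon(b, c(idx, gv), c(rep(1, length(idx)), -1), 0, 0)
  }
  for (m in gB@markers$id) {
    idx <- c(pairVar[pairB == m], if (m %in% names(selfB)) selfB[[m]])
    gv <- vB$gIdx[[extremity(m, "t")]]
    addCon(b, c(idx, gv), c(rep(1, length(idx)), -1), 0, 0)
  }

  ## C.28 on extremity edges (both siblings), self edges
  y28 <- function(u, v, x) {     # y_v + rank_u (1 - x) >= y_u, both ways
    ru <- rank[[u]]; rv <- rank[[v]]
    addCon(b, c(yIdx[vi[[v]]], yIdx[vi[[u]]], x), c(1, -1, -ru), -ru, NA)
    addCon(b, c(yIdx[vi[[u]]], yIdx[vi[[v]]], x), c(1, -1, -rv), -rv, NA)
  }
  lEq <- function(u, v, x) {     # l equal across selected edge
    addCon(b, c(lIdx[vi[[u]]], lIdx[vi[[v]]], x), c(1, -1, 1), NA, 1)
    addCon(b, c(lIdx[vi[[v]]], lIdx[vi[[u]]], x), c(1, -1, 1), NA, 1)
  }
  for (p in pairs) {
    for (sd in c("t", "h")) {
      u <- paste0("A|", extremity(p$a, sd)); v <- paste0("B|", extremity(p$b, sd))
      y28(u, v, p$var)
      lEq(u, v, p$var)                                         # C.31 (ext)
    }
  }
  selfCon <- function(m, side, x) {
    ut <- paste0(side, "|", extremity(m, "t"))
    uh <- paste0(side, "|", extremity(m, "h"))
    for (u in c(ut, uh)) {
      ## C.28 (self): y_u <= rank_u (1 - x)
      addCon(b, c(yIdx[vi[[u]]], x), c(1, rank[[u]]), NA, rank[[u]])
      if (side == "A")                                          # C.30
        addCon(b, c(lIdx[vi[[u]]], x), c(1, 1), NA, 1)
      else
        addCon(b, c(lIdx[vi[[u]]], x), c(1, -1), 0, NA)
    }
  }
  for (m in names(selfA)) selfCon(m, "A", selfA[[m]])
  for (m in names(selfB)) selfCon(m, "B", selfB[[m]])

  ## telomere report variables -------------------------------------------
  telA <- verts$vid[verts$telomeric & verts$side == "A"]
  telB <- verts$vid[verts$telomeric & verts$side == "B"]
  rAB <- integer(0); rAb <- integer(0); rAa <- integer(0)
  raB <- integer(0); rBb <- integer(0)
  for (v in telA) {
    rAB[[v]] <- addVar(b, en(paste0("rAB|", v)), 0, 1, "B")
    rAb[[v]] <- addVar(b, en(paste0("rAb|", v)), 0, 1, "B")
    rAa[[v]] <- addVar(b, en(paste0("rAa|", v)), 0, 1, "B")
    addCon(b, c(rAB[[v]], zIdx[vi[[v]]]), c(1, -1), NA, 0)      # C.36
    addCon(b, c(rAb[[v]], rAa[[v]], yIdx[vi[[v]]]), c(1, 1, 1), 1, NA) # C.37
    for (r in c(rAb[[v]], rAa[[v]]))                            # C.38
      addCon(b, c(yIdx[vi[[v]]], r), c(1, rank[[v]]), NA, rank[[v]])
  }
  for (v in telB) {
    raB[[v]] <- addVar(b, en(paste0("raB|", v)), 0, 1, "B")
    rBb[[v]] <- addVar(b, en(paste0("rBb|", v)), 0, 1, "B")
    addCon(b, c(raB[[v]], rBb[[v]], yIdx[vi[[v]]]), c(1, 1, 1), 1, NA)  # C.37
    for (r in c(raB[[v]], rBb[[v]]))                            # C.38
      addCon(b, c(yIdx[vi[[v]]], r), c(1, rank[[v]]), NA, rank[[v]])
  }

  ## adjacency edges: inherit global selection (C.21), y propagation,
  ## l propagation with ab-flip charges (C.31) and telomere reporting
  ## (C.35/C.39)
  rabIdx <- integer()
  adjSide <- function(side, gmaps) {
    a <- gmaps$adjacencies
    for (i in seq_len(nrow(a))) {
      x <- gmaps$selIdx[i]
      u <- paste0(side, "|", a$e1[i]); v <- paste0(side, "|", a$e2[i])
      y28(u, v, x)
      t1 <- isTelomericExtremity(a$e1[i]); t2 <- isTelomericExtremity(a$e2[i])
      if (!t1 && !t2) {
        if (side == "A") {
          rab <- addVar(b, en(paste0("rab|", nodeA, "|", i)), 0, 1, "B")
          rabIdx <<- c(rabIdx, rab)
          ## l_u <= l_v + rab + (1 - x), both orientations
          addCon(b, c(lIdx[vi[[u]]], lIdx[vi[[v]]], rab, x),
                 c(1, -1, -1, 1), NA, 1)
          addCon(b, c(lIdx[vi[[v]]], lIdx[vi[[u]]], rab, x),
                 c(1, -1, -1, 1), NA, 1)
        } else {
          lEq(u, v, x)
        }
      } else {
        tl <- if (t1) u else v
        ex <- if (t1) v else u
        le <- lIdx[vi[[ex]]]
        if (side == "A") {
          ## C.35: l_u <= rAB + rAb + (1 - x)
          addCon(b, c(le, rAB[[tl]], rAb[[tl]], x), c(1, -1, -1, 1), NA, 1)
          ## C.39 guards: AB/Ab need neighbor label 1, Aa needs 0
          addCon(b, c(rAB[[tl]], le, x), c(1, -1, 1), NA, 1)
          addCon(b, c(rAb[[tl]], le, x), c(1, -1, 1), NA, 1)
          addCon(b, c(rAa[[tl]], le, x), c(1, 1, 1), NA, 2)
        } else {
          ## C.35: 1 - l_u <= raB + (1 - x)  =>  x <= l_u + raB
          addCon(b, c(x, le, raB[[tl]]), c(1, -1, -1), NA, 0)
          ## guards: aB needs neighbor label 0, Bb label 1
          addCon(b, c(raB[[tl]], le, x), c(1, 1, 1), NA, 2)
          addCon(b, c(rBb[[tl]], le, x), c(1, -1, 1), NA, 1)
        }
      }
    }
  }
  adjSide("A", vA)
  adjSide("B", vB)

  ## cycle reports on A-side marker extremities
  rcIdx <- integer()
  for (i in which(!verts$telomeric & verts$side == "A")) {
    rc <- addVar(b, en(paste0("rc|", verts$vid[i])), 0, 1, "B")
    addCon(b, c(rc, zIdx[i]), c(1, -1), NA, 0)                  # C.32
    rcIdx <- c(rcIdx, rc)
  }

  ## circular singletons -------------------------------------------------
  nSelf <- length(selfA) + length(selfB)
  rsIdx <- integer()
  mode <- singletonMode
  if (mode == "auto" || mode == "enumerate") {
    cap <- max(1L, ceiling(capFactor * nSelf))
    cycA <- enumerateSingletonCycles(vA$adjacencies, names(selfA), cap)
    cycB <- if (!is.null(cycA))
      enumerateSingletonCycles(vB$adjacencies, names(selfB), cap) else NULL
    tooMany <- is.null(cycA) || is.null(cycB) ||
      (length(cycA) + length(cycB)) > cap
    if (tooMany && mode == "enumerate")
      stop("too many circular-singleton candidates for enumeration mode")
    mode <- if (tooMany) "count" else "enumerated"
    if (mode == "enumerated") {
      emitCyc <- function(cycles, selfMap, gmaps, tag) {
        for (k in seq_along(cycles)) {
          cy <- cycles[[k]]
          rs <- addVar(b, en(paste0("rs", tag, "|", k)), 0, 1, "B")
          rsIdx <<- c(rsIdx, rs)
          edgeVars <- c(gmaps$selIdx[cy$adjRows],
                        unlist(selfMap[cy$markers], use.names = FALSE))
          addCon(b, c(edgeVars, rs), c(rep(1, length(edgeVars)), -1),
                 NA, length(edgeVars) - 1)
        }
      }
      emitCyc(cycA, as.list(selfA), vA, "A")
      emitCyc(cycB, as.list(selfB), vB, "B")
    }
  }
  if (mode == "count") {
    K <- max(1L, nSelf)
    gadget <- function(side, selfMap, gmaps) {
      caps <- names(selfMap)
      if (!length(caps)) return()
      exts <- paste0(side, "|", c(extremity(caps, "t"), extremity(caps, "h")))
      dI <- integer(); wI <- integer(); rI <- integer()
      for (v in exts) {
        dI[[v]] <- addVar(b, en(paste0("d|", v)), 0, 1, "B")
        wI[[v]] <- addVar(b, en(paste0("w|", v)), 0, K, "I")
        rI[[v]] <- addVar(b, en(paste0("rs|", v)), 0, 1, "B")
        rsIdx <<- c(rsIdx, rI[[v]])
      }
      flip <- function(u, v, x) {                               # C.24
        addCon(b, c(dI[[u]], dI[[v]], x), c(1, 1, 1), NA, 2)
        addCon(b, c(dI[[u]], dI[[v]], x), c(1, 1, -1), 0, NA)
      }
      for (m in caps) {
        u <- paste0(side, "|", extremity(m, "t"))
        v <- paste0(side, "|", extremity(m, "h"))
        x <- selfMap[[m]]
        flip(u, v, x)
        ## C.25 (conditional on selection): |w_u - w_v| <= K (1 - x)
        addCon(b, c(wI[[u]], wI[[v]], x), c(1, -1, K), NA, K)
        addCon(b, c(wI[[v]], wI[[u]], x), c(1, -1, K), NA, K)
      }
      a <- gmaps$adjacencies
      for (i in seq_len(nrow(a))) {
        u <- paste0(side, "|", a$e1[i]); v <- paste0(side, "|", a$e2[i])
        if (!(u %in% exts) || !(v %in% exts)) next
        x <- gmaps$selIdx[i]
        flip(u, v, x)
        ## C.26: K (1 - x + rs_u + rs_v) + w_v >= w_u + d_v - d_u
        c26 <- function(uu, vv) {
          addCon(b, c(x, rI[[uu]], rI[[vv]], wI[[vv]], wI[[uu]],
                      dI[[vv]], dI[[uu]]),
                 c(-K, K, K, 1, -1, -1, 1), -K, NA)
        }
        c26(u, v); c26(v, u)
      }
    }
    gadget("A", as.list(selfA), vA)
    gadget("B", as.list(selfB), vB)
  }

  ## distance assembly ---------------------------------------------------
  ub <- nV + 2L
  pmaxa <- addVar(b, en("pmaxa"), 0, ub, "I")
  pmaxb <- addVar(b, en("pmaxb"), 0, ub, "I")
  qI <- addVar(b, en("q"), -ub, ub, "I")
  fI <- addVar(b, en("f"), 0, 2L * nV + 2L, "I", obj = alpha)
  sumGe <- function(target, items) {       # target >= sum(items)
    if (length(items))
      addCon(b, c(target, items), c(1, rep(-1, length(items))), 0, NA)
  }
  sumGe(pmaxa, unlist(rAa)); sumGe(pmaxa, unlist(raB))
  sumGe(pmaxb, unlist(rAb)); sumGe(pmaxb, unlist(rBb))
  ## 2q >= p_ab + pmaxa + pmaxb - p_AB
  addCon(b, c(qI, rabIdx, pmaxa, pmaxb, unlist(rAB)),
         c(2, rep(-1, length(rabIdx)), -1, -1,
           rep(1, length(rAB))), 0, NA)
  ## f = n - c + q + s
  addCon(b, c(fI, pairVar, rcIdx, qI, rsIdx),
         c(1, rep(-1, length(pairVar)), rep(1, length(rcIdx)), -1,
           rep(-1, length(rsIdx))), 0, 0)

  list(name = edgeName, nodeA = nodeA, nodeB = nodeB,
       f = fI, pairVar = pairVar, pairA = pairA, pairB = pairB,
       rc = rcIdx, rs = rsIdx, singletonMode = mode)
}

#' Build the small parsimony linearization ILP
#'
#' Emits the full model for a phylogeny whose nodes carry (degenerate)
#' genomes: global linearization variables and constraints per node, one
#' comparison-diagram decomposition per tree edge, the closed-form distance
#' assembly, and the weighted objective
#' \eqn{\min \sum_E (\alpha f_E - (1-\alpha) w_E)}.
#'
#' @param phylogeny a \code{\linkS4class{Phylogeny}} with genomes bound to
#'   all nodes (leaves non-degenerate).
#' @param weights named list (per node) of candidate adjacency weights
#'   (named numeric keyed by telomere-anonymized adjacency key), or a single
#'   numeric vector applied to every node.
#' @param bounds optional family copy-number bounds as returned by
#'   \code{\link{readFamilyBounds}}; families not listed default to "every
#'   candidate marker occurs".
#' @param alpha trade-off between tree distance and adjacency weight in
#'   [0, 1]; 1 = pure distance minimization.
#' @param betaEmulation optional non-negative number subtracted from the
#'   weight of every telomeric candidate adjacency before assembly
#'   (emulates an explicit telomere penalty; a predecessor default of
#'   alpha' = 1/2, beta' = 1/4 corresponds to \code{alpha = 2/3},
#'   \code{betaEmulation = 1}).
#' @param singletonMode "auto" (enumerate candidate circular singletons up
#'   to twice the number of self edges, else switch to the counting
#'   gadget), "enumerate" or "count".
#' @param lowerBounds optional data.frame with columns \code{leaf1},
#'   \code{leaf2}, \code{distance}: per leaf pair, the summed branch
#'   distances on the connecting tree path are constrained to be at least
#'   the pairwise distance (see \code{\link{leafPairLowerBounds}}).
#' @return an \code{\linkS4class{ILPModel}} with decode metadata.
#' @export
buildSppModel <- function(phylogeny, weights = NULL, bounds = NULL,
                          alpha = 1, betaEmulation = NULL,
                          singletonMode = c("auto", "enumerate", "count"),
                          lowerBounds = NULL) {
  singletonMode <- match.arg(singletonMode)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  nodes <- phylogeny@nodes
  if (!all(nodes %in% names(phylogeny@genomes)))
    stop("every tree node needs a genome; missing: ",
         paste(setdiff(nodes, names(phylogeny@genomes)), collapse = ", "))
  genomes <- phylogeny@genomes
  edges <- phylogeny@edges
  deg <- table(factor(c(edges$parent, edges$child), levels = nodes))

  perNodeWeights <- function(node) {
    w <- if (is.list(weights)) weights[[node]] else weights
    if (is.null(w)) w <- numeric()
    if (!is.null(betaEmulation) && length(w)) {
      telo <- grepl("*:o", names(w), fixed = TRUE)
      w[telo] <- w[telo] - betaEmulation
    }
    w
  }

  b <- newModelBuilder()
  gm <- list(); bndAll <- list(); wAll <- list()
  for (nd in nodes) {
    bndAll[[nd]] <- nodeBounds(nd, genomes[[nd]], bounds)
    wAll[[nd]] <- perNodeWeights(nd)
    gm[[nd]] <- emitGlobalNode(b, nd, genomes[[nd]], bndAll[[nd]],
                               as.integer(deg[[nd]]), alpha, wAll[[nd]])
  }
  edgeMaps <- list()
  for (i in seq_len(nrow(edges))) {
    nm <- paste0(edges$parent[i], "->", edges$child[i])
    edgeMaps[[nm]] <- emitLocalEdge(b, nm, edges$parent[i], edges$child[i],
                                    genomes, gm, bndAll, alpha, singletonMode)
  }
  if (!is.null(lowerBounds) && nrow(lowerBounds)) {           # C.opt
    for (i in seq_len(nrow(lowerBounds))) {
      path <- treePathEdges(phylogeny, lowerBounds$leaf1[i],
                            lowerBounds$leaf2[i])
      fIdx <- vapply(path, function(nm) edgeMaps[[nm]]$f, integer(1))
      addCon(b, fIdx, rep(1, length(fIdx)), lowerBounds$distance[i], NA)
    }
  }
  finalizeModel(b, maps = list(nodes = gm, edges = edgeMaps,
                               alpha = alpha, weights = wAll,
                               degree = as.list(deg)))
}

## Names of the tree edges on the path between two nodes.
treePathEdges <- function(phylogeny, from, to) {
  par <- stats::setNames(phylogeny@edges$parent, phylogeny@edges$child)
  anc <- function(x) {
    out <- x
    while (x %in% names(par)) { x <- par[[x]]; out <- c(out, x) }
    out
  }
  aF <- anc(from); aT <- anc(to)
  meet <- aF[aF %in% aT][1]
  up <- function(x, stopAt) {
    nm <- character()
    while (x != stopAt) {
      nm <- c(nm, paste0(par[[x]], "->", x))
      x <- par[[x]]
    }
    nm
  }
  c(up(from, meet), up(to, meet))
}
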