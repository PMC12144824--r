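#' @include genome.R io.R
NULL

#' Simulation settings
#'
#' Defaults follow the linear-chromosome benchmark protocol: a balanced
#' four-leaf tree, 100-marker root genomes, 30 operations per branch with
#' duplication rate 0.4, deletion rate 0.2, insertion rate 0.1 (remainder
#' DCJ), Zipf length exponent 6.0 for duplications and 4.0 for indels
#' (lengths truncated at 20), and 30 adversarial noise adjacencies per
#' internal node.
#'
#' @param tree Newick string with labeled internal nodes.
#' @param rootMarkers number of markers in the root genome.
#' @param chromosomes number of root chromosomes.
#' @param circular logical: circular root chromosomes?
#' @param opsPerBranch operations per tree branch.
#' @param dupRate,delRate,insRate per-operation probabilities of
#'   duplication, deletion and insertion; the remainder is the DCJ rate.
#' @param zipfDup,zipfIndel Zipf exponents for duplication and indel
#'   segment lengths.
#' @param zipfMax truncation of the Zipf length distributions.
#' @param noise adversarial noise adjacencies per internal node.
#' @param seed RNG seed; identical seeds yield identical ground truths.
#' @return list of settings for \code{\link{simulateEvolution}}.
#' @export
simulationConfig <- function(
    tree = "(((A:1.0,B:1.0)F:1.0),((C:1.0,D:1.0)G:1.0))Root;",
    rootMarkers = 100L, chromosomes = 1L, circular = FALSE,
    opsPerBranch = 30L, dupRate = 0.4, delRate = 0.2, insRate = 0.1,
    zipfDup = 6.0, zipfIndel = 4.0, zipfMax = 20L,
    noise = 30L, seed = 1L) {
  rates <- c(dupRate, delRate, insRate)
  if (any(rates < 0) || sum(rates) > 1)
    stop("rates must be non-negative and sum to at most 1")
  if (rootMarkers < 1L || chromosomes < 1L || chromosomes > rootMarkers)
    stop("invalid root genome size/structure")
  list(tree = tree, rootMarkers = as.integer(rootMarkers),
       chromosomes = as.integer(chromosomes), circular = circular,
       opsPerBranch = as.integer(opsPerBranch),
       dupRate = dupRate, delRate = delRate, insRate = insRate,
       zipfDup = zipfDup, zipfIndel = zipfIndel,
       zipfMax = as.integer(zipfMax),
       noise = as.integer(noise), seed = as.integer(seed))
}

## ---- operations on the chromosome-list representation -----------------
## A working genome is list(chroms = list(list(ids, signs, circular)),
## famOf = named character).  Marker ids are "<family>_<copy>"; the copy
## counter is global to one simulation so ids stay unique across the tree.

chromsToAdjIds <- function(chroms) {
  adjs <- list()
  for (ch in chroms) {
    n <- length(ch$ids)
    left <- ifelse(ch$signs > 0L, extremity(ch$ids, "t"), extremity(ch$ids, "h"))
    right <- ifelse(ch$signs > 0L, extremity(ch$ids, "h"), extremity(ch$ids, "t"))
    if (n > 1L)
      for (i in 1:(n - 1L)) adjs[[length(adjs) + 1L]] <- c(right[i], left[i + 1L])
    if (ch$circular) adjs[[length(adjs) + 1L]] <- c(right[n], left[1L])
    else {
      adjs[[length(adjs) + 1L]] <- c("TEL", left[1L])
      adjs[[length(adjs) + 1L]] <- c(right[n], "TEL")
    }
  }
  adjs
}

adjIdsToChroms <- function(adjs, ids) {
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
  seen <- new.env(parent = emptyenv())
  chroms <- list()
  walk <- function(start, circular) {
    cid <- character(); csg <- integer()
    e <- start
    repeat {
      m <- extremityMarker(e); side <- extremitySide(e)
      cid <- c(cid, m); csg <- c(csg, if (side == "t") 1L else -1L)
      assign(m, TRUE, envir = seen)
      exit <- extremity(m, if (side == "t") "h" else "t")
      nxt <- if (exists(exit, envir = partner)) get(exit, envir = partner)
             else NULL
      if (is.null(nxt)) break
      if (circular && nxt == start) break
      e <- nxt
    }
    list(ids = cid, signs = csg, circular = circular)
  }
  for (e in telAt) {
    if (exists(extremityMarker(e), envir = seen)) next
    chroms[[length(chroms) + 1L]] <- walk(e, FALSE)
  }
  for (m in ids) {
    if (exists(m, envir = seen)) next
    chroms[[length(chroms) + 1L]] <- walk(extremity(m, "t"), TRUE)
  }
  chroms
}

opDCJ <- function(chroms) {
  adjs <- chromsToAdjIds(chroms)
  nA <- length(adjs)
  singles <- which(vapply(adjs, function(a) a[1] != "TEL" && a[2] != "TEL",
                          logical(1)))
  nMoves <- (if (nA >= 2L) choose(nA, 2L) * 2L else 0L) + length(singles)
  if (nMoves == 0L) return(NULL)
  pick <- sample.int(nMoves, 1L)
  if (nA >= 2L && pick <= choose(nA, 2L) * 2L) {
    pr <- utils::combn(nA, 2L)
    k <- ceiling(pick / 2L)
    mode <- pick - (k - 1L) * 2L
    i <- pr[1, k]; j <- pr[2, k]
    p <- adjs[[i]]; q <- adjs[[j]]
    newA <- if (mode == 1L) list(c(p[1], q[1]), c(p[2], q[2]))
            else list(c(p[1], q[2]), c(p[2], q[1]))
    adjs <- c(adjs[-c(i, j)], newA)
  } else {
    i <- singles[pick - (if (nA >= 2L) choose(nA, 2L) * 2L else 0L)]
    p <- adjs[[i]]
    adjs <- c(adjs[-i], list(c(p[1], "TEL"), c(p[2], "TEL")))
  }
  ids <- unlist(lapply(chroms, `[[`, "ids"))
  adjIdsToChroms(adjs, ids)
}

## Pick a contiguous segment: returns list(chrom index, positions) or NULL.
pickSegment <- function(chroms, len) {
  sizes <- lengths(lapply(chroms, `[[`, "ids"))
  ok <- which(sizes >= 1L)
  if (!length(ok)) return(NULL)
  ci <- ok[sample.int(length(ok), 1L)]
  n <- sizes[ci]
  len <- min(len, n)
  start <- sample.int(if (chroms[[ci]]$circular) n else n - len + 1L, 1L)
  pos <- if (chroms[[ci]]$circular) ((start - 1L + 0:(len - 1L)) %% n) + 1L
         else start:(start + len - 1L)
  list(ci = ci, pos = pos)
}

insertIntoChroms <- function(chroms, ids, signs, avoid = NULL) {
  ## choose a random gap over all chromosomes; avoid = c(chrom, gap)
  gaps <- list()
  for (ci in seq_along(chroms)) {
    n <- length(chroms[[ci]]$ids)
    gs <- if (chroms[[ci]]$circular) seq_len(n) else 0:n
    for (g in gs) gaps[[length(gaps) + 1L]] <- c(ci, g)
  }
  if (!is.null(avoid) && length(gaps) > 1L)
    gaps <- Filter(function(g) !identical(g, avoid), gaps)
  g <- gaps[[sample.int(length(gaps), 1L)]]
  ci <- g[1]; gp <- g[2]
  ch <- chroms[[ci]]
  ord <- c(seq_len(gp), 0L, if (gp < length(ch$ids)) (gp + 1L):length(ch$ids))
  nid <- character(); nsg <- integer()
  for (k in ord) {
    if (k == 0L) { nid <- c(nid, ids); nsg <- c(nsg, signs) }
    else { nid <- c(nid, ch$ids[k]); nsg <- c(nsg, ch$signs[k]) }
  }
  chroms[[ci]] <- list(ids = nid, signs = nsg, circular = ch$circular)
  chroms
}

#' Simulate genome evolution along a phylogeny
#'
#' Builds a root genome of single-copy families and evolves it along every
#' branch with the configured number of operations, each drawn by rate:
#' tandem-free segmental duplication (new copies keep their family),
#' segmental deletion, segmental insertion of novel single-copy families,
#' or a uniformly random DCJ (two cuts and a random rejoin; single cuts
#' create telomeres, so chromosome counts drift).  All intermediate genomes
#' remain valid.
#'
#' @param config settings from \code{\link{simulationConfig}}.
#' @return a \code{\linkS4class{GroundTruth}}: the phylogeny with true
#'   genomes at every node, the true adjacency sets of the internal nodes
#'   (telomere-anonymized keys) and a per-branch operation log.
#' @export
simulateEvolution <- function(config) {
  set.seed(config$seed)
  phy <- readPhylogeny(config$tree)
  state <- new.env(parent = emptyenv())
  state$copyN <- integer()       # per-family copy counter
  state$insN <- 0L
  newId <- function(fam) {
    k <- (state$copyN[fam] %||% NA_integer_)
    k <- if (is.na(k)) 1L else k + 1L
    state$copyN[fam] <- k
    paste0(fam, "_", k)
  }
  ## root genome
  fams <- as.character(seq_len(config$rootMarkers))
  ids <- vapply(fams, newId, character(1))
  famOf <- stats::setNames(fams, ids)
  split_ <- sort(rep_len(seq_len(config$chromosomes), config$rootMarkers))
  chroms <- lapply(seq_len(config$chromosomes), function(ci) {
    sel <- which(split_ == ci)
    list(ids = ids[sel], signs = rep(1L, length(sel)),
         circular = config$circular)
  })

  logRows <- list()
  applyOps <- function(chroms, famOf, branch) {
    for (k in seq_len(config$opsPerBranch)) {
      for (attempt in 1:50) {
        u <- stats::runif(1)
        done <- FALSE
        if (u < config$dupRate) {
          len <- rzipf(1, config$zipfDup, config$zipfMax)
          seg <- pickSegment(chroms, len)
          if (!is.null(seg)) {
            ch <- chroms[[seg$ci]]
            segIds <- ch$ids[seg$pos]; segSg <- ch$signs[seg$pos]
            nid <- vapply(unname(famOf[segIds]), newId, character(1))
            famOf[nid] <- famOf[segIds]
            ## tandem-free: do not re-insert directly after the source
            avoid <- c(seg$ci, seg$pos[length(seg$pos)])
            chroms <- insertIntoChroms(chroms, nid, segSg, avoid = avoid)
            logRows[[length(logRows) + 1L]] <<-
              data.frame(branch = branch, op = "dup", len = length(nid))
            done <- TRUE
          }
        } else if (u < config$dupRate + config$delRate) {
          len <- rzipf(1, config$zipfIndel, config$zipfMax)
          seg <- pickSegment(chroms, len)
          total <- sum(lengths(lapply(chroms, `[[`, "ids")))
          if (!is.null(seg) && total - length(seg$pos) >= 1L) {
            ch <- chroms[[seg$ci]]
            keep <- setdiff(seq_along(ch$ids), seg$pos)
            ## preserve order after circular wrap removal
            if (ch$circular && length(keep)) {
              last <- seg$pos[length(seg$pos)]
              keep <- ((last + seq_len(length(ch$ids)) - 1L) %% length(ch$ids)) + 1L
              keep <- keep[!(keep %in% seg$pos)]
            }
            famOf <- famOf[setdiff(names(famOf), ch$ids[seg$pos])]
            if (length(keep))
              chroms[[seg$ci]] <- list(ids = ch$ids[keep],
                                       signs = ch$signs[keep],
                                       circular = ch$circular)
            else chroms <- chroms[-seg$ci]
            logRows[[length(logRows) + 1L]] <<-
              data.frame(branch = branch, op = "del", len = length(seg$pos))
            done <- TRUE
          }
        } else if (u < config$dupRate + config$delRate + config$insRate) {
          len <- rzipf(1, config$zipfIndel, config$zipfMax)
          state$insN <- state$insN + 1L
          nf <- paste0("ins", state$insN, ".", seq_len(len))
          nid <- vapply(nf, newId, character(1))
          famOf[nid] <- nf
          chroms <- insertIntoChroms(chroms, nid, rep(1L, len))
          logRows[[length(logRows) + 1L]] <<-
            data.frame(branch = branch, op = "ins", len = len)
          done <- TRUE
        } else {
          nc <- opDCJ(chroms)
          if (!is.null(nc)) {
            chroms <- nc
            logRows[[length(logRows) + 1L]] <<-
              data.frame(branch = branch, op = "dcj", len = NA_integer_)
            done <- TRUE
          }
        }
        if (done) break
        if (attempt == 50L) stop("no applicable operation after 50 attempts")
      }
    }
    list(chroms = chroms, famOf = famOf)
  }

  genomes <- list()
  mkGenome <- function(node, chroms, famOf) {
    ids <- unlist(lapply(chroms, `[[`, "ids"))
    genomeFromChromosomes(node, chroms, famOf[ids])
  }
  recurse <- function(node, chroms, famOf) {
    genomes[[node]] <<- mkGenome(node, chroms, famOf)
    for (ch in phy@edges$child[phy@edges$parent == node]) {
      res <- applyOps(chroms, famOf, paste0(node, "->", ch))
      recurse(ch, res$chroms, res$famOf)
    }
  }
  recurse(phy@root, chroms, famOf)
  phy <- bindGenomes(phy, genomes)
  internal <- setdiff(phy@nodes, phy@leaves)
  trueAdj <- lapply(internal, function(nd) {
    a <- phy@genomes[[nd]]@adjacencies
    adjKeyAnon(a$e1, a$e2)
  })
  names(trueAdj) <- internal
  opLog <- if (length(logRows)) do.call(rbind, logRows) else
    data.frame(branch = character(), op = character(), len = integer())
  new("GroundTruth", phylogeny = phy, trueAdjacencies = trueAdj,
      opLog = opLog, config = config)
}

setMethod("show", "GroundTruth", function(object) {
  sizes <- vapply(object@phylogeny@genomes, function(g) nrow(g@markers),
                  integer(1))
  cat("GroundTruth: ", length(sizes), " genomes (",
      min(sizes), "-", max(sizes), " markers), ",
      nrow(object@opLog), " operations, seed ", object@config$seed,
      "\n", sep = "")
})

#' Add adversarial candidate-adjacency noise at the internal nodes
#'
#' Replaces every internal node's true genome by a degenerate genome whose
#' candidate set is the true adjacency set plus \code{k} uniformly drawn
#' false adjacencies between marker extremities (never duplicating a true
#' adjacency).  All candidates, true and false alike, receive weight 1, so
#' the noise is adversarial: indistinguishable from truth by weight.
#'
#' @param truth a \code{\linkS4class{GroundTruth}}.
#' @param k noise adjacencies per internal node.
#' @param seed RNG seed.
#' @return list with \code{phylogeny} (internal nodes degenerate) and
#'   \code{weights} (per-node candidate weights).
#' @export
addNoise <- function(truth, k, seed = 1L) {
  set.seed(seed)
  phy <- truth@phylogeny
  weights <- list()
  for (nd in setdiff(phy@nodes, phy@leaves)) {
    g <- phy@genomes[[nd]]
    ext <- extremities(g)
    trueKeys <- adjKeyAnon(g@adjacencies$e1, g@adjacencies$e2)
    pool <- t(utils::combn(ext, 2L))
    poolKeys <- adjKeyAnon(pool[, 1], pool[, 2])
    free <- which(!(poolKeys %in% trueKeys))
    if (k > length(free))
      stop("not enough non-true extremity pairs for ", k,
           " noise adjacencies at node ", nd)
    sel <- if (k) sample(free, k) else integer()
    a2 <- rbind(g@adjacencies,
                data.frame(e1 = pool[sel, 1], e2 = pool[sel, 2],
                           stringsAsFactors = FALSE))
    D <- DegenerateGenome(nd, g@markers, telomeres = g@telomeres,
                          adjacencies = a2)
    phy@genomes[[nd]] <- D
    weights[[nd]] <- stats::setNames(rep(1, nrow(a2)),
                                     adjKeyAnon(a2$e1, a2$e2))
  }
  list(phylogeny = phy, weights = weights)
}
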