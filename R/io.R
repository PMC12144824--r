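#' @include genome.R
NULL

#' Parse genomes in UniMoG dialect
#'
#' Genomes are given as \code{>name} headers followed by one or more
#' chromosome lines of whitespace-separated signed family names, terminated
#' by \code{|} (linear) or \code{)} (circular).  The k-th occurrence of a
#' family name across the whole input becomes marker \code{family_k}, so
#' marker ids are unique across all genomes parsed together.
#'
#' @param text character scalar (file content) or vector of lines.
#' @param file path to read instead of \code{text}.
#' @return named list of \code{\linkS4class{Genome}} objects.
#' @examples
#' gs <- readUnimog(">A\n1 2 |\n>B\n1 -2 )")
#' gs$A
#' @export
readUnimog <- function(text = NULL, file = NULL) {
  if (is.null(text)) text <- readLines(file)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  famCount <- new.env(parent = emptyenv())
  nextCopy <- function(fam) {
    k <- (if (exists(fam, envir = famCount)) get(fam, envir = famCount) else 0L) + 1L
    assign(fam, k, envir = famCount)
    paste0(fam, "_", k)
  }
  genomes <- list()
  cur <- NULL
  curChroms <- list()
  flush <- function() {
    if (is.null(cur)) return()
    if (!length(curChroms))
      stop("genome '", cur, "' has no chromosomes")
    fams <- unlist(lapply(curChroms, function(ch) ch$fams))
    ids <- unlist(lapply(curChroms, function(ch) ch$ids))
    chroms <- lapply(curChroms, function(ch)
      list(ids = ch$ids, signs = ch$signs, circular = ch$circular))
    g <- genomeFromChromosomes(cur, chroms,
                               stats::setNames(fams, ids))
    if (cur %in% names(genomes))
      stop("duplicate genome name '", cur, "'")
    genomes[[cur]] <<- g
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    if (startsWith(ln, ">")) {
      flush()
      cur <- trimws(sub("^>", "", ln))
      if (!nzchar(cur)) stop("empty genome name at line ", i)
      curChroms <- list()
    } else {
      if (is.null(cur)) stop("chromosome before genome header at line ", i)
      toks <- strsplit(ln, "[ \t]+")[[1]]
      term <- toks[length(toks)]
      if (!(term %in% c("|", ")")))
        stop("line ", i, ": chromosome must end with '|' or ')', got '",
             term, "'")
      toks <- toks[-length(toks)]
      if (!length(toks)) stop("line ", i, ": empty chromosome")
      signs <- ifelse(startsWith(toks, "-"), -1L, 1L)
      fams <- sub("^[-+]", "", toks)
      if (any(!nzchar(fams)) || any(grepl("[:|)]", fams)))
        stop("line ", i, ": malformed marker token")
      ids <- vapply(fams, nextCopy, character(1), USE.NAMES = FALSE)
      curChroms[[length(curChroms) + 1L]] <-
        list(ids = ids, fams = fams, signs = signs, circular = term == ")")
    }
  }
  flush()
  if (!length(genomes)) stop("no genomes in input")
  genomes
}

#' Write genomes in UniMoG dialect
#'
#' Inverse of \code{\link{readUnimog}} up to marker-copy renaming:
#' re-parsing the output reproduces the same genome graphs.
#'
#' @param genomes a \code{\linkS4class{Genome}} or list of them.
#' @param file optional path; when \code{NULL} the text is returned.
#' @return the UniMoG text, invisibly when written to a file.
#' @export
writeUnimog <- function(genomes, file = NULL) {
  if (is(genomes, "Genome")) genomes <- list(genomes)
  out <- character()
  for (g in genomes) {
    out <- c(out, paste0(">", g@name))
    fam <- stats::setNames(g@markers$family, g@markers$id)
    for (ch in chromosomes(g)) {
      toks <- paste0(ifelse(ch$signs < 0L, "-", ""), fam[ch$ids])
      out <- c(out, paste(c(toks, if (ch$circular) ")" else "|"),
                          collapse = " "))
    }
  }
  txt <- paste(out, collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Parse a candidate-adjacency table
#'
#' Tab-separated columns: \code{genome}, \code{marker1}, \code{side1},
#' \code{marker2}, \code{side2} and optional \code{weight}.  Sides are
#' \code{t} (tail), \code{h} (head) or \code{o} (telomere); a row with side
#' \code{o} creates a telomeric adjacency (the marker column then names the
#' telomere; repeated names share the telomere, \code{.} creates a fresh
#' one).  Marker ids follow the \code{<family>_<copy>} convention of
#' \code{\link{readUnimog}}; an id without the suffix denotes copy 1.
#' Lines starting with \code{#} are comments; a header line is recognized
#' and skipped; a missing weight column defaults to weight 0.
#'
#' @param text character scalar or vector of lines.
#' @param file path to read instead of \code{text}.
#' @return list with elements \code{genomes} (named list of
#'   \code{\linkS4class{DegenerateGenome}}) and \code{weights} (named list,
#'   per genome, of numeric weights keyed by telomere-anonymized adjacency
#'   key).
#' @export
readAdjacencies <- function(text = NULL, file = NULL) {
  if (is.null(text)) text <- readLines(file)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) && grepl("^genome\\b", lines[1], ignore.case = TRUE))
    lines <- lines[-1]
  if (!length(lines)) stop("empty adjacency table")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 5L)
  if (length(bad))
    stop("adjacency table line ", bad[1], ": expected >= 5 tab-separated fields")

  perGenome <- new.env(parent = emptyenv())
  getG <- function(gn) {
    if (!exists(gn, envir = perGenome))
      assign(gn, list(mark = character(), tel = character(),
                      e1 = character(), e2 = character(), w = numeric(),
                      telN = 0L),
             envir = perGenome)
    get(gn, envir = perGenome)
  }
  normId <- function(id) {
    if (grepl("_[0-9]+$", id)) id else paste0(id, "_1")
  }
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    gn <- f[1]
    sides <- c(f[3], f[5])
    if (!all(sides %in% c("t", "h", "o")))
      stop("line ", i, ": unknown side code '",
           paste(setdiff(sides, c("t", "h", "o")), collapse = ","), "'")
    if (all(sides == "o"))
      stop("line ", i, ": adjacency joining two telomeres is not allowed")
    st <- getG(gn)
    ends <- character(2)
    for (k in 1:2) {
      mk <- f[2 * k]
      if (sides[k] == "o") {
        if (mk == "." || !nzchar(mk)) {
          st$telN <- st$telN + 1L
          mk <- paste0("tel", st$telN)
        }
        st$tel <- union(st$tel, mk)
        ends[k] <- extremity(mk, "o")
      } else {
        mk <- normId(mk)
        st$mark <- union(st$mark, mk)
        ends[k] <- extremity(mk, sides[k])
      }
    }
    w <- if (length(f) >= 6L && nzchar(f[6])) as.numeric(f[6]) else 0
    st$e1 <- c(st$e1, ends[1]); st$e2 <- c(st$e2, ends[2]); st$w <- c(st$w, w)
    assign(gn, st, envir = perGenome)
  }
  genomes <- list(); weights <- list()
  for (gn in ls(perGenome)) {
    st <- get(gn, envir = perGenome)
    key <- adjKey(st$e1, st$e2)
    keep <- !duplicated(key)
    fam <- sub("_[0-9]+$", "", st$mark)
    genomes[[gn]] <- DegenerateGenome(
      gn,
      markers = data.frame(id = st$mark, family = fam,
                           stringsAsFactors = FALSE),
      telomeres = st$tel,
      adjacencies = data.frame(e1 = st$e1[keep], e2 = st$e2[keep],
                               stringsAsFactors = FALSE))
    weights[[gn]] <- stats::setNames(st$w[keep],
                                     adjKeyAnon(st$e1[keep], st$e2[keep]))
  }
  list(genomes = genomes, weights = weights)
}

#' Read a rooted phylogeny with labeled internal nodes
#'
#' @param text Newick string (internal node labels mandatory).
#' @param file path to read instead of \code{text}.
#' @param genomes optional named list of (degenerate) genomes to bind to the
#'   nodes by name.
#' @return a \code{\linkS4class{Phylogeny}}.
#' @export
readPhylogeny <- function(text = NULL, file = NULL, genomes = list()) {
  tr <- if (is.null(text)) ape::read.tree(file = file) else
    ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick input")
  tr <- ape::collapse.singles(tr)
  nTip <- length(tr$tip.label)
  nInt <- tr$Nnode
  intLabels <- tr$node.label
  if (is.null(intLabels) || any(!nzchar(intLabels)))
    stop("all internal nodes must be labeled")
  labels <- c(tr$tip.label, intLabels)
  if (anyDuplicated(labels)) stop("duplicated node names in tree")
  edges <- data.frame(parent = labels[tr$edge[, 1]],
                      child = labels[tr$edge[, 2]],
                      stringsAsFactors = FALSE)
  root <- labels[nTip + 1L]
  phy <- new("Phylogeny", nodes = labels, edges = edges, root = root,
             leaves = tr$tip.label, genomes = list())
  if (length(genomes)) phy <- bindGenomes(phy, genomes)
  phy
}

#' Bind genomes to phylogeny nodes
#'
#' @param phylogeny a \code{\linkS4class{Phylogeny}}.
#' @param genomes named list of (degenerate) genomes; names must match node
#'   names.
#' @return the phylogeny with genomes attached (validated).
#' @export
bindGenomes <- function(phylogeny, genomes) {
  unknown <- setdiff(names(genomes), phylogeny@nodes)
  if (length(unknown))
    stop("genome(s) without tree node: ", paste(unknown, collapse = ", "))
  phylogeny@genomes[names(genomes)] <- genomes
  validObject(phylogeny)
  phylogeny
}

#' Tree edges of a phylogeny
#'
#' @param phylogeny a \code{\linkS4class{Phylogeny}}.
#' @return data.frame with columns \code{parent}, \code{child}.
#' @export
treeEdges <- function(phylogeny) phylogeny@edges

setMethod("show", "Phylogeny", function(object) {
  cat("Phylogeny: ", length(object@nodes), " nodes (",
      length(object@leaves), " leaves), root '", object@root, "', ",
      nrow(object@edges), " edges; ",
      sum(object@nodes %in% names(object@genomes)),
      " node(s) carry genomes\n", sep = "")
})

#' Read per-family marker copy-number bounds for ancestral genomes
#'
#' Tab-separated columns \code{genome}, \code{family}, \code{low},
#' \code{high}.  Families not listed default to "every candidate marker
#' occurs" (low = high = number of candidate copies).
#'
#' @param text character scalar or vector of lines.
#' @param file path to read instead of \code{text}.
#' @return data.frame with columns \code{genome}, \code{family}, \code{low},
#'   \code{high}.
#' @export
readFamilyBounds <- function(text = NULL, file = NULL) {
  if (is.null(text)) text <- readLines(file)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) && grepl("^genome\\b", lines[1], ignore.case = TRUE))
    lines <- lines[-1]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 4L)) stop("bounds table: expected 4 fields per line")
  out <- data.frame(genome = vapply(f, `[`, "", 1L),
                    family = vapply(f, `[`, "", 2L),
                    low = as.integer(vapply(f, `[`, "", 3L)),
                    high = as.integer(vapply(f, `[`, "", 4L)),
                    stringsAsFactors = FALSE)
  if (any(out$low < 0L | out$low > out$high))
    stop("bounds must satisfy 0 <= low <= high")
  out
}
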