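#' @include AllClasses.R
NULL

#' Construct a degenerate genome
#'
#' @param name genome label.
#' @param markers data.frame with columns \code{id}, \code{family}.
#' @param telomeres character vector of telomere ids.
#' @param adjacencies data.frame with columns \code{e1}, \code{e2}.
#' @return a \code{\linkS4class{DegenerateGenome}}.
#' @export
DegenerateGenome <- function(name, markers, telomeres = character(),
                             adjacencies = data.frame(e1 = character(),
                                                      e2 = character())) {
  markers <- data.frame(id = as.character(markers$id),
                        family = as.character(markers$family),
                        stringsAsFactors = FALSE)
  adjacencies <- data.frame(e1 = as.character(adjacencies$e1),
                            e2 = as.character(adjacencies$e2),
                            stringsAsFactors = FALSE)
  new("DegenerateGenome", name = name, markers = markers,
      telomeres = as.character(telomeres), adjacencies = adjacencies)
}

#' Construct a genome (validated perfect adjacency matching)
#'
#' @inheritParams DegenerateGenome
#' @return a \code{\linkS4class{Genome}}.
#' @export
Genome <- function(name, markers, telomeres = character(),
                   adjacencies = data.frame(e1 = character(),
                                            e2 = character())) {
  d <- DegenerateGenome(name, markers, telomeres, adjacencies)
  new("Genome", d)
}

#' @rdname genome-accessors
#' @export
setGeneric("genomeName", function(x) standardGeneric("genomeName"))
#' @rdname genome-accessors
#' @export
setGeneric("markerTable", function(x) standardGeneric("markerTable"))
#' @rdname genome-accessors
#' @export
setGeneric("adjacencyTable", function(x) standardGeneric("adjacencyTable"))
#' @rdname genome-accessors
#' @export
setGeneric("telomeres", function(x) standardGeneric("telomeres"))
#' @rdname genome-accessors
#' @export
setGeneric("extremities", function(x) standardGeneric("extremities"))

#' Accessors for (degenerate) genomes
#'
#' \code{genomeName} returns the label; \code{markerTable} the marker/family
#' table; \code{adjacencyTable} the candidate adjacency edges;
#' \code{telomeres} the telomere ids; \code{extremities} the marker
#' extremity encodings (telomeres excluded, as in the set E of the genome
#' graph).
#'
#' @param x a \code{\linkS4class{DegenerateGenome}}.
#' @return see description.
#' @name genome-accessors
#' @aliases genomeName,DegenerateGenome-method
NULL

setMethod("genomeName", "DegenerateGenome", function(x) x@name)
setMethod("markerTable", "DegenerateGenome", function(x) x@markers)
setMethod("adjacencyTable", "DegenerateGenome", function(x) x@adjacencies)
setMethod("telomeres", "DegenerateGenome", function(x) x@telomeres)
setMethod("extremities", "DegenerateGenome", function(x) {
  if (!nrow(x@markers)) return(character())
  c(extremity(x@markers$id, "t"), extremity(x@markers$id, "h"))
})

setMethod("show", "DegenerateGenome", function(object) {
  cat(class(object), " '", object@name, "': ",
      nrow(object@markers), " markers (",
      length(unique(object@markers$family)), " families), ",
      length(object@telomeres), " telomeres, ",
      nrow(object@adjacencies), " adjacencies\n", sep = "")
})

setMethod("show", "Genome", function(object) {
  ch <- chromosomes(object)
  cat("Genome '", object@name, "': ", nrow(object@markers),
      " markers on ", length(ch), " chromosome(s) (",
      sum(!vapply(ch, `[[`, logical(1), "circular")), " linear, ",
      sum(vapply(ch, `[[`, logical(1), "circular")), " circular)\n",
      sep = "")
})

#' Family copy-number table of a genome
#'
#' @param x a \code{\linkS4class{DegenerateGenome}}.
#' @return named integer vector: number of markers per family.
#' @export
familyCounts <- function(x) {
  tab <- table(x@markers$family)
  stats::setNames(as.integer(tab), names(tab))
}

#' Decompose a genome into chromosomes
#'
#' Walks the genome graph (a disjoint union of simple paths and cycles) and
#' returns the chromosomes in reading order.
#'
#' @param x a \code{\linkS4class{Genome}}.
#' @return list of chromosomes, each a list with elements \code{ids}
#'   (marker ids in order), \code{signs} (+1/-1 orientation) and
#'   \code{circular} (logical).
#' @export
chromosomes <- function(x) {
  stopifnot(is(x, "Genome"))
  a <- x@adjacencies
  if (!nrow(x@markers)) return(list())
  ## partner map: extremity -> extremity over adjacency edges
  adjOf <- c(stats::setNames(a$e2, a$e1), stats::setNames(a$e1, a$e2))
  fam <- stats::setNames(x@markers$family, x@markers$id)
  seen <- new.env(parent = emptyenv())
  out <- list()

  walk <- function(start, circular) {
    ids <- character(); signs <- integer()
    e <- start
    repeat {
      m <- extremityMarker(e)
      side <- extremitySide(e)
      ids <- c(ids, m)
      signs <- c(signs, if (side == "t") 1L else -1L)
      assign(m, TRUE, envir = seen)
      exit <- extremity(m, if (side == "t") "h" else "t")
      nxt <- adjOf[[exit]]
      if (isTelomericExtremity(nxt)) break
      if (circular && extremityMarker(nxt) == extremityMarker(start) &&
          nxt == start) break
      e <- nxt
    }
    list(ids = ids, signs = signs, circular = circular)
  }

  ## linear chromosomes: start from telomeres
  for (t in x@telomeres) {
    e <- adjOf[[extremity(t, "o")]]
    if (is.null(e)) next
    m <- extremityMarker(e)
    if (exists(m, envir = seen)) next
    out[[length(out) + 1L]] <- walk(e, circular = FALSE)
  }
  ## circular chromosomes: remaining markers
  for (m in x@markers$id) {
    if (exists(m, envir = seen)) next
    out[[length(out) + 1L]] <- walk(extremity(m, "t"), circular = TRUE)
  }
  out
}

#' Build a genome from chromosome descriptions
#'
#' @param name genome label.
#' @param chroms list of chromosomes as returned by \code{\link{chromosomes}}
#'   (elements \code{ids}, \code{signs}, \code{circular}).
#' @param families named character vector mapping marker ids to families.
#' @return a \code{\linkS4class{Genome}}; telomeres are created at the ends
#'   of linear chromosomes with ids \code{tel1}, \code{tel2}, ...
#' @export
genomeFromChromosomes <- function(name, chroms, families) {
  e1 <- character(); e2 <- character()
  tel <- character(); telN <- 0L
  ids <- character()
  newTel <- function() {
    telN <<- telN + 1L
    t <- paste0("tel", telN)
    tel <<- c(tel, t)
    t
  }
  for (ch in chroms) {
    n <- length(ch$ids)
    if (n == 0L) next
    ids <- c(ids, ch$ids)
    left <- ifelse(ch$signs > 0L, extremity(ch$ids, "t"), extremity(ch$ids, "h"))
    right <- ifelse(ch$signs > 0L, extremity(ch$ids, "h"), extremity(ch$ids, "t"))
    if (n > 1L) {
      e1 <- c(e1, right[-n]); e2 <- c(e2, left[-1L])
    }
    if (ch$circular) {
      e1 <- c(e1, right[n]); e2 <- c(e2, left[1L])
    } else {
      e1 <- c(e1, extremity(newTel(), "o"), right[n])
      e2 <- c(e2, left[1L], extremity(newTel(), "o"))
    }
  }
  Genome(name,
         markers = data.frame(id = ids, family = unname(families[ids]),
                              stringsAsFactors = FALSE),
         telomeres = tel,
         adjacencies = data.frame(e1 = e1, e2 = e2, stringsAsFactors = FALSE))
}
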