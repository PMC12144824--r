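#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------
## In-memory MILP builder.  Models are accumulated in an environment with
## pre-grown vectors and finalized into an ILPModel (triplet form), which
## any MILP backend can consume; the bundled backend is HiGHS through
## scipy.optimize.milp, driven over a JSON batch interface.

newModelBuilder <- function() {
  b <- new.env(parent = emptyenv())
  b$nvar <- 0L
  b$names <- character(); b$lb <- numeric(); b$ub <- numeric()
  b$vtype <- character(); b$obj <- numeric()
  b$objConst <- 0
  b$ai <- integer(); b$aj <- integer(); b$ax <- numeric()
  b$lo <- numeric(); b$hi <- numeric()
  b$nrow <- 0L
  b
}

addVar <- function(b, name, lb, ub, vtype = "B", obj = 0) {
  b$nvar <- b$nvar + 1L
  b$names[b$nvar] <- name
  b$lb[b$nvar] <- lb; b$ub[b$nvar] <- ub
  b$vtype[b$nvar] <- vtype; b$obj[b$nvar] <- obj
  b$nvar
}

addObj <- function(b, idx, coef) {
  b$obj[idx] <- b$obj[idx] + coef
  invisible(NULL)
}

## One linear constraint: lo <= sum(coefs * x[idx]) <= hi  (NA = infinite)
addCon <- function(b, idx, coefs, lo = NA_real_, hi = NA_real_) {
  b$nrow <- b$nrow + 1L
  k <- length(idx)
  at <- length(b$ai)
  b$ai[at + seq_len(k)] <- rep.int(b$nrow, k)
  b$aj[at + seq_len(k)] <- idx
  b$ax[at + seq_len(k)] <- coefs
  b$lo[b$nrow] <- lo; b$hi[b$nrow] <- hi
  invisible(b$nrow)
}

finalizeModel <- function(b, maps = list()) {
  new("ILPModel", nvar = b$nvar, varNames = b$names,
      lb = b$lb, ub = b$ub, vtype = b$vtype,
      obj = b$obj, objConst = b$objConst,
      ai = b$ai, aj = b$aj, ax = b$ax,
      lo = b$lo, hi = b$hi, maps = maps)
}

setMethod("show", "ILPModel", function(object) {
  cat("ILPModel: ", object@nvar, " variables (",
      sum(object@vtype == "B"), " binary, ",
      sum(object@vtype == "I"), " integer, ",
      sum(object@vtype == "C"), " continuous), ",
      length(object@lo), " constraints, ",
      length(object@ai), " nonzeros\n", sep = "")
})

#' Number of variables / constraints of a model
#'
#' @param model an \code{\linkS4class{ILPModel}}.
#' @return named integer vector with elements \code{variables},
#'   \code{constraints}, \code{nonzeros}.
#' @export
modelSize <- function(model) {
  c(variables = model@nvar, constraints = length(model@lo),
    nonzeros = length(model@ai))
}

## Check a candidate assignment against all constraints/bounds.
## Returns TRUE or a character description of the first violation.
checkAssignment <- function(model, x, tol = 1e-6) {
  if (length(x) != model@nvar) return("wrong assignment length")
  lb <- ifelse(is.na(model@lb), -Inf, model@lb)
  ub <- ifelse(is.na(model@ub), Inf, model@ub)
  if (any(x < lb - tol | x > ub + tol))
    return(paste("bound violated at", model@varNames[
      which(x < lb - tol | x > ub + tol)[1]]))
  if (length(model@lo)) {
    ax <- rep(0, length(model@lo))
    sums <- tapply(model@ax * x[model@aj], model@ai, sum)
    ax[as.integer(names(sums))] <- sums
    lo <- ifelse(is.na(model@lo), -Inf, model@lo)
    hi <- ifelse(is.na(model@hi), Inf, model@hi)
    bad <- which(ax < lo - tol | ax > hi + tol)
    if (length(bad)) return(paste("constraint", bad[1], "violated"))
  }
  TRUE
}

#' Export a model in CPLEX LP format
#'
#' @param model an \code{\linkS4class{ILPModel}}.
#' @param file output path.
#' @return the path, invisibly.
#' @export
exportLP <- function(model, file) {
  vn <- gsub("[^A-Za-z0-9_]", "_", model@varNames)
  vn <- paste0("x", seq_along(vn), "_", vn)
  term <- function(coef, var) {
    sprintf("%s %.12g %s", ifelse(coef < 0, "-", "+"), abs(coef), var)
  }
  lines <- c("Minimize", paste(" obj:",
    paste(term(model@obj[model@obj != 0],
               vn[which(model@obj != 0)]), collapse = " ")))
  lines <- c(lines, "Subject To")
  rows <- split(seq_along(model@ai), model@ai)
  for (r in names(rows)) {
    i <- as.integer(r)
    expr <- paste(term(model@ax[rows[[r]]], vn[model@aj[rows[[r]]]]),
                  collapse = " ")
    lo <- model@lo[i]; hi <- model@hi[i]
    if (!is.na(lo) && !is.na(hi) && lo == hi)
      lines <- c(lines, sprintf(" c%d: %s = %.12g", i, expr, lo))
    else {
      if (!is.na(lo)) lines <- c(lines, sprintf(" c%dl: %s >= %.12g", i, expr, lo))
      if (!is.na(hi)) lines <- c(lines, sprintf(" c%du: %s <= %.12g", i, expr, hi))
    }
  }
  lines <- c(lines, "Bounds")
  for (j in seq_len(model@nvar)) {
    lo <- if (is.na(model@lb[j])) "-inf" else sprintf("%.12g", model@lb[j])
    hi <- if (is.na(model@ub[j])) "+inf" else sprintf("%.12g", model@ub[j])
    lines <- c(lines, sprintf(" %s <= %s <= %s", lo, vn[j], hi))
  }
  gen <- vn[model@vtype == "I"]
  bin <- vn[model@vtype == "B"]
  if (length(gen)) lines <- c(lines, "General", paste("", gen, collapse = ""))
  if (length(bin)) lines <- c(lines, "Binary", paste("", bin, collapse = ""))
  lines <- c(lines, "End")
  writeLines(lines, file)
  invisible(file)
}

pythonBinary <- function() {
  p <- Sys.getenv("GENOMEPARSIMONY_PYTHON", "")
  if (nzchar(p)) return(p)
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p))
    stop("no 'python' interpreter found; the MILP backend requires one ",
         "with scipy >= 1.9 installed")
  p
}

solverScript <- function() {
  s <- system.file("python", "milp_solve.py", package = "GenomeParsimony")
  if (!nzchar(s)) {
    ## during development (pkgload) the inst/ prefix is present
    s <- file.path("inst", "python", "milp_solve.py")
  }
  if (!file.exists(s)) stop("MILP backend script not found")
  normalizePath(s)
}

#' Solve a batch of MILP models
#'
#' Runs every model through the HiGHS solver bundled with scipy, in a
#' single interpreter invocation.  Deterministic: HiGHS runs single-threaded
#' with fixed settings, so identical models yield identical solutions.
#'
#' @param models list of \code{\linkS4class{ILPModel}}s.
#' @param timeLimit per-model wall-clock limit in seconds.
#' @param mipRelGap optional relative gap at which the solver may stop.
#' @return list of solutions: \code{status} (0 = optimal), \code{message},
#'   \code{x} (assignment, named by variable), \code{objective}, \code{gap}.
#' @export
solveModels <- function(models, timeLimit = NULL, mipRelGap = NULL) {
  stopifnot(is.list(models))
  INF <- 1e30   # sentinel: the backend maps |x| >= 1e29 to infinity
  fin_ <- function(x, s) ifelse(is.na(x), s, x)
  payload <- lapply(models, function(m) {
    list(nvar = m@nvar, obj = I(m@obj), objconst = m@objConst,
         lb = I(fin_(m@lb, -INF)), ub = I(fin_(m@ub, INF)),
         vtype = I(m@vtype),
         ai = I(m@ai), aj = I(m@aj), ax = I(m@ax),
         nrow = length(m@lo), lo = I(fin_(m@lo, -INF)),
         hi = I(fin_(m@hi, INF)),
         time_limit = timeLimit, mip_rel_gap = mipRelGap)
  })
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA,
                       null = "null")
  status <- system2(pythonBinary(), c(solverScript(), fin, fout),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout))
    stop("MILP backend failed:\n", paste(status, collapse = "\n"))
  res <- jsonlite::read_json(fout, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  lapply(seq_along(res), function(i) {
    r <- res[[i]]
    if (!is.null(r$x)) {
      r$x <- as.numeric(r$x)
      names(r$x) <- models[[i]]@varNames
    }
    r
  })
}

solveModel <- function(model, timeLimit = NULL, mipRelGap = NULL) {
  solveModels(list(model), timeLimit, mipRelGap)[[1]]
}
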