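test_that("pairwise ILP reproduces the in-paralog example optimum", {
  ex <- workedExample()
  expect_equal(dcjIndelDistanceILP(ex$A, ex$B), 3L)
})

test_that("pairwise ILP optimum equals the exhaustive matching distance", {
  seeds <- 201:230
  pairs <- lapply(seeds, randomTinyPair)
  phys <- lapply(pairs, function(p) pairPhylogeny(p$A, p$B))
  models <- lapply(phys, buildSppModel, alpha = 1)
  sols <- solveModels(models)
  for (i in seq_along(pairs)) {
    dec <- decodeSolution(models[[i]], sols[[i]], phys[[i]])
    expect_equal(treeDistance(dec),
                 distanceMaxMatching(pairs[[i]]$A, pairs[[i]]$B),
                 label = paste("ILP vs matching enumeration, seed", seeds[i]))
    ## decoded genomes are valid and reproduce the input pair
    for (g in dec@linearizations) expect_true(validObject(g))
  }
})

test_that("ILP distance is symmetric", {
  for (seed in c(301, 302, 303)) {
    p <- randomTinyPair(seed)
    expect_equal(dcjIndelDistanceILP(p$A, p$B), dcjIndelDistanceILP(p$B, p$A))
  }
})

test_that("global constraints: bounds can drop marker copies", {
  ## ancestor with two copies of family 1 and bounds (1,1): one copy kept
  anc <- readUnimog(">X\n1 1 2 |")$X
  leafs <- readUnimog(">L1\n1 2 |\n>L2\n1 2 |")
  D <- as(anc, "DegenerateGenome")
  ## also allow the ancestor to bridge over a dropped copy
  ids <- markerTable(anc)$id
  D@adjacencies <- unique(rbind(D@adjacencies,
    data.frame(e1 = extremity(ids[1], "h"), e2 = extremity(ids[3], "t"))))
  D <- augmentSafer(D)$genome
  phy <- new("Phylogeny", nodes = c("X", "L1", "L2"),
             edges = data.frame(parent = c("X", "X"),
                                child = c("L1", "L2")),
             root = "X", leaves = c("L1", "L2"),
             genomes = list(X = D, L1 = leafs$L1, L2 = leafs$L2))
  bounds <- data.frame(genome = "X", family = "1", low = 1L, high = 1L)
  sol <- solveSpp(phy, bounds = bounds, alpha = 1)
  expect_equal(sum(markerTable(sol@linearizations$X)$family == "1"), 1L)
  expect_equal(treeDistance(sol), 0L)
  ## dropped markers appear in no adjacency
  a <- adjacencyTable(sol@linearizations$X)
  present <- markerTable(sol@linearizations$X)$id
  mk <- extremityMarker(c(a$e1, a$e2))
  expect_true(all(mk[!isTelomericExtremity(c(a$e1, a$e2))] %in% present))
})

test_that("star tree with truthful candidates reaches distance zero", {
  gs <- readUnimog(">L1\n1 2 3 4 |\n>L2\n1 2 3 4 |\n>L3\n1 2 3 4 |")
  anc <- readUnimog(">X\n1 2 3 4 |")$X
  phy <- new("Phylogeny", nodes = c("X", "L1", "L2", "L3"),
             edges = data.frame(parent = rep("X", 3),
                                child = c("L1", "L2", "L3")),
             root = "X", leaves = c("L1", "L2", "L3"),
             genomes = c(list(X = as(anc, "DegenerateGenome")), gs))
  sol <- solveSpp(phy, alpha = 1)
  expect_equal(treeDistance(sol), 0L)
})

test_that("enlarging the candidate set never increases the optimum", {
  gs <- readUnimog(">L1\n1 2 3 |\n>L2\n3 -2 1 |")
  anc <- readUnimog(">X\n1 2 3 |")$X
  D <- as(anc, "DegenerateGenome")
  mkPhy <- function(D) new("Phylogeny", nodes = c("X", "L1", "L2"),
                           edges = data.frame(parent = c("X", "X"),
                                              child = c("L1", "L2")),
                           root = "X", leaves = c("L1", "L2"),
                           genomes = list(X = D, L1 = gs$L1, L2 = gs$L2))
  d0 <- treeDistance(solveSpp(mkPhy(D), alpha = 1))
  ids <- markerTable(anc)$id
  D2 <- D
  D2@adjacencies <- unique(rbind(D@adjacencies, data.frame(
    e1 = extremity(c(ids[1], ids[2]), "h"),
    e2 = extremity(c(ids[3], ids[3]), "h"))))
  d1 <- treeDistance(solveSpp(mkPhy(D2), alpha = 1))
  expect_lte(d1, d0)
})

test_that("both circular-singleton encodings yield identical optima", {
  ## P carries a circular chromosome of singular markers
  gs <- readUnimog(">P\n1 2 |\n5 6 )\n>Q\n1 2 |")
  phy <- pairPhylogeny(gs$P, gs$Q)
  mE <- buildSppModel(phy, alpha = 1, singletonMode = "enumerate")
  mC <- buildSppModel(phy, alpha = 1, singletonMode = "count")
  sE <- solveModel(mE); sC <- solveModel(mC)
  expect_equal(sE$objective, sC$objective)
  expect_equal(treeDistance(decodeSolution(mE, sE, phy)), 1L)
  expect_equal(treeDistance(decodeSolution(mC, sC, phy)), 1L)
})

test_that("objective trades distance against adjacency weight", {
  ## alpha = 0: any maximum-weight linearization is optimal, distance ignored
  gs <- readUnimog(">L1\n1 2 |\n>L2\n1 2 |")
  anc <- readUnimog(">X\n1 2 |")$X
  D <- augmentSafer(as(anc, "DegenerateGenome"))$genome
  ids <- markerTable(anc)$id
  w <- stats::setNames(
    rep(1, nrow(adjacencyTable(as(anc, "DegenerateGenome")))),
    adjKeyAnon(adjacencyTable(anc)$e1, adjacencyTable(anc)$e2))
  phy <- new("Phylogeny", nodes = c("X", "L1", "L2"),
             edges = data.frame(parent = c("X", "X"),
                                child = c("L1", "L2")),
             root = "X", leaves = c("L1", "L2"),
             genomes = list(X = D, L1 = gs$L1, L2 = gs$L2))
  s1 <- solveSpp(phy, weights = list(X = w), alpha = 1)
  expect_equal(treeDistance(s1), 0L)
  s0 <- solveSpp(phy, weights = list(X = w), alpha = 0)
  ## weight part: all weight-1 candidates of X selected, counted once per
  ## incident branch
  expect_equal(s0@objective, -2 * sum(w))
  expect_error(solveSpp(phy, alpha = 1.2), "alpha")
})

test_that("model size grows linearly with total diagram size", {
  sizes <- c(10L, 20L, 40L, 80L)
  rows <- lapply(sizes, function(n) {
    cfg <- simulationConfig(rootMarkers = n, opsPerBranch = max(2L, n %/% 10L),
                            noise = 0L, seed = 400L + n)
    tr <- simulateEvolution(cfg)
    phy <- addNoise(tr, 0L, seed = 1L)$phylogeny
    model <- buildSppModel(phy, alpha = 1)
    ## total diagram size: vertices plus edges over all branches
    tot <- 0
    for (i in seq_len(nrow(treeEdges(phy)))) {
      d <- buildCFMRD(phy@genomes[[treeEdges(phy)$parent[i]]],
                      phy@genomes[[treeEdges(phy)$child[i]]])
      tot <- tot + nrow(d@vertices) + nrow(d@edges)
    }
    c(size = tot, vars = unname(modelSize(model)["variables"]),
      cons = unname(modelSize(model)["constraints"]))
  })
  df <- as.data.frame(do.call(rbind, rows))
  fitV <- stats::lm(vars ~ size, data = df)
  fitC <- stats::lm(cons ~ size, data = df)
  expect_gt(summary(fitV)$r.squared, 0.999)
  expect_gt(summary(fitC)$r.squared, 0.999)
})

test_that("decode recomputes the objective from the linearizations", {
  p <- randomTinyPair(777)
  phy <- pairPhylogeny(p$A, p$B)
  sol <- solveSpp(phy, alpha = 1)
  expect_equal(sol@objective, sol@recomputedObjective, tolerance = 1e-9)
  expect_equal(sol@gap, 0)
})
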