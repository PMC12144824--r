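test_that("simulation is deterministic under a fixed seed", {
  cfg <- simulationConfig(rootMarkers = 15L, opsPerBranch = 5L, seed = 9L)
  t1 <- simulateEvolution(cfg)
  t2 <- simulateEvolution(cfg)
  expect_identical(writeUnimog(t1@phylogeny@genomes),
                   writeUnimog(t2@phylogeny@genomes))
  expect_identical(t1@trueAdjacencies, t2@trueAdjacencies)
  t3 <- simulateEvolution(simulationConfig(rootMarkers = 15L,
                                           opsPerBranch = 5L, seed = 10L))
  expect_false(identical(writeUnimog(t1@phylogeny@genomes),
                         writeUnimog(t3@phylogeny@genomes)))
})

test_that("every simulated genome is valid and ops are logged", {
  cfg <- simulationConfig(rootMarkers = 20L, opsPerBranch = 6L, seed = 21L,
                          chromosomes = 2L)
  tr <- simulateEvolution(cfg)
  for (g in tr@phylogeny@genomes) expect_true(validObject(g))
  expect_equal(nrow(tr@opLog), 6L * nrow(treeEdges(tr@phylogeny)))
  expect_true(all(tr@opLog$op %in% c("dup", "del", "ins", "dcj")))
})

test_that("zero operations per branch leave all genomes identical", {
  cfg <- simulationConfig(rootMarkers = 8L, opsPerBranch = 0L, seed = 2L)
  tr <- simulateEvolution(cfg)
  canon <- unique(vapply(tr@phylogeny@genomes, function(g)
    paste(sort(adjKeyAnon(adjacencyTable(g)$e1, adjacencyTable(g)$e2)),
          collapse = ";"), character(1)))
  expect_length(canon, 1L)
  nz <- addNoise(tr, 0L, seed = 1L)
  sol <- solveSpp(nz$phylogeny, alpha = 1)
  expect_equal(treeDistance(sol), 0L)
})

test_that("circular root chromosomes are supported", {
  cfg <- simulationConfig(rootMarkers = 10L, opsPerBranch = 3L,
                          circular = TRUE, seed = 5L)
  tr <- simulateEvolution(cfg)
  root <- tr@phylogeny@genomes[[tr@phylogeny@root]]
  for (g in tr@phylogeny@genomes) expect_true(validObject(g))
})

test_that("per-branch distance never exceeds the simulated operation count", {
  cfg <- simulationConfig(rootMarkers = 8L, opsPerBranch = 3L,
                          tree = "(A:1,B:1)R;", noise = 0L, seed = 13L)
  tr <- simulateEvolution(cfg)
  gR <- tr@phylogeny@genomes$R
  expect_lte(dcjIndelDistanceILP(gR, tr@phylogeny@genomes$A), 3L)
  expect_lte(dcjIndelDistanceILP(gR, tr@phylogeny@genomes$B), 3L)
})

test_that("noise adjacencies are false, counted, and reproducible", {
  cfg <- simulationConfig(rootMarkers = 12L, opsPerBranch = 2L, seed = 3L)
  tr <- simulateEvolution(cfg)
  nz <- addNoise(tr, 5L, seed = 8L)
  for (nd in names(tr@trueAdjacencies)) {
    D <- nz$phylogeny@genomes[[nd]]
    keys <- adjKeyAnon(adjacencyTable(D)$e1, adjacencyTable(D)$e2)
    expect_equal(nrow(adjacencyTable(D)),
                 length(tr@trueAdjacencies[[nd]]) + 5L)
    expect_true(all(tr@trueAdjacencies[[nd]] %in% keys))
    expect_false(anyDuplicated(keys) > 0)   # noise never duplicates truth
  }
  nz2 <- addNoise(tr, 5L, seed = 8L)
  expect_identical(
    adjacencyTable(nz$phylogeny@genomes[[names(tr@trueAdjacencies)[1]]]),
    adjacencyTable(nz2$phylogeny@genomes[[names(tr@trueAdjacencies)[1]]]))
})

test_that("the worked-example fixture matches its printed description", {
  ex <- workedExample()
  expect_equal(nrow(markerTable(ex$A)), 5L)
  expect_length(chromosomes(ex$A), 1L)
  expect_false(chromosomes(ex$A)[[1]]$circular)
  fams <- familyCounts(ex$A)
  expect_equal(unname(fams[c("1", "2", "3", "4")]), c(2L, 1L, 1L, 1L))
  ## the resolved homology is a matching on the family homology
  famA <- stats::setNames(markerTable(ex$A)$family, markerTable(ex$A)$id)
  famB <- stats::setNames(markerTable(ex$B)$family, markerTable(ex$B)$id)
  expect_equal(unname(famA[ex$matching$a]), unname(famB[ex$matching$b]))
})
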