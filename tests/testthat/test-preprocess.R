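test_that("warm start is feasible and bounds the optimum from above", {
  cfg <- simulationConfig(rootMarkers = 12L, opsPerBranch = 3L,
                          tree = "(A:1,B:1)R;", noise = 0L, seed = 31L)
  tr <- simulateEvolution(cfg)
  nz <- addNoise(tr, 4L, seed = 5L)
  ws <- initialSolution(nz$phylogeny, weights = nz$weights, alpha = 1)
  for (g in ws$linearizations) expect_true(validObject(g))
  sol <- solveSpp(nz$phylogeny, weights = nz$weights, alpha = 1)
  expect_gte(ws$objective, treeDistance(sol))
})

test_that("warm start on an identical leaf pair reaches distance zero", {
  gs <- readUnimog(">A\n1 2 3 |\n>B\n1 2 3 |")
  phy <- new("Phylogeny", nodes = c("R", "A", "B"),
             edges = data.frame(parent = c("R", "R"), child = c("A", "B")),
             root = "R", leaves = c("A", "B"),
             genomes = list(R = as(readUnimog(">R\n1 2 3 |")$R,
                                   "DegenerateGenome"),
                            A = gs$A, B = gs$B))
  ws <- initialSolution(phy, alpha = 1)
  expect_equal(sum(ws$distances$distance), 0L)
})

test_that("non-linearizable nodes are reported with guidance", {
  D <- DegenerateGenome("X", data.frame(id = c("a_1", "b_1"),
                                        family = c("a", "b")),
                        adjacencies = data.frame(e1 = c("a_1:h", "a_1:h"),
                                                 e2 = c("b_1:t", "b_1:h")))
  lf <- readUnimog(">A\na b |")$A
  phy <- new("Phylogeny", nodes = c("X", "A"),
             edges = data.frame(parent = "X", child = "A"),
             root = "X", leaves = "A",
             genomes = list(X = D, A = lf))
  expect_error(initialSolution(phy), "not linearizable")
})

test_that("leaf pair bounds: count, values, and no effect on the optimum", {
  cfg <- simulationConfig(rootMarkers = 10L, opsPerBranch = 2L,
                          noise = 0L, seed = 37L)
  tr <- simulateEvolution(cfg)
  phy <- tr@phylogeny
  lb <- leafPairLowerBounds(phy)
  expect_equal(nrow(lb), choose(4, 2))             # all leaf pairs
  expect_true(all(lb$distance >= 0L))
  dz <- addNoise(tr, 0L, seed = 1L)
  s0 <- solveSpp(dz$phylogeny, alpha = 1)
  s1 <- solveSpp(dz$phylogeny, alpha = 1, lowerBounds = lb)
  expect_equal(treeDistance(s1), treeDistance(s0))

  ## identical leaves give a vacuous zero bound
  gs <- readUnimog(">A\n1 2 |\n>B\n1 2 |")
  phy2 <- new("Phylogeny", nodes = c("R", "A", "B"),
              edges = data.frame(parent = c("R", "R"), child = c("A", "B")),
              root = "R", leaves = c("A", "B"),
              genomes = list(R = as(gs$A, "DegenerateGenome"),
                             A = gs$A, B = gs$B))
  lb2 <- leafPairLowerBounds(phy2)
  expect_equal(lb2$distance, 0L)
})

test_that("two-leaf tree with a C.opt cut still attains the pairwise distance", {
  p <- randomTinyPair(911)
  phy <- pairPhylogeny(p$A, p$B)
  d <- distanceMaxMatching(p$A, p$B)
  model <- buildSppModel(phy, alpha = 1,
                         lowerBounds = data.frame(leaf1 = "B.",
                                                  leaf2 = "A.",
                                                  distance = d))
  sol <- decodeSolution(model, solveModel(model), phy)
  expect_equal(treeDistance(sol), d)
})
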