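test_that("comparison diagram of the in-paralog example has the expected edges", {
  ex <- workedExample()
  d <- buildCFMRD(ex$A, ex$B)
  tab <- table(d@edges$type)
  ## singular families 4 and 5 contribute the only self edges
  expect_equal(unname(tab[["self"]]), 2L)
  selfV <- d@edges[d@edges$type == "self", ]
  expect_setequal(extremityMarker(sub("^[AB]\\|", "", selfV$u)),
                  c("4_1", "5_1"))
  ## family 1: 2x2 pairings, families 2 and 3: 1x1, two edges per pairing
  expect_equal(unname(tab[["ext"]]), 2L * 4L + 2L * 1L + 2L * 1L)
  ## adjacency edges: all adjacencies of both genomes
  expect_equal(unname(tab[["adj"]]),
               nrow(adjacencyTable(ex$A)) + nrow(adjacencyTable(ex$B)))
  ## ranks are a bijection onto 1..n
  expect_setequal(d@vertices$rank, seq_len(nrow(d@vertices)))
})

test_that("trivial diagrams: identical and disjoint genomes", {
  gs <- readUnimog(">X\n1 |\n>Y\n1 |")
  d <- buildCFMRD(gs$X, gs$Y)
  expect_equal(sum(d@edges$type == "ext"), 2L)
  expect_equal(sum(d@edges$type == "self"), 0L)
  gs2 <- readUnimog(">X\n1 2 |\n>Y\n3 4 |")
  d2 <- buildCFMRD(gs2$X, gs2$Y)
  expect_equal(sum(d2@edges$type == "ext"), 0L)
  expect_equal(sum(d2@edges$type == "self"), 4L)
})

test_that("census of the worked example reproduces the printed counts and paths", {
  ex <- workedExample()
  cen <- componentCensus(ex$A, ex$B, ex$matching)
  expect_equal(cen@c, 2L)
  expect_equal(cen@s, 0L)
  expect_equal(cen@n, 4L)
  expect_equal(unname(cen@paths[c("AB", "ab", "aB", "Ab")]),
               rep(1L, 4L))
  expect_equal(sum(cen@paths), 4L)

  ## the four path components, as vertex sets (telomeres anonymized):
  ## reconstruct the resolved graph and compare component memberships
  sel <- rbind(
    data.frame(u = paste0("A|", adjacencyTable(ex$A)$e1),
               v = paste0("A|", adjacencyTable(ex$A)$e2)),
    data.frame(u = paste0("B|", adjacencyTable(ex$B)$e1),
               v = paste0("B|", adjacencyTable(ex$B)$e2)),
    data.frame(u = paste0("A|", extremity(ex$matching$a, "t")),
               v = paste0("B|", extremity(ex$matching$b, "t"))),
    data.frame(u = paste0("A|", extremity(ex$matching$a, "h")),
               v = paste0("B|", extremity(ex$matching$b, "h"))))
  g <- igraph::graph_from_data_frame(sel, directed = FALSE)
  comp <- igraph::components(g)$membership
  members <- split(names(comp), comp)
  strip <- function(v) sort(sub("^[AB]\\|", "", v[!endsWith(v, ":o")]))
  got <- lapply(members, strip)
  expectPath <- function(markers) {
    expect_true(any(vapply(got, identical, logical(1), sort(markers))))
  }
  expectPath(c("1_1:t", "1_3:t"))                      # telomere-to-telomere
  expectPath(c("4_1:t", "2_1:h", "2_2:h", "5_1:t"))    # ab
  expectPath(c("4_1:h", "3_1:h", "3_2:h"))             # aB
  expectPath(c("3_1:t", "3_2:t", "5_1:h"))             # Ab
})

test_that("census demands a resolved homology", {
  ex <- workedExample()
  bad <- rbind(ex$matching,
               data.frame(a = "1_1", b = "1_4"))   # 1_1 matched twice
  expect_error(componentCensus(ex$A, ex$B, bad), "not resolved")
  expect_error(componentCensus(ex$A, ex$B, data.frame(a = "1_1", b = "2_2")),
               "same family")
})

test_that("closed-form distance matches hand-traced cases", {
  ## genome against itself, circular: n cycles, distance 0
  gc <- readUnimog(">X\n1 2 3 )\n>Y\n1 2 3 )")
  m <- data.frame(a = c("1_1", "2_1", "3_1"), b = c("1_2", "2_2", "3_2"))
  cen <- componentCensus(gc$X, gc$Y, m)
  expect_equal(cen@c, 3L); expect_equal(cen@n, 3L)
  expect_equal(dcjIndelDistance(cen), 0L)

  ## single-marker genome vs empty genome: two telomere-to-singular paths,
  ## one deletion
  gA <- Genome("A", data.frame(id = "1_1", family = "1"),
               telomeres = c("t1", "t2"),
               adjacencies = data.frame(e1 = c("t1:o", "1_1:h"),
                                        e2 = c("1_1:t", "t2:o")))
  gE <- Genome("E", data.frame(id = character(), family = character()))
  cen2 <- componentCensus(gA, gE, data.frame(a = character(), b = character()))
  expect_equal(unname(cen2@paths[["Aa"]]), 2L)
  expect_equal(sum(cen2@paths), 2L)
  expect_equal(dcjIndelDistance(cen2), 1L)

  ## circular singleton costs one indel
  gS <- Genome("S", data.frame(id = "1_1", family = "1"), character(),
               data.frame(e1 = "1_1:h", e2 = "1_1:t"))
  cen3 <- componentCensus(gS, gE, data.frame(a = character(), b = character()))
  expect_equal(cen3@s, 1L)
  expect_equal(dcjIndelDistance(cen3), 1L)
})

test_that("maximum-matching distance: enumeration structure and trivial cases", {
  ex <- workedExample()
  ## family 1 has two maximum pairings; 2 and 3 are forced
  ms <- maximumMatchings(ex$A, ex$B)
  expect_length(ms, 2L)
  expect_equal(distanceMaxMatching(ex$A, ex$B), 3L)

  ## all single-copy: exactly one maximum matching
  gs <- readUnimog(">P\n1 2 |\n>Q\n2 -1 |")
  expect_length(maximumMatchings(gs$P, gs$Q), 1L)

  ## A = [1 1], B = [1]: two symmetric matchings, equal value
  g2 <- readUnimog(">R\n1 1 |\n>S\n1 |")
  ms2 <- maximumMatchings(g2$R, g2$S)
  expect_length(ms2, 2L)
  ds <- vapply(ms2, function(m)
    dcjIndelDistance(componentCensus(g2$R, g2$S, m)), integer(1))
  expect_equal(ds[1], ds[2])
  expect_equal(min(ds), 1L)

  expect_error(maximumMatchings(ex$A, ex$B, budget = 1L), "budget")
})

test_that("distance is symmetric and zero on identity", {
  for (seed in 1:8) {
    p <- randomTinyPair(seed)
    expect_equal(distanceMaxMatching(p$A, p$B), distanceMaxMatching(p$B, p$A))
    idm <- data.frame(a = markerTable(p$A)$id, b = markerTable(p$A)$id)
    ## self-comparison under the identity homology
    expect_equal(dcjIndelDistance(componentCensus(p$A, p$A, idm)), 0L)
  }
})

test_that("operation-count oracle agrees with the closed form on tiny cases", {
  gs <- readUnimog(">P\n1 2 |\n>Q\n1 -2 |")
  expect_equal(bfsDistanceOracle(gs$P, gs$Q)$distance, 1L)     # one inversion
  gc <- readUnimog(">X\n1 2 3 )\n>Y\n1 2 3 )")
  expect_equal(bfsDistanceOracle(gc$X, gc$Y)$distance, 0L)
  ## deletion example must agree with the census-based value above
  gA <- Genome("A", data.frame(id = "1_1", family = "1"),
               telomeres = c("t1", "t2"),
               adjacencies = data.frame(e1 = c("t1:o", "1_1:h"),
                                        e2 = c("1_1:t", "t2:o")))
  gE <- Genome("E", data.frame(id = character(), family = character()))
  expect_equal(bfsDistanceOracle(gA, gE, maxOps = 3)$distance, 1L)

  ## path-class interplay: deleting across a matched marker is costly, and
  ## a linear-vs-circular copy adds one operation (same-genome
  ## telomere-to-telomere paths carry coefficient zero)
  gx <- readUnimog(">A\n4 2 |\n1 |\n>B\n2 5 |\n1 )")
  expect_equal(distanceMaxMatching(gx$A, gx$B), 3L)
  expect_equal(bfsDistanceOracle(gx$A, gx$B, maxOps = 4,
                                 maxStates = 60000)$distance, 3L)
})

test_that("oracle agreement on randomized tiny instances", {
  nChecked <- 0L
  for (seed in 101:130) {
    p <- randomTinyPair(seed)
    dMM <- distanceMaxMatching(p$A, p$B)
    bfs <- bfsDistanceOracle(p$A, p$B, maxOps = 4L, maxStates = 30000L)
    if (bfs$complete) {
      expect_equal(bfs$distance, dMM,
                   label = paste("bfs vs closed form, seed", seed))
      nChecked <- nChecked + 1L
    }
  }
  expect_gte(nChecked, 20L)
})
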