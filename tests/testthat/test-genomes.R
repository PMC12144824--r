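test_that("UniMoG parsing builds valid genome graphs", {
  gs <- readUnimog(">A\n1 2 |")
  a <- gs$A
  expect_s4_class(a, "Genome")
  expect_equal(nrow(markerTable(a)), 2L)
  expect_equal(length(telomeres(a)), 2L)
  keys <- adjKey(adjacencyTable(a)$e1, adjacencyTable(a)$e2)
  expect_setequal(keys, c(adjKey("tel1:o", "1_1:t"), adjKey("1_1:h", "2_1:t"),
                          adjKey("2_1:h", "tel2:o")))

  ## circular chromosome: no telomeres, wrap adjacency, ")" terminator
  ci <- readUnimog(">C\n1 -2 )")$C
  expect_length(telomeres(ci), 0L)
  expect_setequal(adjKey(adjacencyTable(ci)$e1, adjacencyTable(ci)$e2),
                  c(adjKey("1_1:h", "2_1:h"), adjKey("2_1:t", "1_1:t")))
  expect_true(chromosomes(ci)[[1]]$circular)
})

test_that("marker copies are disambiguated across genomes of one file", {
  gs <- readUnimog(">A\n1 1 2 4 -3 |\n>B\n1 1 2 5 3 |")
  expect_equal(markerTable(gs$A)$id, c("1_1", "1_2", "2_1", "4_1", "3_1"))
  expect_equal(markerTable(gs$B)$id, c("1_3", "1_4", "2_2", "5_1", "3_2"))
  expect_equal(unname(familyCounts(gs$A)), c(2L, 1L, 1L, 1L))
})

test_that("write/parse round trip is the identity on the genome graph", {
  for (seed in 1:12) {
    p <- randomTinyPair(seed)
    txt <- writeUnimog(list(p$A, p$B))
    back <- readUnimog(txt)
    for (nm in c("A", "B")) {
      orig <- p[[nm]]; re <- back[[nm]]
      ## same family multiset per chromosome, up to marker-copy renaming
      canon <- function(g) {
        fam <- stats::setNames(markerTable(g)$family, markerTable(g)$id)
        sort(vapply(chromosomes(g), function(ch)
          paste(ch$circular,
                min(paste(ifelse(ch$signs < 0, "-", "+"), fam[ch$ids],
                          collapse = " ")), collapse = "|"),
          character(1)))
      }
      expect_identical(canon(re), canon(orig))
      expect_equal(nrow(adjacencyTable(re)), nrow(adjacencyTable(orig)))
    }
  }
})

test_that("malformed input is rejected with informative errors", {
  expect_error(readUnimog(">A\n1 2"), "must end with")
  expect_error(readUnimog(">A\n|"), "empty chromosome")
  expect_error(readUnimog(">A\n1 |\n>A\n2 |"), "duplicate genome name")
  expect_error(readAdjacencies("X\t1\tq\t2\tt\t1"), "unknown side code")
  expect_error(readAdjacencies("X\t.\to\t.\to\t1"), "two telomeres")
  expect_error(readPhylogeny("(A,B);"), "labeled")
})

test_that("genome validity enforces the perfect-matching property", {
  ## an extremity in two adjacencies is a degenerate genome, not a genome
  mk <- data.frame(id = c("a_1", "b_1"), family = c("a", "b"))
  adj <- data.frame(e1 = c("a_1:h", "a_1:h"), e2 = c("b_1:t", "b_1:h"))
  expect_error(Genome("X", mk, character(), adj), "perfect matching")
  expect_s4_class(DegenerateGenome("X", mk, character(), adj),
                  "DegenerateGenome")
  expect_error(DegenerateGenome("X", mk, c("t1", "t2"),
                                data.frame(e1 = "t1:o", e2 = "t2:o")),
               "two telomeres")
})

test_that("telomere count is twice the number of linear chromosomes", {
  for (seed in 1:10) {
    g <- randomTinyPair(seed)$A
    nLin <- sum(!vapply(chromosomes(g), `[[`, logical(1), "circular"))
    expect_length(telomeres(g), 2L * nLin)
  }
})

test_that("adjacency tables parse into degenerate genomes with weights", {
  res <- readAdjacencies(paste(
    "X\t1\th\t2\tt\t1.5",
    "X\t1\th\t3\tt\t0.25",
    "X\t.\to\t1\tt",
    sep = "\n"))
  D <- res$genomes$X
  expect_equal(nrow(adjacencyTable(D)), 3L)        # conflicts retained
  expect_equal(unname(res$weights$X[adjKeyAnon("1_1:h", "2_1:t")]), 1.5)
  expect_equal(unname(res$weights$X[adjKeyAnon("tel1:o", "1_1:t")]), 0)
})

test_that("phylogeny parsing requires labels and binds genomes", {
  phy <- readPhylogeny("(((A:1.0,B:1.0)F:1.0),((C:1.0,D:1.0)G:1.0))Root;")
  expect_length(phy@nodes, 7L)
  expect_equal(nrow(treeEdges(phy)), 6L)
  expect_error(bindGenomes(phy, list(Z = readUnimog(">Z\n1 |")$Z)),
               "without tree node")
})

test_that("family bounds parse and validate", {
  b <- readFamilyBounds("X\t1\t0\t2\nX\t2\t1\t1")
  expect_equal(b$low, c(0L, 1L))
  expect_error(readFamilyBounds("X\t1\t2\t1"), "low <= high")
})
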