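test_that("coverage weights count incident non-telomeric extremities", {
  expect_equal(linearizationWeight("1_1:h", "2_1:t"), 2L)
  expect_equal(linearizationWeight("1_1:t", "t1:o"), 1L)
  expect_error(linearizationWeight("t1:o", "t2:o"), "two telomeres")
})

test_that("uncoverable extremities make a degenerate genome infeasible", {
  D <- DegenerateGenome("D", data.frame(id = c("a_1", "b_1"),
                                        family = c("a", "b")),
                        adjacencies = data.frame(e1 = c("a_1:h", "a_1:h"),
                                                 e2 = c("b_1:t", "b_1:h")))
  r <- tryLinearize(D)
  expect_false(r$feasible)
  expect_lt(r$matchingWeight, 2L * nrow(markerTable(D)))
})

test_that("every genome is its own unique linearization", {
  g <- readUnimog(">A\n1 2 -3 |\n4 )")$A
  r <- tryLinearize(as(g, "DegenerateGenome"))
  expect_true(r$feasible)
  expect_equal(r$matchingWeight, 2L * nrow(markerTable(g)))
  expect_setequal(
    adjKey(adjacencyTable(r$linearization)$e1,
           adjacencyTable(r$linearization)$e2),
    adjKey(adjacencyTable(g)$e1, adjacencyTable(g)$e2))
})

test_that("matching feasibility matches exhaustive subset search", {
  feas <- c(); Ds <- list()
  for (seed in 1:40) Ds[[seed]] <- randomDegenerateGenome(seed)
  res <- tryLinearizeList(Ds)
  for (seed in 1:40) {
    expect_equal(res[[seed]]$feasible, subsetLinearizable(Ds[[seed]]),
                 label = paste("linearizability, seed", seed))
    if (res[[seed]]$feasible)
      expect_s4_class(res[[seed]]$linearization, "Genome")
    ## matching weight equals the number of covered extremities
    expect_lte(res[[seed]]$matchingWeight, 2L * nrow(markerTable(Ds[[seed]])))
  }
})

test_that("candidate weights break ties among maximum-coverage matchings", {
  ## two alternative linearizations of a 2-marker circular candidate set:
  ## {a_1:h b_1:t, b_1:h a_1:t} vs {a_1:h b_1:h, a_1:t b_1:t}
  D <- DegenerateGenome("D", data.frame(id = c("a_1", "b_1"),
                                        family = c("a", "b")),
                        adjacencies = data.frame(
                          e1 = c("a_1:h", "b_1:h", "a_1:h", "a_1:t"),
                          e2 = c("b_1:t", "a_1:t", "b_1:h", "b_1:t")))
  w <- stats::setNames(c(0, 0, 2, 2),
                       c(adjKeyAnon("a_1:h", "b_1:t"),
                         adjKeyAnon("b_1:h", "a_1:t"),
                         adjKeyAnon("a_1:h", "b_1:h"),
                         adjKeyAnon("a_1:t", "b_1:t")))
  r <- tryLinearize(D, w)
  expect_true(r$feasible)
  k <- adjKey(adjacencyTable(r$linearization)$e1,
              adjacencyTable(r$linearization)$e2)
  expect_setequal(k, c(adjKey("a_1:h", "b_1:h"), adjKey("a_1:t", "b_1:t")))
  expect_equal(r$candidateWeight, 4)
})

test_that("local-guarantee augmentation touches only problematic components", {
  ## a proper genome decomposes into even paths: untouched
  g <- as(readUnimog(">A\n1 |")$A, "DegenerateGenome")
  expect_equal(nrow(adjacencyTable(augmentLocalGuarantees(g))),
               nrow(adjacencyTable(g)))

  ## fully connected component on 4 extremities stays untouched
  fc <- DegenerateGenome("F", data.frame(id = c("a_1", "b_1"),
                                         family = c("a", "b")),
                         adjacencies = data.frame(
                           e1 = c("a_1:t", "a_1:t", "a_1:t", "a_1:h", "a_1:h",
                                  "b_1:t"),
                           e2 = c("a_1:h", "b_1:t", "b_1:h", "b_1:t", "b_1:h",
                                  "b_1:h")))
  expect_equal(nrow(adjacencyTable(augmentLocalGuarantees(fc))),
               nrow(adjacencyTable(fc)))

  ## isolated extremities (odd components) gain telomeres: here a_1:t and
  ## b_1:h are in no candidate adjacency
  odd <- DegenerateGenome("O", data.frame(id = c("a_1", "b_1"),
                                          family = c("a", "b")),
                          adjacencies = data.frame(e1 = "a_1:h",
                                                   e2 = "b_1:t"))
  aug <- augmentLocalGuarantees(odd)
  expect_equal(nrow(adjacencyTable(aug)), 1L + 2L)
  expect_true(tryLinearize(aug)$feasible)

  ## an odd conflict cycle is augmented in full
  cyc <- DegenerateGenome("C", data.frame(id = c("a_1", "b_1", "c_1"),
                                          family = c("a", "b", "c")),
                          adjacencies = data.frame(
                            e1 = c("a_1:h", "b_1:t", "c_1:h"),
                            e2 = c("b_1:t", "c_1:h", "a_1:h")))
  augC <- augmentLocalGuarantees(cyc)
  expect_gt(nrow(adjacencyTable(augC)), nrow(adjacencyTable(cyc)))
  expect_true(tryLinearize(augC)$feasible)
})

test_that("safer augmentation connects every extremity to a telomere", {
  for (seed in c(3, 9, 17)) {
    D <- randomDegenerateGenome(seed)
    res <- augmentSafer(D)
    k <- 2L * nrow(markerTable(D))
    expect_equal(length(telomeres(res$genome)) - length(telomeres(D)), k)
    expect_equal(nrow(adjacencyTable(res$genome)) -
                   nrow(adjacencyTable(D)), k)
    expect_true(all(res$weights == 0))
    expect_true(tryLinearize(res$genome)$feasible)
    ## idempotent
    again <- augmentSafer(res$genome)
    expect_equal(nrow(adjacencyTable(again$genome)),
                 nrow(adjacencyTable(res$genome)))
  }
})

test_that("augmentation modes always yield linearizable genomes", {
  Ds <- lapply(41:55, randomDegenerateGenome)
  resL <- tryLinearizeList(lapply(Ds, augmentLocalGuarantees))
  resS <- tryLinearizeList(lapply(Ds, function(D) augmentSafer(D)$genome))
  for (i in seq_along(Ds)) {
    expect_true(resL[[i]]$feasible)
    expect_true(resS[[i]]$feasible)
  }
})
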