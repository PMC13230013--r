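test_that("metabolite-edge assignment reproduces the hand-traced maps", {
  em <- assignMetabolitesToEdges(w1Network())
  expect_equal(em$M, 4)
  Me <- unname(em$Me)
  expect_equal(Me[4, 1], 1)                 # ENV -> t1 supply
  expect_equal(Me[1, 2], 2)                 # t1 -> t2
  expect_equal(Me[2, 3], 3); expect_equal(Me[3, 2], 3)  # competition
  expect_equal(Me[2, 4], 4); expect_equal(Me[3, 4], 4)  # waste
  expect_equal(sum(Me != 0), 6)

  # single taxon + ENV
  iso <- augmentEnvironment(InteractionNetwork(matrix(0, 1, 1)))
  em1 <- assignMetabolitesToEdges(iso)
  expect_equal(em1$M, 2)
  expect_equal(unname(em1$Me[2, 1]), 1)
  expect_equal(unname(em1$Me[1, 2]), 2)

  # closed 3-cycle: waste allocated but stamped on no edge
  cyc <- matrix(0, 3, 3); cyc[1, 2] <- cyc[2, 3] <- cyc[3, 1] <- 1
  em3 <- assignMetabolitesToEdges(augmentEnvironment(InteractionNetwork(cyc)))
  expect_equal(em3$M, 4)
  expect_false(any(em3$Me == 4))

  expect_error(assignMetabolitesToEdges(w1Network(augmented = FALSE)),
               "augmented")
})

test_that("metabolite-node assignment marks consumers and producers", {
  net <- w1Network()
  em <- assignMetabolitesToEdges(net)
  Ms <- assignMetabolitesToNodes(net, em)
  cons <- function(i) which(Ms[, i, "consumption"] == 1)
  prod <- function(i) which(Ms[, i, "production"] == 1)
  expect_equal(cons(1), 1);     expect_equal(prod(1), 2)
  expect_equal(cons(2), c(2, 3)); expect_equal(prod(2), 4)
  expect_equal(cons(3), 3);     expect_equal(prod(3), 4)
  expect_equal(cons(4), 4);     expect_equal(prod(4), 1)   # ENV

  # support mismatch is rejected
  bad <- em; bad$Me[1, 3] <- 9L
  expect_error(assignMetabolitesToNodes(net, bad), "support")
})

test_that("every non-waste metabolite has a consumer on random pipelines", {
  for (s in 1:50) {
    top <- if (s %% 2 == 0) "er" else "ba"
    net <- randomNetwork(s, S = 15, topology = top)
    em <- assignMetabolitesToEdges(net)
    Ms <- assignMetabolitesToNodes(net, em)
    nTax <- dim(Ms)[2] - 1
    for (m in seq_len(em$M - 1))
      expect_true(any(Ms[m, seq_len(nTax), "consumption"] == 1))
  }
})

test_that("C and D reproduce the hand-traced matrices", {
  mod <- buildCommunityModel(w1Network())
  expect_equal(unname(consumerMatrix(mod)),
               rbind(c(1, 0, 0, 0), c(0, 1, 1, 0), c(0, 0, 1, 0)))
  D <- unname(metabolicMatrix(mod))
  expected <- matrix(0, 4, 4)
  expected[2, 1] <- 1; expected[4, 2] <- 1; expected[4, 3] <- 1
  expect_equal(D, expected)

  iso <- augmentEnvironment(InteractionNetwork(matrix(0, 1, 1)))
  modIso <- buildCommunityModel(iso)
  expect_equal(unname(consumerMatrix(modIso)), matrix(c(1, 0), 1))
  expect_equal(unname(metabolicMatrix(modIso))[2, 1], 1)
})

test_that("metabolite count identity holds on random networks", {
  # M = #{taxa with >= 1 positive in-edge} + #{negative pairs} + 1:
  # one metabolite per fed taxon, one per competition, one waste shared by
  # all edges into ENV (the W1 trace pins the count to taxa only)
  for (s in 1:200) {
    top <- if (s %% 2 == 0) "er" else "ba"
    net <- randomNetwork(s, S = 5 + (s %% 20), topology = top,
                         nneg = (s %% 4) / 10)
    A <- adjacency(net)
    em <- assignMetabolitesToEdges(net)
    nPosIn <- sum(vapply(seq_len(ncol(A) - 1), function(j) any(A[, j] > 0),
                         logical(1)))
    nNegPairs <- sum(A == -1) / 2
    expect_identical(em$M, as.integer(nPosIn + nNegPairs + 1))
  }
})

test_that("waste is never consumed by any taxon", {
  for (s in 1:25) {
    mod <- buildCommunityModel(randomNetwork(s, S = 20, nneg = 0.2))
    expect_true(all(consumerMatrix(mod)[, wasteIndex(mod)] == 0))
  }
})

test_that("weight sampling preserves zero patterns and D normalisation", {
  net <- randomNetwork(2, S = 15, nneg = 0.2)
  bin <- buildCommunityModel(net)
  for (dist in c("normal", "gamma", "dirichlet")) {
    mod <- buildCommunityModel(net, cSampling = weightSampling(dist),
                               dSampling = weightSampling(dist), seed = 7)
    expect_identical(consumerMatrix(mod) > 0, consumerMatrix(bin) > 0)
    expect_identical(metabolicMatrix(mod) > 0, metabolicMatrix(bin) > 0)
    expect_true(all(consumerMatrix(mod)[consumerMatrix(mod) != 0] > 0))
    cs <- colSums(metabolicMatrix(mod))
    expect_true(all(abs(cs[cs > 0] - 1) < 1e-12))
  }
  expect_error(weightSampling("gamma", shape = -1), "gamma")
})

test_that("reconstruction inverts the interpretation on worked examples", {
  net <- w1Network()
  mod <- buildCommunityModel(net)
  rec <- reconstructNetwork(consumerMatrix(mod), metabolicMatrix(mod))
  expect_identical(adjacency(rec), adjacency(net))

  # two taxa, one positive edge
  A2 <- matrix(0, 2, 2); A2[1, 2] <- 1
  net2 <- augmentEnvironment(InteractionNetwork(A2))
  mod2 <- buildCommunityModel(net2)
  rec2 <- reconstructNetwork(consumerMatrix(mod2), metabolicMatrix(mod2))
  A2r <- adjacency(rec2)
  expect_equal(sum(A2r[1:2, 1:2] == 1), 1)
  expect_identical(A2r, adjacency(net2))
})

test_that("round trip is the identity on random disambiguated networks", {
  cases <- expand.grid(S = c(10, 25, 50), top = c("er", "ba"),
                       stringsAsFactors = FALSE)
  s <- 0
  for (r in seq_len(nrow(cases))) {
    for (rep in 1:34) {
      s <- s + 1
      net <- randomNetwork(s, S = cases$S[r], topology = cases$top[r],
                           nneg = 0.1)
      mod <- buildCommunityModel(net)
      rec <- reconstructNetwork(consumerMatrix(mod), metabolicMatrix(mod))
      expect_identical(adjacency(rec), adjacency(net))
    }
  }
})

test_that("C/D/Me matrices round-trip through CSV", {
  mod <- buildCommunityModel(randomNetwork(3, S = 10))
  f <- tempfile(fileext = ".csv")
  writeMatrixCSV(consumerMatrix(mod), f)
  expect_equal(readMatrixCSV(f), consumerMatrix(mod))
  writeMatrixCSV(metabolicMatrix(mod), f)
  expect_equal(readMatrixCSV(f), metabolicMatrix(mod))
})
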