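test_that("ER generator honours the edge-probability limits", {
  empty <- generateERNetwork(50, p = 0, seed = 1)
  expect_equal(sum(adjacency(empty) != 0), 0)

  full <- generateERNetwork(10, p = 1, seed = 1)
  expect_equal(sum(adjacency(full) == 1), 90)
  expect_true(all(diag(adjacency(full)) == 0))

  expect_error(generateERNetwork(50, p = 1.5), "p")
  expect_error(generateERNetwork(1, p = 0.5), "S")
})

test_that("ER edge counts match the binomial expectation over replicates", {
  S <- 50; p <- 0.1; n <- 200
  counts <- vapply(seq_len(n), function(s)
    sum(adjacency(generateERNetwork(S, p, seed = s)) != 0), numeric(1))
  trials <- S * (S - 1)
  expMean <- trials * p
  se <- sqrt(trials * p * (1 - p) / n)
  expect_lt(abs(mean(counts) - expMean), 3 * se)
})

test_that("directed BA generator produces the expected attachment counts", {
  # degenerate size: seed graph only
  seedOnly <- generateBANetwork(3, k = 3, seed = 1)
  expect_equal(sum(adjacency(seedOnly) != 0), 0)
  expect_error(generateBANetwork(3, k = 5), "k")

  net <- generateBANetwork(100, k = 3, seed = 7)
  A <- adjacency(net)
  nEdges <- sum(A == 1)
  nAttach <- 3 * (100 - 3)
  expect_gte(nEdges, nAttach)            # each attachment adds >= 1 edge
  expect_lte(nEdges, 2 * nAttach)        # bidirectional doubles at most
})

test_that("BA total-degree distribution is heavy-tailed", {
  hits <- vapply(1:40, function(s) {
    A <- adjacency(generateBANetwork(250, k = 2, seed = s))
    deg <- rowSums(A != 0) + colSums(A != 0)
    max(deg) > 5 * median(deg)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("competition assignment converts the requested pair fraction", {
  net <- generateERNetwork(20, 0.15, seed = 4)
  A <- adjacency(net)
  nPairs <- sum(upper.tri(A) & (A != 0 | t(A) != 0))
  expect_gte(nPairs, 10)  # fixture sanity

  unchanged <- assignCompetitions(net, nneg = 0, seed = 1)
  expect_identical(adjacency(unchanged), A)

  allNeg <- assignCompetitions(net, nneg = 1, seed = 1)
  expect_equal(sum(adjacency(allNeg) == 1), 0)
  expect_equal(sum(adjacency(allNeg) == -1), 2 * nPairs)

  some <- assignCompetitions(net, nneg = 0.1, seed = 2)
  expect_equal(sum(adjacency(some) == -1), 2 * round(0.1 * nPairs))
  # mutuality invariant
  As <- adjacency(some)
  expect_identical(As == -1, t(As) == -1)
})

test_that("disambiguation unions competitor out-neighbourhoods", {
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- -1
  A[1, 3] <- 1
  A[2, 4] <- 1
  out <- adjacency(disambiguateCompetitors(InteractionNetwork(A)))
  expect_equal(out[1, 3], 1); expect_equal(out[1, 4], 1)
  expect_equal(out[2, 3], 1); expect_equal(out[2, 4], 1)
  expect_equal(out[1, 2], -1); expect_equal(out[2, 1], -1)
})

test_that("disambiguation is the identity without competitors and idempotent", {
  noNeg <- generateERNetwork(15, 0.2, seed = 9)
  expect_identical(adjacency(disambiguateCompetitors(noNeg)),
                   adjacency(noNeg))
  for (s in 1:100) {
    net <- assignCompetitions(generateERNetwork(12, 0.2, seed = s),
                              nneg = 0.3, seed = s + 1000)
    once <- disambiguateCompetitors(net)
    twice <- disambiguateCompetitors(once)
    expect_identical(adjacency(twice), adjacency(once))
  }
})

test_that("ENV augmentation closes production and consumption", {
  # hand-traced example: t1 consumes nothing, t2 and t3 produce nothing
  aug <- w1Network(augmented = TRUE)
  A <- adjacency(aug)
  expect_true(hasEnv(aug))
  expect_identical(rownames(A)[4], "ENV")
  expect_equal(A[4, 1], 1)                    # ENV -> t1
  expect_equal(A[2, 4], 1); expect_equal(A[3, 4], 1)
  expect_equal(sum(A != 0), 6)                # 3 original + 3 added edges

  # already-closed cycle: ENV gets no incident edges
  cyc <- matrix(0, 3, 3); cyc[1, 2] <- cyc[2, 3] <- cyc[3, 1] <- 1
  Ac <- adjacency(augmentEnvironment(InteractionNetwork(cyc)))
  expect_equal(sum(Ac[4, ]) + sum(Ac[, 4]), 0)

  # isolated taxon is wired both ways
  iso <- augmentEnvironment(InteractionNetwork(matrix(0, 1, 1)))
  expect_equal(adjacency(iso)[1, 2], 1)
  expect_equal(adjacency(iso)[2, 1], 1)

  expect_error(augmentEnvironment(aug), "already")
})

test_that("after augmentation every taxon consumes and produces", {
  for (s in 1:30) {
    net <- randomNetwork(s, S = 20, nneg = 0.2)
    A <- adjacency(net)
    n <- nrow(A)
    for (i in seq_len(n - 1)) {
      expect_true(any(A[i, ] == 1))                   # produces something
      expect_true(any(A[, i] != 0))                   # consumes something
    }
    expect_identical(A == -1, t(A) == -1)
  }
})

test_that("generators are reproducible and seeds differ", {
  a <- generateNetwork("ba", S = 30, k = 2, nneg = 0.1, seed = 5)
  b <- generateNetwork("ba", S = 30, k = 2, nneg = 0.1, seed = 5)
  c <- generateNetwork("ba", S = 30, k = 2, nneg = 0.1, seed = 6)
  expect_identical(adjacency(a), adjacency(b))
  expect_false(identical(adjacency(a), adjacency(c)))
})

test_that("adjacency and edge-list files round-trip", {
  net <- randomNetwork(11, S = 12)
  f <- tempfile(fileext = ".csv")
  writeAdjacency(net, f)
  back <- readAdjacency(f)
  expect_identical(adjacency(back), adjacency(net))
  expect_true(hasEnv(back))

  ef <- tempfile(fileext = ".tsv")
  writeEdgeList(net, ef)
  el <- read.delim(ef)
  expect_equal(nrow(el), sum(adjacency(net) != 0))
  expect_true(all(el$sign %in% c(-1, 1)))
})
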