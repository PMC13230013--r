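test_that("clrm transforms follow the printed formula", {
  expect_equal(clrm(c(2, 8, 0)), c(0.5, 2, 0))
  expect_equal(clrm(c(4, 4)), c(1, 1))
  expect_equal(clrm(c(4, 4), log = TRUE), c(0, 0))
  expect_error(clrm(c(0, 0)), "all-zero")
  # unit geometric mean over the nonzero support, any vector
  set.seed(42)
  for (i in 1:20) {
    y <- rpois(30, 5)
    if (all(y == 0)) next
    z <- clrm(y)
    nz <- z[z != 0]
    expect_lt(abs(prod(nz)^(1 / length(nz)) - 1), 1e-12)
  }
})

test_that("perfectly correlated taxa are always detected", {
  base <- c(5, 9, 14, 3, 22, 40, 7, 11, 2, 30)
  Y <- rbind(base, base, rev(base) + 1)
  inf <- inferPearsonNetwork(Y, nPerm = 199, alpha = 0.05, seed = 1)
  expect_equal(adjacency(inf)[1, 2], 1L)
  expect_equal(inf@r[1, 2], 1)
  expect_error(inferPearsonNetwork(Y, nPerm = 0), "nPerm")
  expect_error(inferPearsonNetwork(Y[, 1:2], nPerm = 10), "samples")
})

test_that("zero-variance taxa never gain edges", {
  set.seed(3)
  Y <- matrix(rpois(5 * 30, 20), 5)
  Y[2, ] <- 0L        # absent taxon: clrm passes zeros through, variance 0
  inf <- inferPearsonNetwork(Y, nPerm = 99, seed = 2)
  expect_true(all(adjacency(inf)[2, ] == 0))
  expect_true(all(inf@p[2, ] == 1))
  expect_true(all(diag(adjacency(inf)) == 0))
})

test_that("type-I error of the permutation test is controlled", {
  set.seed(7)
  falseRates <- vapply(1:60, function(s) {
    Y <- matrix(rpois(10 * 100, 50), 10)
    inf <- inferPearsonNetwork(Y, nPerm = 199, alpha = 0.05,
                               correction = "BH", seed = s)
    sum(adjacency(inf)) / 2 / choose(10, 2)
  }, numeric(1))
  # with BH under a global null the familywise false-edge rate ~ alpha
  expect_lt(mean(falseRates), 0.06)
})

test_that("undirected truth collapses orientation and sign", {
  A <- matrix(0, 3, 3); A[1, 2] <- 1
  U <- asUndirectedTruth(InteractionNetwork(A))
  expect_equal(U[1, 2], 1L); expect_equal(U[2, 1], 1L)

  B <- matrix(0, 3, 3); B[1, 2] <- B[2, 1] <- -1
  U2 <- asUndirectedTruth(InteractionNetwork(B))
  expect_equal(sum(U2), 2L)    # one undirected edge

  expect_equal(sum(asUndirectedTruth(InteractionNetwork(matrix(0, 3, 3)))), 0L)

  # ENV stripped before conversion
  net <- randomNetwork(2, S = 10)
  expect_equal(dim(asUndirectedTruth(net)), c(10, 10))
})

test_that("MCC matches its formula and conventions", {
  truth <- randomUndirected(8, 0.3)
  expect_equal(mcc(truth, truth), 1)
  comp <- 1L - truth; diag(comp) <- 0L
  expect_equal(mcc(comp, truth), -1)

  # hand-evaluated confusion matrix: TP=4, TN=90, FP=3, FN=3 -> 351/651
  expect_equal(mccFromCounts(4, 90, 3, 3), 351 / 651)

  # the same counts realised (up to the pair total a graph permits) on a
  # 14-node toy: 91 pairs, TP=4, FP=3, FN=3, TN=81
  n <- 14
  pairs <- t(combn(n, 2))
  mk <- function(idx) {
    A <- matrix(0L, n, n)
    A[pairs[idx, , drop = FALSE]] <- 1L
    A[pairs[idx, c(2, 1), drop = FALSE]] <- 1L
    A
  }
  tr <- mk(1:7)                      # 7 true edges
  pr <- mk(c(1:4, 8:10))             # 4 TP, 3 FP
  expect_equal(mcc(pr, tr), (4 * 81 - 3 * 3) / sqrt(7 * 7 * 84 * 84))

  # denominator-zero convention
  none <- matrix(0L, 5, 5)
  expect_equal(mcc(none, none), 0)
  expect_error(mcc(matrix(0L, 4, 4), matrix(0L, 5, 5)), "node set")
})

test_that("random matched-edge predictors score MCC ~ 0 on average", {
  set.seed(5)
  truth <- asUndirectedTruth(generateERNetwork(30, 0.1, seed = 5))
  nEdge <- sum(truth) / 2
  pairs <- which(upper.tri(truth))
  vals <- vapply(1:2000, function(i) {
    P <- matrix(0L, 30, 30)
    P[sample(pairs, nEdge)] <- 1L
    P[lower.tri(P)] <- t(P)[lower.tri(P)]
    mcc(P, truth)
  }, numeric(1))
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)) + 0.005)
})

test_that("topology metrics match hand-worked small graphs", {
  path <- matrix(0L, 3, 3)
  path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1L
  m <- topologyMetrics(path)
  expect_equal(m$diameter, 2)
  expect_equal(m$radius, 1)
  expect_equal(m$meanClustering, 0)
  expect_equal(m$meanDistance, 4 / 3)
  expect_equal(unname(m$betweenness), c(0, 1, 0))

  tri <- matrix(1L, 3, 3); diag(tri) <- 0L
  mt <- topologyMetrics(tri)
  expect_equal(mt$diameter, 1)
  expect_equal(mt$radius, 1)
  expect_equal(mt$meanClustering, 1)
  expect_equal(mt$meanDistance, 1)
  expect_equal(unname(mt$betweenness), c(0, 0, 0))

  # edge + isolated node: disconnected conventions
  two <- matrix(0L, 3, 3); two[1, 2] <- two[2, 1] <- 1L
  md <- topologyMetrics(two)
  expect_equal(md$diameter, 1)
  expect_true(is.na(md$radius))
  expect_true(is.na(md$meanDistance))
  expect_true(all(c("radius", "meanDistance") %in% md$undefined))

  # empty graph: everything undefined
  m0 <- topologyMetrics(matrix(0L, 0, 0))
  expect_true(is.na(m0$diameter))
})

test_that("topology metrics agree with the brute-force oracle", {
  # exhaustive over all graphs on <= 4 nodes
  for (n in 2:4) {
    up <- which(upper.tri(matrix(0, n, n)))
    for (code in 0:(2^length(up) - 1)) {
      A <- matrix(0L, n, n)
      A[up] <- as.integer(intToBits(code))[seq_along(up)]
      A[lower.tri(A)] <- t(A)[lower.tri(A)]
      got <- topologyMetrics(A)
      ora <- bruteTopology(A)
      expect_equal(got$diameter, ora$diameter)
      expect_equal(got$radius, ora$radius)
      expect_equal(got$meanDistance, ora$meanDistance)
      expect_equal(got$meanClustering, ora$meanClustering)
      expect_equal(unname(got$betweenness), ora$betweenness)
      expect_equal(unname(got$degree), ora$degree)
    }
  }
  # random graphs on 5..7 nodes
  set.seed(123)
  for (n in 5:7) {
    for (r in 1:200) {
      A <- randomUndirected(n, runif(1, 0.1, 0.9))
      got <- topologyMetrics(A)
      ora <- bruteTopology(A)
      expect_equal(got$diameter, ora$diameter)
      expect_equal(got$radius, ora$radius)
      expect_equal(got$meanDistance, ora$meanDistance)
      expect_equal(got$meanClustering, ora$meanClustering)
      expect_equal(unname(got$betweenness), ora$betweenness)
    }
  }
})

test_that("inferred networks and metric reports are written to disk", {
  set.seed(8)
  Y <- matrix(rpois(6 * 40, 30), 6)
  Y[2, ] <- Y[1, ] + rpois(40, 2)          # one strong association
  inf <- inferPearsonNetwork(Y, nPerm = 199, seed = 3)
  f <- tempfile(fileext = ".tsv")
  writeInferredNetwork(inf, f)
  el <- read.delim(f)
  expect_equal(nrow(el), sum(adjacency(inf)) / 2)

  mt <- topologyMetrics(adjacency(inf))
  g <- tempfile(fileext = ".tsv")
  writeTopologyReport(mt, g)
  kv <- read.delim(g)
  expect_true("diameter" %in% kv$key)
  expect_true(file.exists(paste0(g, ".degree.tsv")))
})
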