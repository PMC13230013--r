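test_that("uptake response functions follow their closed forms", {
  lin <- micrmParams()
  expect_equal(uptakeResponse(1000, lin), 1000)
  expect_equal(uptakeResponse(0, lin), 0)

  hill <- micrmParams(response = "hill", sigmaMax = 5, nHill = 2, kHalf = 20)
  expect_equal(uptakeResponse(20, hill), 2.5)      # half saturation
  expect_lt(abs(uptakeResponse(1e6, hill) - 5), 1e-6)
  expect_equal(uptakeResponse(0, hill), 0)
  # monotone nondecreasing
  r <- seq(0, 200, by = 5)
  expect_true(all(diff(uptakeResponse(r, hill)) >= 0))
  expect_error(uptakeResponse(-1, lin), "negative")
})

test_that("community derivatives match the hand-evaluated example", {
  sc <- singleConsumer()
  p <- micrmParams()
  d <- communityDerivatives(1, c(1000, 0), sc$C, sc$D, p, c(0, 0))
  expect_equal(unname(d$dN), 199)                  # (1-0.8)*1000 - 1
  expect_equal(unname(d$dR), c(-1000, 800))

  # empty community: resources only see the supply
  d0 <- communityDerivatives(0, c(10, 10), sc$C, sc$D, p, c(3, 0))
  expect_equal(unname(d0$dN), 0)
  expect_equal(unname(d0$dR), c(3, 0))

  # full leakage: no energy retained, pure maintenance decay
  pl <- micrmParams(l = 1)
  dl <- communityDerivatives(c(2, 3), c(1, 0),
                             rbind(c(1, 0), c(1, 0)),
                             matrix(c(0, 1, 0, 0), 2), pl, c(0, 0))
  expect_equal(dl$dN, -pl@g * pl@mc * c(2, 3))

  expect_error(communityDerivatives(-1, c(1, 1), sc$C, sc$D, p, c(0, 0)),
               "negative")
  expect_error(communityDerivatives(NaN, c(1, 1), sc$C, sc$D, p, c(0, 0)),
               "finite")
})

test_that("with zero leakage no byproduct is secreted", {
  p0 <- micrmParams(l = 0)
  mod <- buildCommunityModel(randomNetwork(5, S = 10))
  M <- nMetabolites(mod)
  C <- consumerMatrix(mod); D <- metabolicMatrix(mod)
  N <- runif(nrow(C), 0.5, 2)
  R <- runif(M, 0, 100)
  d <- communityDerivatives(N, R, C, D, p0, numeric(M))
  # every resource can only be drained: dR = -uptake exactly
  uptake <- R * drop(crossprod(C, N))
  expect_equal(d$dR, -uptake)
})

test_that("supply construction follows mode and supplied set", {
  p <- micrmParams()
  sup <- makeSupply(p, 1:4, M = 5)
  expect_equal(sup$fn(numeric(5)), c(1000, 1000, 1000, 1000, 0))
  expect_error(makeSupply(p, c(1, 5), M = 5), "waste")

  bol <- makeSupply(micrmParams(supplyMode = "bolus"), 1:4, M = 5)
  expect_equal(bol$fn(runif(5)), numeric(5))

  logi <- makeSupply(micrmParams(replenishment = "logistic"), 1, M = 2)
  expect_equal(logi$fn(c(0, 0))[1], 1000)
  expect_equal(logi$fn(c(1000, 0))[1], 0)

  # seeded choice of the supplied fraction
  s1 <- chooseSupplied(5, fr = 0.5, seed = 3)
  expect_length(s1, 2)                            # round(0.5 * 4)
  expect_identical(s1, chooseSupplied(5, fr = 0.5, seed = 3))
  expect_false(5 %in% chooseSupplied(5, fr = 1, seed = 1))
})

test_that("community initialisation honours the init spec", {
  sc <- singleConsumer()
  p <- micrmParams()
  sup <- makeSupply(p, 1, M = 2)

  cst <- initCommunity(sc$C, p, sup, list(type = "constant", value = 2))
  expect_equal(cst$N, 2)
  expect_equal(cst$R, c(1000, 0))

  C5 <- matrix(1, 5, 2); C5[, 2] <- 0
  vals <- c(0.1, 1, 2, 3, 10)
  usr <- initCommunity(C5, p, sup, list(type = "values", values = vals))
  expect_equal(usr$N, vals)
  expect_error(
    initCommunity(C5, p, sup, list(type = "values", values = 1:3)),
    "length")

  # heavy-tailed sampler: positive skew in every seeded draw
  Cbig <- matrix(1, 250, 2); Cbig[, 2] <- 0
  for (s in 1:50) {
    n0 <- initCommunity(Cbig, p, sup,
                        list(type = "lognormal", meanlog = 0, sdlog = 2),
                        seed = s)$N
    expect_true(all(n0 > 0))
    m <- mean(n0)
    expect_gt(mean((n0 - m)^3) / mean((n0 - m)^2)^1.5, 0)
  }
})

test_that("single-consumer steady state matches the closed form", {
  sc <- singleConsumer()
  p <- micrmParams()
  sup <- makeSupply(p, 1, M = 2)                  # kappa = R0/tau = 1000
  ss <- integrateToSteadyState(list(N = 1, R = c(1000, 0)), sc$C, sc$D, p,
                               sup)
  expect_true(ss@converged)
  # R* = mc / ((1-l) we) = 5; N* = kappa / R* = 200
  expect_lt(abs(ss@R[[1]] - 5) / 5, 0.01)
  expect_lt(abs(ss@N[[1]] - 200) / 200, 0.01)
  expect_equal(survivors(ss), 1L)

  # doubling the supply doubles the abundance
  p2 <- micrmParams(R0 = 2000)
  sup2 <- makeSupply(p2, 1, M = 2)
  ss2 <- integrateToSteadyState(list(N = 1, R = c(2000, 0)), sc$C, sc$D, p2,
                                sup2)
  expect_lt(abs(ss2@N[[1]] - 2 * ss@N[[1]]) / (2 * ss@N[[1]]), 0.01)
})

test_that("no taxa means resources follow the supply alone", {
  sc <- singleConsumer()
  p <- micrmParams(tChunk = 10, tMax = 10)
  sup <- makeSupply(p, 1, M = 2)
  ss <- integrateToSteadyState(list(N = 0, R = c(0, 0)), sc$C, sc$D, p, sup)
  # constant supply: R grows linearly at R0/tau
  expect_lt(abs(ss@R[[1]] - 1000 * 10) / 1e4, 0.01)

  plog <- micrmParams(replenishment = "logistic", tChunk = 50)
  slog <- makeSupply(plog, 1, M = 2)
  sslog <- integrateToSteadyState(list(N = 0, R = c(0, 0)), sc$C, sc$D,
                                  plog, slog)
  expect_lt(abs(sslog@R[[1]] - 1000) / 1000, 0.01)   # logistic: R -> R0
})

test_that("survivors satisfy the zero-growth condition at steady state", {
  for (s in c(2, 7, 21)) {
    mod <- buildCommunityModel(randomNetwork(s, S = 20, nneg = 0.1))
    p <- micrmParams(fr = 0.5)
    res <- simulateCommunity(mod, p, seed = s)
    ss <- res$steadyState
    expect_true(ss@converged)
    if (length(survivors(ss)) == 0) next
    C <- consumerMatrix(mod)
    surplus <- (1 - p@l) * p@we *
      drop(C %*% uptakeResponse(ss@R, p)) - p@mc
    expect_true(all(abs(surplus[survivors(ss)]) < 10 * p@ssTol))
    expect_true(all(ss@N >= 0) && all(ss@R >= 0))
  }
})
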