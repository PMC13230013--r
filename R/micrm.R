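#' Uptake response function
#'
#' Maps a resource concentration to the per-unit-consumer uptake rate:
#' linear (`sigma(R) = R`) or Hill type III
#' (`sigma(R) = sigmaMax R^n / (kHalf^n + R^n)`). Monotone nondecreasing with
#' `sigma(0) = 0`.
#'
#' @param R nonnegative concentration (vectorised).
#' @param params a [MicrmParams-class].
#' @return Uptake rate(s), same length as `R`.
#' @export
#' @examples
#' uptakeResponse(1000, micrmParams())                       # 1000
#' uptakeResponse(20, micrmParams(response = "hill"))        # sigmaMax / 2
uptakeResponse <- function(R, params) {
  stopifnot(is(params, "MicrmParams"))
  if (any(R < 0)) stop("negative resource concentration")
  switch(params@response,
    linear = R,
    hill = {
      Rn <- R^params@nHill
      params@sigmaMax * Rn / (params@kHalf^params@nHill + Rn)
    })
}

# internal, tolerant version used inside the integrator (clamps tiny
# negatives produced by the solver instead of erroring)
.sigma <- function(R, params) {
  R <- pmax(R, 0)
  if (params@response == "linear") return(R)
  Rn <- R^params@nHill
  params@sigmaMax * Rn / (params@kHalf^params@nHill + Rn)
}

# d sigma / d R; the steady-state criterion tracks the effective resource
# availability sigma(R) rather than R itself (see integrateToSteadyState)
.sigmaPrime <- function(R, params) {
  R <- pmax(R, 0)
  if (params@response == "linear") return(rep(1, length(R)))
  Kn <- params@kHalf^params@nHill
  Rn <- R^params@nHill
  params@sigmaMax * params@nHill * Kn * R^(params@nHill - 1) / (Kn + Rn)^2
}

.derivs <- function(N, R, C, D, params, kappa) {
  u <- .sigma(R, params)
  Nc <- pmax(N, 0)
  energy <- (1 - params@l) * params@we * drop(C %*% u)   # per-capita influx
  dN <- params@g * Nc * (energy - params@mc)
  uptake <- u * drop(crossprod(C, Nc))                   # per-resource drain
  secretion <- params@l * drop(D %*% uptake)
  dR <- kappa(R) - uptake + secretion
  list(dN = dN, dR = dR)
}

#' Community derivatives of the consumer-resource model
#'
#' Evaluates the right-hand side of the dynamics. Each taxon grows at a rate
#' proportional to its energy surplus (uptake energy after leakage, minus the
#' maintenance cost); each resource changes by supply, consumer uptake and
#' leaked byproduct secretion routed through the metabolic matrix:
#' \deqn{dN_i = g N_i (\sum_\alpha (1-l) w_e C_{i\alpha} \sigma(R_\alpha) - m_c)}
#' \deqn{dR_\alpha = \kappa_\alpha(R) - \sum_i N_i C_{i\alpha} \sigma(R_\alpha)
#'   + l \sum_i \sum_\beta D_{\alpha\beta} N_i C_{i\beta} \sigma(R_\beta)}
#'
#' @param N taxon abundance vector (length S).
#' @param R resource concentration vector (length M).
#' @param C consumer-preference matrix S x M.
#' @param D metabolic matrix M x M.
#' @param params a [MicrmParams-class].
#' @param kappa supply function of `R` returning a length-M vector (see
#'   [makeSupply()]); a numeric vector is accepted and treated as constant.
#' @return A list with `dN` and `dR`.
#' @export
#' @examples
#' C <- matrix(c(1, 0), 1); D <- matrix(0, 2, 2); D[2, 1] <- 1
#' communityDerivatives(1, c(1000, 0), C, D, micrmParams(),
#'                      kappa = c(0, 0))
communityDerivatives <- function(N, R, C, D, params, kappa) {
  stopifnot(is(params, "MicrmParams"))
  if (any(!is.finite(N)) || any(!is.finite(R)))
    stop("non-finite community state")
  if (any(N < 0) || any(R < 0))
    stop("negative community state")
  if (length(N) != nrow(C) || length(R) != ncol(C) ||
      !all(dim(D) == ncol(C)))
    stop("inconsistent dimensions between state, C and D")
  if (is.numeric(kappa)) {
    kv <- kappa
    kappa <- function(R) kv
  }
  .derivs(N, R, C, D, params, kappa)
}

#' Construct the resource supply
#'
#' Constant mode supplies `R0/tau` (or, with logistic replenishment,
#' `(R0 - R)/tau`) on the supplied metabolite set and 0 elsewhere; bolus mode
#' supplies nothing (`kappa = 0`) and the supplied resources are instead
#' provided once in the initial condition. The waste metabolite is never
#' supplied.
#'
#' @param params a [MicrmParams-class].
#' @param suppliedSet integer indices of supplied metabolites (non-waste).
#' @param M total metabolite count.
#' @param wasteIndex index of the waste metabolite (excluded from supply).
#' @return A list with elements `mode`, `supplied`, `rates` (base supply
#'   rates, zero in bolus mode) and `fn(R)` returning the supply vector.
#' @export
#' @examples
#' sup <- makeSupply(micrmParams(), suppliedSet = 1:4, M = 5, wasteIndex = 5)
#' sup$fn(numeric(5))
makeSupply <- function(params, suppliedSet, M, wasteIndex = M) {
  stopifnot(is(params, "MicrmParams"))
  suppliedSet <- as.integer(suppliedSet)
  if (any(suppliedSet == wasteIndex))
    stop("the waste metabolite cannot be supplied")
  if (any(suppliedSet < 1 | suppliedSet > M))
    stop("supplied metabolite indices out of range")
  rates <- numeric(M)
  if (params@supplyMode == "constant")
    rates[suppliedSet] <- params@R0 / params@tau
  force(params)
  fn <- if (params@supplyMode == "bolus") {
    function(R) numeric(M)
  } else if (params@replenishment == "logistic") {
    supplied <- suppliedSet
    function(R) {
      k <- numeric(M)
      k[supplied] <- (params@R0 - R[supplied]) / params@tau
      k
    }
  } else {
    function(R) rates
  }
  list(mode = params@supplyMode, supplied = suppliedSet, rates = rates,
       fn = fn)
}

#' Choose which metabolites are supplied
#'
#' Draws `round(fr * (M - 1))` non-waste metabolites uniformly without
#' replacement.
#'
#' @param M total metabolite count.
#' @param fr fraction of non-waste metabolites supplied.
#' @param wasteIndex waste metabolite index (excluded).
#' @param seed optional integer seed.
#' @return Sorted integer vector of supplied metabolite indices.
#' @export
chooseSupplied <- function(M, fr, wasteIndex = M, seed = NULL) {
  .checkFraction(fr, "fr")
  .setSeed(seed)
  pool <- setdiff(seq_len(M), wasteIndex)
  nSup <- round(fr * length(pool))
  sort(.sampleInt(pool, nSup))
}

#' Initialise the community state
#'
#' Taxon abundances are drawn from a heavy-tailed log-normal sampler (the
#' built-in emulation of the strongly right-skewed abundance distributions of
#' real 16S count tables), set to a constant, or taken verbatim from a
#' user-supplied vector or file. Resources start at `R0` on the supplied set
#' and 0 elsewhere (the environment is assumed to be provisioned before the
#' taxa are introduced), in both supply modes.
#'
#' @param C consumer-preference matrix (supplies the taxon count).
#' @param params a [MicrmParams-class].
#' @param supply result of [makeSupply()].
#' @param init list describing the abundance initialisation: one of
#'   `list(type = "lognormal", meanlog = 0, sdlog = 2)`,
#'   `list(type = "constant", value = 1)`,
#'   `list(type = "values", values = <numeric length S>)` or
#'   `list(type = "file", path = <one abundance per line>)`.
#' @param seed optional integer seed.
#' @return A list with `N`, `R` and `t = 0`.
#' @export
#' @examples
#' C <- matrix(c(1, 0), 1)
#' sup <- makeSupply(micrmParams(), 1, M = 2)
#' initCommunity(C, micrmParams(), sup, list(type = "constant", value = 1))
initCommunity <- function(C, params, supply,
                          init = list(type = "lognormal", meanlog = 0,
                                      sdlog = 2),
                          seed = NULL) {
  stopifnot(is(params, "MicrmParams"))
  S <- nrow(C)
  M <- ncol(C)
  .setSeed(seed)
  N0 <- switch(init$type,
    lognormal = rlnorm(S,
                       meanlog = if (is.null(init$meanlog)) 0 else init$meanlog,
                       sdlog = if (is.null(init$sdlog)) 2 else init$sdlog),
    constant = rep(init$value, S),
    values = init$values,
    file = scan(init$path, what = double(), quiet = TRUE),
    stop("unknown initialisation type: ", init$type))
  if (length(N0) != S)
    stop(sprintf("initial abundances have length %d, expected %d",
                 length(N0), S))
  if (any(N0 <= 0)) stop("initial abundances must be strictly positive")
  R0v <- numeric(M)
  R0v[supply$supplied] <- params@R0
  list(N = as.numeric(N0), R = R0v, t = 0)
}

# resources tracked by the convergence criterion: those consumed by at least
# one extant taxon. Pure sinks (waste, resources whose consumers went
# extinct) grow linearly under constant supply and are excluded.
.trackedResources <- function(N, C) {
  alive <- N > 0
  if (!any(alive)) return(rep(FALSE, ncol(C)))
  colSums(C[alive, , drop = FALSE] > 0) > 0
}

#' Integrate the community dynamics to steady state
#'
#' Stiff-capable integration (`deSolve::lsoda`) in chunks of `tChunk`. After
#' each chunk, taxa below the extinction threshold are clamped to 0 and tiny
#' solver negatives are zeroed. Convergence is declared when the maximum
#' relative derivative `|dN|/(|N| + 1e-8)` over taxa and the relative
#' stationarity of the effective resource availability
#' `|sigma'(R) dR|/(sigma(R) + 1e-8)` over tracked resources fall below
#' `ssTol` (for the linear response the resource criterion is the plain
#' relative derivative of `R`). Resources no extant taxon consumes (e.g.
#' waste), and resources a saturated community cannot absorb, accumulate
#' linearly under constant supply without affecting growth; they do not
#' block convergence. Failure to converge by `tMax` is reported via the
#' `converged` flag, never silently accepted.
#'
#' @param state0 list with `N` and `R` (see [initCommunity()]).
#' @param C,D model matrices.
#' @param params a [MicrmParams-class].
#' @param supply result of [makeSupply()] (or a bare `kappa` function).
#' @return A [SteadyState-class].
#' @export
#' @examples
#' C <- matrix(c(1, 0), 1); D <- matrix(0, 2, 2); D[2, 1] <- 1
#' p <- micrmParams()
#' sup <- makeSupply(p, 1, M = 2)
#' ss <- integrateToSteadyState(list(N = 1, R = c(1000, 0)), C, D, p, sup)
#' round(c(ss@N, ss@R[1]), 2)    # N* = 200, R* = 5
integrateToSteadyState <- function(state0, C, D, params, supply) {
  stopifnot(is(params, "MicrmParams"))
  kappa <- if (is.function(supply)) supply else supply$fn
  S <- nrow(C)
  M <- ncol(C)
  N <- as.numeric(state0$N)
  R <- as.numeric(state0$R)
  if (length(N) != S || length(R) != M)
    stop("state dimensions do not match C")
  rhs <- function(t, y, parms) {
    d <- .derivs(y[seq_len(S)], y[S + seq_len(M)], C, D, params, kappa)
    list(c(d$dN, d$dR))
  }
  # analytic Jacobian of the stiff system (the supply term is constant or
  # diagonal-linear in R, handled via kappaPrime)
  kappaPrime <- numeric(M)
  if (is.list(supply) && supply$mode == "constant" &&
      params@replenishment == "logistic")
    kappaPrime[supply$supplied] <- -1 / params@tau
  lwe <- (1 - params@l) * params@we
  jac <- function(t, y, parms) {
    N <- pmax(y[seq_len(S)], 0)
    R <- y[S + seq_len(M)]
    sg <- .sigma(R, params)
    sp <- .sigmaPrime(R, params)
    en <- lwe * drop(C %*% sg)
    Csg <- sweep(C, 2, sg, "*")
    uptot <- drop(crossprod(C, N))
    J <- matrix(0, S + M, S + M)
    iN <- seq_len(S); iR <- S + seq_len(M)
    J[iN, iN] <- diag(params@g * (en - params@mc), S)
    J[iN, iR] <- params@g * lwe * (N * sweep(C, 2, sp, "*"))
    J[iR, iN] <- -t(Csg) + params@l * (D %*% t(Csg))
    J[iR, iR] <- -diag(uptot * sp, M) +
      params@l * sweep(D, 2, uptot * sp, "*") + diag(kappaPrime, M)
    J
  }
  t <- 0
  converged <- FALSE
  while (t < params@tMax) {
    out <- suppressWarnings(
      deSolve::lsoda(c(N, R), c(t, t + params@tChunk), rhs, NULL,
                     jacfunc = jac, jactype = "fullusr",
                     rtol = 1e-7, atol = 1e-9, maxsteps = 50000))
    istate <- attr(out, "istate")[1]
    # istate -1 = maxsteps reached inside a very stiff transient: keep the
    # partial progress and continue from the time actually reached
    if (istate < 0 && istate != -1)
      stop(sprintf("ODE integration failed at t = %g (lsoda istate %d)",
                   t, istate))
    tReached <- out[nrow(out), 1]
    if (tReached <= t)
      stop(sprintf("ODE integration stalled at t = %g (lsoda istate %d)",
                   t, istate))
    y <- out[nrow(out), -1]
    N <- pmax(y[seq_len(S)], 0)
    R <- pmax(y[S + seq_len(M)], 0)
    N[N < params@extinctionThreshold] <- 0
    t <- tReached
    d <- .derivs(N, R, C, D, params, kappa)
    relN <- abs(d$dN) / (abs(N) + 1e-8)
    tracked <- .trackedResources(N, C)
    # resources enter the dynamics only through sigma(R): convergence is
    # declared when the effective availability sigma is stationary (for the
    # linear response this is the plain relative derivative of R; under a
    # saturating response, resources the community cannot absorb accumulate
    # without affecting growth and must not block convergence)
    dSig <- .sigmaPrime(R, params) * d$dR
    sig <- .sigma(R, params)
    relR <- abs(dSig[tracked]) / (abs(sig[tracked]) + 1e-8)
    if (max(c(relN, relR, 0)) < params@ssTol) {
      converged <- TRUE
      break
    }
  }
  names(N) <- rownames(C)
  names(R) <- colnames(C)
  new("SteadyState", N = N, R = R, t = t, converged = converged,
      survivors = which(unname(N) > params@extinctionThreshold))
}

#' Simulate a community to its reference steady state
#'
#' Convenience wrapper: chooses the supplied metabolite set (fraction `fr` of
#' non-waste metabolites), initialises abundances and resources, and
#' integrates to steady state. Stage seeds derive from the master seed.
#'
#' @param model a [CommunityModel-class].
#' @param params a [MicrmParams-class].
#' @param init abundance initialisation (see [initCommunity()]).
#' @param seed master seed.
#' @return A list with `steadyState` ([SteadyState-class]), `supply` and
#'   `state0`.
#' @export
#' @examples
#' net <- generateNetwork("er", S = 8, p = 0.25, nneg = 0.1, seed = 1)
#' mod <- buildCommunityModel(net)
#' res <- simulateCommunity(mod, micrmParams(), seed = 1)
#' res$steadyState
simulateCommunity <- function(model, params = micrmParams(),
                              init = list(type = "lognormal", meanlog = 0,
                                          sdlog = 2),
                              seed = NULL) {
  stopifnot(is(model, "CommunityModel"))
  M <- nMetabolites(model)
  sseed <- if (is.null(seed)) NULL else stageSeed(seed, "supply")
  iseed <- if (is.null(seed)) NULL else stageSeed(seed, "init")
  supplied <- chooseSupplied(M, params@fr, wasteIndex(model), seed = sseed)
  supply <- makeSupply(params, supplied, M, wasteIndex(model))
  state0 <- initCommunity(model@C, params, supply, init, seed = iseed)
  ss <- integrateToSteadyState(state0, model@C, model@D, params, supply)
  list(steadyState = ss, supply = supply, state0 = state0)
}
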