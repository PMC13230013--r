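#' Design per-sample environmental perturbations
#'
#' For each of `B` biological samples, draws the fraction of perturbable
#' resources `fp` (default `U(0, 1)`), the scale factor `ps` (default
#' `U(2, 10)`), a direction (up or down with probability 1/2 each), and a
#' uniformly chosen target set of `round(fp * |perturbable|)` resources
#' without replacement. Fully reproducible given the seed.
#'
#' @param perturbable integer indices of perturbable resources (nonzero
#'   supply rates in constant mode; nonzero steady-state concentrations in
#'   bolus mode).
#' @param B number of biological samples.
#' @param fp either a fixed value in `[0, 1]` or a range `c(min, max)` to
#'   draw from uniformly.
#' @param ps either a fixed value `>= 1` or a range `c(min, max)`.
#' @param mode `"constant"` or `"bolus"`.
#' @param seed optional integer seed.
#' @return A [PerturbationDesign-class].
#' @export
#' @examples
#' designPerturbations(1:10, B = 5, seed = 1)
#' designPerturbations(1:10, B = 3, fp = 0.1, ps = 2, seed = 1)
designPerturbations <- function(perturbable, B, fp = c(0, 1), ps = c(2, 10),
                                mode = c("constant", "bolus"), seed = NULL) {
  mode <- match.arg(mode)
  perturbable <- as.integer(perturbable)
  if (length(perturbable) == 0)
    stop("the perturbable resource set is empty")
  if (B < 1) stop("B must be >= 1")
  .setSeed(seed)
  drawv <- function(spec, n) {
    if (length(spec) == 1L) rep(as.numeric(spec), n)
    else runif(n, spec[1], spec[2])
  }
  fpv <- drawv(fp, B)
  psv <- drawv(ps, B)
  if (any(fpv < 0 | fpv > 1)) stop("fp must be in [0, 1]")
  if (any(psv < 1)) stop("ps must be >= 1")
  dir <- sample(c("up", "down"), B, replace = TRUE)
  targets <- lapply(seq_len(B), function(k) {
    nT <- round(fpv[k] * length(perturbable))
    if (nT == 0) integer(0) else sort(.sampleInt(perturbable, nT))
  })
  new("PerturbationDesign", fp = fpv, ps = psv, direction = dir,
      targets = targets, mode = mode,
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

#' Apply one perturbation to a converged steady state
#'
#' Constant mode: the supply rates of the targeted resources are multiplied
#' (up) or divided (down) by the sample's scale factor; integration restarts
#' from the steady state itself. Bolus mode: the nonzero steady-state
#' concentrations of the targeted resources are scaled and supply stays off.
#'
#' @param ss a converged [SteadyState-class].
#' @param design a [PerturbationDesign-class].
#' @param k sample index within the design.
#' @param supply the supply used to reach `ss` (see [makeSupply()]).
#' @param params a [MicrmParams-class].
#' @return A list with `state0` (list `N`, `R`) and `supply` (perturbed).
#' @export
applyPerturbation <- function(ss, design, k, supply, params) {
  stopifnot(is(ss, "SteadyState"), is(design, "PerturbationDesign"))
  if (design@mode != params@supplyMode)
    stop(sprintf("design mode '%s' does not match supply mode '%s'",
                 design@mode, params@supplyMode))
  tg <- design@targets[[k]]
  fac <- if (design@direction[k] == "up") design@ps[k] else 1 / design@ps[k]
  N0 <- unname(ss@N)
  R0v <- unname(ss@R)
  if (design@mode == "constant") {
    rates <- supply$rates
    rates[tg] <- rates[tg] * fac
    pk <- list(mode = "constant", supplied = supply$supplied, rates = rates,
               fn = local({ r <- rates; function(R) r }))
    if (params@replenishment == "logistic" && length(tg))
      pk$fn <- local({
        base <- supply$fn; t2 <- tg; f2 <- fac
        function(R) { k0 <- base(R); k0[t2] <- k0[t2] * f2; k0 }
      })
    list(state0 = list(N = N0, R = R0v), supply = pk)
  } else {
    sc <- intersect(tg, which(R0v > 0))  # only nonzero concentrations scale
    R0v[sc] <- R0v[sc] * fac
    list(state0 = list(N = N0, R = R0v), supply = supply)
  }
}

#' Generate biological samples by perturb-and-reconverge
#'
#' For each sample of the design: perturb the environment of the reference
#' steady state, re-integrate to a new steady state, and store the resulting
#' taxon abundances as one column of `X`. All samples share the same `C` and
#' `D` (the same ground-truth network); extinct taxa stay extinct.
#' Per-sample non-convergence is recorded in the flags and the run continues.
#'
#' @param ss the reference [SteadyState-class].
#' @param design a [PerturbationDesign-class].
#' @param model a [CommunityModel-class] (or a list with `C` and `D`).
#' @param params a [MicrmParams-class].
#' @param supply the supply used to reach `ss`.
#' @return A [SampleAbundances-class] with `X` of dimension S x B.
#' @export
#' @examples
#' net <- generateNetwork("er", S = 8, p = 0.25, nneg = 0.1, seed = 1)
#' mod <- buildCommunityModel(net)
#' sim <- simulateCommunity(mod, micrmParams(), seed = 1)
#' des <- designPerturbations(sim$supply$supplied, B = 3, seed = 2)
#' generateSamples(sim$steadyState, des, mod, micrmParams(), sim$supply)
generateSamples <- function(ss, design, model, params, supply) {
  C <- if (is(model, "CommunityModel")) model@C else model$C
  D <- if (is(model, "CommunityModel")) model@D else model$D
  B <- length(design@fp)
  X <- matrix(0, nrow(C), B,
              dimnames = list(rownames(C), sprintf("s%d", seq_len(B))))
  conv <- logical(B)
  for (k in seq_len(B)) {
    pk <- applyPerturbation(ss, design, k, supply, params)
    ssk <- integrateToSteadyState(pk$state0, C, D, params, pk$supply)
    X[, k] <- ssk@N
    conv[k] <- ssk@converged
  }
  new("SampleAbundances", X = X, converged = conv, design = design)
}
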