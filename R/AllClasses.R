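#' InteractionNetwork: a directed, signed microbial interaction network
#'
#' Wraps a square adjacency matrix `A` with entries in `{-1, 0, +1}` over `S`
#' taxa (plus, optionally, a final environment node labelled `"ENV"`).
#' `A[i, j] = +1` encodes a metabolite-mediated positive interaction
#' (taxon `i` produces a metabolite consumed by taxon `j`); mutual
#' `A[i, j] = A[j, i] = -1` encodes competition for a shared metabolite.
#' Self-interactions are disallowed, and every negative entry must be mutual.
#'
#' @slot A integer matrix; the signed adjacency, with taxon labels as
#'   dimnames.
#' @slot hasEnv logical; whether the last node is the environment (ENV).
#' @slot topologyMeta list; generator name and parameters (for provenance).
#' @aliases InteractionNetwork
#' @exportClass InteractionNetwork
setClass("InteractionNetwork",
  slots = c(A = "matrix", hasEnv = "logical", topologyMeta = "list"),
  prototype = prototype(A = matrix(integer(), 0, 0), hasEnv = FALSE,
                        topologyMeta = list())
)

setValidity("InteractionNetwork", function(object) {
  A <- object@A
  msg <- character()
  if (nrow(A) != ncol(A)) msg <- c(msg, "adjacency matrix must be square")
  if (!all(A %in% c(-1, 0, 1))) msg <- c(msg, "entries must be in {-1, 0, 1}")
  if (nrow(A) > 0 && any(diag(A) != 0)) msg <- c(msg, "diagonal must be zero")
  neg <- A == -1
  if (!identical(neg, t(neg)))
    msg <- c(msg, "every -1 entry must be mutual: A[i,j] = -1 <=> A[j,i] = -1")
  if (is.null(rownames(A)) || is.null(colnames(A)) ||
      !identical(rownames(A), colnames(A)))
    msg <- c(msg, "A must carry identical row and column labels")
  if (length(object@hasEnv) != 1L || is.na(object@hasEnv))
    msg <- c(msg, "hasEnv must be TRUE or FALSE")
  if (isTRUE(object@hasEnv)) {
    if (nrow(A) < 1 || rownames(A)[nrow(A)] != "ENV")
      msg <- c(msg, "augmented networks must have 'ENV' as the last node")
  } else if (nrow(A) > 0 && "ENV" %in% rownames(A)) {
    msg <- c(msg, "'ENV' label present but hasEnv is FALSE")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an InteractionNetwork
#'
#' @param A square signed matrix with entries in `{-1, 0, 1}`; dimnames are
#'   taken as taxon labels (generated as `t1, t2, ...` when absent).
#' @param hasEnv logical; `TRUE` when the last node is the environment.
#' @param topologyMeta list of provenance information.
#' @return An [InteractionNetwork-class] object.
#' @export
#' @examples
#' A <- matrix(0, 3, 3); A[1, 2] <- 1; A[2, 3] <- A[3, 2] <- -1
#' net <- InteractionNetwork(A)
#' net
InteractionNetwork <- function(A, hasEnv = FALSE, topologyMeta = list()) {
  A <- as.matrix(A)
  storage.mode(A) <- "integer"
  if (is.null(rownames(A))) {
    lab <- .defaultLabels(nrow(A))
    if (isTRUE(hasEnv) && nrow(A) > 0) lab[nrow(A)] <- "ENV"
    dimnames(A) <- list(lab, lab)
  } else {
    colnames(A) <- rownames(A)
  }
  new("InteractionNetwork", A = A, hasEnv = isTRUE(hasEnv),
      topologyMeta = topologyMeta)
}

#' CommunityModel: consumer-resource interpretation of a network
#'
#' Holds the metabolite-mediated interpretation of an augmented
#' [InteractionNetwork-class]: the metabolite-edge map `Me`, the
#' metabolite-species map `Ms`, the consumer-preference matrix `C`
#' (taxa x metabolites; the ENV row is dropped because the environment is not
#' a consumer in the dynamics) and the column-stochastic metabolic matrix `D`
#' (produced x consumed). The last metabolite is the waste metabolite `w`,
#' produced but consumed by no taxon.
#'
#' @slot network the augmented [InteractionNetwork-class] the model derives
#'   from.
#' @slot Me integer matrix over augmented nodes; `Me[i, j]` is the metabolite
#'   carried by edge `i -> j` (0 when no edge).
#' @slot Ms binary array `M x nodes x 2`; slice `"consumption"` and
#'   `"production"`.
#' @slot C numeric matrix `S x M`; consumer preferences (waste column all
#'   zero).
#' @slot D numeric matrix `M x M`; rows = produced, columns = consumed; every
#'   nonzero column sums to 1.
#' @slot metaboliteNames character; `m1 ... m(M-1)` and `"w"`.
#' @aliases CommunityModel
#' @exportClass CommunityModel
setClass("CommunityModel",
  slots = c(network = "InteractionNetwork", Me = "matrix", Ms = "array",
            C = "matrix", D = "matrix", metaboliteNames = "character")
)

setValidity("CommunityModel", function(object) {
  msg <- character()
  M <- length(object@metaboliteNames)
  n <- nrow(object@Me)
  if (!isTRUE(object@network@hasEnv))
    msg <- c(msg, "network must be augmented (hasEnv = TRUE)")
  if (nrow(object@Me) != ncol(object@Me))
    msg <- c(msg, "Me must be square")
  if (!identical(dim(object@Ms), c(M, n, 2L)))
    msg <- c(msg, "Ms must have dimensions M x nodes x 2")
  if (nrow(object@C) != n - 1L || ncol(object@C) != M)
    msg <- c(msg, "C must be (nodes - 1) x M (ENV row dropped)")
  if (nrow(object@D) != M || ncol(object@D) != M)
    msg <- c(msg, "D must be M x M")
  if (any(object@C < 0) || any(object@D < 0))
    msg <- c(msg, "C and D must be nonnegative")
  if (M > 0 && any(object@C[, M] != 0))
    msg <- c(msg, "waste column of C must be all zero")
  cs <- colSums(object@D)
  bad <- cs > 0 & abs(cs - 1) > 1e-8
  if (any(bad))
    msg <- c(msg, "every nonzero column of D must sum to 1")
  if (length(msg)) msg else TRUE
})

#' MicrmParams: parameters of the consumer-resource dynamics
#'
#' Scalar parameters of the microbial consumer-resource model together with
#' supply-mode, uptake-response and integration settings. Defaults follow the
#' reference parameterisation: unit conversion factor and maintenance cost,
#' leakage 0.8, unit energy content, intrinsic equilibrium resource abundance
#' 1000, linear uptake response, constant supply of all non-waste resources.
#'
#' @slot g numeric; conversion factor from energy uptake to growth rate
#'   (1/energy).
#' @slot mc numeric; maintenance cost (energy/time).
#' @slot l numeric in `[0, 1]`; leakage fraction of consumed energy secreted
#'   as byproducts.
#' @slot we numeric; energy content per unit resource (energy/mass).
#' @slot R0 numeric; intrinsic equilibrium resource abundance (mass/volume).
#' @slot tau numeric; supply timescale (time); constant supply is `R0/tau`.
#' @slot response character; `"linear"` or `"hill"` uptake response.
#' @slot sigmaMax,nHill,kHalf numeric; Hill response parameters
#'   `sigma(R) = sigmaMax R^n / (kHalf^n + R^n)`.
#' @slot supplyMode character; `"constant"` supply rate or one-time `"bolus"`.
#' @slot replenishment character; `"constant"` (`kappa = R0/tau`) or
#'   `"logistic"` (`kappa = (R0 - R)/tau`) supply on the supplied set.
#' @slot fr numeric in `[0, 1]`; fraction of non-waste resources supplied.
#' @slot extinctionThreshold numeric; abundances below this are clamped to 0
#'   at integration chunk boundaries.
#' @slot ssTol numeric; steady-state tolerance on relative derivatives.
#' @slot tChunk,tMax numeric; integration chunk length and horizon.
#' @aliases MicrmParams
#' @exportClass MicrmParams
setClass("MicrmParams",
  slots = c(g = "numeric", mc = "numeric", l = "numeric", we = "numeric",
            R0 = "numeric", tau = "numeric", response = "character",
            sigmaMax = "numeric", nHill = "numeric", kHalf = "numeric",
            supplyMode = "character", replenishment = "character",
            fr = "numeric", extinctionThreshold = "numeric",
            ssTol = "numeric", tChunk = "numeric", tMax = "numeric")
)

setValidity("MicrmParams", function(object) {
  msg <- character()
  sc <- c("g", "mc", "l", "we", "R0", "tau", "sigmaMax", "nHill", "kHalf",
          "fr", "extinctionThreshold", "ssTol", "tChunk", "tMax")
  for (s in sc) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v))
      msg <- c(msg, sprintf("'%s' must be a single non-missing number", s))
  }
  if (length(msg)) return(msg)
  if (object@l < 0 || object@l > 1) msg <- c(msg, "l must be in [0, 1]")
  if (object@fr < 0 || object@fr > 1) msg <- c(msg, "fr must be in [0, 1]")
  for (s in c("g", "mc", "we", "R0", "tau", "sigmaMax", "nHill", "kHalf"))
    if (slot(object, s) < 0) msg <- c(msg, sprintf("'%s' must be >= 0", s))
  if (!object@response %in% c("linear", "hill"))
    msg <- c(msg, "response must be 'linear' or 'hill'")
  if (!object@supplyMode %in% c("constant", "bolus"))
    msg <- c(msg, "supplyMode must be 'constant' or 'bolus'")
  if (!object@replenishment %in% c("constant", "logistic"))
    msg <- c(msg, "replenishment must be 'constant' or 'logistic'")
  if (object@tChunk <= 0 || object@tMax <= 0)
    msg <- c(msg, "tChunk and tMax must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct MicrmParams
#'
#' @param g,mc,l,we,R0,tau scalar model parameters (see
#'   [MicrmParams-class]).
#' @param response `"linear"` or `"hill"`.
#' @param sigmaMax,nHill,kHalf Hill-response parameters (used when
#'   `response = "hill"`).
#' @param supplyMode `"constant"` or `"bolus"`.
#' @param replenishment `"constant"` or `"logistic"` form of the supply term.
#' @param fr fraction of non-waste resources supplied.
#' @param extinctionThreshold,ssTol,tChunk,tMax integration controls.
#' @return A [MicrmParams-class] object.
#' @export
#' @examples
#' micrmParams()                      # reference defaults
#' micrmParams(response = "hill", fr = 0.05)
micrmParams <- function(g = 1, mc = 1, l = 0.8, we = 1, R0 = 1000, tau = 1,
                        response = c("linear", "hill"), sigmaMax = 5,
                        nHill = 2, kHalf = 20,
                        supplyMode = c("constant", "bolus"),
                        replenishment = c("constant", "logistic"),
                        fr = 1, extinctionThreshold = 1e-6, ssTol = 1e-6,
                        tChunk = 100, tMax = 1e5) {
  new("MicrmParams", g = g, mc = mc, l = l, we = we, R0 = R0, tau = tau,
      response = match.arg(response), sigmaMax = sigmaMax, nHill = nHill,
      kHalf = kHalf, supplyMode = match.arg(supplyMode),
      replenishment = match.arg(replenishment), fr = fr,
      extinctionThreshold = extinctionThreshold, ssTol = ssTol,
      tChunk = tChunk, tMax = tMax)
}

#' SteadyState: converged community state
#'
#' @slot N numeric; taxon abundances at convergence (mass/volume).
#' @slot R numeric; resource concentrations at convergence.
#' @slot t numeric; integration time reached.
#' @slot converged logical; whether the steady-state criterion was met before
#'   `tMax`.
#' @slot survivors integer; indices of taxa above the extinction threshold.
#' @aliases SteadyState
#' @exportClass SteadyState
setClass("SteadyState",
  slots = c(N = "numeric", R = "numeric", t = "numeric",
            converged = "logical", survivors = "integer")
)

setValidity("SteadyState", function(object) {
  msg <- character()
  if (any(object@N < 0)) msg <- c(msg, "N must be nonnegative")
  if (any(object@R < 0)) msg <- c(msg, "R must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' PerturbationDesign: per-sample environmental perturbations
#'
#' For each of `B` biological samples: the drawn fraction of perturbable
#' resources `fp`, scale factor `ps`, direction (up/down), and the targeted
#' metabolite indices.
#'
#' @slot fp numeric vector length B.
#' @slot ps numeric vector length B; scale factors (>= 1).
#' @slot direction character vector length B; `"up"` or `"down"`.
#' @slot targets list of integer vectors; targeted metabolite indices.
#' @slot mode character; `"constant"` (supply rates scaled) or `"bolus"`
#'   (steady-state concentrations scaled).
#' @slot seed integer or NULL-equivalent numeric; the seed the design was
#'   drawn with (NA when none).
#' @aliases PerturbationDesign
#' @exportClass PerturbationDesign
setClass("PerturbationDesign",
  slots = c(fp = "numeric", ps = "numeric", direction = "character",
            targets = "list", mode = "character", seed = "numeric")
)

setValidity("PerturbationDesign", function(object) {
  msg <- character()
  B <- length(object@fp)
  if (length(object@ps) != B || length(object@direction) != B ||
      length(object@targets) != B)
    msg <- c(msg, "fp, ps, direction and targets must all have length B")
  if (any(object@fp < 0 | object@fp > 1)) msg <- c(msg, "fp must be in [0,1]")
  if (any(object@ps < 1)) msg <- c(msg, "ps must be >= 1")
  if (!all(object@direction %in% c("up", "down")))
    msg <- c(msg, "direction must be 'up' or 'down'")
  if (!object@mode %in% c("constant", "bolus"))
    msg <- c(msg, "mode must be 'constant' or 'bolus'")
  if (length(msg)) msg else TRUE
})

#' SampleAbundances: per-sample steady-state abundances
#'
#' The absolute-abundance matrix `X` (taxa x samples), one column per
#' perturbed re-converged steady state, with per-sample convergence flags and
#' the design that produced them.
#'
#' @slot X numeric matrix S x B; nonnegative.
#' @slot converged logical vector length B.
#' @slot design the [PerturbationDesign-class] used.
#' @aliases SampleAbundances
#' @exportClass SampleAbundances
setClass("SampleAbundances",
  slots = c(X = "matrix", converged = "logical", design = "PerturbationDesign")
)

setValidity("SampleAbundances", function(object) {
  msg <- character()
  if (any(object@X < 0)) msg <- c(msg, "X must be nonnegative")
  if (ncol(object@X) != length(object@converged))
    msg <- c(msg, "one convergence flag per sample required")
  if (length(msg)) msg else TRUE
})

#' CountTable: synthetic 16S count table
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] carrying the integer
#' count assay `"counts"` (taxa x samples), per-sample library sizes in
#' `colData(x)$librarySize`, and simulation provenance in `metadata()`.
#' Column sums of the count assay equal the library sizes exactly, by
#' construction of the without-replacement sequencing model.
#'
#' @aliases CountTable
#' @exportClass CountTable
setClass("CountTable", contains = "SummarizedExperiment")

setValidity("CountTable", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  y <- SummarizedExperiment::assay(object, "counts")
  if (any(y < 0) || any(y != round(y)))
    msg <- c(msg, "counts must be nonnegative integers")
  if (!"librarySize" %in%
      colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain 'librarySize'")
  else if (!isTRUE(all(colSums(y) == object$librarySize)))
    msg <- c(msg, "column sums must equal library sizes")
  if (length(msg)) msg else TRUE
})

#' InferredNetwork: result of a network-inference method
#'
#' A symmetric, binary, zero-diagonal adjacency over taxa, together with the
#' per-pair association statistic and (adjusted) permutation p-values.
#'
#' @slot adjacency integer matrix; symmetric 0/1, zero diagonal.
#' @slot r numeric matrix; association statistic per pair.
#' @slot p numeric matrix; empirical permutation p-values.
#' @slot q numeric matrix; multiplicity-adjusted p-values.
#' @slot meta list; inference settings (transform, permutation scheme,
#'   correction, alpha, seed).
#' @aliases InferredNetwork
#' @exportClass InferredNetwork
setClass("InferredNetwork",
  slots = c(adjacency = "matrix", r = "matrix", p = "matrix", q = "matrix",
            meta = "list")
)

setValidity("InferredNetwork", function(object) {
  A <- object@adjacency
  msg <- character()
  if (nrow(A) != ncol(A)) msg <- c(msg, "adjacency must be square")
  if (!all(A %in% c(0, 1))) msg <- c(msg, "adjacency must be binary")
  if (!identical(A == 1, t(A) == 1)) msg <- c(msg, "adjacency must be symmetric")
  if (nrow(A) > 0 && any(diag(A) != 0)) msg <- c(msg, "diagonal must be zero")
  if (length(msg)) msg else TRUE
})
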