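#' Modified centred log-ratio transform with zero passthrough
#'
#' Divides the nonzero entries of a count vector by the geometric mean of the
#' nonzero entries and passes zeros through unchanged (the classical clr is
#' undefined on the zero-inflated compositions of 16S data). In ratio mode
#' the transformed nonzero entries have unit geometric mean by construction;
#' log mode additionally applies `log` to the transformed nonzero entries
#' (zeros stay 0), which is the form handed to Pearson correlation.
#'
#' @param y nonnegative count vector, not all zero.
#' @param log logical; apply `log` to the transformed nonzero entries.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' clrm(c(2, 8, 0))              # geometric mean of {2, 8} is 4
#' clrm(c(4, 4), log = TRUE)     # (0, 0)
clrm <- function(y, log = FALSE) {
  if (any(y < 0)) stop("counts must be nonnegative")
  nz <- y != 0
  if (!any(nz)) stop("clrm is undefined on an all-zero vector")
  out <- as.numeric(y)
  out[nz] <- y[nz] / .geomean(y[nz])
  if (log) out[nz] <- base::log(out[nz])
  out
}

#' Infer an undirected association network by Pearson + permutation
#'
#' Each sample column is clrm-transformed (log mode by default), pairwise
#' Pearson correlations are computed across samples, and two-sided empirical
#' p-values are obtained by independently shuffling each taxon's values
#' across samples: `p = (1 + #{|r_perm| >= |r_obs|}) / (1 + nPerm)`. Edges
#' passing the multiplicity correction at level `alpha` are kept. Taxa with
#' zero variance get `p = 1` and no edges.
#'
#' @param counts a [CountTable-class] or an integer matrix (taxa x samples).
#' @param nPerm number of permutations (> 0).
#' @param alpha significance level after correction.
#' @param correction a `stats::p.adjust` method (default `"BH"`).
#' @param logMode logical; clrm log mode (default TRUE).
#' @param seed optional integer seed for the permutations.
#' @return An [InferredNetwork-class].
#' @export
#' @examples
#' Y <- matrix(rpois(10 * 20, 50), 10)
#' inferPearsonNetwork(Y, nPerm = 99, seed = 1)
inferPearsonNetwork <- function(counts, nPerm = 1000, alpha = 0.05,
                                correction = "BH", logMode = TRUE,
                                seed = NULL) {
  Y <- if (is(counts, "CountTable"))
    SummarizedExperiment::assay(counts, "counts") else as.matrix(counts)
  S <- nrow(Y)
  B <- ncol(Y)
  if (B < 3) stop("at least 3 samples are required")
  if (nPerm < 1) stop("nPerm must be >= 1 (degenerate null otherwise)")
  .setSeed(seed)
  Z <- apply(Y, 2, clrm, log = logMode)
  Z <- matrix(Z, nrow = S)
  constant <- apply(Z, 1, function(z) stats::var(z) == 0)
  robs <- suppressWarnings(cor(t(Z)))
  robs[is.na(robs)] <- 0
  exceed <- matrix(0, S, S)
  for (b in seq_len(nPerm)) {
    Zp <- t(apply(Z, 1, sample))
    rp <- suppressWarnings(cor(t(Zp)))
    rp[is.na(rp)] <- 0
    exceed <- exceed + (abs(rp) >= abs(robs))
  }
  p <- (1 + exceed) / (1 + nPerm)
  p[constant, ] <- 1
  p[, constant] <- 1
  diag(p) <- 1
  ut <- upper.tri(p)
  q <- p
  q[ut] <- p.adjust(p[ut], method = correction)
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  adjm <- matrix(0L, S, S)
  adjm[q <= alpha] <- 1L
  diag(adjm) <- 0L
  lab <- if (is.null(rownames(Y))) .defaultLabels(S) else rownames(Y)
  dimnames(adjm) <- dimnames(robs) <- dimnames(p) <- dimnames(q) <-
    list(lab, lab)
  new("InferredNetwork", adjacency = adjm, r = robs, p = p, q = q,
      meta = list(method = "pearson-permutation", transform = "clrm",
                  logMode = logMode, nPerm = nPerm, alpha = alpha,
                  correction = correction,
                  permutationScheme = "independent within-taxon shuffles, two-sided",
                  seed = seed))
}

#' Collapse a directed signed network to the undirected truth
#'
#' Inference methods for cross-sectional data can only recover undirected
#' networks: the ground truth is converted by placing an undirected edge
#' `{i, j}` whenever either direction carries a nonzero entry; signs are
#' discarded and the ENV node (if present) is stripped first.
#'
#' @param net an [InteractionNetwork-class].
#' @return Symmetric binary integer matrix over taxa.
#' @export
#' @examples
#' net <- generateNetwork("er", S = 10, p = 0.2, nneg = 0.1, seed = 1)
#' truth <- asUndirectedTruth(net)
asUndirectedTruth <- function(net) {
  stopifnot(is(net, "InteractionNetwork"))
  A <- adjacency(net)
  if (hasEnv(net)) {
    n <- nrow(A)
    A <- A[-n, -n, drop = FALSE]
  }
  U <- (A != 0L) | (t(A) != 0L)
  storage.mode(U) <- "integer"
  U
}

.asBinaryAdjacency <- function(x) {
  if (is(x, "InferredNetwork")) return(x@adjacency)
  if (is(x, "InteractionNetwork")) return(asUndirectedTruth(x))
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  x
}

#' Matthews correlation coefficient for edge recovery
#'
#' Treats edge prediction as binary classification over unordered taxon
#' pairs: `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
#' ranging from -1 to 1 with 0 the expected score of a random classifier.
#' The denominator-zero convention returns 0.
#'
#' @param inferred symmetric binary adjacency (or [InferredNetwork-class]).
#' @param truth symmetric binary adjacency (or [InteractionNetwork-class],
#'   collapsed with [asUndirectedTruth()]).
#' @return MCC in `[-1, 1]`.
#' @export
#' @examples
#' truth <- matrix(0L, 3, 3); truth[1, 2] <- truth[2, 1] <- 1L
#' mcc(truth, truth)   # 1
mcc <- function(inferred, truth) {
  P <- .asBinaryAdjacency(inferred)
  Tm <- .asBinaryAdjacency(truth)
  if (!all(dim(P) == dim(Tm)))
    stop("inferred and truth networks are over different node sets")
  ut <- upper.tri(P)
  p <- P[ut] != 0
  t_ <- Tm[ut] != 0
  mccFromCounts(TP = sum(p & t_), TN = sum(!p & !t_),
                FP = sum(p & !t_), FN = sum(!p & t_))
}

#' @rdname mcc
#' @param TP,TN,FP,FN confusion-matrix counts over unordered pairs.
#' @export
#' @examples
#' mccFromCounts(TP = 4, TN = 90, FP = 3, FN = 3)   # 351/651
mccFromCounts <- function(TP, TN, FP, FN) {
  den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  if (den == 0) return(0)
  (TP * TN - FP * FN) / den
}

#' Topological and structural metrics of an undirected network
#'
#' Computes diameter, radius, mean distance, mean clustering coefficient,
#' degree histogram and betweenness centrality, with the disconnected-graph
#' conventions: the diameter is the maximum diameter over connected
#' components and the radius the minimum radius over components; the radius
#' is `NA` (undefined) when an isolated node exists, and the mean distance
#' `NA` when the graph is disconnected. The mean distance uses the
#' ordered-pair normalisation `sum(d_ij) / (S (S - 1))`; betweenness is the
#' unnormalised sum over unordered pairs excluding the focal node; clustering
#' of nodes with degree < 2 counts as 0.
#'
#' @param graph symmetric binary adjacency (or [InferredNetwork-class] /
#'   [InteractionNetwork-class]).
#' @return A list with `diameter`, `radius`, `meanDistance`,
#'   `meanClustering`, `degree`, `degreeHistogram`, `betweenness`,
#'   `connected` and `undefined` (character vector naming undefined
#'   metrics).
#' @export
#' @examples
#' path <- matrix(0L, 3, 3)
#' path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1L
#' topologyMetrics(path)[c("diameter", "radius", "meanDistance")]
topologyMetrics <- function(graph) {
  A <- .asBinaryAdjacency(graph)
  S <- nrow(A)
  undef <- character()
  if (S == 0) {
    return(list(diameter = NA_real_, radius = NA_real_,
                meanDistance = NA_real_, meanClustering = NA_real_,
                degree = integer(0), degreeHistogram = table(integer(0)),
                betweenness = numeric(0), connected = NA,
                undefined = c("diameter", "radius", "meanDistance",
                              "meanClustering")))
  }
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)
  connected <- comp$no == 1
  isolated <- any(comp$csize == 1)
  dm <- igraph::distances(g)
  finite <- is.finite(dm) & upper.tri(dm)
  # diameter: max over components; radius: min component radius
  diam <- if (any(finite)) max(dm[finite]) else 0
  radius <- NA_real_
  if (isolated) {
    undef <- c(undef, "radius")
  } else {
    radius <- min(vapply(seq_len(comp$no), function(ci) {
      v <- which(comp$membership == ci)
      ecc <- apply(dm[v, v, drop = FALSE], 1, max)
      min(ecc)
    }, numeric(1)))
  }
  if (connected && S > 1) {
    meanDist <- sum(dm[upper.tri(dm)]) * 2 / (S * (S - 1))
  } else {
    meanDist <- NA_real_
    undef <- c(undef, "meanDistance")
  }
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  meanClust <- sum(cc) / S
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  list(diameter = diam, radius = radius, meanDistance = meanDist,
       meanClustering = meanClust, degree = deg,
       degreeHistogram = table(deg), betweenness = btw,
       connected = connected, undefined = undef)
}
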