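#' Assign a metabolite to every edge (metabolite-edge association)
#'
#' Scans taxa `j = 1..S-1` in index order: all positive in-edges of a node
#' share one metabolite (the node's food source), each unseen competitive
#' pair receives its own metabolite, and finally the waste metabolite
#' `w = m + 1` is allocated and stamped on every positive in-edge of ENV.
#' Metabolite indices are allocated in deterministic scan order so the map is
#' bit-reproducible.
#'
#' @param net an augmented [InteractionNetwork-class].
#' @return A list with `M` (total metabolite count, waste included), `Me`
#'   (integer matrix over augmented nodes; `Me[i, j]` is the metabolite on
#'   edge `i -> j`, 0 when absent) and `wasteIndex` (`= M`).
#' @export
#' @examples
#' A <- matrix(0, 3, 3); A[1, 2] <- 1; A[2, 3] <- A[3, 2] <- -1
#' net <- augmentEnvironment(InteractionNetwork(A))
#' assignMetabolitesToEdges(net)$Me
assignMetabolitesToEdges <- function(net) {
  stopifnot(is(net, "InteractionNetwork"))
  if (!hasEnv(net))
    stop("network must be augmented with ENV (see augmentEnvironment())")
  A <- adjacency(net)
  n <- nrow(A)                       # ENV is node n
  Me <- matrix(0L, n, n, dimnames = dimnames(A))
  m <- 0L
  for (j in seq_len(n - 1L)) {
    Ejp <- which(A[, j] > 0)
    if (length(Ejp)) {
      m <- m + 1L
      Me[Ejp, j] <- m
    }
    Ejn <- which(A[, j] < 0)
    for (i in Ejn[Ejn > j]) {        # each pair seen once (i > j guard)
      m <- m + 1L
      Me[i, j] <- m
      Me[j, i] <- m
    }
  }
  ESp <- which(A[, n] > 0)
  w <- m + 1L                        # waste allocated unconditionally
  if (length(ESp)) Me[ESp, n] <- w
  list(M = w, Me = Me, wasteIndex = w)
}

#' Mark consumed and produced metabolites per node
#'
#' For every positive edge `(i, j)` carrying metabolite `m`, the source `i`
#' is marked as a producer of `m` and the target `j` as a consumer; for every
#' competitive edge both endpoints are marked as consumers. Entries are
#' overwrite-idempotent. The waste metabolite ends up consumed only by ENV.
#'
#' @param net an augmented [InteractionNetwork-class].
#' @param edgeMap result of [assignMetabolitesToEdges()] for `net`.
#' @return Binary array `Ms` of dimension `M x nodes x 2` with slices
#'   `"consumption"` and `"production"`.
#' @export
assignMetabolitesToNodes <- function(net, edgeMap) {
  stopifnot(is(net, "InteractionNetwork"))
  A <- adjacency(net)
  Me <- edgeMap$Me
  if (!identical(dim(A), dim(Me)) || !identical(Me != 0L, A != 0L))
    stop("metabolite-edge map does not match the network's edge support")
  n <- nrow(A)
  M <- edgeMap$M
  Ms <- array(0L, dim = c(M, n, 2L),
              dimnames = list(NULL, rownames(A),
                              c("consumption", "production")))
  idx <- which(A != 0L, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    m <- Me[i, j]
    if (A[i, j] > 0L) {              # i produces m, j consumes it
      Ms[m, i, "production"] <- 1L
      Ms[m, j, "consumption"] <- 1L
    } else {                         # competition: both consume m
      Ms[m, i, "consumption"] <- 1L
      Ms[m, j, "consumption"] <- 1L
    }
  }
  Ms
}

#' Specify how to sample quantitative weights for C or D
#'
#' Binary matrices can be given quantitative heterogeneity by sampling the
#' nonzero entries. Zeros are always preserved; draws are strictly positive
#' (normal draws are truncated at 0 by resampling). Dirichlet sampling is
#' applied per nonzero support of each row (C) or column (D).
#'
#' @param distribution `"binary"` (leave as is), `"normal"`, `"gamma"` or
#'   `"dirichlet"`.
#' @param mean,sd normal parameters.
#' @param shape,scale gamma parameters.
#' @param alpha dirichlet concentration (scalar, recycled over the support).
#' @return A list describing the sampling, for [buildCommunityModel()].
#' @export
#' @examples
#' weightSampling("gamma", shape = 2, scale = 0.5)
weightSampling <- function(distribution = c("binary", "normal", "gamma",
                                            "dirichlet"),
                           mean = 1, sd = 0.1, shape = 2, scale = 0.5,
                           alpha = 1) {
  distribution <- match.arg(distribution)
  if (distribution == "normal" && (sd <= 0 || mean <= 0))
    stop("normal sampling requires mean > 0 and sd > 0")
  if (distribution == "gamma" && (shape <= 0 || scale <= 0))
    stop("gamma sampling requires shape > 0 and scale > 0")
  if (distribution == "dirichlet" && alpha <= 0)
    stop("dirichlet sampling requires alpha > 0")
  list(distribution = distribution, mean = mean, sd = sd, shape = shape,
       scale = scale, alpha = alpha)
}

# strictly positive draws for nonzero supports
.sampleSupport <- function(n, spec) {
  switch(spec$distribution,
    normal = {
      x <- rnorm(n, spec$mean, spec$sd)
      while (any(x <= 0)) x[x <= 0] <- rnorm(sum(x <= 0), spec$mean, spec$sd)
      x
    },
    gamma = rgamma(n, shape = spec$shape, scale = spec$scale),
    dirichlet = {
      g <- rgamma(n, shape = spec$alpha, scale = 1)
      g / sum(g)
    })
}

# apply a weightSampling spec along rows (C) or columns (D) of a binary matrix
.applySampling <- function(mat, margin, spec) {
  if (spec$distribution == "binary") return(mat)
  if (margin == 1L) {
    for (i in seq_len(nrow(mat))) {
      s <- which(mat[i, ] > 0)
      if (length(s)) mat[i, s] <- .sampleSupport(length(s), spec)
    }
  } else {
    for (j in seq_len(ncol(mat))) {
      s <- which(mat[, j] > 0)
      if (length(s)) mat[s, j] <- .sampleSupport(length(s), spec)
    }
  }
  mat
}

#' Build the consumer-preference and metabolic matrices
#'
#' Derives `C` (taxa x metabolites; the transpose of the consumption slice of
#' `Ms`, with the ENV row dropped because the environment is not a consumer
#' in the dynamics) and `D` (produced x consumed; `D[beta, alpha] = 1`
#' whenever some taxon consumes `alpha` and produces `beta`; ENV is excluded
#' from the node loop so waste is never recycled). Optional weight sampling
#' is applied to C rows and/or D columns, then every nonzero column of D is
#' normalised to sum 1.
#'
#' @param net an augmented [InteractionNetwork-class].
#' @param cSampling,dSampling [weightSampling()] specs (default binary).
#' @param seed optional integer seed for the weight draws.
#' @return A [CommunityModel-class].
#' @export
#' @examples
#' net <- generateNetwork("er", S = 10, p = 0.2, nneg = 0.1, seed = 1)
#' mod <- buildCommunityModel(net)
#' dim(consumerMatrix(mod))
buildCommunityModel <- function(net, cSampling = weightSampling("binary"),
                                dSampling = weightSampling("binary"),
                                seed = NULL) {
  em <- assignMetabolitesToEdges(net)
  Ms <- assignMetabolitesToNodes(net, em)
  n <- dim(Ms)[2]
  M <- em$M
  .setSeed(seed)
  Msc <- Ms[, , "consumption", drop = FALSE]
  dim(Msc) <- dim(Ms)[1:2]
  Cfull <- t(Msc)
  C <- Cfull[seq_len(n - 1L), , drop = FALSE]                # drop ENV row
  storage.mode(C) <- "double"
  D <- matrix(0, M, M)
  for (i in seq_len(n - 1L)) {                               # ENV excluded
    cons <- which(Ms[, i, "consumption"] == 1L)
    prod <- which(Ms[, i, "production"] == 1L)
    if (length(cons) && length(prod)) D[prod, cons] <- 1
  }
  C <- .applySampling(C, 1L, cSampling)
  D <- .applySampling(D, 2L, dSampling)
  cs <- colSums(D)
  nz <- cs > 0
  D[, nz] <- sweep(D[, nz, drop = FALSE], 2, cs[nz], "/")
  mnames <- c(sprintf("m%d", seq_len(M - 1L)), "w")
  dimnames(C) <- list(taxonNames(net), mnames)
  dimnames(D) <- list(mnames, mnames)
  new(Class = "CommunityModel", network = net, Me = em$Me, Ms = Ms, C = C,
      D = D, metaboliteNames = mnames)
}

#' Reconstruct the interaction network from C and D (inverse map)
#'
#' Correctness oracle for the interpretation pipeline: rebuilds the augmented
#' adjacency from the consumer-preference and metabolic matrices alone.
#' Metabolites consumed by two or more taxa mark their consumers as mutually
#' competitive; a metabolite with a single taxon consumer `j` receives `+1`
#' edges from every taxon whose consumed metabolites map onto it through `D`
#' (competitive pairs keep their `-1`); ENV edges are then rebuilt by the
#' energy-closure rule (taxa producing nothing feed waste to ENV, taxa
#' consuming nothing are supplied by ENV). On disambiguated augmented
#' networks `reconstructNetwork(consumerMatrix(m), metabolicMatrix(m))`
#' equals the original network.
#'
#' @param C consumer-preference matrix (taxa x metabolites).
#' @param D metabolic matrix (produced x consumed).
#' @param labels optional taxon labels (defaults to rownames of `C`).
#' @return The reconstructed augmented [InteractionNetwork-class].
#' @export
#' @examples
#' net <- generateNetwork("er", S = 10, p = 0.2, nneg = 0.1, seed = 1)
#' mod <- buildCommunityModel(net)
#' rec <- reconstructNetwork(consumerMatrix(mod), metabolicMatrix(mod))
#' identical(adjacency(rec), adjacency(net))
reconstructNetwork <- function(C, D, labels = rownames(C)) {
  S <- nrow(C)
  M <- ncol(C)
  if (is.null(labels)) labels <- .defaultLabels(S)
  A <- matrix(0L, S, S, dimnames = list(labels, labels))
  consumed <- lapply(seq_len(S), function(i) which(C[i, ] > 0))
  # competitive pairs: metabolites shared by >= 2 taxa
  comp <- matrix(FALSE, S, S)
  for (a in seq_len(M)) {
    Ta <- which(C[, a] > 0)
    if (length(Ta) >= 2) {
      prs <- utils::combn(Ta, 2)
      comp[cbind(prs[1, ], prs[2, ])] <- TRUE
      comp[cbind(prs[2, ], prs[1, ])] <- TRUE
    }
  }
  # positive edges: uniquely consumed metabolites, producers via D
  for (a in seq_len(M)) {
    Ta <- which(C[, a] > 0)
    if (length(Ta) != 1L) next
    j <- Ta
    prod <- vapply(seq_len(S),
                   function(i) length(consumed[[i]]) > 0 &&
                     any(D[a, consumed[[i]]] > 0),
                   logical(1))
    for (i in setdiff(which(prod), j))
      if (!comp[i, j]) A[i, j] <- 1L
  }
  A[comp] <- -1L
  augmentEnvironment(InteractionNetwork(A))
}
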