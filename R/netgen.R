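#' Generate an Erdos-Renyi random interaction network
#'
#' Every ordered pair of distinct taxa carries a directed edge independently
#' with probability `p`. All edges start with weight `+1`; competitive pairs
#' are assigned afterwards with [assignCompetitions()].
#'
#' @param S integer >= 2; number of taxa.
#' @param p probability in `[0, 1]` of each directed edge.
#' @param seed optional integer seed.
#' @return An [InteractionNetwork-class] with all-positive edges.
#' @export
#' @examples
#' net <- generateERNetwork(20, p = 0.1, seed = 1)
#' sum(adjacency(net) != 0)
generateERNetwork <- function(S, p, seed = NULL) {
  if (!is.numeric(S) || length(S) != 1L || S < 2 || S != round(S))
    stop("'S' must be a single integer >= 2")
  .checkFraction(p, "p")
  .setSeed(seed)
  S <- as.integer(S)
  A <- matrix(rbinom(S * S, 1L, p), S, S)
  diag(A) <- 0L
  InteractionNetwork(A, topologyMeta = list(topology = "er", S = S, p = p,
                                            seed = seed))
}

#' Generate a directed Barabasi-Albert scale-free interaction network
#'
#' Preferential attachment on `k` seed nodes: each new node attaches to `k`
#' distinct existing nodes chosen with probability proportional to their
#' current total degree (uniformly while all degrees are zero). Each
#' attachment is oriented with equal probability 1/3 as an outgoing edge, an
#' ingoing edge, or both (bidirectional). All edges are `+1`.
#'
#' @param S integer; number of taxa.
#' @param k integer >= 1 and < S; number of seed nodes and of attachments per
#'   new node.
#' @param seed optional integer seed.
#' @return An [InteractionNetwork-class] with all-positive edges.
#' @export
#' @examples
#' net <- generateBANetwork(50, k = 3, seed = 1)
generateBANetwork <- function(S, k, seed = NULL) {
  if (!is.numeric(S) || length(S) != 1L || S < 1 || S != round(S))
    stop("'S' must be a single positive integer")
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("'k' must be a single integer >= 1")
  if (k >= S && S != k)
    stop("'k' must be < S")
  if (k > S) stop("'k' must be <= S")
  .setSeed(seed)
  S <- as.integer(S); k <- as.integer(k)
  A <- matrix(0L, S, S)
  deg <- rep(0L, S)  # total (undirected) attachment degree
  if (S > k) {
    for (v in (k + 1L):S) {
      existing <- seq_len(v - 1L)
      w <- deg[existing] + as.integer(all(deg[existing] == 0L))
      targets <- if (length(existing) <= k) existing else
        sample(existing, k, prob = w)
      orient <- sample(c("out", "in", "both"), length(targets),
                       replace = TRUE)
      for (idx in seq_along(targets)) {
        u <- targets[idx]
        if (orient[idx] %in% c("out", "both")) A[v, u] <- 1L
        if (orient[idx] %in% c("in", "both")) A[u, v] <- 1L
        deg[u] <- deg[u] + 1L
        deg[v] <- deg[v] + 1L
      }
    }
  }
  InteractionNetwork(A, topologyMeta = list(topology = "ba", S = S, k = k,
                                            seed = seed))
}

#' Convert a fraction of connected pairs to mutual competition
#'
#' A uniformly chosen fraction `nneg` of connected unordered node pairs is
#' converted to mutual competition: both `A[i, j]` and `A[j, i]` are set to
#' `-1`, overwriting any `+1`. The number of converted pairs is
#' `round(nneg * number of connected pairs)`, sampled without replacement.
#'
#' @param net an [InteractionNetwork-class] without ENV, all edges `+1`.
#' @param nneg fraction in `[0, 1]` of connected pairs made competitive.
#' @param seed optional integer seed.
#' @return The signed [InteractionNetwork-class].
#' @export
#' @examples
#' net <- generateERNetwork(20, 0.2, seed = 1)
#' sgn <- assignCompetitions(net, nneg = 0.1, seed = 2)
#' sum(adjacency(sgn) == -1) / 2   # number of competitive pairs
assignCompetitions <- function(net, nneg, seed = NULL) {
  stopifnot(is(net, "InteractionNetwork"))
  if (hasEnv(net)) stop("assignCompetitions() must run before ENV augmentation")
  .checkFraction(nneg, "nneg")
  A <- adjacency(net)
  if (any(A < 0)) stop("network already carries negative edges")
  .setSeed(seed)
  conn <- which(upper.tri(A) & (A != 0 | t(A) != 0), arr.ind = TRUE)
  nPairs <- nrow(conn)
  nConv <- round(nneg * nPairs)
  if (nConv > 0) {
    pick <- conn[.sampleInt(seq_len(nPairs), nConv), , drop = FALSE]
    A[pick] <- -1L
    A[pick[, c(2, 1), drop = FALSE]] <- -1L
  }
  meta <- net@topologyMeta
  meta$nneg <- nneg
  InteractionNetwork(A, topologyMeta = meta)
}

# positive out-neighbour sets of every node
.posOut <- function(A) lapply(seq_len(nrow(A)), function(i) which(A[i, ] == 1))

#' Remove the consumer-resource interpretation ambiguity
#'
#' When two taxa compete for a metabolite, consuming it lets both produce the
#' same byproducts under a shared metabolic matrix, so distinct networks
#' would map to the same `(C, D)`. The transform forces the two members of
#' every mutual-negative pair to share their positive out-neighbour sets
#' (union), adding `+1` edges where the entry is currently 0 (never toward
#' the pair itself, and never overwriting a `-1`), iterated to a fixed point.
#' After this rewiring the map from the network to `(C, D)` is invertible.
#'
#' @param net a signed [InteractionNetwork-class] without ENV.
#' @return The disambiguated [InteractionNetwork-class].
#' @export
#' @examples
#' A <- matrix(0, 4, 4)
#' A[1, 2] <- A[2, 1] <- -1   # competitors
#' A[1, 3] <- 1; A[2, 4] <- 1
#' adjacency(disambiguateCompetitors(InteractionNetwork(A)))
disambiguateCompetitors <- function(net) {
  stopifnot(is(net, "InteractionNetwork"))
  if (hasEnv(net))
    stop("disambiguateCompetitors() must run before ENV augmentation")
  A <- adjacency(net)
  pairs <- which(upper.tri(A) & A == -1, arr.ind = TRUE)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      out <- union(which(A[i, ] == 1), which(A[j, ] == 1))
      out <- setdiff(out, c(i, j))
      for (p in out) {
        if (A[i, p] == 0L) { A[i, p] <- 1L; changed <- TRUE }
        if (A[j, p] == 0L) { A[j, p] <- 1L; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  InteractionNetwork(A, topologyMeta = net@topologyMeta)
}

#' Append the environment (ENV) node
#'
#' Energy conservation requires every taxon to consume and produce at least
#' one metabolite. ENV is appended as the last node; every taxon with no
#' positive outgoing edge (it produces nothing) gains a `taxon -> ENV` edge,
#' and every taxon with no incoming edge of any sign (it consumes nothing;
#' competitive edges already confer consumption) gains an `ENV -> taxon`
#' edge.
#'
#' @param net a disambiguated signed [InteractionNetwork-class].
#' @return The augmented [InteractionNetwork-class] (`hasEnv = TRUE`).
#' @export
#' @examples
#' A <- matrix(0, 3, 3)
#' A[1, 2] <- 1; A[2, 3] <- A[3, 2] <- -1
#' adjacency(augmentEnvironment(InteractionNetwork(A)))
augmentEnvironment <- function(net) {
  stopifnot(is(net, "InteractionNetwork"))
  if (hasEnv(net)) stop("network is already augmented with ENV")
  A <- adjacency(net)
  S <- nrow(A)
  n <- S + 1L
  Aa <- matrix(0L, n, n)
  Aa[seq_len(S), seq_len(S)] <- A
  lab <- c(rownames(A), "ENV")
  dimnames(Aa) <- list(lab, lab)
  for (i in seq_len(S)) {
    if (!any(A[i, ] == 1L)) Aa[i, n] <- 1L       # produces nothing -> waste
    if (all(A[, i] == 0L)) Aa[n, i] <- 1L        # consumes nothing -> supplied
  }
  InteractionNetwork(Aa, hasEnv = TRUE, topologyMeta = net@topologyMeta)
}

#' Generate a signed, disambiguated, ENV-augmented interaction network
#'
#' One-call pipeline: topology generation (ER or directed BA), competition
#' assignment, disambiguation, ENV augmentation. Stage seeds are derived from
#' the master seed with [stageSeed()].
#'
#' @param topology `"er"` or `"ba"`.
#' @param S number of taxa.
#' @param p ER edge probability (ER only).
#' @param k number of BA seed nodes (BA only).
#' @param nneg fraction of connected pairs made competitive.
#' @param seed master seed.
#' @param augment logical; append ENV (default TRUE).
#' @return An [InteractionNetwork-class].
#' @export
#' @examples
#' net <- generateNetwork("er", S = 25, p = 0.1, nneg = 0.1, seed = 1)
generateNetwork <- function(topology = c("er", "ba"), S, p = NULL, k = NULL,
                            nneg = 0, seed = NULL, augment = TRUE) {
  topology <- match.arg(topology)
  tseed <- if (is.null(seed)) NULL else stageSeed(seed, "topology")
  cseed <- if (is.null(seed)) NULL else stageSeed(seed, "competition")
  net <- switch(topology,
    er = {
      if (is.null(p)) stop("ER topology requires 'p'")
      generateERNetwork(S, p, seed = tseed)
    },
    ba = {
      if (is.null(k)) stop("BA topology requires 'k'")
      generateBANetwork(S, k, seed = tseed)
    })
  net <- assignCompetitions(net, nneg, seed = cseed)
  net <- disambiguateCompetitors(net)
  if (augment) net <- augmentEnvironment(net)
  net
}
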