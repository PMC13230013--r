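# Shared fixtures built in code.

# Three-taxon worked example: t1 -> t2 positive, t2 <-> t3 competitive.
# Hand-traced interpretation: M = 4 with m1 = ENV -> t1 supply, m2 = t1's
# product consumed by t2, m3 = the competition metabolite, w = waste.
w1Network <- function(augmented = TRUE) {
  A <- matrix(0, 3, 3)
  A[1, 2] <- 1
  A[2, 3] <- A[3, 2] <- -1
  net <- InteractionNetwork(A)
  if (augmented) augmentEnvironment(net) else net
}

# Minimal community: one taxon eating one supplied resource, excreting waste.
singleConsumer <- function() {
  C <- matrix(c(1, 0), 1, dimnames = list("t1", c("m1", "w")))
  D <- matrix(0, 2, 2, dimnames = list(c("m1", "w"), c("m1", "w")))
  D[2, 1] <- 1
  list(C = C, D = D)
}

# Random disambiguated augmented network via the exported pipeline.
randomNetwork <- function(seed, S = 15, topology = "er", p = 0.15, k = 3,
                          nneg = 0.1) {
  generateNetwork(topology, S = S, p = p, k = k, nneg = nneg, seed = seed)
}

# Independent all-pairs-shortest-path oracle for topology metrics: distances
# by breadth-first search on the raw adjacency (no graph library), plus
# direct evaluation of the printed metric formulas.
bruteTopology <- function(A) {
  S <- nrow(A)
  dm <- matrix(Inf, S, S)
  diag(dm) <- 0
  for (s in seq_len(S)) {
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) nxt <- union(nxt, which(A[v, ] != 0))
      nxt <- nxt[dm[s, nxt] == Inf & nxt != s]
      dm[s, nxt] <- d
      frontier <- nxt
    }
  }
  comp <- rep(NA_integer_, S)
  ci <- 0
  for (s in seq_len(S)) {
    if (is.na(comp[s])) {
      ci <- ci + 1
      comp[is.finite(dm[s, ])] <- ci
    }
  }
  sizes <- tabulate(comp)
  finite <- is.finite(dm) & row(dm) != col(dm)
  diam <- if (any(finite)) max(dm[finite]) else 0
  radius <- if (any(sizes == 1)) NA_real_ else {
    min(vapply(seq_len(ci), function(cc) {
      v <- which(comp == cc)
      min(apply(dm[v, v, drop = FALSE], 1, max))
    }, numeric(1)))
  }
  meanDist <- if (ci == 1 && S > 1) sum(dm[finite]) / (S * (S - 1)) else
    NA_real_
  # clustering: C(i) = 2 e_i / (deg (deg - 1)), 0 when deg < 2
  cc <- vapply(seq_len(S), function(i) {
    nb <- which(A[i, ] != 0)
    if (length(nb) < 2) return(0)
    e <- sum(A[nb, nb] != 0) / 2
    2 * e / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  # betweenness: count shortest paths sigma(i, j) along increasing distance,
  # then sigma(i, j | z) = sigma(i, z) sigma(z, j) when z lies on a geodesic
  sigma <- matrix(0, S, S)
  for (i in seq_len(S)) for (j in seq_len(S)) {
    if (i == j) { sigma[i, j] <- 1; next }
    if (!is.finite(dm[i, j])) next
    ord <- order(dm[i, ])
    cnt <- rep(0, S); cnt[i] <- 1
    for (v in ord) {
      if (v == i || !is.finite(dm[i, v])) next
      pred <- which(A[, v] != 0 & dm[i, ] == dm[i, v] - 1)
      cnt[v] <- sum(cnt[pred])
    }
    sigma[i, j] <- cnt[j]
  }
  btw <- vapply(seq_len(S), function(z) {
    tot <- 0
    for (i in seq_len(S - 1)) for (j in (i + 1):S) {
      if (i == z || j == z || sigma[i, j] == 0) next
      if (is.finite(dm[i, z]) && is.finite(dm[z, j]) &&
          dm[i, z] + dm[z, j] == dm[i, j])
        tot <- tot + sigma[i, z] * sigma[z, j] / sigma[i, j]
    }
    tot
  }, numeric(1))
  list(diameter = diam, radius = radius, meanDistance = meanDist,
       meanClustering = sum(cc) / S, betweenness = btw,
       degree = rowSums(A != 0), connected = ci == 1)
}

# random symmetric binary adjacency on n nodes with each edge independently
# present with probability pr
randomUndirected <- function(n, pr) {
  A <- matrix(0L, n, n)
  up <- which(upper.tri(A))
  A[up] <- rbinom(length(up), 1L, pr)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  A
}
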