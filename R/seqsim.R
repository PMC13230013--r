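#' Quantise absolute abundances to an integer molecule pool
#'
#' The without-replacement sequencing model draws from a finite integer pool,
#' so each abundance column is scaled by `poolScale` and rounded half-to-even
#' (deterministic across platforms). Zeros stay zero. With
#' `poolScale = "auto"` a single global factor is chosen so that the smallest
#' column total is at least `100 * max(librarySizes)`, approximating the
#' large-pool (multinomial) regime.
#'
#' @param X nonnegative abundance matrix (taxa x samples) or a
#'   [SampleAbundances-class].
#' @param poolScale positive scale factor, or `"auto"`.
#' @param maxLibrary largest library size to be drawn (required for
#'   `"auto"`).
#' @return Integer matrix of the same dimension.
#' @export
#' @examples
#' quantizeAbundances(matrix(c(0.4, 0.6), 2), poolScale = 10)
quantizeAbundances <- function(X, poolScale = 1, maxLibrary = NULL) {
  if (is(X, "SampleAbundances")) X <- abundances(X)
  if (any(X < 0)) stop("abundances must be nonnegative")
  if (identical(poolScale, "auto")) {
    if (is.null(maxLibrary))
      stop("poolScale = 'auto' requires 'maxLibrary'")
    minTot <- min(colSums(X))
    if (minTot <= 0) stop("a sample column is entirely zero")
    poolScale <- 100 * maxLibrary / minTot
  }
  if (!is.numeric(poolScale) || poolScale <= 0)
    stop("'poolScale' must be positive or 'auto'")
  Q <- round(X * poolScale)      # round() is half-to-even in R
  storage.mode(Q) <- "integer"
  Q
}

#' Draw from a multivariate hypergeometric distribution
#'
#' Exact draw via sequential conditional univariate hypergeometric sampling:
#' category `i` is drawn as `Hyper(m_i, sum(m_{i+1..}), remaining draws)`.
#' The output sums to `l` exactly and never exceeds `m` elementwise, so
#' compositionality is enforced and structural zeros are preserved.
#'
#' @param m integer vector; population counts per category.
#' @param l number of draws (`<= sum(m)`).
#' @param seed optional integer seed.
#' @return Integer vector of category counts summing to `l`.
#' @export
#' @examples
#' mvhyperSample(c(50, 30, 20), 10, seed = 1)
mvhyperSample <- function(m, l, seed = NULL) {
  m <- as.numeric(m)
  if (any(m < 0) || any(m != round(m)))
    stop("'m' must be nonnegative integers")
  if (l < 0 || l != round(l)) stop("'l' must be a nonnegative integer")
  total <- sum(m)
  if (total < l)
    stop(sprintf("population size %d is smaller than the %d draws requested",
                 total, l))
  .setSeed(seed)
  K <- length(m)
  out <- numeric(K)
  rem <- total
  left <- l
  for (i in seq_len(K)) {
    if (left == 0) break
    rem <- rem - m[i]
    if (rem == 0) {              # last nonempty tail: take the remainder
      out[i] <- left
      left <- 0
    } else {
      x <- rhyper(1, m[i], rem, left)
      out[i] <- x
      left <- left - x
    }
  }
  as.integer(out)
}

#' Draw per-sample library sizes
#'
#' @param B number of samples.
#' @param spec a list: `list(mode = "constant", value = )`,
#'   `list(mode = "user", values = )` or
#'   `list(mode = "lognormal", meanlog = , sdlog = )`. The default log-normal
#'   (`meanlog = log(5e4)`, `sdlog = 0.3`) emulates the uneven sequencing
#'   depths of real 16S runs.
#' @param seed optional integer seed.
#' @return Integer vector of length `B`, all `>= 1`.
#' @export
#' @examples
#' drawLibrarySizes(5, seed = 1)
drawLibrarySizes <- function(B,
                             spec = list(mode = "lognormal",
                                         meanlog = log(5e4), sdlog = 0.3),
                             seed = NULL) {
  .setSeed(seed)
  l <- switch(spec$mode,
    constant = rep(spec$value, B),
    user = {
      if (length(spec$values) != B)
        stop("user library sizes must have length B")
      spec$values
    },
    lognormal = rlnorm(B,
                       meanlog = if (is.null(spec$meanlog)) log(5e4) else
                         spec$meanlog,
                       sdlog = if (is.null(spec$sdlog)) 0.3 else spec$sdlog),
    stop("unknown library-size mode: ", spec$mode))
  l <- as.integer(pmax(round(l), 1))
  if (any(l < 1)) stop("library sizes must be >= 1")
  l
}

#' Simulate the sequencing of absolute abundances
#'
#' Converts the per-sample absolute abundances into a synthetic 16S count
#' table: each column is quantised to an integer molecule pool and
#' subsampled without replacement to the sample's library size with a
#' multivariate hypergeometric draw. Column sums equal the library sizes
#' exactly, structural zeros are preserved, and only technical zeros can be
#' added.
#'
#' @param X abundance matrix (taxa x samples) or [SampleAbundances-class].
#' @param libSpec library-size specification (see [drawLibrarySizes()]), or
#'   an integer vector of length B.
#' @param poolScale scale for [quantizeAbundances()] (default 1; `"auto"`
#'   available).
#' @param seed master seed; library sizes and draws use stage-derived seeds.
#' @return A [CountTable-class] (a `SummarizedExperiment` with assay
#'   `"counts"` and `colData` column `librarySize`).
#' @export
#' @examples
#' X <- matrix(c(500, 300, 200, 100, 700, 200), 3)
#' simulateCounts(X, libSpec = c(100L, 100L), seed = 1)
simulateCounts <- function(X,
                           libSpec = list(mode = "lognormal",
                                          meanlog = log(5e4), sdlog = 0.3),
                           poolScale = 1, seed = NULL) {
  meta <- list(poolScale = poolScale)
  if (is(X, "SampleAbundances")) {
    meta$design <- X@design
    meta$converged <- X@converged
    X <- abundances(X)
  }
  B <- ncol(X)
  lseed <- if (is.null(seed)) NULL else stageSeed(seed, "libraries")
  qseed <- if (is.null(seed)) NULL else stageSeed(seed, "sequencing")
  l <- if (is.numeric(libSpec)) {
    if (length(libSpec) != B) stop("library sizes must have length B")
    as.integer(libSpec)
  } else {
    drawLibrarySizes(B, libSpec, seed = lseed)
  }
  Q <- quantizeAbundances(X, poolScale, maxLibrary = max(l))
  short <- colSums(Q) < l
  if (any(short))
    stop(sprintf(
      "sample(s) %s have fewer pool molecules than their library size; increase 'poolScale'",
      paste(which(short), collapse = ", ")))
  .setSeed(qseed)
  Y <- vapply(seq_len(B), function(k) mvhyperSample(Q[, k], l[k]),
              integer(nrow(X)))
  Y <- matrix(Y, nrow = nrow(X), ncol = B)
  dimnames(Y) <- list(
    if (is.null(rownames(X))) .defaultLabels(nrow(X)) else rownames(X),
    if (is.null(colnames(X))) sprintf("s%d", seq_len(B)) else colnames(X))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = Y),
    colData = S4Vectors::DataFrame(librarySize = l,
                                   row.names = colnames(Y)),
    metadata = meta)
  new("CountTable", se)
}
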