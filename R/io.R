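#' Read and write adjacency matrices
#'
#' Dense CSV with a header row and a first column of taxon labels, entries in
#' `{-1, 0, 1}`; the environment node is labelled `"ENV"` (last) when
#' present.
#'
#' @param net an [InteractionNetwork-class].
#' @param path file path.
#' @return `writeAdjacency()` returns `path` invisibly; `readAdjacency()`
#'   returns an [InteractionNetwork-class].
#' @export
#' @examples
#' net <- generateNetwork("er", S = 5, p = 0.3, nneg = 0.1, seed = 1)
#' f <- tempfile(fileext = ".csv")
#' writeAdjacency(net, f)
#' identical(adjacency(readAdjacency(f)), adjacency(net))
writeAdjacency <- function(net, path) {
  stopifnot(is(net, "InteractionNetwork"))
  write.csv(as.data.frame(adjacency(net)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname writeAdjacency
#' @export
readAdjacency <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  A <- as.matrix(df)
  hasEnv <- nrow(A) > 0 && rownames(A)[nrow(A)] == "ENV"
  InteractionNetwork(A, hasEnv = hasEnv)
}

#' Write a network as an edge list
#'
#' TSV with columns `source`, `target`, `sign`.
#'
#' @param net an [InteractionNetwork-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(net, path) {
  stopifnot(is(net, "InteractionNetwork"))
  A <- adjacency(net)
  idx <- which(A != 0L, arr.ind = TRUE)
  df <- data.frame(source = rownames(A)[idx[, 1]],
                   target = colnames(A)[idx[, 2]],
                   sign = A[idx])
  df <- df[order(df$source, df$target), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write labelled numeric matrices (C, D, Me, X, counts)
#'
#' Dense CSV with row and column labels; used for the consumer-preference
#' matrix `C` (columns `m1..m(M-1)`, waste `"w"`), the metabolic matrix `D`
#' and the metabolite-edge map `Me`.
#'
#' @param mat labelled matrix.
#' @param path file path.
#' @return `writeMatrixCSV()` returns `path` invisibly; `readMatrixCSV()` the
#'   matrix.
#' @export
writeMatrixCSV <- function(mat, path) {
  write.csv(as.data.frame(mat), path, row.names = TRUE)
  invisible(path)
}

#' @rdname writeMatrixCSV
#' @export
readMatrixCSV <- function(path) {
  as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
}

#' Write a steady state as TSV
#'
#' Taxon table (`taxon`, `Nss`, `survivor`) and, optionally alongside,
#' a resource table (`metabolite`, `Rss`).
#'
#' @param ss a [SteadyState-class].
#' @param path taxon TSV path.
#' @param resourcePath optional resource TSV path.
#' @return `path`, invisibly.
#' @export
writeSteadyState <- function(ss, path, resourcePath = NULL) {
  stopifnot(is(ss, "SteadyState"))
  taxa <- data.frame(
    taxon = if (is.null(names(ss@N))) .defaultLabels(length(ss@N)) else
      names(ss@N),
    Nss = unname(ss@N),
    survivor = seq_along(ss@N) %in% ss@survivors)
  write.table(taxa, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(resourcePath)) {
    res <- data.frame(
      metabolite = if (is.null(names(ss@R))) sprintf("m%d", seq_along(ss@R))
        else names(ss@R),
      Rss = unname(ss@R))
    write.table(res, resourcePath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Write sample abundances with design provenance
#'
#' `X` as a TSV (taxa x samples) plus a metadata sidecar TSV with one row per
#' sample: `sample`, `fp`, `ps`, `direction`, `targets`
#' (comma-separated metabolite indices) and `converged`.
#'
#' @param samples a [SampleAbundances-class].
#' @param path abundance TSV path.
#' @param metaPath sidecar TSV path (default `<path>.design.tsv`).
#' @return `path`, invisibly.
#' @export
writeSampleAbundances <- function(samples, path,
                                  metaPath = paste0(path, ".design.tsv")) {
  stopifnot(is(samples, "SampleAbundances"))
  write.table(abundances(samples), path, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  d <- samples@design
  meta <- data.frame(
    sample = colnames(abundances(samples)),
    fp = d@fp, ps = d@ps, direction = d@direction,
    targets = vapply(d@targets, paste, character(1), collapse = ","),
    converged = samples@converged)
  write.table(meta, metaPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a count table as TSV
#'
#' Taxa as rows, samples as columns, integer cells; a sample-metadata TSV
#' with the library sizes is written alongside.
#'
#' @param counts a [CountTable-class].
#' @param path count TSV path.
#' @param metaPath sample-metadata TSV path (default `<path>.samples.tsv`).
#' @return `writeCountTable()` returns `path` invisibly; `readCountTable()` a
#'   [CountTable-class].
#' @export
#' @examples
#' ct <- simulateCounts(matrix(c(500, 300, 200, 100), 2),
#'                      libSpec = c(50L, 50L), seed = 1)
#' f <- tempfile(fileext = ".tsv")
#' writeCountTable(ct, f)
#' ct2 <- readCountTable(f)
writeCountTable <- function(counts, path,
                            metaPath = paste0(path, ".samples.tsv")) {
  stopifnot(is(counts, "CountTable"))
  Y <- SummarizedExperiment::assay(counts, "counts")
  write.table(Y, path, sep = "\t", quote = FALSE, row.names = TRUE,
              col.names = NA)
  meta <- data.frame(sample = colnames(Y),
                     librarySize = librarySizes(counts))
  write.table(meta, metaPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCountTable
#' @export
readCountTable <- function(path, metaPath = paste0(path, ".samples.tsv")) {
  Y <- as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
  storage.mode(Y) <- "integer"
  l <- if (file.exists(metaPath)) {
    as.integer(read.delim(metaPath)$librarySize)
  } else {
    as.integer(colSums(Y))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = Y),
    colData = S4Vectors::DataFrame(librarySize = l,
                                   row.names = colnames(Y)))
  new("CountTable", se)
}

#' Write an inferred network and its metrics
#'
#' Edge list TSV with `source`, `target`, `r`, `p`, `q` for retained edges,
#' and a key-value metrics file.
#'
#' @param inferred an [InferredNetwork-class].
#' @param path edge-list TSV path.
#' @return `path`, invisibly.
#' @export
writeInferredNetwork <- function(inferred, path) {
  stopifnot(is(inferred, "InferredNetwork"))
  A <- inferred@adjacency
  idx <- which(upper.tri(A) & A == 1L, arr.ind = TRUE)
  df <- data.frame(source = rownames(A)[idx[, 1]],
                   target = colnames(A)[idx[, 2]],
                   r = inferred@r[idx], p = inferred@p[idx],
                   q = inferred@q[idx])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write topology metrics as a key-value file
#'
#' Scalar metrics one per line as `key<TAB>value` (undefined metrics as
#' `NA`); degree histogram and betweenness written to sibling TSVs.
#'
#' @param metrics result of [topologyMetrics()].
#' @param path key-value file path.
#' @return `path`, invisibly.
#' @export
writeTopologyReport <- function(metrics, path) {
  kv <- data.frame(
    key = c("diameter", "radius", "mean_distance", "mean_clustering",
            "connected"),
    value = c(metrics$diameter, metrics$radius, metrics$meanDistance,
              metrics$meanClustering, as.numeric(metrics$connected)))
  write.table(kv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  dh <- as.data.frame(metrics$degreeHistogram)
  names(dh) <- c("degree", "count")
  write.table(dh, paste0(path, ".degree.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  bt <- data.frame(node = names(metrics$betweenness),
                   betweenness = unname(metrics$betweenness))
  write.table(bt, paste0(path, ".betweenness.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
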