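#' @name micnetsim-accessors
#' @title Accessors for micnetsim classes
#' @description Accessor generics for the core classes: `adjacency()` returns
#' the signed adjacency matrix, `nTaxa()` the number of taxa (ENV excluded),
#' `hasEnv()` whether the environment node is present, `taxonNames()` the
#' taxon labels, `consumerMatrix()` / `metabolicMatrix()` the `C` and `D`
#' matrices, `metaboliteEdgeMap()` the `Me` matrix, `nMetabolites()` /
#' `wasteIndex()` the metabolite count `M` and the waste index (always `M`),
#' `abundances()` the abundance vector/matrix, and `librarySizes()` the
#' per-sample sequencing depths.
#' @param x an object of the documented classes.
#' @return See each method's description.
NULL

#' @rdname micnetsim-accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @rdname micnetsim-accessors
#' @export
setGeneric("nTaxa", function(x) standardGeneric("nTaxa"))
#' @rdname micnetsim-accessors
#' @export
setGeneric("hasEnv", function(x) standardGeneric("hasEnv"))
#' @rdname micnetsim-accessors
#' @export
setGeneric("taxonNames", function(x) standardGeneric("taxonNames"))
#' @rdname micnetsim-accessors
#' @export
setGeneric("consumerMatrix", function(x) standardGeneric("consumerMatrix"))
#' @rdname micnetsim-accessors
#' @export
setGeneric("metabolicMatrix", function(x) standardGeneric("metabolicMatrix"))
#' @rdname micnetsim-accessors
#' @export
setGeneric("metaboliteEdgeMap",
           function(x) standardGeneric("metaboliteEdgeMap"))
#' @rdname micnetsim-accessors
#' @export
setGeneric("nMetabolites", function(x) standardGeneric("nMetabolites"))
#' @rdname micnetsim-accessors
#' @export
setGeneric("wasteIndex", function(x) standardGeneric("wasteIndex"))
#' @rdname micnetsim-accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
#' @rdname micnetsim-accessors
#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))
#' @rdname micnetsim-accessors
#' @export
setGeneric("survivors", function(x) standardGeneric("survivors"))

#' @rdname micnetsim-accessors
#' @aliases adjacency,InteractionNetwork-method
setMethod("adjacency", "InteractionNetwork", function(x) x@A)
#' @rdname micnetsim-accessors
setMethod("adjacency", "InferredNetwork", function(x) x@adjacency)
#' @rdname micnetsim-accessors
setMethod("nTaxa", "InteractionNetwork",
          function(x) nrow(x@A) - as.integer(x@hasEnv))
#' @rdname micnetsim-accessors
setMethod("nTaxa", "CommunityModel", function(x) nrow(x@C))
#' @rdname micnetsim-accessors
setMethod("hasEnv", "InteractionNetwork", function(x) x@hasEnv)
#' @rdname micnetsim-accessors
setMethod("taxonNames", "InteractionNetwork", function(x) {
  lab <- rownames(x@A)
  if (x@hasEnv) lab[-length(lab)] else lab
})
#' @rdname micnetsim-accessors
setMethod("taxonNames", "CommunityModel",
          function(x) taxonNames(x@network))
#' @rdname micnetsim-accessors
setMethod("consumerMatrix", "CommunityModel", function(x) x@C)
#' @rdname micnetsim-accessors
setMethod("metabolicMatrix", "CommunityModel", function(x) x@D)
#' @rdname micnetsim-accessors
setMethod("metaboliteEdgeMap", "CommunityModel", function(x) x@Me)
#' @rdname micnetsim-accessors
setMethod("nMetabolites", "CommunityModel",
          function(x) length(x@metaboliteNames))
#' @rdname micnetsim-accessors
setMethod("wasteIndex", "CommunityModel",
          function(x) length(x@metaboliteNames))
#' @rdname micnetsim-accessors
setMethod("abundances", "SteadyState", function(x) x@N)
#' @rdname micnetsim-accessors
setMethod("abundances", "SampleAbundances", function(x) x@X)
#' @rdname micnetsim-accessors
setMethod("survivors", "SteadyState", function(x) x@survivors)
#' @rdname micnetsim-accessors
setMethod("librarySizes", "CountTable", function(x) x$librarySize)

#' @describeIn InteractionNetwork-class compact display.
#' @param object an object of the class.
setMethod("show", "InteractionNetwork", function(object) {
  A <- object@A
  np <- sum(A == 1)
  nn <- sum(A == -1) / 2
  cat(sprintf(
    "InteractionNetwork: %d taxa%s, %d positive edge(s), %d competitive pair(s)\n",
    nTaxa(object), if (object@hasEnv) " + ENV" else "", np, nn))
  if (length(object@topologyMeta))
    cat("  topology:", paste(names(object@topologyMeta),
        vapply(object@topologyMeta, function(v) paste(format(v), collapse = ","),
               character(1)), sep = "=", collapse = " "), "\n")
})

#' @describeIn CommunityModel-class compact display.
#' @param object an object of the class.
setMethod("show", "CommunityModel", function(object) {
  cat(sprintf(
    "CommunityModel: %d taxa, %d metabolites (waste = m%d 'w')\n",
    nTaxa(object), nMetabolites(object), wasteIndex(object)))
  cat(sprintf("  C: %d x %d (%d nonzero), D: %d x %d (%d nonzero)\n",
              nrow(object@C), ncol(object@C), sum(object@C > 0),
              nrow(object@D), ncol(object@D), sum(object@D > 0)))
})

#' @describeIn SteadyState-class compact display.
#' @param object an object of the class.
setMethod("show", "SteadyState", function(object) {
  cat(sprintf(
    "SteadyState: %d/%d taxa surviving at t = %g (%s)\n",
    length(object@survivors), length(object@N), object@t,
    if (object@converged) "converged" else "NOT converged"))
})

#' @describeIn PerturbationDesign-class compact display.
#' @param object an object of the class.
setMethod("show", "PerturbationDesign", function(object) {
  cat(sprintf(
    "PerturbationDesign: %d samples, mode '%s', %d..%d targets per sample\n",
    length(object@fp), object@mode,
    if (length(object@targets)) min(lengths(object@targets)) else 0L,
    if (length(object@targets)) max(lengths(object@targets)) else 0L))
})

#' @describeIn SampleAbundances-class compact display.
#' @param object an object of the class.
setMethod("show", "SampleAbundances", function(object) {
  cat(sprintf(
    "SampleAbundances: %d taxa x %d samples (%d converged)\n",
    nrow(object@X), ncol(object@X), sum(object@converged)))
})

#' @describeIn InferredNetwork-class compact display.
#' @param object an object of the class.
setMethod("show", "InferredNetwork", function(object) {
  cat(sprintf("InferredNetwork: %d taxa, %d edge(s)\n",
              nrow(object@adjacency), sum(object@adjacency) / 2))
})
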