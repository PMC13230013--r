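.defaultConfig <- function() {
  list(
    network = list(topology = "er", S = 50, p = 0.1, k = 3, nneg = 0.1,
                   adjacencyFile = NULL),
    weights = list(C = list(distribution = "binary"),
                   D = list(distribution = "binary")),
    micrm = list(),                       # overrides for micrmParams()
    init = list(type = "lognormal", meanlog = 0, sdlog = 2),
    perturbation = list(B = 30, fp = c(0, 1), ps = c(2, 10)),
    sequencing = list(librarySize = list(mode = "lognormal",
                                         meanlog = log(5e4), sdlog = 0.3),
                      poolScale = "auto"),
    benchmark = list(enabled = FALSE, nPerm = 1000, alpha = 0.05,
                     correction = "BH", logMode = TRUE)
  )
}

.mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Load a pipeline configuration
#'
#' Reads a YAML file (or takes a nested list) and merges it over the
#' defaults: `network` (topology, S, p, k, nneg, or `adjacencyFile` for a
#' user network), `weights` (C/D sampling), `micrm` (any [micrmParams()]
#' argument), `init`, `perturbation` (B, fp, ps), `sequencing` (librarySize
#' spec, poolScale) and `benchmark` (enabled, nPerm, alpha, correction).
#'
#' @param config path to a YAML file, or a nested list (possibly partial).
#' @return The merged configuration list.
#' @export
#' @examples
#' cfg <- pipelineConfig(list(network = list(S = 10, p = 0.3)))
#' cfg$network$S
pipelineConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  .mergeConfig(.defaultConfig(), config)
}

.asSamplingSpec <- function(x) {
  do.call(weightSampling, c(list(distribution = x$distribution),
                            x[setdiff(names(x), "distribution")]))
}

#' Run the full simulation pipeline
#'
#' One-command orchestration of the stages: network generation (or a
#' user-supplied adjacency), competition assignment, disambiguation, ENV
#' augmentation, consumer/metabolic-matrix construction, integration to the
#' reference steady state, perturbation-driven sample generation, sequencing
#' simulation, and (optionally) Pearson-permutation inference scored against
#' the ground truth. Every output is reproducible from the configuration and
#' the master seed; all artefacts plus the resolved configuration are
#' written to `outdir` when given.
#'
#' @param config configuration (list or YAML path; see [pipelineConfig()]).
#' @param seed master seed; per-stage seeds derive from it via [stageSeed()].
#' @param outdir optional output directory (created if needed).
#' @param verbose logical; per-stage log lines with wall times.
#' @return A list with `network`, `model`, `steadyState`, `supply`,
#'   `samples`, `counts`, and (when enabled) `inference` with the inferred
#'   network, MCC and topology reports.
#' @export
#' @examples
#' res <- runPipeline(list(network = list(S = 10, p = 0.2),
#'                         perturbation = list(B = 4),
#'                         sequencing = list(librarySize =
#'                           list(mode = "constant", value = 1000))),
#'                    seed = 1)
#' dim(SummarizedExperiment::assay(res$counts))
runPipeline <- function(config = list(), seed = 1, outdir = NULL,
                        verbose = FALSE) {
  cfg <- pipelineConfig(config)
  t0 <- proc.time()[3]
  stage <- function(msg) {
    if (verbose)
      message(sprintf("[%.1fs] %s", proc.time()[3] - t0, msg))
  }
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  outfile <- function(f) file.path(outdir, f)

  # ---- network -----------------------------------------------------------
  nc <- cfg$network
  if (!is.null(nc$adjacencyFile)) {
    raw <- readAdjacency(nc$adjacencyFile)
    if (hasEnv(raw)) stop("stage network: user adjacency must not contain ENV")
    net <- augmentEnvironment(disambiguateCompetitors(raw))
  } else {
    net <- tryCatch(
      generateNetwork(nc$topology, S = nc$S, p = nc$p, k = nc$k,
                      nneg = nc$nneg, seed = seed),
      error = function(e) stop("stage network: ", conditionMessage(e),
                               call. = FALSE))
  }
  stage(sprintf("network: %d taxa, %d edges", nTaxa(net),
                sum(adjacency(net) != 0)))

  # ---- interpretation ----------------------------------------------------
  model <- buildCommunityModel(
    net,
    cSampling = .asSamplingSpec(cfg$weights$C),
    dSampling = .asSamplingSpec(cfg$weights$D),
    seed = stageSeed(seed, "weights"))
  stage(sprintf("interpretation: M = %d metabolites", nMetabolites(model)))

  # ---- dynamics ----------------------------------------------------------
  params <- do.call(micrmParams, cfg$micrm)
  sim <- simulateCommunity(model, params, init = cfg$init, seed = seed)
  ss <- sim$steadyState
  if (!ss@converged)
    warning("reference steady state did not converge within tMax")
  stage(sprintf("steady state: %d/%d survivors at t = %g (converged: %s)",
                length(ss@survivors), nTaxa(net), ss@t, ss@converged))

  # ---- samples -----------------------------------------------------------
  pc <- cfg$perturbation
  perturbable <- if (params@supplyMode == "constant")
    which(sim$supply$rates > 0) else which(ss@R > 0)
  design <- designPerturbations(perturbable, B = pc$B, fp = pc$fp,
                                ps = pc$ps, mode = params@supplyMode,
                                seed = stageSeed(seed, "perturbation"))
  samples <- generateSamples(ss, design, model, params, sim$supply)
  stage(sprintf("samples: %d columns (%d converged)",
                ncol(abundances(samples)), sum(samples@converged)))

  # ---- sequencing --------------------------------------------------------
  sq <- cfg$sequencing
  counts <- simulateCounts(samples, libSpec = sq$librarySize,
                           poolScale = sq$poolScale, seed = seed)
  stage("sequencing: count table simulated")

  # ---- benchmark (optional) ---------------------------------------------
  inference <- NULL
  bc <- cfg$benchmark
  if (isTRUE(bc$enabled)) {
    inferred <- inferPearsonNetwork(counts, nPerm = bc$nPerm,
                                    alpha = bc$alpha,
                                    correction = bc$correction,
                                    logMode = isTRUE(bc$logMode),
                                    seed = stageSeed(seed, "inference"))
    truth <- asUndirectedTruth(net)
    inference <- list(inferred = inferred,
                      mcc = mcc(inferred, truth),
                      truthMetrics = topologyMetrics(truth),
                      inferredMetrics = topologyMetrics(inferred))
    stage(sprintf("benchmark: MCC = %.3f", inference$mcc))
  }

  # ---- artefacts ---------------------------------------------------------
  if (!is.null(outdir)) {
    Ataxa <- adjacency(net)
    n <- nrow(Ataxa)
    taxaNet <- InteractionNetwork(Ataxa[-n, -n, drop = FALSE])
    writeAdjacency(taxaNet, outfile("adjacency_taxa.csv"))
    writeAdjacency(net, outfile("adjacency_augmented.csv"))
    writeEdgeList(net, outfile("edges.tsv"))
    writeMatrixCSV(consumerMatrix(model), outfile("C.csv"))
    writeMatrixCSV(metabolicMatrix(model), outfile("D.csv"))
    writeMatrixCSV(metaboliteEdgeMap(model), outfile("Me.csv"))
    writeSteadyState(ss, outfile("steady_state.tsv"),
                     outfile("steady_state_resources.tsv"))
    writeSampleAbundances(samples, outfile("X.tsv"))
    writeCountTable(counts, outfile("counts.tsv"))
    if (!is.null(inference)) {
      writeInferredNetwork(inference$inferred,
                           outfile("inferred_edges.tsv"))
      writeTopologyReport(inference$inferredMetrics,
                          outfile("metrics_inferred.tsv"))
      writeTopologyReport(inference$truthMetrics,
                          outfile("metrics_truth.tsv"))
      cat(sprintf("mcc\t%.6f\n", inference$mcc),
          file = outfile("mcc.tsv"))
    }
    provenance <- cfg
    provenance$seed <- seed
    yaml::write_yaml(provenance, outfile("config.yaml"))
  }
  stage("done")
  invisible(list(network = net, model = model, steadyState = ss,
                 supply = sim$supply, samples = samples, counts = counts,
                 inference = inference, config = cfg, seed = seed))
}
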