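#' @import methods
#' @importFrom stats cor p.adjust rhyper rlnorm rnorm rgamma runif rbinom
#' @importFrom utils read.csv write.csv read.delim write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame metadata
NULL

# Hierarchical RNG: every pipeline stage draws from its own stream derived
# from the master seed, so a stage is reproducible in isolation.
.STAGE_OFFSETS <- c(
  topology     = 104729L,
  competition  = 224737L,
  weights      = 350377L,
  supply       = 479909L,
  init         = 611953L,
  perturbation = 746773L,
  libraries    = 882377L,
  sequencing   = 1020379L,
  inference    = 1159523L
)

#' Derive a stage-specific seed from a master seed
#'
#' Each simulation stage (topology generation, competition assignment, weight
#' sampling, supply choice, community initialisation, perturbation design,
#' library sizes, sequencing, inference) uses an independent seed derived
#' deterministically from the master seed, so that re-running a single stage
#' with the same master seed reproduces exactly the same draws.
#'
#' @param seed integer master seed.
#' @param stage character; one of the stage names used by [runPipeline()].
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' stageSeed(1, "topology")
stageSeed <- function(seed, stage) {
  stage <- match.arg(stage, names(.STAGE_OFFSETS))
  s <- (as.double(seed) %% 2147483647) * 48271 + .STAGE_OFFSETS[[stage]]
  as.integer(s %% 2147483646) + 1L
}

.setSeed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

.checkFraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single number in [0, 1]", name), call. = FALSE)
  x
}

# geometric mean of a strictly positive vector
.geomean <- function(x) exp(mean(log(x)))

# sample skewness (method-of-moments)
.skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}

# sample() without the length-1 surprise
.sampleInt <- function(x, size) {
  if (length(x) == 1L) return(rep(x, length.out = size))
  sample(x, size)
}

.defaultLabels <- function(S) sprintf("t%d", seq_len(S))
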