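#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowData colData assay<-
NULL

#' Simulation configuration
#'
#' Parameters for the synthetic-data generator. Defaults emulate the
#' Stage-58 lower-jaw design: two conditions (normal, deformed) with four
#' replicate pools each, ten exogenous spike-in controls, two 60mer probes
#' per transcript, log-normal intensities with per-array monotone (affine
#' on the log2 scale) distortions, and a planted set of transcripts
#' down-regulated in the deformed condition.
#'
#' @slot seed integer RNG seed; identical configurations give
#'   byte-identical outputs.
#' @slot nTranscripts number of unique transcripts in the catalogue.
#' @slot nAntisensePairs number of planted sense/antisense transcript
#'   pairs (each pair shares one reference-species locus, hit on opposite
#'   strands).
#' @slot nSpikeins number of spike-in control species at fixed,
#'   condition-independent concentrations.
#' @slot conditions data.frame with columns `name` and `n_replicates`.
#' @slot nDeGenes number of transcripts with a planted expression shift.
#' @slot deLog2fcRange length-2 numeric, log2 fold-change range for
#'   planted effects (negative = down in the second condition).
#' @slot intensityLocation,intensityScale mean and sd of transcript
#'   baseline expression on the log2 scale.
#' @slot probeNoiseSd sd of independent probe-level noise (log2 scale).
#' @slot flagMissingnessRate probability that a spot's detection flag is
#'   set to 0 for technical reasons, independent of condition.
#' @slot arrayDistortion strength of per-array affine distortion on the
#'   log2 scale (0 = none).
#' @slot senseAntisenseRatio linear-scale expression ratio applied to
#'   planted sense members over their antisense partners.
#' @export
setClass("SimulationConfig",
  representation(
    seed = "integer",
    nTranscripts = "integer",
    nAntisensePairs = "integer",
    nSpikeins = "integer",
    conditions = "data.frame",
    nDeGenes = "integer",
    deLog2fcRange = "numeric",
    intensityLocation = "numeric",
    intensityScale = "numeric",
    probeNoiseSd = "numeric",
    flagMissingnessRate = "numeric",
    arrayDistortion = "numeric",
    senseAntisenseRatio = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (length(object@seed) != 1L) msg <- c(msg, "seed must be a single integer")
  if (object@nTranscripts < 1L) msg <- c(msg, "nTranscripts must be >= 1")
  if (object@nDeGenes > object@nTranscripts)
    msg <- c(msg, "nDeGenes must not exceed nTranscripts")
  if (2L * object@nAntisensePairs > object@nTranscripts)
    msg <- c(msg, "antisense pairs need 2 transcripts each")
  if (object@flagMissingnessRate < 0 || object@flagMissingnessRate > 1)
    msg <- c(msg, "flagMissingnessRate must lie in [0, 1]")
  if (!all(c("name", "n_replicates") %in% names(object@conditions)))
    msg <- c(msg, "conditions needs columns 'name' and 'n_replicates'")
  if (length(object@deLog2fcRange) != 2L)
    msg <- c(msg, "deLog2fcRange must have length 2")
  if (object@senseAntisenseRatio <= 0)
    msg <- c(msg, "senseAntisenseRatio must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a [SimulationConfig-class]
#'
#' @param seed integer RNG seed.
#' @param nTranscripts,nAntisensePairs,nSpikeins,nDeGenes counts; see the
#'   class documentation.
#' @param conditions data.frame of condition names and replicate counts;
#'   the default is the Stage-58 design (4 normal, 4 deformed pools).
#' @param deLog2fcRange planted log2 fold-change range; the default plants
#'   down-regulation, as observed for the deformed mandible.
#' @param intensityLocation,intensityScale,probeNoiseSd log2-scale
#'   intensity model parameters.
#' @param flagMissingnessRate technical flag drop-out probability.
#' @param arrayDistortion per-array affine log-scale distortion strength.
#' @param senseAntisenseRatio sense:antisense expression ratio for planted
#'   pairs.
#' @return a validated `SimulationConfig`.
#' @examples
#' cfg <- SimulationConfig(seed = 1, nTranscripts = 50)
#' @export
SimulationConfig <- function(seed = 1L,
                             nTranscripts = 200L,
                             nAntisensePairs = 10L,
                             nSpikeins = 10L,
                             conditions = data.frame(
                               name = c("normal", "deformed"),
                               n_replicates = c(4L, 4L)
                             ),
                             nDeGenes = 20L,
                             deLog2fcRange = c(-4, -1),
                             intensityLocation = 10,
                             intensityScale = 1.5,
                             probeNoiseSd = 0.25,
                             flagMissingnessRate = 0.02,
                             arrayDistortion = 0.3,
                             senseAntisenseRatio = 5) {
  new("SimulationConfig",
    seed = as.integer(seed),
    nTranscripts = as.integer(nTranscripts),
    nAntisensePairs = as.integer(nAntisensePairs),
    nSpikeins = as.integer(nSpikeins),
    conditions = conditions,
    nDeGenes = as.integer(nDeGenes),
    deLog2fcRange = as.numeric(deLog2fcRange),
    intensityLocation = as.numeric(intensityLocation),
    intensityScale = as.numeric(intensityScale),
    probeNoiseSd = as.numeric(probeNoiseSd),
    flagMissingnessRate = as.numeric(flagMissingnessRate),
    arrayDistortion = as.numeric(arrayDistortion),
    senseAntisenseRatio = as.numeric(senseAntisenseRatio)
  )
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat("  seed:", object@seed, "\n")
  cat("  transcripts:", object@nTranscripts,
      "(", object@nAntisensePairs, "antisense pairs,",
      object@nDeGenes, "DE )\n")
  cat("  conditions:",
      paste(sprintf("%s x%d", object@conditions$name,
                    object@conditions$n_replicates), collapse = ", "), "\n")
  cat("  spike-ins:", object@nSpikeins,
      " missingness:", object@flagMissingnessRate, "\n")
})

#' Ground truth of a simulation
#'
#' Records what the generator planted so downstream modules can be scored
#' against it: planted differential-expression effects, sense/antisense
#' pair memberships, cluster memberships of simulated ESTs, and planted
#' qPCR amplification efficiencies.
#'
#' @slot deTranscripts data.frame (`transcript_id`, `log2fc`).
#' @slot antisensePairs data.frame (`sense_id`, `antisense_id`,
#'   `subject_id`).
#' @slot clusterMembership data.frame (`est_id`, `transcript_id`); empty
#'   until ESTs are simulated.
#' @slot qpcrEfficiencies named numeric of planted per-assay amplification
#'   factors; empty until qPCR data are simulated.
#' @export
setClass("GroundTruth",
  representation(
    deTranscripts = "data.frame",
    antisensePairs = "data.frame",
    clusterMembership = "data.frame",
    qpcrEfficiencies = "numeric"
  ),
  prototype(
    deTranscripts = data.frame(transcript_id = character(), log2fc = numeric()),
    antisensePairs = data.frame(sense_id = character(),
                                antisense_id = character(),
                                subject_id = character()),
    clusterMembership = data.frame(est_id = character(),
                                   transcript_id = character()),
    qpcrEfficiencies = numeric()
  )
)

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:",
      nrow(object@deTranscripts), "DE transcripts,",
      nrow(object@antisensePairs), "antisense pairs,",
      nrow(object@clusterMembership), "EST memberships,",
      length(object@qpcrEfficiencies), "qPCR assays\n")
})

#' Probe-level expression dataset
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment]
#' with two assays: `intensities` (positive, linear-scale one-colour
#' signals) and `flags` (binary detection flags; 1 means the spot
#' intensity differed significantly from the local background, 0 is
#' treated as a missing value). `rowData` carries `probe_id`,
#' `transcript_id`, `probe_index` and `is_spike`; `colData` carries
#' `stage`, `condition` and `replicate`.
#'
#' @export
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
  msg <- character()
  an <- names(assays(object))
  if (!all(c("intensities", "flags") %in% an))
    return("assays 'intensities' and 'flags' are required")
  fl <- assay(object, "flags")
  if (!all(fl %in% c(0, 1)))
    msg <- c(msg, "flags must be binary")
  x <- assay(object, "intensities")
  if (any(x[fl == 1] <= 0))
    msg <- c(msg, "intensities must be positive where flag = 1")
  rd <- rowData(object)
  need <- c("probe_id", "transcript_id", "probe_index", "is_spike")
  if (!all(need %in% names(rd)))
    msg <- c(msg, paste("rowData needs columns:", paste(need, collapse = ", ")))
  cd <- colData(object)
  if (!all(c("stage", "condition", "replicate") %in% names(cd)))
    msg <- c(msg, "colData needs stage, condition, replicate")
  if (length(msg)) msg else TRUE
})

#' Construct an [ExpressionDataset-class]
#'
#' @param intensities probes x samples numeric matrix, positive linear
#'   scale.
#' @param flags binary matrix of the same shape; 0 marks a missing value.
#' @param probeData data.frame/DataFrame with `probe_id`, `transcript_id`,
#'   `probe_index`, `is_spike` (one row per probe).
#' @param sampleData data.frame/DataFrame with `stage`, `condition`,
#'   `replicate` (one row per sample).
#' @return an `ExpressionDataset`.
#' @export
ExpressionDataset <- function(intensities, flags, probeData, sampleData) {
  se <- SummarizedExperiment(
    assays = SimpleList(intensities = as.matrix(intensities),
                        flags = as.matrix(flags)),
    rowData = DataFrame(probeData),
    colData = DataFrame(sampleData)
  )
  rownames(se) <- probeData$probe_id
  new("ExpressionDataset", se)
}

#' Result of a two-class SAM analysis
#'
#' @slot probes per-probe table: group means (log2), `d` statistic, linear
#'   fold-change `ratio_fc` and `signed_fc`, `q_value` (percent) and
#'   `significant` flag.
#' @slot transcripts transcript-level aggregation of significant probes.
#' @slot delta tuned threshold on the deviation from the
#'   permutation-expected order statistics.
#' @slot s0 exchangeability (fudge) factor added to each probe's standard
#'   error.
#' @slot fdr estimated false discovery rate at `delta` (fraction).
#' @slot pi0 estimated proportion of non-differential probes.
#' @slot nPermutations number of label permutations used.
#' @slot dbar permutation-expected order statistics, aligned with sorted
#'   observed `d`.
#' @export
setClass("SamResult",
  representation(
    probes = "data.frame",
    transcripts = "data.frame",
    delta = "numeric",
    s0 = "numeric",
    fdr = "numeric",
    pi0 = "numeric",
    nPermutations = "integer",
    dbar = "numeric"
  )
)

setMethod("show", "SamResult", function(object) {
  cat("SamResult:", nrow(object@probes), "probes tested,",
      sum(object@probes$significant), "significant at delta =",
      signif(object@delta, 4), "\n")
  cat("  s0 =", signif(object@s0, 4),
      " pi0 =", signif(object@pi0, 4),
      " estimated FDR =", signif(object@fdr, 4),
      " (", object@nPermutations, "permutations )\n")
})

setMethod("show", "ExpressionDataset", function(object) {
  callNextMethod()
  cat("spike-in probes:", sum(rowData(object)$is_spike), "\n")
})
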