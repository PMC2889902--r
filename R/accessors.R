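# Accessor generics and methods for the core containers.

#' @rdname ExpressionDataset-class
#' @param object an object.
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname ExpressionDataset-class
#' @export
setMethod("intensities", "ExpressionDataset", function(object)
  assay(object, "intensities"))

#' @rdname ExpressionDataset-class
#' @export
setGeneric("detectionFlags", function(object) standardGeneric("detectionFlags"))

#' @rdname ExpressionDataset-class
#' @export
setMethod("detectionFlags", "ExpressionDataset", function(object)
  assay(object, "flags"))

#' @rdname ExpressionDataset-class
#' @export
setGeneric("probeInfo", function(object) standardGeneric("probeInfo"))

#' @rdname ExpressionDataset-class
#' @export
setMethod("probeInfo", "ExpressionDataset", function(object)
  as.data.frame(rowData(object)))

#' @rdname ExpressionDataset-class
#' @export
setGeneric("sampleInfo", function(object) standardGeneric("sampleInfo"))

#' @rdname ExpressionDataset-class
#' @export
setMethod("sampleInfo", "ExpressionDataset", function(object)
  as.data.frame(colData(object)))

#' @rdname ExpressionDataset-class
#' @export
setGeneric("spikeProbes", function(object) standardGeneric("spikeProbes"))

#' Spike-in probe identifiers
#' @rdname ExpressionDataset-class
#' @export
setMethod("spikeProbes", "ExpressionDataset", function(object)
  rowData(object)$probe_id[rowData(object)$is_spike])

#' Replace the intensity assay, keeping flags and annotation
#'
#' @param object an [ExpressionDataset-class].
#' @param value replacement probes x samples matrix.
#' @rdname ExpressionDataset-class
#' @export
setGeneric("intensities<-", function(object, value)
  standardGeneric("intensities<-"))

#' @rdname ExpressionDataset-class
#' @export
setMethod("intensities<-", "ExpressionDataset", function(object, value) {
  assay(object, "intensities") <- value
  validObject(object)
  object
})

#' @rdname SamResult-class
#' @param object an object.
#' @export
setGeneric("samProbes", function(object) standardGeneric("samProbes"))

#' @rdname SamResult-class
#' @export
setMethod("samProbes", "SamResult", function(object) object@probes)

#' @rdname SamResult-class
#' @export
setGeneric("samTranscripts", function(object) standardGeneric("samTranscripts"))

#' @rdname SamResult-class
#' @export
setMethod("samTranscripts", "SamResult", function(object) object@transcripts)

#' @rdname GroundTruth-class
#' @param object an object.
#' @export
setGeneric("deTruth", function(object) standardGeneric("deTruth"))

#' @rdname GroundTruth-class
#' @export
setMethod("deTruth", "GroundTruth", function(object) object@deTranscripts)

#' @rdname GroundTruth-class
#' @export
setGeneric("antisenseTruth", function(object) standardGeneric("antisenseTruth"))

#' @rdname GroundTruth-class
#' @export
setMethod("antisenseTruth", "GroundTruth", function(object)
  object@antisensePairs)

#' @rdname GroundTruth-class
#' @export
setGeneric("clusterTruth", function(object) standardGeneric("clusterTruth"))

#' @rdname GroundTruth-class
#' @export
setMethod("clusterTruth", "GroundTruth", function(object)
  object@clusterMembership)

#' @rdname GroundTruth-class
#' @export
setGeneric("efficiencyTruth", function(object)
  standardGeneric("efficiencyTruth"))

#' @rdname GroundTruth-class
#' @export
setMethod("efficiencyTruth", "GroundTruth", function(object)
  object@qpcrEfficiencies)
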