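# Accessor generics shared across the container classes.

#' Sampling rate accessor
#' @param x a [RawRecording-class] or [EpochSet-class]
#' @return sampling rate in Hz
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Channel label accessor
#' @param x an object with per-channel metadata
#' @return character vector of channel labels
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' Channel role accessor (EEG/EOG)
#' @param x an object with per-channel metadata
#' @return character vector of roles, `"EEG"` or `"EOG"`
#' @export
setGeneric("channelRoles", function(x) standardGeneric("channelRoles"))

#' Event table accessor
#' @param x a [RawRecording-class]
#' @return data.frame with columns `sample` (0-based) and `code`
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' Per-trial class label accessor
#' @param x an [EpochSet-class], [FeatureTable-class] or [GroundTruth-class]
#' @return factor of class labels
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' Estimated or planted mixing matrix accessor
#' @param x an [ICDecomposition-class] or [GroundTruth-class]
#' @return channels x components/sources matrix
#' @export
setGeneric("mixingMatrix", function(x) standardGeneric("mixingMatrix"))

#' Unmixing matrix accessor
#' @param x an [ICDecomposition-class]
#' @return components x channels matrix
#' @export
setGeneric("unmixingMatrix", function(x) standardGeneric("unmixingMatrix"))

#' Source time-course accessor
#' @param x an [ICDecomposition-class] or [GroundTruth-class]
#' @return components/sources x samples matrix
#' @export
setGeneric("sourceSignals", function(x) standardGeneric("sourceSignals"))

#' Artifact flag accessor
#' @param x an [ICDecomposition-class]
#' @return logical vector, one flag per component
#' @export
setGeneric("artifactFlags", function(x) standardGeneric("artifactFlags"))

#' Artifact-correlation score accessor
#' @param x an [ICDecomposition-class]
#' @return components x EOG-channels matrix of |correlation|
#' @export
setGeneric("xcorrScores", function(x) standardGeneric("xcorrScores"))

#' Feature matrix accessor
#' @param x a [FeatureTable-class]
#' @return trials x features numeric matrix with named columns
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' Embedding eigenvalue accessor
#' @param x an [EmbeddingResult-class]
#' @return retained eigenvalues, ascending
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' Embedding coordinate accessor
#' @param x an [EmbeddingResult-class]
#' @return trials x r coordinate matrix
#' @export
setGeneric("coordinates", function(x) standardGeneric("coordinates"))
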