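# Accessor and show methods.

#' Raw signal matrix of a recording or decomposition input
#'
#' @param x a [RawRecording-class]
#' @return channels x samples numeric matrix in microvolts
#' @export
recordingData <- function(x) {
  stopifnot(is(x, "RawRecording"))
  x@data
}

#' Epoch array accessor
#'
#' @param x an [EpochSet-class]
#' @return trials x channels x samples array
#' @export
epochData <- function(x) {
  stopifnot(is(x, "EpochSet"))
  x@data
}

#' @describeIn samplingRate of a continuous recording
#' @export
setMethod("samplingRate", "RawRecording", function(x) x@fs)
#' @describeIn samplingRate of an epoch set
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@fs)

#' @describeIn channelLabels of a continuous recording
#' @export
setMethod("channelLabels", "RawRecording", function(x) x@channelLabels)
#' @describeIn channelLabels of an epoch set
#' @export
setMethod("channelLabels", "EpochSet", function(x) x@channelLabels)
#' @describeIn channelLabels channels entering a decomposition
#' @export
setMethod("channelLabels", "ICDecomposition", function(x) x@channelLabels)

#' @describeIn channelRoles of a continuous recording
#' @export
setMethod("channelRoles", "RawRecording", function(x) x@channelRoles)
#' @describeIn channelRoles of an epoch set
#' @export
setMethod("channelRoles", "EpochSet", function(x) x@channelRoles)

#' @describeIn eventTable of a continuous recording
#' @export
setMethod("eventTable", "RawRecording", function(x) x@events)

#' @describeIn classLabels of an epoch set
#' @export
setMethod("classLabels", "EpochSet", function(x) x@labels)
#' @describeIn classLabels of a feature table
#' @export
setMethod("classLabels", "FeatureTable", function(x) x@labels)
#' @describeIn classLabels planted by the generator
#' @export
setMethod("classLabels", "GroundTruth", function(x) x@classLabels)

#' @describeIn mixingMatrix estimated by SOBI
#' @export
setMethod("mixingMatrix", "ICDecomposition", function(x) x@mixing)
#' @describeIn mixingMatrix planted by the generator
#' @export
setMethod("mixingMatrix", "GroundTruth", function(x) x@mixingMatrix)

#' @describeIn unmixingMatrix estimated by SOBI
#' @export
setMethod("unmixingMatrix", "ICDecomposition", function(x) x@unmixing)

#' @describeIn sourceSignals estimated by SOBI
#' @export
setMethod("sourceSignals", "ICDecomposition", function(x) x@sources)
#' @describeIn sourceSignals planted by the generator
#' @export
setMethod("sourceSignals", "GroundTruth", function(x) x@sourceSignals)

#' @describeIn artifactFlags flags set by [flagArtifacts()]
#' @export
setMethod("artifactFlags", "ICDecomposition", function(x) x@artifactFlags)

#' @describeIn xcorrScores scores set by [flagArtifacts()]
#' @export
setMethod("xcorrScores", "ICDecomposition", function(x) x@xcorrScores)

#' @describeIn featureMatrix trials x features matrix
#' @export
setMethod("featureMatrix", "FeatureTable", function(x) x@matrix)

#' @describeIn eigenvalues retained non-trivial eigenvalues
#' @export
setMethod("eigenvalues", "EmbeddingResult", function(x) x@eigenvalues)

#' @describeIn coordinates embedded trial coordinates
#' @export
setMethod("coordinates", "EmbeddingResult", function(x) x@coordinates)

setMethod("show", "RawRecording", function(object) {
  cat(sprintf(
    "RawRecording: %d channels (%d EEG, %d EOG) x %d samples @ %g Hz (%.1f s), %d events\n",
    nrow(object@data), sum(object@channelRoles == "EEG"),
    sum(object@channelRoles == "EOG"), ncol(object@data), object@fs,
    ncol(object@data) / object@fs, nrow(object@events)
  ))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "EpochSet: %d trials x %d channels x %d samples @ %g Hz, window [%g, %g) s\n",
    d[1], d[2], d[3], object@fs, object@window[1], object@window[2]
  ))
  print(table(object@labels))
})

setMethod("show", "ICDecomposition", function(object) {
  cat(sprintf(
    "ICDecomposition: %d components x %d samples, %d flagged as artifact%s\n",
    nrow(object@sources), ncol(object@sources), sum(object@artifactFlags),
    if (isTRUE(object@lowConfidence)) " [low confidence]" else ""
  ))
})

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf(
    "FeatureTable '%s': %d trials x %d features\n",
    object@subjectId, nrow(object@matrix), ncol(object@matrix)
  ))
  print(table(object@labels))
})

setMethod("show", "AnovaResult", function(object) {
  cat(sprintf("Two-way ANOVA for %s (alpha = %g)%s\n", object@featureName,
              object@alpha,
              if (object@degenerate) " [degenerate: zero error MS]" else ""))
  print(object@table, digits = 4)
})

setMethod("show", "NeighborGraph", function(object) {
  cat(sprintf(
    "NeighborGraph: %d nodes, k = %d, %s weights, %d edges\n",
    nrow(object@weights), object@nNeighbors, object@scheme,
    sum(object@weights > 0) / 2
  ))
})

setMethod("show", "EmbeddingResult", function(object) {
  cat(sprintf(
    "EmbeddingResult: %d points in %d dimensions, %d connected component(s)\n",
    nrow(object@coordinates), object@r, object@nComponents
  ))
  cat("retained eigenvalues:", format(object@eigenvalues, digits = 4), "\n")
})

setMethod("show", "ClassificationReport", function(object) {
  cat(sprintf("ClassificationReport (seed %d, %d folds):\n",
              object@seed, length(unique(object@folds))))
  print(object@metrics, digits = 4)
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d sources (%d artifact) x %d samples, %d trials\n",
    nrow(object@sourceSignals), length(object@artifactSourceIndices),
    ncol(object@sourceSignals), length(object@classLabels)
  ))
})
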