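#' @import methods
NULL

MI_CLASSES <- c("left_hand", "right_hand", "foot", "tongue")

#' Continuous multichannel EEG/EOG recording
#'
#' Container for a continuous recording: a channels-by-samples matrix in
#' microvolts, per-channel labels and roles (EEG or EOG), the sampling rate,
#' and an event table of `(sample, code)` trial markers (0-based sample
#' indices).
#'
#' @slot data numeric matrix, channels x samples, microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channelLabels character vector, one label per row of `data`.
#' @slot channelRoles character vector, `"EEG"` or `"EOG"` per channel.
#' @slot events data.frame with integer columns `sample` (0-based) and `code`.
#'
#' @exportClass RawRecording
setClass("RawRecording",
  representation(
    data = "matrix",
    fs = "numeric",
    channelLabels = "character",
    channelRoles = "character",
    events = "data.frame"
  )
)

setValidity("RawRecording", function(object) {
  msg <- character()
  if (nrow(object@data) != length(object@channelLabels))
    msg <- c(msg, "channel label count must equal data row count")
  if (nrow(object@data) != length(object@channelRoles))
    msg <- c(msg, "channel role count must equal data row count")
  if (!all(object@channelRoles %in% c("EEG", "EOG")))
    msg <- c(msg, "channel roles must be 'EEG' or 'EOG'")
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (nrow(object@events) > 0) {
    if (!all(c("sample", "code") %in% names(object@events)))
      msg <- c(msg, "events must have columns 'sample' and 'code'")
    else if (any(object@events$sample < 0) ||
             any(object@events$sample >= ncol(object@data)))
      msg <- c(msg, "event sample indices out of range")
  }
  if (length(msg)) msg else TRUE
})

#' Epoched trials
#'
#' Trials x channels x samples array with one four-class motor-imagery label
#' per trial and the extraction window (seconds, relative to trial onset,
#' half-open).
#'
#' @slot data numeric array, trials x channels x samples.
#' @slot labels factor of per-trial classes with levels
#'   `left_hand, right_hand, foot, tongue`.
#' @slot fs sampling rate in Hz.
#' @slot window numeric length-2, `(start_s, end_s)` relative to trial onset.
#' @slot channelLabels,channelRoles per-channel metadata, as in
#'   [RawRecording-class].
#' @slot dropped integer, trials discarded because the window ran out of range.
#'
#' @exportClass EpochSet
setClass("EpochSet",
  representation(
    data = "array",
    labels = "factor",
    fs = "numeric",
    window = "numeric",
    channelLabels = "character",
    channelRoles = "character",
    dropped = "integer"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be a 3-D array")
  else {
    if (d[1] != length(object@labels))
      msg <- c(msg, "label count must equal trial count")
    if (d[2] != length(object@channelLabels))
      msg <- c(msg, "channel label count must equal channel dimension")
    ns <- round(diff(object@window) * object@fs)
    if (length(object@window) == 2L && abs(ns - d[3]) > 0.5)
      msg <- c(msg, "window length times fs must equal sample count")
  }
  if (length(object@window) != 2L || diff(object@window) <= 0)
    msg <- c(msg, "window must be an increasing (start, end) pair")
  if (length(msg)) msg else TRUE
})

#' Blind source separation result
#'
#' Mixing/unmixing matrices and source time courses from SOBI, plus the
#' per-component ocular-artifact evidence: the maximum absolute zero-lag
#' correlation of each source against each EOG reference channel, and the
#' boolean artifact flags derived from it.
#'
#' @slot mixing channels x components matrix (estimated A).
#' @slot unmixing components x channels matrix (estimated W, with
#'   `unmixing %*% mixing` = identity up to numerical tolerance).
#' @slot sources components x samples matrix of estimated source signals.
#' @slot xcorrScores components x EOG-channels matrix of |correlation|.
#' @slot artifactFlags logical per component.
#' @slot channelLabels labels of the (EEG) channels that entered the
#'   decomposition.
#' @slot center per-channel means removed before decomposition.
#' @slot lowConfidence TRUE when the lagged covariance structure was too weak
#'   for SOBI's assumptions (near-white sources).
#'
#' @exportClass ICDecomposition
setClass("ICDecomposition",
  representation(
    mixing = "matrix",
    unmixing = "matrix",
    sources = "matrix",
    xcorrScores = "matrix",
    artifactFlags = "logical",
    channelLabels = "character",
    center = "numeric",
    lowConfidence = "logical"
  )
)

setValidity("ICDecomposition", function(object) {
  msg <- character()
  p <- ncol(object@mixing)
  if (nrow(object@unmixing) != p)
    msg <- c(msg, "unmixing rows must equal mixing columns")
  if (nrow(object@sources) != p)
    msg <- c(msg, "source rows must equal component count")
  if (length(object@artifactFlags) &&
      length(object@artifactFlags) != p)
    msg <- c(msg, "artifact flag count must equal component count")
  pr <- object@unmixing %*% object@mixing
  if (max(abs(pr - diag(nrow(pr)))) > 1e-6)
    msg <- c(msg, "unmixing %*% mixing must be identity within tolerance")
  if (length(object@xcorrScores) &&
      (any(object@xcorrScores < 0) || any(object@xcorrScores > 1 + 1e-12)))
    msg <- c(msg, "xcorr scores must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic recording
#'
#' Everything the generator knows and downstream estimators are asked to
#' recover: the mixing matrix, the source signals, which sources are
#' artifacts, per-trial class labels, the Hurst exponent planted for each
#' class, and trial onset samples.
#'
#' @slot mixingMatrix channels x sources weights (full column rank).
#' @slot sourceSignals sources x samples matrix.
#' @slot artifactSourceIndices integer indices of artifact sources.
#' @slot classLabels factor, one class per trial.
#' @slot hurstPerClass named numeric, target Hurst exponent per class.
#' @slot onsets integer 0-based sample index of each trial onset.
#'
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    mixingMatrix = "matrix",
    sourceSignals = "matrix",
    artifactSourceIndices = "integer",
    classLabels = "factor",
    hurstPerClass = "numeric",
    onsets = "integer"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (ncol(object@mixingMatrix) != nrow(object@sourceSignals))
    msg <- c(msg, "mixing columns must equal source count")
  if (qr(object@mixingMatrix)$rank < ncol(object@mixingMatrix))
    msg <- c(msg, "mixing matrix must have full column rank")
  if (length(object@artifactSourceIndices) &&
      (any(object@artifactSourceIndices < 1) ||
       any(object@artifactSourceIndices > nrow(object@sourceSignals))))
    msg <- c(msg, "artifact source indices out of range")
  if (length(msg)) msg else TRUE
})

#' Per-trial feature matrix (the "CompEn" set)
#'
#' Trials x (channels x 4 features) matrix with named columns
#' `<channel>.<feature>` for feature in FD, Hur, TsEn, DispEn, plus per-trial
#' class labels.
#'
#' @slot matrix numeric trials x features matrix, no missing values.
#' @slot labels factor, class per trial.
#' @slot subjectId opaque tag.
#'
#' @exportClass FeatureTable
setClass("FeatureTable",
  representation(
    matrix = "matrix",
    labels = "factor",
    subjectId = "character"
  )
)

setValidity("FeatureTable", function(object) {
  msg <- character()
  if (nrow(object@matrix) != length(object@labels))
    msg <- c(msg, "label count must equal trial count")
  if (anyNA(object@matrix))
    msg <- c(msg, "feature matrix must not contain missing values")
  if (is.null(colnames(object@matrix)))
    msg <- c(msg, "feature columns must be named")
  if (length(msg)) msg else TRUE
})

#' Two-way ANOVA decomposition
#'
#' Fixed-effects sums-of-squares table for a balanced class x channel design
#' with interaction, computed directly from cell means.
#'
#' @slot featureName label of the analysed feature.
#' @slot table data.frame with rows class, channel, interaction, error, total
#'   and columns `ss`, `df`, `ms`, `F`, `p`.
#' @slot alpha significance level.
#' @slot degenerate TRUE when the error mean square was zero.
#'
#' @exportClass AnovaResult
setClass("AnovaResult",
  representation(
    featureName = "character",
    table = "data.frame",
    alpha = "numeric",
    degenerate = "logical"
  )
)

setValidity("AnovaResult", function(object) {
  msg <- character()
  tb <- object@table
  if (any(tb$ss < -1e-8)) msg <- c(msg, "sums of squares must be non-negative")
  p <- tb$p[!is.na(tb$p)]
  if (any(p < 0 | p > 1)) msg <- c(msg, "p-values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' k-nearest-neighbour similarity graph
#'
#' Symmetric non-negative weight matrix over trials (OR-symmetrized kNN) with
#' its degree vector, as input to the Laplacian Eigenmap.
#'
#' @slot weights symmetric trial x trial matrix, zero diagonal.
#' @slot degree numeric, row sums of `weights`.
#' @slot nNeighbors the k used to build the graph.
#' @slot features the standardized feature matrix the graph was built on
#'   (kept for out-of-sample extension).
#' @slot scheme `"binary"` or `"heat"`.
#' @slot heatT heat-kernel bandwidth (heat scheme only).
#'
#' @exportClass NeighborGraph
setClass("NeighborGraph",
  representation(
    weights = "matrix",
    degree = "numeric",
    nNeighbors = "integer",
    features = "matrix",
    scheme = "character",
    heatT = "numeric"
  )
)

setValidity("NeighborGraph", function(object) {
  msg <- character()
  W <- object@weights
  if (nrow(W) != ncol(W)) msg <- c(msg, "weight matrix must be square")
  else {
    if (max(abs(W - t(W))) > 1e-12) msg <- c(msg, "weights must be symmetric")
    if (any(diag(W) != 0)) msg <- c(msg, "diagonal must be zero")
    if (any(W < 0)) msg <- c(msg, "weights must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Laplacian Eigenmap embedding
#'
#' Solution of the generalized eigenproblem L y = lambda D y on a neighbour
#' graph: the retained (non-trivial) eigenvalues in ascending order and the
#' trial coordinates Y satisfying Y' D Y = I.
#'
#' @slot eigenvalues retained eigenvalues, ascending, all >= -1e-10.
#' @slot coordinates trials x r coordinate matrix.
#' @slot r embedding dimension.
#' @slot allEigenvalues full ascending spectrum (including trivial ones).
#' @slot nComponents number of connected components (zero-eigenvalue
#'   multiplicity).
#' @slot degree the graph degree vector (for the Y' D Y = I constraint).
#'
#' @exportClass EmbeddingResult
setClass("EmbeddingResult",
  representation(
    eigenvalues = "numeric",
    coordinates = "matrix",
    r = "integer",
    allEigenvalues = "numeric",
    nComponents = "integer",
    degree = "numeric"
  )
)

setValidity("EmbeddingResult", function(object) {
  msg <- character()
  if (is.unsorted(object@eigenvalues, strictly = FALSE))
    msg <- c(msg, "eigenvalues must be ascending")
  if (length(object@eigenvalues) && min(object@eigenvalues) < -1e-10)
    msg <- c(msg, "eigenvalues must be non-negative within tolerance")
  if (ncol(object@coordinates) != object@r)
    msg <- c(msg, "coordinate columns must equal r")
  if (length(msg)) msg else TRUE
})

#' Cross-validated classification report
#'
#' Per-classifier accuracy, macro precision/recall (all in percent), 4x4
#' confusion matrices in fixed class order (left hand, right hand, foot,
#' tongue; rows = true class), the fold assignment and the seed used.
#'
#' @slot metrics data.frame with columns classifier, accuracy, macroPrecision,
#'   macroRecall.
#' @slot confusion named list of 4x4 confusion matrices.
#' @slot folds integer fold assignment per trial.
#' @slot seed integer master seed.
#'
#' @exportClass ClassificationReport
setClass("ClassificationReport",
  representation(
    metrics = "data.frame",
    confusion = "list",
    folds = "integer",
    seed = "integer"
  )
)

setValidity("ClassificationReport", function(object) {
  msg <- character()
  for (cm in object@confusion) {
    if (!all(dim(cm) == c(4L, 4L)))
      msg <- c(msg, "confusion matrices must be 4x4")
  }
  if (length(msg)) msg else TRUE
})
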