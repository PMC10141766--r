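# Ocular-artifact detection by cross-correlation against EOG references,
# and reconstruction with the flagged components zeroed.

#' Zero-lag normalized cross-correlation
#'
#' `XCorr(x, y) = sum((x - xbar)(y - ybar)) / sqrt(sum((x - xbar)^2)
#' sum((y - ybar)^2))`, the Pearson form at lag zero, used to score each
#' independent component against the EOG reference channels.
#'
#' @param x,y numeric vectors of equal length >= 2 with nonzero variance.
#' @return correlation in \[-1, 1\].
#' @examples
#' xcorr(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' @export
xcorr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("x and y must have equal length >= 2")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlation undefined: zero variance input")
  .pearson(x, y)
}

#' Score and flag artifact components against EOG references
#'
#' Computes, for every component, the absolute zero-lag correlation with
#' every EOG channel; a component is flagged as artifact iff its maximum
#' absolute correlation over the EOG channels reaches `threshold`. Flags
#' are monotone: lowering the threshold can only add flags.
#'
#' @param dec an [ICDecomposition-class] from [sobi()].
#' @param eog EOG reference signals time-aligned with the sources: an
#'   EOG-channels x samples matrix, or a [RawRecording-class] whose EOG
#'   channels are used.
#' @param threshold absolute-correlation cutoff in (0, 1), default 0.5.
#' @return the decomposition with `xcorrScores` and `artifactFlags` filled.
#' @export
flagArtifacts <- function(dec, eog, threshold = 0.5) {
  stopifnot(is(dec, "ICDecomposition"))
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  if (is(eog, "RawRecording")) {
    sel <- eog@channelRoles == "EOG"
    if (!any(sel)) stop("recording has no EOG channels")
    eog <- eog@data[sel, , drop = FALSE]
  }
  eog <- as.matrix(eog)
  if (nrow(eog) == 0) stop("no EOG reference channels supplied")
  if (ncol(eog) != ncol(dec@sources))
    stop("EOG references must be time-aligned with the sources")
  scores <- matrix(0, nrow(dec@sources), nrow(eog))
  for (i in seq_len(nrow(dec@sources)))
    for (j in seq_len(nrow(eog)))
      scores[i, j] <- abs(.pearson(dec@sources[i, ], eog[j, ]))
  out <- dec
  out@xcorrScores <- scores
  out@artifactFlags <- apply(scores, 1, max) >= threshold
  out
}

#' Zero flagged components and reconstruct the cleaned recording
#'
#' Scores the components against the recording's EOG channels
#' ([flagArtifacts()]), zeroes the source rows of every flagged component,
#' and reconstructs the cleaned EEG channels as
#' `xhat = mixing %*% sources_zeroed` (channel means restored). EOG
#' channels are passed through unchanged.
#'
#' @param dec an [ICDecomposition-class] fitted on the recording's EEG
#'   channels.
#' @param rec the [RawRecording-class] the decomposition was fitted on
#'   (must contain at least one EOG channel).
#' @param threshold absolute-correlation cutoff in (0, 1), default 0.5.
#' @return list with `decomposition` (flags and scores filled, flagged
#'   source rows zeroed) and `cleaned` (a [RawRecording-class]).
#' @export
removeArtifacts <- function(dec, rec, threshold = 0.5) {
  stopifnot(is(dec, "ICDecomposition"), is(rec, "RawRecording"))
  if (!any(rec@channelRoles == "EOG"))
    stop("recording has no EOG channels to reference artifacts against")
  dec <- flagArtifacts(dec, rec, threshold)
  if (all(dec@artifactFlags))
    stop("every component is flagged as artifact; refusing to zero the ",
         "whole recording (threshold ", threshold, " is too permissive)")
  shat <- dec@sources
  shat[dec@artifactFlags, ] <- 0
  dec@sources <- shat
  xhat <- dec@mixing %*% shat + dec@center

  cleaned <- rec
  eegIdx <- which(rec@channelRoles == "EEG")
  if (length(eegIdx) != nrow(xhat))
    stop("decomposition channel count does not match the recording")
  cleaned@data[eegIdx, ] <- xhat
  list(decomposition = dec, cleaned = cleaned)
}
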