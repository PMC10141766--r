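# Batch feature extraction: the "CompEn" set (FD, Hur, TsEn, DispEn) per
# trial and EEG channel.

FEATURE_NAMES <- c("FD", "Hur", "TsEn", "DispEn")

#' Compute the CompEn feature set over an epoch set
#'
#' For every trial and EEG channel, computes Higuchi fractal dimension
#' ([higuchiFD()]), rescaled-range Hurst exponent ([hurstRS()]), Tsallis
#' entropy via the Sneddon approximation ([tsallisSneddon()]) and dispersion
#' entropy ([dispersionEntropy()]). Columns are named
#' `<channel>.<feature>`.
#'
#' @param epochs an [EpochSet-class].
#' @param kmax Higuchi maximum interval.
#' @param minSubset smallest R/S block length.
#' @param m,c,d dispersion-entropy parameters.
#' @param subjectId opaque tag stored on the table.
#' @return a [FeatureTable-class] with `channels x 4` columns.
#' @export
computeFeatures <- function(epochs, kmax = 20, minSubset = 64,
                            m = 2, c = 2, d = 1, subjectId = "S1") {
  stopifnot(is(epochs, "EpochSet"))
  eeg <- which(epochs@channelRoles == "EEG")
  nTrial <- dim(epochs@data)[1]
  chLab <- epochs@channelLabels[eeg]
  cols <- as.vector(t(outer(chLab, FEATURE_NAMES, paste, sep = ".")))
  M <- matrix(NA_real_, nTrial, length(cols), dimnames = list(NULL, cols))
  for (tr in seq_len(nTrial)) {
    for (j in seq_along(eeg)) {
      x <- epochs@data[tr, eeg[j], ]
      base <- (j - 1) * 4L
      M[tr, base + 1L] <- suppressWarnings(higuchiFD(x, kmax))
      M[tr, base + 2L] <- hurstRS(x, minSubset)
      M[tr, base + 3L] <- tsallisSneddon(x)
      M[tr, base + 4L] <- dispersionEntropy(x, m = m, c = c, d = d)
    }
  }
  new("FeatureTable", matrix = M, labels = epochs@labels,
      subjectId = subjectId)
}
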