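# Synthetic four-class motor-imagery recordings with known ground truth.

#' Per-class signal signature for the synthetic generator
#'
#' Each motor-imagery class is given a complexity signature: the Hurst
#' exponent of the fractional Gaussian noise its channels carry during the
#' imagery window, the depth of the mu-band (10 Hz) event-related
#' desynchronization, and the channels expressing it.
#'
#' @param classLabel one of `left_hand`, `right_hand`, `foot`, `tongue`.
#' @param hurst target Hurst exponent, strictly in (0, 1).
#' @param erdDepth fractional attenuation of the 10 Hz oscillation during
#'   imagery, in \[0, 1\].
#' @param erdChannels channel labels expressing the signature (must be a
#'   subset of the montage used at generation time).
#' @param oscAmplitude baseline 10 Hz oscillation amplitude in microvolts.
#' @return a named list of class `"ClassSignature"`.
#' @export
classSignature <- function(classLabel, hurst, erdDepth = 0.5,
                           erdChannels = character(), oscAmplitude = 5) {
  classLabel <- match.arg(classLabel, MI_CLASSES)
  if (hurst <= 0 || hurst >= 1) stop("hurst must lie strictly in (0, 1)")
  if (erdDepth < 0 || erdDepth > 1) stop("erdDepth must lie in [0, 1]")
  structure(list(classLabel = classLabel, hurst = hurst, erdDepth = erdDepth,
                 erdChannels = erdChannels, oscAmplitude = oscAmplitude),
            class = "ClassSignature")
}

#' Artifact model for the synthetic generator
#'
#' Blink transients on the EOG channels propagated into frontal EEG, plus
#' power-line interference on every channel.
#'
#' @param blinkRate blink events per minute.
#' @param blinkAmplitude blink peak amplitude in microvolts.
#' @param blinkFrontalGain propagation weights into the EEG channels, either
#'   a single decay description (`NULL` = default exponential fall-off over
#'   the channel order, frontal channels first) or a numeric vector with one
#'   weight per EEG channel.
#' @param lineFreq power-line frequency in Hz (default 50).
#' @param lineAmplitude line interference amplitude in microvolts.
#' @return a named list of class `"ArtifactSpec"`.
#' @export
artifactSpec <- function(blinkRate = 12, blinkAmplitude = 100,
                         blinkFrontalGain = NULL, lineFreq = 50,
                         lineAmplitude = 5) {
  if (blinkAmplitude < 0 || lineAmplitude < 0 || blinkRate < 0)
    stop("amplitudes and rates must be non-negative")
  if (lineFreq <= 0) stop("lineFreq must be positive")
  structure(list(blinkRate = blinkRate, blinkAmplitude = blinkAmplitude,
                 blinkFrontalGain = blinkFrontalGain, lineFreq = lineFreq,
                 lineAmplitude = lineAmplitude),
            class = "ArtifactSpec")
}

#' Standard 22 EEG + 3 EOG montage
#'
#' Channel labels follow the Graz four-class motor-imagery layout (22
#' Ag/AgCl scalp electrodes around the sensorimotor strip plus three EOG
#' references). Smaller montages for fast simulations take the first
#' `nEEG` scalp labels.
#'
#' @param nEEG number of EEG channels (1..22).
#' @param nEOG number of EOG channels (>= 1).
#' @return list with character vectors `labels` and `roles`.
#' @export
defaultMontage <- function(nEEG = 22, nEOG = 3) {
  scalp <- c("Fz", "FC3", "FC1", "FCz", "FC2", "FC4", "C5", "C3", "C1", "Cz",
             "C2", "C4", "C6", "CP3", "CP1", "CPz", "CP2", "CP4", "P1", "Pz",
             "P2", "POz")
  if (nEEG < 1 || nEEG > length(scalp)) stop("nEEG must be in 1..22")
  if (nEOG < 1) stop("at least one EOG channel is required")
  labels <- c(scalp[seq_len(nEEG)], paste0("EOG", seq_len(nEOG)))
  list(labels = labels,
       roles = c(rep("EEG", nEEG), rep("EOG", nEOG)))
}

#' Default four-class signatures over a montage
#'
#' Assigns each class a disjoint group of EEG channels and a distinct Hurst
#' exponent, giving planted, recoverable class structure.
#'
#' @param montage montage list from [defaultMontage()].
#' @param hurst named or unnamed numeric of length 4, Hurst exponent per
#'   class in the order left hand, right hand, foot, tongue.
#' @param erdDepth,oscAmplitude passed to [classSignature()].
#' @return list of four `ClassSignature` objects.
#' @export
defaultSignatures <- function(montage = defaultMontage(),
                              hurst = c(0.35, 0.5, 0.65, 0.8),
                              erdDepth = 0.5, oscAmplitude = 5) {
  eeg <- montage$labels[montage$roles == "EEG"]
  groups <- split(eeg, factor(cut(seq_along(eeg), 4, labels = FALSE),
                              levels = 1:4))
  mapply(function(cl, h, chans) {
    classSignature(cl, h, erdDepth = erdDepth, erdChannels = chans,
                   oscAmplitude = oscAmplitude)
  }, MI_CLASSES, hurst, groups, SIMPLIFY = FALSE)
}

# Gaussian-windowed biphasic blink pulse, `width` seconds long, unit peak.
blinkPulse <- function(fs, width = 0.3) {
  t <- seq(-width / 2, width / 2, by = 1 / fs)
  s <- width / 6
  p <- -t / s * exp(-t^2 / (2 * s^2))
  p / max(abs(p))
}

#' Event codes of the four motor-imagery classes
#'
#' The standard cue annotation codes of the four-class Graz paradigm
#' (769 = left hand, 770 = right hand, 771 = foot, 772 = tongue).
#'
#' @return named integer vector.
#' @export
miEventCodes <- function() {
  c(left_hand = 769L, right_hand = 770L, foot = 771L, tongue = 772L)
}

#' Generate a synthetic four-class motor-imagery recording
#'
#' Builds a continuous multichannel recording following the standard trial
#' schedule (fixation 0–2 s, cue at 2 s, imagery until 6 s, then an
#' inter-trial gap): each EEG channel carries a background fractional
#' Gaussian noise source (H = 0.5, i.e. white) at `backgroundRms` microvolts;
#' during a trial's imagery window the channels named by the trial class's
#' signature instead carry fGn with the class Hurst exponent, and their
#' 10 Hz oscillation is attenuated by the signature's ERD depth. Blink
#' transients (Gaussian-windowed biphasic pulses, 300 ms) are written to the
#' EOG channels and propagated into EEG channels with the frontal gain
#' profile; a line-frequency sinusoid is added to every channel. Neural
#' sources are mixed into the EEG channels by a random full-rank,
#' diagonally dominant mixing matrix recorded in the returned ground truth.
#'
#' @param montage list with `labels` and `roles` ([defaultMontage()]); needs
#'   at least 2 EEG and 1 EOG channel.
#' @param nTrials total trial count, divisible by 4 (balanced classes).
#' @param signatures list of four [classSignature()] objects (one per class).
#' @param artifacts an [artifactSpec()].
#' @param fs sampling rate in Hz.
#' @param seed integer seed; identical arguments and seed give bit-identical
#'   output.
#' @param interTrialGap seconds of rest between trials.
#' @param backgroundRms background noise RMS in microvolts.
#' @param mixingStrength off-diagonal scale of the random mixing matrix.
#' @return list with elements `recording` ([RawRecording-class]) and
#'   `truth` ([GroundTruth-class]).
#' @examples
#' sim <- simulateRecording(defaultMontage(4, 1), nTrials = 4, seed = 1)
#' sim$recording
#' @export
simulateRecording <- function(montage = defaultMontage(),
                              nTrials = 8,
                              signatures = defaultSignatures(montage),
                              artifacts = artifactSpec(),
                              fs = 250, seed = NULL,
                              interTrialGap = 1.5,
                              backgroundRms = 10,
                              mixingStrength = 0.05) {
  roles <- montage$roles
  labels <- montage$labels
  nEEG <- sum(roles == "EEG")
  nEOG <- sum(roles == "EOG")
  if (nEEG < 2 || nEOG < 1)
    stop("montage needs at least 2 EEG channels and 1 EOG channel")
  if (nTrials %% 4 != 0)
    stop("nTrials must be divisible by 4 for balanced classes")
  sigClasses <- vapply(signatures, `[[`, "", "classLabel")
  if (!setequal(sigClasses, MI_CLASSES))
    stop("signatures must cover exactly the four classes")
  eegLabels <- labels[roles == "EEG"]
  for (s in signatures)
    if (!all(s$erdChannels %in% eegLabels))
      stop("erdChannels of class '", s$classLabel,
           "' are not all EEG channels of the montage")

  fixation <- 2; imagery <- 4
  period <- fixation + imagery + interTrialGap
  nSamp <- as.integer(ceiling((nTrials * period + 2) * fs))
  perClass <- nTrials / 4

  withSeed(seed, {
    # balanced, shuffled class sequence
    classes <- factor(sample(rep(MI_CLASSES, perClass)), levels = MI_CLASSES)
    onsets <- as.integer(floor((seq_len(nTrials) - 1) * period * fs))

    # neural sources: one per EEG channel, white background replaced by
    # class fGn inside imagery windows of that class's channels
    S <- matrix(stats::rnorm(nEEG * nSamp), nEEG, nSamp) * backgroundRms
    hurstPerClass <- vapply(signatures, `[[`, 0, "hurst")
    names(hurstPerClass) <- sigClasses
    for (tr in seq_len(nTrials)) {
      sig <- signatures[[match(as.character(classes[tr]), sigClasses)]]
      i0 <- onsets[tr] + as.integer(fixation * fs) + 1L
      i1 <- min(onsets[tr] + as.integer((fixation + imagery) * fs), nSamp)
      len <- i1 - i0 + 1L
      for (ch in sig$erdChannels) {
        k <- match(ch, eegLabels)
        S[k, i0:i1] <- fgnSim(len, sig$hurst) * backgroundRms
      }
    }

    # 10 Hz oscillation with ERD attenuation during own-class imagery
    tAxis <- (seq_len(nSamp) - 1) / fs
    for (sig in signatures) {
      if (sig$oscAmplitude <= 0 || !length(sig$erdChannels)) next
      gain <- rep(1, nSamp)
      for (tr in which(classes == sig$classLabel)) {
        i0 <- onsets[tr] + as.integer(fixation * fs) + 1L
        i1 <- min(onsets[tr] + as.integer((fixation + imagery) * fs), nSamp)
        gain[i0:i1] <- 1 - sig$erdDepth
      }
      for (ch in sig$erdChannels) {
        k <- match(ch, eegLabels)
        phase <- stats::runif(1, 0, 2 * pi)
        S[k, ] <- S[k, ] + sig$oscAmplitude * gain * sin(2 * pi * 10 * tAxis + phase)
      }
    }

    # blink source
    blink <- numeric(nSamp)
    nBlinks <- stats::rpois(1, artifacts$blinkRate * nSamp / fs / 60)
    if (nBlinks > 0 && artifacts$blinkAmplitude > 0) {
      pulse <- blinkPulse(fs) * artifacts$blinkAmplitude
      starts <- sort(sample.int(nSamp - length(pulse), nBlinks))
      for (s0 in starts) {
        idx <- s0:(s0 + length(pulse) - 1)
        blink[idx] <- blink[idx] + pulse
      }
    }
    gains <- artifacts$blinkFrontalGain
    if (is.null(gains)) gains <- 0.7 * exp(-(seq_len(nEEG) - 1) / 3)
    if (length(gains) != nEEG)
      stop("blinkFrontalGain must have one weight per EEG channel")

    # mixing: diagonally dominant random full-rank for the neural block,
    # blink column with the frontal gain profile
    Aneural <- diag(nEEG) + mixingStrength * matrix(stats::rnorm(nEEG^2), nEEG)
    A <- matrix(0, nEEG + nEOG, nEEG + 1L)
    A[seq_len(nEEG), seq_len(nEEG)] <- Aneural
    A[seq_len(nEEG), nEEG + 1L] <- gains
    A[nEEG + seq_len(nEOG), nEEG + 1L] <- 1
    sources <- rbind(S, blink)

    X <- A %*% sources
    # EOG sensor noise and common line interference sit outside the mixing
    X[nEEG + seq_len(nEOG), ] <- X[nEEG + seq_len(nEOG), ] +
      matrix(stats::rnorm(nEOG * nSamp), nEOG, nSamp) * backgroundRms / 5
    if (artifacts$lineAmplitude > 0) {
      line <- artifacts$lineAmplitude *
        sin(2 * pi * artifacts$lineFreq * tAxis + stats::runif(1, 0, 2 * pi))
      X <- sweep(X, 2, line, `+`)
    }

    # reorder rows to the montage order (EEG first then EOG already)
    rownames(X) <- c(eegLabels, labels[roles == "EOG"])
    X <- X[labels, , drop = FALSE]

    codes <- miEventCodes()
    events <- data.frame(sample = onsets,
                         code = unname(codes[as.character(classes)]))

    rec <- new("RawRecording", data = unname(X), fs = fs,
               channelLabels = labels, channelRoles = roles, events = events)
    truth <- new("GroundTruth",
                 mixingMatrix = A, sourceSignals = sources,
                 artifactSourceIndices = nEEG + 1L,
                 classLabels = classes, hurstPerClass = hurstPerClass,
                 onsets = onsets)
    list(recording = rec, truth = truth)
  })
}
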