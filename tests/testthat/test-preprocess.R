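# Filters, SOBI separation, cross-correlation artifact rejection.

fs <- 250
tt <- (0:4999) / fs

test_that("notch filter removes the line frequency and spares the passband", {
  x50 <- sin(2 * pi * 50 * tt)
  y <- notchFilter(x50, 50, fs = fs)
  # steady-state response, away from the forward-backward settling edges
  core <- 500:4500
  expect_lt(sd(y[core]) / sd(x50[core]), 0.01)     # > 40 dB down
  x10 <- sin(2 * pi * 10 * tt)
  expect_lt(abs(sd(notchFilter(x10, 50, fs = fs)[core]) / sd(x10[core]) - 1),
            0.05)
  dc <- rep(3, 1000)
  expect_lt(max(abs(notchFilter(dc, 50, fs = fs) - 3)), 1e-3)
  expect_error(notchFilter(x10, 200, fs = fs), "fs/2")
})

test_that("band-pass attenuates out-of-band tones and passes in-band ones", {
  core <- 500:4500
  x2 <- sin(2 * pi * 2 * tt)
  expect_lt(sd(bandpassFilter(x2, 8, 30, fs = fs)[core]) / sd(x2[core]), 0.1)
  x60 <- sin(2 * pi * 60 * tt)
  expect_lt(sd(bandpassFilter(x60, 8, 30, fs = fs)[core]) / sd(x60[core]), 0.1)
  x15 <- sin(2 * pi * 15 * tt)
  expect_lt(abs(sd(bandpassFilter(x15, 8, 30, fs = fs)[core]) /
                  sd(x15[core]) - 1), 0.1)
  expect_error(bandpassFilter(x15, 30, 8, fs = fs), "low < high")
})

test_that("band-passed white noise keeps less than 10% spectral mass outside the band", {
  set.seed(31)
  y <- bandpassFilter(rnorm(2^14), 8, 30, fs = fs)
  sp <- spec.pgram(ts(y, frequency = fs), plot = FALSE, taper = 0)
  inBand <- sp$freq >= 8 & sp$freq <= 30
  expect_lt(sum(sp$spec[!inBand]) / sum(sp$spec), 0.10)
})

test_that("filtering is zero-phase (no lag on a band-limited burst)", {
  burst <- exp(-((0:999) - 500)^2 / 2000) * sin(2 * pi * 15 * (0:999) / fs)
  y <- bandpassFilter(burst, 8, 30, fs = fs)
  cc <- ccf(y, burst, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("SOBI recovers mixed AR(1) sources (Amari index oracle)", {
  set.seed(32)
  idx <- replicate(5, {
    n <- 20000
    S <- rbind(arima.sim(list(ar = 0.9), n), arima.sim(list(ar = -0.5), n),
               arima.sim(list(ar = 0.3), n))
    A <- matrix(rnorm(9), 3)
    dec <- sobi(A %*% S, nLags = 50)
    amariIndex(unmixingMatrix(dec) %*% A)
  })
  expect_lt(max(idx), 0.1)
})

test_that("identity mixing of independent coloured sources gives a signed permutation", {
  set.seed(33)
  n <- 20000
  S <- rbind(arima.sim(list(ar = 0.8), n), arima.sim(list(ar = -0.6), n),
             arima.sim(list(ar = 0.2), n))
  dec <- sobi(S, nLags = 50)
  P <- unmixingMatrix(dec) %*% diag(3)
  # each row/column dominated by a single entry
  expect_lt(amariIndex(P), 0.1)
  rowRatio <- apply(abs(P), 1, function(r) sort(r, decreasing = TRUE)[2] / max(r))
  expect_lt(max(rowRatio), 0.2)
})

test_that("temporally white sources are reported as a low-confidence failure mode", {
  set.seed(34)
  X <- matrix(rnorm(3 * 20000), 3)
  expect_warning(dec <- sobi(X, nLags = 20), "low-confidence")
  expect_true(dec@lowConfidence)
})

test_that("Amari index is invariant to relabeling and sign flips of components", {
  set.seed(35)
  P <- matrix(rnorm(16), 4) + 4 * diag(4)
  perm <- diag(c(1, -1, 1, -1))[sample(4), ]  # signed permutation
  expect_equal(amariIndex(perm %*% P), amariIndex(P), tolerance = 1e-12)
  expect_equal(amariIndex(P %*% perm), amariIndex(P), tolerance = 1e-12)
  expect_equal(amariIndex(diag(c(2, -3, 0.5, 1))), 0)
})

test_that("xcorr matches its closed form and rejects degenerate input", {
  expect_equal(xcorr(1:10, 1:10), 1.0)
  expect_equal(xcorr(1:10, -(1:10)), -1.0)
  expect_equal(xcorr(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(xcorr(1:5, 1:4), "equal length")
  expect_error(xcorr(rep(1, 5), 1:5), "zero variance")
})

test_that("blink components are flagged and zeroing de-correlates frontal EEG from EOG", {
  sim <- smallSim(seed = 36, nTrials = 8)
  rec <- notchFilter(sim$recording)
  dec <- sobi(rec)
  res <- removeArtifacts(dec, rec, threshold = 0.5)
  flags <- artifactFlags(res$decomposition)
  expect_equal(sum(flags), 1)
  expect_equal(which(flags), blinkComponent(dec, sim$truth))
  eog <- recordingData(rec)[channelRoles(rec) == "EOG", , drop = FALSE]
  frontal <- recordingData(res$cleaned)[1, ]  # strongest blink gain
  expect_lt(abs(xcorr(frontal, eog[1, ])), 0.2)
})

test_that("flags are monotone in the threshold and extremes behave", {
  sim <- smallSim(seed = 37, nTrials = 8)
  rec <- notchFilter(sim$recording)
  dec <- sobi(rec)
  fHi <- artifactFlags(flagArtifacts(dec, rec, threshold = 0.6))
  fLo <- artifactFlags(flagArtifacts(dec, rec, threshold = 0.2))
  expect_true(all(fLo[fHi]))  # lowering the threshold never unflags

  # threshold 1: no flags, reconstruction returns the input
  res <- removeArtifacts(dec, rec, threshold = 1)
  expect_false(any(artifactFlags(res$decomposition)))
  eeg <- channelRoles(rec) == "EEG"
  relErr <- max(abs(recordingData(res$cleaned)[eeg, ] -
                      recordingData(rec)[eeg, ])) /
    max(abs(recordingData(rec)[eeg, ]))
  expect_lt(relErr, 1e-6)
})

test_that("artifact rejection refuses to destroy the data or run without EOG", {
  sim <- smallSim(seed = 38, nTrials = 4)
  rec <- notchFilter(sim$recording)
  dec <- sobi(rec)
  eegOnly <- new("RawRecording",
                 data = recordingData(rec)[channelRoles(rec) == "EEG", ],
                 fs = samplingRate(rec),
                 channelLabels = channelLabels(rec)[channelRoles(rec) == "EEG"],
                 channelRoles = rep("EEG", sum(channelRoles(rec) == "EEG")),
                 events = eventTable(rec))
  expect_error(removeArtifacts(dec, eegOnly), "no EOG")
  # force every score above an absurdly low threshold
  expect_error(removeArtifacts(dec, rec, threshold = 1e-12), "refusing")
})

test_that("reconstruction with no flags is numerically exact (A y = x)", {
  set.seed(39)
  n <- 6000
  X <- matrix(0, 4, n)
  for (i in 1:4) X[i, ] <- arima.sim(list(ar = 0.9 - 0.4 * i / 4), n)
  X <- matrix(rnorm(16), 4) %*% X
  dec <- sobi(X, nLags = 30)
  recon <- mixingMatrix(dec) %*% sourceSignals(dec) + dec@center
  expect_lt(max(abs(recon - X)) / max(abs(X)), 1e-6)
})
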