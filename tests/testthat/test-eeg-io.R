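# EDF round trip, event annotations, epoching.

test_that("EDF round trip preserves signals within 16-bit quantization", {
  sim <- smallSim(seed = 21, nTrials = 4, nEEG = 4)
  rec <- sim$recording
  f <- withr::local_tempfile(fileext = ".edf")
  writeEDF(rec, f)
  back <- readRecording(f, format = "edf")

  expect_equal(channelLabels(back), channelLabels(rec))
  expect_equal(channelRoles(back), channelRoles(rec))
  expect_equal(samplingRate(back), samplingRate(rec))
  n <- ncol(recordingData(rec))
  amp <- max(abs(recordingData(rec)))
  err <- max(abs(recordingData(back)[, 1:n] - recordingData(rec)))
  expect_lt(err, amp / 32767)  # one digitization step
  expect_equal(eventTable(back), eventTable(rec))
})

test_that("python mne reads our EDF identically (independent oracle)", {
  sim <- smallSim(seed = 22, nTrials = 4, nEEG = 3)
  f <- withr::local_tempfile(fileext = ".edf")
  out <- withr::local_tempfile(fileext = ".txt")
  writeEDF(sim$recording, f)
  script <- sprintf("
import mne, numpy as np
raw = mne.io.read_raw_edf(%s, verbose='ERROR')
d = raw.get_data() * 1e6  # mne reports volts
ann = raw.annotations
with open(%s, 'w') as fh:
    fh.write(' '.join(raw.ch_names) + '\\n')
    fh.write(str(raw.info['sfreq']) + '\\n')
    fh.write(' '.join('%%.6f' %% v for v in d[:, 1000]) + '\\n')
    fh.write(' '.join('%%g:%%s' %% (a['onset'], a['description']) for a in ann) + '\\n')
", deparse(f), deparse(out))
  status <- system2("python", "-", input = script, stdout = FALSE,
                    stderr = FALSE)
  expect_identical(status, 0L)
  lines <- readLines(out)
  expect_equal(strsplit(lines[1], " ")[[1]], channelLabels(sim$recording))
  expect_equal(as.numeric(lines[2]), 250)
  vals <- as.numeric(strsplit(lines[3], " ")[[1]])
  expect_equal(vals, recordingData(sim$recording)[, 1001], tolerance = 1e-3)
  ann <- strsplit(strsplit(lines[4], " ")[[1]], ":")
  codes <- as.integer(vapply(ann, `[`, "", 2))
  expect_setequal(codes, eventTable(sim$recording)$code)
})

test_that("a recording without annotations reads with an empty event table", {
  rec <- new("RawRecording",
             data = matrix(sin(seq_len(1000) / 5), 2, 500, byrow = TRUE),
             fs = 250, channelLabels = c("Cz", "EOG1"),
             channelRoles = c("EEG", "EOG"),
             events = data.frame(sample = integer(), code = integer()))
  f <- withr::local_tempfile(fileext = ".edf")
  writeEDF(rec, f)
  expect_warning(back <- readRecording(f), "no event annotations")
  expect_equal(nrow(eventTable(back)), 0)
})

test_that("truncated and malformed files fail closed", {
  sim <- smallSim(seed = 23, nTrials = 4, nEEG = 3)
  f <- withr::local_tempfile(fileext = ".edf")
  writeEDF(sim$recording, f)
  full <- readBin(f, "raw", file.size(f))
  g <- withr::local_tempfile(fileext = ".edf")
  writeBin(full[1:(length(full) - 5000)], g)
  expect_error(readRecording(g), "truncated")

  h <- withr::local_tempfile(fileext = ".edf")
  writeBin(charToRaw(paste(rep("junk", 100), collapse = "")), h)
  expect_error(readRecording(h), "malformed EDF")
  expect_error(readRecording("/nonexistent/file.edf"), "not found")
})

test_that("GDF input is reported as unsupported", {
  expect_error(readRecording("whatever.gdf", format = "gdf"), "GDF")
})

test_that("epoching slices half-open windows at the documented lengths", {
  sim <- smallSim(seed = 24, nTrials = 8, nEEG = 4)
  ep <- epochRecording(sim$recording, window = c(0, 6))
  expect_equal(dim(epochData(ep)), c(8, 5, 1500))  # 6 s at 250 Hz
  expect_equal(as.vector(table(classLabels(ep))), rep(2, 4))
  # epochs agree with direct slices of the continuous data
  on <- sim$truth@onsets[1]
  expect_equal(epochData(ep)[1, , ],
               recordingData(sim$recording)[, (on + 1):(on + 1500)])

  ep2 <- epochRecording(sim$recording, window = c(2, 6))
  expect_equal(dim(epochData(ep2))[3], 1000)
  expect_equal(epochData(ep2)[1, , ],
               recordingData(sim$recording)[, (on + 501):(on + 1500)])
})

test_that("degenerate windows and unusable trials are handled", {
  sim <- smallSim(seed = 25, nTrials = 4, nEEG = 4)
  expect_error(epochRecording(sim$recording, window = c(0, 0)), "increasing")
  expect_error(epochRecording(sim$recording, window = c(3, 1)), "increasing")
  # a window far beyond the recording drops every trial
  expect_error(
    suppressMessages(epochRecording(sim$recording, window = c(0, 1e4))),
    "no usable trials")
  # events with unknown codes are ignored, not fatal
  rec <- sim$recording
  rec@events <- rbind(rec@events, data.frame(sample = 10L, code = 1023L))
  expect_message(ep <- epochRecording(rec), "unknown codes")
  expect_equal(dim(epochData(ep))[1], 4)
})

test_that("round trip through EDF preserves per-trial epochs", {
  sim <- smallSim(seed = 26, nTrials = 4, nEEG = 4)
  f <- withr::local_tempfile(fileext = ".edf")
  writeEDF(sim$recording, f)
  back <- readRecording(f)
  epA <- epochRecording(sim$recording, c(0, 6))
  epB <- epochRecording(back, c(0, 6))
  expect_equal(classLabels(epB), classLabels(epA))
  amp <- max(abs(recordingData(sim$recording)))
  expect_lt(max(abs(epochData(epB) - epochData(epA))), amp / 32767)
})
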