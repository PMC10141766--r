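# EDF(+) reading and writing, and epoching.
#
# EDF stores 16-bit integers per channel per 1-s data record with an ASCII
# header; EDF+ adds an annotation channel carrying time-stamped event lists
# (TALs). The writer emits EDF+C with one annotation channel encoding trial
# onsets and their class event codes; the reader recovers data (up to the
# 16-bit quantization), channel roles and events.

padString <- function(s, width) {
  s <- substr(s, 1, width)
  sprintf(paste0("%-", width, "s"), s)
}

edfNumber <- function(x, width = 8) {
  s <- formatC(x, format = "g", width = 1, digits = 7)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4)
  if (nchar(s) > width) stop("number does not fit EDF field: ", x)
  padString(s, width)
}

#' Write a recording to an EDF+ file
#'
#' Signals are scaled per channel into the full 16-bit digital range;
#' events are written as EDF+ annotations (onset in seconds, the event code
#' as annotation text). The recording is padded with zeros to a whole number
#' of 1-second data records.
#'
#' @param rec a [RawRecording-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeEDF <- function(rec, path) {
  stopifnot(is(rec, "RawRecording"))
  X <- rec@data
  fs <- rec@fs
  if (abs(fs - round(fs)) > 1e-9) stop("writeEDF requires an integer sampling rate")
  fs <- as.integer(round(fs))
  nCh <- nrow(X)
  nRec <- as.integer(ceiling(ncol(X) / fs))
  if (ncol(X) < nRec * fs)
    X <- cbind(X, matrix(0, nCh, nRec * fs - ncol(X)))

  amp <- pmax(apply(abs(X), 1, max) * 1.0001, 1)
  amp <- signif(amp, 6)

  annBytes <- 120L  # 60 two-byte "samples" of annotation text per record
  ns <- nCh + 1L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    padString("0", 8),
    padString("X X X X", 80),
    padString("Startdate X X X X", 80),
    "01.01.00", "00.00.00",
    padString(as.character(256 * (ns + 1L)), 8),
    padString("EDF+C", 44),
    padString(as.character(nRec), 8),
    padString("1", 8),
    padString(as.character(ns), 4)
  ), con, eos = NULL)
  lab <- c(rec@channelLabels, "EDF Annotations")
  writeChar(paste(vapply(lab, padString, "", 16), collapse = ""), con, eos = NULL)
  writeChar(paste(rep(padString("", 80), ns), collapse = ""), con, eos = NULL)
  writeChar(paste(vapply(c(rep("uV", nCh), ""), padString, "", 8),
                  collapse = ""), con, eos = NULL)
  writeChar(paste(c(vapply(-amp, edfNumber, ""), edfNumber(-1)),
                  collapse = ""), con, eos = NULL)
  writeChar(paste(c(vapply(amp, edfNumber, ""), edfNumber(1)),
                  collapse = ""), con, eos = NULL)
  writeChar(paste(rep(padString("-32768", 8), ns), collapse = ""), con, eos = NULL)
  writeChar(paste(rep(padString("32767", 8), ns), collapse = ""), con, eos = NULL)
  writeChar(paste(rep(padString("", 80), ns), collapse = ""), con, eos = NULL)
  writeChar(paste(vapply(as.character(c(rep(fs, nCh), annBytes / 2)),
                         padString, "", 8), collapse = ""), con, eos = NULL)
  writeChar(paste(rep(padString("", 32), ns), collapse = ""), con, eos = NULL)

  # digitize with the same affine map the reader inverts:
  # dig = (phys - physMin) / (physMax - physMin) * (digMax - digMin) + digMin
  dig <- round(sweep(sweep(X, 1, -amp), 1, 2 * amp / 65535, `/`)) - 32768
  dig[dig > 32767] <- 32767; dig[dig < -32768] <- -32768
  storage.mode(dig) <- "integer"

  evOnset <- rec@events$sample / fs
  evCode <- rec@events$code
  tal <- function(txt) c(charToRaw(txt), as.raw(0))
  for (r in seq_len(nRec) - 1L) {
    for (ch in seq_len(nCh))
      writeBin(dig[ch, (r * fs + 1):((r + 1) * fs)], con, size = 2,
               endian = "little")
    ann <- tal(sprintf("+%g\x14\x14", r))
    inRec <- which(evOnset >= r & evOnset < r + 1)
    for (i in inRec)
      ann <- c(ann, tal(sprintf("+%g\x14%d\x14", evOnset[i], evCode[i])))
    if (length(ann) > annBytes)
      stop("too many events in one data record for the annotation channel")
    writeBin(c(ann, raw(annBytes - length(ann))), con)
  }
  invisible(path)
}

#' Read a continuous recording from disk
#'
#' Parses an EDF(+) file: channels in stored order, EOG channels flagged by
#' label match (case-insensitive `"EOG"`), events taken from EDF+
#' annotations whose text parses as an integer event code. A file without
#' annotations yields an empty event table with a warning. Truncated or
#' malformed files fail without returning a partial object.
#'
#' @param path file path.
#' @param format `"edf"` (supported) or `"gdf"` (not implemented; convert
#'   GDF recordings to EDF first).
#' @return a [RawRecording-class].
#' @export
readRecording <- function(path, format = c("edf", "gdf")) {
  format <- match.arg(format)
  if (format == "gdf")
    stop("GDF reading is not implemented; convert the recording to EDF")
  if (!file.exists(path)) stop("file not found: ", path)

  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 256))
  if (nchar(hdr) < 256) stop("malformed EDF: header shorter than 256 bytes")
  fld <- function(from, len) trimws(substr(hdr, from, from + len - 1))
  if (fld(1, 8) != "0") stop("malformed EDF: bad version field '", fld(1, 8), "'")
  headerBytes <- as.integer(fld(185, 8))
  nRec <- as.integer(fld(237, 8))
  recDur <- as.numeric(fld(245, 8))
  ns <- as.integer(fld(253, 4))
  if (is.na(ns) || ns < 1) stop("malformed EDF: bad signal count field")

  shdr <- rawToChar(readBin(con, "raw", 256L * ns))
  if (nchar(shdr) < 256L * ns)
    stop("malformed EDF: truncated signal header")
  sfld <- function(offset, width) {
    vapply(seq_len(ns), function(i)
      trimws(substr(shdr, offset * ns + (i - 1) * width + 1,
                    offset * ns + i * width)), "")
  }
  labels <- sfld(0, 16)
  physMin <- as.numeric(sfld(96 + 8, 8))      # after transducer(80)+dim(8)
  physMax <- as.numeric(sfld(96 + 16, 8))
  digMin <- as.numeric(sfld(96 + 24, 8))
  digMax <- as.numeric(sfld(96 + 32, 8))
  spr <- as.integer(sfld(96 + 40 + 80, 8))
  if (anyNA(c(physMin, physMax, digMin, digMax, spr)))
    stop("malformed EDF: unparseable signal header numbers")

  isAnn <- labels == "EDF Annotations"
  recBytes <- sum(spr) * 2L
  body <- readBin(con, "raw", nRec * recBytes)
  if (length(body) < nRec * recBytes)
    stop("malformed EDF: truncated at data record ",
         length(body) %/% recBytes + 1, " of ", nRec)

  dataCh <- which(!isAnn)
  fs <- spr[dataCh[1]] / recDur
  if (any(spr[dataCh] != spr[dataCh[1]]))
    stop("malformed EDF: channels with differing sampling rates are not supported")

  X <- matrix(0, length(dataCh), nRec * spr[dataCh[1]])
  events <- data.frame(sample = integer(), code = integer())
  offs <- c(0L, cumsum(spr * 2L))
  for (r in seq_len(nRec) - 1L) {
    base <- r * recBytes
    for (j in seq_along(dataCh)) {
      ch <- dataCh[j]
      raw <- body[(base + offs[ch] + 1):(base + offs[ch] + spr[ch] * 2L)]
      dig <- readBin(raw, "integer", spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      gain <- (physMax[ch] - physMin[ch]) / (digMax[ch] - digMin[ch])
      X[j, (r * spr[ch] + 1):((r + 1) * spr[ch])] <-
        physMin[ch] + (dig - digMin[ch]) * gain
    }
    for (ch in which(isAnn)) {
      raw <- body[(base + offs[ch] + 1):(base + offs[ch] + spr[ch] * 2L)]
      # TALs are NUL-terminated; split into chunks between NUL bytes
      nz <- raw != as.raw(0)
      starts <- which(nz & !c(FALSE, nz[-length(nz)]))
      ends <- which(nz & !c(nz[-1], FALSE))
      txt <- lapply(seq_along(starts), function(s)
        strsplit(rawToChar(raw[starts[s]:ends[s]]), "\x14",
                 fixed = TRUE)[[1]])
      for (tl in txt) {
        # a TAL is onset[, duration] followed by annotation strings
        if (length(tl) < 2) next
        onset <- suppressWarnings(as.numeric(sub("\x15.*", "", tl[1])))
        code <- suppressWarnings(as.integer(tl[2]))
        if (!is.na(onset) && !is.na(code))
          events <- rbind(events,
                          data.frame(sample = as.integer(round(onset * fs)),
                                     code = code))
      }
    }
  }
  if (nrow(events) == 0)
    warning("no event annotations found; event table is empty")
  events <- events[order(events$sample), , drop = FALSE]
  rownames(events) <- NULL

  roles <- ifelse(grepl("EOG", labels[dataCh], ignore.case = TRUE),
                  "EOG", "EEG")
  new("RawRecording", data = X, fs = fs, channelLabels = labels[dataCh],
      channelRoles = roles, events = events)
}

#' Slice a continuous recording into labelled epochs
#'
#' One epoch per trial-onset event whose code appears in `classEventCodes`,
#' sliced `[start, end)` in half-open 0-based sample coordinates
#' (`sample index = floor(t * fs)` relative to the onset sample). Trials
#' whose window runs outside the recording are dropped and counted; events
#' with unknown codes are ignored with a message.
#'
#' @param rec a [RawRecording-class].
#' @param window numeric `(start_s, end_s)` relative to trial onset; the
#'   default 0–6 s gives the standard 1500-sample analysis window at 250 Hz,
#'   `c(2, 6)` restricts to the cue-to-end imagery interval.
#' @param classEventCodes named integer vector mapping class labels to event
#'   codes (default [miEventCodes()]).
#' @return an [EpochSet-class].
#' @export
epochRecording <- function(rec, window = c(0, 6),
                           classEventCodes = miEventCodes()) {
  stopifnot(is(rec, "RawRecording"))
  if (length(window) != 2 || diff(window) <= 0)
    stop("window must be an increasing (start, end) pair in seconds")
  if (!all(MI_CLASSES %in% names(classEventCodes)))
    stop("classEventCodes must name all four classes")
  fs <- rec@fs
  ev <- rec@events
  known <- ev$code %in% classEventCodes
  if (any(!known))
    message(sum(!known), " event(s) with unknown codes ignored")
  ev <- ev[known, , drop = FALSE]
  if (nrow(ev) == 0) stop("no trial-onset events with known class codes")

  i0 <- ev$sample + floor(window[1] * fs)
  i1 <- ev$sample + floor(window[2] * fs)   # exclusive
  ok <- i0 >= 0 & i1 <= ncol(rec@data)
  dropped <- sum(!ok)
  if (dropped > 0)
    message(dropped, " trial(s) dropped: window out of recording range")
  if (!any(ok)) stop("no usable trials: every epoch window is out of range")
  ev <- ev[ok, , drop = FALSE]; i0 <- i0[ok]; i1 <- i1[ok]

  len <- i1[1] - i0[1]
  arr <- array(0, c(nrow(ev), nrow(rec@data), len))
  for (tr in seq_len(nrow(ev)))
    arr[tr, , ] <- rec@data[, (i0[tr] + 1):i1[tr]]
  classOf <- names(classEventCodes)[match(ev$code, classEventCodes)]
  new("EpochSet", data = arr,
      labels = factor(classOf, levels = MI_CLASSES),
      fs = fs, window = as.numeric(window),
      channelLabels = rec@channelLabels, channelRoles = rec@channelRoles,
      dropped = as.integer(dropped))
}
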