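## WAV (RIFF) input/output and amplitude-envelope call segmentation.
## The reader/writer covers the two dialects used throughout: 16-bit integer
## PCM (format tag 1) and 32-bit IEEE float (format tag 3), mono or
## multichannel; multichannel input is averaged to mono (single-microphone
## field recordings).

#' Read a WAV file
#'
#' Reads a RIFF WAV file (16-bit PCM or 32-bit float), averages channels to
#' mono, and scales samples to the nominal -1..+1 range.
#'
#' @param path path to a `.wav` file.
#' @param label label to attach; defaults to the file name.
#' @return a [Waveform-class].
#' @seealso [writeWav()]
#' @export
readWav <- function(path, label = basename(path)) {
  if (!file.exists(path) || dir.exists(path))
    stopInput("cannot read WAV file: '", path, "' does not exist")
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stopInput("'", path, "' is not a RIFF/WAV file")
  readBin(con, "integer", 1L, 4L, endian = "little")  # chunk size
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stopInput("'", path, "' is not a WAV file")

  fmt <- NULL
  dataRaw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || !nzchar(id)) break
    size <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (length(size) == 0L) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audioFormat = sum(as.integer(body[1:2]) * c(1L, 256L)),
        nChannels   = sum(as.integer(body[3:4]) * c(1L, 256L)),
        sampleRate  = sum(as.integer(body[5:8]) * 256^(0:3)),
        bitsPerSample = sum(as.integer(body[15:16]) * c(1L, 256L)))
    } else if (identical(id, "data")) {
      dataRaw <- readBin(con, "raw", size)
    } else {
      seek(con, size + size %% 2L, origin = "current")
      next
    }
    if (size %% 2L) readBin(con, "raw", 1L)
    if (!is.null(fmt) && !is.null(dataRaw)) break
  }
  if (is.null(fmt) || is.null(dataRaw) || length(dataRaw) == 0L)
    stopInput("'", path, "' is unreadable or empty (missing fmt/data chunk)")

  x <- switch(as.character(fmt$audioFormat),
    "1" = {
      if (fmt$bitsPerSample != 16L)
        stopInput("'", path, "': only 16-bit PCM is supported, got ",
                  fmt$bitsPerSample, "-bit")
      readBin(dataRaw, "integer", length(dataRaw) %/% 2L, 2L,
              signed = TRUE, endian = "little") / 32768
    },
    "3" = {
      if (fmt$bitsPerSample != 32L)
        stopInput("'", path, "': only 32-bit float is supported, got ",
                  fmt$bitsPerSample, "-bit")
      readBin(dataRaw, "double", length(dataRaw) %/% 4L, 4L,
              endian = "little")
    },
    stopInput("'", path, "': unsupported WAV format tag ", fmt$audioFormat))

  if (fmt$nChannels > 1L) {
    n <- length(x) %/% fmt$nChannels
    x <- rowMeans(matrix(x[seq_len(n * fmt$nChannels)],
                         nrow = n, byrow = TRUE))
  }
  if (length(x) == 0L)
    stopInput("'", path, "' contains no samples")
  waveform(x, fmt$sampleRate, label)
}

#' Write a WAV file
#'
#' @param wave a [Waveform-class].
#' @param path output path.
#' @param encoding `"pcm16"` (16-bit integer PCM) or `"float32"`
#'   (bit-exact round trips).
#' @return `path`, invisibly.
#' @export
writeWav <- function(wave, path, encoding = c("pcm16", "float32")) {
  stopifnot(is(wave, "Waveform"))
  validObject(wave)
  encoding <- match.arg(encoding)
  x <- samples(wave)
  sr <- as.integer(round(sampleRate(wave)))
  bytesPer <- if (encoding == "pcm16") 2L else 4L
  dataSize <- length(x) * bytesPer
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stopInput("cannot write '", path, "': ",
                                                conditionMessage(e)))
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  fmtTag <- if (encoding == "pcm16") 1L else 3L
  writeBin(fmtTag, con, 2L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")                    # mono
  writeBin(sr, con, 4L, endian = "little")
  writeBin(sr * bytesPer, con, 4L, endian = "little")         # byte rate
  writeBin(bytesPer, con, 2L, endian = "little")              # block align
  writeBin(8L * bytesPer, con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, 4L, endian = "little")
  if (encoding == "pcm16") {
    q <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
    writeBin(q, con, 2L, endian = "little")
  } else {
    writeBin(x, con, 4L, endian = "little")
  }
  invisible(path)
}

#' Segment a recording into calls
#'
#' Detects call intervals as stretches where the smoothed amplitude envelope
#' exceeds a threshold relative to its peak. The envelope is the absolute
#' signal low-pass smoothed with a moving-average window; the threshold is
#' expressed in dB below the envelope peak, so segmentation is invariant to
#' global gain. Above-threshold runs separated by gaps shorter than
#' `minGap` are merged, and runs shorter than `minDur` are dropped.
#'
#' @param wave a [Waveform-class].
#' @param thresholdDb detection threshold in dB relative to the envelope
#'   peak (negative; default -25).
#' @param minGap gaps shorter than this (s) are merged.
#' @param minDur segments shorter than this (s) are dropped.
#' @param smoothWindow envelope smoothing window (s).
#' @return a data frame with columns `start_s`, `end_s` (possibly 0 rows),
#'   time-ordered and disjoint.
#' @export
segmentCalls <- function(wave, thresholdDb = -25, minGap = 0.05,
                         minDur = 0.03, smoothWindow = 0.005) {
  stopifnot(is(wave, "Waveform"), thresholdDb < 0, minGap >= 0, minDur >= 0)
  x <- abs(samples(wave))
  sr <- sampleRate(wave)
  w <- max(1L, as.integer(round(smoothWindow * sr)))
  env <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  env[is.na(env)] <- 0
  peak <- max(env)
  empty <- data.frame(start_s = numeric(), end_s = numeric())
  if (peak <= 0) return(empty)
  above <- env >= peak * dbToAmp(thresholdDb)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- cbind(starts[r$values], ends[r$values])
  if (nrow(seg) == 0L) return(empty)
  # merge gaps shorter than minGap
  gapSamp <- minGap * sr
  merged <- seg[1, , drop = FALSE]
  if (nrow(seg) > 1L) for (i in 2:nrow(seg)) {
    if (seg[i, 1] - merged[nrow(merged), 2] - 1L < gapSamp)
      merged[nrow(merged), 2] <- seg[i, 2]
    else merged <- rbind(merged, seg[i, ])
  }
  keep <- (merged[, 2] - merged[, 1] + 1L) >= minDur * sr
  merged <- merged[keep, , drop = FALSE]
  data.frame(start_s = (merged[, 1] - 1L) / sr, end_s = merged[, 2] / sr)
}

#' Extract one segment of a waveform
#'
#' @param wave a [Waveform-class].
#' @param start_s,end_s segment bounds in seconds.
#' @return a [Waveform-class] holding the segment.
#' @export
cropWaveform <- function(wave, start_s, end_s) {
  stopifnot(is(wave, "Waveform"), end_s > start_s)
  sr <- sampleRate(wave)
  i0 <- max(1L, as.integer(floor(start_s * sr)) + 1L)
  i1 <- min(length(samples(wave)), as.integer(ceiling(end_s * sr)))
  waveform(samples(wave)[i0:i1], sr, wave@label)
}
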