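# Signal builders and independent oracles shared across the tests.

sineWave <- function(freq, dur = 0.16, sr = 44100, amp = 0.9) {
  t <- (seq_len(round(dur * sr)) - 1) / sr
  waveform(amp * sin(2 * pi * freq * t), sr)
}

# sinusoid whose instantaneous frequency is an arbitrary function of time
fmWave <- function(freqFun, dur = 0.16, sr = 44100, amp = 0.9) {
  t <- (seq_len(round(dur * sr)) - 1) / sr
  f <- freqFun(t)
  waveform(amp * sin(2 * pi * cumsum(f) / sr), sr)
}

# direct-summation oracle for the eight spectrum descriptors; written
# independently of spectralDescriptors() (explicit loops, no shared code)
descriptorOracle <- function(freqs, mass) {
  m <- mass / sum(mass)
  modeF <- freqs[order(m, decreasing = TRUE)[1]]
  cum <- 0; q25 <- NA; q75 <- NA
  for (i in seq_along(m)) {
    cum <- cum + m[i]
    if (is.na(q25) && cum >= 0.25) q25 <- freqs[i]
    if (is.na(q75) && cum >= 0.75) q75 <- freqs[i]
  }
  cent <- 0
  for (i in seq_along(m)) cent <- cent + freqs[i] * m[i]
  v <- s3 <- s4 <- 0
  for (i in seq_along(m)) {
    d <- freqs[i] - cent
    v <- v + d^2 * m[i]; s3 <- s3 + d^3 * m[i]; s4 <- s4 + d^4 * m[i]
  }
  gm <- exp(sum(log(m)) / length(m))
  c(mode_freq = modeF, q25 = q25, q75 = q75, iqr = q75 - q25,
    centroid = cent, skewness = s3 / v^1.5, kurtosis = s4 / v^2,
    sfm = gm / mean(m))
}

# write an arbitrary 16-bit PCM WAV (any channel count / rate), bypassing
# the package writer; used to probe reader preconditions
writeRawPcmWav <- function(path, channelMatrix, sr) {
  x <- as.vector(t(channelMatrix))  # interleave
  nch <- ncol(channelMatrix)
  con <- file(path, "wb")
  on.exit(close(con))
  dataSize <- length(x) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")
  writeBin(as.integer(nch), con, 2L, endian = "little")
  writeBin(as.integer(sr), con, 4L, endian = "little")
  writeBin(as.integer(sr * 2L * nch), con, 4L, endian = "little")
  writeBin(as.integer(2L * nch), con, 2L, endian = "little")
  writeBin(16L, con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, 4L, endian = "little")
  writeBin(as.integer(pmax(-32768, pmin(32767, round(x * 32768)))), con,
           2L, endian = "little")
  invisible(path)
}

# a small two-species feature-table config for fast simulation tests
smallConfig <- function(model = defaultAllometryModel(), nAlligator = 10,
                        nNile = 10, callsMean = 5, callsSd = 2) {
  populationConfig(nPerSpecies = c(american_alligator = nAlligator,
                                   nile_crocodile = nNile),
                   model = model, callsMean = callsMean, callsSd = callsSd)
}

quietAnalyze <- function(trials)
  suppressWarnings(suppressMessages(analyzeCaptiveExperiment(trials)))
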