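## Frequency-spectrum descriptors: averaged short-time magnitude spectrum
## within an analysis band, and the eight spectrum-shape descriptors computed
## from it (mode, energy quartiles, interquartile range, centroid, skewness,
## kurtosis and spectral flatness).

#' Spectrum analysis settings
#'
#' @param fftWindow FFT window length in samples (power of two >= 64).
#' @param overlapFraction frame overlap in `[0, 1)`. The conventional
#'   analysis uses 0.99; values around 0.75 are spectrally near-equivalent
#'   for these descriptors and much cheaper.
#' @param bandLow,bandHigh analysis band in Hz (default 0--5000).
#' @return a `SpectrumConfig` list.
#' @export
spectrumConfig <- function(fftWindow = 1024L, overlapFraction = 0.99,
                           bandLow = 0, bandHigh = 5000) {
  if (!isCount(fftWindow) || fftWindow < 64 ||
      bitwAnd(as.integer(fftWindow), as.integer(fftWindow) - 1L) != 0L)
    stopInput("fftWindow must be a power of two >= 64")
  if (overlapFraction < 0 || overlapFraction >= 1)
    stopInput("overlapFraction must lie in [0, 1)")
  if (!(bandLow >= 0 && bandLow < bandHigh))
    stopInput("need 0 <= bandLow < bandHigh")
  structure(list(fftWindow = as.integer(fftWindow),
                 overlapFraction = overlapFraction,
                 bandLow = bandLow, bandHigh = bandHigh),
            class = "SpectrumConfig")
}

#' Averaged magnitude spectrum of a call
#'
#' Splits the waveform into Hann-windowed overlapping frames, averages the
#' frame magnitude spectra, restricts the result to the analysis band and
#' normalizes it to unit mass. The returned object is the probability-mass
#' view of the call's frequency spectrum on which [spectralDescriptors()]
#' operates.
#'
#' @param wave a [Waveform-class] at least one FFT window long.
#' @param config a [spectrumConfig()].
#' @return a `PowerSpectrum` list with fields `freqs` (Hz, ascending) and
#'   `mass` (non-negative, summing to one).
#' @export
meanSpectrum <- function(wave, config = spectrumConfig()) {
  stopifnot(is(wave, "Waveform"), inherits(config, "SpectrumConfig"))
  x <- samples(wave)
  sr <- sampleRate(wave)
  N <- config$fftWindow
  if (config$bandHigh > sr / 2)
    stopInput("bandHigh exceeds the Nyquist frequency (", sr / 2, " Hz)")
  if (length(x) < N)
    stopInput("call shorter than one FFT window (", length(x), " < ", N,
              " samples); zero-pad the call or use a smaller fftWindow")
  hop <- max(1L, as.integer(round(N * (1 - config$overlapFraction))))
  starts <- seq.int(1L, length(x) - N + 1L, by = hop)
  win <- hannWindow(N)
  nBins <- N %/% 2L + 1L
  acc <- numeric(nBins)
  # frames processed in blocks to bound memory at very high overlaps
  blockSize <- 4096L
  for (b in seq.int(1L, length(starts), by = blockSize)) {
    idx <- starts[b:min(length(starts), b + blockSize - 1L)]
    frames <- vapply(idx, function(i) x[i:(i + N - 1L)] * win, numeric(N))
    mag <- Mod(mvfft(frames))[seq_len(nBins), , drop = FALSE]
    acc <- acc + rowSums(mag)
  }
  spec <- acc / length(starts)
  freqs <- (seq_len(nBins) - 1L) * sr / N
  keep <- freqs >= config$bandLow & freqs <= config$bandHigh
  spec <- spec[keep]
  freqs <- freqs[keep]
  tot <- sum(spec)
  if (tot <= 0) stopInput("spectrum has no energy in the analysis band")
  structure(list(freqs = freqs, mass = spec / tot), class = "PowerSpectrum")
}

#' Construct a PowerSpectrum from explicit bins
#'
#' Mostly useful for tests and for descriptor computation on idealized
#' (line) spectra; mass is normalized to one.
#'
#' @param freqs bin frequencies in Hz, strictly increasing.
#' @param mass non-negative bin masses (any scale).
#' @return a `PowerSpectrum`.
#' @export
powerSpectrum <- function(freqs, mass) {
  stopifnot(length(freqs) == length(mass), length(freqs) >= 1L,
            all(is.finite(freqs)), all(is.finite(mass)), all(mass >= 0))
  if (length(freqs) > 1L && any(diff(freqs) <= 0))
    stopInput("freqs must be strictly increasing")
  if (sum(mass) <= 0) stopInput("mass must contain some energy")
  structure(list(freqs = freqs, mass = mass / sum(mass)),
            class = "PowerSpectrum")
}

#' The eight frequency-spectrum descriptors
#'
#' Computes, from a normalized call spectrum: the mode (frequency of maximal
#' energy), the first and third energy quartiles Q25 and Q75 (first frequency
#' at which cumulative mass reaches 0.25 / 0.75, no interpolation), their
#' difference IQR, the spectral centroid (mass-weighted mean frequency), the
#' skewness and kurtosis of the mass distribution over frequency (third and
#' fourth standardized central moments), and the spectral flatness sfm
#' (geometric over arithmetic mean of the bin magnitudes; near 1 for noise,
#' near 0 for a pure tone).
#'
#' A degenerate spectrum (all mass in one bin) has undefined moments;
#' skewness and kurtosis are returned as 0 by convention and the result is
#' flagged with `attr(, "degenerate")`.
#'
#' @param spectrum a `PowerSpectrum` from [meanSpectrum()] or
#'   [powerSpectrum()].
#' @return a named numeric vector with elements `mode_freq`, `q25`, `q75`,
#'   `iqr`, `centroid`, `skewness`, `kurtosis`, `sfm`.
#' @export
spectralDescriptors <- function(spectrum) {
  stopifnot(inherits(spectrum, "PowerSpectrum"))
  f <- spectrum$freqs
  m <- spectrum$mass
  modeFreq <- f[which.max(m)]
  cm <- cumsum(m)
  q25 <- f[which(cm >= 0.25 - 1e-12)[1L]]
  q75 <- f[which(cm >= 0.75 - 1e-12)[1L]]
  centroid <- sum(f * m)
  v <- sum((f - centroid)^2 * m)
  degenerate <- v <= (1e-12 * max(centroid, 1))^2
  if (degenerate) {
    skewness <- 0
    kurtosis <- 0
  } else {
    s <- sqrt(v)
    skewness <- sum((f - centroid)^3 * m) / s^3
    kurtosis <- sum((f - centroid)^4 * m) / s^4
  }
  # flatness on the magnitudes; the GM/AM ratio is invariant to the unit-mass
  # normalization, and any zero bin sends the geometric mean to zero
  sfm <- if (any(m == 0)) 0 else exp(mean(log(m))) / mean(m)
  out <- c(mode_freq = modeFreq, q25 = q25, q75 = q75, iqr = q75 - q25,
           centroid = centroid, skewness = skewness, kurtosis = kurtosis,
           sfm = sfm)
  attr(out, "degenerate") <- degenerate
  out
}
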