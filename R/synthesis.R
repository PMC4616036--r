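## Synthesis of experimental stimuli: frequency-modulated pure tones defined
## by their start/mean/end pitch, harmonic-stack call mimics with a spectral
## tilt, and assembly of playback series.

#' Design a piecewise-linear F0 contour from printed constraints
#'
#' The contour family is a two-segment piecewise-linear trajectory rising
#' from `fStart` to a peak at `peakTimeFraction * duration`, then descending
#' to `fEnd`. The peak frequency is solved in closed form so that the
#' time-average of the contour equals `fMean`: with peak fraction p, the
#' time-average is `(p*(fStart+fPeak) + (1-p)*(fPeak+fEnd))/2`, hence
#' `fPeak = 2*fMean - p*fStart - (1-p)*fEnd`. If the solved peak falls below
#' both endpoints the requested mean cannot be met by a rise-fall shape; the
#' contour falls back to a single linear segment from `fStart` to `fEnd`
#' (with a warning) and `achievedMean` records the attainable mean.
#'
#' @param fStart,fMean,fEnd contour anchors in Hz (> 0).
#' @param duration contour duration in seconds (> 0).
#' @param peakTimeFraction position of the peak, 0..1 (default 0.25; the
#'   early peak mirrors the rise-fall shape of natural juvenile calls).
#' @return a [ContourSpec-class].
#' @examples
#' designContour(630, 638, 350, 0.16)  # solved peak: 856 Hz
#' designContour(300, 384, 200, 0.16)  # solved peak: 543 Hz
#' @export
designContour <- function(fStart, fMean, fEnd, duration,
                          peakTimeFraction = 0.25) {
  stopifnot(fStart > 0, fEnd > 0, fMean > 0, duration > 0,
            peakTimeFraction >= 0, peakTimeFraction <= 1)
  p <- peakTimeFraction
  fPeak <- 2 * fMean - p * fStart - (1 - p) * fEnd
  if (fPeak <= 0)
    stopInput("requested mean pitch ", fMean,
              " Hz is infeasible for this contour family (solved peak <= 0)")
  shape <- "two_segment"
  achieved <- fMean
  if (fPeak < max(fStart, fEnd)) {
    shape <- "linear"
    achieved <- (fStart + fEnd) / 2
    fPeak <- max(fStart, fEnd)
    warning(sprintf(paste0("mean pitch %g Hz not achievable with a rise-fall",
                           " contour; falling back to a linear segment with",
                           " mean %g Hz"), fMean, achieved))
  }
  new("ContourSpec", fStart = fStart, fMean = fMean, fEnd = fEnd,
      fPeak = fPeak, duration = duration, peakTimeFraction = p,
      shape = shape, achievedMean = achieved)
}

#' Instantaneous frequency of a designed contour
#'
#' @param spec a [ContourSpec-class].
#' @param t times in seconds (0..duration); values are clamped to the
#'   contour support.
#' @return frequencies in Hz; exactly `fStart` at t = 0 and `fEnd` at
#'   t = duration.
#' @export
contourFrequency <- function(spec, t) {
  stopifnot(is(spec, "ContourSpec"))
  t <- pmin(pmax(t, 0), spec@duration)
  if (spec@shape == "linear")
    return(spec@fStart + (spec@fEnd - spec@fStart) * t / spec@duration)
  tp <- spec@peakTimeFraction * spec@duration
  ifelse(t <= tp,
         spec@fStart + if (tp > 0) (spec@fPeak - spec@fStart) * t / tp else 0,
         spec@fPeak + (spec@fEnd - spec@fPeak) * (t - tp) /
           (spec@duration - tp))
}

# raised-cosine onset/offset envelope
rampEnvelope <- function(n, nr) {
  env <- rep(1, n)
  if (nr > 0L) {
    ramp <- 0.5 - 0.5 * cos(pi * seq_len(nr) / nr)
    env[seq_len(nr)] <- ramp
    env[n + 1L - seq_len(nr)] <- ramp
  }
  env
}

# per-sample phase (radians) following a contour; trapezoidal integration of
# the instantaneous frequency
contourPhase <- function(spec, sampleRate) {
  n <- as.integer(round(spec@duration * sampleRate))
  t <- (seq_len(n) - 1L) / sampleRate
  f <- contourFrequency(spec, t)
  2 * pi * (cumsum(f) - f / 2 - f[1L] / 2) / sampleRate
}

#' Synthesize a frequency-modulated pure tone
#'
#' A sinusoid whose instantaneous frequency follows the designed contour
#' (phase is the cumulative integral of frequency, so there are no phase
#' discontinuities), with raised-cosine onset/offset ramps. The sample count
#' is exactly `round(duration * sampleRate)` so the duration is recoverable.
#'
#' @param spec a [ContourSpec-class].
#' @param sampleRate sample rate in Hz (default 44100).
#' @param amplitude peak amplitude, 0..1.
#' @param ramp_s onset/offset ramp length in seconds (must not exceed half
#'   the duration).
#' @param label label for the waveform.
#' @return a [Waveform-class].
#' @export
synthFMTone <- function(spec, sampleRate = 44100, amplitude = 0.9,
                        ramp_s = 0.005, label = "") {
  stopifnot(is(spec, "ContourSpec"), amplitude >= 0, amplitude <= 1)
  if (spec@fPeak >= sampleRate / 2)
    stopInput("contour peak ", spec@fPeak, " Hz reaches Nyquist")
  if (ramp_s > spec@duration / 2)
    stopInput("ramp_s exceeds half the stimulus duration")
  n <- as.integer(round(spec@duration * sampleRate))
  x <- amplitude * sin(contourPhase(spec, sampleRate)) *
    rampEnvelope(n, as.integer(round(ramp_s * sampleRate)))
  waveform(x, sampleRate, label)
}

#' Harmonic-call specification
#'
#' @param contour a [ContourSpec-class] for the fundamental.
#' @param nHarmonics number of harmonic partials (>= 1).
#' @param spectralTilt amplitude decay per harmonic step, in dB (0 = flat,
#'   negative = energy concentrated in low harmonics).
#' @param ramp_s onset/offset ramp in seconds.
#' @return a `HarmonicCallSpec` list.
#' @export
harmonicCallSpec <- function(contour, nHarmonics = 8L, spectralTilt = -6,
                             ramp_s = 0.005) {
  stopifnot(is(contour, "ContourSpec"), isCount(nHarmonics))
  structure(list(contour = contour, nHarmonics = as.integer(nHarmonics),
                 spectralTilt = spectralTilt, ramp_s = ramp_s),
            class = "HarmonicCallSpec")
}

#' Synthesize a harmonic-stack call mimic
#'
#' Sum of `nHarmonics` partials at integer multiples of the contour
#' frequency, with amplitudes decaying by `spectralTilt` dB per harmonic
#' step and a common raised-cosine envelope. With a single harmonic this
#' reduces exactly to [synthFMTone()].
#'
#' @param spec a [harmonicCallSpec()].
#' @param sampleRate sample rate in Hz.
#' @param amplitude peak-amplitude bound, 0..1.
#' @param label label for the waveform.
#' @return a [Waveform-class].
#' @export
synthHarmonicCall <- function(spec, sampleRate = 44100, amplitude = 0.9,
                              label = "") {
  stopifnot(inherits(spec, "HarmonicCallSpec"))
  contour <- spec$contour
  if (spec$nHarmonics * contour@fPeak >= sampleRate / 2)
    stopInput("highest harmonic (", spec$nHarmonics * contour@fPeak,
              " Hz) reaches Nyquist; reduce nHarmonics or the pitch")
  if (spec$ramp_s > contour@duration / 2)
    stopInput("ramp_s exceeds half the call duration")
  n <- as.integer(round(contour@duration * sampleRate))
  phase <- contourPhase(contour, sampleRate)
  amps <- dbToAmp(spec$spectralTilt * (seq_len(spec$nHarmonics) - 1L))
  x <- numeric(n)
  for (k in seq_len(spec$nHarmonics)) x <- x + amps[k] * sin(k * phase)
  x <- amplitude * x / sum(amps)
  x <- x * rampEnvelope(n, as.integer(round(spec$ramp_s * sampleRate)))
  waveform(x, sampleRate, label)
}

#' Assemble a playback series
#'
#' Concatenates `nCalls` copies of a call separated by silences of
#' `gap_s` plus a uniform jitter of up to `jitter_s` (seeded, reproducible).
#' Gaps that would become negative are clipped to zero with a warning.
#'
#' @param call a [Waveform-class].
#' @param nCalls number of call repetitions (>= 1).
#' @param gap_s nominal silence between calls in seconds.
#' @param jitter_s half-width of the uniform gap jitter in seconds.
#' @param seed integer seed for the jitter (NULL = current RNG stream).
#' @return a [Waveform-class] of duration
#'   `nCalls * duration(call) + sum(gaps)`.
#' @export
buildPlaybackSeries <- function(call, nCalls, gap_s = 2, jitter_s = 0,
                                seed = NULL) {
  stopifnot(is(call, "Waveform"), isCount(nCalls), gap_s >= 0, jitter_s >= 0)
  sr <- sampleRate(call)
  nGaps <- nCalls - 1L
  gaps <- withSeed(seed, gap_s + runif(nGaps, -jitter_s, jitter_s))
  if (nGaps > 0L && any(gaps < 0)) {
    warning("negative jittered gap clipped to 0 s")
    gaps <- pmax(gaps, 0)
  }
  pieces <- vector("list", 2L * nCalls - 1L)
  for (i in seq_len(nCalls)) {
    pieces[[2L * i - 1L]] <- samples(call)
    if (i <= nGaps) pieces[[2L * i]] <- numeric(round(gaps[i] * sr))
  }
  waveform(unlist(pieces), sr, call@label)
}

#' The three experimental stimulus designs
#'
#' Contour specifications of the synthetic playback signals: a
#' frequency-modulated pure tone pitched like a small juvenile's call
#' (`SYNTsmall`: start 630 Hz, mean 638 Hz, end 350 Hz, 160 ms), the same
#' tone pitched like a large juvenile's call (`SYNTlarge`: 300/384/200 Hz,
#' 160 ms) and an unmodulated 500 Hz control (`NOFM`, same duration).
#'
#' @return a named list of [ContourSpec-class] objects with elements
#'   `SYNTsmall`, `SYNTlarge`, `NOFM`.
#' @export
stimulusSpecs <- function() {
  list(SYNTsmall = designContour(630, 638, 350, 0.16),
       SYNTlarge = designContour(300, 384, 200, 0.16),
       NOFM      = designContour(500, 500, 500, 0.16))
}
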