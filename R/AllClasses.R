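#' Waveform: sampled mono audio
#'
#' Container for one call or stimulus: a dimensionless amplitude sequence
#' (nominal range -1..+1) with its sample rate. Sample rates below 10 kHz are
#' rejected because the 0--5 kHz analysis band must lie below Nyquist.
#'
#' @slot samples numeric vector of amplitudes.
#' @slot sampleRate sampling frequency in Hz (>= 10000).
#' @slot label free-text label.
#' @seealso [waveform()], [readWav()], [writeWav()]
#' @exportClass Waveform
setClass("Waveform",
  representation(samples = "numeric", sampleRate = "numeric",
                 label = "character"),
  prototype(samples = numeric(), sampleRate = 44100, label = ""))

setValidity("Waveform", function(object) {
  msg <- character()
  if (length(object@samples) < 1L)
    msg <- c(msg, "waveform must contain at least one sample")
  if (length(object@samples) && !all(is.finite(object@samples)))
    msg <- c(msg, "all samples must be finite")
  if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
      object@sampleRate < 10000)
    msg <- c(msg, "sample rate must be a single value >= 10000 Hz (the 5 kHz analysis band must be below Nyquist)")
  if (length(msg)) msg else TRUE
})

#' Construct a Waveform
#'
#' @param samples numeric amplitude vector (nominal range -1..+1).
#' @param sampleRate sample rate in Hz, >= 10000.
#' @param label optional free-text label.
#' @return a [Waveform-class] object.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 1, by = 1/44100)), 44100, "a4")
#' duration(w)
#' @export
waveform <- function(samples, sampleRate, label = "") {
  obj <- new("Waveform", samples = as.numeric(samples),
             sampleRate = as.numeric(sampleRate), label = as.character(label))
  validObject(obj)
  obj
}

#' PitchContour: a tracked fundamental-frequency trajectory
#'
#' Frame-wise F0 estimates at (strictly increasing) frame centre times, with a
#' voicing flag per frame. `callDuration` records the duration of the call the
#' contour was extracted from (NA for hand-built contours); it enables the
#' edge-extension used by [summarizeContour()].
#'
#' @slot times frame centre times in seconds, strictly increasing.
#' @slot f0 F0 per frame in Hz (NA where unvoiced).
#' @slot voiced logical voicing flag per frame.
#' @slot callDuration call duration in seconds, or NA.
#' @slot fmin,fmax the tracker search band in Hz.
#' @exportClass PitchContour
setClass("PitchContour",
  representation(times = "numeric", f0 = "numeric", voiced = "logical",
                 callDuration = "numeric", fmin = "numeric", fmax = "numeric"),
  prototype(callDuration = NA_real_, fmin = NA_real_, fmax = NA_real_))

setValidity("PitchContour", function(object) {
  msg <- character()
  n <- length(object@times)
  if (length(object@f0) != n || length(object@voiced) != n)
    msg <- c(msg, "times, f0 and voiced must have equal length")
  if (n > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  v <- object@voiced & !is.na(object@f0)
  if (any(object@voiced & is.na(object@f0)))
    msg <- c(msg, "voiced frames must carry an F0 value")
  if (!is.na(object@fmin) && !is.na(object@fmax) && any(v)) {
    f <- object@f0[v]
    if (any(f < object@fmin - 1e-6 | f > object@fmax + 1e-6))
      msg <- c(msg, "voiced F0 values must lie within [fmin, fmax]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PitchContour
#'
#' @param times frame centre times (s), strictly increasing.
#' @param f0 F0 values in Hz (NA allowed on unvoiced frames).
#' @param voiced logical voicing flags; defaults to `!is.na(f0)`.
#' @param callDuration duration (s) of the parent call, or NA.
#' @param fmin,fmax tracker search band (Hz), or NA.
#' @return a [PitchContour-class] object.
#' @export
pitchContour <- function(times, f0, voiced = !is.na(f0),
                         callDuration = NA_real_,
                         fmin = NA_real_, fmax = NA_real_) {
  obj <- new("PitchContour", times = as.numeric(times), f0 = as.numeric(f0),
             voiced = as.logical(voiced),
             callDuration = as.numeric(callDuration),
             fmin = as.numeric(fmin), fmax = as.numeric(fmax))
  validObject(obj)
  obj
}

#' ContourSpec: a piecewise-linear F0 trajectory design
#'
#' An F0 trajectory defined by its start, mean and end pitch and duration,
#' realized as a two-segment piecewise-linear contour that rises from
#' `fStart` to `fPeak` at `peakTimeFraction * duration` and then falls to
#' `fEnd`; `fPeak` is solved in closed form so that the time-average of the
#' contour equals `fMean`. When that solution would fall below both
#' endpoints the contour degenerates to a single linear segment
#' (`shape == "linear"`) and `achievedMean` records the attainable mean.
#'
#' @slot fStart,fMean,fEnd,fPeak frequencies in Hz.
#' @slot duration duration in seconds.
#' @slot peakTimeFraction position of the peak as a fraction of duration.
#' @slot shape `"two_segment"` or `"linear"`.
#' @slot achievedMean realized time-average of the contour in Hz.
#' @seealso [designContour()], [contourFrequency()], [synthFMTone()]
#' @exportClass ContourSpec
setClass("ContourSpec",
  representation(fStart = "numeric", fMean = "numeric", fEnd = "numeric",
                 fPeak = "numeric", duration = "numeric",
                 peakTimeFraction = "numeric", shape = "character",
                 achievedMean = "numeric"))

setValidity("ContourSpec", function(object) {
  msg <- character()
  for (s in c("fStart", "fMean", "fEnd", "fPeak", "duration"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)) ||
        slot(object, s) <= 0)
      msg <- c(msg, paste(s, "must be a single positive finite number"))
  if (length(object@peakTimeFraction) != 1L ||
      object@peakTimeFraction < 0 || object@peakTimeFraction > 1)
    msg <- c(msg, "peakTimeFraction must lie in [0, 1]")
  if (!object@shape %in% c("two_segment", "linear"))
    msg <- c(msg, "shape must be 'two_segment' or 'linear'")
  if (length(msg)) msg else TRUE
})

#' AcousticSpace: the two-dimensional PCA call space
#'
#' Result of a correlation-matrix PCA of the 13 call descriptors with the
#' first two components (acoustic dimensions AD1 and AD2) retained. The sign
#' convention is fixed so that the spectral centroid loads positively on AD1
#' and mean pitch positively on AD2; AD1 then reads as "wider / higher-energy
#' frequency band" and AD2 as "higher-pitched".
#'
#' @slot loadings orthonormal 13 x 2 rotation matrix.
#' @slot explainedVariance fraction of total variance per retained component.
#' @slot callScores per-call AD1/AD2 score matrix.
#' @slot individualScores per-individual mean AD1/AD2 scores (may be empty).
#' @slot center,scale the standardization applied to each descriptor.
#' @seealso [fitAcousticSpace()]
#' @exportClass AcousticSpace
setClass("AcousticSpace",
  representation(loadings = "matrix", explainedVariance = "numeric",
                 callScores = "matrix", individualScores = "matrix",
                 center = "numeric", scale = "numeric"))

setValidity("AcousticSpace", function(object) {
  msg <- character()
  if (ncol(object@loadings) != 2L)
    msg <- c(msg, "exactly two acoustic dimensions are retained")
  if (length(object@explainedVariance) != 2L ||
      any(object@explainedVariance <= 0) || any(object@explainedVariance > 1))
    msg <- c(msg, "explainedVariance must be two fractions in (0, 1]")
  if (length(object@explainedVariance) == 2L &&
      diff(object@explainedVariance) > 1e-12)
    msg <- c(msg, "AD1 must explain at least as much variance as AD2")
  if (length(msg)) msg else TRUE
})
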