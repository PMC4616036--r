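#' @name callometry-accessors
#' @title Accessors for callometry classes
#' @description Slot accessors for the S4 containers; user code should use
#'   these rather than `@`.
#' @param x an object.
#' @param object an object (for `show`).
NULL

#' @describeIn callometry-accessors amplitude samples of a Waveform.
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @describeIn callometry-accessors sample rate in Hz.
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @describeIn callometry-accessors duration in seconds.
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @export
#' @describeIn callometry-accessors samples of a Waveform.
setMethod("samples", "Waveform", function(x) x@samples)

#' @export
#' @describeIn callometry-accessors sample rate of a Waveform.
setMethod("sampleRate", "Waveform", function(x) x@sampleRate)

#' @export
#' @describeIn callometry-accessors duration of a Waveform.
setMethod("duration", "Waveform",
          function(x) length(x@samples) / x@sampleRate)

#' @export
#' @describeIn callometry-accessors design duration of a ContourSpec.
setMethod("duration", "ContourSpec", function(x) x@duration)

setMethod("show", "Waveform", function(object) {
  cat(sprintf("Waveform%s: %d samples @ %g Hz (%.3f s), peak %.3f\n",
              if (nzchar(object@label)) paste0(" '", object@label, "'") else "",
              length(object@samples), object@sampleRate,
              duration(object), max(abs(object@samples))))
})

setMethod("show", "PitchContour", function(object) {
  nv <- sum(object@voiced)
  cat(sprintf("PitchContour: %d frames (%d voiced)", length(object@times), nv))
  if (nv)
    cat(sprintf(", F0 %.0f-%.0f Hz", min(object@f0[object@voiced]),
                max(object@f0[object@voiced])))
  cat("\n")
})

setMethod("show", "ContourSpec", function(object) {
  cat(sprintf(paste0("ContourSpec (%s): start %.0f Hz, mean %.0f Hz, end %.0f Hz,",
                     " peak %.0f Hz @ %.0f%%, %.0f ms\n"),
              object@shape, object@fStart, object@fMean, object@fEnd,
              object@fPeak, 100 * object@peakTimeFraction,
              1000 * object@duration))
})

setMethod("show", "AcousticSpace", function(object) {
  cat(sprintf("AcousticSpace: %d calls, AD1 %.1f%% / AD2 %.1f%% of variance\n",
              nrow(object@callScores), 100 * object@explainedVariance[1],
              100 * object@explainedVariance[2]))
})

#' @describeIn callometry-accessors 13 x 2 orthonormal loading matrix.
#' @export
setGeneric("adLoadings", function(x) standardGeneric("adLoadings"))

#' @export
#' @describeIn callometry-accessors loadings of an AcousticSpace.
setMethod("adLoadings", "AcousticSpace", function(x) x@loadings)

#' @describeIn callometry-accessors per-call AD score matrix.
#' @export
setGeneric("callScores", function(x) standardGeneric("callScores"))

#' @export
#' @describeIn callometry-accessors call scores of an AcousticSpace.
setMethod("callScores", "AcousticSpace", function(x) x@callScores)

#' @describeIn callometry-accessors per-individual mean AD scores.
#' @export
setGeneric("individualScores", function(x) standardGeneric("individualScores"))

#' @export
#' @describeIn callometry-accessors individual scores of an AcousticSpace.
setMethod("individualScores", "AcousticSpace", function(x) x@individualScores)

#' @describeIn callometry-accessors fraction of variance per dimension.
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' @export
#' @describeIn callometry-accessors explained variance of an AcousticSpace.
setMethod("explainedVariance", "AcousticSpace",
          function(x) x@explainedVariance)

#' Component-correlation loadings of an acoustic space
#'
#' The orthonormal loadings rescaled by the component standard deviations,
#' i.e. the correlations between each (standardized) descriptor and each
#' acoustic dimension; this is the scale on which such loading tables are
#' conventionally reported.
#'
#' @param x an [AcousticSpace-class].
#' @return a 13 x 2 matrix of correlations.
#' @export
componentCorrelations <- function(x) {
  stopifnot(is(x, "AcousticSpace"))
  ev <- x@explainedVariance * nrow(x@loadings)
  sweep(x@loadings, 2L, sqrt(ev), `*`)
}
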