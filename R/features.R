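## Per-call descriptor extraction and feature-matrix assembly.

#' Compute the 13 call descriptors of one call
#'
#' Runs the spectral analysis ([meanSpectrum()] + [spectralDescriptors()])
#' and the pitch analysis ([extractF0Contour()] + [correctOctaveJumps()] +
#' [summarizeContour()]) on a single-call waveform and returns the 13
#' analysis variables in canonical order.
#'
#' @param wave a [Waveform-class] holding one call.
#' @param spectrum a [spectrumConfig()].
#' @param fmin,fmax,frame_s,hop_s,voicingThreshold tracker settings, see
#'   [extractF0Contour()].
#' @return named numeric vector of length 13 (`mean_pitch`, `start_pitch`,
#'   `max_pitch`, `min_pitch`, `end_pitch`, `mode_freq`, `q25`, `q75`,
#'   `iqr`, `centroid`, `skewness`, `kurtosis`, `sfm`).
#' @export
acousticFeatures <- function(wave, spectrum = spectrumConfig(),
                             fmin = 150, fmax = 1200, frame_s = 0.010,
                             hop_s = 0.005, voicingThreshold = 0.45) {
  stopifnot(is(wave, "Waveform"))
  sdesc <- spectralDescriptors(meanSpectrum(wave, spectrum))
  contour <- correctOctaveJumps(
    extractF0Contour(wave, fmin = fmin, fmax = fmax, frame_s = frame_s,
                     hop_s = hop_s, voicingThreshold = voicingThreshold))
  pit <- summarizeContour(contour)
  out <- c(pit, sdesc)[featureNames()]
  attr(out, "degenerate") <- attr(sdesc, "degenerate")
  out
}

#' Assemble the call-by-descriptor feature matrix
#'
#' Aligns a collection of calls with their metadata and extracts the 13
#' descriptors per call. Calls whose extraction fails (e.g. unvoiced calls)
#' are dropped with a message and recorded in the `exclusions` attribute;
#' calls with no matching metadata row, or duplicate metadata ids, are
#' errors.
#'
#' @param calls named list of [Waveform-class] objects; names are call ids.
#' @param metadata data frame with one row per call id: columns `call_id`,
#'   `individual_id`, `species`, `body_length_cm`.
#' @param ... passed to [acousticFeatures()].
#' @return a list with `features` (matrix, one row per retained call),
#'   `covariates` (aligned data frame) and attribute-style `exclusions`
#'   data frame (`call_id`, `reason`).
#' @export
assembleFeatureMatrix <- function(calls, metadata, ...) {
  if (is.null(names(calls)) || any(!nzchar(names(calls))))
    stopInput("calls must be a named list (names are call ids)")
  need <- c("call_id", "individual_id", "species", "body_length_cm")
  missing <- setdiff(need, names(metadata))
  if (length(missing))
    stopInput("metadata lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(metadata$call_id))
    stopInput("duplicate metadata call id(s): ",
              paste(unique(metadata$call_id[duplicated(metadata$call_id)]),
                    collapse = ", "))
  orphans <- setdiff(names(calls), metadata$call_id)
  if (length(orphans))
    stopInput("call(s) without metadata: ", paste(orphans, collapse = ", "))

  feats <- list()
  keep <- character()
  excl <- list()
  for (id in names(calls)) {
    row <- tryCatch(acousticFeatures(calls[[id]], ...),
                    error = function(e) e)
    if (inherits(row, "error")) {
      message("excluding call '", id, "': ", conditionMessage(row))
      excl[[length(excl) + 1L]] <- data.frame(call_id = id,
                                              reason = conditionMessage(row))
    } else {
      feats[[length(feats) + 1L]] <- row
      keep <- c(keep, id)
    }
  }
  if (!length(feats)) stopInput("no call could be analysed")
  features <- do.call(rbind, feats)
  rownames(features) <- keep
  covariates <- metadata[match(keep, metadata$call_id), , drop = FALSE]
  rownames(covariates) <- keep
  out <- list(features = features, covariates = covariates,
              exclusions = if (length(excl)) do.call(rbind, excl)
                           else data.frame(call_id = character(),
                                           reason = character()))
  out
}
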