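## Seeded generator of size-graded synthetic call populations: the stand-in
## for the study's undeposited recordings. Individuals get a species, a body
## length and an individual-level acoustic offset; each call draws
## call-level noise, builds a pitch contour whose mean follows the species
## allometry, and sets the harmonic spectral tilt so that the call's
## spectral centroid follows the centroid allometry. The same per-call
## ground-truth parameters drive two rendering paths: full audio synthesis
## (synthHarmonicCall) and a fast analytic path that computes the 13
## descriptors directly from the idealized contour and harmonic line
## spectrum.

#' Sample a roster of individuals
#'
#' Body lengths are drawn uniformly over `sizeRange`, independently per
#' individual, seeded and reproducible.
#'
#' @param nPerSpecies named integer vector: individuals per species.
#' @param sizeRange total body length range in cm (default 20--120); a
#'   named list of per-species ranges is also accepted.
#' @param seed integer seed (NULL = current RNG stream).
#' @return data frame with `individual_id`, `species`, `body_length_cm`.
#' @examples
#' sampleIndividuals(c(nile_crocodile = 3), seed = 1)
#' @export
sampleIndividuals <- function(nPerSpecies, sizeRange = c(20, 120),
                              seed = NULL) {
  if (is.null(names(nPerSpecies)) || any(!nzchar(names(nPerSpecies))))
    stopInput("nPerSpecies must be a named vector")
  if (any(nPerSpecies < 1)) stopInput("need at least one individual per species")
  withSeed(seed, {
    rows <- lapply(names(nPerSpecies), function(sp) {
      rng <- if (is.list(sizeRange)) sizeRange[[sp]] else sizeRange
      if (is.null(rng) || length(rng) != 2L || rng[1] > rng[2])
        stopInput("invalid size range for species '", sp, "'")
      n <- nPerSpecies[[sp]]
      data.frame(species = sp,
                 body_length_cm = runif(n, rng[1], rng[2]))
    })
    out <- do.call(rbind, rows)
    out$individual_id <- sprintf("ind%03d", seq_len(nrow(out)))
    out[c("individual_id", "species", "body_length_cm")]
  })
}

# centroid (Hz) of a K-harmonic stack at fundamental f0 with tilt dB/harmonic
stackCentroid <- function(tilt, f0, K) {
  k <- seq_len(K)
  a <- dbToAmp(tilt * (k - 1))
  f0 * sum(k * a) / sum(a)
}

# solve the spectral tilt so the stack centroid matches a target; targets
# outside the attainable range are clamped to it
solveTilt <- function(f0, K, targetCentroid, range = c(-30, 12)) {
  lo <- stackCentroid(range[1], f0, K)
  hi <- stackCentroid(range[2], f0, K)
  target <- min(max(targetCentroid, lo * 1.001), hi * 0.999)
  uniroot(function(tl) stackCentroid(tl, f0, K) - target,
          interval = range, tol = 1e-6)$root
}

# ground-truth parameters for one call of one individual. indOffsets is a
# list(pitch=, centroid=) of individual-level offsets; call-level noise is
# drawn from the current RNG stream.
callParams <- function(individual, model, indOffsets) {
  fMean <- model$pitchIntercepts[[individual$species]] +
    model$slopePitch * individual$body_length_cm +
    indOffsets$pitch + rnorm(1, 0, model$callSdPitch)
  centTarget <- model$centroidIntercepts[[individual$species]] +
    model$slopeCentroid * individual$body_length_cm +
    indOffsets$centroid + rnorm(1, 0, model$callSdCentroid)
  if (!is.finite(fMean) || fMean <= 50)
    stopInput("generated mean pitch (", round(fMean),
              " Hz) is out of range; check model parameters")
  jit <- function(x) x * exp(rnorm(1, 0, model$shapeJitterSd))
  endRatio <- min(0.99, jit(model$endRatio))
  peakFrac <- min(0.6, max(0.02, jit(model$peakTimeFraction)))
  # keep the rise-fall design solvable: peak >= start requires
  # startRatio <= (2 - (1-p) * endRatio) / (1 + p) in units of the mean
  startRatio <- max(1.01, min(jit(model$startRatio),
                              0.995 * (2 - (1 - peakFrac) * endRatio) /
                                (1 + peakFrac)))
  contour <- designContour(startRatio * fMean, fMean, endRatio * fMean,
                           model$callDuration, peakFrac)
  K <- max(3L, min(as.integer(floor(model$bandHigh / fMean)), 20L))
  tilt <- solveTilt(fMean, K, centTarget)
  list(contour = contour, nHarmonics = K, tilt = tilt,
       targetCentroid = centTarget, fMean = fMean)
}

# analytic 13-descriptor vector for one call's ground-truth parameters;
# spectral descriptors come from the idealized harmonic line spectrum,
# pitch descriptors from the contour anchors. Multiplicative measurement
# noise (model$measurementCv) is drawn from the current RNG stream.
analyticFeatures <- function(params, model) {
  contour <- params$contour
  k <- seq_len(params$nHarmonics)
  amps <- dbToAmp(params$tilt * (k - 1))
  spec <- powerSpectrum(k * params$fMean, amps)
  sdesc <- spectralDescriptors(spec)
  pit <- c(mean_pitch = contour@achievedMean,
           start_pitch = contour@fStart,
           max_pitch = max(contour@fPeak, contour@fStart, contour@fEnd),
           min_pitch = min(contour@fStart, contour@fEnd),
           end_pitch = contour@fEnd)
  feats <- c(pit, sdesc)[featureNames()]
  noise <- exp(rnorm(length(feats), 0, model$measurementCv))
  feats <- feats * noise
  # restore the exact identities the descriptors obey
  if (feats["q25"] > feats["q75"])
    feats[c("q25", "q75")] <- feats[c("q75", "q25")]
  feats["iqr"] <- feats[["q75"]] - feats[["q25"]]
  feats["sfm"] <- min(max(feats[["sfm"]], 0), 1)
  feats["max_pitch"] <- max(feats[["max_pitch"]], feats[["start_pitch"]],
                            feats[["end_pitch"]], feats[["mean_pitch"]])
  feats["min_pitch"] <- min(feats[["min_pitch"]], feats[["start_pitch"]],
                            feats[["end_pitch"]], feats[["mean_pitch"]])
  feats
}

#' Generate one synthetic call
#'
#' Draws call-level noise, builds the call's contour and spectral tilt from
#' the individual's allometry, and renders the audio via
#' [synthHarmonicCall()].
#'
#' @param individual one row of a [sampleIndividuals()] roster (list or
#'   single-row data frame with `species` and `body_length_cm`).
#' @param model an `AllometryModel`.
#' @param indOffsets individual-level offsets, `list(pitch=, centroid=)`;
#'   zero by default. Draw once per individual to induce the
#'   individual-level random effect.
#' @param sampleRate audio sample rate.
#' @param seed optional seed for this call's noise.
#' @return list with `waveform` ([Waveform-class]) and `truth` (one-row
#'   data frame of realized contour and tilt parameters).
#' @export
generateCall <- function(individual, model,
                         indOffsets = list(pitch = 0, centroid = 0),
                         sampleRate = 44100, seed = NULL) {
  validateAllometryModel(model)
  if (!individual$species %in% model$species)
    stopInput("unknown species '", individual$species, "'")
  withSeed(seed, {
    params <- callParams(individual, model, indOffsets)
    wav <- synthHarmonicCall(
      harmonicCallSpec(params$contour, params$nHarmonics, params$tilt),
      sampleRate = sampleRate)
    truth <- data.frame(
      individual_id = if (!is.null(individual$individual_id))
        individual$individual_id else NA_character_,
      species = individual$species,
      body_length_cm = individual$body_length_cm,
      f_start = params$contour@fStart, f_mean = params$contour@achievedMean,
      f_end = params$contour@fEnd, f_peak = params$contour@fPeak,
      peak_time_fraction = params$contour@peakTimeFraction,
      n_harmonics = params$nHarmonics, tilt_db = params$tilt,
      target_centroid = params$targetCentroid)
    list(waveform = wav, truth = truth)
  })
}

validatePopulationConfig <- function(config) {
  required <- c("nPerSpecies", "model")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stopInput("population config is missing key(s): ",
              paste(missing, collapse = ", "))
  if (is.null(names(config$nPerSpecies)))
    stopInput("population config: nPerSpecies must be named by species")
  bad <- setdiff(names(config$nPerSpecies), config$model$species)
  if (length(bad))
    stopInput("population config: species not in model: ",
              paste(bad, collapse = ", "))
  config$sizeRange <- config$sizeRange %||% c(20, 120)
  config$callsMean <- config$callsMean %||% 15
  config$callsSd <- config$callsSd %||% 5
  config$sampleRate <- config$sampleRate %||% 44100
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Population configuration
#'
#' @param nPerSpecies named vector of individuals per species. The default
#'   mirrors the recorded study sample (76 American alligators, 60 Nile
#'   crocodiles, 9 spectacled caimans, 5 Morelet's and 14 Orinoco
#'   crocodiles).
#' @param model an `AllometryModel`.
#' @param sizeRange body length range in cm: a single range applied to all
#'   species or a named per-species list. The default reproduces the
#'   recorded per-species ranges (alligator 24--113, Nile 26--118, caiman
#'   25--60, Morelet's 51--61, Orinoco 30--100 cm).
#' @param callsMean,callsSd the per-individual call count is drawn from a
#'   rounded normal with this mean and SD, truncated to 1..20 (the study
#'   selected 1--20 calls per individual, mean 15 +- 5).
#' @param sampleRate audio sample rate.
#' @return a validated config list.
#' @export
populationConfig <- function(nPerSpecies = c(american_alligator = 76,
                                             nile_crocodile = 60,
                                             spectacled_caiman = 9,
                                             morelets_crocodile = 5,
                                             orinoco_crocodile = 14),
                             model = defaultAllometryModel(),
                             sizeRange = list(
                               american_alligator = c(24, 113),
                               nile_crocodile = c(26, 118),
                               spectacled_caiman = c(25, 60),
                               morelets_crocodile = c(51, 61),
                               orinoco_crocodile = c(30, 100)),
                             callsMean = 15, callsSd = 5,
                             sampleRate = 44100) {
  validatePopulationConfig(list(nPerSpecies = nPerSpecies, model = model,
                                sizeRange = sizeRange, callsMean = callsMean,
                                callsSd = callsSd, sampleRate = sampleRate))
}

#' Generate a synthetic call dataset
#'
#' Samples a roster, draws per-individual call counts (truncated to 1..20)
#' and individual-level acoustic offsets, and generates every call. With
#' `audio = TRUE` and an output directory, per-call WAV files are written
#' together with `metadata.csv` (individual_id, species, body_length_cm,
#' wav_path) and `ground_truth.csv`; with `audio = FALSE` only the
#' ground-truth table (plus analytic features, see
#' [simulateFeatureTable()]) is produced, which is orders of magnitude
#' faster and is the path used for large simulation studies.
#'
#' @param config a [populationConfig()].
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of (config, seed).
#' @param audio render audio for every call.
#' @param dir output directory for WAV files (required when `audio = TRUE`
#'   and `writeFiles = TRUE`).
#' @param writeFiles write WAV/CSV outputs to `dir`.
#' @return list with `truth` (per-call ground truth), `metadata` (per-call
#'   metadata incl. `wav_path` when files are written), and `waveforms`
#'   (list of [Waveform-class], NULL when `audio = FALSE`).
#' @export
generateDataset <- function(config = populationConfig(), seed = 1,
                            audio = TRUE, dir = NULL, writeFiles = !is.null(dir)) {
  config <- validatePopulationConfig(config)
  validateAllometryModel(config$model)
  if (isTRUE(writeFiles)) {
    if (is.null(dir)) stopInput("writeFiles = TRUE needs an output dir")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  }
  withSeed(seed, {
    roster <- sampleIndividuals(config$nPerSpecies, config$sizeRange)
    truthRows <- list()
    waveforms <- if (audio) list() else NULL
    meta <- list()
    for (i in seq_len(nrow(roster))) {
      ind <- roster[i, ]
      nCalls <- min(20L, max(1L, as.integer(round(
        rnorm(1, config$callsMean, config$callsSd)))))
      offsets <- list(
        pitch = rnorm(1, 0, config$model$individualSdPitch),
        centroid = rnorm(1, 0, config$model$individualSdCentroid))
      for (j in seq_len(nCalls)) {
        params <- callParams(ind, config$model, offsets)
        row <- data.frame(
          individual_id = ind$individual_id, species = ind$species,
          body_length_cm = ind$body_length_cm, call_index = j,
          f_start = params$contour@fStart,
          f_mean = params$contour@achievedMean,
          f_end = params$contour@fEnd, f_peak = params$contour@fPeak,
          peak_time_fraction = params$contour@peakTimeFraction,
          n_harmonics = params$nHarmonics, tilt_db = params$tilt,
          target_centroid = params$targetCentroid)
        truthRows[[length(truthRows) + 1L]] <- row
        wavPath <- NA_character_
        if (audio) {
          wav <- synthHarmonicCall(
            harmonicCallSpec(params$contour, params$nHarmonics, params$tilt),
            sampleRate = config$sampleRate,
            label = paste0(ind$individual_id, "_call", j))
          if (isTRUE(writeFiles)) {
            wavPath <- file.path(dir, sprintf("%s_call%02d.wav",
                                              ind$individual_id, j))
            writeWav(wav, wavPath)
          } else {
            waveforms[[length(waveforms) + 1L]] <- wav
          }
        }
        meta[[length(meta) + 1L]] <- data.frame(
          individual_id = ind$individual_id, species = ind$species,
          body_length_cm = ind$body_length_cm, call_index = j,
          wav_path = wavPath)
      }
    }
    truth <- do.call(rbind, truthRows)
    metadata <- do.call(rbind, meta)
    if (isTRUE(writeFiles)) {
      write.csv(truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
      write.csv(metadata, file.path(dir, "metadata.csv"), row.names = FALSE)
    }
    list(truth = truth, metadata = metadata, waveforms = waveforms)
  })
}

#' Simulate a call-feature table without audio rendering
#'
#' The fast simulation path: generates the same population as
#' [generateDataset()] but computes the 13 descriptors analytically from
#' each call's ground-truth contour and harmonic line spectrum (plus a small
#' multiplicative measurement noise), skipping synthesis and signal
#' analysis. Used for replicate-heavy studies (type-I error, power,
#' parameter recovery).
#'
#' @param config a [populationConfig()].
#' @param seed integer seed.
#' @return data frame with `individual_id`, `species`, `body_length_cm`,
#'   `call_index` and the 13 descriptor columns.
#' @export
simulateFeatureTable <- function(config = populationConfig(), seed = 1) {
  config <- validatePopulationConfig(config)
  validateAllometryModel(config$model)
  withSeed(seed, {
    roster <- sampleIndividuals(config$nPerSpecies, config$sizeRange)
    rows <- vector("list", nrow(roster))
    for (i in seq_len(nrow(roster))) {
      ind <- roster[i, ]
      nCalls <- min(20L, max(1L, as.integer(round(
        rnorm(1, config$callsMean, config$callsSd)))))
      offsets <- list(
        pitch = rnorm(1, 0, config$model$individualSdPitch),
        centroid = rnorm(1, 0, config$model$individualSdCentroid))
      feats <- matrix(NA_real_, nCalls, 13L,
                      dimnames = list(NULL, featureNames()))
      for (j in seq_len(nCalls)) {
        params <- callParams(ind, config$model, offsets)
        feats[j, ] <- analyticFeatures(params, config$model)
      }
      rows[[i]] <- cbind(
        data.frame(individual_id = ind$individual_id, species = ind$species,
                   body_length_cm = ind$body_length_cm,
                   call_index = seq_len(nCalls)),
        as.data.frame(feats))
    }
    do.call(rbind, rows)
  })
}
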