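## Orchestration layer: file-based entry points tying the stages together.
## Each function reads/writes standard CSV/JSON/WAV artifacts and is a thin
## deterministic wrapper over the analysis functions; inst/cli/callometry.R
## exposes them as shell subcommands.

readConfigFile <- function(path) {
  if (is.null(path)) return(list())
  if (!file.exists(path)) stopInput("config file '", path, "' not found")
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

logMsg <- function(...) message("[callometry] ", ...)

#' Synthesize the experimental stimuli to WAV files
#'
#' Writes one WAV per stimulus. By default the three standard designs
#' ([stimulusSpecs()]) are produced; a config file (YAML or JSON) may
#' instead define stimuli as a list of entries with keys `name`,
#' `f_start_hz`, `f_mean_hz`, `f_end_hz`, `duration_s` and optional
#' `peak_time_fraction`.
#'
#' @param outDir output directory (created if needed).
#' @param configFile optional YAML/JSON stimulus definition file.
#' @param sampleRate sample rate in Hz.
#' @return named character vector of written paths, invisibly.
#' @export
runStimulusSynthesis <- function(outDir, configFile = NULL,
                                 sampleRate = 44100) {
  cfg <- readConfigFile(configFile)
  specs <- if (!is.null(cfg$stimuli)) {
    stims <- cfg$stimuli
    if (is.data.frame(stims)) stims <- split(stims, seq_len(nrow(stims)))
    out <- lapply(stims, function(s) {
      need <- c("name", "f_start_hz", "f_mean_hz", "f_end_hz", "duration_s")
      missing <- setdiff(need, names(s))
      if (length(missing))
        stopInput("stimulus entry lacks key(s): ",
                  paste(missing, collapse = ", "))
      designContour(s$f_start_hz, s$f_mean_hz, s$f_end_hz, s$duration_s,
                    s$peak_time_fraction %||% 0.25)
    })
    names(out) <- vapply(stims, function(s) s$name, character(1))
    out
  } else stimulusSpecs()
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(specs), function(nm) {
    wav <- synthFMTone(specs[[nm]], sampleRate = sampleRate, label = nm)
    p <- file.path(outDir, paste0(nm, ".wav"))
    writeWav(wav, p)
    p
  }, character(1))
  logMsg("wrote ", length(paths), " stimulus file(s) to ", outDir)
  invisible(paths)
}

#' Simulate a synthetic call dataset to disk
#'
#' Runs [generateDataset()] with audio rendering and writes WAVs,
#' `metadata.csv` and `ground_truth.csv` under `outDir`.
#'
#' @param outDir output directory.
#' @param configFile optional YAML/JSON file overriding
#'   [populationConfig()] entries (`nPerSpecies`, `sizeRange`, `callsMean`,
#'   `callsSd`, `sampleRate`).
#' @param seed integer seed.
#' @return the [generateDataset()] result, invisibly.
#' @export
runSimulation <- function(outDir, configFile = NULL, seed = 1) {
  cfg <- readConfigFile(configFile)
  base <- populationConfig()
  if (!is.null(cfg$nPerSpecies))
    base$nPerSpecies <- unlist(cfg$nPerSpecies)
  for (key in c("sizeRange", "callsMean", "callsSd", "sampleRate"))
    if (!is.null(cfg[[key]])) base[[key]] <- unlist(cfg[[key]])
  base <- validatePopulationConfig(base)
  logMsg("simulating ", sum(base$nPerSpecies), " individuals (seed ", seed, ")")
  res <- generateDataset(base, seed = seed, audio = TRUE, dir = outDir,
                         writeFiles = TRUE)
  logMsg("wrote ", nrow(res$metadata), " calls to ", outDir)
  invisible(res)
}

#' Extract the 13 descriptors for a directory of call WAVs
#'
#' Reads `metadataCsv` (columns `individual_id`, `species`,
#' `body_length_cm`, `wav_path`; an optional `call_id` column defaults to
#' the WAV base name), analyses each call and writes one CSV row per call.
#' Failed calls are excluded with a logged reason.
#'
#' @param metadataCsv path to the metadata CSV; relative `wav_path` entries
#'   are resolved against its directory.
#' @param outCsv output features CSV path.
#' @param segment segment each file with [segmentCalls()] and analyse the
#'   longest segment (for recordings that are not pre-trimmed).
#' @param ... passed to [acousticFeatures()].
#' @return the feature data frame, invisibly.
#' @export
runFeatureExtraction <- function(metadataCsv, outCsv, segment = FALSE, ...) {
  if (!file.exists(metadataCsv))
    stopInput("metadata file '", metadataCsv, "' not found")
  meta <- read.csv(metadataCsv, stringsAsFactors = FALSE)
  need <- c("individual_id", "species", "body_length_cm", "wav_path")
  missing <- setdiff(need, names(meta))
  if (length(missing))
    stopInput("metadata lacks column(s): ", paste(missing, collapse = ", "))
  if (is.null(meta$call_id))
    meta$call_id <- sub("\\.wav$", "", basename(meta$wav_path),
                        ignore.case = TRUE)
  root <- dirname(metadataCsv)
  rows <- list()
  for (i in seq_len(nrow(meta))) {
    p <- meta$wav_path[i]
    if (!file.exists(p)) p <- file.path(root, meta$wav_path[i])
    feats <- tryCatch({
      wav <- readWav(p)
      if (segment) {
        seg <- segmentCalls(wav)
        if (nrow(seg) == 0L) stopInput("no call detected")
        longest <- which.max(seg$end_s - seg$start_s)
        wav <- cropWaveform(wav, seg$start_s[longest], seg$end_s[longest])
      }
      acousticFeatures(wav, ...)
    }, error = function(e) e)
    if (inherits(feats, "error")) {
      logMsg("excluding '", meta$call_id[i], "': ", conditionMessage(feats))
      next
    }
    rows[[length(rows) + 1L]] <- cbind(
      meta[i, c("call_id", "individual_id", "species", "body_length_cm")],
      as.data.frame(as.list(feats)))
  }
  if (!length(rows)) stopInput("no call could be analysed")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  write.csv(out, outCsv, row.names = FALSE)
  logMsg("wrote ", nrow(out), " feature row(s) to ", outCsv)
  invisible(out)
}

#' Run the size-coding analysis on a features CSV
#'
#' Fits the acoustic space, runs the mixed-model likelihood-ratio tests for
#' size, species and their interaction on both acoustic dimensions and,
#' when exactly two species dominate the data (or `compareSpecies` is
#' given), the per-species mean-pitch and centroid regressions with line
#' comparison. Writes `loadings.csv` (component correlations),
#' `scores.csv` and `results.json` under `outDir`.
#'
#' @param featuresCsv features CSV as written by [runFeatureExtraction()]
#'   (or [simulateFeatureTable()] saved to CSV).
#' @param outDir output directory.
#' @param compareSpecies optional character vector of exactly two species
#'   for the regression line comparison.
#' @return list with `space`, `tests`, `lineComparisons`, invisibly.
#' @export
runSizeAnalysis <- function(featuresCsv, outDir, compareSpecies = NULL) {
  if (!file.exists(featuresCsv))
    stopInput("features file '", featuresCsv, "' not found")
  feats <- read.csv(featuresCsv, stringsAsFactors = FALSE)
  need <- c("individual_id", "species", "body_length_cm", featureNames())
  missing <- setdiff(need, names(feats))
  if (length(missing))
    stopInput("features lack column(s): ", paste(missing, collapse = ", "))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  space <- fitAcousticSpace(feats, individual = feats$individual_id)
  tests <- testSizeEffect(callScores(space), feats$body_length_cm,
                          feats$species, feats$individual_id)
  lineComparisons <- NULL
  if (!is.null(compareSpecies)) {
    if (length(compareSpecies) != 2L)
      stopInput("compareSpecies must name exactly two species")
    indMeans <- stats::aggregate(
      feats[c("mean_pitch", "centroid", "body_length_cm")],
      by = list(individual_id = feats$individual_id,
                species = feats$species), FUN = mean)
    sub <- indMeans[indMeans$species %in% compareSpecies, ]
    lineComparisons <- list(
      mean_pitch = regressAndCompareLines(sub$mean_pitch,
                                          sub$body_length_cm, sub$species),
      centroid = regressAndCompareLines(sub$centroid,
                                        sub$body_length_cm, sub$species))
  }
  write.csv(data.frame(descriptor = rownames(adLoadings(space)),
                       componentCorrelations(space)),
            file.path(outDir, "loadings.csv"), row.names = FALSE)
  write.csv(data.frame(call_id = feats$call_id %||% seq_len(nrow(feats)),
                       individual_id = feats$individual_id,
                       callScores(space)),
            file.path(outDir, "scores.csv"), row.names = FALSE)
  resultsOut <- list(
    explained_variance = explainedVariance(space),
    tests = tests)
  if (!is.null(lineComparisons))
    resultsOut$line_comparisons <- lapply(lineComparisons, function(lc)
      list(perSpecies = lc$perSpecies,
           slope_t = lc$slopeTest$t, slope_p = lc$slopeTest$p,
           intercept_t = lc$interceptTest$t,
           intercept_p = lc$interceptTest$p))
  jsonlite::write_json(resultsOut, file.path(outDir, "results.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  logMsg("size analysis written to ", outDir)
  invisible(list(space = space, tests = tests,
                 lineComparisons = lineComparisons))
}

#' Run the playback analysis on a trials CSV
#'
#' Auto-detects the trial format: captive triplets (columns `orientation`,
#' `n_approaching`, `max_approach`) are collapsed into the PCA composite
#' score; field observations (columns `approach_fraction` / `retreat_m`,
#' empty where absent) are coded on the -2..+2 intensity scale. Mixing both
#' formats in one file is an error. The stimulus effect is then tested with
#' the mixed-model LRT, followed (>= 3 categories) by post-hoc pairwise
#' comparisons; results go to a JSON file.
#'
#' @param trialsCsv trials CSV with `unit_id`, `stimulus`, `order_index`
#'   plus the format-specific columns.
#' @param outJson output JSON path.
#' @return the results list, invisibly.
#' @export
runPlaybackAnalysis <- function(trialsCsv, outJson) {
  if (!file.exists(trialsCsv))
    stopInput("trials file '", trialsCsv, "' not found")
  trials <- read.csv(trialsCsv, stringsAsFactors = FALSE)
  need <- c("unit_id", "stimulus", "order_index")
  missing <- setdiff(need, names(trials))
  if (length(missing))
    stopInput("trials lack column(s): ", paste(missing, collapse = ", "))
  captiveCols <- c("orientation", "n_approaching", "max_approach")
  fieldCols <- c("approach_fraction", "retreat_m")
  isCaptive <- all(captiveCols %in% names(trials))
  isField <- any(fieldCols %in% names(trials))
  if (isCaptive && isField)
    stopInput("trials mix captive (", paste(captiveCols, collapse = "/"),
              ") and field (", paste(fieldCols, collapse = "/"),
              ") formats; split them into separate files")
  if (!isCaptive && !isField)
    stopInput("trials match neither the captive nor the field format")
  if (isCaptive) {
    scores <- compositeResponseScore(trials)
    scoreTable <- data.frame(trials[need],
                             composite_pc1 = as.numeric(scores))
  } else {
    af <- trials$approach_fraction
    rm_ <- trials$retreat_m
    scores <- vapply(seq_len(nrow(trials)), function(i) {
      a <- if (!is.null(af) && !is.na(af[i])) af[i] else NULL
      r <- if (!is.null(rm_) && !is.na(rm_[i])) rm_[i] else NULL
      as.numeric(scoreFieldResponse(a, r))
    }, numeric(1))
    scoreTable <- data.frame(trials[need], intensity = scores)
  }
  test <- testStimulusEffect(scores, trials$stimulus, trials$unit_id,
                             trials$order_index)
  pairwise <- if (nlevels(factor(trials$stimulus)) >= 3L)
    posthocPairwise(test) else NULL
  res <- list(format = if (isCaptive) "captive" else "field",
              scores = scoreTable,
              stimulus_test = list(chisq = test$chisq, df = test$df,
                                   p = test$p))
  if (!is.null(pairwise)) res$pairwise <- pairwise
  jsonlite::write_json(res, outJson, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  logMsg("playback analysis written to ", outJson)
  invisible(res)
}
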