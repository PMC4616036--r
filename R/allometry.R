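## Allometric calibration of the synthetic call population.
##
## The generator is anchored to the published per-size-class acoustic means
## of the five study species: class means of mean pitch and spectral
## centroid by 20-cm body-length class, together with the number of
## recorded individuals per class. Calibration regresses these class means
## on the class midpoints (weighted by individual counts, single-individual
## classes excluded) with one shared slope across species and per-species
## intercepts, mirroring the finding that the species share a common
## allometric slope while differing in level.

#' Published per-size-class acoustic anchors
#'
#' Class means of the call mean pitch and spectral centroid by 20-cm total
#' body-length class for the five study species, with the number of
#' recorded individuals per class. These values anchor the default
#' calibration of the synthetic population generator.
#'
#' @return a data frame with columns `species`, `class_mid` (cm), `n`
#'   (individuals), `mean_pitch` (Hz), `centroid` (Hz).
#' @export
allometryAnchors <- function() {
  data.frame(
    species = rep(c("american_alligator", "spectacled_caiman",
                    "nile_crocodile", "morelets_crocodile",
                    "orinoco_crocodile"),
                  times = c(5L, 3L, 5L, 2L, 5L)),
    class_mid = c(30, 50, 70, 90, 110,
                  30, 50, 70,
                  30, 50, 70, 90, 110,
                  50, 70,
                  30, 50, 70, 90, 110),
    n = c(31L, 1L, 23L, 15L, 6L,
          5L, 3L, 1L,
          18L, 17L, 11L, 13L, 1L,
          4L, 1L,
          1L, 1L, 10L, 1L, 1L),
    mean_pitch = c(593, 418, 461, 459, 405,
                   376, 383, 358,
                   456, 416, 412, 389, 222,
                   413, 377,
                   432, 405, 433, 402, 413),
    centroid = c(1164, 958, 1035, 884, 863,
                 1766, 1377, 1009,
                 2490, 2448, 2187, 2161, 1555,
                 2429, 2366,
                 2897, 2084, 2269, 1988, 2075))
}

# weighted shared-slope fit of one response across species; anchors with
# n < minN are excluded. Returns list(slope, intercepts named by species).
sharedSlopeFit <- function(anchors, response, minN = 2L) {
  a <- anchors[anchors$n >= minN, ]
  y <- a[[response]]
  num <- 0
  den <- 0
  for (sp in unique(a$species)) {
    i <- a$species == sp
    if (sum(i) < 2L) next  # a single class pins an intercept, not a slope
    w <- a$n[i]
    xm <- sum(w * a$class_mid[i]) / sum(w)
    ym <- sum(w * y[i]) / sum(w)
    num <- num + sum(w * (a$class_mid[i] - xm) * (y[i] - ym))
    den <- den + sum(w * (a$class_mid[i] - xm)^2)
  }
  slope <- num / den
  intercepts <- vapply(unique(a$species), function(sp) {
    i <- a$species == sp
    w <- a$n[i]
    sum(w * (y[i] - slope * a$class_mid[i])) / sum(w)
  }, numeric(1))
  list(slope = slope, intercepts = intercepts)
}

#' Build the default allometry model from the published anchors
#'
#' @param anchors anchor table, see [allometryAnchors()].
#' @param individualSdPitch,callSdPitch between-individual and
#'   within-individual (call-to-call) SD of mean pitch, Hz.
#' @param individualSdCentroid,callSdCentroid the same for the spectral
#'   centroid target, Hz.
#' @param startRatio,endRatio mean start/end pitch as a fraction of mean
#'   pitch (contour shape; values follow the published class means, where
#'   start pitch is ~1.25-1.3x and end pitch ~0.7x the mean pitch). The
#'   start ratio is clamped per call so the rise-fall contour with the
#'   requested mean stays solvable.
#' @param shapeJitterSd SD of the per-call multiplicative jitter applied to
#'   the contour-shape ratios.
#' @param measurementCv multiplicative measurement noise applied per
#'   descriptor on the analytic feature path.
#' @return an `AllometryModel` list with per-species intercepts, shared
#'   negative slopes (Hz/cm) for mean pitch and centroid, noise SDs and
#'   contour-shape parameters.
#' @export
defaultAllometryModel <- function(anchors = allometryAnchors(),
                                  individualSdPitch = 45, callSdPitch = 30,
                                  individualSdCentroid = 150,
                                  callSdCentroid = 100,
                                  startRatio = 1.25, endRatio = 0.68,
                                  shapeJitterSd = 0.05,
                                  measurementCv = 0.03) {
  pitch <- sharedSlopeFit(anchors, "mean_pitch")
  cent <- sharedSlopeFit(anchors, "centroid")
  model <- list(
    species = names(pitch$intercepts),
    pitchIntercepts = pitch$intercepts,
    slopePitch = pitch$slope,
    centroidIntercepts = cent$intercepts,
    slopeCentroid = cent$slope,
    individualSdPitch = individualSdPitch, callSdPitch = callSdPitch,
    individualSdCentroid = individualSdCentroid,
    callSdCentroid = callSdCentroid,
    startRatio = startRatio, endRatio = endRatio,
    peakTimeFraction = 0.1, shapeJitterSd = shapeJitterSd,
    measurementCv = measurementCv,
    callDuration = 0.16, bandHigh = 5000)
  class(model) <- "AllometryModel"
  validateAllometryModel(model)
  model
}

validateAllometryModel <- function(model) {
  if (!inherits(model, "AllometryModel"))
    stopInput("not an AllometryModel")
  if (!(model$slopePitch < 0))
    stopInput("slopePitch must be negative (larger animals call lower)")
  if (!(model$slopeCentroid < 0))
    stopInput("slopeCentroid must be negative")
  sds <- c(model$individualSdPitch, model$callSdPitch,
           model$individualSdCentroid, model$callSdCentroid)
  if (any(sds < 0)) stopInput("noise SDs must be >= 0")
  invisible(model)
}

#' Modify an allometry model
#'
#' Convenience for simulation experiments: returns the model with the named
#' components replaced (e.g. `slopePitch = 0` for a null generator).
#' Validity checks on slope signs are skipped for zero slopes so that null
#' models can be expressed.
#'
#' @param model an `AllometryModel`.
#' @param ... components to replace.
#' @return the modified model.
#' @export
updateAllometryModel <- function(model, ...) {
  stopifnot(inherits(model, "AllometryModel"))
  repl <- list(...)
  unknown <- setdiff(names(repl), names(model))
  if (length(unknown))
    stopInput("unknown model component(s): ", paste(unknown, collapse = ", "))
  model[names(repl)] <- repl
  if (model$slopePitch > 0 || model$slopeCentroid > 0)
    stopInput("slopes must be <= 0")
  model
}
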