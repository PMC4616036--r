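## Fundamental-frequency tracking and contour summaries.
##
## The tracker is a normalized cross-correlation pitch estimator: per frame,
## a short analysis segment is correlated against itself at candidate lags
## spanning [1/fmax, 1/fmin]; the correlation is normalized by the energies
## of both segments, so a perfectly periodic frame scores 1 regardless of
## amplitude or of window tapering. Among the local maxima of the
## correlation function, candidates within `peakMargin` of the best peak are
## collected and the smallest lag (highest F0 candidate) wins, which
## suppresses subharmonic (half-frequency) errors; the winning lag is
## refined by parabolic interpolation. Each frame's estimate represents the
## centre of the correlated stretch, so the reported frame times are
## `t0 + (window + lag)/2`.

#' Extract an F0 contour
#'
#' @param wave a [Waveform-class] at least one analysis frame
#'   (`frame_s + 1/fmin`) long.
#' @param fmin,fmax F0 search band in Hz. Defaults cover the juvenile
#'   crocodilian range (contour values roughly 130--970 Hz) with margin.
#' @param frame_s correlation segment length in seconds. Short segments keep
#'   the first and last estimates close to the call edges, which matters for
#'   start/end pitch; the segment must still be of the order of one period
#'   of `fmin`.
#' @param hop_s hop between frames in seconds.
#' @param voicingThreshold a frame is voiced iff its best normalized
#'   correlation reaches this value (0..1).
#' @param peakMargin relative margin within which a smaller-lag local
#'   maximum is preferred over the global one.
#' @return a [PitchContour-class]; errors with "unvoiced call" if no frame
#'   is voiced.
#' @examples
#' w <- synthFMTone(designContour(500, 500, 500, 0.16), 44100)
#' summarizeContour(extractF0Contour(w))
#' @export
extractF0Contour <- function(wave, fmin = 150, fmax = 1200, frame_s = 0.010,
                             hop_s = 0.005, voicingThreshold = 0.45,
                             peakMargin = 0.1) {
  stopifnot(is(wave, "Waveform"), fmin > 0, fmin < fmax,
            voicingThreshold > 0, voicingThreshold < 1)
  sr <- sampleRate(wave)
  if (fmax > sr / 4)
    stopInput("fmax must not exceed a quarter of the sample rate")
  x <- samples(wave)
  W <- as.integer(round(frame_s * sr))
  lagMax <- as.integer(ceiling(sr / fmin))
  lagMin <- max(2L, as.integer(floor(sr / fmax)))
  span <- W + lagMax
  if (length(x) < span)
    stopInput("waveform shorter than one analysis frame (needs ",
              span, " samples)")
  hop <- max(1L, as.integer(round(hop_s * sr)))
  starts <- seq.int(1L, length(x) - span + 1L, by = hop)
  lags <- lagMin:lagMax
  lagIdx <- outer(seq_len(W), lags, `+`)  # window indices at each lag

  times <- f0 <- rep(NA_real_, length(starts))
  voiced <- logical(length(starts))
  for (k in seq_along(starts)) {
    i <- starts[k]
    seg <- x[i:(i + span - 1L)]
    a <- seg[seq_len(W)]
    ea <- sum(a * a)
    times[k] <- (i - 1L) / sr + (W + lagMax) / (2 * sr)  # provisional
    if (ea < 1e-10) next
    c2 <- cumsum(seg * seg)
    eb <- c2[lags + W] - c2[lags]
    num <- colSums(a * matrix(seg[lagIdx], nrow = W))
    r <- ifelse(eb > 1e-10, num / sqrt(ea * eb), 0)
    n <- length(r)
    if (n < 3L) next
    isMax <- c(FALSE, r[2:(n - 1L)] > r[1:(n - 2L)] &
                      r[2:(n - 1L)] >= r[3:n], FALSE)
    if (!any(isMax)) next
    best <- max(r[isMax])
    if (best < voicingThreshold) next
    cand <- which(isMax & r >= best - peakMargin * abs(best))
    j <- cand[1L]  # smallest lag among near-best candidates
    # parabolic refinement of the peak lag
    lag <- lags[j]
    if (j > 1L && j < n) {
      denom <- r[j - 1L] - 2 * r[j] + r[j + 1L]
      if (is.finite(denom) && abs(denom) > 1e-12) {
        d <- 0.5 * (r[j - 1L] - r[j + 1L]) / denom
        if (abs(d) <= 1) lag <- lag + d
      }
    }
    f <- sr / lag
    f0[k] <- min(max(f, fmin), fmax)
    voiced[k] <- TRUE
    times[k] <- (i - 1L) / sr + (W + lag) / (2 * sr)
  }
  # guard strict monotonicity of times (lag-dependent centres)
  for (k in seq_along(times)[-1L])
    if (times[k] <= times[k - 1L]) times[k] <- times[k - 1L] + 1e-6
  if (!any(voiced)) stopInput("unvoiced call")
  pitchContour(times, f0, voiced, callDuration = duration(wave),
               fmin = fmin, fmax = fmax)
}

#' Repair octave jumps in a pitch contour
#'
#' A tracked contour occasionally contains frames estimated at twice or half
#' the true F0. Each voiced frame is compared with the running median of its
#' five nearest voiced neighbours; a frame whose ratio to that median falls
#' within `ratioTol` of exactly 2 (or whose inverse ratio does) is replaced
#' by half (twice) its value. The rule is applied until no frame changes, so
#' the operation is idempotent; genuinely smooth contours are untouched
#' because their local ratios never approach 2.
#'
#' @param contour a [PitchContour-class] with at least one voiced frame.
#' @param ratioTol half-width of the ratio window around 2 (default 0.25).
#' @return the corrected [PitchContour-class].
#' @export
correctOctaveJumps <- function(contour, ratioTol = 0.25) {
  stopifnot(is(contour, "PitchContour"), ratioTol > 0, ratioTol < 1)
  f0 <- contour@f0
  vIdx <- which(contour@voiced)
  if (length(vIdx) == 0L) stopInput("contour has no voiced frame")
  if (length(vIdx) < 2L) return(contour)
  for (pass in seq_len(10L)) {
    changed <- FALSE
    v <- f0[vIdx]
    for (k in seq_along(vIdx)) {
      nb <- setdiff(seq(max(1L, k - 2L), min(length(vIdx), k + 2L)), k)
      if (!length(nb)) next
      med <- median(v[nb])
      ratio <- v[k] / med
      if (abs(ratio - 2) <= ratioTol) {
        f0[vIdx[k]] <- v[k] / 2
        changed <- TRUE
      } else if (abs(1 / ratio - 2) <= ratioTol) {
        f0[vIdx[k]] <- v[k] * 2
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pitchContour(contour@times, f0, contour@voiced, contour@callDuration,
               contour@fmin, contour@fmax)
}

#' Summarize a pitch contour into the five pitch descriptors
#'
#' Returns start, maximum, minimum, mean and end pitch. When the contour
#' carries its call duration (as tracker output does) and `extend = TRUE`,
#' the contour is first extended to the call edges: start and end pitch are
#' obtained by local-linear extrapolation of the nearest voiced frames to
#' t = 0 and t = duration (frame estimates represent frame centres, so the
#' first/last frame values themselves sit up to half a frame inside the
#' call), and mean pitch is the time-weighted (trapezoidal) mean of the
#' extended contour. Min and max are taken over the extended contour, so the
#' ordering invariants min <= start, end, mean <= max always hold. Without a
#' call duration the literal frame conventions apply: start/end are the
#' first/last voiced frame values and mean is the arithmetic frame mean.
#'
#' @param contour a [PitchContour-class] with >= 1 voiced frame.
#' @param extend extend the contour to the call edges when possible.
#' @param edgeFrames number of voiced frames in each edge fit.
#' @param maxEdgeGap maximum gap (s) between the call edge and the nearest
#'   voiced frame for extrapolation to be attempted.
#' @return named numeric vector `start_pitch`, `max_pitch`, `min_pitch`,
#'   `mean_pitch`, `end_pitch` (Hz).
#' @export
summarizeContour <- function(contour, extend = TRUE, edgeFrames = 5L,
                             maxEdgeGap = 0.03) {
  stopifnot(is(contour, "PitchContour"))
  v <- contour@voiced
  if (!any(v)) stopInput("contour has no voiced frame")
  t <- contour@times[v]
  f <- contour@f0[v]
  n <- length(f)
  D <- contour@callDuration
  doExtend <- isTRUE(extend) && !is.na(D) && n >= 3L

  extrapolate <- function(tt, ff, at) {
    fit <- lm(ff ~ tt)
    val <- unname(predict(fit, data.frame(tt = at)))
    # clamp implausible extrapolations back towards the observed range
    min(max(val, 0.6 * min(ff)), 1.6 * max(ff))
  }
  if (doExtend) {
    k <- min(as.integer(edgeFrames), n)
    startP <- if (t[1L] <= maxEdgeGap && k >= 3L)
      extrapolate(t[seq_len(k)], f[seq_len(k)], 0) else f[1L]
    endP <- if (D - t[n] <= maxEdgeGap && k >= 3L)
      extrapolate(t[n - k + seq_len(k)], f[n - k + seq_len(k)], D) else f[n]
    tt <- c(0, t, D)
    ff <- c(startP, f, endP)
    meanP <- sum((ff[-1L] + ff[-length(ff)]) / 2 * diff(tt)) / (D - 0)
    allF <- ff
  } else {
    startP <- f[1L]
    endP <- f[n]
    meanP <- mean(f)
    allF <- f
  }
  c(start_pitch = startP, max_pitch = max(allF), min_pitch = min(allF),
    mean_pitch = meanP, end_pitch = endP)
}

#' Export a pitch contour as a two-column data frame
#'
#' @param contour a [PitchContour-class].
#' @return data frame with `time_s` and `f0_hz` (NA on unvoiced frames),
#'   suitable for `write.csv`.
#' @export
contourAsDataFrame <- function(contour) {
  stopifnot(is(contour, "PitchContour"))
  data.frame(time_s = contour@times,
             f0_hz = ifelse(contour@voiced, contour@f0, NA_real_))
}
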