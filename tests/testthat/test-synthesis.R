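# Contour design closed form, FM/harmonic synthesis, playback assembly.

test_that("the closed-form peak reproduces hand-checkable solutions", {
  small <- designContour(630, 638, 350, 0.16, 0.25)
  expect_equal(small@fPeak, 856)
  large <- designContour(300, 384, 200, 0.16, 0.25)
  expect_equal(large@fPeak, 543)
  flat <- designContour(500, 500, 500, 0.16, 0.25)
  expect_equal(flat@fPeak, 500)
  expect_identical(flat@shape, "two_segment")
})

test_that("the realized contour's time-average equals the design mean", {
  set.seed(41)
  for (i in 1:10) {
    fm <- runif(1, 250, 650)
    spec <- designContour(runif(1, 1.0, 1.1) * fm, fm,
                          runif(1, 0.6, 0.8) * fm, runif(1, 0.1, 0.3),
                          peakTimeFraction = runif(1, 0.05, 0.12))
    tGrid <- seq(0, spec@duration, length.out = 20001)
    f <- contourFrequency(spec, tGrid)
    trapz <- sum((f[-1] + f[-length(f)]) / 2 * diff(tGrid)) / spec@duration
    expect_lt(abs(trapz - spec@fMean) / spec@fMean, 0.005)
  }
})

test_that("contour endpoints are exact and infeasible designs error", {
  spec <- designContour(630, 638, 350, 0.16)
  expect_identical(contourFrequency(spec, 0), 630)
  expect_identical(contourFrequency(spec, 0.16), 350)
  expect_error(designContour(500, 50, 500, 0.16), "infeasible")
  expect_warning(fallback <- designContour(500, 450, 500, 0.16),
                 "linear")
  expect_identical(fallback@shape, "linear")
  expect_equal(fallback@achievedMean, 500)
})

test_that("synthFMTone yields the exact sample count and click-free output", {
  spec <- designContour(500, 500, 500, 0.16)
  w <- synthFMTone(spec, 44100)
  expect_identical(length(samples(w)), 7056L)
  expect_equal(duration(w), 0.16)

  small <- synthFMTone(designContour(630, 638, 350, 0.16), 44100,
                       amplitude = 0.9)
  maxStep <- 2 * pi * 856 / 44100 * 0.9  # steepest sinusoid increment
  expect_lt(max(abs(diff(samples(small)))), maxStep * 1.1)

  silent <- synthFMTone(spec, 44100, amplitude = 0)
  expect_true(all(samples(silent) == 0))
  expect_error(synthFMTone(spec, 44100, ramp_s = 0.1), "ramp")
})

test_that("a single-harmonic call is exactly the FM tone", {
  spec <- designContour(450, 430, 300, 0.16)
  a <- synthFMTone(spec, 44100)
  b <- synthHarmonicCall(harmonicCallSpec(spec, 1, -6), 44100)
  expect_lt(max(abs(samples(a) - samples(b))), 1e-9)
})

test_that("harmonic stacks show the designed partials and tilt", {
  spec <- designContour(450, 450, 450, 0.3)
  w <- synthHarmonicCall(harmonicCallSpec(spec, 6, -6), 44100)
  x <- samples(w)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_along(x) / length(x))
  mag <- Mod(fft(x * win))[1:4000]
  freqs <- (0:3999) * 44100 / length(x)
  peakAmp <- vapply(1:6, function(k) {
    sel <- abs(freqs - k * 450) < 30
    max(mag[sel])
  }, numeric(1))
  stepDb <- 20 * log10(peakAmp[-1] / peakAmp[-6])
  expect_true(all(abs(stepDb + 6) < 0.5))

  cLow <- spectralDescriptors(meanSpectrum(
    synthHarmonicCall(harmonicCallSpec(spec, 6, -12), 44100)))[["centroid"]]
  cHigh <- spectralDescriptors(meanSpectrum(
    synthHarmonicCall(harmonicCallSpec(spec, 6, -3), 44100)))[["centroid"]]
  expect_gt(cHigh, cLow)
})

test_that("Nyquist violations are refused", {
  spec <- designContour(3000, 3000, 3000, 0.1)
  expect_error(synthHarmonicCall(harmonicCallSpec(spec, 10, -6), 44100),
               "Nyquist")
})

test_that("playback series have the designed arithmetic and determinism", {
  call <- synthFMTone(designContour(500, 500, 500, 0.16), 44100)
  expect_identical(samples(buildPlaybackSeries(call, 1)), samples(call))
  series <- buildPlaybackSeries(call, 8, gap_s = 2, jitter_s = 0)
  expect_equal(duration(series), 8 * 0.16 + 7 * 2)

  a <- buildPlaybackSeries(call, 5, gap_s = 0.8, jitter_s = 0.2, seed = 7)
  b <- buildPlaybackSeries(call, 5, gap_s = 0.8, jitter_s = 0.2, seed = 7)
  expect_identical(samples(a), samples(b))
  expect_warning(buildPlaybackSeries(call, 3, gap_s = 0.01, jitter_s = 0.5,
                                     seed = 3), "clipped")
})

test_that("the three stimulus designs carry the printed anchors", {
  sp <- stimulusSpecs()
  expect_equal(sp$SYNTsmall@fStart, 630)
  expect_equal(sp$SYNTsmall@fMean, 638)
  expect_equal(sp$SYNTsmall@fEnd, 350)
  expect_equal(sp$SYNTlarge@fStart, 300)
  expect_equal(sp$SYNTlarge@fMean, 384)
  expect_equal(sp$SYNTlarge@fEnd, 200)
  expect_equal(sp$NOFM@fStart, 500)
  expect_true(all(vapply(sp, function(s) s@duration == 0.16, logical(1))))
})
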