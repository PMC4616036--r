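# callometry

Acoustic allometry of juvenile crocodilian calls: feature extraction,
size-coding statistics, playback-stimulus synthesis and response scoring.

Juvenile crocodilians (alligators, caimans, crocodiles) utter short
harmonic calls whose structure changes as the animal grows: the
fundamental frequency F0 (pitch) and the spectral energy distribution both
shift downward with total body length. That embedded size information is
behaviourally relevant — mothers respond more readily to the calls of
smaller juveniles — and probing it requires a chain of tools that this
package provides as tested, reusable R code:

* **Audio I/O and segmentation** — WAV read/write (16-bit PCM and 32-bit
  float) and amplitude-envelope call segmentation
  (`readWav()`, `writeWav()`, `segmentCalls()`).
* **The 13 call descriptors** — eight spectrum descriptors from a
  Hann-windowed averaged magnitude spectrum within 0–5 kHz (mode, energy
  quartiles Q25/Q75, IQR, centroid ∑ fₖ mₖ, skewness, kurtosis, spectral
  flatness sfm = geometric/arithmetic mean) plus five pitch-contour
  summaries (start/max/min/mean/end pitch) from a normalized
  cross-correlation F0 tracker with automatic octave-jump repair
  (`meanSpectrum()`, `spectralDescriptors()`, `extractF0Contour()`,
  `correctOctaveJumps()`, `summarizeContour()`, `acousticFeatures()`).
* **Stimulus synthesis** — frequency-modulated pure tones designed from
  start/mean/end pitch constraints with the peak frequency solved in
  closed form, `f_peak = 2 f_mean − p f_start − (1−p) f_end`; harmonic
  stacks with a spectral tilt; playback-series assembly
  (`designContour()`, `synthFMTone()`, `synthHarmonicCall()`,
  `buildPlaybackSeries()`, `stimulusSpecs()`).
* **Synthetic call population** — a seeded generator of size-graded calls
  calibrated to published per-size-class acoustic means, with
  species-specific intercepts, a shared allometric slope, individual- and
  call-level noise, and both an audio and a fast analytic rendering path
  (`defaultAllometryModel()`, `generateDataset()`,
  `simulateFeatureTable()`).
* **Size-coding statistics** — correlation-matrix PCA into two acoustic
  dimensions (AD1 ≈ spectral energy distribution, AD2 ≈ pitch),
  likelihood-ratio tests of size, species and their interaction in linear
  mixed models with individual random intercepts, and two-species
  regression line comparison (`fitAcousticSpace()`, `testSizeEffect()`,
  `regressAndCompareLines()`).
* **Playback analysis** — the ordinal −2..+2 field intensity scale, the
  PCA composite score for captive three-criterion observations,
  mixed-model stimulus tests and Tukey-style simultaneous post-hoc
  contrasts, plus a seeded experiment simulator (`scoreFieldResponse()`,
  `compositeResponseScore()`, `testStimulusEffect()`,
  `posthocPairwise()`, `simulatePlaybackExperiment()`).
* **Pipeline commands** — file-based orchestration
  (`runStimulusSynthesis()`, `runSimulation()`, `runFeatureExtraction()`,
  `runSizeAnalysis()`, `runPlaybackAnalysis()`) and a thin CLI wrapper at
  `inst/cli/callometry.R`.

## Worked example

Design the high-pitched experimental stimulus from its printed anchors,
synthesize it, and verify that the pitch tracker recovers the design:

```r
library(callometry)

spec <- stimulusSpecs()$SYNTsmall
spec
#> ContourSpec (two_segment): start 630 Hz, mean 638 Hz, end 350 Hz, peak 856 Hz @ 25%, 160 ms

wave <- synthFMTone(spec, sampleRate = 44100)
wave
#> Waveform: 7056 samples @ 44100 Hz (0.160 s), peak 0.900

contour <- correctOctaveJumps(extractF0Contour(wave))
round(summarizeContour(contour), 1)
#> start_pitch   max_pitch   min_pitch  mean_pitch   end_pitch
#>       637.4       843.9       349.9       638.3       349.9
```

The tracked start, mean and end pitch (637.4 / 638.3 / 349.9 Hz) recover
the design constraints (630 / 638 / 350 Hz) within ~1%.

Simulate a study-scale synthetic population and test whether the acoustic
space encodes body size:

```r
ft <- simulateFeatureTable(populationConfig(), seed = 1)
space <- fitAcousticSpace(ft, individual = ft$individual_id)
space
#> AcousticSpace: 2429 calls, AD1 62.6% / AD2 26.3% of variance

round(componentCorrelations(space)[c("mean_pitch", "centroid", "q75", "sfm"), ], 2)
#>              AD1  AD2
#> mean_pitch -0.72 0.67
#> centroid    0.90 0.42
#> q75         0.91 0.39
#> sfm         0.93 0.32

testSizeEffect(callScores(space), ft$body_length_cm, ft$species, ft$individual_id)
#>    ad        term chisq df       p
#> 1 AD1        size  15.2  1 9.8e-05
#> 2 AD1     species 391.3  4 2.1e-83
#> 3 AD1 interaction   0.5  4 9.7e-01
#> 4 AD2        size 144.8  1 2.4e-33
#> 5 AD2     species  89.0  4 2.2e-18
#> 6 AD2 interaction   1.6  4 8.0e-01
```

Spectral-energy descriptors dominate AD1 and mean pitch dominates AD2;
body size is a strong predictor of both acoustic dimensions, species
differ in level, and there is no size-by-species interaction — the
generator's shared allometric slope is correctly recovered as a common
rule across species.

See the vignette (`vignettes/acoustic-allometry.Rmd`) for the models, the
calibration of the synthetic population, and the simulation studies that
verify type-I error, power and family-wise error control.

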