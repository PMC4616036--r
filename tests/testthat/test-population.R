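# Synthetic population generator: rosters, calls, datasets, calibration.

test_that("rosters are seeded, uniform and range-respecting", {
  a <- sampleIndividuals(c(nile_crocodile = 5, american_alligator = 3),
                         seed = 9)
  b <- sampleIndividuals(c(nile_crocodile = 5, american_alligator = 3),
                         seed = 9)
  expect_identical(a, b)

  big <- sampleIndividuals(c(nile_crocodile = 1000), c(20, 120), seed = 2)
  expect_lt(abs(mean(big$body_length_cm) - 70), 2)

  fixed <- sampleIndividuals(c(nile_crocodile = 4), c(55, 55), seed = 1)
  expect_true(all(fixed$body_length_cm == 55))
  expect_error(sampleIndividuals(c(5, 3)), "named")
})

test_that("the default calibration has negative shared slopes anchored to the published class means", {
  m <- defaultAllometryModel()
  expect_lt(m$slopePitch, 0)
  expect_lt(m$slopeCentroid, 0)
  # predictions at the Nile 30/90 cm anchors stay within one printed class SD
  pred <- m$pitchIntercepts[["nile_crocodile"]] + m$slopePitch * c(30, 90)
  expect_lt(abs(pred[1] - 456), 93)
  expect_lt(abs(pred[2] - 389), 47)
  predC <- m$centroidIntercepts[["nile_crocodile"]] + m$slopeCentroid * c(30, 90)
  expect_lt(abs(predC[1] - 2490), 540)
  expect_lt(abs(predC[2] - 2161), 159)
  expect_setequal(m$species,
                  c("american_alligator", "spectacled_caiman",
                    "nile_crocodile", "morelets_crocodile",
                    "orinoco_crocodile"))
})

noiseless <- function() defaultAllometryModel(
  individualSdPitch = 0, callSdPitch = 0, individualSdCentroid = 0,
  callSdCentroid = 0, shapeJitterSd = 0, measurementCv = 0)

test_that("with zero noise a smaller Nile crocodile calls higher, matching the anchors within tracker tolerance", {
  m <- noiseless()
  tracked <- vapply(c(30, 90), function(len) {
    g <- generateCall(list(species = "nile_crocodile",
                           body_length_cm = len), m, seed = 1)
    s <- summarizeContour(correctOctaveJumps(extractF0Contour(g$waveform)))
    c(s[["mean_pitch"]], g$truth$f_mean)
  }, numeric(2))
  expect_gt(tracked[1, 1], tracked[2, 1] * 0.97)  # tracked vs generator truth
  expect_lt(tracked[1, 1], tracked[2, 1] * 1.03)
  expect_gt(tracked[1, 1], tracked[1, 2])         # 30 cm call higher pitched
  # generator targets sit within one printed class SD of the anchors
  expect_lt(abs(tracked[2, 1] - 456), 93)
  expect_lt(abs(tracked[2, 2] - 389), 47)
})

test_that("zero-noise generation is deterministic and null slopes remove the size effect", {
  m <- noiseless()
  ind <- list(species = "american_alligator", body_length_cm = 60)
  g1 <- generateCall(ind, m, seed = 4)
  g2 <- generateCall(ind, m, seed = 4)
  expect_identical(g1$truth, g2$truth)
  expect_identical(samples(g1$waveform), samples(g2$waveform))

  nullM <- updateAllometryModel(m, slopePitch = -1e-12)
  f1 <- generateCall(list(species = "nile_crocodile", body_length_cm = 25),
                     nullM, seed = 1)$truth$f_mean
  f2 <- generateCall(list(species = "nile_crocodile", body_length_cm = 115),
                     nullM, seed = 1)$truth$f_mean
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("tracked pitch and measured centroid decrease monotonically with length", {
  m <- noiseless()
  stats <- vapply(c(30, 60, 90), function(len) {
    g <- generateCall(list(species = "american_alligator",
                           body_length_cm = len), m, seed = 2)
    s <- summarizeContour(correctOctaveJumps(extractF0Contour(g$waveform)))
    d <- spectralDescriptors(meanSpectrum(g$waveform))
    c(s[["mean_pitch"]], d[["centroid"]])
  }, numeric(2))
  expect_true(all(diff(stats[1, ]) < 0))
  expect_true(all(diff(stats[2, ]) < 0))
})

test_that("datasets are reproducible and respect the call-count bounds", {
  cfg <- smallConfig(nAlligator = 4, nNile = 4, callsMean = 3, callsSd = 4)
  d1 <- generateDataset(cfg, seed = 5, audio = FALSE)
  d2 <- generateDataset(cfg, seed = 5, audio = FALSE)
  expect_identical(d1$truth, d2$truth)
  counts <- table(d1$truth$individual_id)
  expect_true(all(counts >= 1 & counts <= 20))

  one <- populationConfig(nPerSpecies = c(nile_crocodile = 6),
                          callsMean = 1, callsSd = 0)
  dOne <- generateDataset(one, seed = 3, audio = FALSE)
  expect_identical(nrow(dOne$truth), 6L)
})

test_that("a study-sized population generates valid features throughout", {
  ft <- simulateFeatureTable(seed = 1)
  expect_gt(nrow(ft), 1000)
  X <- ft[featureNames()]
  expect_true(all(complete.cases(X)))
  expect_true(all(ft$q25 <= ft$q75))
  expect_equal(ft$iqr, ft$q75 - ft$q25, tolerance = 1e-12)
  expect_true(all(ft$sfm >= 0 & ft$sfm <= 1))
  expect_true(all(ft$min_pitch <= ft$mean_pitch + 1e-9))
  expect_true(all(ft$mean_pitch <= ft$max_pitch + 1e-9))
  expect_true(all(X > -Inf))
})

test_that("config validation names the offending keys", {
  expect_error(generateDataset(list(model = defaultAllometryModel()),
                               audio = FALSE),
               "nPerSpecies")
  expect_error(
    populationConfig(nPerSpecies = c(dragon = 3)),
    "dragon")
  expect_error(generateCall(list(species = "dragon", body_length_cm = 50),
                            defaultAllometryModel()),
               "dragon")
  expect_error(updateAllometryModel(defaultAllometryModel(), nonsense = 1),
               "nonsense")
})

test_that("audio and analytic paths agree on the features of the same call", {
  m <- noiseless()
  ind <- list(species = "nile_crocodile", body_length_cm = 50)
  g <- generateCall(ind, m, seed = 6)
  measured <- acousticFeatures(g$waveform)
  expect_equal(measured[["mean_pitch"]], g$truth$f_mean, tolerance = 0.03)
  expect_equal(measured[["centroid"]], g$truth$target_centroid,
               tolerance = 0.05)
})
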