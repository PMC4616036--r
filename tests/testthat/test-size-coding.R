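# Feature assembly, acoustic space, mixed-model LRTs, line comparison.

makeCalls <- function(n, seed = 1) {
  set.seed(seed)
  calls <- lapply(seq_len(n), function(i) {
    fm <- runif(1, 350, 550)
    synthHarmonicCall(harmonicCallSpec(
      designContour(1.1 * fm, fm, 0.7 * fm, 0.16, 0.1), 6,
      runif(1, -8, -2)), 44100)
  })
  names(calls) <- sprintf("call%02d", seq_len(n))
  calls
}

test_that("feature assembly aligns calls with metadata and logs exclusions", {
  calls <- makeCalls(3)
  meta <- data.frame(call_id = names(calls),
                     individual_id = c("a", "a", "b"),
                     species = "nile_crocodile",
                     body_length_cm = c(40, 40, 70))
  res <- assembleFeatureMatrix(calls, meta)
  expect_identical(nrow(res$features), 3L)
  expect_identical(res$covariates$call_id, names(calls))
  expect_identical(nrow(res$exclusions), 0L)

  calls$unvoiced <- waveform(rnorm(7056) * 1e-3, 44100)
  meta2 <- rbind(meta, data.frame(call_id = "unvoiced", individual_id = "b",
                                  species = "nile_crocodile",
                                  body_length_cm = 70))
  expect_message(res2 <- assembleFeatureMatrix(calls, meta2), "excluding")
  expect_identical(nrow(res2$features), 3L)
  expect_identical(res2$exclusions$call_id, "unvoiced")

  expect_error(assembleFeatureMatrix(calls, meta), "without metadata")
  metaDup <- rbind(meta2, meta2[1, ])
  expect_error(assembleFeatureMatrix(calls, metaDup), "duplicate")
})

test_that("the acoustic space matches an independent eigendecomposition", {
  ft <- simulateFeatureTable(smallConfig(), seed = 17)
  sp <- fitAcousticSpace(ft)
  X <- scale(as.matrix(ft[featureNames()]))
  eig <- eigen(cor(as.matrix(ft[featureNames()])))
  expect_equal(explainedVariance(sp), eig$values[1:2] / 13,
               tolerance = 1e-9, ignore_attr = TRUE)
  for (j in 1:2) {
    v <- eig$vectors[, j]
    got <- adLoadings(sp)[, j]
    expect_equal(abs(sum(v * got)), 1, tolerance = 1e-8)  # same axis, any sign
  }
  # orthonormal loadings, orthogonal scores
  expect_equal(crossprod(adLoadings(sp)), diag(2), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_lt(abs(cor(callScores(sp)[, 1], callScores(sp)[, 2])), 1e-9)
  # sign conventions
  expect_gt(adLoadings(sp)["centroid", "AD1"], 0)
  expect_gt(adLoadings(sp)["mean_pitch", "AD2"], 0)
})

test_that("a single latent factor concentrates variance on AD1", {
  set.seed(19)
  latent <- rnorm(200)
  X <- sapply(seq_len(13), function(j) latent + rnorm(200, 0, 0.01))
  colnames(X) <- featureNames()
  sp <- fitAcousticSpace(X)
  expect_gt(explainedVariance(sp)[1], 0.95)
})

test_that("duplicating all rows leaves loadings and explained variance unchanged", {
  ft <- simulateFeatureTable(smallConfig(), seed = 23)
  a <- fitAcousticSpace(ft)
  b <- fitAcousticSpace(rbind(ft, ft))
  expect_equal(adLoadings(a), adLoadings(b), tolerance = 1e-9)
  expect_equal(explainedVariance(a), explainedVariance(b), tolerance = 1e-9)
})

test_that("degenerate feature input is rejected with a named column", {
  ft <- simulateFeatureTable(smallConfig(), seed = 3)
  ft$sfm <- 0.5
  expect_error(fitAcousticSpace(ft), "sfm")
  expect_error(fitAcousticSpace(ft[1:10, ]), "14")
})

test_that("per-individual scores are the means of the call scores", {
  ft <- simulateFeatureTable(smallConfig(nAlligator = 3, nNile = 3),
                             seed = 29)
  sp <- fitAcousticSpace(ft, individual = ft$individual_id)
  ind <- individualScores(sp)
  byHand <- tapply(callScores(sp)[, "AD1"], ft$individual_id, mean)
  expect_equal(unname(ind[names(byHand), "AD1"]), as.numeric(byHand),
               tolerance = 1e-12)
})

test_that("size LRT finds a strong effect with correct df and scale invariance", {
  ft <- simulateFeatureTable(seed = 31)
  sp <- fitAcousticSpace(ft)
  res <- suppressWarnings(testSizeEffect(callScores(sp), ft$body_length_cm,
                                         ft$species, ft$individual_id))
  expect_identical(nrow(res), 6L)
  expect_identical(res$df[res$term == "size"], c(1L, 1L))
  expect_identical(res$df[res$term == "species"], c(4L, 4L))
  expect_identical(res$df[res$term == "interaction"], c(4L, 4L))
  expect_true(all(res$p[res$term == "size"] < 0.001))
  expect_true(all(res$chisq >= 0))

  resM <- suppressWarnings(testSizeEffect(callScores(sp),
                                          ft$body_length_cm / 100,
                                          ft$species, ft$individual_id,
                                          terms = "size"))
  expect_equal(resM$chisq, res$chisq[res$term == "size"], tolerance = 1e-4)
})

test_that("line comparison matches closed-form least squares", {
  # hand-built 4-point-per-group dataset with a known OLS solution
  sizes <- c(20, 40, 60, 80, 20, 40, 60, 80)
  vals <- c(604, 551, 522, 479, 507, 468, 445, 406)
  spp <- rep(c("a", "b"), each = 4)
  lc <- regressAndCompareLines(vals, sizes, spp)
  # normal-equations oracle per group
  for (g in c("a", "b")) {
    x <- sizes[spp == g]; y <- vals[spp == g]
    slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    icept <- mean(y) - slope * mean(x)
    row <- lc$perSpecies[lc$perSpecies$species == g, ]
    expect_equal(row$slope, slope, tolerance = 1e-9)
    expect_equal(row$intercept, icept, tolerance = 1e-9)
  }
  expect_lt(lc$slopeTest$p, 1)

  # identical groups: slope difference exactly zero
  same <- regressAndCompareLines(c(vals[1:4], vals[1:4]), sizes, spp)
  expect_equal(unname(same$slopeTest$t), 0, tolerance = 1e-9)

  expect_error(regressAndCompareLines(vals[1:6], sizes[1:6],
                                      c("a", "a", "a", "a", "b", "b")),
               ">= 3")
  expect_error(regressAndCompareLines(vals, sizes, rep("a", 8)), "two")
})

test_that("equal-slope generators reject intercepts but rarely slopes", {
  rejSlope <- 0; rejIcept <- 0
  for (r in 1:10) {
    ft <- simulateFeatureTable(smallConfig(nAlligator = 25, nNile = 25,
                                           callsMean = 8), seed = 500 + r)
    ind <- stats::aggregate(
      ft[c("mean_pitch", "body_length_cm")],
      by = list(individual_id = ft$individual_id, species = ft$species),
      FUN = mean)
    lc <- regressAndCompareLines(ind$mean_pitch, ind$body_length_cm,
                                 ind$species)
    rejSlope <- rejSlope + (lc$slopeTest$p < 0.05)
    rejIcept <- rejIcept + (lc$interceptTest$p < 0.05)
  }
  expect_lte(rejSlope, 3)   # shared-slope generator: slope test ~null
  expect_gte(rejIcept, 8)   # intercepts differ strongly between species
})
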