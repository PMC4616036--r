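# Response scoring, composite PC1, stimulus LRT and post-hoc contrasts.

test_that("the field intensity scale is total and respects its boundaries", {
  expect_identical(scoreFieldResponse(approachFraction = 0.9), 2L)
  expect_identical(scoreFieldResponse(approachFraction = 0.51), 2L)
  expect_identical(scoreFieldResponse(approachFraction = 0.5), 1L)   # exactly half -> +1
  expect_identical(scoreFieldResponse(approachFraction = 0.1), 1L)
  expect_identical(scoreFieldResponse(), 0L)
  expect_identical(scoreFieldResponse(approachFraction = 0), 0L)
  expect_identical(scoreFieldResponse(retreat_m = 0), 0L)
  expect_identical(scoreFieldResponse(retreat_m = 3), -1L)
  expect_identical(scoreFieldResponse(retreat_m = 5), -1L)           # exactly 5 m -> -1
  expect_identical(scoreFieldResponse(retreat_m = 7), -2L)
  expect_error(scoreFieldResponse(approachFraction = 0.2, retreat_m = 1),
               "not both")
})

test_that("the composite score orders trials by response strength", {
  trials <- data.frame(orientation = c(1, 1, 1, 2),
                       n_approaching = c(2, 2, 2, 6),
                       max_approach = c(1, 1, 1, 2))
  sc <- compositeResponseScore(trials)
  expect_identical(which.max(sc), 4L)
})

test_that("perfectly correlated criteria collapse onto one component", {
  trials <- data.frame(orientation = c(0, 1, 2, 1),
                       n_approaching = c(0, 3, 6, 3),
                       max_approach = c(0, 1, 2, 1))
  sc <- compositeResponseScore(trials)
  expect_equal(attr(sc, "explainedVariance"), 1, tolerance = 1e-9)
  expect_gt(attr(sc, "loadings")[["n_approaching"]], 0)
})

test_that("composite scores match a direct eigendecomposition oracle", {
  trials <- data.frame(orientation = c(0, 2, 1, 2),
                       n_approaching = c(1, 5, 2, 9),
                       max_approach = c(0, 2, 2, 1))
  sc <- compositeResponseScore(trials)
  Z <- scale(as.matrix(trials))
  eig <- eigen(cor(as.matrix(trials)))
  v <- eig$vectors[, 1]
  if (v[2] < 0) v <- -v  # n_approaching loads positively
  oracle <- as.numeric(Z %*% v)
  expect_equal(as.numeric(sc), oracle, tolerance = 1e-9)
})

test_that("composite score is invariant to affine rescaling of a criterion", {
  set.seed(61)
  trials <- data.frame(orientation = sample(0:2, 12, TRUE),
                       n_approaching = rpois(12, 3),
                       max_approach = sample(0:2, 12, TRUE))
  a <- compositeResponseScore(trials)
  trials2 <- trials
  trials2$n_approaching <- trials2$n_approaching * 10 + 3
  b <- compositeResponseScore(trials2)
  expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-9)
})

test_that("constant criteria are dropped or refused", {
  trials <- data.frame(orientation = c(1, 1, 1, 1),
                       n_approaching = c(0, 2, 4, 1),
                       max_approach = c(0, 1, 2, 1))
  expect_warning(sc <- compositeResponseScore(trials), "orientation")
  expect_length(sc, 4L)
  allConst <- data.frame(orientation = c(1, 1, 1),
                         n_approaching = c(2, 2, 2),
                         max_approach = c(1, 1, 1))
  expect_error(suppressWarnings(compositeResponseScore(allConst)),
               "constant")
})

test_that("the stimulus LRT detects an injected effect and guards its inputs", {
  set.seed(71)
  tr <- simulatePlaybackExperiment(8, c(SYNTsmall = 2, SYNTlarge = 0,
                                        NOFM = 0), seed = 71)
  res <- quietAnalyze(tr)
  expect_identical(res$test$df, 2L)
  expect_lt(res$test$p, 0.01)
  expect_s4_class(res$test$model, "lmerMod")

  sub <- tr[tr$stimulus == "NOFM", ]
  sc <- rnorm(nrow(sub))
  expect_error(testStimulusEffect(sc, sub$stimulus, sub$unit_id,
                                  sub$order_index), ">= 2")
  expect_error(testStimulusEffect(sc[1:3], tr$stimulus[1:3],
                                  rep("u1", 3), 1:3), ">= 4")
})

test_that("order can be modelled as a fixed covariate on request", {
  tr <- simulatePlaybackExperiment(8, c(SYNTsmall = 2, SYNTlarge = 0,
                                        NOFM = 0), seed = 73)
  sc <- suppressWarnings(compositeResponseScore(tr))
  expect_message(
    res <- suppressWarnings(
      testStimulusEffect(sc, tr$stimulus, tr$unit_id, tr$order_index,
                         orderAsFixed = TRUE)),
    "fixed covariate")
  expect_lt(res$p, 0.05)
})

test_that("post-hoc contrasts reproduce the elevated-category pattern", {
  set.seed(79)
  tr <- simulatePlaybackExperiment(8, c(SYNTsmall = 2.5, SYNTlarge = 0,
                                        NOFM = 0), seed = 79)
  res <- quietAnalyze(tr)
  pw <- res$pairwise
  expect_identical(nrow(pw), 3L)
  sig <- setNames(pw$p_adjusted < 0.05, pw$contrast)
  expect_true(sig[["SYNTsmall - NOFM"]])
  expect_true(sig[["SYNTsmall - SYNTlarge"]])
  expect_false(sig[["SYNTlarge - NOFM"]])
  # adjusted never below the unadjusted two-sided p (up to the Monte Carlo
  # error of the single-step multivariate-t adjustment)
  unadj <- 2 * pt(-abs(pw$z), df = 14)
  expect_true(all(pw$p_adjusted >= unadj - 0.005))
})

test_that("two-category tests refuse post-hoc comparisons", {
  tr <- simulatePlaybackExperiment(6, c(small_calls = 1, large_calls = 0),
                                   seed = 83)
  sc <- suppressWarnings(compositeResponseScore(tr))
  t2 <- suppressWarnings(testStimulusEffect(sc, tr$stimulus, tr$unit_id,
                                            tr$order_index))
  expect_error(posthocPairwise(t2), ">= 3")
})
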