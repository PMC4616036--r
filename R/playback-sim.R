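## Seeded simulator of the captive three-stimulus playback experiment: the
## harness for calibrating the stimulus test and post-hoc comparisons.
## Clusters of females are repeatedly exposed to each stimulus; a latent
## response strength (stimulus effect + cluster intercept + order effect +
## trial noise) is mapped monotonically onto the three observed criteria.

#' Simulate a captive playback experiment
#'
#' Each of `nClusters` clusters is tested once with every stimulus, in a
#' per-cluster randomized order. The latent response strength is
#' `stimulusEffects[stimulus] + cluster + order + noise` with Gaussian
#' cluster, order and trial components; it is discretized into the
#' orientation (0..2) and maximal-approach (0..2) codes and drives a
#' Poisson count of approaching females.
#'
#' @param nClusters number of clusters (experimental units).
#' @param stimulusEffects named numeric vector of latent stimulus means;
#'   the default encodes no stimulus effect (a null experiment).
#' @param clusterSd,orderSd,noiseSd SDs of the latent components.
#' @param seed integer seed.
#' @return data frame with `unit_id`, `stimulus`, `order_index`,
#'   `orientation`, `n_approaching`, `max_approach` and the latent
#'   `latent` column (ground truth).
#' @export
simulatePlaybackExperiment <- function(nClusters = 8,
                                       stimulusEffects = c(SYNTsmall = 0,
                                                           SYNTlarge = 0,
                                                           NOFM = 0),
                                       clusterSd = 0.5, orderSd = 0.2,
                                       noiseSd = 0.5, seed = NULL) {
  stopifnot(isCount(nClusters), !is.null(names(stimulusEffects)))
  stimuli <- names(stimulusEffects)
  withSeed(seed, {
    clusterEff <- rnorm(nClusters, 0, clusterSd)
    orderEff <- rnorm(length(stimuli), 0, orderSd)
    rows <- list()
    for (cl in seq_len(nClusters)) {
      ord <- sample(stimuli)
      for (pos in seq_along(ord)) {
        latent <- stimulusEffects[[ord[pos]]] + clusterEff[cl] +
          orderEff[pos] + rnorm(1, 0, noiseSd)
        orientation <- sum(latent > c(-0.5, 0.5))
        maxApproach <- sum(latent > c(0, 1))
        nApproach <- rpois(1, exp(pmin(0.3 + 0.8 * latent, 3)))
        rows[[length(rows) + 1L]] <- data.frame(
          unit_id = sprintf("cluster%02d", cl), stimulus = ord[pos],
          order_index = pos, orientation = orientation,
          n_approaching = nApproach, max_approach = maxApproach,
          latent = latent)
      }
    }
    do.call(rbind, rows)
  })
}

#' Score and test a simulated (or observed) captive experiment
#'
#' Convenience wrapper: builds the composite score over all trials, tests
#' the stimulus effect and (with >= 3 categories) runs the post-hoc
#' pairwise comparisons.
#'
#' @param trials captive trial table as from
#'   [simulatePlaybackExperiment()] (columns `unit_id`, `stimulus`,
#'   `order_index`, `orientation`, `n_approaching`, `max_approach`).
#' @return list with `scores`, `test` (a `stimulusTest`) and `pairwise`
#'   (data frame or NULL with two categories).
#' @export
analyzeCaptiveExperiment <- function(trials) {
  scores <- compositeResponseScore(trials)
  test <- testStimulusEffect(scores, trials$stimulus, trials$unit_id,
                             trials$order_index)
  pairwise <- if (nlevels(factor(trials$stimulus)) >= 3L)
    posthocPairwise(test) else NULL
  list(scores = scores, test = test, pairwise = pairwise)
}
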