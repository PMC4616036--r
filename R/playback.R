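## Playback-response scoring and analysis: the ordinal field intensity
## scale, the PCA composite score for the captive three-criterion
## observations, the mixed-model stimulus test and post-hoc simultaneous
## pairwise comparisons.

#' Score a field playback response on the ethological intensity scale
#'
#' Maps one observed movement to the ordinal -2..+2 scale: +2 = approach of
#' more than half the loudspeaker distance, +1 = partial approach (half or
#' less), 0 = no movement, -1 = retreat of up to 5 m, -2 = retreat of more
#' than 5 m. Boundary convention: exactly half the distance scores +1 and a
#' retreat of exactly 5 m scores -1 (the stronger codes require "more
#' than").
#'
#' @param approachFraction fraction (0..1) of the initial
#'   loudspeaker-female distance covered towards the loudspeaker, or NULL.
#' @param retreat_m retreat distance in meters (>= 0), or NULL. Supplying
#'   both is an error; supplying neither means no movement.
#' @return integer intensity in -2..+2.
#' @export
scoreFieldResponse <- function(approachFraction = NULL, retreat_m = NULL) {
  if (!is.null(approachFraction) && !is.null(retreat_m))
    stopInput("supply either an approach or a retreat, not both")
  if (!is.null(approachFraction)) {
    stopifnot(length(approachFraction) == 1L, approachFraction >= 0,
              approachFraction <= 1)
    if (approachFraction == 0) return(0L)
    return(if (approachFraction > 0.5) 2L else 1L)
  }
  if (!is.null(retreat_m)) {
    stopifnot(length(retreat_m) == 1L, retreat_m >= 0)
    if (retreat_m == 0) return(0L)
    return(if (retreat_m > 5) -2L else -1L)
  }
  0L
}

#' Composite response score for captive playback trials
#'
#' The captive response to one playback is recorded as three non-independent
#' criteria: `orientation` (0..2), `n_approaching` (count of females
#' approaching) and `max_approach` (0..2). They are collapsed into a single
#' composite score: the first principal component of the standardized
#' criteria, with its sign fixed so that `n_approaching` loads positively
#' (higher score = more females reacting, closer approach). Constant
#' criterion columns are dropped with a warning; if all are constant the
#' score is undefined.
#'
#' @param trials data frame with columns `orientation`, `n_approaching`,
#'   `max_approach` (>= 3 rows).
#' @return numeric vector of per-trial composite scores, with attributes
#'   `loadings` and `explainedVariance`.
#' @export
compositeResponseScore <- function(trials) {
  need <- c("orientation", "n_approaching", "max_approach")
  missing <- setdiff(need, names(trials))
  if (length(missing))
    stopInput("trials lack column(s): ", paste(missing, collapse = ", "))
  X <- as.matrix(trials[need])
  if (nrow(X) < 3L) stopInput("need >= 3 trials for a composite score")
  if (!all(X[, "orientation"] %in% 0:2) || !all(X[, "max_approach"] %in% 0:2))
    stopInput("orientation and max_approach must be in {0, 1, 2}")
  if (any(X[, "n_approaching"] < 0))
    stopInput("n_approaching must be >= 0")
  sds <- apply(X, 2L, sd)
  if (all(sds == 0))
    stopInput("all response criteria are constant; composite undefined")
  if (any(sds == 0)) {
    warning("dropping constant criterion column(s): ",
            paste(need[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  pca <- prcomp(X, center = TRUE, scale. = TRUE)
  pc1 <- pca$x[, 1L]
  load <- pca$rotation[, 1L]
  anchor <- if ("n_approaching" %in% names(load)) "n_approaching"
            else names(load)[1L]
  if (load[anchor] < 0) {
    pc1 <- -pc1
    load <- -load
  }
  structure(pc1, loadings = load,
            explainedVariance = pca$sdev[1L]^2 / sum(pca$sdev^2))
}

#' Mixed-model test of the stimulus effect on playback responses
#'
#' Fits a maximum-likelihood linear mixed model of the response score with
#' the stimulus category as fixed effect and random intercepts for the
#' experimental unit (cluster or female) and the playback order, and
#' compares it against the reduced model lacking the stimulus term by a
#' likelihood-ratio test. With very few order levels the order intercept is
#' often estimated at zero (singular fit, warned); `orderAsFixed = TRUE`
#' instead models order as a fixed covariate.
#'
#' @param scores numeric response scores (composite or intensity).
#' @param stimulus stimulus category per trial (>= 2 categories).
#' @param unit experimental unit id per trial (>= 4 units).
#' @param order playback order index per trial.
#' @param orderAsFixed model order as a fixed effect instead of a random
#'   intercept.
#' @return a list of class `stimulusTest` with `chisq`, `df`, `p` and the
#'   fitted full model (`model`).
#' @export
testStimulusEffect <- function(scores, stimulus, unit, order,
                               orderAsFixed = FALSE) {
  n <- length(scores)
  stopifnot(length(stimulus) == n, length(unit) == n, length(order) == n)
  stimulus <- factor(stimulus)
  if (nlevels(stimulus) < 2L)
    stopInput("need >= 2 stimulus categories")
  if (length(unique(unit)) < 4L)
    stopInput("need >= 4 experimental units")
  if (any(table(stimulus) < 2L))
    warning("stimulus category with a single trial: ",
            paste(names(which(table(stimulus) < 2L)), collapse = ", "))
  dat <- data.frame(y = scores, stimulus = stimulus, unit = factor(unit),
                    order = factor(order))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  if (orderAsFixed) {
    message("modelling playback order as a fixed covariate")
    full <- lme4::lmer(y ~ stimulus + order + (1 | unit), data = dat,
                       REML = FALSE, control = ctrl)
    reduced <- lme4::lmer(y ~ order + (1 | unit), data = dat,
                          REML = FALSE, control = ctrl)
  } else {
    full <- lme4::lmer(y ~ stimulus + (1 | unit) + (1 | order), data = dat,
                       REML = FALSE, control = ctrl)
    reduced <- lme4::lmer(y ~ (1 | unit) + (1 | order), data = dat,
                          REML = FALSE, control = ctrl)
  }
  if (lme4::isSingular(full))
    warning("singular fit: a random-effect variance is estimated at zero")
  chisq <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(reduced))))
  df <- nlevels(stimulus) - 1L
  structure(list(chisq = chisq, df = df,
                 p = pchisq(chisq, df, lower.tail = FALSE),
                 model = full),
            class = "stimulusTest")
}

#' @export
print.stimulusTest <- function(x, ...) {
  cat(sprintf("Stimulus effect (LRT): chisq = %.3f, df = %d, p = %.4g\n",
              x$chisq, x$df, x$p))
  invisible(x)
}

#' Post-hoc pairwise stimulus comparisons
#'
#' All pairwise (Tukey-style) contrasts of the stimulus category means, with
#' single-step multiplicity adjustment over the contrast family (via
#' `multcomp::glht`). The contrasts are computed from a REML refit of the
#' stimulus model (the ML fit is only appropriate for the likelihood-ratio
#' test) and referenced against a t distribution with containment degrees
#' of freedom, `n - (categories - 1) - (units - 1) - 1`; with the small
#' unit counts of playback experiments the asymptotic normal reference
#' would be anti-conservative.
#'
#' @param test a `stimulusTest` from [testStimulusEffect()], fitted with
#'   >= 3 stimulus categories.
#' @return data frame with columns `contrast`, `estimate`, `z` (the t/z
#'   statistic), `p_adjusted`.
#' @export
posthocPairwise <- function(test) {
  stopifnot(inherits(test, "stimulusTest"))
  model <- test$model
  nCat <- length(fixef_levels(model))
  if (nCat < 3L) stopInput("post-hoc comparisons need >= 3 categories")
  mf <- model.frame(model)
  remlFit <- update(model, REML = TRUE)
  df <- max(1L, nrow(mf) - (nCat - 1L) -
              (length(unique(mf$unit)) - 1L) - 1L)
  glht <- multcomp::glht(remlFit,
                         linfct = multcomp::mcp(stimulus = "Tukey"),
                         df = df)
  s <- summary(glht)
  data.frame(contrast = names(s$test$coefficients),
             estimate = as.numeric(s$test$coefficients),
             z = as.numeric(s$test$tstat),
             p_adjusted = as.numeric(s$test$pvalues))
}

#' @importFrom stats update
NULL

fixef_levels <- function(model) {
  levels(model.frame(model)$stimulus)
}

#' @importFrom stats model.frame
NULL
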