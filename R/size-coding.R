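## Size-coding inference: linear mixed-model likelihood-ratio tests of the
## acoustic-dimension scores, and per-species allometric regressions with
## slope/intercept comparison.

#' Mixed-model likelihood-ratio tests of size, species and their interaction
#'
#' For each acoustic dimension, fits maximum-likelihood linear mixed models
#' with a random intercept per individual and compares nested fixed-effect
#' structures by likelihood-ratio tests: `size` compares size + species
#' against species alone, `species` compares size + species against size
#' alone, and `interaction` compares size * species against size + species.
#' ML (not REML) fits are used throughout because REML likelihoods are not
#' comparable across fixed-effect structures. The chi-square statistic is
#' twice the log-likelihood difference, with degrees of freedom equal to the
#' parameter difference (1 for size, number of species - 1 for species and
#' for the interaction).
#'
#' Singular fits (zero estimated random-effect variance) produce a warning
#' but still return a result.
#'
#' @param scores matrix or data frame of per-call AD scores (columns AD1,
#'   AD2, or any subset), e.g. [callScores()] of a fitted space.
#' @param size numeric size covariate per call (body length, cm).
#' @param species factor/character species per call.
#' @param individual individual identity per call (random-intercept
#'   grouping).
#' @param terms which terms to test.
#' @return data frame with columns `ad`, `term`, `chisq`, `df`, `p`.
#' @export
testSizeEffect <- function(scores, size, species, individual,
                           terms = c("size", "species", "interaction")) {
  terms <- match.arg(terms, several.ok = TRUE)
  scores <- as.data.frame(scores)
  n <- nrow(scores)
  stopifnot(length(size) == n, length(species) == n, length(individual) == n)
  species <- factor(species)
  nSpecies <- nlevels(species)
  if (nSpecies < 2L && any(c("species", "interaction") %in% terms))
    stopInput("species/interaction tests need >= 2 species")
  dat <- data.frame(size = as.numeric(size), species = species,
                    individual = factor(individual))
  fitML <- function(formula, data) {
    lme4::lmer(formula, data = data, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))
  }
  out <- list()
  for (ad in names(scores)) {
    dat$y <- scores[[ad]]
    additive <- fitML(y ~ size + species + (1 | individual), dat)
    if (lme4::isSingular(additive))
      warning("singular fit (zero random-effect variance) for ", ad)
    for (term in terms) {
      full <- switch(term,
        size = additive,
        species = additive,
        interaction = fitML(y ~ size * species + (1 | individual), dat))
      reduced <- switch(term,
        size = fitML(y ~ species + (1 | individual), dat),
        species = fitML(y ~ size + (1 | individual), dat),
        interaction = additive)
      chisq <- max(0, 2 * (as.numeric(logLik(full)) -
                           as.numeric(logLik(reduced))))
      df <- attr(logLik(full), "df") - attr(logLik(reduced), "df")
      out[[length(out) + 1L]] <- data.frame(
        ad = ad, term = term, chisq = chisq, df = df,
        p = pchisq(chisq, df, lower.tail = FALSE))
    }
  }
  do.call(rbind, out)
}

#' Per-species allometric regressions and line comparison
#'
#' Fits an ordinary least-squares regression of a per-individual acoustic
#' descriptor on body size separately for two species, then compares the two
#' lines through a pooled two-line model: the slope difference is the
#' size-by-species interaction term of `value ~ size * species`, and the
#' intercept difference is the species term of the common-slope model
#' `value ~ size + species`.
#'
#' @param values per-individual descriptor values (e.g. individual mean
#'   pitch, Hz).
#' @param sizes body lengths (cm), same length.
#' @param species species labels; exactly two distinct values, each with at
#'   least three individuals.
#' @return a list of class `lineComparison` with elements `perSpecies`
#'   (data frame of slope/intercept estimates and standard errors),
#'   `slopeTest` and `interceptTest` (each `t`, `df`, `p`).
#' @export
regressAndCompareLines <- function(values, sizes, species) {
  stopifnot(length(values) == length(sizes),
            length(values) == length(species))
  species <- factor(as.character(species))
  if (nlevels(species) != 2L)
    stopInput("line comparison needs exactly two species, got ",
              nlevels(species))
  counts <- table(species)
  if (any(counts < 3L))
    stopInput("need >= 3 individuals per species; ",
              paste(names(counts)[counts < 3L], collapse = ", "),
              " has fewer")
  dat <- data.frame(value = values, size = sizes, species = species)
  perSpecies <- do.call(rbind, lapply(levels(species), function(sp) {
    fit <- lm(value ~ size, data = dat[dat$species == sp, ])
    cf <- summary(fit)$coefficients
    data.frame(species = sp,
               intercept = cf[1L, 1L], intercept_se = cf[1L, 2L],
               slope = cf[2L, 1L], slope_se = cf[2L, 2L])
  }))
  fullFit <- lm(value ~ size * species, data = dat)
  addFit <- lm(value ~ size + species, data = dat)
  cfFull <- summary(fullFit)$coefficients
  cfAdd <- summary(addFit)$coefficients
  intRow <- grep("^size:species", rownames(cfFull))
  spRow <- grep("^species", rownames(cfAdd))
  out <- list(
    perSpecies = perSpecies,
    slopeTest = list(t = cfFull[intRow, 3L], df = fullFit$df.residual,
                     p = cfFull[intRow, 4L]),
    interceptTest = list(t = cfAdd[spRow, 3L], df = addFit$df.residual,
                         p = cfAdd[spRow, 4L]))
  class(out) <- "lineComparison"
  out
}

#' @export
print.lineComparison <- function(x, ...) {
  cat("Allometric regression line comparison\n")
  print(x$perSpecies, row.names = FALSE)
  cat(sprintf("slope difference:     t = %.3f, p = %.4g\n",
              x$slopeTest$t, x$slopeTest$p))
  cat(sprintf("intercept difference: t = %.3f, p = %.4g\n",
              x$interceptTest$t, x$interceptTest$p))
  invisible(x)
}
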