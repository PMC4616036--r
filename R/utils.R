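## Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so package functions do not perturb the
# user's random stream. seed = NULL leaves the current stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed), seed >= 0)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# dB <-> linear amplitude ratio
dbToAmp <- function(db) 10^(db / 20)

# Hann window of length n
hannWindow <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
}

stopInput <- function(...) stop(..., call. = FALSE)

isCount <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

#' Canonical names of the 13 call descriptors
#'
#' The five pitch summaries followed by the eight spectrum descriptors, in
#' the column order used throughout the package.
#'
#' @return character vector of length 13.
#' @export
featureNames <- function() {
  c("mean_pitch", "start_pitch", "max_pitch", "min_pitch", "end_pitch",
    "mode_freq", "q25", "q75", "iqr", "centroid",
    "skewness", "kurtosis", "sfm")
}
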