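## The two-dimensional acoustic space: correlation-matrix PCA of the 13 call
## descriptors, first two components retained as acoustic dimensions AD1 and
## AD2. PCA is fitted on call-level rows (the mixed models downstream are
## call-level with individual random intercepts); per-individual mean scores
## serve the acoustic-space plot analogue and the allometric regressions.

#' Fit the acoustic space
#'
#' Standardizes each descriptor to zero mean and unit variance (the 13
#' variables carry mixed units), performs a PCA and retains the first two
#' components. Signs are fixed so the spectral centroid loads positively on
#' AD1 and mean pitch positively on AD2.
#'
#' @param features numeric matrix or data frame with the 13 descriptor
#'   columns (extra columns are ignored); >= 14 rows required.
#' @param individual optional vector of individual ids (one per row) used
#'   to compute per-individual mean scores.
#' @return an [AcousticSpace-class].
#' @export
fitAcousticSpace <- function(features, individual = NULL) {
  features <- as.data.frame(features)
  missing <- setdiff(featureNames(), names(features))
  if (length(missing))
    stopInput("features lack descriptor column(s): ",
              paste(missing, collapse = ", "))
  X <- as.matrix(features[featureNames()])
  if (nrow(X) < 14L)
    stopInput("need more calls than descriptors (>= 14 rows), got ", nrow(X))
  if (anyNA(X)) stopInput("features contain missing values")
  sds <- apply(X, 2L, sd)
  if (any(sds == 0))
    stopInput("constant descriptor column(s): ",
              paste(featureNames()[sds == 0], collapse = ", "))
  pca <- prcomp(X, center = TRUE, scale. = TRUE)
  rot <- pca$rotation[, 1:2, drop = FALSE]
  scores <- pca$x[, 1:2, drop = FALSE]
  if (rot["centroid", 1L] < 0) {
    rot[, 1L] <- -rot[, 1L]
    scores[, 1L] <- -scores[, 1L]
  }
  if (rot["mean_pitch", 2L] < 0) {
    rot[, 2L] <- -rot[, 2L]
    scores[, 2L] <- -scores[, 2L]
  }
  colnames(rot) <- colnames(scores) <- c("AD1", "AD2")
  indScores <- matrix(numeric(), 0L, 2L,
                      dimnames = list(NULL, c("AD1", "AD2")))
  if (!is.null(individual)) {
    if (length(individual) != nrow(X))
      stopInput("individual must have one entry per feature row")
    indScores <- rbind(
      AD1 = tapply(scores[, 1L], individual, mean),
      AD2 = tapply(scores[, 2L], individual, mean))
    indScores <- t(indScores)
  }
  new("AcousticSpace", loadings = rot,
      explainedVariance = pca$sdev[1:2]^2 / sum(pca$sdev^2),
      callScores = scores, individualScores = indScores,
      center = pca$center, scale = pca$scale)
}
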