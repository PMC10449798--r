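## Evaluation metrics and response-variability analysis.

#' Part-weighted mapping accuracy
#'
#' Pools partial credit across problems: \eqn{\sum n_{correct} / \sum
#' n_{parts}}. With \code{pooled = FALSE} the unweighted mean of per-problem
#' accuracies is returned instead (a sensitivity variant).
#'
#' @param records data frame with columns \code{nCorrect} and \code{nParts}
#'   (one row per problem; extra columns such as \code{category} are
#'   allowed).
#' @param pooled part-weighted pooling (default) vs per-problem mean.
#' @return Accuracy fraction in [0, 1].
#' @examples
#' mappingAccuracy(data.frame(nCorrect = c(2, 9), nParts = c(4, 10)))
#' @export
mappingAccuracy <- function(records, pooled = TRUE) {
  if (NROW(records) == 0)
    .pamStop("invalid_input", "no evaluation records supplied")
  if (any(records$nCorrect < 0) || any(records$nCorrect > records$nParts))
    .pamStop("invalid_input", "need 0 <= nCorrect <= nParts")
  if (pooled) {
    sum(records$nCorrect) / sum(records$nParts)
  } else {
    mean(records$nCorrect / records$nParts)
  }
}

#' Chance-level accuracy
#'
#' Expected accuracy of a uniformly random one-to-one mapping: for a problem
#' with n parts each part is matched correctly with probability 1/n, so
#' chance is the mean of 1/n over problems.
#'
#' @param nPartsPerProblem integer vector of part counts (all \eqn{\ge 1}).
#' @return Chance accuracy fraction.
#' @examples
#' chanceLevel(rep(10, 100))  # 0.1
#' @export
chanceLevel <- function(nPartsPerProblem) {
  if (any(nPartsPerProblem < 1))
    .pamStop("invalid_input", "part counts must be >= 1")
  mean(1 / nPartsPerProblem)
}

#' Chance-normalized accuracy
#'
#' Rescales accuracy to the percentage of the range between chance and
#' perfect performance: \eqn{100 (acc - chance) / (1 - chance)}. Negative
#' values indicate below-chance performance.
#'
#' @param accuracy raw accuracy fraction(s).
#' @param chance chance-level fraction(s), strictly below 1.
#' @return Percentage(s).
#' @examples
#' chanceNormalize(0.632, 0.10)  # 59.1...
#' @export
chanceNormalize <- function(accuracy, chance) {
  if (any(chance >= 1))
    .pamStop("invalid_input", "chance level must be below 1")
  100 * (accuracy - chance) / (1 - chance)
}

#' Category-balanced average accuracy
#'
#' Unweighted mean of per-category accuracies, used when problem counts are
#' heavily imbalanced across categories (e.g. few car problems, many plane
#' problems).
#'
#' @param perCategory named numeric vector or list of per-category pooled
#'   accuracies.
#' @return Fraction in [0, 1].
#' @export
categoryBalancedAverage <- function(perCategory) {
  v <- unlist(perCategory, use.names = FALSE)
  if (length(v) == 0)
    .pamStop("invalid_input", "need at least one category")
  mean(v)
}

#' Relative error-rate reduction
#'
#' \eqn{100 ((1 - acc_{base}) - (1 - acc_{model})) / (1 - acc_{base})}: the
#' percentage of the baseline's error rate removed by the model.
#'
#' @param accModel model accuracy fraction.
#' @param accBaseline baseline accuracy fraction, strictly below 1.
#' @return Percentage.
#' @export
relativeErrorReduction <- function(accModel, accBaseline) {
  if (any(accBaseline >= 1))
    .pamStop("invalid_input", "baseline accuracy must be below 1")
  100 * (accModel - accBaseline) / (1 - accBaseline)
}

.placementMatrix <- function(placements) {
  if (inherits(placements, "PlacementSet")) placements <- placements$placements
  pl <- as.matrix(placements)
  if (ncol(pl) != 2L)
    .pamStop("invalid_input", "placements must be n x 2 coordinates")
  .assertFinite(pl, "placements")
  pl
}

#' Marker offsets from the mean placement
#'
#' Euclidean distance of each placement to the coordinate mean of all
#' placements - the response-variability measure for a marker.
#'
#' @param placements a \code{PlacementSet} from [makePlacements()] or an
#'   n x 2 coordinate matrix.
#' @return Numeric vector of per-placement distances.
#' @export
markerOffsetFromMean <- function(placements) {
  pl <- .placementMatrix(placements)
  if (nrow(pl) < 2)
    .pamStop("invalid_input", "need at least 2 placements")
  ctr <- colMeans(pl)
  sqrt(rowSums(t(t(pl) - ctr)^2))
}

#' Bimodality analysis of marker placements
#'
#' Tests whether 2D placements form two response clusters. The placements
#' are projected onto their first principal axis (the dip test is
#' one-dimensional); Hartigan's dip test is applied to the projection. If
#' the dip p-value is below \code{pThreshold}, the placements are split into
#' two clusters with k-means (k-means++ seeding, fixed seed) and each
#' placement's distance to its nearest cluster mean is returned; otherwise
#' the analysis falls back to [markerOffsetFromMean()]. Degenerate
#' (all-identical) placements are reported unimodal with zero distances.
#'
#' @param placements a \code{PlacementSet} or n x 2 matrix, \eqn{n \ge 8}.
#' @param pThreshold dip-test significance threshold; default 0.05.
#' @param seed seed for the 2-cluster split and the dip-test null
#'   simulation.
#' @param nsim Monte-Carlo replicates for the dip-test p-value.
#' @return A list: \code{bimodal} (logical), \code{pValue}, \code{dip},
#'   \code{distances} (per placement, to the overall mean or to the nearest
#'   cluster mean), and for bimodal sets \code{clusterMeans} (2 x 2) and
#'   \code{cluster} (memberships).
#' @export
bimodalityAnalysis <- function(placements, pThreshold = 0.05, seed = 1L,
                               nsim = 1000L) {
  pl <- .placementMatrix(placements)
  n <- nrow(pl)
  if (n < 8)
    .pamStop("invalid_input", "need at least 8 placements, got %d", n)

  if (max(apply(pl, 2, function(v) diff(range(v)))) < .NORM_EPS) {
    return(list(bimodal = FALSE, pValue = 1, dip = 0,
                distances = rep(0, n)))
  }

  proj <- stats::prcomp(pl, center = TRUE, scale. = FALSE)$x[, 1L]
  dt <- dipTest(proj, nsim = nsim, seed = seed)

  if (dt$pValue < pThreshold) {
    km <- .withSeed(seed, {
      ctr <- .kmeansppCenters(pl, 2L)
      suppressWarnings(stats::kmeans(pl, centers = ctr, iter.max = 100L,
                                     algorithm = "Lloyd"))
    })
    dists <- sqrt(rowSums((pl - km$centers[km$cluster, , drop = FALSE])^2))
    list(bimodal = TRUE, pValue = dt$pValue, dip = dt$statistic,
         distances = unname(dists), clusterMeans = unname(km$centers),
         cluster = unname(km$cluster))
  } else {
    list(bimodal = FALSE, pValue = dt$pValue, dip = dt$statistic,
         distances = markerOffsetFromMean(pl))
  }
}
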