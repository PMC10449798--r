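## Spatial-relation edge embeddings.
##
## Every ordered node pair (i, j) gets a relation vector built from the node
## coordinates c_i, c_j and the object centroid c_0: three angular components
## (cosines between the difference vectors) and the three difference vectors
## themselves, normalized by the elementwise coordinate range of the graph.
## Both parts are dimensionless, so the embeddings are invariant to
## translation and uniform scaling of the object.

.NORM_EPS <- 1e-12

#' Cosine of the angle between two vectors
#'
#' Returns \eqn{a \cdot b / (|a||b|)}, clamped to \eqn{[-1, 1]}. If either
#' vector has norm below \code{1e-12} the result is 0: coincident keypoints
#' occur in noisy annotations and a neutral value is preferable to an error.
#'
#' @param a,b numeric vectors of equal length.
#' @return A scalar in \eqn{[-1, 1]}.
#' @examples
#' cosAngle(c(1, 0), c(1, 1))  # 1/sqrt(2)
#' @export
cosAngle <- function(a, b) {
  if (length(a) != length(b))
    .pamStop("dimension_mismatch",
             "vectors of length %d and %d", length(a), length(b))
  na <- sqrt(sum(a * a))
  nb <- sqrt(sum(b * b))
  if (na < .NORM_EPS || nb < .NORM_EPS) return(0)
  max(-1, min(1, sum(a * b) / (na * nb)))
}

#' Angular relation between two nodes
#'
#' The three cosines
#' \eqn{\cos\theta(c_i - c_j, c_i - c_0)},
#' \eqn{\cos\theta(c_i - c_0, c_j - c_0)},
#' \eqn{\cos\theta(c_i - c_j, c_j - c_0)}, in that order. Components whose
#' arguments include a zero vector are 0 exactly.
#'
#' @param ci,cj node coordinates.
#' @param c0 object centroid.
#' @param convention \code{"cosine"} returns the cosines; with
#'   \code{"one-minus-cosine"} each non-degenerate component v becomes
#'   \code{1 - v} (an affine variant some similarity conventions use;
#'   degenerate components stay 0).
#' @return Numeric length-3 vector.
#' @export
angularRelation <- function(ci, cj, c0,
                            convention = c("cosine", "one-minus-cosine")) {
  convention <- match.arg(convention)
  if (length(ci) != length(cj) || length(ci) != length(c0))
    .pamStop("dimension_mismatch", "ci, cj, c0 must have equal length")
  dij <- ci - cj
  di0 <- ci - c0
  dj0 <- cj - c0
  norms <- c(sqrt(sum(dij^2)), sqrt(sum(di0^2)), sqrt(sum(dj0^2)))
  val <- c(cosAngle(dij, di0), cosAngle(di0, dj0), cosAngle(dij, dj0))
  if (convention == "one-minus-cosine") {
    degen <- c(norms[1] < .NORM_EPS || norms[2] < .NORM_EPS,
               norms[2] < .NORM_EPS || norms[3] < .NORM_EPS,
               norms[1] < .NORM_EPS || norms[3] < .NORM_EPS)
    val[!degen] <- 1 - val[!degen]
  }
  val
}

#' Difference relation between two nodes
#'
#' The concatenation \eqn{[c_j - c_i, c_i - c_0, c_j - c_0]}, divided
#' elementwise by the coordinate range of the graph's nodes
#' (\code{max - min} per axis). Range components below \code{1e-12} are
#' replaced by 1 before dividing, so degenerate axes pass the raw
#' differences through.
#'
#' @param ci,cj node coordinates.
#' @param c0 object centroid.
#' @param rangeVec nonnegative per-axis coordinate range of the graph.
#' @return Numeric vector of length \code{3 * length(ci)}.
#' @export
differenceRelation <- function(ci, cj, c0, rangeVec) {
  d <- length(ci)
  if (length(cj) != d || length(c0) != d || length(rangeVec) != d)
    .pamStop("dimension_mismatch",
             "ci, cj, c0 and rangeVec must have equal length")
  if (any(rangeVec < 0))
    .pamStop("invalid_input", "rangeVec must be elementwise nonnegative")
  g <- ifelse(rangeVec < .NORM_EPS, 1, rangeVec)
  c(cj - ci, ci - c0, cj - c0) / rep(g, 3L)
}

#' Full edge attribute vector
#'
#' Concatenates the angular and difference relations; length 9 in 2D and 12
#' in 3D. \code{extra} allows user-supplied components (e.g. topological
#' relations) to be appended.
#'
#' @inheritParams differenceRelation
#' @inheritParams angularRelation
#' @param extra optional numeric vector appended to the embedding.
#' @return Numeric vector of length \code{3 + 3d + length(extra)}.
#' @export
edgeAttributes <- function(ci, cj, c0, rangeVec,
                           convention = c("cosine", "one-minus-cosine"),
                           extra = NULL) {
  c(angularRelation(ci, cj, c0, convention),
    differenceRelation(ci, cj, c0, rangeVec),
    extra)
}
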