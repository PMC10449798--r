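## Synthetic fixtures with known ground truth.
##
## These generators stand in for the pretrained vision encoders: they emit
## part-structured attribute vectors whose within-part similarity exceeds
## between-part similarity, with controllable noise, so every stage of the
## mapping pipeline can be exercised against a known correspondence.

## random unit vectors with all pairwise cosines below `maxCos`
.separatedUnitVectors <- function(n, k, maxCos = 0.5, maxTries = 100L) {
  for (t in seq_len(maxTries)) {
    A <- matrix(stats::rnorm(n * k), n, k)
    A <- A / sqrt(rowSums(A^2))
    S <- tcrossprod(A)
    diag(S) <- 0
    if (max(abs(S)) < maxCos) return(A)
  }
  .pamStop("generation_failure",
           "could not draw %d unit vectors in %d dims with pairwise |cos| < %g after %d tries",
           n, k, maxCos, maxTries)
}

.renormRows <- function(A) {
  nr <- sqrt(rowSums(A^2))
  nr[nr < .NORM_EPS] <- 1
  A / nr
}

#' Generate a source/target graph pair with known correspondence
#'
#' Draws a source graph with random coordinates in \eqn{[0,1]^d} and
#' well-separated unit-norm attribute vectors (pairwise cosine below 0.5),
#' then builds the target as a node-permuted copy with i.i.d. Gaussian noise
#' added to the attributes (renormalized afterwards, so \code{sigmaAttr}
#' controls angular corruption independently of vector norm) and to the
#' coordinates. With both sigmas 0 and no reflection, target node
#' \code{permutation[i]} is an exact copy of source node i.
#'
#' @param N number of parts (\eqn{\ge 2}).
#' @param d spatial dimension, 2 or 3.
#' @param k attribute dimension (\eqn{\ge 2}).
#' @param sigmaAttr attribute noise standard deviation (per component, added
#'   before renormalization); 0 = clean, values around 10 saturate.
#' @param sigmaCoord coordinate noise standard deviation, in units of the
#'   unit box.
#' @param reflect mirror the target's x axis about its own coordinate
#'   midline (emulates a horizontally reflected image).
#' @param seed integer seed; identical seeds give bit-identical fixtures.
#' @return A list of class \code{"GroundTruthPair"}: \code{source},
#'   \code{target} ([AnalogyGraph-class]), \code{permutation} (source i maps
#'   to target \code{permutation[i]}), and \code{params}.
#' @examples
#' pair <- makeGraphPair(N = 5, seed = 3)
#' pair$permutation
#' @export
makeGraphPair <- function(N, d = 2L, k = 16L, sigmaAttr = 0,
                          sigmaCoord = 0, reflect = FALSE, seed = 1L) {
  if (N < 2) .pamStop("invalid_input", "N must be at least 2")
  if (k < 2) .pamStop("invalid_input", "k must be at least 2")
  .withSeed(seed, {
    attrs <- .separatedUnitVectors(N, k)
    coords <- matrix(stats::runif(N * d), N, d)
    perm <- sample.int(N)

    tAttrs <- matrix(0, N, k)
    tCoords <- matrix(0, N, d)
    tAttrs[perm, ] <- attrs + matrix(stats::rnorm(N * k, sd = sigmaAttr),
                                     N, k)
    tCoords[perm, ] <- coords + matrix(stats::rnorm(N * d, sd = sigmaCoord),
                                       N, d)
    tAttrs <- .renormRows(tAttrs)
    if (reflect) {
      mid <- (max(tCoords[, 1L]) + min(tCoords[, 1L]))
      tCoords[, 1L] <- mid - tCoords[, 1L]
    }
    structure(list(
      source = buildGraph(coords, attrs),
      target = buildGraph(tCoords, tAttrs),
      permutation = perm,
      params = list(N = N, d = d, k = k, sigmaAttr = sigmaAttr,
                    sigmaCoord = sigmaCoord, reflect = reflect, seed = seed)
    ), class = "GroundTruthPair")
  })
}

#' Accuracy of a decoded assignment against the true permutation
#'
#' Fraction of source nodes whose decoded target-side match is correct:
#' source node i is correctly mapped when the target node
#' \code{permutation[i]} decodes back to i.
#'
#' @param assignment integer per-target source ids (from [hardDecode()] or
#'   [decodedAssignment()]).
#' @param permutation true source-to-target permutation.
#' @return Fraction in [0, 1].
#' @export
pairAccuracy <- function(assignment, permutation) {
  mean(assignment[permutation] == seq_along(permutation))
}

## part layout templates: axis-aligned boxes (center, half-sizes), 8 parts
.partTemplates <- list(
  quadruped = list(
    torso     = list(c(0.0,  0.0, 0.6), c(0.50, 0.20, 0.20)),
    head      = list(c(0.85, 0.0, 1.05), c(0.15, 0.12, 0.12)),
    neck      = list(c(0.62, 0.0, 0.88), c(0.10, 0.08, 0.12)),
    tail      = list(c(-0.65, 0.0, 0.75), c(0.12, 0.04, 0.18)),
    leg_fl    = list(c(0.38,  0.14, 0.22), c(0.05, 0.05, 0.22)),
    leg_fr    = list(c(0.38, -0.14, 0.22), c(0.05, 0.05, 0.22)),
    leg_bl    = list(c(-0.38,  0.14, 0.22), c(0.05, 0.05, 0.22)),
    leg_br    = list(c(-0.38, -0.14, 0.22), c(0.05, 0.05, 0.22))
  ),
  chair = list(
    seat       = list(c(0.0, 0.0, 0.45), c(0.25, 0.25, 0.03)),
    back       = list(c(-0.23, 0.0, 0.75), c(0.03, 0.25, 0.28)),
    leg_fl     = list(c(0.20,  0.20, 0.22), c(0.03, 0.03, 0.22)),
    leg_fr     = list(c(0.20, -0.20, 0.22), c(0.03, 0.03, 0.22)),
    leg_bl     = list(c(-0.20,  0.20, 0.22), c(0.03, 0.03, 0.22)),
    leg_br     = list(c(-0.20, -0.20, 0.22), c(0.03, 0.03, 0.22)),
    stretcher1 = list(c(0.0,  0.20, 0.18), c(0.20, 0.02, 0.02)),
    stretcher2 = list(c(0.0, -0.20, 0.18), c(0.20, 0.02, 0.02))
  )
)

#' Generate a part-structured synthetic point cloud
#'
#' Samples points uniformly on axis-aligned boxes forming the eight parts of
#' a stylized quadruped (torso, head, neck, tail, four legs) or chair (seat,
#' back, four legs, two stretchers). Each point receives a 64-dimensional
#' pseudo-embedding: a one-hot part signature plus isotropic Gaussian noise.
#' These reproduce the single property the mapping consumes from learned
#' point encoders - within-part cosine similarity exceeding between-part
#' similarity - without any model weights.
#'
#' @param template \code{"quadruped"} or \code{"chair"}.
#' @param nPoints number of points (at least the part count, 8); points are
#'   allocated to parts proportional to box surface area.
#' @param sigmaEmbed embedding noise standard deviation; default 0.05.
#' @param k embedding dimension; default 64.
#' @param seed integer seed.
#' @return A list with \code{points} (nPoints x 3), \code{embeddings}
#'   (nPoints x k), \code{partLabels} (integer, 1..8),
#'   \code{partNames}, and \code{template}.
#' @export
makePointObject <- function(template = c("quadruped", "chair"),
                            nPoints = 2000L, sigmaEmbed = 0.05,
                            k = 64L, seed = 1L) {
  template <- match.arg(template)
  parts <- .partTemplates[[template]]
  nParts <- length(parts)
  if (nPoints < nParts)
    .pamStop("invalid_input",
             "nPoints must be at least the part count (%d)", nParts)
  if (k < nParts)
    .pamStop("invalid_input", "embedding dim must be at least %d", nParts)

  .withSeed(seed, {
    areas <- vapply(parts, function(p) {
      h <- p[[2L]]
      8 * (h[1] * h[2] + h[1] * h[3] + h[2] * h[3])
    }, numeric(1L))
    counts <- pmax(1L, as.integer(round(nPoints * areas / sum(areas))))
    ## fix rounding so the total is exactly nPoints
    while (sum(counts) > nPoints) {
      i <- which.max(counts)
      counts[i] <- counts[i] - 1L
    }
    while (sum(counts) < nPoints) {
      i <- which.min(counts / areas)
      counts[i] <- counts[i] + 1L
    }

    pts <- vector("list", nParts)
    for (p in seq_len(nParts)) {
      ctr <- parts[[p]][[1L]]
      h <- parts[[p]][[2L]]
      m <- counts[p]
      ## uniform on the box surface: pick a face weighted by its area
      faceArea <- rep(c(h[2] * h[3], h[1] * h[3], h[1] * h[2]), each = 2L)
      face <- sample.int(6L, m, replace = TRUE, prob = faceArea)
      u <- matrix(stats::runif(m * 3L, -1, 1), m, 3L)
      axis <- (face + 1L) %/% 2L               # 1, 1, 2, 2, 3, 3
      sgn <- ifelse(face %% 2L == 1L, 1, -1)
      u[cbind(seq_len(m), axis)] <- sgn
      pts[[p]] <- t(ctr + t(u) * h)
    }
    points <- do.call(rbind, pts)
    labels <- rep(seq_len(nParts), counts)
    emb <- matrix(stats::rnorm(nPoints * k, sd = sigmaEmbed), nPoints, k)
    emb[cbind(seq_len(nPoints), labels)] <-
      emb[cbind(seq_len(nPoints), labels)] + 1
    list(points = points, embeddings = emb, partLabels = labels,
         partNames = names(parts), template = template)
  })
}

#' Simulate marker-placement distributions
#'
#' Emulates per-participant 2D marker placements: either a single isotropic
#' Gaussian (consistent responses) or a two-component mixture (split
#' responses, as when participants disagree about which part corresponds).
#'
#' @param mode \code{"unimodal"} or \code{"bimodal"}.
#' @param means a length-2 vector (unimodal) or a 2 x 2 matrix / list of two
#'   length-2 vectors (bimodal; the two means must differ).
#' @param sigma shared isotropic standard deviation in pixels.
#' @param n number of placements (\eqn{\ge 3}).
#' @param weight mixture weight of the first component (bimodal only).
#' @param seed integer seed.
#' @return A list of class \code{"PlacementSet"}: \code{placements}
#'   (n x 2 matrix), \code{mode}, \code{means}, \code{sigma}, \code{weight}.
#' @export
makePlacements <- function(mode = c("unimodal", "bimodal"), means,
                           sigma, n, weight = 0.5, seed = 1L) {
  mode <- match.arg(mode)
  if (n < 3) .pamStop("invalid_input", "need at least 3 placements")
  if (mode == "unimodal") {
    means <- matrix(as.numeric(means), 1L, 2L, byrow = TRUE)
  } else {
    if (is.list(means)) means <- do.call(rbind, means)
    means <- matrix(as.numeric(means), ncol = 2L)
    if (nrow(means) != 2L || all(means[1L, ] == means[2L, ]))
      .pamStop("invalid_input", "bimodal mode needs two distinct means")
  }
  .withSeed(seed, {
    comp <- if (mode == "unimodal") rep(1L, n) else
      ifelse(stats::runif(n) < weight, 1L, 2L)
    pl <- means[comp, , drop = FALSE] +
      matrix(stats::rnorm(n * 2L, sd = sigma), n, 2L)
    structure(list(placements = pl, mode = mode, means = means,
                   sigma = sigma, weight = weight),
              class = "PlacementSet")
  })
}
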