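#' @import methods
NULL

## ---- condition helpers -----------------------------------------------------

## classed conditions so callers can distinguish failure modes
.pamStop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(paste0("pamatch_", class), "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

.assertFinite <- function(x, what) {
  if (!all(is.finite(x)))
    .pamStop("invalid_input", "%s contains non-finite values", what)
  invisible(TRUE)
}

## ---- AnalogyGraph ----------------------------------------------------------

#' Attributed part graph
#'
#' An \code{AnalogyGraph} holds the part structure extracted from one object:
#' one node per labeled part, carrying its spatial coordinates (2D pixel or
#' 3D model units) and an attribute vector (an externally computed embedding),
#' plus one directed relation edge for every ordered pair of distinct nodes.
#' Edge attributes are spatial-relation embeddings: three angular components
#' (cosines of angles between difference vectors involving the object
#' centroid) concatenated with range-normalized coordinate differences, so an
#' edge vector has length 9 in 2D and 12 in 3D.
#'
#' Edges are stored in lexicographic order of the ordered pairs
#' \eqn{(i, j), j \neq i}; there are exactly \eqn{N(N-1)} of them.
#'
#' @slot coords numeric matrix, N x d, node coordinates.
#' @slot attrs numeric matrix, N x k, node attribute vectors.
#' @slot labels character vector of part names (may be empty strings).
#' @slot centroid numeric vector of length d, the object centroid used by the
#'   relation embeddings.
#' @slot edgeIndex integer matrix, N(N-1) x 2, ordered (src, dst) pairs,
#'   1-based.
#' @slot edgeAttrs numeric matrix, N(N-1) x (3 + 3d), relation embeddings
#'   aligned with \code{edgeIndex}.
#'
#' @seealso [buildGraph()], [edgeAttributes()], [graduatedAssignment()]
#' @export
setClass("AnalogyGraph",
  representation(
    coords    = "matrix",
    attrs     = "matrix",
    labels    = "character",
    centroid  = "numeric",
    edgeIndex = "matrix",
    edgeAttrs = "matrix"
  )
)

setValidity("AnalogyGraph", function(object) {
  n <- nrow(object@coords)
  d <- ncol(object@coords)
  msgs <- character()
  if (n < 2) msgs <- c(msgs, "a graph needs at least 2 nodes")
  if (!d %in% c(2L, 3L))
    msgs <- c(msgs, "spatial dimension must be 2 or 3")
  if (nrow(object@attrs) != n)
    msgs <- c(msgs, "attrs must have one row per node")
  if (length(object@labels) != n)
    msgs <- c(msgs, "labels must have one entry per node")
  if (length(object@centroid) != d)
    msgs <- c(msgs, "centroid length must equal the spatial dimension")
  if (!all(is.finite(object@coords)) || !all(is.finite(object@attrs)) ||
      !all(is.finite(object@centroid)) || !all(is.finite(object@edgeAttrs)))
    msgs <- c(msgs, "coords, attrs, centroid and edge attributes must be finite")
  ne <- n * (n - 1L)
  if (nrow(object@edgeIndex) != ne || nrow(object@edgeAttrs) != ne)
    msgs <- c(msgs, sprintf("edge count must be exactly N(N-1) = %d", ne))
  if (nrow(object@edgeIndex) == ne &&
      !identical(unname(object@edgeIndex), .orderedPairs(n)))
    msgs <- c(msgs, "edges must enumerate all ordered pairs lexicographically")
  if (ncol(object@edgeAttrs) < 3 + 3 * d)
    msgs <- c(msgs, "edge attribute dimension must be at least 3 + 3d")
  if (length(msgs)) msgs else TRUE
})

## all ordered pairs (i, j), j != i, lexicographic in (i, j)
.orderedPairs <- function(n) {
  i <- rep(seq_len(n), each = n - 1L)
  j <- unlist(lapply(seq_len(n), function(k) seq_len(n)[-k]),
              use.names = FALSE)
  cbind(as.integer(i), as.integer(j))
}

## ---- PAMConfig -------------------------------------------------------------

#' Configuration for graduated-assignment inference
#'
#' Bundles the tunable parameters of the mapping algorithm. \code{alpha}
#' weights node against edge similarity (1 = nodes only, 0 = edges only;
#' 0.9 is the working default). The inverse temperature starts at
#' \code{beta0} and is multiplied by \code{betaGrowth} after every outer
#' iteration, so the soft assignment anneals toward a permutation.
#'
#' @slot alpha numeric in [0, 1], node-similarity weight.
#' @slot beta0 positive numeric, initial inverse temperature.
#' @slot betaGrowth numeric > 1, per-iteration multiplier for beta.
#' @slot iterations positive integer, outer iterations (500 for 2D graphs,
#'   200 for 3D cluster graphs).
#' @slot sinkhornIterations positive integer, row/column normalization passes
#'   per outer iteration.
#' @slot presimIterations positive integer, bistochastic pre-normalization
#'   passes applied to the similarity tensors.
#' @slot seed integer seed governing any randomized helper.
#' @slot angularConvention either \code{"cosine"} or
#'   \code{"one-minus-cosine"}; convention used for angular edge components.
#' @export
setClass("PAMConfig",
  representation(
    alpha              = "numeric",
    beta0              = "numeric",
    betaGrowth         = "numeric",
    iterations         = "integer",
    sinkhornIterations = "integer",
    presimIterations   = "integer",
    seed               = "integer",
    angularConvention  = "character"
  )
)

setValidity("PAMConfig", function(object) {
  msgs <- character()
  if (length(object@alpha) != 1 || object@alpha < 0 || object@alpha > 1)
    msgs <- c(msgs, "alpha must be a scalar in [0, 1]")
  if (length(object@beta0) != 1 || object@beta0 <= 0)
    msgs <- c(msgs, "beta0 must be positive")
  if (length(object@betaGrowth) != 1 || object@betaGrowth <= 1)
    msgs <- c(msgs, "betaGrowth must exceed 1")
  if (object@iterations < 1L) msgs <- c(msgs, "iterations must be >= 1")
  if (object@sinkhornIterations < 1L)
    msgs <- c(msgs, "sinkhornIterations must be >= 1")
  if (object@presimIterations < 0L)
    msgs <- c(msgs, "presimIterations must be >= 0")
  if (!object@angularConvention %in% c("cosine", "one-minus-cosine"))
    msgs <- c(msgs, "angularConvention must be 'cosine' or 'one-minus-cosine'")
  if (length(msgs)) msgs else TRUE
})

#' Create a PAMConfig
#'
#' @param dim either \code{"2d"} or \code{"3d"}; selects the default
#'   iteration count (500 for 2D image graphs, 200 for 3D cluster graphs).
#' @param alpha node-similarity weight in [0, 1]; default 0.9.
#' @param beta0 initial inverse temperature; default 0.1.
#' @param betaGrowth geometric growth factor of beta per iteration; the
#'   default depends on \code{dim} (1.015 for the 500-iteration 2D
#'   setting, 1.04 for the 200-iteration 3D setting) so that both schedules
#'   anneal the inverse temperature to a few hundred, far enough to sharpen
#'   the mapping into a near-permutation while keeping each annealing step
#'   gentle (abrupt late-stage steps can freeze symmetric ties into
#'   many-to-one decodes).
#' @param iterations number of outer iterations; defaults from \code{dim}.
#' @param sinkhornIterations row/column normalization passes per iteration;
#'   default 30 (enough balancing per step to keep symmetric near-ties from
#'   freezing into many-to-one decodes late in the anneal).
#' @param presimIterations bistochastic pre-normalization passes on the
#'   similarity tensors; default 10.
#' @param seed integer seed.
#' @param angularConvention \code{"cosine"} (default) or
#'   \code{"one-minus-cosine"} for the angular edge components.
#' @return A validated [PAMConfig-class] object.
#' @examples
#' cfg <- pamConfig("2d")
#' cfg@iterations
#' @export
pamConfig <- function(dim = c("2d", "3d"), alpha = 0.9, beta0 = 0.1,
                      betaGrowth = NULL, iterations = NULL,
                      sinkhornIterations = 30L, presimIterations = 10L,
                      seed = 1L,
                      angularConvention = c("cosine", "one-minus-cosine")) {
  dim <- match.arg(dim)
  if (is.null(iterations))
    iterations <- if (dim == "2d") 500L else 200L
  if (is.null(betaGrowth))
    betaGrowth <- if (dim == "2d") 1.015 else 1.04
  new("PAMConfig",
      alpha = as.numeric(alpha), beta0 = as.numeric(beta0),
      betaGrowth = as.numeric(betaGrowth),
      iterations = as.integer(iterations),
      sinkhornIterations = as.integer(sinkhornIterations),
      presimIterations = as.integer(presimIterations),
      seed = as.integer(seed),
      angularConvention = match.arg(angularConvention))
}

## ---- MappingResult ---------------------------------------------------------

#' Result of graduated-assignment inference
#'
#' Holds the final soft correspondence matrix \code{M} (source rows, target
#' columns; rows sum to 1), the hard per-target decode (for each target node,
#' the source node with the strongest mapping), the per-iteration energy
#' trace, and the annealing state at termination.
#'
#' @slot M numeric matrix, N_source x N_target, nonnegative, row-stochastic.
#' @slot assignment integer vector of length N_target; entry i' is the source
#'   node index (1-based) decoded for target node i'.
#' @slot energyTrace numeric vector, energy after each outer iteration.
#' @slot iterationsRun integer, number of outer iterations executed.
#' @slot finalBeta numeric, inverse temperature after the last iteration.
#' @export
setClass("MappingResult",
  representation(
    M             = "matrix",
    assignment    = "integer",
    energyTrace   = "numeric",
    iterationsRun = "integer",
    finalBeta     = "numeric"
  )
)

setValidity("MappingResult", function(object) {
  msgs <- character()
  if (any(object@M < -1e-8) || any(object@M > 1 + 1e-8))
    msgs <- c(msgs, "mapping strengths must lie in [0, 1]")
  if (nrow(object@M) >= 1 &&
      any(abs(rowSums(object@M) - 1) > 1e-6))
    msgs <- c(msgs, "rows of M must sum to 1")
  if (length(object@assignment) != ncol(object@M))
    msgs <- c(msgs, "assignment must have one entry per target node")
  if (length(object@assignment) &&
      (min(object@assignment) < 1L || max(object@assignment) > nrow(object@M)))
    msgs <- c(msgs, "assignment entries must be valid source indices")
  if (length(object@energyTrace) != object@iterationsRun)
    msgs <- c(msgs, "energy trace length must equal iterations run")
  if (object@finalBeta <= 0) msgs <- c(msgs, "finalBeta must be positive")
  if (length(msgs)) msgs else TRUE
})

## ---- PointCloudObject ------------------------------------------------------

#' Clustered 3D point cloud
#'
#' A point cloud with per-point attribute vectors, partitioned into K part
#' clusters by k-means on the attribute vectors. Cluster centers are
#' coordinate means, cluster embeddings are attribute means, and the object
#' center is the mean of the cluster centers; these define the part-level
#' graph used for 3D analogical mapping.
#'
#' @slot points numeric matrix, Np x 3.
#' @slot embeddings numeric matrix, Np x k.
#' @slot clusterLabels integer vector of length Np, values in 1..K.
#' @slot clusterCenters numeric matrix, K x 3.
#' @slot clusterEmbeddings numeric matrix, K x k.
#' @slot objectCenter numeric vector of length 3.
#' @seealso [clusterPoints()], [graphFromClusters()], [transferMarker()]
#' @export
setClass("PointCloudObject",
  representation(
    points            = "matrix",
    embeddings        = "matrix",
    clusterLabels     = "integer",
    clusterCenters    = "matrix",
    clusterEmbeddings = "matrix",
    objectCenter      = "numeric"
  )
)

setValidity("PointCloudObject", function(object) {
  msgs <- character()
  np <- nrow(object@points)
  k  <- nrow(object@clusterCenters)
  if (ncol(object@points) != 3L) msgs <- c(msgs, "points must be Np x 3")
  if (nrow(object@embeddings) != np)
    msgs <- c(msgs, "embeddings must align with points")
  if (length(object@clusterLabels) != np)
    msgs <- c(msgs, "one cluster label per point required")
  if (k >= 1 && !setequal(unique(object@clusterLabels), seq_len(k)))
    msgs <- c(msgs, "every cluster must be nonempty")
  for (c in seq_len(k)) {
    sel <- object@clusterLabels == c
    if (any(sel)) {
      ctr <- colMeans(object@points[sel, , drop = FALSE])
      if (max(abs(ctr - object@clusterCenters[c, ])) > 1e-8)
        msgs <- c(msgs, "cluster centers must equal coordinate means")
      emb <- colMeans(object@embeddings[sel, , drop = FALSE])
      if (max(abs(emb - object@clusterEmbeddings[c, ])) > 1e-8)
        msgs <- c(msgs, "cluster embeddings must equal attribute means")
    }
  }
  if (k >= 1 &&
      max(abs(object@objectCenter - colMeans(object@clusterCenters))) > 1e-8)
    msgs <- c(msgs, "object center must be the mean of cluster centers")
  if (length(msgs)) unique(msgs) else TRUE
})

#' Construct a marker annotation
#'
#' A marker is a colored annotation at a 3D location on an object (it is not
#' itself a point of the cloud).
#'
#' @param color identifier, e.g. \code{"red"}.
#' @param coords numeric length-3 coordinates.
#' @return A list with class \code{"pamMarker"}.
#' @export
marker <- function(color, coords) {
  coords <- as.numeric(coords)
  .assertFinite(coords, "marker coords")
  structure(list(color = as.character(color), coords = coords),
            class = "pamMarker")
}

#' @useDynLib pamatch, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL
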