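## Graph assembly and pair validation.

#' Build an attributed part graph
#'
#' Assembles an [AnalogyGraph-class] from part coordinates and attribute
#' vectors, computing the relation embedding of every ordered node pair.
#' 2D coordinates follow image conventions: 0-based pixels, origin top-left,
#' y increasing downward. 3D coordinates are taken as-is in model units.
#'
#' The centroid defaults to the elementwise mean of the part coordinates;
#' supply \code{centroid} when a better estimate is available (e.g. a
#' centroid derived from segmentation masks). The per-axis coordinate range
#' used by the difference relations is always computed from this graph's own
#' nodes.
#'
#' @param coords numeric matrix (N x d, d in 2:3) or list of length-d
#'   vectors.
#' @param attrs numeric matrix (N x k) or list of length-k vectors; node
#'   attribute vectors, stored unnormalized (cosine similarity makes scale
#'   irrelevant).
#' @param labels optional character vector of part names.
#' @param centroid optional length-d vector; default is the coordinate mean.
#' @param angularConvention convention for the angular edge components, see
#'   [angularRelation()].
#' @return A validated [AnalogyGraph-class].
#' @examples
#' g <- buildGraph(rbind(c(0, 0), c(2, 0), c(1, 2)), diag(3))
#' nNodes(g)
#' @export
buildGraph <- function(coords, attrs, labels = NULL, centroid = NULL,
                       angularConvention = c("cosine", "one-minus-cosine")) {
  angularConvention <- match.arg(angularConvention)
  if (is.list(coords)) coords <- do.call(rbind, coords)
  if (is.list(attrs)) attrs <- do.call(rbind, attrs)
  coords <- as.matrix(coords)
  attrs <- as.matrix(attrs)
  storage.mode(coords) <- "double"
  storage.mode(attrs) <- "double"
  n <- nrow(coords)
  if (n < 2)
    .pamStop("invalid_input", "a graph needs at least 2 parts, got %d", n)
  if (nrow(attrs) != n)
    .pamStop("dimension_mismatch",
             "%d coordinate rows but %d attribute rows", n, nrow(attrs))
  d <- ncol(coords)
  if (!d %in% c(2L, 3L))
    .pamStop("dimension_mismatch", "spatial dimension must be 2 or 3")
  .assertFinite(coords, "coords")
  .assertFinite(attrs, "attrs")
  if (is.null(labels)) labels <- rep("", n)
  if (length(labels) != n)
    .pamStop("dimension_mismatch", "need one label per part")
  if (is.null(centroid)) {
    centroid <- colMeans(coords)
  } else {
    centroid <- as.numeric(centroid)
    if (length(centroid) != d)
      .pamStop("dimension_mismatch", "centroid must have length %d", d)
    .assertFinite(centroid, "centroid")
  }
  rangeVec <- apply(coords, 2, max) - apply(coords, 2, min)

  pairs <- .orderedPairs(n)
  ea <- matrix(0, nrow(pairs), 3L + 3L * d)
  for (r in seq_len(nrow(pairs))) {
    ea[r, ] <- edgeAttributes(coords[pairs[r, 1L], ], coords[pairs[r, 2L], ],
                              centroid, rangeVec, angularConvention)
  }
  new("AnalogyGraph", coords = coords, attrs = attrs,
      labels = as.character(labels), centroid = centroid,
      edgeIndex = pairs, edgeAttrs = ea)
}

#' Validate that two graphs can be mapped
#'
#' Checks that source and target share the spatial dimension d and attribute
#' dimension k. A warning (class \code{pamatch_unequal_sizes}) is emitted
#' when the node counts differ; mapping still proceeds with a rectangular
#' correspondence matrix.
#'
#' @param G source [AnalogyGraph-class].
#' @param Gp target [AnalogyGraph-class].
#' @return Named integer vector \code{c(nSource, nTarget)}.
#' @export
validatePair <- function(G, Gp) {
  if (spatialDim(G) != spatialDim(Gp))
    .pamStop("incompatible_graphs",
             "spatial dimensions differ: %d vs %d",
             spatialDim(G), spatialDim(Gp))
  if (attrDim(G) != attrDim(Gp))
    .pamStop("incompatible_graphs",
             "attribute dimensions differ: %d vs %d",
             attrDim(G), attrDim(Gp))
  ns <- nNodes(G)
  nt <- nNodes(Gp)
  if (ns != nt)
    warning(structure(
      class = c("pamatch_unequal_sizes", "warning", "condition"),
      list(message = sprintf("graphs have unequal sizes: %d vs %d", ns, nt),
           call = sys.call(-1))))
  c(nSource = ns, nTarget = nt)
}
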