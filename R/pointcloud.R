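## Part graphs from 3D point clouds, and marker transfer.

## k-means++ seeding: D^2-weighted sampling of initial centers.
.kmeansppCenters <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- X[idx, ]
  d2 <- rowSums((X - rep(centers[1L, ], each = n))^2)
  for (c in seq_len(k)[-1L]) {
    if (all(d2 <= 0)) {
      idx <- sample.int(n, 1L)   # duplicate points; fall back to uniform
    } else {
      idx <- sample.int(n, 1L, prob = d2)
    }
    centers[c, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums((X - rep(centers[c, ], each = n))^2))
  }
  centers
}

## run set.seed without disturbing the caller's RNG stream
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Cluster a point cloud into part nodes
#'
#' Groups the points of a cloud into \code{K} clusters by k-means with
#' k-means++ seeding, clustering on the per-point attribute (embedding)
#' vectors, not on the coordinates. Cluster coordinate centers, mean
#' embeddings and the object center (mean of cluster centers) are computed
#' for the part-level graph.
#'
#' If a fit produces an empty cluster it is retried with a fresh seed, up to
#' \code{nRestarts} times; among successful fits the one with the lowest
#' total within-cluster sum of squares is kept.
#'
#' @param points numeric matrix, Np x 3, model units.
#' @param embeddings numeric matrix, Np x k (k typically 64).
#' @param K number of clusters; default 8.
#' @param seed integer seed for the k-means++ seeding.
#' @param nRestarts restarts with distinct seeds; default 10.
#' @return A [PointCloudObject-class].
#' @export
clusterPoints <- function(points, embeddings, K = 8L, seed = 1L,
                          nRestarts = 10L) {
  points <- as.matrix(points)
  embeddings <- as.matrix(embeddings)
  storage.mode(points) <- "double"
  storage.mode(embeddings) <- "double"
  np <- nrow(points)
  if (ncol(points) != 3L)
    .pamStop("invalid_input", "points must be an Np x 3 matrix")
  if (nrow(embeddings) != np)
    .pamStop("dimension_mismatch",
             "%d points but %d embedding rows", np, nrow(embeddings))
  if (np < K)
    .pamStop("invalid_input", "need at least K = %d points, got %d", K, np)
  .assertFinite(points, "points")
  .assertFinite(embeddings, "embeddings")

  best <- NULL
  for (r in seq_len(nRestarts)) {
    fit <- .withSeed(seed + (r - 1L), tryCatch({
      ctr <- .kmeansppCenters(embeddings, K)
      km <- suppressWarnings(
        stats::kmeans(embeddings, centers = ctr, iter.max = 100L,
                      algorithm = "Lloyd"))
      if (any(km$size == 0L)) NULL else km
    }, error = function(e) NULL))
    if (!is.null(fit) &&
        (is.null(best) || fit$tot.withinss < best$tot.withinss))
      best <- fit
  }
  if (is.null(best))
    .pamStop("cluster_failure",
             "no clustering without empty clusters found in %d restarts",
             nRestarts)

  labels <- as.integer(best$cluster)
  centers <- t(vapply(seq_len(K), function(c)
    colMeans(points[labels == c, , drop = FALSE]), numeric(3L)))
  cembed <- t(vapply(seq_len(K), function(c)
    colMeans(embeddings[labels == c, , drop = FALSE]),
    numeric(ncol(embeddings))))
  new("PointCloudObject", points = points, embeddings = embeddings,
      clusterLabels = labels, clusterCenters = centers,
      clusterEmbeddings = cembed, objectCenter = colMeans(centers))
}

#' Part-level graph of a clustered cloud
#'
#' One node per cluster: coordinates are the cluster coordinate centers,
#' attributes the cluster mean embeddings, and the graph centroid is the
#' object center (mean of cluster centers). Edges carry the 3D relation
#' embeddings (length 12).
#'
#' @param obj a [PointCloudObject-class].
#' @param angularConvention see [angularRelation()].
#' @return An [AnalogyGraph-class] with \code{nClusters(obj)} nodes.
#' @export
graphFromClusters <- function(obj,
                              angularConvention = c("cosine",
                                                    "one-minus-cosine")) {
  stopifnot(is(obj, "PointCloudObject"))
  buildGraph(clusterCenters(obj), clusterEmbeddings(obj),
             labels = as.character(seq_len(nClusters(obj))),
             centroid = objectCenter(obj),
             angularConvention = match.arg(angularConvention))
}

#' Assign a marker to its nearest cluster
#'
#' Returns the cluster whose coordinate center is closest (Euclidean) to the
#' marker; ties break toward the lowest cluster id.
#'
#' @param mark a marker from [marker()], or a length-3 coordinate vector.
#' @param obj a [PointCloudObject-class].
#' @return Integer cluster id in 1..K.
#' @export
assignMarkerToCluster <- function(mark, obj) {
  coords <- if (inherits(mark, "pamMarker")) mark$coords else as.numeric(mark)
  if (length(coords) != 3L)
    .pamStop("dimension_mismatch", "marker coordinates must have length 3")
  d2 <- rowSums(t(t(clusterCenters(obj)) - coords)^2)
  which.min(d2)   # which.min already prefers the lowest index on ties
}

## the three distances for an arbitrary location + embedding
.scoreTriple <- function(coords, embedding, obj, cluster) {
  ctr <- clusterCenters(obj)[cluster, ]
  cem <- clusterEmbeddings(obj)[cluster, ]
  list(
    dLocal  = sqrt(sum((coords - ctr)^2)),
    dGlobal = sqrt(sum((coords - objectCenter(obj))^2)),
    dFeat   = sqrt(sum((embedding - cem)^2))
  )
}

#' Three-distance profile of a cloud point
#'
#' For a point of the cloud and a (matched) cluster, computes
#' \code{dLocal} (distance to the cluster's coordinate center),
#' \code{dGlobal} (distance to the object center) and \code{dFeat}
#' (Euclidean distance in embedding space to the cluster's mean embedding).
#' These triples drive marker transfer: the chosen target point is the one
#' whose triple best matches the source marker's.
#'
#' @param pointIndex index of a point of \code{obj}.
#' @param obj a [PointCloudObject-class].
#' @param cluster cluster id the distances are computed against.
#' @return A list of class \code{"TransferScores"} with \code{dLocal},
#'   \code{dGlobal}, \code{dFeat}.
#' @export
transferScores <- function(pointIndex, obj, cluster) {
  stopifnot(is(obj, "PointCloudObject"))
  if (pointIndex < 1L || pointIndex > nPoints(obj))
    .pamStop("invalid_input", "point index %d out of range", pointIndex)
  if (cluster < 1L || cluster > nClusters(obj))
    .pamStop("invalid_input", "cluster id %d out of range", cluster)
  structure(.scoreTriple(pointCoords(obj)[pointIndex, ],
                         pointEmbeddings(obj)[pointIndex, ],
                         obj, cluster),
            class = "TransferScores")
}

## scores for a source marker: the marker is an annotation, not a cloud
## point, so its feature distance borrows the embedding of the nearest
## source point.
.markerScores <- function(coords, obj, cluster) {
  d2 <- rowSums(t(t(pointCoords(obj)) - coords)^2)
  nearest <- which.min(d2)
  .scoreTriple(coords, pointEmbeddings(obj)[nearest, ], obj, cluster)
}

#' Transfer a marker from a source to a target object
#'
#' The source marker is assigned to its nearest source cluster; the mapping
#' gives the corresponding target cluster; among the target points of that
#' cluster, the transferred location is the point minimizing
#' \deqn{d_\delta = \tfrac{1}{3}\left(|d_{local} - d'_{local}| +
#'   |d_{global} - d'_{global}| + |d_{feat} - d'_{feat}|\right)}
#' between the source marker's distance triple and the candidate's. Ties
#' break toward the lowest point index.
#'
#' The corresponding target cluster is the target node decoded to the
#' marker's source cluster; if several target nodes decode there, the one
#' with the largest mapping strength wins, and if none does, the strongest
#' target column of the source cluster's row of M is used.
#'
#' @param mark a marker from [marker()].
#' @param sourceObj,targetObj clustered [PointCloudObject-class] objects.
#' @param mapping a [MappingResult-class] from mapping the source cluster
#'   graph to the target cluster graph, or an integer assignment vector
#'   (per-target source ids) for a pre-decoded mapping.
#' @return A marker (class \code{"pamMarker"}) with the transferred 3D
#'   coordinates, plus fields \code{pointIndex}, \code{sourceCluster},
#'   \code{targetCluster} and \code{dDelta}.
#' @export
transferMarker <- function(mark, sourceObj, targetObj, mapping) {
  stopifnot(inherits(mark, "pamMarker"))
  srcCluster <- assignMarkerToCluster(mark, sourceObj)

  if (is(mapping, "MappingResult")) {
    assignment <- decodedAssignment(mapping)
    M <- mappingMatrix(mapping)
  } else {
    assignment <- as.integer(mapping)
    M <- NULL
  }
  cand <- which(assignment == srcCluster)
  if (length(cand) == 0L) {
    if (is.null(M))
      .pamStop("transfer_failure",
               "no target cluster is mapped to source cluster %d",
               srcCluster)
    tgtCluster <- which.max(M[srcCluster, ])
  } else if (length(cand) == 1L) {
    tgtCluster <- cand
  } else {
    tgtCluster <- if (is.null(M)) cand[1L] else
      cand[which.max(M[srcCluster, cand])]
  }

  inCluster <- which(clusterLabels(targetObj) == tgtCluster)
  if (length(inCluster) == 0L)
    .pamStop("transfer_failure", "matched target cluster %d is empty",
             tgtCluster)

  src <- .markerScores(mark$coords, sourceObj, srcCluster)
  dd <- vapply(inCluster, function(p) {
    tr <- .scoreTriple(pointCoords(targetObj)[p, ],
                       pointEmbeddings(targetObj)[p, ],
                       targetObj, tgtCluster)
    (abs(src$dLocal - tr$dLocal) + abs(src$dGlobal - tr$dGlobal) +
       abs(src$dFeat - tr$dFeat)) / 3
  }, numeric(1L))
  pick <- inCluster[which.min(dd)]

  out <- marker(mark$color, pointCoords(targetObj)[pick, ])
  out$pointIndex <- pick
  out$sourceCluster <- srcCluster
  out$targetCluster <- tgtCluster
  out$dDelta <- min(dd)
  out
}
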