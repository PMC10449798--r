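## Accessor generics and show methods. Slot access from user code is
## discouraged; these are the supported surface.

#' @rdname AnalogyGraph-class
#' @param x,object an object.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))
#' @rdname AnalogyGraph-class
#' @export
setGeneric("spatialDim", function(x) standardGeneric("spatialDim"))
#' @rdname AnalogyGraph-class
#' @export
setGeneric("attrDim", function(x) standardGeneric("attrDim"))
#' @rdname AnalogyGraph-class
#' @export
setGeneric("nodeCoords", function(x) standardGeneric("nodeCoords"))
#' @rdname AnalogyGraph-class
#' @export
setGeneric("nodeAttrs", function(x) standardGeneric("nodeAttrs"))
#' @rdname AnalogyGraph-class
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))
#' @rdname AnalogyGraph-class
#' @export
setGeneric("graphCentroid", function(x) standardGeneric("graphCentroid"))
#' @rdname AnalogyGraph-class
#' @export
setGeneric("edgePairs", function(x) standardGeneric("edgePairs"))
#' @rdname AnalogyGraph-class
#' @export
setGeneric("edgeFeatures", function(x) standardGeneric("edgeFeatures"))

#' @rdname MappingResult-class
#' @param x an object.
#' @export
setGeneric("mappingMatrix", function(x) standardGeneric("mappingMatrix"))
#' @rdname MappingResult-class
#' @export
setGeneric("decodedAssignment",
           function(x) standardGeneric("decodedAssignment"))
#' @rdname MappingResult-class
#' @export
setGeneric("energyTrace", function(x) standardGeneric("energyTrace"))

#' @rdname PointCloudObject-class
#' @param x an object.
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))
#' @rdname PointCloudObject-class
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))
#' @rdname PointCloudObject-class
#' @export
setGeneric("pointCoords", function(x) standardGeneric("pointCoords"))
#' @rdname PointCloudObject-class
#' @export
setGeneric("pointEmbeddings", function(x) standardGeneric("pointEmbeddings"))
#' @rdname PointCloudObject-class
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname PointCloudObject-class
#' @export
setGeneric("clusterCenters", function(x) standardGeneric("clusterCenters"))
#' @rdname PointCloudObject-class
#' @export
setGeneric("clusterEmbeddings",
           function(x) standardGeneric("clusterEmbeddings"))
#' @rdname PointCloudObject-class
#' @export
setGeneric("objectCenter", function(x) standardGeneric("objectCenter"))

## ---- AnalogyGraph methods --------------------------------------------------

#' @rdname AnalogyGraph-class
#' @export
setMethod("nNodes", "AnalogyGraph", function(x) nrow(x@coords))
#' @rdname AnalogyGraph-class
#' @export
setMethod("spatialDim", "AnalogyGraph", function(x) ncol(x@coords))
#' @rdname AnalogyGraph-class
#' @export
setMethod("attrDim", "AnalogyGraph", function(x) ncol(x@attrs))
#' @rdname AnalogyGraph-class
#' @export
setMethod("nodeCoords", "AnalogyGraph", function(x) x@coords)
#' @rdname AnalogyGraph-class
#' @export
setMethod("nodeAttrs", "AnalogyGraph", function(x) x@attrs)
#' @rdname AnalogyGraph-class
#' @export
setMethod("nodeLabels", "AnalogyGraph", function(x) x@labels)
#' @rdname AnalogyGraph-class
#' @export
setMethod("graphCentroid", "AnalogyGraph", function(x) x@centroid)
#' @rdname AnalogyGraph-class
#' @export
setMethod("edgePairs", "AnalogyGraph", function(x) x@edgeIndex)
#' @rdname AnalogyGraph-class
#' @export
setMethod("edgeFeatures", "AnalogyGraph", function(x) x@edgeAttrs)

setMethod("show", "AnalogyGraph", function(object) {
  cat(sprintf(
    "AnalogyGraph: %d nodes (%dD, attr dim %d), %d relation edges\n",
    nNodes(object), spatialDim(object), attrDim(object),
    nrow(object@edgeIndex)))
  lb <- object@labels[nzchar(object@labels)]
  if (length(lb))
    cat("  labels: ", paste(utils::head(lb, 8), collapse = ", "),
        if (length(lb) > 8) ", ..." else "", "\n", sep = "")
  cat("  centroid: ",
      paste(signif(object@centroid, 4), collapse = ", "), "\n", sep = "")
})

setMethod("show", "PAMConfig", function(object) {
  cat("PAMConfig:\n",
      sprintf("  alpha=%g beta0=%g betaGrowth=%g iterations=%d\n",
              object@alpha, object@beta0, object@betaGrowth,
              object@iterations),
      sprintf("  sinkhorn=%d presim=%d seed=%d angular=%s\n",
              object@sinkhornIterations, object@presimIterations,
              object@seed, object@angularConvention), sep = "")
})

## ---- MappingResult methods -------------------------------------------------

#' @rdname MappingResult-class
#' @export
setMethod("mappingMatrix", "MappingResult", function(x) x@M)
#' @rdname MappingResult-class
#' @export
setMethod("decodedAssignment", "MappingResult", function(x) x@assignment)
#' @rdname MappingResult-class
#' @export
setMethod("energyTrace", "MappingResult", function(x) x@energyTrace)

setMethod("show", "MappingResult", function(object) {
  cat(sprintf(
    "MappingResult: %d x %d mapping, %d iterations, final beta %.3g\n",
    nrow(object@M), ncol(object@M), object@iterationsRun,
    object@finalBeta))
  cat("  decoded assignment (target -> source): ",
      paste(utils::head(object@assignment, 12), collapse = " "),
      if (length(object@assignment) > 12) " ..." else "", "\n", sep = "")
  if (length(object@energyTrace))
    cat(sprintf("  energy: %.5g -> %.5g\n",
                object@energyTrace[1],
                object@energyTrace[length(object@energyTrace)]))
})

## ---- PointCloudObject methods ----------------------------------------------

#' @rdname PointCloudObject-class
#' @export
setMethod("nPoints", "PointCloudObject", function(x) nrow(x@points))
#' @rdname PointCloudObject-class
#' @export
setMethod("nClusters", "PointCloudObject",
          function(x) nrow(x@clusterCenters))
#' @rdname PointCloudObject-class
#' @export
setMethod("pointCoords", "PointCloudObject", function(x) x@points)
#' @rdname PointCloudObject-class
#' @export
setMethod("pointEmbeddings", "PointCloudObject", function(x) x@embeddings)
#' @rdname PointCloudObject-class
#' @export
setMethod("clusterLabels", "PointCloudObject", function(x) x@clusterLabels)
#' @rdname PointCloudObject-class
#' @export
setMethod("clusterCenters", "PointCloudObject", function(x) x@clusterCenters)
#' @rdname PointCloudObject-class
#' @export
setMethod("clusterEmbeddings", "PointCloudObject",
          function(x) x@clusterEmbeddings)
#' @rdname PointCloudObject-class
#' @export
setMethod("objectCenter", "PointCloudObject", function(x) x@objectCenter)

setMethod("show", "PointCloudObject", function(object) {
  cat(sprintf(
    "PointCloudObject: %d points, %d clusters, embedding dim %d\n",
    nPoints(object), nClusters(object), ncol(object@embeddings)))
  cat("  cluster sizes: ",
      paste(tabulate(object@clusterLabels, nClusters(object)),
            collapse = " "), "\n", sep = "")
})
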