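## File formats: graph JSON, ASCII point clouds (PLY / XYZ), embedding and
## mapping CSV, marker JSON. All formats are plain text.

#' Write a graph to JSON
#'
#' Format: \code{{"dim": d, "centroid": [...], "parts": [{"id": 0, "label":
#' "...", "coords": [...], "attr": [...]}, ...]}} with 0-based part ids in
#' file order. Numbers are written at full precision so a read round-trip
#' reproduces the graph bit-exactly.
#'
#' @param graph an [AnalogyGraph-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGraphJson <- function(graph, path) {
  stopifnot(is(graph, "AnalogyGraph"))
  parts <- lapply(seq_len(nNodes(graph)), function(i) {
    list(id = i - 1L,
         label = nodeLabels(graph)[i],
         coords = nodeCoords(graph)[i, ],
         attr = nodeAttrs(graph)[i, ])
  })
  obj <- list(dim = spatialDim(graph),
              centroid = graphCentroid(graph),
              parts = parts)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a graph from JSON
#'
#' Accepts the format written by [writeGraphJson()]. Attribute vectors may
#' alternatively live in a separate CSV matrix (rows = parts, in file
#' order) referenced by an \code{"attr_file"} entry, resolved relative to
#' the JSON file's directory.
#'
#' @param path JSON file path.
#' @param angularConvention see [angularRelation()].
#' @return An [AnalogyGraph-class] (edges recomputed from the coordinates
#'   and centroid).
#' @export
readGraphJson <- function(path, angularConvention = "cosine") {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coords <- do.call(rbind, lapply(obj$parts$coords, as.numeric))
  labels <- if (!is.null(obj$parts$label)) as.character(obj$parts$label)
            else NULL
  if (!is.null(obj$attr_file)) {
    attrs <- readEmbeddingsCsv(file.path(dirname(path), obj$attr_file))
  } else {
    attrs <- do.call(rbind, lapply(obj$parts$attr, as.numeric))
  }
  centroid <- if (!is.null(obj$centroid)) as.numeric(obj$centroid) else NULL
  buildGraph(coords, attrs, labels = labels, centroid = centroid,
             angularConvention = angularConvention)
}

#' Read an ASCII point cloud
#'
#' Supports ASCII PLY (vertex element with x, y, z properties) and plain
#' whitespace-separated XYZ tables. The format is detected from the file
#' header.
#'
#' @param path point-cloud file.
#' @return Numeric matrix, Np x 3.
#' @export
readPointCloud <- function(path) {
  first <- readLines(path, n = 1L)
  if (identical(trimws(first), "ply")) {
    lines <- readLines(path)
    endHdr <- which(trimws(lines) == "end_header")[1L]
    if (is.na(endHdr))
      .pamStop("invalid_input", "PLY file without end_header: %s", path)
    hdr <- lines[seq_len(endHdr)]
    fmt <- grep("^format", trimws(hdr), value = TRUE)
    if (length(fmt) && !grepl("ascii", fmt[1L]))
      .pamStop("invalid_input", "only ASCII PLY is supported")
    vline <- grep("^element vertex", trimws(hdr), value = TRUE)
    if (!length(vline))
      .pamStop("invalid_input", "PLY file without a vertex element")
    nv <- as.integer(strsplit(trimws(vline[1L]), "\\s+")[[1L]][3L])
    ## property order within the vertex element
    ele <- grep("^element", trimws(hdr))
    vstart <- ele[grepl("^element vertex", trimws(hdr)[ele])][1L]
    vend <- if (any(ele > vstart)) min(ele[ele > vstart]) else endHdr
    props <- trimws(hdr)[(vstart + 1L):(vend - 1L)]
    props <- props[grepl("^property", props)]
    pnames <- vapply(strsplit(props, "\\s+"), function(p) p[3L], "")
    xyz <- match(c("x", "y", "z"), pnames)
    if (any(is.na(xyz)))
      .pamStop("invalid_input", "PLY vertex element lacks x/y/z properties")
    body <- lines[(endHdr + 1L):(endHdr + nv)]
    vals <- utils::read.table(text = body)
    as.matrix(vals[, xyz, drop = FALSE])
  } else {
    as.matrix(utils::read.table(path)[, 1:3, drop = FALSE])
  }
}

#' Write an ASCII PLY point cloud
#'
#' @param points numeric matrix, Np x 3.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePointCloudPly <- function(points, path) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(points)),
               "property float x", "property float y", "property float z",
               "end_header"), con)
  utils::write.table(format(points, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an embedding matrix from CSV
#'
#' A headerless numeric CSV, rows aligned with point (or part) order.
#'
#' @param path CSV file.
#' @return Numeric matrix.
#' @export
readEmbeddingsCsv <- function(path) {
  as.matrix(utils::read.csv(path, header = FALSE))
}

#' Read markers from JSON
#'
#' Format: \code{[{"color": "red", "coords": [x, y, z]}, ...]}.
#'
#' @param path JSON file.
#' @return List of markers (class \code{"pamMarker"}).
#' @export
readMarkersJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(obj, function(m) marker(m$color, unlist(m$coords)))
}

#' Write a decoded mapping to CSV
#'
#' Columns \code{target_id}, \code{source_id}, \code{strength} with 0-based
#' ids (matching the graph JSON format). Optionally also writes the full
#' soft mapping matrix (rows = source, cols = target).
#'
#' @param result a [MappingResult-class].
#' @param path output CSV.
#' @param matrixPath optional path for the full-matrix CSV.
#' @return \code{path}, invisibly.
#' @export
writeMappingCsv <- function(result, path, matrixPath = NULL) {
  stopifnot(is(result, "MappingResult"))
  M <- mappingMatrix(result)
  asg <- decodedAssignment(result)
  df <- data.frame(
    target_id = seq_along(asg) - 1L,
    source_id = asg - 1L,
    strength = M[cbind(asg, seq_along(asg))]
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(matrixPath))
    utils::write.table(M, matrixPath, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  invisible(path)
}
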