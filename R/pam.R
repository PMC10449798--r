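## Probabilistic analogical mapping by graduated assignment.
##
## The posterior over mappings combines a likelihood that rewards similarity
## of mapped nodes and of mapped relation edges with an entropy prior that
## favors one-to-one (isomorphic) mappings:
##
##   log p(G, G' | M) = (1-a) * sum_{i, j!=i, i', j'!=i'}
##                        M[i,i'] M[j,j'] sim(r_ij, r_i'j') / (N(N-1))
##                    +   a  * sum_{i,i'} M[i,i'] sim(o_i, o_i') / N
##   log p(M)         = (1/beta) * sum M log M
##
## Inference minimizes the corresponding energy E(M) = -log likelihood
## - log prior with a graduated assignment (softassign) loop: exponentiate a
## per-entry compatibility score at inverse temperature beta, renormalize
## rows and columns (Sinkhorn), and anneal beta upward so the soft mapping
## sharpens toward a permutation.

.cosineMatrix <- function(A, B) {
  na <- sqrt(rowSums(A * A))
  nb <- sqrt(rowSums(B * B))
  na[na < .NORM_EPS] <- Inf   # zero vectors get similarity 0
  nb[nb < .NORM_EPS] <- Inf
  S <- (A / na) %*% t(B / nb)
  pmin(pmax(S, -1), 1)
}

#' Node and edge similarity tensors
#'
#' Computes the cosine similarity between every source and target node
#' attribute vector, and between every source and target relation edge.
#' Edge rows/columns are indexed by the ordered pairs (i, j != i) in
#' lexicographic order, matching [edgePairs()].
#'
#' @param G,Gp source and target [AnalogyGraph-class] objects.
#' @return A list of class \code{"SimilarityTensors"} with elements
#'   \code{nodeSim} (N x N'), \code{edgeSim} (N(N-1) x N'(N'-1)),
#'   \code{srcPairs}, \code{tgtPairs}, \code{nSource}, \code{nTarget} and
#'   \code{normalized} (FALSE until [bistochasticNormalize()] is applied).
#' @export
similarityTensors <- function(G, Gp) {
  nn <- suppressWarnings(validatePair(G, Gp))
  structure(list(
    nodeSim = .cosineMatrix(nodeAttrs(G), nodeAttrs(Gp)),
    edgeSim = .cosineMatrix(edgeFeatures(G), edgeFeatures(Gp)),
    srcPairs = edgePairs(G),
    tgtPairs = edgePairs(Gp),
    nSource = unname(nn[1L]),
    nTarget = unname(nn[2L]),
    normalized = FALSE
  ), class = "SimilarityTensors")
}

#' Iterative bistochastic normalization
#'
#' Maps raw cosine similarities from \eqn{[-1, 1]} to \eqn{[0, 1]} via
#' \eqn{(s + 1)/2} (an order-preserving affine map; Sinkhorn balancing
#' requires nonnegative entries) and then applies \code{nIter} alternating
#' row-sum and column-sum normalizations. Ten iterations bring all row and
#' column sums of a square matrix within about 1e-3 of 1.
#'
#' @param S numeric matrix (raw cosine similarities, or any finite matrix).
#' @param nIter number of row+column normalization passes; default 10.
#' @param shift apply the \eqn{(s+1)/2} range map first (set to FALSE when
#'   \code{S} is already nonnegative).
#' @return The balanced nonnegative matrix.
#' @examples
#' bistochasticNormalize(matrix(c(2, 1, 1, 2), 2), nIter = 1, shift = FALSE)
#' @export
bistochasticNormalize <- function(S, nIter = 10L, shift = TRUE) {
  S <- as.matrix(S)
  .assertFinite(S, "similarity matrix")
  if (shift) S <- (S + 1) / 2
  if (all(S == 0))
    .pamStop("degenerate_similarity",
             "similarity matrix is identically zero after shifting")
  if (any(S < 0))
    .pamStop("invalid_input",
             "matrix has negative entries; use shift = TRUE for raw cosines")
  for (it in seq_len(nIter)) {
    rs <- rowSums(S)
    S <- S / ifelse(rs > 0, rs, 1)
    cs <- colSums(S)
    S <- t(t(S) / ifelse(cs > 0, cs, 1))
  }
  S
}

## Apply the bistochastic pre-normalization to both tensors.
.normalizeTensors <- function(tensors, nIter = 10L) {
  if (isTRUE(tensors$normalized)) return(tensors)
  tensors$nodeSim <- bistochasticNormalize(tensors$nodeSim, nIter)
  tensors$edgeSim <- bistochasticNormalize(tensors$edgeSim, nIter)
  tensors$normalized <- TRUE
  tensors
}

#' Mapping log-likelihood
#'
#' Evaluates the log-likelihood of a soft mapping: the edge term sums
#' \code{M[i,i'] M[j,j'] edgeSim[(i,j),(i',j')]} over all ordered pairs and
#' is divided by \eqn{N(N-1)}; the node term sums
#' \code{M[i,i'] nodeSim[i,i']} and is divided by \eqn{N}
#' (N = number of source nodes). \code{alpha} interpolates between the two.
#'
#' @param M numeric mapping matrix, N x N'.
#' @param tensors a \code{SimilarityTensors} list from
#'   [similarityTensors()].
#' @param alpha node-similarity weight in [0, 1].
#' @return Scalar log-likelihood.
#' @export
mapLogLikelihood <- function(M, tensors, alpha) {
  ns <- tensors$nSource
  sp <- tensors$srcPairs
  tp <- tensors$tgtPairs
  ## A[p, q] = M[i_p, i'_q] * M[j_p, j'_q]
  A <- M[sp[, 1L], tp[, 1L], drop = FALSE] *
       M[sp[, 2L], tp[, 2L], drop = FALSE]
  edgeTerm <- sum(A * tensors$edgeSim) / (ns * (ns - 1))
  nodeTerm <- sum(M * tensors$nodeSim) / ns
  (1 - alpha) * edgeTerm + alpha * nodeTerm
}

#' Log prior favoring isomorphic mappings
#'
#' \eqn{\log p(M) = (1/\beta) \sum M \log M} with \eqn{0 \log 0 = 0}.
#' The value is the negative entropy of M scaled by \eqn{1/\beta}: it is 0
#' for a permutation matrix and most negative for a uniform mapping, so
#' higher \eqn{\beta} weakens the pull toward one-to-one structure in the
#' prior (and strengthens it in the annealed update).
#'
#' @param M nonnegative mapping matrix.
#' @param beta positive inverse temperature.
#' @return Scalar \eqn{\le 0}.
#' @export
priorLog <- function(M, beta) {
  if (any(M < 0))
    .pamStop("invalid_input", "mapping entries must be nonnegative")
  lm <- ifelse(M > 0, log(M), 0)
  sum(M * lm) / beta
}

#' Energy of a mapping
#'
#' The graduated-assignment objective: negative log-likelihood minus the
#' log prior. Lower is better; the decoded permutation should never have
#' higher energy than the uniform mapping.
#'
#' @inheritParams mapLogLikelihood
#' @param beta positive inverse temperature.
#' @return Scalar energy.
#' @export
pamEnergy <- function(M, tensors, alpha, beta) {
  -mapLogLikelihood(M, tensors, alpha) - priorLog(M, beta)
}

## Precompute the linear operator behind the edge compatibility term:
## Emat[(i,i'), (j,j')] = edgeSim[(i,j), (i',j')] for i!=j, i'!=j',
## with (i,i') vectorized column-major so Emat %*% vec(M) works directly.
.edgeOperator <- function(tensors) {
  ns <- tensors$nSource
  nt <- tensors$nTarget
  sp <- tensors$srcPairs
  tp <- tensors$tgtPairs
  rIdx <- outer(sp[, 1L], (tp[, 1L] - 1L) * ns, `+`)
  cIdx <- outer(sp[, 2L], (tp[, 2L] - 1L) * ns, `+`)
  E <- matrix(0, ns * nt, ns * nt)
  E[cbind(as.vector(rIdx), as.vector(cIdx))] <- as.vector(tensors$edgeSim)
  E
}

#' Per-entry compatibility scores
#'
#' The gradient-style score driving each softassign update:
#' \deqn{Q_{ii'} = (1-\alpha) \sum_{j \ne i, j' \ne i'} M_{jj'}
#'   \mathrm{edgeSim}[(i,j),(i',j')] / (2(N-1)) + \alpha\,
#'   \mathrm{nodeSim}_{ii'}.}
#' The edge term is normalized by the number of edges per node,
#' \eqn{2(N-1)}, rather than the total edge count, because the score judges
#' one candidate node-to-node mapping at a time. For rectangular problems
#' the denominator generalizes to \eqn{(N-1) + (N'-1)}.
#'
#' @inheritParams mapLogLikelihood
#' @return Numeric N x N' matrix of compatibilities.
#' @export
compatibility <- function(M, tensors, alpha) {
  .compatibility(M, tensors, alpha, .edgeOperator(tensors))
}

.compatibility <- function(M, tensors, alpha, E) {
  ns <- tensors$nSource
  nt <- tensors$nTarget
  denom <- (ns - 1) + (nt - 1)
  q <- as.vector(E %*% as.vector(M)) / denom
  (1 - alpha) * matrix(q, ns, nt) + alpha * tensors$nodeSim
}

## Sinkhorn balancing of the mapping matrix: rows are driven to sum 1; for
## rectangular problems columns are scaled toward ns/nt so the total mass
## stays ns. Each pass ends on the row step, keeping M row-stochastic.
.sinkhornMapping <- function(M, nIter) {
  ns <- nrow(M)
  nt <- ncol(M)
  colTarget <- ns / nt
  for (s in seq_len(nIter)) {
    cs <- colSums(M)
    M <- M * rep(colTarget / ifelse(cs > 0, cs, 1), each = ns)
    rs <- rowSums(M)
    M <- M / ifelse(rs > 0, rs, 1)
  }
  M
}

#' Graduated-assignment mapping inference
#'
#' Runs the full annealed inference between two attributed graphs:
#' \enumerate{
#'   \item compute node/edge cosine similarity tensors and apply the
#'     bistochastic pre-normalization (\code{config@presimIterations}
#'     passes, default 10);
#'   \item initialize M uniformly (every entry \eqn{1/N});
#'   \item per iteration: compute the compatibility scores Q, set
#'     \eqn{M \leftarrow \exp(\beta Q)} elementwise, apply
#'     \code{config@sinkhornIterations} row/column normalization passes,
#'     then grow \eqn{\beta \leftarrow \beta \cdot} \code{betaGrowth};
#'   \item after exactly \code{config@iterations} iterations (no early
#'     stopping), decode the hard assignment with [hardDecode()].
#' }
#' The energy of M (with the normalized tensors, at the iteration's beta) is
#' recorded after every iteration for diagnostics.
#'
#' @param G,Gp source and target [AnalogyGraph-class] objects.
#' @param config a [PAMConfig-class]; see [pamConfig()].
#' @return A [MappingResult-class].
#' @examples
#' pair <- makeGraphPair(N = 4, seed = 7)
#' res <- graduatedAssignment(pair$source, pair$target,
#'                            pamConfig("2d", iterations = 150L))
#' decodedAssignment(res)
#' @export
graduatedAssignment <- function(G, Gp, config = pamConfig("2d")) {
  stopifnot(is(config, "PAMConfig"))
  validObject(config)
  tensors <- similarityTensors(G, Gp)
  tensors <- .normalizeTensors(tensors, config@presimIterations)
  ns <- tensors$nSource
  nt <- tensors$nTarget
  E <- .edgeOperator(tensors)

  loop <- .gaLoopCpp(E, tensors$nodeSim, config@alpha, config@beta0,
                     config@betaGrowth, config@iterations,
                     config@sinkhornIterations)
  M <- loop$M
  trace <- as.numeric(loop$trace)
  new("MappingResult", M = M, assignment = hardDecode(M),
      energyTrace = trace, iterationsRun = config@iterations,
      finalBeta = loop$finalBeta)
}

#' Hard decode of a soft mapping
#'
#' For each target column, returns the source row with the strongest mapping
#' strength; ties break toward the smallest source index. This is a per-node
#' argmax, not a one-to-one (Hungarian) decode: two targets may select the
#' same source.
#'
#' @param M nonnegative mapping matrix (source rows, target columns).
#' @return Integer vector of length \code{ncol(M)}.
#' @examples
#' hardDecode(matrix(c(0.6, 0.4, 0.7, 0.3), 2))  # both targets pick source 1
#' @export
hardDecode <- function(M) {
  as.integer(apply(as.matrix(M), 2, which.max))
}
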