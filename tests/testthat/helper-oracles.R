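## Independent reference implementations used to check the package's fast
## paths. These deliberately use naive loops / enumeration.

## all permutations of 1..n as rows
allPermutations <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- allPermutations(n - 1)
  out <- NULL
  for (i in seq_len(n)) out <- rbind(out, cbind(i, p + (p >= i)))
  unname(out)
}

## exhaustive maximizer of the mapping log-likelihood over permutation
## matrices; returns the source -> target permutation
bestPermutation <- function(tensors, alpha) {
  n <- tensors$nSource
  perms <- allPermutations(n)
  best <- NULL
  bv <- -Inf
  for (r in seq_len(nrow(perms))) {
    P <- matrix(0, n, n)
    P[cbind(seq_len(n), perms[r, ])] <- 1
    v <- mapLogLikelihood(P, tensors, alpha)
    if (v > bv) { bv <- v; best <- perms[r, ] }
  }
  best
}

## naive double-loop cosine similarity
bruteCosineMatrix <- function(A, B) {
  S <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B)))
      S[i, j] <- cosAngle(A[i, ], B[j, ])
  S
}

## quadruple-loop evaluation of the mapping log-likelihood
bruteLogLikelihood <- function(M, tensors, alpha) {
  ns <- tensors$nSource
  nt <- tensors$nTarget
  sp <- tensors$srcPairs
  tp <- tensors$tgtPairs
  edge <- 0
  for (p in seq_len(nrow(sp)))
    for (q in seq_len(nrow(tp)))
      edge <- edge + M[sp[p, 1], tp[q, 1]] * M[sp[p, 2], tp[q, 2]] *
        tensors$edgeSim[p, q]
  node <- 0
  for (i in seq_len(ns))
    for (ip in seq_len(nt))
      node <- node + M[i, ip] * tensors$nodeSim[i, ip]
  (1 - alpha) * edge / (ns * (ns - 1)) + alpha * node / ns
}

## double-sum compatibility scores
bruteCompatibility <- function(M, tensors, alpha) {
  ns <- tensors$nSource
  nt <- tensors$nTarget
  sp <- tensors$srcPairs
  tp <- tensors$tgtPairs
  pairRow <- function(i, j) which(sp[, 1] == i & sp[, 2] == j)
  pairCol <- function(i, j) which(tp[, 1] == i & tp[, 2] == j)
  Q <- matrix(0, ns, nt)
  for (i in seq_len(ns))
    for (ip in seq_len(nt)) {
      acc <- 0
      for (j in seq_len(ns)[-i])
        for (jp in seq_len(nt)[-ip])
          acc <- acc + M[j, jp] *
            tensors$edgeSim[pairRow(i, j), pairCol(ip, jp)]
      Q[i, ip] <- (1 - alpha) * acc / ((ns - 1) + (nt - 1)) +
        alpha * tensors$nodeSim[i, ip]
    }
  Q
}

## accuracy of a decoded assignment for a GroundTruthPair
decodeAccuracy <- function(pair, config = pamConfig("2d")) {
  res <- graduatedAssignment(pair$source, pair$target, config)
  pairAccuracy(decodedAssignment(res), pair$permutation)
}

## do two labelings describe the identical partition (up to relabeling)?
samePartition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

## hand-assembled similarity tensors for tiny closed-form checks
constantTensors <- function(n, nodeVal = 1, edgeVal = 1) {
  pairs <- pamatch:::.orderedPairs(n)
  structure(list(
    nodeSim = matrix(nodeVal, n, n),
    edgeSim = matrix(edgeVal, nrow(pairs), nrow(pairs)),
    srcPairs = pairs, tgtPairs = pairs,
    nSource = n, nTarget = n, normalized = TRUE
  ), class = "SimilarityTensors")
}
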