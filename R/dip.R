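## Hartigan's dip statistic and a Monte-Carlo unimodality test.
##
## The dip of an empirical distribution function F_n is the smallest
## sup-norm distance between F_n and any unimodal distribution function
## (convex below its mode, concave above, with an atom allowed at the
## mode). It is computed here by the modal-interval algorithm: working in
## count units (F at x_i has value i out of n), iteratively narrow a
## candidate modal interval [low, high] by fitting the greatest convex
## minorant (GCM) and least concave majorant (LCM) of the points (x_i, i)
## on the interval. The binding constraints, each of the form
## 2*n*dip >= value, are
##   * within the modal interval: LCM(x) - GCM(x) + 1 at curve touch
##     points (the +1 accounts for the unit jump of F at each data point);
##   * left of the modal interval (convex side): i + 1 - GCM(x_i);
##   * right of it (concave side): LCM(x_i) - i + 1.
## The dip is the largest such value over the narrowing sequence, divided
## by 2n. An all-equal sample is a point mass (unimodal); its dip is 0.

## lower (convex minorant) hull of points (x, y), x sorted nondecreasing;
## returns indices of the touch points, ascending
.lowerHull <- function(x, y) {
  n <- length(x)
  st <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    while (top >= 2L) {
      a <- st[top - 1L]
      b <- st[top]
      ## pop b if slope(a,b) >= slope(b,i) (cross-multiplied form; safe
      ## with zero-width segments from tied x values)
      if ((y[b] - y[a]) * (x[i] - x[b]) >= (y[i] - y[b]) * (x[b] - x[a]))
        top <- top - 1L
      else break
    }
    top <- top + 1L
    st[top] <- i
  }
  st[seq_len(top)]
}

## upper (concave majorant) hull touch indices, ascending
.upperHull <- function(x, y) {
  n <- length(x)
  st <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    while (top >= 2L) {
      a <- st[top - 1L]
      b <- st[top]
      if ((y[b] - y[a]) * (x[i] - x[b]) <= (y[i] - y[b]) * (x[b] - x[a]))
        top <- top - 1L
      else break
    }
    top <- top + 1L
    st[top] <- i
  }
  st[seq_len(top)]
}

## evaluate a piecewise-linear hull (touch indices over data x, values = the
## indices themselves) at data indices `at`; `lower` picks which value a
## vertical (tied-x) segment takes
.hullEval <- function(touch, x, at, lower = TRUE) {
  seg <- findInterval(at, touch, rightmost.closed = FALSE)
  seg[seg < 1L] <- 1L
  seg[seg >= length(touch)] <- length(touch) - 1L
  t1 <- touch[seg]
  t2 <- touch[seg + 1L]
  out <- numeric(length(at))
  for (q in seq_along(at)) {
    i <- at[q]
    if (i <= touch[1L]) { out[q] <- touch[1L]; next }
    if (i >= touch[length(touch)]) { out[q] <- touch[length(touch)]; next }
    a <- t1[q]; b <- t2[q]
    if (x[b] > x[a]) {
      out[q] <- a + (x[i] - x[a]) * (b - a) / (x[b] - x[a])
    } else {
      out[q] <- if (lower) a else b
    }
  }
  out
}

#' Hartigan's dip statistic
#'
#' The smallest sup-norm distance between the empirical distribution
#' function of \code{x} and the class of unimodal distribution functions.
#' Large values indicate departure from unimodality. The dip of any sample
#' with at least two distinct values is at least \eqn{1/(2n)}; a sample of
#' two equal point masses attains the maximum for its size
#' (e.g. \code{dipStatistic(c(0, 1)) == 0.25}).
#'
#' @param x numeric vector, \eqn{n \ge 2} (an all-equal sample returns 0).
#' @return The dip statistic, a scalar in \eqn{[0, 0.25]}.
#' @examples
#' dipStatistic(c(rep(0, 20), rep(10, 20)))  # 0.25, maximally bimodal
#' @export
dipStatistic <- function(x) {
  x <- sort(as.numeric(x))
  .assertFinite(x, "x")
  n <- length(x)
  if (n < 2) .pamStop("invalid_input", "need at least 2 observations")
  if (x[n] == x[1L]) return(0)

  y <- seq_len(n)
  low <- 1L
  high <- n
  D <- 1          # count units; the 1/(2n) lower bound
  for (round in seq_len(n)) {
    idx <- low:high
    gT <- idx[.lowerHull(x[idx], y[idx])]
    lT <- idx[.upperHull(x[idx], y[idx])]

    ## largest gap between the curves, checked at all touch points
    gapAtG <- .hullEval(lT, x, gT, lower = FALSE) - gT + 1
    gapAtL <- lT - .hullEval(gT, x, lT, lower = TRUE) + 1
    d <- max(gapAtG, gapAtL)
    if (d <= D) break

    ## bracket of the argmax by touch points of the two curves
    if (max(gapAtG) >= max(gapAtL)) {
      at <- gT[which.max(gapAtG)]
    } else {
      at <- lT[which.max(gapAtL)]
    }
    newLow <- max(gT[gT <= at])
    newHigh <- min(lT[lT >= at])

    ## the regions peeled off become pure convex / concave sides
    if (newLow > low) {
      i <- low:newLow
      D <- max(D, max(i + 1 - .hullEval(gT, x, i, lower = TRUE)))
    }
    if (newHigh < high) {
      i <- newHigh:high
      D <- max(D, max(.hullEval(lT, x, i, lower = FALSE) - i + 1))
    }
    if (newLow == low && newHigh == high) { D <- max(D, d); break }
    low <- newLow
    high <- newHigh
  }
  D / (2 * n)
}

#' Monte-Carlo dip test of unimodality
#'
#' Compares the sample's dip statistic with its null distribution under
#' samples of the same size from the uniform distribution (the standard
#' calibration for the dip test: among unimodal distributions the uniform
#' is asymptotically least favorable). The p-value is the fraction of null
#' dips at least as large as the observed one (with the +1 continuity
#' correction).
#'
#' @param x numeric sample, \eqn{n \ge 4}.
#' @param nsim number of null simulations; default 1000.
#' @param seed integer seed for the null draws.
#' @return A list with \code{statistic} (the dip), \code{pValue}, \code{n}
#'   and \code{nsim}.
#' @export
dipTest <- function(x, nsim = 1000L, seed = 1L) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4) .pamStop("invalid_input", "need at least 4 observations")
  stat <- dipStatistic(x)
  null <- .withSeed(seed, vapply(seq_len(nsim), function(b)
    dipStatistic(stats::runif(n)), numeric(1L)))
  list(statistic = stat,
       pValue = (sum(null >= stat) + 1) / (nsim + 1),
       n = n, nsim = as.integer(nsim))
}
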