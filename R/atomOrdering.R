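## Best-fit-plane atom ordering: choose the initial atom (C1) and following
## atom (C2) of a homocyclic ring from the signed distances to the ring's
## orthogonal least-squares plane.

#' Fit the best plane through ring atoms
#'
#' Orthogonal least-squares plane through N ring atoms: the plane passes
#' through the centroid and its normal (the eigenvector of the 3x3 scatter
#' matrix with the smallest eigenvalue) minimizes the sum of squared
#' perpendicular distances.  The signed distance SD of atom i is the dot
#' product of \code{coords[i,] - centroid} with the unit normal; atoms
#' "above" the plane (positive side of the normal) get positive SD.  The
#' normal's sign is fixed deterministically so that the first atom with a
#' nonzero SD has SD > 0; all downstream statistics are invariant to this
#' choice.
#'
#' @param coords numeric N x 3 matrix of Cartesian coordinates (Angstrom),
#'   N = 5 or 6, in cyclic ring order.
#' @return A [PlaneFit-class] with \code{normal}, \code{centroid} and
#'   \code{sd} filled (SDdev/SDsum still empty).
#' @examples
#' hexagon <- cbind(cos(2 * pi * (0:5) / 6), sin(2 * pi * (0:5) / 6), 0)
#' signedDistances(fitPlane(hexagon))  # all ~0: the ring is planar
#' @export
fitPlane <- function(coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3 || !nrow(coords) %in% c(5L, 6L))
    stop("coords must be an N x 3 matrix with N = 5 or 6")
  if (!all(is.finite(coords))) stop("coords must be finite")
  centroid <- colMeans(coords)
  centred <- sweep(coords, 2, centroid)
  e <- eigen(crossprod(centred), symmetric = TRUE)
  ## eigenvalues descending; collinear points leave two near-zero values
  scale2 <- max(e$values[1], .Machine$double.eps)
  if (e$values[2] / scale2 < 1e-12)
    stop("degenerate geometry: ring atoms are collinear")
  normal <- e$vectors[, 3]
  sd <- as.numeric(centred %*% normal)
  nz <- which(abs(sd) > 1e-12)
  if (length(nz) > 0 && sd[nz[1]] < 0) {
    normal <- -normal
    sd <- -sd
  }
  new("PlaneFit", normal = normal, centroid = centroid, sd = sd,
      sdDev = numeric(0), sdSum = numeric(0))
}

#' Neighbour-deviation statistics of signed distances
#'
#' Fills the SDdev and SDsum slots of a [PlaneFit-class]:
#' \code{sdDev[i] = |sd[i] - sd[i+1]|} for the cyclic neighbour pair
#' (i, i+1), and \code{sdSum[i] = sdDev[i-1] + sdDev[i]}, i.e. the sum of
#' the deviations of atom i from both its ring neighbours.  Both are
#' invariant to flipping the plane normal (they use absolute differences).
#'
#' @param plane a [PlaneFit-class] with \code{sd} populated.
#' @return The same [PlaneFit-class] with \code{sdDev} and \code{sdSum}
#'   filled.
#' @export
computeSdStatistics <- function(plane) {
  stopifnot(is(plane, "PlaneFit"))
  sd <- plane@sd
  n <- length(sd)
  if (n == 0) stop("plane has no signed distances")
  nxt <- c(2:n, 1)
  prv <- c(n, 1:(n - 1))
  sdDev <- abs(sd - sd[nxt])
  sdSum <- sdDev[prv] + sdDev
  initialize(plane, sdDev = sdDev, sdSum = sdSum)
}

## indices of tied maxima (within tol of the max)
.tiedMax <- function(v, tol = 1e-9) which(v >= max(v) - tol)

#' Select the initial and following ring atoms
#'
#' Chooses C1 as the ring atom with the highest SDsum and C2 as the
#' neighbour of C1 on the higher-SDdev edge, then re-indexes the ring so
#' that C1 comes first and traversal proceeds toward C2.  Ties (exact
#' symmetry, e.g. an ideal chair where all SDsum are equal) are broken
#' deterministically by the lowest file serial; downstream puckering
#' parameters do not depend on which tied atom wins.
#'
#' @param ring a [RingInstance-class] (atoms in cyclic order).
#' @param plane optional [PlaneFit-class] for the ring; computed (with SD
#'   statistics) when missing.
#' @param tieBreak tie-break rule; only \code{"lowest_serial"} is defined.
#' @return An [OrderedRing-class].
#' @export
selectInitialFollowing <- function(ring, plane = NULL,
                                   tieBreak = "lowest_serial") {
  stopifnot(is(ring, "RingInstance"))
  tieBreak <- match.arg(tieBreak, "lowest_serial")
  atoms <- ring@atoms
  n <- nrow(atoms)
  if (is.null(plane))
    plane <- computeSdStatistics(fitPlane(as.matrix(atoms[, c("x", "y", "z")])))
  if (length(plane@sdSum) != n)
    plane <- computeSdStatistics(plane)
  serial <- atoms$serial
  cand <- .tiedMax(plane@sdSum)
  c1 <- cand[which.min(serial[cand])]
  nxt <- c1 %% n + 1L
  prv <- (c1 - 2L) %% n + 1L
  ## edge (c1, nxt) has deviation sdDev[c1]; edge (prv, c1) has sdDev[prv]
  devNext <- plane@sdDev[c1]
  devPrev <- plane@sdDev[prv]
  if (abs(devNext - devPrev) <= 1e-9) {
    c2 <- if (serial[nxt] <= serial[prv]) nxt else prv
  } else {
    c2 <- if (devNext > devPrev) nxt else prv
  }
  direction <- if (c2 == nxt) 1L else -1L
  idx <- ((c1 - 1L + direction * (0:(n - 1L))) %% n) + 1L
  new("OrderedRing", atoms = atoms[idx, , drop = FALSE],
      originIndex = as.integer(c1), direction = direction,
      plane = plane)
}

#' Order a ring for puckering analysis
#'
#' Convenience wrapper: fit the best plane, compute the SD statistics and
#' select the initial/following atoms in one call.
#'
#' @inheritParams selectInitialFollowing
#' @return An [OrderedRing-class].
#' @export
orderRingAtoms <- function(ring, tieBreak = "lowest_serial") {
  selectInitialFollowing(ring, plane = NULL, tieBreak = tieBreak)
}

#' Dump SD statistics of a ring as a data.frame
#'
#' Debug/plotting aid: one row per ring atom with its name, serial, signed
#' distance, SDdev (to the next atom, cyclically) and SDsum.
#'
#' @param ring a [RingInstance-class].
#' @return data.frame with columns \code{name}, \code{serial}, \code{sd},
#'   \code{sd_dev_next}, \code{sd_sum}.
#' @export
sdStatisticsTable <- function(ring) {
  plane <- computeSdStatistics(
    fitPlane(as.matrix(ring@atoms[, c("x", "y", "z")])))
  data.frame(name = ring@atoms$name, serial = ring@atoms$serial,
              sd = plane@sd, sd_dev_next = plane@sdDev,
              sd_sum = plane@sdSum, stringsAsFactors = FALSE)
}
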