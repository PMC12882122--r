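## CCP4/MRC density maps: binary I/O (mode 2, little-endian), sigma-scaled
## trilinear interpolation at atom centres, and per-ring coverage calls.

## crystallographic orthogonalization matrix (columns = cell vectors a,b,c)
.orthoMatrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; c <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, b * cos(ga), c * cos(be),
           0, b * sin(ga), c * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0,           c * v / sin(ga)),
         nrow = 3, byrow = TRUE)
}

#' Build a DensityMap from a grid in memory
#'
#' Wraps a 3D array of density values as a [DensityMap-class], computing
#' the full-grid mean and rms used for sigma scaling.  The array is in
#' file axis order: element \code{[i, j, k]} sits at grid node
#' \code{start + (i, j, k) - 1} along the crystal axes given by
#' \code{axisOrder}.
#'
#' @param grid 3D numeric array.
#' @param cell numeric(6): cell lengths (Angstrom) and angles (degrees).
#' @param axisOrder integer(3), permutation of 1:3 (default 1:3).
#' @param start integer(3) grid start indices (default 0).
#' @param sampling integer(3) grid sampling along the cell a, b, c axes.
#' @param periodic logical or \code{"auto"}: wrap positions by unit-cell
#'   translations.  \code{"auto"} enables wrapping exactly when the grid
#'   covers the full cell (dimension equals sampling on every axis).
#' @return A [DensityMap-class].
#' @export
densityMapFromGrid <- function(grid, cell, axisOrder = 1:3,
                               start = c(0L, 0L, 0L), sampling,
                               periodic = "auto") {
  axisOrder <- as.integer(axisOrder)
  sampling <- as.integer(sampling)
  if (identical(periodic, "auto"))
    periodic <- all(dim(grid) == sampling[axisOrder])
  m <- mean(grid)
  rms <- sqrt(mean((grid - m)^2))
  new("DensityMap", grid = grid, cell = as.numeric(cell),
      axisOrder = axisOrder, start = as.integer(start),
      sampling = sampling, periodic = isTRUE(periodic),
      mean = m, rms = rms)
}

#' Read a CCP4/MRC density map
#'
#' Parses the 1024-byte header (grid dimensions, mode, start indices,
#' sampling, cell, axis order) and the mode-2 (32-bit float) data block of
#' a little-endian CCP4/MRC map.  The mean and rms used for sigma scaling
#' are recomputed over the full grid rather than trusted from the header.
#'
#' @param path map file.
#' @inheritParams densityMapFromGrid
#' @return A [DensityMap-class].
#' @seealso [writeCcp4Map()], [interpolateSigma()]
#' @export
readCcp4Map <- function(path, periodic = "auto") {
  con <- file(path, "rb")
  on.exit(close(con))
  hdrInt <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdrFlt <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  seek(con, 208)
  magic <- rawToChar(readBin(con, "raw", n = 4))
  if (!identical(substr(magic, 1, 3), "MAP"))
    stop("map-format error: missing 'MAP ' magic in ", path)
  dims <- hdrInt[1:3]
  mode <- hdrInt[4]
  if (mode != 2L)
    stop("map-format error: only mode 2 (float32) maps are supported, got ",
         mode)
  if (any(dims < 2)) stop("map-format error: degenerate grid dimensions")
  start <- hdrInt[5:7]
  sampling <- hdrInt[8:10]
  cell <- hdrFlt[11:16]
  axisOrder <- hdrInt[17:19]
  nsymbt <- hdrInt[24]
  seek(con, 1024 + nsymbt)
  vals <- readBin(con, "numeric", n = prod(dims), size = 4, endian = "little")
  if (length(vals) < prod(dims))
    stop("map-format error: truncated data block in ", path)
  densityMapFromGrid(array(vals, dim = dims), cell = cell,
                     axisOrder = axisOrder, start = start,
                     sampling = sampling, periodic = periodic)
}

#' Write a CCP4/MRC density map
#'
#' Writes a [DensityMap-class] as a little-endian mode-2 CCP4/MRC file
#' (1024-byte header, no symmetry block, float32 data).
#'
#' @param map a [DensityMap-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCcp4Map <- function(map, path) {
  stopifnot(is(map, "DensityMap"))
  con <- file(path, "wb")
  on.exit(close(con))
  wInt <- function(x) writeBin(as.integer(x), con, size = 4,
                               endian = "little")
  wFlt <- function(x) writeBin(as.numeric(x), con, size = 4,
                               endian = "little")
  g <- map@grid
  wInt(dim(g)); wInt(2L)                 # NC NR NS, MODE
  wInt(map@start); wInt(map@sampling)    # NCSTART.., NX NY NZ
  wFlt(map@cell)                         # cell lengths + angles
  wInt(map@axisOrder)                    # MAPC MAPR MAPS
  wFlt(c(min(g), max(g), map@mean))      # AMIN AMAX AMEAN
  wInt(c(1L, 0L))                        # ISPG, NSYMBT
  wInt(rep(0L, 25))                      # EXTRA (words 25-49)
  wFlt(c(0, 0, 0))                       # ORIGIN (words 50-52)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # little-endian stamp
  wFlt(sqrt(mean((g - mean(g))^2)))      # ARMS
  wInt(0L)                               # NLABL
  writeBin(raw(800), con)                # labels
  wFlt(as.numeric(g))
  invisible(path)
}

## continuous file-axis grid coordinates of a Cartesian position
.fileCoords <- function(map, position) {
  frac <- solve(.orthoMatrix(map@cell), position)
  u <- frac * map@sampling              # grid units along crystal axes a,b,c
  u[map@axisOrder] - map@start
}

#' Sigma-scaled trilinear interpolation
#'
#' Interpolates the map value at a Cartesian position from the eight
#' surrounding grid nodes (trilinear blend) and returns it in sigma units:
#' \code{(value - mean) / rms} with mean and rms computed over the full
#' grid.  Positions in periodic (full-cell) maps are wrapped by unit-cell
#' translations; positions outside a non-periodic box map raise an
#' out-of-bounds error.
#'
#' @param map a [DensityMap-class].
#' @param position numeric(3) Cartesian coordinates (Angstrom), or an
#'   N x 3 matrix of positions.
#' @return numeric vector of interpolated values in sigma units.
#' @export
interpolateSigma <- function(map, position) {
  stopifnot(is(map, "DensityMap"))
  if (is.matrix(position))
    return(vapply(seq_len(nrow(position)),
                  function(i) interpolateSigma(map, position[i, ]),
                  numeric(1)))
  dims <- dim(map@grid)
  t <- .fileCoords(map, as.numeric(position))
  i0 <- floor(t)
  f <- t - i0
  idx <- matrix(0L, nrow = 2, ncol = 3)
  for (k in 1:3) {
    if (map@periodic) {
      idx[, k] <- (c(i0[k], i0[k] + 1) %% dims[k]) + 1L
    } else {
      if (t[k] < -1e-9 || t[k] > dims[k] - 1 + 1e-9)
        stop("out-of-bounds: position outside non-periodic map")
      lo <- min(max(i0[k], 0), dims[k] - 2)
      f[k] <- t[k] - lo
      idx[, k] <- c(lo, lo + 1) + 1L
    }
  }
  val <- 0
  for (a in 1:2) for (b in 1:2) for (cc in 1:2) {
    w <- (if (a == 1) 1 - f[1] else f[1]) *
         (if (b == 1) 1 - f[2] else f[2]) *
         (if (cc == 1) 1 - f[3] else f[3])
    val <- val + w * map@grid[idx[a, 1], idx[b, 2], idx[cc, 3]]
  }
  (val - map@mean) / map@rms
}

#' Electron-density coverage of a ring
#'
#' Interpolates the sigma-scaled density at every ring atom centre and
#' flags each atom as covered when its value is strictly greater than the
#' threshold; the ring is all-covered when every atom is.
#'
#' @param ring a [RingInstance-class] (or an N x 3 coordinate matrix).
#' @param map a [DensityMap-class].
#' @param thresholdSigma coverage threshold in sigma units (default 1.5;
#'   1.2 is a common alternative).
#' @param onError \code{"uncovered"} (default) marks an atom whose
#'   interpolation fails (e.g. outside a box map) as not covered, with a
#'   warning; \code{"error"} propagates the failure.
#' @return A [CoverageResult-class].
#' @export
ringCoverage <- function(ring, map, thresholdSigma = 1.5,
                         onError = c("uncovered", "error")) {
  onError <- match.arg(onError)
  coords <- if (is(ring, "RingInstance"))
    as.matrix(ring@atoms[, c("x", "y", "z")]) else as.matrix(ring)
  vals <- vapply(seq_len(nrow(coords)), function(i) {
    if (onError == "error") return(interpolateSigma(map, coords[i, ]))
    tryCatch(interpolateSigma(map, coords[i, ]), error = function(e) {
      warning("atom ", i, " marked not covered: ", conditionMessage(e))
      NA_real_
    })
  }, numeric(1))
  covered <- !is.na(vals) & vals > thresholdSigma
  new("CoverageResult", valuesSigma = vals, covered = covered,
      allCovered = all(covered), thresholdSigma = thresholdSigma)
}
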