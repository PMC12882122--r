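#' @import methods
NULL

## Atom tables ---------------------------------------------------------------
##
## Ligand atoms are carried as a plain data.frame with one row per atom and a
## fixed set of columns.  .atomColumns() is the contract shared by the parsers,
## the fixture writers and the ring extractor.

.atomColumns <- function() {
  c("serial", "name", "element", "x", "y", "z",
    "altloc", "occupancy", "chain", "resno", "comp_id", "entry_id")
}

.checkAtomTable <- function(atoms) {
  missing <- setdiff(.atomColumns(), names(atoms))
  if (length(missing) > 0)
    stop("atom table lacks column(s): ", paste(missing, collapse = ", "))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    stop("atom table contains non-finite coordinates")
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1, na.rm = TRUE))
    stop("occupancy outside [0, 1]")
  invisible(atoms)
}

#' Chemical component bond dictionary
#'
#' Holds the bond rows of one or more chemical components as read from a
#' CCD-style mmCIF dictionary: for every bond the two atom names, the formal
#' bond order (\code{single}, \code{double}, \code{triple} or
#' \code{aromatic}) and the dictionary's aromatic flag.
#'
#' @slot bonds data.frame with columns \code{comp_id}, \code{atom1},
#'   \code{atom2}, \code{order}, \code{aromatic}.
#' @seealso [loadComponentBonds()]
#' @exportClass ComponentBondTable
setClass("ComponentBondTable", representation(bonds = "data.frame"))

setValidity("ComponentBondTable", function(object) {
  b <- object@bonds
  need <- c("comp_id", "atom1", "atom2", "order", "aromatic")
  if (!all(need %in% names(b)))
    return(paste("bonds must have columns", paste(need, collapse = ", ")))
  if (nrow(b) == 0) return(TRUE)
  if (any(b$atom1 == b$atom2))
    return("bond endpoints must be distinct atom names")
  key <- paste(b$comp_id, pmin(b$atom1, b$atom2), pmax(b$atom1, b$atom2))
  if (anyDuplicated(key))
    return("duplicated bond (unordered atom pair) within a component")
  if (!all(b$order %in% c("single", "double", "triple", "aromatic")))
    return("bond order must be single/double/triple/aromatic")
  TRUE
})

#' A ring instance extracted from a structure
#'
#' A cyclically ordered list of 5 or 6 ring atoms together with its ring-type
#' classification and provenance (which entry, component, chain and residue
#' it came from).  Consecutive atoms (cyclically) are bonded in the
#' component's bond graph.
#'
#' @slot atoms data.frame of ring atoms in cyclic order (see
#'   [parseStructure()] for the columns).
#' @slot ringType one of \code{"cyclohexane"}, \code{"cyclopentane"},
#'   \code{"benzene"}, \code{"other"} or \code{"unclassified"}.
#' @slot provenance named list: \code{entry_id}, \code{comp_id},
#'   \code{chain}, \code{resno}, \code{altloc}.
#' @exportClass RingInstance
setClass("RingInstance",
         representation(atoms = "data.frame", ringType = "character",
                        provenance = "list"))

setValidity("RingInstance", function(object) {
  n <- nrow(object@atoms)
  if (!n %in% c(5L, 6L)) return("a ring must have 5 or 6 atoms")
  ok <- c("cyclohexane", "cyclopentane", "benzene", "other", "unclassified")
  if (!object@ringType %in% ok)
    return(paste("ringType must be one of", paste(ok, collapse = ", ")))
  if (object@ringType %in% c("cyclohexane", "cyclopentane", "benzene") &&
      !all(object@atoms$element == "C"))
    return("target ring types must be all-carbon")
  TRUE
})

#' Best-fit plane of a ring
#'
#' Orthogonal least-squares plane through the ring atoms (unit normal and
#' centroid) with the per-atom signed distances SD and, once
#' [computeSdStatistics()] has run, the neighbour deviations SDdev and the
#' per-atom sums SDsum used to pick the initial and following atoms.
#'
#' @slot normal unit 3-vector.
#' @slot centroid 3-vector (Angstrom).
#' @slot sd signed atom-plane distances in ring order (Angstrom).
#' @slot sdDev \code{sdDev[i] = |sd[i] - sd[i+1]|} (cyclic); empty until
#'   computed.
#' @slot sdSum \code{sdSum[i] = sdDev[i-1] + sdDev[i]} (cyclic); empty until
#'   computed.
#' @exportClass PlaneFit
setClass("PlaneFit",
         representation(normal = "numeric", centroid = "numeric",
                        sd = "numeric", sdDev = "numeric", sdSum = "numeric"))

setValidity("PlaneFit", function(object) {
  if (length(object@normal) != 3 || length(object@centroid) != 3)
    return("normal and centroid must be 3-vectors")
  if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-9)
    return("normal must have unit length")
  n <- length(object@sd)
  if (length(object@sdDev) > 0 && length(object@sdDev) != n)
    return("sdDev must have one entry per atom")
  if (length(object@sdSum) > 0 && length(object@sdSum) != n)
    return("sdSum must have one entry per atom")
  TRUE
})

#' A ring re-indexed to start at the initial atom
#'
#' The ring's atoms rotated (and possibly reflected) so that the initial
#' atom C1 comes first and traversal proceeds toward the following atom C2.
#'
#' @slot atoms data.frame of ring atoms, C1 first.
#' @slot originIndex index of C1 in the input ordering.
#' @slot direction +1 (input sense) or -1 (reversed).
#' @slot plane the [PlaneFit-class] used for the selection.
#' @exportClass OrderedRing
setClass("OrderedRing",
         representation(atoms = "data.frame", originIndex = "integer",
                        direction = "integer", plane = "PlaneFit"))

setValidity("OrderedRing", function(object) {
  if (!object@direction %in% c(-1L, 1L)) return("direction must be +1 or -1")
  if (!nrow(object@atoms) %in% c(5L, 6L)) return("5 or 6 atoms required")
  TRUE
})

#' Hill-Reilly puckering parameters
#'
#' The N-3 flap angles (degrees) of the triangular decomposition of an
#' ordered 5- or 6-membered ring: three angles for six-rings, two for
#' five-rings.  After sign normalization the last angle is non-negative
#' (mirror images are not distinguished).
#'
#' @slot theta numeric vector of flap angles in degrees.
#' @slot normalized logical; TRUE once [normalizeSign()] has been applied.
#' @exportClass PuckerParameters
setClass("PuckerParameters",
         representation(theta = "numeric", normalized = "logical"))

setValidity("PuckerParameters", function(object) {
  if (!length(object@theta) %in% c(2L, 3L))
    return("theta must have 2 (five-ring) or 3 (six-ring) components")
  if (any(object@theta <= -180 | object@theta > 180))
    return("theta components must lie in (-180, 180]")
  if (isTRUE(object@normalized) && object@theta[length(object@theta)] < 0)
    return("normalized parameters must have a non-negative last component")
  TRUE
})

#' Conformation assignment of a ring
#'
#' Nearest reference conformation in flap-angle space, the runner-up, and
#' whether the assigned conformation is energetically unfavourable for the
#' ring type.
#'
#' @slot conformation assigned conformation name.
#' @slot distance Euclidean distance in degrees to the assigned reference.
#' @slot runnerUp second-nearest conformation name (NA if only one
#'   candidate).
#' @slot runnerUpDistance its distance (Inf if only one candidate).
#' @slot unfavourable logical.
#' @exportClass ConformationAssignment
setClass("ConformationAssignment",
         representation(conformation = "character", distance = "numeric",
                        runnerUp = "character", runnerUpDistance = "numeric",
                        unfavourable = "logical"))

setValidity("ConformationAssignment", function(object) {
  if (object@distance > object@runnerUpDistance + 1e-12)
    return("assigned distance must not exceed the runner-up distance")
  TRUE
})

#' Electron-density map
#'
#' A CCP4/MRC-style density grid: the 3D value array in file axis order,
#' the unit cell, the header's axis permutation, start indices and
#' sampling, plus the full-grid mean and rms used for sigma scaling.
#'
#' @slot grid 3D numeric array indexed (column, row, section).
#' @slot cell numeric(6): a, b, c (Angstrom), alpha, beta, gamma (degrees).
#' @slot axisOrder integer(3): which crystal axis (1 = a, 2 = b, 3 = c) runs
#'   along file columns, rows and sections (header MAPC/MAPR/MAPS).
#' @slot start integer(3): grid start indices along columns, rows, sections.
#' @slot sampling integer(3): grid sampling along the a, b, c cell axes
#'   (header NX/NY/NZ).
#' @slot periodic logical; TRUE when the grid covers the full unit cell so
#'   positions wrap crystallographically.
#' @slot mean,rms full-grid statistics; \code{rms > 0}.
#' @exportClass DensityMap
setClass("DensityMap",
         representation(grid = "array", cell = "numeric",
                        axisOrder = "integer", start = "integer",
                        sampling = "integer", periodic = "logical",
                        mean = "numeric", rms = "numeric"))

setValidity("DensityMap", function(object) {
  d <- dim(object@grid)
  if (length(d) != 3) return("grid must be a 3D array")
  if (any(d < 2)) return("grid must have at least 2 nodes per axis")
  if (length(object@cell) != 6) return("cell must be numeric(6)")
  if (any(object@cell[1:3] <= 0)) return("cell lengths must be positive")
  if (!identical(sort(object@axisOrder), 1:3))
    return("axisOrder must be a permutation of 1:3")
  if (!(object@rms > 0)) return("map rms must be positive")
  TRUE
})

#' Electron-density coverage of a ring
#'
#' Per-atom sigma-scaled density values at atom centres, per-atom covered
#' flags (strictly above the threshold), and the ring-level all-covered
#' flag.
#'
#' @slot valuesSigma per-atom interpolated values in sigma units (NA when
#'   interpolation failed).
#' @slot covered per-atom logical.
#' @slot allCovered logical.
#' @slot thresholdSigma threshold used (sigma units).
#' @exportClass CoverageResult
setClass("CoverageResult",
         representation(valuesSigma = "numeric", covered = "logical",
                        allCovered = "logical", thresholdSigma = "numeric"))

setValidity("CoverageResult", function(object) {
  if (length(object@covered) != length(object@valuesSigma))
    return("covered and valuesSigma must have the same length")
  want <- !is.na(object@valuesSigma) &
    object@valuesSigma > object@thresholdSigma
  if (!identical(object@covered, want))
    return("covered flags must equal valuesSigma > thresholdSigma (strict)")
  if (!identical(object@allCovered, all(object@covered)))
    return("allCovered must be the conjunction of the covered flags")
  TRUE
})

## show methods --------------------------------------------------------------

setMethod("show", "RingInstance", function(object) {
  p <- object@provenance
  cat(sprintf("RingInstance: %d-membered %s ring\n", nrow(object@atoms),
              object@ringType))
  cat(sprintf("  %s / %s chain %s residue %s altloc '%s'\n",
              p$entry_id, p$comp_id, p$chain, p$resno,
              if (nzchar(p$altloc)) p$altloc else " "))
  cat("  atoms:", paste(object@atoms$name, collapse = "-"), "\n")
})

setMethod("show", "PlaneFit", function(object) {
  cat("PlaneFit\n  normal:  ", paste(sprintf("%.4f", object@normal),
                                     collapse = " "), "\n")
  cat("  SD (A):  ", paste(sprintf("%+.3f", object@sd), collapse = " "), "\n")
  if (length(object@sdSum))
    cat("  SDsum:   ", paste(sprintf("%.3f", object@sdSum),
                             collapse = " "), "\n")
})

setMethod("show", "PuckerParameters", function(object) {
  cat(sprintf("PuckerParameters (%s): %s\n",
              if (object@normalized) "sign-normalized" else "raw",
              paste(sprintf("%.1f", object@theta), collapse = ", ")))
})

setMethod("show", "ConformationAssignment", function(object) {
  cat(sprintf("ConformationAssignment: %s (distance %.2f deg%s)%s\n",
              object@conformation, object@distance,
              if (is.finite(object@runnerUpDistance))
                sprintf(", runner-up %s at %.2f", object@runnerUp,
                        object@runnerUpDistance) else "",
              if (object@unfavourable) " [energetically unfavourable]" else ""))
})

setMethod("show", "DensityMap", function(object) {
  d <- dim(object@grid)
  cat(sprintf("DensityMap: %d x %d x %d grid (%s)\n", d[1], d[2], d[3],
              if (object@periodic) "periodic" else "box"))
  cat(sprintf("  cell: %.2f %.2f %.2f A, %.1f %.1f %.1f deg\n",
              object@cell[1], object@cell[2], object@cell[3],
              object@cell[4], object@cell[5], object@cell[6]))
  cat(sprintf("  mean %.4g, rms %.4g\n", object@mean, object@rms))
})

setMethod("show", "CoverageResult", function(object) {
  cat(sprintf("CoverageResult: %d/%d atoms covered at %.2f sigma%s\n",
              sum(object@covered), length(object@covered),
              object@thresholdSigma,
              if (object@allCovered) " (all covered)" else ""))
})
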