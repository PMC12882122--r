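## Accessor generics.  Slot access from user code should go through these.

#' @export
setGeneric("ringType", function(x) standardGeneric("ringType"))
#' @export
setGeneric("ringAtoms", function(x) standardGeneric("ringAtoms"))
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @export
setGeneric("theta", function(x) standardGeneric("theta"))
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @export
setGeneric("signedDistances", function(x) standardGeneric("signedDistances"))
#' @export
setGeneric("sdDev", function(x) standardGeneric("sdDev"))
#' @export
setGeneric("sdSum", function(x) standardGeneric("sdSum"))
#' @export
setGeneric("planeNormal", function(x) standardGeneric("planeNormal"))
#' @export
setGeneric("planeCentroid", function(x) standardGeneric("planeCentroid"))
#' @export
setGeneric("assignedConformation",
           function(x) standardGeneric("assignedConformation"))
#' @export
setGeneric("assignmentDistance",
           function(x) standardGeneric("assignmentDistance"))
#' @export
setGeneric("isUnfavourable", function(x) standardGeneric("isUnfavourable"))
#' @export
setGeneric("valuesSigma", function(x) standardGeneric("valuesSigma"))
#' @export
setGeneric("coveredAtoms", function(x) standardGeneric("coveredAtoms"))
#' @export
setGeneric("allCovered", function(x) standardGeneric("allCovered"))
#' @export
setGeneric("mapGrid", function(x) standardGeneric("mapGrid"))
#' @export
setGeneric("mapCell", function(x) standardGeneric("mapCell"))
#' @export
setGeneric("mapRms", function(x) standardGeneric("mapRms"))
#' @export
setGeneric("mapMean", function(x) standardGeneric("mapMean"))
#' @export
setGeneric("componentIds", function(x) standardGeneric("componentIds"))
#' @export
setGeneric("componentBonds",
           function(x, compId) standardGeneric("componentBonds"))

#' Accessors for ringconf classes
#'
#' Small accessor methods returning slot contents: ring type, atoms and
#' provenance of a [RingInstance-class]; flap angles of
#' [PuckerParameters-class]; plane geometry and SD statistics of a
#' [PlaneFit-class]; assignment fields of a
#' [ConformationAssignment-class]; grid, cell and statistics of a
#' [DensityMap-class]; per-atom values and flags of a
#' [CoverageResult-class]; component ids and per-component bond rows of a
#' [ComponentBondTable-class].
#'
#' @param x an object of the documented class.
#' @param compId a component identifier present in the table.
#' @return The corresponding slot value (a vector, data.frame or list).
#' @name accessors
#' @aliases ringType ringAtoms provenance theta isNormalized signedDistances
#'   sdDev sdSum planeNormal planeCentroid assignedConformation
#'   assignmentDistance isUnfavourable valuesSigma coveredAtoms allCovered
#'   mapGrid mapCell mapRms mapMean componentIds componentBonds
NULL

#' @rdname accessors
setMethod("ringType", "RingInstance", function(x) x@ringType)
#' @rdname accessors
setMethod("ringAtoms", "RingInstance", function(x) x@atoms)
#' @rdname accessors
setMethod("ringAtoms", "OrderedRing", function(x) x@atoms)
#' @rdname accessors
setMethod("provenance", "RingInstance", function(x) x@provenance)
#' @rdname accessors
setMethod("theta", "PuckerParameters", function(x) x@theta)
#' @rdname accessors
setMethod("isNormalized", "PuckerParameters", function(x) x@normalized)
#' @rdname accessors
setMethod("signedDistances", "PlaneFit", function(x) x@sd)
#' @rdname accessors
setMethod("sdDev", "PlaneFit", function(x) x@sdDev)
#' @rdname accessors
setMethod("sdSum", "PlaneFit", function(x) x@sdSum)
#' @rdname accessors
setMethod("planeNormal", "PlaneFit", function(x) x@normal)
#' @rdname accessors
setMethod("planeCentroid", "PlaneFit", function(x) x@centroid)
#' @rdname accessors
setMethod("assignedConformation", "ConformationAssignment",
          function(x) x@conformation)
#' @rdname accessors
setMethod("assignmentDistance", "ConformationAssignment",
          function(x) x@distance)
#' @rdname accessors
setMethod("isUnfavourable", "ConformationAssignment",
          function(x) x@unfavourable)
#' @rdname accessors
setMethod("valuesSigma", "CoverageResult", function(x) x@valuesSigma)
#' @rdname accessors
setMethod("coveredAtoms", "CoverageResult", function(x) x@covered)
#' @rdname accessors
setMethod("allCovered", "CoverageResult", function(x) x@allCovered)
#' @rdname accessors
setMethod("mapGrid", "DensityMap", function(x) x@grid)
#' @rdname accessors
setMethod("mapCell", "DensityMap", function(x) x@cell)
#' @rdname accessors
setMethod("mapRms", "DensityMap", function(x) x@rms)
#' @rdname accessors
setMethod("mapMean", "DensityMap", function(x) x@mean)
#' @rdname accessors
setMethod("componentIds", "ComponentBondTable",
          function(x) unique(x@bonds$comp_id))
#' @rdname accessors
setMethod("componentBonds", "ComponentBondTable", function(x, compId) {
  x@bonds[x@bonds$comp_id == compId, , drop = FALSE]
})
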