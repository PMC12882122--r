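## End-to-end driver: structures + dictionary + maps + resolutions -> report.

#' Analyze ring conformations across structure files
#'
#' Runs the whole workflow: parse each structure, find all-carbon 5/6
#' rings per ligand residue, classify their ring type from the bond
#' dictionary, compute and sign-normalize the Hill-Reilly flap angles,
#' assign the nearest reference conformation, evaluate electron-density
#' coverage where a map is available, and flag experimentally supported
#' rings.  Rings classified \code{"other"} are dropped.
#'
#' @param structureFiles character vector of PDB/mmCIF files.
#' @param dictionary path to a CCD-style bond dictionary, or a
#'   [ComponentBondTable-class].
#' @param mapFiles named character vector of CCP4/MRC map files keyed by
#'   entry id (or NULL: coverage columns stay NA).
#' @param resolutions named numeric vector keyed by entry id, a path to a
#'   resolution table ([readResolutionTable()]), or NULL.
#' @param mode ring-type classification mode, see [classifyRingType()].
#' @param altloc altloc selection, see [findCarbonRings()].
#' @param thresholdSigma coverage threshold in sigma units.
#' @param resolutionCutoff inclusive support cutoff in Angstrom.
#' @param reference reference conformer table.
#' @return data.frame of per-ring report rows (fixed column order, see
#'   [writeRingCsv()]).
#' @examples
#' dir <- file.path(tempdir(), "ringconf-demo")
#' manifest <- writeFixtureBundle(dir, seed = 7)
#' rows <- analyzeStructures(manifest$pdb,
#'                           file.path(dir, "components.cif"),
#'                           mapFiles = setNames(manifest$map,
#'                                               manifest$entry_id),
#'                           resolutions = file.path(dir, "resolution.csv"))
#' rows[, c("entry_id", "ring_type", "conformation", "supported")]
#' @export
analyzeStructures <- function(structureFiles, dictionary, mapFiles = NULL,
                              resolutions = NULL,
                              mode = c("aromatic_flag", "paper_replication"),
                              altloc = "A", thresholdSigma = 1.5,
                              resolutionCutoff = 2.0,
                              reference = referenceConformers()) {
  mode <- match.arg(mode)
  bonds <- if (is(dictionary, "ComponentBondTable")) dictionary
    else loadComponentBonds(dictionary)
  if (is.character(resolutions) && length(resolutions) == 1 &&
      file.exists(resolutions))
    resolutions <- readResolutionTable(resolutions)
  rows <- list()
  for (sf in structureFiles) {
    atoms <- parseStructure(sf)
    rings <- findCarbonRings(atoms, bonds, altloc = altloc)
    rings <- lapply(rings, classifyRingType, bonds = bonds, mode = mode)
    rings <- Filter(function(r) ringType(r) %in%
                      c("cyclohexane", "cyclopentane", "benzene"), rings)
    if (length(rings) == 0) next
    entry <- provenance(rings[[1]])$entry_id
    map <- NULL
    if (!is.null(mapFiles) && entry %in% names(mapFiles))
      map <- readCcp4Map(mapFiles[[entry]])
    res <- if (!is.null(resolutions) && entry %in% names(resolutions))
      resolutions[[entry]] else NA
    for (ring in rings) {
      analysis <- analyzeRing(ring, reference)
      cov <- if (is.null(map)) NULL
        else ringCoverage(ring, map, thresholdSigma)
      rows[[length(rows) + 1L]] <- ringReportRow(
        ring, analysis, cov, res, resolutionCutoff)
    }
  }
  if (length(rows) == 0)
    return(stats::setNames(
      data.frame(matrix(nrow = 0, ncol = length(.reportColumns()))),
      .reportColumns()))
  do.call(rbind, rows)
}
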