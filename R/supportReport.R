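## Per-ring report rows, experimental-support calls, summary tables and
## CSV round-tripping.

## round half away from zero to `digits` decimals (presentation convention)
.roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Is a ring supported by experimental data?
#'
#' A ring is experimentally supported when the structure was refined at a
#' resolution of 2 Angstrom or better (inclusive) and every ring atom is
#' covered by electron density.  A missing resolution makes the ring
#' unsupported, with a missing-metadata warning.
#'
#' @param resolution resolution in Angstrom (NA when unknown).
#' @param coverage a [CoverageResult-class].
#' @param resolutionCutoff inclusive cutoff in Angstrom (default 2.0).
#' @return logical.
#' @export
isSupported <- function(resolution, coverage, resolutionCutoff = 2.0) {
  stopifnot(is(coverage, "CoverageResult"))
  if (is.na(resolution)) {
    warning("missing-metadata: no resolution value; ring marked unsupported")
    return(FALSE)
  }
  if (resolution <= 0) stop("resolution must be positive")
  resolution <= resolutionCutoff && coverage@allCovered
}

## fixed output column order
.reportColumns <- function() {
  c("entry_id", "component_id", "chain", "residue_number", "altloc",
    "ring_type", "atom_names", "theta_1", "theta_2", "theta_3",
    "conformation", "distance_deg", "unfavourable", "resolution_A",
    "atoms_covered", "all_covered", "supported")
}

#' Build one report row for an analyzed ring
#'
#' Joins the ring's provenance, flap angles, conformation assignment,
#' coverage and resolution into a single data.frame row with the fixed
#' report column order.
#'
#' @param ring a classified [RingInstance-class].
#' @param analysis result of [analyzeRing()] for the ring.
#' @param coverage a [CoverageResult-class] (or NULL: coverage columns NA).
#' @param resolution resolution in Angstrom (NA when unknown).
#' @param resolutionCutoff inclusive support cutoff, Angstrom.
#' @return one-row data.frame.
#' @export
ringReportRow <- function(ring, analysis, coverage = NULL, resolution = NA,
                          resolutionCutoff = 2.0) {
  p <- ring@provenance
  th <- theta(analysis$parameters)
  asg <- analysis$assignment
  nCov <- if (is.null(coverage)) NA_integer_ else sum(coveredAtoms(coverage))
  allCov <- if (is.null(coverage)) NA else allCovered(coverage)
  sup <- if (is.null(coverage)) FALSE
    else isSupported(resolution, coverage, resolutionCutoff)
  data.frame(entry_id = p$entry_id, component_id = p$comp_id,
             chain = p$chain, residue_number = p$resno, altloc = p$altloc,
             ring_type = ring@ringType,
             atom_names = paste(ring@atoms$name, collapse = ","),
             theta_1 = th[1], theta_2 = th[2],
             theta_3 = if (length(th) >= 3) th[3] else NA_real_,
             conformation = assignedConformation(asg),
             distance_deg = assignmentDistance(asg),
             unfavourable = isUnfavourable(asg),
             resolution_A = as.numeric(resolution),
             atoms_covered = nCov, all_covered = allCov, supported = sup,
             stringsAsFactors = FALSE)
}

## conformations in reference-table order per ring type
.conformationOrder <- function(reference = referenceConformers()) {
  split(reference$conformation, reference$ring_type)[
    unique(reference$ring_type)]
}

#' Summarize report rows into an occurrence table
#'
#' Per ring type: the number and percentage of rings in each conformation,
#' for all rings and for the experimentally supported subset, plus
#' energetically favourable/unfavourable subtotals and totals.
#' Percentages are relative to the ring type's total number of rings (for
#' both the all-rings and the supported columns) and are rounded half-up
#' to two decimals.  Favourable conformations are chair for cyclohexane,
#' half-chair and envelope for cyclopentane, and flat for benzene.
#'
#' @param rows report rows (data.frame as built by [ringReportRow()]).
#' @return data.frame with columns \code{ring_type}, \code{conformation}
#'   (conformation name, \code{"favourable"}, \code{"unfavourable"} or
#'   \code{"total"}), \code{n_all}, \code{pct_all}, \code{n_supported},
#'   \code{pct_supported}.  Empty input gives an empty table.
#' @export
aggregateReport <- function(rows) {
  empty <- data.frame(ring_type = character(0), conformation = character(0),
                      n_all = integer(0), pct_all = numeric(0),
                      n_supported = integer(0), pct_supported = numeric(0),
                      stringsAsFactors = FALSE)
  if (is.null(rows) || nrow(rows) == 0) return(empty)
  out <- list()
  for (rt in intersect(c("cyclohexane", "cyclopentane", "benzene"),
                       unique(rows$ring_type))) {
    sub <- rows[rows$ring_type == rt, , drop = FALSE]
    total <- nrow(sub)
    fav <- .favourableConformations[[rt]]
    confs <- unique(c(intersect(
      unlist(.conformationOrder()[rt], use.names = FALSE),
      sub$conformation), sort(unique(sub$conformation))))
    line <- function(label, sel) {
      nAll <- sum(sel)
      nSup <- sum(sel & sub$supported)
      data.frame(ring_type = rt, conformation = label, n_all = nAll,
                 pct_all = .roundHalfUp(100 * nAll / total),
                 n_supported = nSup,
                 pct_supported = .roundHalfUp(100 * nSup / total),
                 stringsAsFactors = FALSE)
    }
    out[[length(out) + 1L]] <- do.call(rbind, c(
      lapply(confs, function(cf) line(cf, sub$conformation == cf)),
      list(line("favourable", sub$conformation %in% fav),
           line("unfavourable", !sub$conformation %in% fav),
           line("total", rep(TRUE, total)))))
  }
  do.call(rbind, out)
}

#' Write and read per-ring report CSV
#'
#' Lossless round-trip of the fixed-order report columns; fields
#' containing commas (the atom-name list) are quoted per the CSV
#' standard.
#'
#' @param rows report rows.
#' @param path CSV file.
#' @return \code{writeRingCsv}: \code{path} invisibly;
#'   \code{readRingCsv}: the rows.
#' @export
writeRingCsv <- function(rows, path) {
  cols <- .reportColumns()
  missing <- setdiff(cols, names(rows))
  if (length(missing) > 0)
    stop("report rows lack column(s): ", paste(missing, collapse = ", "))
  utils::write.csv(rows[, cols, drop = FALSE], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname writeRingCsv
#' @export
readRingCsv <- function(path) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(entry_id = "character",
                                         component_id = "character",
                                         chain = "character",
                                         altloc = "character",
                                         atom_names = "character",
                                         conformation = "character"),
                          na.strings = "")
  rows$altloc[is.na(rows$altloc)] <- ""
  rows$unfavourable <- as.logical(rows$unfavourable)
  rows$all_covered <- as.logical(rows$all_covered)
  rows$supported <- as.logical(rows$supported)
  rows
}

#' Read a resolution metadata table
#'
#' Two-column table (\code{entry_id}, \code{resolution} in Angstrom),
#' comma- or tab-separated, mapping structure entries to their refinement
#' resolution.  Duplicate entry ids are an error.
#'
#' @param path table file.
#' @return named numeric vector: resolutions keyed by entry id.
#' @export
readResolutionTable <- function(path) {
  sep <- if (grepl("\t", readLines(path, n = 1))) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2)
    stop("resolution table must have entry_id and resolution columns")
  names(tab)[1:2] <- c("entry_id", "resolution")
  if (anyDuplicated(tab$entry_id))
    stop("duplicate entry id(s) in resolution table: ",
         paste(unique(tab$entry_id[duplicated(tab$entry_id)]),
               collapse = ", "))
  stats::setNames(as.numeric(tab$resolution), tab$entry_id)
}
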