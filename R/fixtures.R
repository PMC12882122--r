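## Synthetic fixtures: parametric ring conformers, structure files (PDB and
## mmCIF), CCD-style bond dictionaries, Gaussian-atom density maps and a
## self-contained bundle for end-to-end runs.

## Out-of-plane displacement models.  Each conformer is a mixture of the
## two lowest pucker modes of a regular N-gon,
##   z_j = q2 * cos(2 * a_j + phi2) + q3 * cos(3 * a_j),   a_j = 2*pi*(j-1)/N
## (the q3 term exists only for six-rings, where cos(3 a_j) alternates +1/-1).
## The (q2, phi2, q3) values below were calibrated once so that the computed,
## sign-normalized flap angles of each conformer land on the corresponding
## reference vector of the shipped conformer table; they are fixture
## constants, not tunables.
.conformerModes <- list(
  cyclohexane = list(
    chair        = c(q2 = 0,        phi2 = 0,        q3 = 0.242447),
    `half-chair` = c(q2 = 0.328368, phi2 = 3.610431, q3 = -0.131978),
    boat         = c(q2 = 0.503854, phi2 = 1.039246, q3 = 0.024772),
    `twist-boat` = c(q2 = 0.530606, phi2 = 4.701027, q3 = -0.001054),
    flat         = c(q2 = 0,        phi2 = 0,        q3 = 0)),
  cyclopentane = list(
    `half-chair` = c(q2 = 0.267956, phi2 = 2.136553, q3 = 0),
    envelope     = c(q2 = 0.270697, phi2 = 3.146206, q3 = 0),
    flat         = c(q2 = 0,        phi2 = 0,        q3 = 0)),
  benzene = list(
    flat         = c(q2 = 0,        phi2 = 0,        q3 = 0)))

.ringSize <- function(ringType)
  if (ringType == "cyclopentane") 5L else 6L

.defaultBondLength <- function(ringType)
  if (ringType == "benzene") 1.39 else 1.54

## uniform random rotation matrix (quaternion method)
.randomRotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Generate coordinates of a parametric ring conformer
#'
#' Places N carbons on a regular N-gon of the requested bond length and
#' applies the out-of-plane displacement pattern of the named conformation
#' (chair: alternating up/down; boat: atoms 1 and 4 on the same side;
#' twist-boat and half-chair: mixtures of the two pucker modes; envelope:
#' one atom lifted out of the plane of the other four; flat: no
#' displacement), then an optional rigid-body pose and isotropic Gaussian
#' coordinate noise.  With the default amplitude the computed flap angles
#' of the noise-free conformer match the shipped reference vectors.
#'
#' @param ringType \code{"cyclohexane"}, \code{"cyclopentane"} or
#'   \code{"benzene"}.
#' @param conformation conformation name valid for the ring type.
#' @param bondLength carbon-carbon bond length in Angstrom (default 1.54
#'   saturated, 1.39 aromatic).
#' @param amplitude scale of the out-of-plane displacement relative to the
#'   calibrated geometry: 1 reproduces the reference flap angles, 0 gives
#'   a flat ring.
#' @param pose \code{NULL} (identity), \code{"random"} (seeded random
#'   rotation plus a translation drawn in [-10, 10] Angstrom), or a list
#'   with elements \code{rotation} (3 x 3) and \code{translation} (3).
#' @param noiseSd isotropic coordinate noise, Angstrom.
#' @param seed integer seed for pose and noise (required when either is
#'   random).
#' @return N x 3 coordinate matrix (Angstrom).
#' @export
makeConformer <- function(ringType, conformation,
                          bondLength = .defaultBondLength(ringType),
                          amplitude = 1, pose = NULL, noiseSd = 0,
                          seed = NULL) {
  ringType <- match.arg(ringType, names(.conformerModes))
  modes <- .conformerModes[[ringType]]
  if (!conformation %in% names(modes))
    stop("unknown conformation '", conformation, "' for ", ringType)
  if (amplitude < 0 || noiseSd < 0)
    stop("amplitude and noiseSd must be non-negative")
  m <- modes[[conformation]]
  n <- .ringSize(ringType)
  ang <- 2 * pi * (0:(n - 1)) / n
  radius <- bondLength / (2 * sin(pi / n))
  z <- amplitude * (m["q2"] * cos(2 * ang + m["phi2"]) +
                      m["q3"] * cos(3 * ang))
  coords <- cbind(x = radius * cos(ang), y = radius * sin(ang),
                  z = as.numeric(z))
  if (!is.null(seed)) set.seed(seed)
  if (identical(pose, "random"))
    pose <- list(rotation = .randomRotation(),
                 translation = stats::runif(3, -10, 10))
  if (!is.null(pose))
    coords <- sweep(coords %*% t(pose$rotation), 2, -pose$translation)
  if (noiseSd > 0)
    coords <- coords + matrix(stats::rnorm(3 * n, 0, noiseSd), ncol = 3)
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  coords
}

#' Wrap conformer coordinates as a RingInstance
#'
#' Convenience for tests and fixtures: builds a classified
#' [RingInstance-class] around a coordinate matrix, with atom names
#' C1..CN and sequential serials.
#'
#' @param coords N x 3 coordinate matrix.
#' @param ringType ring type label.
#' @param compId,entryId,chain,resno,altloc provenance fields.
#' @return A [RingInstance-class].
#' @export
ringFromCoords <- function(coords, ringType = "cyclohexane",
                           compId = "CHX", entryId = "synth", chain = "A",
                           resno = 1L, altloc = "") {
  n <- nrow(coords)
  atoms <- data.frame(serial = seq_len(n), name = paste0("C", seq_len(n)),
                      element = "C", x = coords[, 1], y = coords[, 2],
                      z = coords[, 3], altloc = altloc, occupancy = 1,
                      chain = chain, resno = as.integer(resno),
                      comp_id = compId, entry_id = entryId,
                      stringsAsFactors = FALSE)
  new("RingInstance", atoms = atoms, ringType = ringType,
      provenance = list(entry_id = entryId, comp_id = compId, chain = chain,
                        resno = as.integer(resno), altloc = altloc))
}

#' Synthetic density map with Gaussian atom peaks
#'
#' Builds a box density map as a sum of isotropic Gaussians at the kept
#' atom positions plus seeded low-amplitude background noise, scaled so
#' that the smallest interpolated sigma value over the kept atom centres
#' equals the requested target.  The achieved sigma value at every atom
#' centre (including dropped atoms) is attached as attribute
#' \code{"atomSigma"} so coverage expectations are checkable.
#'
#' @param atoms N x 3 matrix of atom positions (Angstrom).
#' @param gridSpacing grid step in Angstrom.
#' @param peakWidth Gaussian standard deviation of each atom peak,
#'   Angstrom.
#' @param peakSigmaTarget target sigma value at the weakest kept atom
#'   centre (default 3).
#' @param dropAtoms integer indices of atoms whose peaks are omitted.
#' @param margin box padding around the atoms, Angstrom.
#' @param noiseFrac background noise standard deviation relative to unit
#'   peak height.
#' @param seed integer seed for the background noise.
#' @return A [DensityMap-class] with attribute \code{"atomSigma"}.
#' @export
makeDensityMap <- function(atoms, gridSpacing = 0.4, peakWidth = 0.8,
                           peakSigmaTarget = 3, dropAtoms = integer(0),
                           margin = 4, noiseFrac = 0.1, seed = 1) {
  atoms <- as.matrix(atoms)
  if (gridSpacing <= 0 || peakWidth <= 0)
    stop("gridSpacing and peakWidth must be positive")
  lo <- apply(atoms, 2, min) - margin
  hi <- apply(atoms, 2, max) + margin
  start <- as.integer(floor(lo / gridSpacing))
  dims <- as.integer(ceiling((hi - start * gridSpacing) / gridSpacing)) + 1L
  if (any(atoms < matrix(start * gridSpacing, nrow(atoms), 3, byrow = TRUE)) ||
      any(atoms > matrix((start + dims - 1) * gridSpacing,
                         nrow(atoms), 3, byrow = TRUE)))
    stop("atoms outside the declared box")
  sampling <- dims + 7L                 # cell larger than the box: not periodic
  cell <- c(sampling * gridSpacing, 90, 90, 90)
  ax <- (start[1] + 0:(dims[1] - 1)) * gridSpacing
  ay <- (start[2] + 0:(dims[2] - 1)) * gridSpacing
  az <- (start[3] + 0:(dims[3] - 1)) * gridSpacing
  keep <- setdiff(seq_len(nrow(atoms)), dropAtoms)
  peaks <- array(0, dim = dims)
  for (i in keep) {
    gx <- exp(-(ax - atoms[i, 1])^2 / (2 * peakWidth^2))
    gy <- exp(-(ay - atoms[i, 2])^2 / (2 * peakWidth^2))
    gz <- exp(-(az - atoms[i, 3])^2 / (2 * peakWidth^2))
    peaks <- peaks + outer(outer(gx, gy), gz)
  }
  set.seed(seed)
  noise <- array(stats::rnorm(prod(dims), 0, noiseFrac), dim = dims)
  buildMap <- function(A)
    densityMapFromGrid(A * peaks + noise, cell = cell, start = start,
                       sampling = sampling, periodic = FALSE)
  atomSigma <- function(map)
    vapply(seq_len(nrow(atoms)),
           function(i) interpolateSigma(map, atoms[i, ]), numeric(1))
  if (length(keep) == 0) {
    map <- buildMap(0)
  } else {
    ## sigma value at the weakest kept peak grows monotonically with the
    ## peak height and saturates; bisect for the target
    target <- function(A) min(atomSigma(buildMap(A))[keep]) - peakSigmaTarget
    loA <- 1e-3; hiA <- 1
    while (target(hiA) < 0 && hiA < 1e6) hiA <- hiA * 4
    if (target(hiA) < 0)
      stop("peakSigmaTarget ", peakSigmaTarget,
           " is not reachable with this geometry")
    for (it in 1:60) {
      mid <- (loA + hiA) / 2
      if (target(mid) < 0) loA <- mid else hiA <- mid
    }
    map <- buildMap(hiA)
  }
  attr(map, "atomSigma") <- atomSigma(map)
  map
}

## ---- structure and dictionary writers -------------------------------------

#' Write ligand atoms as a minimal PDB file
#'
#' Emits HETATM records (fixed-column PDB format) for an atom table and a
#' terminating END record.
#'
#' @param atoms atom data.frame (see [parseStructure()] for columns).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeStructurePdb <- function(atoms, path) {
  .checkAtomTable(atoms)
  lines <- sprintf(
    "HETATM%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    atoms$serial,
    ifelse(nchar(atoms$name) < 4, paste0(" ", atoms$name), atoms$name),
    ifelse(nzchar(atoms$altloc), atoms$altloc, " "),
    atoms$comp_id, atoms$chain, atoms$resno,
    atoms$x, atoms$y, atoms$z, atoms$occupancy, 0, atoms$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write ligand atoms as a minimal mmCIF file
#'
#' Emits a single \code{_atom_site} loop carrying the same fields as
#' [writeStructurePdb()].
#'
#' @inheritParams writeStructurePdb
#' @param entryId data block name; defaults to the entry id of the first
#'   atom.
#' @return \code{path}, invisibly.
#' @export
writeStructureCif <- function(atoms, path, entryId = atoms$entry_id[1]) {
  .checkAtomTable(atoms)
  hdr <- c(paste0("data_", entryId), "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "auth_asym_id",
                    "auth_seq_id", "Cartn_x", "Cartn_y", "Cartn_z",
                    "occupancy")))
  rows <- sprintf("HETATM %d %s %s %s %s %s %d %.3f %.3f %.3f %.2f",
                  atoms$serial, atoms$element, atoms$name,
                  ifelse(nzchar(atoms$altloc), atoms$altloc, "."),
                  atoms$comp_id, atoms$chain, atoms$resno,
                  atoms$x, atoms$y, atoms$z, atoms$occupancy)
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}

## built-in fixture components: ring bond lists
.fixtureComponents <- function() {
  ringBonds <- function(comp, n, orders, arom) {
    a <- paste0("C", 1:n)
    data.frame(comp_id = comp, atom1 = a, atom2 = a[c(2:n, 1)],
               order = orders, aromatic = arom, stringsAsFactors = FALSE)
  }
  list(
    CHX = ringBonds("CHX", 6, "single", FALSE),
    CPX = ringBonds("CPX", 5, "single", FALSE),
    BNZ = ringBonds("BNZ", 6, rep(c("single", "double"), 3), TRUE),
    ## naphthalene-like fused bicyclic with Kekule orders: 10 atoms, 11 bonds
    NPH = data.frame(
      comp_id = "NPH",
      atom1 = c("C1", "C2", "C3", "C4", "C4A", "C8A",
                "C4A", "C5", "C6", "C7", "C8"),
      atom2 = c("C2", "C3", "C4", "C4A", "C8A", "C1",
                "C5", "C6", "C7", "C8", "C8A"),
      order = c("double", "single", "double", "single", "double", "single",
                "single", "double", "single", "double", "single"),
      aromatic = TRUE, stringsAsFactors = FALSE),
    ## cyclohexanone-like: saturated six-ring with an exocyclic double-bonded O
    CXK = rbind(ringBonds("CXK", 6, "single", FALSE),
                data.frame(comp_id = "CXK", atom1 = "C1", atom2 = "O1",
                           order = "double", aromatic = FALSE)))
}

#' Write a CCD-style component bond dictionary
#'
#' Emits one \code{_chem_comp_bond} loop per component in CCD mmCIF
#' layout (SING/DOUB/TRIP/AROM value orders, Y/N aromatic flags).  The
#' built-in components are CHX (cyclohexane), CPX (cyclopentane), BNZ
#' (benzene, Kekule orders with aromatic flags), NPH (a naphthalene-like
#' fused bicyclic) and CXK (a cyclohexanone-like ring); a custom bond
#' data.frame with the same columns can be supplied instead.
#'
#' @param path output file.
#' @param components character vector of built-in component ids, or a
#'   data.frame with columns \code{comp_id}, \code{atom1}, \code{atom2},
#'   \code{order}, \code{aromatic}.
#' @return \code{path}, invisibly.
#' @export
writeComponentDictionary <- function(path,
                                     components = c("CHX", "CPX", "BNZ")) {
  if (is.data.frame(components)) {
    bonds <- components
  } else {
    all <- .fixtureComponents()
    bad <- setdiff(components, names(all))
    if (length(bad) > 0)
      stop("unknown built-in component(s): ", paste(bad, collapse = ", "))
    bonds <- do.call(rbind, all[components])
  }
  orderOut <- c(single = "SING", double = "DOUB", triple = "TRIP",
                aromatic = "AROM")[bonds$order]
  lines <- c("data_components", "loop_",
             paste0("_chem_comp_bond.",
                    c("comp_id", "atom_id_1", "atom_id_2", "value_order",
                      "pdbx_aromatic_flag")),
             sprintf("%s %s %s %s %s", bonds$comp_id, bonds$atom1,
                     bonds$atom2, orderOut,
                     ifelse(bonds$aromatic, "Y", "N")),
             "#")
  writeLines(lines, path)
  invisible(path)
}

#' Write a self-contained fixture bundle
#'
#' Generates one single-ligand entry per spec row: a conformer geometry,
#' the same structure as PDB and mmCIF, a per-entry density map with
#' Gaussian atom peaks, a shared component dictionary and a resolution
#' table.  Deterministic for a fixed seed.  The default spec set covers
#' every (ring type, conformation) pair of the reference table.
#'
#' @param dir output directory (created if needed).
#' @param specs data.frame with columns \code{ring_type},
#'   \code{conformation} and optionally \code{resolution},
#'   \code{noise_sd}, \code{drop_atoms} (count of peaks to omit).
#' @param seed integer master seed.
#' @return data.frame manifest: one row per entry with its file paths,
#'   ground-truth conformation and resolution.
#' @export
writeFixtureBundle <- function(dir, specs = NULL, seed = 1) {
  if (is.null(specs)) {
    specs <- do.call(rbind, lapply(names(.conformerModes), function(rt)
      data.frame(ring_type = rt,
                 conformation = names(.conformerModes[[rt]]),
                 stringsAsFactors = FALSE)))
    specs$resolution <- rep_len(c(1.5, 2.0, 2.5), nrow(specs))
  }
  if (is.null(specs$resolution)) specs$resolution <- 1.5
  if (is.null(specs$noise_sd)) specs$noise_sd <- 0
  if (is.null(specs$drop_atoms)) specs$drop_atoms <- 0L
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "structures"), showWarnings = FALSE)
  dir.create(file.path(dir, "maps"), showWarnings = FALSE)
  compOf <- c(cyclohexane = "CHX", cyclopentane = "CPX", benzene = "BNZ")
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    rt <- specs$ring_type[i]
    entry <- sprintf("fx%02d", i)
    coords <- makeConformer(rt, specs$conformation[i], pose = "random",
                            noiseSd = specs$noise_sd[i],
                            seed = seed * 1000L + i)
    ring <- ringFromCoords(coords, ringType = rt, compId = compOf[[rt]],
                           entryId = entry, resno = 101L)
    pdb <- file.path(dir, "structures", paste0(entry, ".pdb"))
    cif <- file.path(dir, "structures", paste0(entry, ".cif"))
    writeStructurePdb(ring@atoms, pdb)
    writeStructureCif(ring@atoms, cif)
    drop <- if (specs$drop_atoms[i] > 0) seq_len(specs$drop_atoms[i])
            else integer(0)
    map <- makeDensityMap(coords, dropAtoms = drop, seed = seed * 1000L + i)
    mapPath <- file.path(dir, "maps", paste0(entry, ".ccp4"))
    writeCcp4Map(map, mapPath)
    data.frame(entry_id = entry, ring_type = rt,
               conformation = specs$conformation[i],
               resolution = specs$resolution[i],
               noise_sd = specs$noise_sd[i],
               dropped_atoms = specs$drop_atoms[i],
               pdb = pdb, cif = cif, map = mapPath,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  writeComponentDictionary(file.path(dir, "components.cif"))
  utils::write.csv(manifest[, c("entry_id", "resolution")],
                   file.path(dir, "resolution.csv"), row.names = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
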