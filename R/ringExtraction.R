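## Structure parsing, CCD-style dictionary parsing, carbon-ring detection
## and ring-type classification.

## ---- minimal mmCIF loop parser --------------------------------------------
##
## Name-driven parser for mmCIF loop_ categories (quoted tokens supported,
## multi-line ;-blocks skipped).  Sufficient for _atom_site coordinate loops
## and _chem_comp_bond dictionary loops; not a general CIF implementation.

.cifTokens <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  if (m[1] == -1) return(character(0))
  tok <- regmatches(line, gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
  gsub("^['\"]|['\"]$", "", tok)
}

.cifLoops <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loops <- list()
  blockName <- NA_character_
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (startsWith(line, "data_")) {
      blockName <- sub("^data_", "", line)
      i <- i + 1L
    } else if (startsWith(line, ";")) {    # skip multi-line text blocks
      i <- i + 1L
      while (i <= n && !startsWith(trimws(lines[i]), ";")) i <- i + 1L
      i <- i + 1L
    } else if (identical(line, "loop_")) {
      i <- i + 1L
      fields <- character(0)
      while (i <= n && startsWith(trimws(lines[i]), "_")) {
        fields <- c(fields, trimws(lines[i]))
        i <- i + 1L
      }
      if (length(fields) == 0)
        stop("parse error in ", path, ": loop_ without item names (line ",
             i, ")")
      cat0 <- sub("\\..*$", "", fields[1])
      cols <- sub("^[^.]*\\.", "", fields)
      values <- character(0)
      while (i <= n) {
        l <- trimws(lines[i])
        if (l == "" || startsWith(l, "#")) { i <- i + 1L; next }
        if (startsWith(l, "_") || identical(l, "loop_") ||
            startsWith(l, "data_") || startsWith(l, ";")) break
        values <- c(values, .cifTokens(l))
        i <- i + 1L
      }
      if (length(values) %% length(fields) != 0)
        stop("parse error in ", path, ": loop ", cat0, " has ",
             length(values), " values for ", length(fields), " items")
      mat <- matrix(values, ncol = length(fields), byrow = TRUE)
      df <- as.data.frame(mat, stringsAsFactors = FALSE)
      names(df) <- cols
      df$.block <- blockName
      loops[[length(loops) + 1L]] <- list(category = cat0, data = df)
    } else {
      i <- i + 1L
    }
  }
  loops
}

.cifCategory <- function(loops, category) {
  hits <- Filter(function(l) identical(l$category, category), loops)
  if (length(hits) == 0) return(NULL)
  do.call(rbind, lapply(hits, `[[`, "data"))
}

## ---- structure parsing ----------------------------------------------------

.entryIdFromPath <- function(path)
  sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path), ignore.case = TRUE)

.parseStructurePdb <- function(path, entryId) {
  pdb <- tryCatch(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
                  error = function(e)
                    stop("parse error reading PDB file ", path, ": ",
                         conditionMessage(e)))
  a <- pdb$atom
  het <- a[a$type == "HETATM" & !(a$resid %in% c("HOH", "WAT", "DOD")), ,
           drop = FALSE]
  data.frame(serial = as.integer(het$eleno), name = het$elety,
             element = ifelse(is.na(het$elesy) | het$elesy == "",
                              substr(gsub("[^A-Za-z].*$", "", het$elety),
                                     1, 1), het$elesy),
             x = het$x, y = het$y, z = het$z,
             altloc = ifelse(is.na(het$alt), "", het$alt),
             occupancy = as.numeric(het$o),
             chain = ifelse(is.na(het$chain), "", het$chain),
             resno = as.integer(het$resno), comp_id = het$resid,
             entry_id = entryId, stringsAsFactors = FALSE)
}

.parseStructureCif <- function(path, entryId) {
  loops <- .cifLoops(path)
  sites <- .cifCategory(loops, "_atom_site")
  if (is.null(sites))
    stop("parse error reading mmCIF file ", path, ": no _atom_site loop")
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(sites)) return(sites[[nm]])
    NULL
  }
  need <- function(v, what) {
    if (is.null(v))
      stop("parse error in ", path, ": _atom_site lacks ", what)
    v
  }
  grp <- pick("group_PDB")
  comp <- need(pick("auth_comp_id", "label_comp_id"), "a component id")
  keep <- if (is.null(grp)) rep(TRUE, nrow(sites)) else grp == "HETATM"
  keep <- keep & !(comp %in% c("HOH", "WAT", "DOD"))
  alt <- pick("label_alt_id")
  alt <- if (is.null(alt)) "" else ifelse(alt %in% c(".", "?"), "", alt)
  occ <- pick("occupancy")
  occ <- if (is.null(occ)) 1 else as.numeric(occ)
  blk <- sites$.block
  ent <- if (!all(is.na(blk)) && nzchar(blk[1])) blk[1] else entryId
  out <- data.frame(
    serial = as.integer(need(pick("id"), "atom ids")),
    name = need(pick("label_atom_id", "auth_atom_id"), "atom names"),
    element = need(pick("type_symbol"), "element symbols"),
    x = as.numeric(need(pick("Cartn_x"), "coordinates")),
    y = as.numeric(need(pick("Cartn_y"), "coordinates")),
    z = as.numeric(need(pick("Cartn_z"), "coordinates")),
    altloc = alt, occupancy = occ,
    chain = need(pick("auth_asym_id", "label_asym_id"), "chain ids"),
    resno = as.integer(need(pick("auth_seq_id", "label_seq_id"),
                            "residue numbers")),
    comp_id = comp, entry_id = ent, stringsAsFactors = FALSE)
  out[keep, , drop = FALSE]
}

#' Parse ligand atoms from a structure file
#'
#' Reads the non-polymer (HETATM) atoms of a legacy PDB or mmCIF
#' coordinate file into a plain atom table: one row per atom with serial,
#' name, element, Cartesian coordinates, altloc, occupancy, chain, residue
#' number, component id and entry id.  Waters are dropped; all altloc
#' copies are returned (downstream steps select one).  PDB files are read
#' with \pkg{bio3d}; mmCIF files with a name-driven \code{_atom_site}
#' parser.
#'
#' @param path structure file.
#' @param format \code{"auto"} (by extension, falling back to content
#'   sniffing), \code{"pdb"} or \code{"mmcif"}.
#' @param entryId entry identifier; defaults to the file base name (mmCIF
#'   data block names take precedence when present).
#' @return data.frame of ligand atoms.
#' @export
parseStructure <- function(path, format = c("auto", "pdb", "mmcif"),
                           entryId = .entryIdFromPath(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    ext <- tolower(sub("^.*\\.", "", basename(path)))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif"
      else if (ext %in% c("pdb", "ent")) "pdb"
      else {
        head <- readLines(path, n = 20, warn = FALSE)
        if (any(grepl("^data_|_atom_site", head))) "mmcif"
        else if (any(grepl("^(ATOM|HETATM|HEADER|CRYST1)", head))) "pdb"
        else stop("format error: cannot recognise ", path,
                  " as PDB or mmCIF")
      }
  }
  atoms <- switch(format,
                  pdb = .parseStructurePdb(path, entryId),
                  mmcif = .parseStructureCif(path, entryId))
  .checkAtomTable(atoms)
}

#' Load a CCD-style component bond dictionary
#'
#' Parses the \code{_chem_comp_bond} loops of a chemical-component
#' dictionary mmCIF file into a [ComponentBondTable-class], preserving
#' bond orders (SING/DOUB/TRIP/AROM, case-insensitive) and aromatic flags
#' (Y/N).
#'
#' @param path dictionary file.
#' @return A [ComponentBondTable-class] covering every component in the
#'   file.
#' @export
loadComponentBonds <- function(path) {
  if (!file.exists(path)) stop("dictionary file not found: ", path)
  loops <- .cifLoops(path)
  b <- .cifCategory(loops, "_chem_comp_bond")
  if (is.null(b))
    stop("parse error in ", path, ": no _chem_comp_bond loop")
  need <- c("comp_id", "atom_id_1", "atom_id_2", "value_order")
  missing <- setdiff(need, names(b))
  if (length(missing) > 0)
    stop("parse error in ", path, ": _chem_comp_bond lacks ",
         paste(missing, collapse = ", "))
  orderIn <- c(SING = "single", DOUB = "double", TRIP = "triple",
               AROM = "aromatic")
  ord <- orderIn[toupper(b$value_order)]
  if (anyNA(ord))
    stop("parse error in ", path, ": unknown bond order(s): ",
         paste(unique(b$value_order[is.na(ord)]), collapse = ", "))
  arom <- if ("pdbx_aromatic_flag" %in% names(b))
    toupper(b$pdbx_aromatic_flag) == "Y" else ord == "aromatic"
  new("ComponentBondTable",
      bonds = data.frame(comp_id = b$comp_id, atom1 = b$atom_id_1,
                         atom2 = b$atom_id_2, order = as.character(ord),
                         aromatic = arom, stringsAsFactors = FALSE))
}

## ---- ring detection -------------------------------------------------------

## smallest cycle through each edge of an undirected graph, as vertex-name
## paths; SSSR-style basis restricted to what the caller keeps
.smallestCyclesPerEdge <- function(g) {
  cycles <- list()
  edges <- igraph::as_edgelist(g, names = TRUE)
  for (e in seq_len(nrow(edges))) {
    h <- igraph::delete_edges(g, igraph::get_edge_ids(g, edges[e, ]))
    sp <- suppressWarnings(
      igraph::shortest_paths(h, from = edges[e, 1], to = edges[e, 2],
                             output = "vpath"))
    p <- sp$vpath[[1]]
    if (length(p) >= 3) cycles[[length(cycles) + 1L]] <- names(p)
  }
  cycles
}

## canonical signature of a cycle up to rotation and reflection
.cycleSignature <- function(atoms) {
  n <- length(atoms)
  best <- NULL
  for (dir in list(atoms, rev(atoms))) {
    for (s in seq_len(n)) {
      rot <- dir[((s - 1 + 0:(n - 1)) %% n) + 1]
      key <- paste(rot, collapse = "|")
      if (is.null(best) || key < best) best <- key
    }
  }
  best
}

#' Find all-carbon 5- and 6-membered rings in a ligand
#'
#' Builds the component bond graph restricted to the heavy atoms present
#' in the structure, enumerates the smallest cycle through every edge
#' (a smallest-set-of-smallest-rings-style basis) and keeps each distinct
#' cycle of exactly 5 or 6 atoms whose members are all carbon.  Fused
#' rings sharing edges are all returned; each ring is reported once up to
#' rotation/reflection of its atom order.  Rings are returned
#' unclassified; see [classifyRingType()].
#'
#' @param atoms atom table from [parseStructure()] (may span several
#'   ligand residues; rings are found per residue).
#' @param bonds a [ComponentBondTable-class].
#' @param altloc which alternate-location copy to analyze: atoms with a
#'   blank altloc or this identifier are used (default \code{"A"}).  Use
#'   \code{NULL} to analyze every altloc present, one ring instance per
#'   altloc.
#' @param onMissing what to do when a residue's component id is absent
#'   from the dictionary or ring-candidate atom names cannot be mapped:
#'   \code{"skip"} (warn and skip the residue) or \code{"error"}.
#' @return list of [RingInstance-class] objects (ring type
#'   \code{"unclassified"}).
#' @export
findCarbonRings <- function(atoms, bonds, altloc = "A",
                            onMissing = c("skip", "error")) {
  onMissing <- match.arg(onMissing)
  stopifnot(is(bonds, "ComponentBondTable"))
  atoms <- atoms[!atoms$element %in% c("H", "D"), , drop = FALSE]
  groups <- split(atoms, paste(atoms$entry_id, atoms$chain, atoms$resno,
                               atoms$comp_id, sep = "\r"))
  rings <- list()
  for (grp in groups) {
    comp <- grp$comp_id[1]
    if (!comp %in% componentIds(bonds)) {
      msg <- paste0("missing-component: ", comp,
                    " not found in the bond dictionary")
      if (onMissing == "error") stop(msg)
      warning(msg, " (residue skipped)")
      next
    }
    compBonds <- componentBonds(bonds, comp)
    altlocs <- if (is.null(altloc))
      unique(grp$altloc[nzchar(grp$altloc)]) else altloc
    if (length(altlocs) == 0) altlocs <- ""
    for (al in altlocs) {
      sub <- grp[grp$altloc == "" | grp$altloc == al, , drop = FALSE]
      ## a blank-altloc atom duplicated by a conformer copy: keep the copy
      sub <- sub[!duplicated(sub$name, fromLast = TRUE), , drop = FALSE]
      keep <- compBonds$atom1 %in% sub$name & compBonds$atom2 %in% sub$name
      eb <- compBonds[keep, , drop = FALSE]
      if (nrow(eb) == 0) next
      g <- igraph::graph_from_data_frame(eb[, c("atom1", "atom2")],
                                         directed = FALSE)
      seen <- character(0)
      for (cyc in .smallestCyclesPerEdge(g)) {
        if (!length(cyc) %in% c(5L, 6L)) next
        rows <- sub[match(cyc, sub$name), , drop = FALSE]
        if (anyNA(rows$serial)) {
          msg <- paste0("mapping error: ring atom names of ", comp,
                        " not present in the structure")
          if (onMissing == "error") stop(msg)
          warning(msg, " (ring skipped)")
          next
        }
        if (!all(rows$element == "C")) next
        sig <- .cycleSignature(cyc)
        if (sig %in% seen) next
        seen <- c(seen, sig)
        rings[[length(rings) + 1L]] <- new(
          "RingInstance", atoms = rows, ringType = "unclassified",
          provenance = list(entry_id = grp$entry_id[1], comp_id = comp,
                            chain = grp$chain[1],
                            resno = grp$resno[1], altloc = al))
      }
    }
  }
  rings
}

## TRUE when the cyclic order vector alternates between two values
.alternates <- function(v, a, b) {
  n <- length(v)
  if (n %% 2 != 0) return(FALSE)
  all(v == rep(c(a, b), n / 2)) || all(v == rep(c(b, a), n / 2))
}

#' Classify a ring as cyclohexane, cyclopentane, benzene or other
#'
#' Inspects only the ring-internal bonds (cyclically consecutive atom
#' pairs) in the component dictionary.  A six-ring whose internal bonds
#' are all single and non-aromatic is a cyclohexane; a five-ring likewise
#' is a cyclopentane.  In \code{"aromatic_flag"} mode a six-ring whose
#' internal bonds all carry the dictionary's aromatic flag is a benzene
#' (this covers fused aromatics recorded with Kekule orders).  In
#' \code{"paper_replication"} mode a benzene requires all-aromatic bond
#' orders, and a six-ring with alternating single/double Kekule orders is
#' classified \code{"other"} (a cyclohexadiene-like pattern), which
#' reproduces the omission of fused aromatic rings by bond-order-based
#' filtering.  Everything else is \code{"other"}.
#'
#' @param ring a [RingInstance-class].
#' @param bonds a [ComponentBondTable-class].
#' @param mode \code{"aromatic_flag"} (default) or
#'   \code{"paper_replication"}.
#' @return The ring with its \code{ringType} slot set.
#' @export
classifyRingType <- function(ring, bonds,
                             mode = c("aromatic_flag", "paper_replication")) {
  mode <- match.arg(mode)
  stopifnot(is(ring, "RingInstance"), is(bonds, "ComponentBondTable"))
  atoms <- ring@atoms
  n <- nrow(atoms)
  compBonds <- componentBonds(bonds, ring@provenance$comp_id)
  key <- paste(pmin(compBonds$atom1, compBonds$atom2),
               pmax(compBonds$atom1, compBonds$atom2))
  a1 <- atoms$name
  a2 <- atoms$name[c(2:n, 1)]
  hit <- match(paste(pmin(a1, a2), pmax(a1, a2)), key)
  type <- "other"
  if (!anyNA(hit) && all(atoms$element == "C")) {
    ord <- compBonds$order[hit]
    arom <- compBonds$aromatic[hit]
    allSingle <- all(ord == "single") && !any(arom)
    if (allSingle) {
      type <- if (n == 6L) "cyclohexane" else "cyclopentane"
    } else if (n == 6L) {
      if (mode == "aromatic_flag") {
        if (all(arom)) type <- "benzene"
      } else {
        if (all(ord == "aromatic")) type <- "benzene"
        ## alternating Kekule orders: cyclohexadiene-like, omitted
      }
    }
  }
  initialize(ring, ringType = type)
}

#' Write one ring as a standalone PDB file
#'
#' Mirrors per-ring extraction output: the ring's atoms, in cyclic order,
#' as a minimal PDB file.
#'
#' @param ring a [RingInstance-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeRingPdb <- function(ring, path) {
  stopifnot(is(ring, "RingInstance"))
  writeStructurePdb(ring@atoms, path)
}
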