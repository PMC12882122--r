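test_that("PDB and mmCIF writers and parsers round-trip ligand atoms", {
  atoms <- makeAtomTable(round(chairCoords(), 3))  # writers emit 3 decimals
  pdb <- withr::local_tempfile(fileext = ".pdb")
  cif <- withr::local_tempfile(fileext = ".cif")
  writeStructurePdb(atoms, pdb)
  writeStructureCif(atoms, cif)
  fromPdb <- parseStructure(pdb, entryId = "fx01")
  fromCif <- parseStructure(cif)
  for (got in list(fromPdb, fromCif)) {
    expect_equal(nrow(got), 6)
    expect_equal(got$name, atoms$name)
    expect_equal(got$serial, atoms$serial)
    expect_equal(got$element, atoms$element)
    expect_equal(got$comp_id, atoms$comp_id)
    expect_equal(got$chain, atoms$chain)
    expect_equal(got$resno, atoms$resno)
    expect_equal(got$occupancy, atoms$occupancy)
    expect_equal(got$altloc, atoms$altloc)
    expect_equal(got$x, atoms$x, tolerance = 1e-8)
    expect_equal(got$y, atoms$y, tolerance = 1e-8)
    expect_equal(got$z, atoms$z, tolerance = 1e-8)
  }
  ## the two formats agree field for field
  expect_equal(fromPdb[, setdiff(names(fromPdb), "entry_id")],
               fromCif[, setdiff(names(fromCif), "entry_id")],
               ignore_attr = TRUE)
})

test_that("alternate-location copies are both returned with altloc set", {
  atoms <- makeAtomTable(chairCoords())
  copyB <- atoms[1, ]
  copyB$serial <- 7L
  copyB$x <- copyB$x + 0.3
  atoms$altloc[1] <- "A"
  copyB$altloc <- "B"
  both <- rbind(atoms, copyB)
  both$occupancy[c(1, 7)] <- 0.5
  for (fmt in c("pdb", "cif")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    if (fmt == "pdb") writeStructurePdb(both, f)
    else writeStructureCif(both, f)
    got <- parseStructure(f)
    expect_equal(nrow(got), 7)
    expect_setequal(got$altloc[got$name == "C1"], c("A", "B"))
  }
})

test_that("unreadable or unrecognisable structure files raise parse errors", {
  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("this is", "not a structure"), bad)
  expect_error(parseStructure(bad), "format error")
  expect_error(parseStructure(bad, format = "mmcif"), "parse error")
  expect_error(parseStructure("no-such-file.pdb"), "not found")
})

test_that("component dictionaries preserve bonds, orders and aromatic flags", {
  dict <- withr::local_tempfile(fileext = ".cif")
  writeComponentDictionary(dict, c("CHX", "BNZ", "NPH"))
  tab <- loadComponentBonds(dict)
  expect_setequal(componentIds(tab), c("CHX", "BNZ", "NPH"))
  chx <- componentBonds(tab, "CHX")
  expect_equal(nrow(chx), 6)
  expect_true(all(chx$order == "single"))
  expect_false(any(chx$aromatic))
  bnz <- componentBonds(tab, "BNZ")
  expect_equal(nrow(bnz), 6)
  expect_true(all(bnz$aromatic))
  expect_setequal(unique(bnz$order), c("single", "double"))
  nph <- componentBonds(tab, "NPH")
  expect_equal(nrow(nph), 11)                      # fused bicyclic: 11 bonds
  expect_equal(length(unique(c(nph$atom1, nph$atom2))), 10)  # over 10 atoms
})

test_that("duplicate or degenerate bond rows are rejected", {
  df <- ringBondDf("CHX", 6)
  expect_error(bondTable(rbind(df, df[1, ])), "duplicated")
  bad <- df
  bad$atom2[1] <- bad$atom1[1]
  expect_error(bondTable(bad), "distinct")
})

test_that("ring detection finds the expected 5/6-carbon rings", {
  ## one cyclohexane
  atoms <- makeAtomTable(chairCoords())
  rings <- findCarbonRings(atoms, bondTable(ringBondDf("CHX", 6)))
  expect_length(rings, 1)
  expect_equal(nrow(ringAtoms(rings[[1]])), 6)

  ## spiro-fused cyclohexane + cyclopentane sharing one atom
  mixBonds <- data.frame(
    comp_id = "MIX",
    atom1 = c(paste0("C", 1:6), "C1", "C7", "C8", "C9", "C10"),
    atom2 = c(paste0("C", c(2:6, 1)), "C7", "C8", "C9", "C10", "C1"),
    order = "single", aromatic = FALSE, stringsAsFactors = FALSE)
  mixAtoms <- makeAtomTable(cbind(1:10, (1:10)^2, 0),
                            names = paste0("C", 1:10), compId = "MIX")
  rings <- findCarbonRings(mixAtoms, bondTable(mixBonds))
  expect_setequal(vapply(rings, function(r) nrow(ringAtoms(r)), 0L),
                  c(5L, 6L))
})

test_that("fused rings sharing an edge are both found, matching a
           brute-force cycle oracle", {
  dict <- withr::local_tempfile(fileext = ".cif")
  writeComponentDictionary(dict, "NPH")
  tab <- loadComponentBonds(dict)
  nph <- componentBonds(tab, "NPH")
  atoms <- makeAtomTable(cbind(1:10, (1:10) %% 3, 0),
                         names = unique(c(nph$atom1, nph$atom2)),
                         compId = "NPH")
  rings <- findCarbonRings(atoms, tab)
  expect_length(rings, 2)
  expect_true(all(vapply(rings, function(r) nrow(ringAtoms(r)), 0L) == 6))
  shared <- intersect(ringAtoms(rings[[1]])$name, ringAtoms(rings[[2]])$name)
  expect_length(shared, 2)                      # one shared edge
  ## oracle: exhaustive simple-cycle enumeration on the 10-atom graph
  oracle <- bruteForceCycles(as.matrix(nph[, c("atom1", "atom2")]))
  got <- vapply(rings, function(r)
    bruteForceCycles(cbind(ringAtoms(r)$name,
                           ringAtoms(r)$name[c(2:6, 1)])), "")
  expect_setequal(got, oracle)
})

test_that("every returned ring is a closed cycle in the bond graph", {
  dict <- withr::local_tempfile(fileext = ".cif")
  writeComponentDictionary(dict, c("CHX", "CPX", "NPH"))
  tab <- loadComponentBonds(dict)
  check <- function(atoms) {
    for (r in findCarbonRings(atoms, tab)) {
      a <- ringAtoms(r)
      comp <- componentBonds(tab, provenance(r)$comp_id)
      key <- paste(pmin(comp$atom1, comp$atom2),
                   pmax(comp$atom1, comp$atom2))
      n <- nrow(a)
      pair <- paste(pmin(a$name, a$name[c(2:n, 1)]),
                    pmax(a$name, a$name[c(2:n, 1)]))
      expect_true(all(pair %in% key))
    }
  }
  check(makeAtomTable(chairCoords()))
  check(makeAtomTable(polygonCoords(5, 1.54), names = paste0("C", 1:5),
                      compId = "CPX"))
  nph <- componentBonds(tab, "NPH")
  check(makeAtomTable(cbind(1:10, 0, (1:10) %% 4),
                      names = unique(c(nph$atom1, nph$atom2)),
                      compId = "NPH"))
})

test_that("missing dictionary components are skipped with a warning or
           raised as errors", {
  atoms <- makeAtomTable(chairCoords(), compId = "XYZ")
  tab <- bondTable(ringBondDf("CHX", 6))
  expect_warning(rings <- findCarbonRings(atoms, tab), "missing-component")
  expect_length(rings, 0)
  expect_error(findCarbonRings(atoms, tab, onMissing = "error"),
               "missing-component.*XYZ")
})

test_that("ring-type classification follows ring-internal bond orders,
           aromatic flags and the requested mode", {
  dict <- withr::local_tempfile(fileext = ".cif")
  writeComponentDictionary(dict, c("CHX", "CPX", "BNZ", "NPH", "CXK"))
  tab <- loadComponentBonds(dict)
  classifyOne <- function(compId, coords, names, mode = "aromatic_flag") {
    atoms <- makeAtomTable(coords, names = names, compId = compId)
    rings <- findCarbonRings(atoms, tab)
    vapply(rings, function(r)
      ringType(classifyRingType(r, tab, mode = mode)), "")
  }
  expect_equal(classifyOne("CHX", chairCoords(), paste0("C", 1:6)),
               "cyclohexane")
  expect_equal(classifyOne("CPX", polygonCoords(5, 1.54), paste0("C", 1:5)),
               "cyclopentane")
  expect_equal(classifyOne("BNZ", polygonCoords(6), paste0("C", 1:6)),
               "benzene")
  nphNames <- unique(c(componentBonds(tab, "NPH")$atom1,
                       componentBonds(tab, "NPH")$atom2))
  nphCoords <- cbind(1:10, (1:10) %% 3, 0)
  ## Kekule-ordered fused aromatic: named benzene when the aromatic flag is
  ## trusted, omitted as "other" in replication mode
  expect_equal(classifyOne("NPH", nphCoords, nphNames),
               c("benzene", "benzene"))
  expect_equal(classifyOne("NPH", nphCoords, nphNames,
                           mode = "paper_replication"),
               c("other", "other"))
  ## exocyclic double bond does not disqualify a saturated ring
  cxk <- rbind(chairCoords(), c(3, 0, 1))
  expect_equal(classifyOne("CXK", cxk, c(paste0("C", 1:6), "O1")),
               "cyclohexane")
})

test_that("classification is invariant to rotation/reflection of the ring
           atom order", {
  tab <- bondTable(ringBondDf("BNZ", 6, order = rep(c("single", "double"), 3),
                              aromatic = TRUE))
  atoms <- makeAtomTable(polygonCoords(6), compId = "BNZ")
  base <- findCarbonRings(atoms, tab)[[1]]
  n <- 6
  for (s in 1:n) for (dir in c(1, -1)) {
    idx <- ((s - 1 + dir * (0:(n - 1))) %% n) + 1
    rot <- initialize(base, atoms = ringAtoms(base)[idx, ])
    expect_equal(ringType(classifyRingType(rot, tab)), "benzene")
  }
})

test_that("extracted rings can be written as standalone PDB files", {
  atoms <- makeAtomTable(chairCoords())
  ring <- findCarbonRings(atoms, bondTable(ringBondDf("CHX", 6)))[[1]]
  f <- withr::local_tempfile(fileext = ".pdb")
  writeRingPdb(ring, f)
  back <- parseStructure(f)
  expect_equal(sort(back$name), sort(ringAtoms(ring)$name))
})
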