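## Shared fixtures and independent oracles for the test suite.

## regular planar N-gon with the given bond length, z = 0
polygonCoords <- function(n, bondLength = 1.39) {
  ang <- 2 * pi * (0:(n - 1)) / n
  r <- bondLength / (2 * sin(pi / n))
  cbind(x = r * cos(ang), y = r * sin(ang), z = 0)
}

## hexagon with alternating +/- z displacement (ideal chair geometry)
chairCoords <- function(d = 0.25, bondLength = 1.54) {
  co <- polygonCoords(6, bondLength)
  co[, 3] <- d * c(1, -1, 1, -1, 1, -1)
  co
}

## brute-force enumeration of all simple cycles of the given lengths in an
## undirected graph given as a two-column edge matrix of vertex names
bruteForceCycles <- function(edges, lengths = c(5L, 6L)) {
  verts <- sort(unique(c(edges[, 1], edges[, 2])))
  adj <- lapply(verts, function(v)
    sort(unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]))))
  names(adj) <- verts
  canon <- function(cyc) {
    n <- length(cyc)
    best <- NULL
    for (d in list(cyc, rev(cyc))) for (s in seq_len(n)) {
      key <- paste(d[((s - 1 + 0:(n - 1)) %% n) + 1], collapse = "|")
      if (is.null(best) || key < best) best <- key
    }
    best
  }
  found <- character(0)
  path <- character(0)
  dfs <- function(v, startV) {
    path <<- c(path, v)
    for (w in adj[[v]]) {
      if (w == startV && length(path) >= 3) {
        if (length(path) %in% lengths) {
          key <- canon(path)
          if (!key %in% found) found <<- c(found, key)
        }
      } else if (!w %in% path && w > startV && length(path) < max(lengths)) {
        dfs(w, startV)
      }
    }
    path <<- path[-length(path)]
  }
  for (v in verts) dfs(v, v)
  found
}

## independently coded trilinear interpolation (sigma units) for orthogonal
## cells with axis order 1:3: duplicates none of the package's code paths
oracleTrilinearSigma <- function(grid, cell, sampling, start, pos,
                                 periodic = FALSE) {
  spacing <- cell[1:3] / sampling
  t <- pos / spacing - start
  dims <- dim(grid)
  val <- 0
  i0 <- floor(t)
  fr <- t - i0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- abs(1 - dx - fr[1]) * abs(1 - dy - fr[2]) * abs(1 - dz - fr[3])
    ix <- i0 + c(dx, dy, dz)
    if (periodic) ix <- ix %% dims
    val <- val + w * grid[ix[1] + 1, ix[2] + 1, ix[3] + 1]
  }
  m <- mean(grid)
  (val - m) / sqrt(mean((grid - m)^2))
}

## atom table for a single synthetic ligand residue
makeAtomTable <- function(coords, names = paste0("C", seq_len(nrow(coords))),
                          element = "C", compId = "CHX", entryId = "fx01",
                          chain = "A", resno = 101L, altloc = "",
                          occupancy = 1, serial = seq_len(nrow(coords))) {
  data.frame(serial = serial, name = names, element = element,
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             altloc = altloc, occupancy = occupancy, chain = chain,
             resno = resno, comp_id = compId, entry_id = entryId,
             stringsAsFactors = FALSE)
}

## bond table object from a plain data.frame
bondTable <- function(df) new("ComponentBondTable", bonds = df)

## simple ring bond data.frame
ringBondDf <- function(comp, n, order = "single", aromatic = FALSE) {
  a <- paste0("C", 1:n)
  data.frame(comp_id = comp, atom1 = a, atom2 = a[c(2:n, 1)],
             order = order, aromatic = aromatic, stringsAsFactors = FALSE)
}
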