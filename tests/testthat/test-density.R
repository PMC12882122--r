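test_that("CCP4 maps round-trip through write and read", {
  set.seed(1)
  ## values on a 1/1024 lattice are exactly representable in float32
  g <- array(round(stats::runif(6 * 7 * 8, -2, 2) * 1024) / 1024,
             dim = c(6, 7, 8))
  map <- densityMapFromGrid(g, cell = c(10, 11, 12, 90, 90, 90),
                            sampling = c(20, 22, 24))
  f <- withr::local_tempfile(fileext = ".ccp4")
  writeCcp4Map(map, f)
  back <- readCcp4Map(f)
  expect_identical(dim(mapGrid(back)), dim(g))
  expect_equal(mapGrid(back), g)                     # float32-exact values
  expect_equal(mapCell(back), mapCell(map), tolerance = 1e-6)
  expect_equal(back@start, map@start)
  expect_equal(back@sampling, map@sampling)
  expect_equal(back@axisOrder, map@axisOrder)
  expect_false(back@periodic)
})

test_that("malformed map files raise format errors", {
  f <- withr::local_tempfile(fileext = ".ccp4")
  writeBin(raw(2048), f)
  expect_error(readCcp4Map(f), "map-format")
})

test_that("grid mean and rms match closed-form values", {
  g <- array(0, dim = c(16, 16, 16))
  g[3, 5, 7] <- 8
  map <- densityMapFromGrid(g, cell = c(16, 16, 16, 90, 90, 90),
                            sampling = c(16, 16, 16))
  n <- 16^3
  m <- 8 / n
  expect_equal(mapMean(map), m)
  expect_equal(mapRms(map), sqrt(((8 - m)^2 + (n - 1) * m^2) / n))
})

test_that("interpolation returns node values at nodes and the 8-corner
           mean at cell centres", {
  set.seed(2)
  g <- array(stats::rnorm(5 * 5 * 5), dim = c(5, 5, 5))
  map <- densityMapFromGrid(g, cell = c(8, 8, 8, 90, 90, 90),
                            sampling = c(8, 8, 8))
  sp <- 1                                  # grid spacing 8 A / 8 samples
  atNode <- interpolateSigma(map, c(2, 3, 1) * sp)
  expect_equal(atNode, (g[3, 4, 2] - mapMean(map)) / mapRms(map),
               tolerance = 1e-12)
  centre <- interpolateSigma(map, c(1.5, 2.5, 3.5) * sp)
  corners <- g[2:3, 3:4, 4:5]
  expect_equal(centre, (mean(corners) - mapMean(map)) / mapRms(map),
               tolerance = 1e-12)
})

test_that("interpolation agrees with an independent trilinear oracle at
           random points", {
  set.seed(3)
  g <- array(stats::rnorm(8 * 8 * 8), dim = c(8, 8, 8))
  cell <- c(10, 12, 14, 90, 90, 90)
  sampling <- c(16, 18, 20)
  start <- c(2L, -1L, 4L)
  map <- densityMapFromGrid(g, cell = cell, start = start,
                            sampling = sampling)
  spacing <- cell[1:3] / sampling
  for (i in 1:100) {
    frac <- stats::runif(3, 0.01, 0.99) * 7
    pos <- (start + frac) * spacing
    expect_equal(interpolateSigma(map, pos),
                 oracleTrilinearSigma(g, cell, sampling, start, pos),
                 tolerance = 1e-9)
  }
})

test_that("interpolation is exact on a trilinear field", {
  ## f(x,y,z) = a + bx + cy + dz + exy + fxz + gyz + hxyz is reproduced
  ## exactly by trilinear interpolation
  co <- c(a = 0.3, b = 1.1, c = -0.7, d = 0.25, e = 0.4, f = -0.2,
          g = 0.15, h = 0.05)
  f <- function(x, y, z)
    co[1] + co[2] * x + co[3] * y + co[4] * z + co[5] * x * y +
      co[6] * x * z + co[7] * y * z + co[8] * x * y * z
  sp <- 0.75
  dims <- c(9, 8, 7)
  nodes <- lapply(dims, function(d) (0:(d - 1)) * sp)
  g <- array(0, dim = dims)
  for (i in 1:dims[1]) for (j in 1:dims[2]) for (k in 1:dims[3])
    g[i, j, k] <- f(nodes[[1]][i], nodes[[2]][j], nodes[[3]][k])
  map <- densityMapFromGrid(g, cell = c((dims + 4) * sp, 90, 90, 90),
                            sampling = dims + 4)
  set.seed(4)
  for (r in 1:50) {
    pos <- stats::runif(3, 0.2, 4.2)
    sigma <- interpolateSigma(map, pos)
    expect_equal(sigma * mapRms(map) + mapMean(map),
                 as.numeric(f(pos[1], pos[2], pos[3])), tolerance = 1e-9)
  }
})

test_that("a map stored with permuted axis order interpolates identically", {
  set.seed(5)
  g <- array(stats::rnorm(6 * 7 * 8), dim = c(6, 7, 8))
  cell <- c(9, 10.5, 12, 90, 90, 90)
  sampling <- c(12, 14, 16)
  start <- c(0L, 1L, -2L)
  canonical <- densityMapFromGrid(g, cell = cell, start = start,
                                  sampling = sampling)
  perm <- c(3L, 1L, 2L)          # file columns run along crystal axis c
  permuted <- densityMapFromGrid(aperm(g, perm), cell = cell,
                                 axisOrder = perm, start = start[perm],
                                 sampling = sampling)
  spacing <- cell[1:3] / sampling
  for (i in 1:100) {
    pos <- (start + stats::runif(3, 0.05, 0.95) * (dim(g) - 1)) * spacing
    expect_equal(interpolateSigma(permuted, pos),
                 interpolateSigma(canonical, pos), tolerance = 1e-9)
  }
  ## and after a write/read round trip
  f <- withr::local_tempfile(fileext = ".ccp4")
  writeCcp4Map(permuted, f)
  back <- readCcp4Map(f)
  pos <- (start + c(2.3, 3.1, 4.7)) * spacing
  expect_equal(interpolateSigma(back, pos),
               interpolateSigma(canonical, pos), tolerance = 1e-6)
})

test_that("full-cell maps wrap crystallographically, box maps raise
           out-of-bounds", {
  set.seed(6)
  g <- array(stats::rnorm(6 * 6 * 6), dim = c(6, 6, 6))
  cell <- c(6, 6, 6, 90, 90, 90)
  periodic <- densityMapFromGrid(g, cell = cell, sampling = c(6, 6, 6))
  expect_true(periodic@periodic)
  pos <- c(1.3, 2.7, 0.4)
  for (shift in list(c(6, 0, 0), c(0, -6, 0), c(6, 6, 12)))
    expect_equal(interpolateSigma(periodic, pos + shift),
                 interpolateSigma(periodic, pos), tolerance = 1e-9)
  box <- densityMapFromGrid(g, cell = c(12, 12, 12, 90, 90, 90),
                            sampling = c(12, 12, 12))
  expect_false(box@periodic)
  expect_error(interpolateSigma(box, c(7.2, 1, 1)), "out-of-bounds")
})

test_that("sigma values are invariant to affine rescaling of the grid", {
  set.seed(7)
  g <- array(stats::rnorm(5 * 5 * 5), dim = c(5, 5, 5))
  m1 <- densityMapFromGrid(g, cell = c(8, 8, 8, 90, 90, 90),
                           sampling = c(8, 8, 8))
  m2 <- densityMapFromGrid(3.7 * g + 11, cell = c(8, 8, 8, 90, 90, 90),
                           sampling = c(8, 8, 8))
  for (i in 1:20) {
    pos <- stats::runif(3, 0.2, 3.8)
    expect_equal(interpolateSigma(m2, pos), interpolateSigma(m1, pos),
                 tolerance = 1e-9)
  }
})

test_that("ring coverage flags atoms strictly above the threshold", {
  co <- makeConformer("cyclohexane", "chair")
  ring <- ringFromCoords(co, "cyclohexane")
  map <- makeDensityMap(co, peakSigmaTarget = 3, seed = 11)
  expect_true(all(attr(map, "atomSigma") >= 3 - 1e-6))
  cov <- ringCoverage(ring, map, 1.5)
  expect_true(allCovered(cov))
  expect_equal(coveredAtoms(cov), rep(TRUE, 6))

  ## removing one atom's peak uncovers exactly that atom
  map2 <- makeDensityMap(co, dropAtoms = 4, seed = 11)
  cov2 <- ringCoverage(ring, map2, 1.5)
  expect_false(allCovered(cov2))
  expect_equal(which(!coveredAtoms(cov2)), 4L)

  ## an absurd threshold uncovers everything
  cov10 <- ringCoverage(ring, map, 10)
  expect_false(any(coveredAtoms(cov10)))

  ## strict ">": a value exactly at the threshold is not covered
  v <- valuesSigma(cov)[2]
  covEq <- ringCoverage(ring, map, thresholdSigma = v)
  expect_false(coveredAtoms(covEq)[2])
})

test_that("atoms covered at 1.5 sigma are a subset of those covered at
           1.2 sigma", {
  set.seed(8)
  for (rep in 1:5) {
    pts <- matrix(stats::runif(30, 2, 8), ncol = 3)
    map <- makeDensityMap(pts, peakSigmaTarget = 2,
                          dropAtoms = sample(10, 3), seed = rep)
    c15 <- ringCoverage(pts, map, 1.5)
    c12 <- ringCoverage(pts, map, 1.2)
    expect_true(all(!coveredAtoms(c15) | coveredAtoms(c12)))
  }
})

test_that("atoms outside a box map are reported uncovered with a warning
           unless errors are requested", {
  co <- makeConformer("cyclohexane", "chair")
  map <- makeDensityMap(co, margin = 3, seed = 1)
  far <- rbind(co[1:5, ], c(50, 50, 50))
  expect_warning(cov <- ringCoverage(far, map, 1.5), "not covered")
  expect_false(coveredAtoms(cov)[6])
  expect_true(is.na(valuesSigma(cov)[6]))
  expect_error(ringCoverage(far, map, 1.5, onError = "error"),
               "out-of-bounds")
})
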