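flatGrid <- function(n = 31, v = 0.002) {
  reciprocalGrid(voxelSize = v, resolutionLimit = 1 / ((n - 1) / 2 * v - v),
                 extent = as.integer(n))
}

test_that("z-score segmentation handles degenerate and textbook cases", {
  g <- flatGrid()
  flat <- intensityModel(array(5, dim = g@extent), g)
  seg <- segmentPeaks(flat, n = 15)
  expect_equal(sum(seg@labels), 0L)

  # single bright voxel in a unit background
  vals <- array(1, dim = g@extent)
  vals[16, 16, 16] <- 100
  m <- intensityModel(vals, g)
  seg <- segmentPeaks(m, n = 15)
  expect_true(seg@labels[16, 16, 16])
  expect_equal(sum(seg@labels), 1L)

  expect_error(segmentPeaks(m, n = 14), "odd")
  expect_error(segmentPeaks(m, n = 33), "extent")
  expect_error(segmentPeaks(m, gammaSchedule = c(2, 1)), "non-decreasing")
})

test_that("segmentation is affine invariant and monotone in gamma", {
  set.seed(3)
  g <- flatGrid()
  vals <- array(exp(rnorm(prod(g@extent), sd = 0.1)), dim = g@extent)
  vals[8:10, 8:10, 8:10] <- vals[8:10, 8:10, 8:10] + 8
  vals[20:21, 22:23, 11:12] <- vals[20:21, 22:23, 11:12] + 15
  m <- intensityModel(vals, g)
  seg <- segmentPeaks(m, n = 9)
  # affine rescaling leaves the labels unchanged
  m2 <- intensityModel(3.7 * vals + 11, g)
  seg2 <- segmentPeaks(m2, n = 9)
  expect_identical(seg@labels, seg2@labels)
  # raising every gamma can only shrink the signal set
  segHi <- segmentPeaks(m, n = 9, gammaSchedule = seq(1.5, 4, length.out = 4))
  expect_true(all(seg@labels[segHi@labels]))
  expect_lte(sum(segHi@labels), sum(seg@labels))
})

test_that("a known Gaussian peak integrates to its analytic weight", {
  # one peak of the toy truth, no background, no noise
  cell <- toyCell()
  grid <- toyGrid()
  set.seed(6)
  O <- SparseEMC:::randomRotationMatrix()
  truth <- makeGroundTruth(cell, grid, orientation = O, seed = 6)
  model <- intensityModel(truth@peaks, grid)
  seg <- segmentPeaks(model, n = 15)
  refl <- integrateReflections(model, cell, O, windowFractions = 0.25,
                               segmentation = seg)
  tab <- peakTable(truth)
  m <- merge(refl[!refl$partial, ], tab, by = c("h", "k", "l"))
  m <- m[m$intensity > 0.2, ]        # interior, non-absent, non-tiny peaks
  expect_gt(nrow(m), 50)
  relErr <- abs(m$I - m$intensity) / m$intensity
  expect_lt(median(relErr), 0.02)
  expect_lt(quantile(relErr, 0.9), 0.05)
})

test_that("integration is linear in the map and flags edge peaks partial", {
  cell <- toyCell()
  grid <- toyGrid()
  set.seed(8)
  O <- SparseEMC:::randomRotationMatrix()
  truth <- makeGroundTruth(cell, grid, orientation = O, seed = 8)
  # mark only the resolution sphere as observed, as a compressed
  # reconstruction would: windows crossing the boundary flag their peaks
  ext <- grid@extent
  ax <- (seq_len(ext[1]) - (ext[1] + 1) / 2) * grid@voxelSize
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  sphere <- r2 <= (1 / grid@resolutionLimit)^2
  model <- intensityModel(truth@peaks, grid, observed = sphere)
  seg <- segmentPeaks(model, n = 15)
  r1 <- integrateReflections(model, cell, O, segmentation = seg)
  m3 <- intensityModel(3 * truth@peaks, grid, observed = sphere)
  r3 <- integrateReflections(m3, cell, O, segmentation = seg)
  ok <- !r1$partial
  expect_equal(r3$I[ok], 3 * r1$I[ok], tolerance = 1e-9)

  # peaks near the resolution edge must be flagged partial
  tab <- peakTable(truth)
  qn <- sqrt(tab$qx^2 + tab$qy^2 + tab$qz^2)
  edge <- merge(r1, tab[qn > 0.98 / grid@resolutionLimit, ],
                by = c("h", "k", "l"))
  expect_true(all(edge$partial))

  # all-zero map integrates to all-zero intensities
  z <- intensityModel(array(0, dim = grid@extent), grid)
  rz <- integrateReflections(z, cell, O, windowFractions = 0.25)
  expect_true(all(rz$I[!rz$partial] == 0))
})

test_that("exclusion zones reject peaks near the beam", {
  cell <- toyCell()
  grid <- toyGrid()
  truth <- makeGroundTruth(cell, grid, orientation = diag(3), seed = 2)
  model <- intensityModel(truth@peaks, grid)
  rAll <- integrateReflections(model, cell, diag(3), windowFractions = 0.25)
  rEx <- integrateReflections(model, cell, diag(3), windowFractions = 0.25,
                              exclusionZones = list(c(0, 0, 0, 0.02)))
  qn <- with(peakTable(truth), sqrt(qx^2 + qy^2 + qz^2))
  inner <- peakTable(truth)[qn < 0.015, c("h", "k", "l")]
  mEx <- merge(rEx, inner, by = c("h", "k", "l"))
  expect_true(all(mEx$partial))
  expect_gt(sum(rEx$partial), sum(rAll$partial))
})

test_that("lattice refinement recovers the generating cell", {
  cell <- toyCell()
  grid <- toyGrid()
  hits <- 0L
  trials <- 6L
  for (s in seq_len(trials)) {
    set.seed(s)
    O <- SparseEMC:::randomRotationMatrix()
    truth <- makeGroundTruth(cell, grid, orientation = O, seed = s)
    model <- intensityModel(truth@peaks, grid)
    seg <- segmentPeaks(model, n = 15)
    est <- unitCell(77 * (1 + runif(1, -0.01, 0.01)),
                    36 * (1 + runif(1, -0.01, 0.01)))
    ref <- refineLattice(model, seg, est, O, searchWidth = 0.04,
                         searchSteps = 5L)
    step <- attr(ref, "step")
    if (abs(ref@a - 77) <= step["a"] + 1e-9 &&
        abs(ref@c - 36) <= step["c"] + 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.95 * trials))

  # candidate set containing only the truth returns the truth
  set.seed(1)
  O <- SparseEMC:::randomRotationMatrix()
  truth <- makeGroundTruth(cell, grid, orientation = O, seed = 1)
  model <- intensityModel(truth@peaks, grid)
  seg <- segmentPeaks(model, n = 15)
  only <- refineLattice(model, seg, cell, O, searchWidth = 1e-12,
                        searchSteps = 1L)
  expect_equal(only@a, 77)
  expect_equal(only@c, 36)

  empty <- new("Segmentation",
               labels = array(FALSE, dim = grid@extent),
               window = 15L, gammaSchedule = 1:3 / 1)
  expect_error(refineLattice(model, empty, cell, O), "impossible")
})

test_that("structure-factor conversion preserves keys and clips negatives", {
  refl <- data.frame(h = c(1, 2, 0), k = c(0, 1, 0), l = c(0, 0, 4),
                     I = c(25, -4, 0), sigma = 1, background = 0,
                     nVoxels = 10L, fraction = 0.1, partial = FALSE)
  sf <- toStructureFactors(refl)
  expect_equal(sf$F, c(5, 0, 0))
  expect_equal(sf$clipped, c(FALSE, TRUE, FALSE))
  expect_identical(sf[, c("h", "k", "l")], refl[, c("h", "k", "l")])
})
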