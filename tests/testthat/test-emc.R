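test_that("orientation posteriors match the brute-force Poisson oracle", {
  W <- matrix(c(2, 0.1, 0.1, 2), 2, 2)
  tw <- twoPixelWorld(W, matrix(c(3, 0), 2, 1))
  P <- computeProbabilities(tw$slices, tw$frames)
  expect_equal(as.numeric(P@values), bruteForcePosterior(W, c(3, 0)),
               tolerance = 1e-12)
  expect_equal(colSums(P@values), 1, tolerance = 1e-12)

  # several random toy cases
  set.seed(9)
  for (i in 1:10) {
    W <- matrix(runif(6, 0.05, 4), 2, 3)
    cnt <- matrix(rpois(2, 2), 2, 1)
    tw <- twoPixelWorld(W, cnt)
    P <- computeProbabilities(tw$slices, tw$frames)
    expect_equal(as.numeric(P@values),
                 bruteForcePosterior(W, as.numeric(cnt)), tolerance = 1e-12)
  }
})

test_that("posterior degenerate cases: single rotation and flat evidence", {
  W1 <- matrix(c(1, 2), 2, 1)
  tw <- twoPixelWorld(W1, matrix(c(5, 1), 2, 3))
  P <- computeProbabilities(tw$slices, tw$frames)
  expect_equal(as.numeric(P@values), rep(1, 3))

  # zero-photon frame with equal slice totals -> uniform posterior
  W <- matrix(c(1, 2, 2, 1, 1.5, 1.5), 2, 3)
  tw <- twoPixelWorld(W, matrix(0, 2, 1))
  P <- computeProbabilities(tw$slices, tw$frames)
  expect_equal(as.numeric(P@values), rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("the M step is the posterior-weighted mean photon count", {
  # one-hot probabilities: row j0 is the plain mean, other rows undefined
  counts <- matrix(c(3, 0, 1, 2, 4, 4), 2, 3)
  W <- matrix(1, 2, 2)
  tw <- twoPixelWorld(W, counts)
  P <- new("ProbabilityMatrix",
           values = matrix(c(1, 0, 1, 0, 1, 0), 2, 3),
           rotations = tw$slices@rotations, logLik = numeric(0))
  up <- maximizeSlices(P, tw$frames, tw$slices)
  expect_equal(up@values[, 1], rowMeans(counts))
  expect_true(all(is.na(up@values[, 2])))

  # uniform probabilities: every defined row equals the global mean
  Pu <- new("ProbabilityMatrix", values = matrix(0.5, 2, 3),
            rotations = tw$slices@rotations, logLik = numeric(0))
  up <- maximizeSlices(Pu, tw$frames, tw$slices)
  expect_equal(up@values[, 1], rowMeans(counts))
  expect_equal(up@values[, 2], rowMeans(counts))

  # hand-evaluated weighted mean on a 2x2 toy
  P2 <- new("ProbabilityMatrix",
            values = matrix(c(0.8, 0.2, 0.3, 0.7, 0.5, 0.5), 2, 3),
            rotations = tw$slices@rotations, logLik = numeric(0))
  up <- maximizeSlices(P2, tw$frames, tw$slices)
  w1 <- c(0.8, 0.3, 0.5)
  expect_equal(up@values[, 1],
               as.numeric(counts %*% w1) / sum(w1), tolerance = 1e-12)
})

test_that("expand and compress are consistent adjoints", {
  w <- .toyWorld()
  map <- suppressMessages(buildPixelMap(w$geom, rotationSet(90), w$grid))
  # smooth model: wide Gaussian over the grid
  ext <- w$grid@extent
  ctr <- (ext[1] + 1) / 2
  ax <- (seq_len(ext[1]) - ctr)
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  smooth <- intensityModel(array(exp(-r2 / 400), dim = ext), w$grid)

  # constant model expands to constant slices
  const <- intensityModel(array(2.5, dim = ext), w$grid)
  sl <- expandSlices(const, map)
  expect_equal(range(sl@values), c(2.5, 2.5))

  # compress of constant slices is constant on visited voxels
  back <- compressModel(sl, map)
  expect_equal(range(back@values[back@observed]), c(2.5, 2.5),
               tolerance = 1e-12)

  # round trip on a smooth model: relative RMS below 5 percent
  sl <- expandSlices(smooth, map)
  m2 <- compressModel(sl, map)
  sl2 <- expandSlices(m2, map)
  relRms <- sqrt(mean((sl2@values - sl@values)^2)) /
    sqrt(mean(sl@values^2))
  expect_lt(relRms, 0.05)

  obs <- m2@observed & smooth@values > 1e-3
  relRmsVox <- sqrt(mean((m2@values[obs] - smooth@values[obs])^2)) /
    sqrt(mean(smooth@values[obs]^2))
  expect_lt(relRmsVox, 0.05)

  # a single nonzero slice entry lands in at most 8 voxels
  oneVals <- matrix(0, nrow(sl@values), ncol(sl@values))
  oneVals[5, 3] <- 7
  one <- new("SliceSet", values = oneVals, pixelIndex = map@pixelIndex,
             rotations = rotationSet(90), grid = w$grid)
  m1 <- compressModel(one, map)
  expect_lte(sum(m1@values > 0), 8L)
})

test_that("a delta peak is visible only near the rotations that cross it", {
  w <- .toyWorld()
  rot <- rotationSet(72)
  map <- suppressMessages(buildPixelMap(w$geom, rot, w$grid))
  # put the delta at the angle-0 position of an off-axis pixel
  px <- which.max(rowSums(map@q0[, c(1, 3)]^2))
  co <- round(mapCoords(map, 0)[px, ])
  vals <- array(0, dim = w$grid@extent)
  vals[co[1], co[2], co[3]] <- 100
  model <- intensityModel(vals, w$grid)
  sl <- expandSlices(model, map)
  prof <- sl@values[px, ]
  expect_gt(prof[1], max(prof[10:63]) * 50)
})

test_that("EMC iteration: fixed point, ascent, and degenerate cases", {
  geom <- toyGeom(n = 24, beamstop = 0, pitch = 0.17)
  grid <- toyGrid(25)
  rot <- rotationSet(24)
  # constant integer model is an exact fixed point (uniform posteriors,
  # constant M step)
  const <- intensityModel(array(2, dim = grid@extent), grid)
  map <- suppressMessages(buildPixelMap(geom, rot, grid))
  lam <- expandSlices(const, map)@values[, 1]
  counts <- matrix(2L, length(map@pixelIndex), 8)
  cm <- Matrix::sparseMatrix(
    i = rep(map@pixelIndex, 8), j = rep(1:8, each = length(map@pixelIndex)),
    x = as.numeric(counts), dims = c(24 * 24, 8))
  frames <- new("FrameSet", counts = as(cm, "CsparseMatrix"),
                trueAngles = rep(0, 8), geometry = geom)
  fit <- suppressMessages(
    emcIterate(frames, geom, rot, const, nIter = 2))
  expect_lt(fit$trace$relRms[2], 1e-12)

  # EM ascent on noisy toy data within interpolation tolerance
  w <- .toyWorld()
  sub <- new("FrameSet", counts = w$frames@counts[, 1:1500],
             trueAngles = w$frames@trueAngles[1:1500], geometry = w$geom)
  seedM <- seedIntensity(w$cell, w$grid, w$truth@orientation, seed = 5)
  fit <- suppressMessages(
    emcIterate(sub, w$geom, w$rot, seedM, nIter = 8))
  ll <- fit$trace$logLik
  expect_true(all(diff(ll) > -0.001 * abs(ll[-length(ll)])))
  expect_true(all(is.finite(fit$trace$rms)))
  # probability columns stay normalized
  expect_lt(max(abs(colSums(fit$probabilities@values) - 1)), 1e-9)

  # one rotation: result equals the compress of the per-pixel mean frame
  rot1 <- rotationSet(1)
  map1 <- suppressMessages(buildPixelMap(w$geom, rot1, w$grid))
  fit1 <- suppressMessages(
    emcIterate(sub, w$geom, rot1, seedM, nIter = 1))
  meanFrame <- rowSums(sub@counts[map1@pixelIndex, , drop = FALSE]) /
    nFrames(sub)
  direct <- compressModel(
    new("SliceSet", values = matrix(meanFrame, ncol = 1),
        pixelIndex = map1@pixelIndex, rotations = rot1, grid = w$grid),
    map1)
  expect_equal(fit1$model@values[direct@observed],
               direct@values[direct@observed], tolerance = 1e-9)

  expect_error(emcIterate(sub, w$geom, w$rot, seedM, nIter = 0), "nIter")
})

test_that("seeding covers every predicted position without symmetry", {
  w <- .toyWorld()
  seedM <- seedIntensity(w$cell, w$grid, w$truth@orientation, seed = 2)
  tabAll <- latticePoints(w$cell, w$truth@orientation,
                          1 / w$grid@resolutionLimit)
  expect_equal(nrow(tabAll),
               bruteForceLatticeCount(77, 36, w$grid@resolutionLimit))
  # forbidden reflections are seeded too (no symmetry imposed)
  forb <- tabAll[tabAll$h == 0 & tabAll$k == 0 & tabAll$l %% 4 != 0, ]
  expect_gt(nrow(forb), 0)
  floorValue <- min(seedM@values)
  co <- round(gridCoords(w$grid, cbind(forb$qx, forb$qy, forb$qz)))
  for (i in seq_len(nrow(co))) {
    expect_gt(seedM@values[co[i, 1], co[i, 2], co[i, 3]], 2 * floorValue)
  }
  # determinism
  seedM2 <- seedIntensity(w$cell, w$grid, w$truth@orientation, seed = 2)
  expect_identical(seedM@values, seedM2@values)
})

test_that("resolution extension equals reference assembly under one-hot P", {
  w <- .toyWorld()
  sub <- new("FrameSet", counts = w$frames@counts[, 1:800],
             trueAngles = w$frames@trueAngles[1:800], geometry = w$geom)
  J <- length(w$rot@angles)
  jdx <- match(sub@trueAngles, w$rot@angles)
  P1 <- matrix(0, J, 800)
  P1[cbind(jdx, seq_len(800))] <- 1
  P <- new("ProbabilityMatrix", values = P1, rotations = w$rot,
           logLik = numeric(0))
  fine <- toyGrid(16)
  ext <- suppressMessages(
    extendResolution(P, sub, w$geom, w$rot, fine))
  expect_equal(dim(ext@values), as.integer(fine@extent))
  ref <- suppressMessages(assembleReference(sub, w$geom, fine))
  expect_equal(ext@values[ext@observed], ref@values[ext@observed],
               tolerance = 1e-9)
  expect_error(extendResolution(P, w$frames, w$geom, w$rot, fine), "frames")
})

test_that("photon-count rescaling is exact and idempotent", {
  w <- .toyWorld()
  model <- intensityModel(array(runif(prod(w$grid@extent)),
                                dim = w$grid@extent), w$grid)
  r1 <- rescaleToPhotonCount(model, w$frames)
  expect_equal(sum(r1@values), totalPhotons(w$frames), tolerance = 1e-9)
  r2 <- rescaleToPhotonCount(r1, w$frames)
  expect_equal(r2@values, r1@values, tolerance = 1e-12)
  expect_equal(sum(rescaleToPhotonCount(model, 500)@values), 500,
               tolerance = 1e-9)
  zero <- intensityModel(array(0, dim = w$grid@extent), w$grid)
  expect_error(rescaleToPhotonCount(zero, w$frames), "all-zero")
})

test_that("the reconstruction gauge follows the seed orientation", {
  # same frames, seed orientations differing by a rotation about the axis:
  # the recovered gauge offsets differ by exactly that angle
  w <- .toyWorld()
  sub <- new("FrameSet", counts = w$frames@counts[, 1:2000],
             trueAngles = w$frames@trueAngles[1:2000], geometry = w$geom)
  delta <- 45
  O1 <- w$truth@orientation
  O2 <- rotationMatrix(w$rot@axis, delta) %*% O1
  fit1 <- suppressMessages(emcIterate(
    sub, w$geom, w$rot, seedIntensity(w$cell, w$grid, O1, seed = 4),
    nIter = 6))
  fit2 <- suppressMessages(emcIterate(
    sub, w$geom, w$rot, seedIntensity(w$cell, w$grid, O2, seed = 4),
    nIter = 6))
  oe1 <- orientationErrors(fit1$probabilities, trueAngles(sub))
  oe2 <- orientationErrors(fit2$probabilities, trueAngles(sub))
  shift <- SparseEMC:::wrapAngle(oe2$offset - oe1$offset)
  expect_equal(min(shift, 360 - shift), delta, tolerance = 1e-9)
  expect_gt(oe2$fractionWithin, 0.5 * oe1$fractionWithin)
})
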