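test_that("reference assembly behaves on empty and single-photon sets", {
  w <- .toyWorld()
  npx <- w$geom@nFast * w$geom@nSlow
  empty <- new("FrameSet",
               counts = as(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                                x = numeric(0),
                                                dims = c(npx, 0L)),
                           "CsparseMatrix"),
               trueAngles = numeric(0), geometry = w$geom)
  ref0 <- suppressMessages(assembleReference(empty, w$geom, w$grid))
  expect_true(all(ref0@values == 0))

  # one frame, one photon: mass confined to the 8 voxels around its position
  px <- which(w$geom@mask)[500]
  one <- new("FrameSet",
             counts = as(Matrix::sparseMatrix(i = px, j = 1L, x = 1,
                                              dims = c(npx, 1L)),
                         "CsparseMatrix"),
             trueAngles = 123, geometry = w$geom)
  ref1 <- suppressMessages(assembleReference(one, w$geom, w$grid))
  expect_lte(sum(ref1@values > 0), 8L)

  # frames without recorded angles cannot be assembled
  anon <- new("FrameSet", counts = one@counts, trueAngles = numeric(0),
              geometry = w$geom)
  expect_error(suppressMessages(assembleReference(anon, w$geom, w$grid)),
               "true angles")
})

test_that("reference assembly on disjoint angle groups is consistent", {
  w <- .toyWorld()
  sel1 <- which(trueAngles(w$frames) == w$rot@angles[3])
  sel2 <- which(trueAngles(w$frames) == w$rot@angles[40])
  take <- function(sel) new("FrameSet",
                            counts = w$frames@counts[, sel, drop = FALSE],
                            trueAngles = w$frames@trueAngles[sel],
                            geometry = w$geom)
  a <- suppressMessages(assembleReference(take(sel1), w$geom, w$grid))
  b <- suppressMessages(assembleReference(take(sel2), w$geom, w$grid))
  ab <- suppressMessages(assembleReference(take(c(sel1, sel2)), w$geom,
                                           w$grid))
  onlyA <- a@observed & !b@observed
  expect_equal(ab@values[onlyA], a@values[onlyA], tolerance = 1e-12)
  onlyB <- b@observed & !a@observed
  expect_equal(ab@values[onlyB], b@values[onlyB], tolerance = 1e-12)
})

test_that("the amplitude R factor matches direct evaluation", {
  mk <- function(I) data.frame(h = seq_along(I), k = 0, l = 0, I = I,
                               partial = FALSE)
  # identical lists give R = 0
  expect_equal(as.numeric(rFactor(mk(c(4, 9, 16)), mk(c(4, 9, 16)))), 0)
  # |F| = {10, 20} vs {8, 22} with s fixed at 1: R = (2 + 2) / 30
  R <- rFactor(mk(c(100, 400)), mk(c(64, 484)), fitScale = FALSE)
  expect_equal(as.numeric(R), 4 / 30, tolerance = 1e-12)
  # global rescaling is absorbed by the fitted scale
  set.seed(2)
  I <- rexp(40) * 100
  R <- rFactor(mk(I), mk(7.3 * I))
  expect_equal(as.numeric(R), 0, tolerance = 1e-12)
  expect_equal(attr(R, "scale"), 1 / sqrt(7.3), tolerance = 1e-9)
  # no common reflections is an error
  a <- mk(c(1, 2)); b <- mk(c(1, 2)); b$h <- b$h + 10
  expect_error(rFactor(a, b), "common")
})

test_that("orientation errors: gauge fitting and thresholds", {
  rot <- rotationSet(60)
  J <- 60
  set.seed(5)
  true <- rot@angles[sample.int(J, 500, TRUE)]
  onehot <- function(assigned) {
    P <- matrix(0, J, length(assigned))
    P[cbind(match(assigned, rot@angles), seq_along(assigned))] <- 1
    new("ProbabilityMatrix", values = P, rotations = rot,
        logLik = numeric(0))
  }
  oe <- orientationErrors(onehot(true), true)
  expect_equal(oe$fractionWithin, 1)
  expect_equal(oe$offset, 0)
  expect_equal(oe$threshold, 3)      # max(1, spacing/2) at 6 deg spacing

  # constant 36-degree shift is recovered as the gauge offset
  shifted <- SparseEMC:::wrapAngle(true + 36)
  oe2 <- orientationErrors(onehot(shifted), true)
  expect_equal(oe2$fractionWithin, 1)
  expect_equal(oe2$offset, 36)

  # reversed sense is found only when the flip is allowed
  flipped <- SparseEMC:::wrapAngle(-true)
  oe3 <- orientationErrors(onehot(flipped), true, tryFlip = TRUE)
  expect_true(oe3$flipped)
  expect_equal(oe3$fractionWithin, 1)
  expect_equal(sum(oe3$histogram$count), 500)
})

test_that("reflection-condition checks grade rule compliance", {
  set.seed(7)
  base <- expand.grid(h = 0:4, k = 0:2, l = 0:5)
  base <- base[!(base$h == 0 & base$k == 0 & base$l == 0), ]
  base$I <- rexp(nrow(base)) * 100 + 50
  base$partial <- FALSE
  forb <- SparseEMC:::applyReflectionRules(base, defaultReflectionRules())
  withRules <- base
  withRules$I[forb] <- withRules$I[forb] * 0.001
  rep1 <- checkReflectionConditions(withRules)
  expect_true(all(rep1$pass[rep1$testable]))
  expect_true(all(rep1$ratio[rep1$testable] < 0.05))

  rep2 <- checkReflectionConditions(base)
  expect_false(any(rep2$pass[rep2$testable]))
  expect_true(all(rep2$ratio[rep2$testable] > 0.2))

  # a class with no forbidden members is not testable
  noForb <- base[!forb, ]
  rep3 <- checkReflectionConditions(noForb)
  expect_true(any(!rep3$testable))
  expect_true(all(is.na(rep3$pass[!rep3$testable])))
})

test_that("background fraction: degenerate splits and rescale guard", {
  g <- reciprocalGrid(voxelSize = 0.002, resolutionLimit = 20,
                      extent = 21L)
  vals <- array(1, dim = g@extent)
  vals[11, 11, 11] <- 1000
  m <- intensityModel(vals, g)
  seg <- new("Segmentation", labels = array(FALSE, dim = g@extent),
             window = 15L, gammaSchedule = 1)
  segPeak <- seg
  segPeak@labels[11, 11, 11] <- TRUE
  total <- sum(vals)
  expect_equal(backgroundFraction(m, seg, total), 1)
  # perfect segmentation of the single peak: background share is the rest
  expect_equal(backgroundFraction(m, segPeak, total),
               (total - 1000) / total)
  expect_error(backgroundFraction(m, seg, total * 2), "rescale")
})
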