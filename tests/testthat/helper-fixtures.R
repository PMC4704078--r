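# Shared toy fixtures.  Everything is generated in code; sizes are kept small
# so the whole suite stays fast.

toyCell <- function() unitCell(77, 36)

toyGrid <- function(resolution = 18) {
  reciprocalGrid(aStar = 1 / 77, divisor = 7, resolutionLimit = resolution)
}

toyGeom <- function(n = 48, beamstop = 3, pitch = 0.085) {
  detectorGeometry(n, n, pixelPitch = pitch, distance = 33, wavelength = 1.54,
                   beamCenter = c(n / 2 + 0.5, n / 2 + 0.5),
                   beamstopRadius = beamstop)
}

# A small calibrated ground truth + frames, memoised per session because
# several test files reuse it.
.toyWorld <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cell <- toyCell()
      grid <- toyGrid()
      geom <- toyGeom()
      rot <- rotationSet(120)
      truth <- makeGroundTruth(cell, grid, seed = 7)
      truth <- calibrateGroundTruth(truth, geom, rot, meanPhotons = 200,
                                    backgroundFraction = 0.8)
      frames <- simulateDataset(truth, geom, rot, nFrames = 4000, seed = 11)
      cache <<- list(cell = cell, grid = grid, geom = geom, rot = rot,
                     truth = truth, frames = frames)
    }
    cache
  }
})

# Independent brute-force enumeration of lattice points inside a resolution
# sphere (oracle for latticePoints / seeding / truth construction).
bruteForceLatticeCount <- function(a, cc, dmin) {
  qmax <- 1 / dmin
  n <- 0L
  for (h in -20:20) for (k in -20:20) for (l in -20:20) {
    if (h == 0 && k == 0 && l == 0) next
    q <- sqrt((h / a)^2 + (k / a)^2 + (l / cc)^2)
    if (q <= qmax) n <- n + 1L
  }
  n
}

# Direct Poisson-product oracle for the orientation posterior of one frame.
bruteForcePosterior <- function(W, counts) {
  un <- vapply(seq_len(ncol(W)), function(j) {
    prod(dpois(counts, W[, j]))
  }, numeric(1))
  un / sum(un)
}

# Tiny two-pixel world used by the closed-form E/M oracles.
twoPixelWorld <- function(W, counts) {
  geom <- detectorGeometry(2, 1, pixelPitch = 0.1, distance = 33,
                           wavelength = 1.54, beamCenter = c(1.5, 1))
  rot <- rotationSet(ncol(W))
  grid <- reciprocalGrid(voxelSize = 0.01, resolutionLimit = 50, extent = 11L)
  slices <- new("SliceSet", values = W, pixelIndex = 1:2, rotations = rot,
                grid = grid)
  cm <- as(as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"),
           "CsparseMatrix")
  frames <- new("FrameSet", counts = cm, trueAngles = numeric(0),
                geometry = geom)
  list(slices = slices, frames = frames)
}

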