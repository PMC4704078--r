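#' @include AllClasses.R geometry.R
NULL

#' Enumerate reciprocal-lattice points inside a resolution sphere
#'
#' @param cell a \linkS4class{UnitCell}.
#' @param orientation 3x3 rotation matrix placing the crystal axes in the lab
#'   frame.
#' @param qmax radius of the resolution sphere (1/Angstrom).
#' @param dropOrigin drop (0,0,0) (the direct beam), default \code{TRUE}.
#' @return data.frame with h, k, l and the lab-frame q vector of every lattice
#'   point with \code{|q| <= qmax}.
#' @export
latticePoints <- function(cell, orientation = diag(3), qmax,
                          dropOrigin = TRUE) {
  hmax <- floor(qmax * cell@a)
  lmax <- floor(qmax * cell@c)
  g <- expand.grid(h = -hmax:hmax, k = -hmax:hmax, l = -lmax:lmax)
  qc <- cbind(g$h * aStar(cell), g$k * aStar(cell), g$l * cStar(cell))
  q <- qc %*% t(orientation)
  keep <- rowSums(q^2) <= qmax^2
  if (dropOrigin) keep <- keep & (g$h != 0 | g$k != 0 | g$l != 0)
  data.frame(h = g$h[keep], k = g$k[keep], l = g$l[keep],
             qx = q[keep, 1], qy = q[keep, 2], qz = q[keep, 3])
}

#' Default space-group reflection conditions
#'
#' Axis-class rules of the tetragonal space group P4(3)2(1)2: reflections
#' (0,0,l) require l = 4n and (h,0,0) / (0,k,0) require an even index (the
#' 0k0 class follows from h00 by the tetragonal symmetry).
#'
#' @return list of rules, each with \code{name}, \code{select(h,k,l)} and
#'   \code{allowed(h,k,l)} predicates.
#' @export
defaultReflectionRules <- function() {
  list(
    list(name = "00l: l = 4n",
         select = function(h, k, l) h == 0 & k == 0,
         allowed = function(h, k, l) l %% 4 == 0),
    list(name = "h00: h = 2n",
         select = function(h, k, l) k == 0 & l == 0,
         allowed = function(h, k, l) h %% 2 == 0),
    list(name = "0k0: k = 2n",
         select = function(h, k, l) h == 0 & l == 0,
         allowed = function(h, k, l) k %% 2 == 0)
  )
}

applyReflectionRules <- function(tab, rules) {
  forb <- rep(FALSE, nrow(tab))
  for (r in rules) {
    sel <- r$select(tab$h, tab$k, tab$l)
    forb <- forb | (sel & !r$allowed(tab$h, tab$k, tab$l))
  }
  forb
}

#' Build a ground-truth intensity: Gaussian Bragg peaks plus diffuse background
#'
#' Places an isotropic 3D Gaussian of width \code{peakSigma} voxels at every
#' reciprocal-lattice point inside the resolution sphere.  True integrated
#' intensities follow a Wilson-like exponential law with mean
#' \eqn{\exp(-decay (|q|/q_{max})^2)}, so bright low-resolution and dim
#' high-resolution peaks both occur.  The diffuse background is a smooth
#' isotropic function of \code{|q|} with the same radial decay (diffuse
#' solvent/air/window scatter tracks the overall scattering power); its
#' absolute magnitude is fixed later by \code{\link{calibrateGroundTruth}}.
#' Friedel symmetry I(hkl) = I(-h,-k,-l) and the space-group absences are
#' imposed on the truth by default (the EMC seed never imposes them).
#'
#' @param cell true \linkS4class{UnitCell}.
#' @param grid target \linkS4class{ReciprocalGrid}; its resolution limit must
#'   not be finer than the grid interior can hold.
#' @param orientation 3x3 crystal orientation matrix, or \code{"random"}
#'   (default) for a uniformly random recorded orientation so lattice axes are
#'   not aligned with the grid.
#' @param peakSigma Gaussian peak width in voxels.
#' @param decay dimensionless radial decay of mean peak intensity and
#'   background.
#' @param spaceGroupRules impose the reflection conditions of
#'   \code{\link{defaultReflectionRules}} (zero forbidden intensities).
#' @param friedel impose Friedel symmetry on true intensities.
#' @param seed RNG seed for orientation and intensity draws.
#' @return an uncalibrated \linkS4class{GroundTruth}.
#' @examples
#' grid <- reciprocalGrid(aStar = 1/77, divisor = 7, resolutionLimit = 18)
#' truth <- makeGroundTruth(unitCell(77, 36), grid, seed = 1)
#' @export
makeGroundTruth <- function(cell, grid, orientation = "random",
                            peakSigma = 0.8, decay = 2,
                            spaceGroupRules = TRUE, friedel = TRUE,
                            seed = 1) {
  set.seed(seed)
  qmax <- 1 / grid@resolutionLimit
  qInterior <- (min(grid@extent - 1) / 2 - 1) * grid@voxelSize
  if (qmax > qInterior + 1e-12) {
    configError("resolution limit %.3g A is finer than the grid interior supports (%.3g A)",
                grid@resolutionLimit, 1 / qInterior)
  }
  if (identical(orientation, "random")) orientation <- randomRotationMatrix()
  tab <- latticePoints(cell, orientation, qmax)
  if (nrow(tab)) {
    qn <- sqrt(tab$qx^2 + tab$qy^2 + tab$qz^2)
    # one exponential draw per Friedel pair when Friedel symmetry is imposed
    key <- hklKey(tab$h, tab$k, tab$l)
    keyF <- pmin(key, hklKey(-tab$h, -tab$k, -tab$l))
    draw <- rexp(nrow(tab))
    if (friedel) {
      first <- !duplicated(if (friedel) keyF else key)
      drawMap <- draw[first]
      names(drawMap) <- keyF[first]
      draw <- drawMap[as.character(keyF)]
    }
    tab$intensity <- as.numeric(draw) * exp(-decay * (qn / qmax)^2)
    if (spaceGroupRules) {
      tab$intensity[applyReflectionRules(tab, defaultReflectionRules())] <- 0
    }
  } else {
    tab$intensity <- numeric(0)
  }
  tab$sigma <- rep(peakSigma, nrow(tab))

  peaks <- array(0, dim = grid@extent)
  live <- tab$intensity > 0
  if (any(live)) {
    centers <- gridCoords(grid, cbind(tab$qx, tab$qy, tab$qz)[live, , drop = FALSE])
    .cpp_add_gaussians(peaks, grid@extent, centers, tab$intensity[live],
                       peakSigma, 4)
  }

  ext <- grid@extent
  ctr <- (ext[1] + 1) / 2
  ax <- (seq_len(ext[1]) - ctr) * grid@voxelSize
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  background <- array(0, dim = ext)
  inside <- r2 <= (qmax + 2 * peakSigma * grid@voxelSize)^2
  background[inside] <- exp(-decay * r2[inside] / qmax^2)

  new("GroundTruth", cell = cell, orientation = orientation, peakTable = tab,
      peaks = peaks, background = background, grid = grid,
      intensity = array(numeric(0), dim = c(0L, 0L, 0L)),
      meanPhotons = numeric(0), backgroundFraction = numeric(0),
      peakScale = numeric(0), backgroundScale = numeric(0))
}

#' Calibrate a ground truth to a photon budget
#'
#' Scales the Bragg and background components so that, averaged over the
#' sampled rotations, a frame records \code{meanPhotons} expected photons of
#' which a fraction \code{backgroundFraction} comes from the diffuse
#' background.  After calibration \code{\link{trueIntensity}} is in
#' expected-photons-per-frame units and expanding it with the same pixel map
#' yields per-pixel Poisson means directly.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param geom the \linkS4class{DetectorGeometry} frames will be recorded on.
#' @param rotations the \linkS4class{RotationSet} used for the angle average.
#' @param meanPhotons target mean photons per frame.
#' @param backgroundFraction share of expected photons from background, in
#'   [0, 1].
#' @return the calibrated \linkS4class{GroundTruth}.
#' @export
calibrateGroundTruth <- function(truth, geom, rotations, meanPhotons = 200,
                                 backgroundFraction = 0.8) {
  if (meanPhotons <= 0) configError("meanPhotons must be > 0")
  if (backgroundFraction < 0 || backgroundFraction > 1)
    configError("backgroundFraction must lie in [0, 1]")
  map <- buildPixelMap(geom, rotations, truth@grid)
  Tp <- mean(colSums(expandArray(truth@peaks, map)))
  Tb <- mean(colSums(expandArray(truth@background, map)))
  sp <- if (Tp > 0) (1 - backgroundFraction) * meanPhotons / Tp else 0
  sb <- if (Tb > 0) backgroundFraction * meanPhotons / Tb else 0
  truth@intensity <- sp * truth@peaks + sb * truth@background
  truth@peakScale <- sp
  truth@backgroundScale <- sb
  truth@meanPhotons <- meanPhotons
  truth@backgroundFraction <- backgroundFraction
  if (nrow(truth@peakTable)) truth@peakTable$photons <- sp * truth@peakTable$intensity
  truth
}

# Expand a raw array over a pixel map (internal; no floor, no class wrapping).
expandArray <- function(arr, map) {
  J <- length(map@rotations@angles)
  W <- matrix(0, nrow(map@q0), J)
  for (j in seq_len(J)) {
    W[, j] <- .cpp_trilinear_gather(arr, map@grid@extent,
                                    mapCoords(map, map@rotations@angles[j]))
  }
  W
}

#' Simulate one sparse frame
#'
#' Per-pixel expected counts are the calibrated true intensity sampled on the
#' Ewald sphere at the given rotation angle (same trilinear interpolation as
#' the EMC expansion); observed counts are independent Poisson draws.
#'
#' @param truth a calibrated \linkS4class{GroundTruth}.
#' @param geom the \linkS4class{DetectorGeometry}.
#' @param angle rotation angle in degrees (normalized mod 360).
#' @param rotations \linkS4class{RotationSet} supplying the rotation axis.
#' @return a \linkS4class{FrameSet} holding the single frame.
#' @export
simulateFrame <- function(truth, geom, angle, rotations = rotationSet(1)) {
  simulateDataset(truth, geom, rotations, nFrames = 1L,
                  mode = "continuous", angles = wrapAngle(angle))
}

#' Simulate a dataset of sparse frames
#'
#' Frames are drawn either at the discrete rotation samples (balanced
#' assignment, shuffled: the experimental analogue is a crystal swept
#' uniformly through many revolutions) or at uniformly random continuous
#' angles.  Photon counts are independent Poisson draws per pixel; for the
#' discrete mode this is realized by the exact decomposition
#' Poisson(sum of means) followed by uniform assignment of photons to the
#' frames sharing an angle, which is distributionally identical and fast.
#' True angles are stored as hidden metadata for validation.
#'
#' @param truth a calibrated \linkS4class{GroundTruth} (see
#'   \code{\link{calibrateGroundTruth}}).
#' @param geom the \linkS4class{DetectorGeometry}.
#' @param rotations the \linkS4class{RotationSet} (discrete mode draws only
#'   these angles).
#' @param nFrames number of frames (0 gives a valid empty set).
#' @param seed RNG seed; the dataset is reproducible from it.
#' @param mode \code{"discrete"} or \code{"continuous"}.
#' @param angles optional explicit per-frame angles (continuous mode only).
#' @return a \linkS4class{FrameSet}.
#' @export
simulateDataset <- function(truth, geom, rotations, nFrames, seed = 1,
                            mode = c("discrete", "continuous"),
                            angles = NULL) {
  mode <- match.arg(mode)
  if (!length(truth@intensity)) {
    configError("ground truth must be calibrated before simulating frames")
  }
  set.seed(seed)
  nFrames <- as.integer(nFrames)
  npx <- geom@nFast * geom@nSlow
  if (nFrames == 0L) {
    return(new("FrameSet",
               counts = as(sparseMatrix(i = integer(0), j = integer(0),
                                        x = numeric(0), dims = c(npx, 0L)),
                           "CsparseMatrix"),
               trueAngles = numeric(0), geometry = geom))
  }
  map <- buildPixelMap(geom, rotations, truth@grid)

  if (mode == "discrete") {
    J <- length(rotations@angles)
    jdx <- sample(rep_len(seq_len(J), nFrames))
    frameAngles <- rotations@angles[jdx]
    iList <- vector("list", J)
    jList <- vector("list", J)
    for (j in seq_len(J)) {
      inGroup <- which(jdx == j)
      ng <- length(inGroup)
      if (!ng) next
      lam <- .cpp_trilinear_gather(truth@intensity, truth@grid@extent,
                                   mapCoords(map, rotations@angles[j]))
      tot <- rpois(length(lam), ng * lam)
      hit <- tot > 0L
      if (!any(hit)) next
      pix <- rep(map@pixelIndex[hit], tot[hit])
      frm <- inGroup[sample.int(ng, length(pix), replace = TRUE)]
      iList[[j]] <- pix
      jList[[j]] <- frm
    }
    counts <- sparseMatrix(i = unlist(iList), j = unlist(jList),
                           x = 1, dims = c(npx, nFrames))
  } else {
    if (is.null(angles)) angles <- runif(nFrames, 0, 360)
    frameAngles <- wrapAngle(angles)
    iList <- vector("list", nFrames)
    jList <- vector("list", nFrames)
    for (k in seq_len(nFrames)) {
      lam <- .cpp_trilinear_gather(truth@intensity, truth@grid@extent,
                                   mapCoords(map, frameAngles[k]))
      cnt <- rpois(length(lam), lam)
      hit <- cnt > 0L
      if (!any(hit)) next
      iList[[k]] <- rep(map@pixelIndex[hit], cnt[hit])
      jList[[k]] <- rep.int(k, sum(cnt[hit]))
    }
    counts <- sparseMatrix(i = unlist(iList), j = unlist(jList),
                           x = 1, dims = c(npx, nFrames))
  }
  new("FrameSet", counts = as(counts, "CsparseMatrix"),
      trueAngles = as.numeric(frameAngles), geometry = geom)
}
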