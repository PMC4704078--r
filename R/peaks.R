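#' @include AllClasses.R
NULL

# Running-window sum of a 3D array: sum over the n^3 cube centered on each
# voxel, truncated at the edges.  Separable cumulative sums along each axis.
boxsum3 <- function(arr, n) {
  h <- (n - 1L) %/% 2L
  runsum1 <- function(a) {
    d <- dim(a)
    m <- matrix(a, d[1], d[2] * d[3])
    C0 <- rbind(0, apply(m, 2, cumsum))
    i <- seq_len(d[1])
    lo <- pmax(1L, i - h)
    hi <- pmin(d[1], i + h)
    array(C0[hi + 1L, , drop = FALSE] - C0[lo, , drop = FALSE], dim = d)
  }
  for (d in 1:3) {
    arr <- runsum1(arr)
    arr <- aperm(arr, c(2, 3, 1))
  }
  arr
}

#' Segment Bragg peaks by iterated local standard score
#'
#' Classifies voxels into signal or background.  Each voxel's standard score
#' is \eqn{z = (W - \mu) / \sigma} with \eqn{\mu, \sigma} the mean and
#' standard deviation over the surrounding \eqn{n \times n \times n} cube
#' (truncated at the map edges); voxels with \eqn{z > \gamma} are labeled
#' signal.  The first pass uses all (observed) voxels; each later pass
#' recomputes \eqn{\mu, \sigma} from the voxels labeled background in the
#' previous pass, with \eqn{\gamma} raised according to the schedule.  A
#' \eqn{\sigma = 0} window (e.g. a perfectly flat map) yields z = 0, i.e.
#' background.  The classification is invariant under affine rescaling
#' \eqn{W \to aW + b} with \eqn{a > 0}.
#'
#' @param model an \linkS4class{IntensityModel}; unobserved voxels are always
#'   background and never enter the window statistics.
#' @param n odd window edge, >= 3 and at most the map extent.
#' @param gammaSchedule non-decreasing thresholds, one per pass (default 4
#'   passes linearly spaced from 1.0 to 3.0).
#' @return a \linkS4class{Segmentation}.
#' @export
segmentPeaks <- function(model, n = 15L,
                         gammaSchedule = seq(1, 3, length.out = 4)) {
  n <- as.integer(n)
  if (n %% 2L == 0L || n < 3L) configError("window size n must be odd and >= 3")
  if (n > min(model@grid@extent)) {
    configError("window size %d exceeds the map extent %d", n, min(model@grid@extent))
  }
  if (any(diff(gammaSchedule) < 0)) configError("gamma schedule must be non-decreasing")
  W <- model@values
  valid <- model@observed
  scaleGuard <- 1e-10 * max(diff(range(W)), 0)
  maskBg <- valid
  signal <- array(FALSE, dim = dim(W))
  for (g in gammaSchedule) {
    cnt <- boxsum3(maskBg + 0, n)
    Sw <- boxsum3(W * maskBg, n)
    Sw2 <- boxsum3(W^2 * maskBg, n)
    ok <- cnt > 0
    mu <- array(0, dim = dim(W)); mu[ok] <- Sw[ok] / cnt[ok]
    v <- array(0, dim = dim(W)); v[ok] <- pmax(Sw2[ok] / cnt[ok] - mu[ok]^2, 0)
    sg <- sqrt(v)
    z <- array(0, dim = dim(W))
    use <- sg > scaleGuard
    z[use] <- (W[use] - mu[use]) / sg[use]
    # sigma = 0 window: a voxel exactly on the flat level is background, a
    # voxel strictly above it is unambiguous signal
    z[!use & (W > mu + scaleGuard)] <- Inf
    signal <- valid & (z > g)
    maskBg <- valid & !signal
  }
  new("Segmentation", labels = signal, window = n,
      gammaSchedule = as.numeric(gammaSchedule))
}

# Ellipsoid radius in (h,k,l) units for an ellipsoid occupying `fraction` of
# the reciprocal unit cell, with principal axes proportional to (a*, a*, c*).
ellipsoidRadius <- function(fraction) (3 * fraction / (4 * pi))^(1 / 3)

# Per-voxel lattice coordinates: fractional Miller indices m = (a q.a^, a
# q.b^, c q.c^) in the crystal frame.  Returns a list of vectors over all
# voxels (column-major order).
voxelMiller <- function(grid, cell, orientation) {
  ext <- grid@extent
  ctr <- (ext + 1) / 2
  ax1 <- (seq_len(ext[1]) - ctr[1]) * grid@voxelSize
  ax2 <- (seq_len(ext[2]) - ctr[2]) * grid@voxelSize
  ax3 <- (seq_len(ext[3]) - ctr[3]) * grid@voxelSize
  vx <- rep(ax1, times = ext[2] * ext[3])
  vy <- rep(rep(ax2, each = ext[1]), times = ext[3])
  vz <- rep(ax3, each = ext[1] * ext[2])
  O <- orientation
  qc1 <- vx * O[1, 1] + vy * O[2, 1] + vz * O[3, 1]
  qc2 <- vx * O[1, 2] + vy * O[2, 2] + vz * O[3, 2]
  qc3 <- vx * O[1, 3] + vy * O[2, 3] + vz * O[3, 3]
  list(m1 = qc1 * cell@a, m2 = qc2 * cell@a, m3 = qc3 * cell@c,
       qn2 = vx^2 + vy^2 + vz^2)
}

#' Refine reciprocal-lattice constants by total segmented intensity
#'
#' Scans a grid of candidate (a, c) cells bracketing the estimate; for each
#' candidate, sums the segmented-signal intensity inside small ellipsoids
#' centered at the candidate's predicted Bragg positions (principal axes
#' proportional to (a*, a*, c*), total volume \code{ellipsoidFraction} of the
#' reciprocal cell).  The candidate with the greatest total intensity wins;
#' ties break toward the candidate closest to the estimate.
#'
#' @param model an \linkS4class{IntensityModel}.
#' @param segmentation a \linkS4class{Segmentation} of \code{model}.
#' @param cellEstimate rough \linkS4class{UnitCell}.
#' @param orientation crystal orientation matrix.
#' @param searchWidth half-width of the search interval, relative (default
#'   2.5 percent of each cell constant).
#' @param searchSteps candidate count per axis (odd keeps the estimate in the
#'   set).
#' @param ellipsoidFraction ellipsoid volume as a fraction of the reciprocal
#'   cell.
#' @return the refined \linkS4class{UnitCell}, with attributes
#'   \code{"score"} (total intensity) and \code{"step"} (search step sizes).
#' @export
refineLattice <- function(model, segmentation, cellEstimate,
                          orientation = diag(3), searchWidth = 0.025,
                          searchSteps = 21L, ellipsoidFraction = 0.02) {
  sig <- which(segmentation@labels)
  if (!length(sig)) semcError("semc_data_error", "empty segmentation: lattice refinement impossible")
  mill <- voxelMiller(model@grid, unitCell(1, 1), orientation)  # crystal-frame q
  qc1 <- mill$m1[sig]; qc2 <- mill$m2[sig]; qc3 <- mill$m3[sig]
  w <- model@values[sig]
  s <- ellipsoidRadius(ellipsoidFraction)
  aCand <- cellEstimate@a * seq(1 - searchWidth, 1 + searchWidth,
                                length.out = searchSteps)
  cCand <- cellEstimate@c * seq(1 - searchWidth, 1 + searchWidth,
                                length.out = searchSteps)
  best <- c(NA, NA); bestScore <- -Inf; bestDist <- Inf
  for (a in aCand) {
    m1 <- qc1 * a; m2 <- qc2 * a
    r1 <- m1 - round(m1); r2 <- m2 - round(m2)
    r12 <- r1^2 + r2^2
    pre <- r12 <= s^2       # cheap prefilter on the tetragonal plane
    for (cc in cCand) {
      m3 <- qc3[pre] * cc
      r3 <- m3 - round(m3)
      inside <- r12[pre] + r3^2 <= s^2
      score <- sum(w[pre][inside])
      dist <- ((a - cellEstimate@a) / cellEstimate@a)^2 +
        ((cc - cellEstimate@c) / cellEstimate@c)^2
      if (score > bestScore + 1e-12 ||
          (abs(score - bestScore) <= 1e-12 && dist < bestDist)) {
        bestScore <- score; best <- c(a, cc); bestDist <- dist
      }
    }
  }
  out <- unitCell(best[1], best[2])
  attr(out, "score") <- bestScore
  attr(out, "step") <- c(a = diff(aCand)[1], c = diff(cCand)[1])
  out
}

#' Integrate background-subtracted Bragg reflections
#'
#' An ellipsoid window (axes proportional to (a*, a*, c*)) is centered on
#' every predicted Bragg position inside the resolution sphere.  Voxels
#' inside a peak's window are its signal candidates; shared voxels go to the
#' nearer peak center (achieved by assigning each voxel to its nearest
#' lattice point).  The window grows through \code{windowFractions} of the
#' reciprocal-cell volume, each peak using the smallest fraction that
#' contains all its segmentation-labeled voxels (the largest fraction when no
#' segmentation is supplied).  The local background mean -- over voxels of
#' the peak's reciprocal cell that lie outside the window and are not
#' segmentation-labeled signal -- is subtracted from each signal voxel before
#' summing; intensities may come out negative and are retained.  Peaks whose
#' window leaves the observed map region (map boundary, never-visited voxels,
#' an exclusion zone) are flagged partial and carry no intensity.
#'
#' @param model an \linkS4class{IntensityModel} (typically rescaled to the
#'   photon count).
#' @param cell refined \linkS4class{UnitCell}.
#' @param orientation crystal orientation matrix.
#' @param windowFractions increasing ellipsoid volumes as fractions of the
#'   reciprocal cell, in (0, 1].
#' @param segmentation optional \linkS4class{Segmentation} steering the
#'   per-peak window choice and protecting the background estimate.
#' @param fractions optional per-reflection window override: a data.frame
#'   with columns h, k, l, fraction (e.g. from a previous integration).  Use
#'   this to integrate two maps with literally identical ellipsoids, as the
#'   reference-vs-reconstruction comparison requires.
#' @param exclusionZones optional list of \code{c(qx, qy, qz, radius)}
#'   spheres (1/Angstrom) to reject, e.g. a beamstop region.
#' @param minCoverage fraction of the nominal ellipsoid voxel count that must
#'   be present and observed for a peak to count as fully recorded.
#' @return a \code{data.frame} (one row per reflection) with columns h, k, l,
#'   I, sigma, background, nVoxels, fraction, partial; partial rows have
#'   \code{I = NA}.  The sigma column is an artifact convention: propagated
#'   counting-style uncertainty from the background spread,
#'   \eqn{\sigma(I) = \sqrt{n_{sig} \mathrm{var}(bg) (1 + n_{sig}/n_{bg})}}.
#' @export
integrateReflections <- function(model, cell, orientation = diag(3),
                                 windowFractions = c(0.10, 0.25, 0.50),
                                 segmentation = NULL, fractions = NULL,
                                 exclusionZones = NULL, minCoverage = 0.9) {
  windowFractions <- sort(windowFractions)
  if (any(windowFractions <= 0 | windowFractions > 1)) {
    configError("window fractions must lie in (0, 1]")
  }
  grid <- model@grid
  qmax <- 1 / grid@resolutionLimit
  peaks <- latticePoints(cell, orientation, qmax)
  if (!nrow(peaks)) {
    return(data.frame(h = integer(0), k = integer(0), l = integer(0),
                      I = numeric(0), sigma = numeric(0),
                      background = numeric(0), nVoxels = integer(0),
                      fraction = numeric(0), partial = logical(0)))
  }
  peakKeys <- hklKey(peaks$h, peaks$k, peaks$l)
  sMax <- ellipsoidRadius(max(windowFractions))

  mill <- voxelMiller(grid, cell, orientation)
  h <- round(mill$m1); k <- round(mill$m2); l <- round(mill$m3)
  r2 <- (mill$m1 - h)^2 + (mill$m2 - k)^2 + (mill$m3 - l)^2
  keyAll <- hklKey(h, k, l)
  pid <- match(keyAll, peakKeys)          # NA for voxels not near a listed peak
  near <- !is.na(pid)

  segLab <- if (is.null(segmentation)) array(FALSE, dim = dim(model@values))
            else segmentation@labels
  obs <- as.vector(model@observed)
  W <- as.vector(model@values)
  segV <- as.vector(segLab)

  nPk <- nrow(peaks)
  # per-peak window fraction: smallest schedule entry containing all
  # segmented voxels of the peak (fallback: smallest fraction)
  sChosen <- rep(ellipsoidRadius(windowFractions[1]), nPk)
  fChosen <- rep(windowFractions[1], nPk)
  if (!is.null(fractions)) {
    ov <- match(peakKeys, hklKey(fractions$h, fractions$k, fractions$l))
    hit <- !is.na(ov)
    fChosen[hit] <- fractions$fraction[ov[hit]]
    sChosen <- ellipsoidRadius(fChosen)
  } else if (!is.null(segmentation)) {
    selSeg <- near & segV & (r2 <= sMax^2)
    if (any(selSeg)) {
      need <- tapply(sqrt(r2[selSeg]), pid[selSeg], max)
      idx <- as.integer(names(need))
      fNeed <- pmin(4 / 3 * pi * as.numeric(need)^3 + 1e-12, max(windowFractions))
      pickFrac <- vapply(fNeed, function(f) {
        windowFractions[which(windowFractions >= f)[1]]
      }, numeric(1))
      fChosen[idx] <- pickFrac
      sChosen[idx] <- ellipsoidRadius(pickFrac)
    }
  } else {
    sChosen[] <- sMax
    fChosen[] <- max(windowFractions)
  }

  sV <- sChosen[pid]                       # per-voxel chosen radius (NA away)
  isSig <- near & obs & (r2 <= sV^2)
  isBg <- near & obs & (r2 > sV^2) & !segV

  sumsOf <- function(sel) {
    cnt <- tabulate(pid[sel], nPk)
    sw <- rowsum(W[sel], pid[sel])
    sw2 <- rowsum(W[sel]^2, pid[sel])
    swFull <- numeric(nPk); swFull[as.integer(rownames(sw))] <- sw
    sw2Full <- numeric(nPk); sw2Full[as.integer(rownames(sw2))] <- sw2
    list(n = cnt, s = swFull, s2 = sw2Full)
  }
  sig <- sumsOf(isSig)
  bg <- sumsOf(isBg)

  bgMean <- ifelse(bg$n > 0, bg$s / bg$n, 0)
  bgVar <- ifelse(bg$n > 1, pmax(bg$s2 / bg$n - bgMean^2, 0), 0)
  I <- sig$s - sig$n * bgMean
  sigma <- sqrt(sig$n * bgVar * (1 + ifelse(bg$n > 0, sig$n / bg$n, 0)))

  # coverage: nominal ellipsoid volume in voxels vs voxels actually present
  cellVoxels <- (aStar(cell) / grid@voxelSize)^2 * (cStar(cell) / grid@voxelSize)
  nNominal <- fChosen * cellVoxels
  partial <- sig$n < minCoverage * nNominal | bg$n < 1
  if (!is.null(exclusionZones)) {
    rPk <- sChosen * pmax(aStar(cell), cStar(cell))   # generous q radius
    for (z in exclusionZones) {
      d <- sqrt((peaks$qx - z[1])^2 + (peaks$qy - z[2])^2 + (peaks$qz - z[3])^2)
      partial <- partial | (d <= z[4] + rPk)
    }
  }
  I[partial] <- NA_real_
  sigma[partial] <- NA_real_

  out <- data.frame(h = peaks$h, k = peaks$k, l = peaks$l, I = I,
                    sigma = sigma, background = bgMean, nVoxels = sig$n,
                    fraction = fChosen, partial = partial)
  out[order(out$h, out$k, out$l), , drop = FALSE]
}

#' Convert integrated intensities to structure-factor amplitudes
#'
#' \eqn{|F| = \sqrt{\max(I, 0)}}; rows whose negative intensity was clipped
#' are marked in the \code{clipped} column.  Ordering and (h, k, l) keys are
#' preserved.
#'
#' @param reflections a reflection data.frame from
#'   \code{\link{integrateReflections}}.
#' @return data.frame with h, k, l, F, clipped (and partial carried through).
#' @export
toStructureFactors <- function(reflections) {
  data.frame(h = reflections$h, k = reflections$k, l = reflections$l,
             F = sqrt(pmax(reflections$I, 0)),
             clipped = !is.na(reflections$I) & reflections$I < 0,
             partial = reflections$partial)
}
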