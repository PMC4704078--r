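#' @include AllClasses.R geometry.R
NULL

#' Seed an initial intensity estimate
#'
#' Places small 3D Gaussian bumps of independent random heights at every
#' reciprocal-lattice point of the (rough) cell estimate inside the resolution
#' sphere, plus a small uniform floor.  Deliberately no symmetry is imposed:
#' Friedel mates get independent heights and systematically absent reflections
#' are seeded too, so any symmetry present in the converged model is evidence
#' of successful orientation recovery rather than an input.
#'
#' @param cellEstimate rough \linkS4class{UnitCell}.
#' @param grid target \linkS4class{ReciprocalGrid}.
#' @param orientation 3x3 crystal orientation matrix (known from indexing a
#'   coarse first pass; in simulations, recorded by the simulator).
#' @param peakWidth Gaussian width of the seeded bumps, voxels.
#' @param radialDecay Wilson-type radial envelope on the random heights:
#'   heights are multiplied by \eqn{\exp(-radialDecay (|q|/q_{max})^2)}, the
#'   same overall falloff a powder pattern of the sample would show.  Set 0
#'   for envelope-free random heights.
#' @param floorFraction uniform floor as a fraction of the mean in-sphere
#'   seed value (keeps every observable voxel strictly positive).
#' @param seed RNG seed for the random heights.
#' @return an \linkS4class{IntensityModel}.
#' @export
seedIntensity <- function(cellEstimate, grid, orientation = diag(3),
                          peakWidth = 1.2, radialDecay = 2,
                          floorFraction = 1e-3, seed = 1) {
  set.seed(seed)
  qmax <- 1 / grid@resolutionLimit
  tab <- latticePoints(cellEstimate, orientation, qmax)
  vals <- array(0, dim = grid@extent)
  if (nrow(tab)) {
    centers <- gridCoords(grid, cbind(tab$qx, tab$qy, tab$qz))
    qn2 <- tab$qx^2 + tab$qy^2 + tab$qz^2
    heights <- rexp(nrow(tab)) * exp(-radialDecay * qn2 / qmax^2)
    .cpp_add_gaussians(vals, grid@extent, centers, heights, peakWidth, 4)
  }
  floorValue <- floorFraction * mean(vals[vals > 0])
  if (!is.finite(floorValue) || floorValue <= 0) floorValue <- floorFraction
  vals <- vals + floorValue
  intensityModel(vals, grid)
}

#' Expand: sample intensity slices for every rotation
#'
#' Trilinear interpolation of the model at each mapped pixel's rotated
#' scattering vector; entries are clamped below by \code{floorValue} so a
#' photon observed anywhere never meets a zero expected count.  Slices are in
#' expected-photons-per-frame units: frames are single fixed-duration
#' exposures of one crystal, so the model carries the per-frame normalization
#' implicitly and no per-frame scale factors are fitted.
#'
#' @param model an \linkS4class{IntensityModel}.
#' @param map a \linkS4class{PixelMap} built on the same grid.
#' @param floorValue lower clamp for slice values.
#' @return a \linkS4class{SliceSet}.
#' @export
expandSlices <- function(model, map, floorValue = 1e-10) {
  if (!identical(model@grid@extent, map@grid@extent) ||
      abs(model@grid@voxelSize - map@grid@voxelSize) > 1e-12) {
    configError("pixel map was built on a different grid than the model")
  }
  W <- expandArray(model@values, map)
  W[W < floorValue] <- floorValue
  new("SliceSet", values = W, pixelIndex = map@pixelIndex,
      rotations = map@rotations, grid = map@grid)
}

# Restrict a FrameSet's counts to the mapped pixels.  Photons on masked
# detector pixels are a data-integrity error; photons on usable pixels that
# merely lie beyond the current stage's resolution range are excluded (they
# belong to a later, finer stage).
framesOnMap <- function(frames, pixelIndex) {
  masked <- which(!frames@geometry@mask)
  if (length(masked)) {
    bad <- sum(frames@counts[masked, , drop = FALSE]@x)
    if (bad > 0) dataError("%d photons fall on masked detector pixels", bad)
  }
  frames@counts[pixelIndex, , drop = FALSE]
}

#' Orientation probabilities of every frame (E step)
#'
#' Under independent per-pixel Poisson statistics and a uniform orientation
#' prior, the posterior that frame k was recorded at rotation j is
#' \deqn{P_{jk} \propto \prod_i W_{ij}^{K_{ik}} e^{-W_{ij}},}
#' evaluated in the log domain: only the sparse nonzero photon counts enter
#' the product term while the exponential term uses each slice's total
#' \eqn{\sum_i W_{ij}}.  Columns are normalized by per-frame log-sum-exp
#' (max subtraction), and the total log-likelihood
#' \eqn{\sum_k \log \sum_j (1/J) \prod_i \mathrm{Poisson}(K_{ik}; W_{ij})}
#' (dropping the W-independent \eqn{\sum \log K!} term) is recorded.
#'
#' A deterministic-annealing exponent \code{beta} may be applied to the
#' per-frame log-likelihoods before normalization (\code{beta < 1} flattens
#' the posteriors; the reported \code{logLik} always refers to the true,
#' unannealed likelihood).
#'
#' @param slices a \linkS4class{SliceSet} (undefined entries not allowed).
#' @param frames a \linkS4class{FrameSet} on the same detector.
#' @param beta annealing exponent in (0, 1].
#' @return a \linkS4class{ProbabilityMatrix} (J x K).
#' @export
computeProbabilities <- function(slices, frames, beta = 1) {
  if (any(is.na(slices@values))) {
    configError("slices contain undefined entries; complete them before the E step")
  }
  K <- framesOnMap(frames, slices@pixelIndex)
  nFr <- ncol(K)
  J <- ncol(slices@values)
  logW <- log(slices@values)
  S <- colSums(slices@values)
  ll <- as.matrix(crossprod(K, logW))            # K x J: sum_i K_ik log W_ij
  ll <- sweep(ll, 2, S, "-")
  jmax <- max.col(ll, ties.method = "first")
  m <- ll[cbind(seq_len(nFr), jmax)]
  logLik <- sum(m + log(rowSums(exp(ll - m)))) - nFr * log(J)
  if (beta != 1) {
    ll <- ll * beta
    m <- m * beta
  }
  P <- exp(ll - m)
  rs <- rowSums(P)
  P <- P / rs
  new("ProbabilityMatrix", values = t(P), rotations = slices@rotations,
      logLik = logLik)
}

#' Update intensity slices (M step)
#'
#' The likelihood-maximizing update is the probability-weighted mean photon
#' count, \eqn{W'_{ij} = \sum_k P_{jk} K_{ik} / \sum_k P_{jk}}.  Rotations
#' whose total posterior mass falls below \code{cutoff} have no data support;
#' their entries are returned as \code{NA} (undefined) so the caller can
#' decide how to fill them (\code{\link{emcIterate}} inherits the previous
#' iteration's values).
#'
#' @param P a \linkS4class{ProbabilityMatrix}.
#' @param frames the \linkS4class{FrameSet}.
#' @param slices the \linkS4class{SliceSet} of the expansion that produced
#'   \code{P} (supplies the pixel indexing).
#' @param cutoff minimum posterior mass per rotation.
#' @return a \linkS4class{SliceSet} with \code{NA} rows for unsupported
#'   rotations.
#' @export
maximizeSlices <- function(P, frames, slices, cutoff = 1e-9) {
  if (nFrames(frames) == 0L) configError("cannot maximize over an empty frame set")
  if (ncol(P@values) != nFrames(frames)) {
    configError("probability matrix covers %d frames but the set has %d",
                ncol(P@values), nFrames(frames))
  }
  K <- framesOnMap(frames, slices@pixelIndex)
  num <- as.matrix(K %*% t(P@values))            # N x J
  wj <- rowSums(P@values)
  W <- sweep(num, 2, wj, "/")
  W[, wj < cutoff] <- NA_real_
  new("SliceSet", values = W, pixelIndex = slices@pixelIndex,
      rotations = slices@rotations, grid = slices@grid)
}

#' Compress: merge slices back into a 3D intensity
#'
#' Adjoint of the expansion: each defined slice value is distributed onto its
#' 8 surrounding voxels with trilinear weights, and every voxel takes the
#' weighted average of the values it received.  Voxels never visited stay 0
#' and are flagged unobserved.
#'
#' @param slices a \linkS4class{SliceSet} (\code{NA} columns are skipped).
#' @param map the \linkS4class{PixelMap} the slices live on.
#' @param grid target grid (defaults to the map's).
#' @return an \linkS4class{IntensityModel}.
#' @export
compressModel <- function(slices, map, grid = map@grid) {
  ext <- grid@extent
  num <- numeric(prod(ext))
  wt <- numeric(prod(ext))
  for (j in seq_along(map@rotations@angles)) {
    v <- slices@values[, j]
    if (anyNA(v)) next
    .cpp_trilinear_scatter(num, wt, ext, mapCoords(map, map@rotations@angles[j]),
                           v, numeric(0))
  }
  vals <- ifelse(wt > 0, num / wt, 0)
  vals[vals < 0] <- 0
  intensityModel(array(vals, dim = ext), grid,
                 observed = array(wt > 0, dim = ext))
}

#' Run the EMC iteration
#'
#' Repeats expand, E step, M step, compress, starting from a seeded model.
#' Convergence is monitored by the r.m.s. change of the 3D intensity between
#' iterations (relative to the r.m.s. of the current model) and by the total
#' log-likelihood, both recorded in the trace.  Slice entries left undefined
#' by the M step inherit the previous expansion's values, and voxels the map
#' never visits keep their previous model values, so unvisited regions are
#' not deleted.  Before the first iteration the seed is rescaled so its mean
#' slice total matches the data's mean photons per frame (the seed's absolute
#' scale is arbitrary; the M step sets the scale from the data thereafter).
#'
#' The E step uses deterministic annealing: the posterior exponent starts at
#' \code{betaStart} and doubles every \code{betaDouble} iterations until it
#' reaches 1.  Flat early posteriors keep the iteration from locking
#' confidently onto wrong orientations while the seed's random peak heights
#' are still being corrected; once beta reaches 1 the iteration is exact EM.
#' Set \code{betaStart = 1} for plain EM.
#'
#' @param frames a \linkS4class{FrameSet}.
#' @param geom the \linkS4class{DetectorGeometry}.
#' @param rotations the \linkS4class{RotationSet}.
#' @param seedModel starting \linkS4class{IntensityModel}.
#' @param nIter maximum iterations (>= 1).
#' @param tol stop when the relative r.m.s. change drops below this (0 =
#'   always run \code{nIter} iterations).
#' @param floorValue slice floor passed to \code{\link{expandSlices}}.
#' @param checkpoint optional path: the current model is saved there each
#'   iteration (run metadata included) so a run can be resumed.
#' @param rescaleSeed pre-scale the seed to the data's photon budget (turn
#'   off when resuming from a checkpoint, whose model already has the data
#'   scale).
#' @param betaStart,betaDouble annealing schedule (see Details).
#' @param iterationOffset iterations already performed (checkpoint resume):
#'   keeps the annealing schedule aligned with the uninterrupted run.
#' @param verbose print a line per iteration.
#' @return list with \code{model} (the final \linkS4class{IntensityModel}),
#'   \code{trace} (data.frame: iteration, rms, relRms, logLik) and
#'   \code{probabilities} (final \linkS4class{ProbabilityMatrix}).
#' @export
emcIterate <- function(frames, geom, rotations, seedModel, nIter = 30,
                       tol = 0, floorValue = 1e-10, checkpoint = NULL,
                       rescaleSeed = TRUE, betaStart = 0.1, betaDouble = 3,
                       iterationOffset = 0, verbose = FALSE) {
  if (nIter < 1) configError("nIter must be >= 1")
  if (nFrames(frames) == 0L) configError("cannot run EMC on an empty frame set")
  map <- buildPixelMap(geom, rotations, seedModel@grid)
  meanK <- totalPhotons(frames) / nFrames(frames)

  model <- seedModel
  if (rescaleSeed) {
    sl0 <- expandSlices(model, map, floorValue)
    model@values <- model@values * (meanK / mean(colSums(sl0@values)))
  }

  trace <- data.frame(iteration = integer(0), rms = numeric(0),
                      relRms = numeric(0), logLik = numeric(0))
  P <- NULL
  for (it in seq_len(nIter)) {
    beta <- min(1, betaStart * 2^((iterationOffset + it - 1) / betaDouble))
    slices <- expandSlices(model, map, floorValue)
    P <- computeProbabilities(slices, frames, beta = beta)
    upd <- maximizeSlices(P, frames, slices)
    undef <- is.na(upd@values)
    if (any(undef)) upd@values[undef] <- slices@values[undef]
    newModel <- compressModel(upd, map)
    keep <- !newModel@observed
    newModel@values[keep] <- model@values[keep]
    if (any(!is.finite(newModel@values))) {
      numericError("non-finite intensity produced at iteration %d", it)
    }
    d <- newModel@values - model@values
    rms <- sqrt(mean(d^2))
    relRms <- rms / sqrt(mean(newModel@values^2))
    trace <- rbind(trace, data.frame(iteration = it, rms = rms,
                                     relRms = relRms, logLik = P@logLik))
    if (verbose) {
      message(sprintf("EMC iter %2d: rms change %.4g (rel %.4g), logLik %.6g",
                      it, rms, relRms, P@logLik))
    }
    model <- newModel
    if (!is.null(checkpoint)) {
      saveEMCCheckpoint(checkpoint, model, trace)
    }
    if (tol > 0 && relRms < tol) break
  }
  list(model = model, trace = trace, probabilities = P)
}

saveEMCCheckpoint <- function(path, model, trace) {
  obj <- list(values = model@values, observed = model@observed,
              voxelSize = model@grid@voxelSize, extent = model@grid@extent,
              resolutionLimit = model@grid@resolutionLimit, trace = trace)
  saveRDS(obj, path)
  invisible(path)
}

#' Resume state from an EMC checkpoint
#' @param path checkpoint file written by \code{\link{emcIterate}}.
#' @return list with \code{model} and \code{trace}.
#' @export
readEMCCheckpoint <- function(path) {
  obj <- readRDS(path)
  grid <- new("ReciprocalGrid", voxelSize = obj$voxelSize,
              extent = obj$extent, resolutionLimit = obj$resolutionLimit)
  list(model = intensityModel(obj$values, grid,
                              observed = obj$observed),
       trace = obj$trace)
}

#' Two-stage resolution extension
#'
#' Single M step plus compression on a finer (and possibly wider-coverage)
#' grid using the converged orientation probabilities unchanged: all photons
#' up to the fine grid's resolution limit are incorporated without further
#' probability updates.
#'
#' @param P converged \linkS4class{ProbabilityMatrix} from a lower-resolution
#'   run over the same frames and rotations.
#' @param frames the full \linkS4class{FrameSet}.
#' @param geom the \linkS4class{DetectorGeometry}.
#' @param rotations the \linkS4class{RotationSet} (must match \code{P}).
#' @param fineGrid the target \linkS4class{ReciprocalGrid}.
#' @return an \linkS4class{IntensityModel} on \code{fineGrid}.
#' @export
extendResolution <- function(P, frames, geom, rotations, fineGrid) {
  if (ncol(P@values) != nFrames(frames)) {
    configError("probability matrix covers %d frames but the set has %d",
                ncol(P@values), nFrames(frames))
  }
  if (!isTRUE(all.equal(P@rotations@angles, rotations@angles))) {
    configError("rotation sets of the probabilities and the extension differ")
  }
  map <- buildPixelMap(geom, rotations, fineGrid)
  shell <- new("SliceSet",
               values = matrix(0, length(map@pixelIndex),
                               length(rotations@angles)),
               pixelIndex = map@pixelIndex, rotations = rotations,
               grid = fineGrid)
  upd <- maximizeSlices(P, frames, shell)
  undef <- is.na(upd@values)
  if (any(undef)) upd@values[undef] <- 0
  compressModel(upd, map)
}

#' Rescale a model to the recorded photon count
#'
#' Multiplies the model so that its voxel sum equals the total number of
#' recorded photons over all frames; this rescaled model is what the peak
#' integration and the background-fraction estimate operate on.
#'
#' @param model an \linkS4class{IntensityModel} with positive sum.
#' @param frames the \linkS4class{FrameSet} supplying the photon total, or a
#'   number.
#' @return the rescaled \linkS4class{IntensityModel}.
#' @export
rescaleToPhotonCount <- function(model, frames) {
  target <- if (is(frames, "FrameSet")) totalPhotons(frames) else as.numeric(frames)
  s <- sum(model@values)
  if (s <= 0) configError("cannot rescale an all-zero model")
  model@values <- model@values * (target / s)
  model
}
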