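#' @include AllClasses.R
NULL

#' Number of frames in a FrameSet
#' @param x a \linkS4class{FrameSet}.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "FrameSet", function(x) ncol(x@counts))

#' Total recorded photons
#' @param x a \linkS4class{FrameSet}.
#' @return total photon count over all frames.
#' @export
setGeneric("totalPhotons", function(x) standardGeneric("totalPhotons"))

#' @rdname totalPhotons
#' @export
setMethod("totalPhotons", "FrameSet", function(x) sum(x@counts@x))

#' Hidden true rotation angles of simulated frames
#' @param x a \linkS4class{FrameSet}.
#' @return numeric vector of degrees, or length-0 when unknown.
#' @export
setGeneric("trueAngles", function(x) standardGeneric("trueAngles"))

#' @rdname trueAngles
#' @export
setMethod("trueAngles", "FrameSet", function(x) x@trueAngles)

#' Sparse count matrix of a FrameSet
#' @param x a \linkS4class{FrameSet}.
#' @return the (nFast*nSlow) x K \code{dgCMatrix} of photon counts.
#' @export
setGeneric("frameCounts", function(x) standardGeneric("frameCounts"))

#' @rdname frameCounts
#' @export
setMethod("frameCounts", "FrameSet", function(x) x@counts)

#' Voxel values of an IntensityModel
#' @param x an \linkS4class{IntensityModel}.
#' @return the 3D array of voxel intensities.
#' @export
setGeneric("intensityValues", function(x) standardGeneric("intensityValues"))

#' @rdname intensityValues
#' @export
setMethod("intensityValues", "IntensityModel", function(x) x@values)

#' Reciprocal grid of an object
#' @param x an object carrying a \linkS4class{ReciprocalGrid}.
#' @return the grid.
#' @export
setGeneric("modelGrid", function(x) standardGeneric("modelGrid"))

#' @rdname modelGrid
#' @export
setMethod("modelGrid", "IntensityModel", function(x) x@grid)

#' @rdname modelGrid
#' @export
setMethod("modelGrid", "GroundTruth", function(x) x@grid)

#' Rotation angles (degrees)
#' @param x a \linkS4class{RotationSet} or \linkS4class{ProbabilityMatrix}.
#' @return numeric vector of angles in degrees.
#' @export
setGeneric("rotationAngles", function(x) standardGeneric("rotationAngles"))

#' @rdname rotationAngles
#' @export
setMethod("rotationAngles", "RotationSet", function(x) x@angles)

#' @rdname rotationAngles
#' @export
setMethod("rotationAngles", "ProbabilityMatrix", function(x) x@rotations@angles)

#' Probability values of a ProbabilityMatrix
#' @param x a \linkS4class{ProbabilityMatrix}.
#' @return the J x K matrix of orientation probabilities.
#' @export
setGeneric("probValues", function(x) standardGeneric("probValues"))

#' @rdname probValues
#' @export
setMethod("probValues", "ProbabilityMatrix", function(x) x@values)

#' Calibrated true intensity of a GroundTruth
#'
#' @param x a calibrated \linkS4class{GroundTruth}.
#' @return an \linkS4class{IntensityModel} in expected-photons-per-frame units.
#' @export
setGeneric("trueIntensity", function(x) standardGeneric("trueIntensity"))

#' @rdname trueIntensity
#' @export
setMethod("trueIntensity", "GroundTruth", function(x) {
  if (!length(x@intensity)) {
    configError("ground truth is not calibrated; run calibrateGroundTruth() first")
  }
  intensityModel(x@intensity, x@grid)
})

#' Peak table of a GroundTruth
#' @param x a \linkS4class{GroundTruth}.
#' @return data.frame of true peaks (h, k, l, q, intensity, photons, sigma).
#' @export
setGeneric("peakTable", function(x) standardGeneric("peakTable"))

#' @rdname peakTable
#' @export
setMethod("peakTable", "GroundTruth", function(x) x@peakTable)

setMethod("show", "DetectorGeometry", function(object) {
  cat(sprintf("DetectorGeometry: %d x %d px @ %.4g mm pitch, D = %.4g mm, lambda = %.4g A\n",
              object@nFast, object@nSlow, object@pixelPitch, object@distance,
              object@wavelength))
  cat(sprintf("  beam center (%.2f, %.2f) px; %d / %d pixels usable\n",
              object@beamCenter[1], object@beamCenter[2], sum(object@mask),
              length(object@mask)))
})

setMethod("show", "RotationSet", function(object) {
  J <- length(object@angles)
  sp <- if (J > 1) diff(object@angles)[1] else NA_real_
  cat(sprintf("RotationSet: %d rotations, spacing %.4g deg, axis (%.3g, %.3g, %.3g)\n",
              J, sp, object@axis[1], object@axis[2], object@axis[3]))
})

setMethod("show", "ReciprocalGrid", function(object) {
  cat(sprintf("ReciprocalGrid: %d x %d x %d voxels, %.5g 1/A per voxel, d_min %.3g A\n",
              object@extent[1], object@extent[2], object@extent[3],
              object@voxelSize, object@resolutionLimit))
})

setMethod("show", "IntensityModel", function(object) {
  show(object@grid)
  cat(sprintf("IntensityModel: sum %.6g, %.1f%% voxels observed\n",
              sum(object@values), 100 * mean(object@observed)))
})

setMethod("show", "FrameSet", function(object) {
  K <- ncol(object@counts)
  tot <- sum(object@counts@x)
  cat(sprintf("FrameSet: %d frames, %.0f photons (%.3g per frame), true angles %s\n",
              K, tot, if (K) tot / K else 0,
              if (length(object@trueAngles)) "recorded" else "unknown"))
})

setMethod("show", "UnitCell", function(object) {
  cat(sprintf("Tetragonal UnitCell: a = b = %.4g A, c = %.4g A\n", object@a, object@c))
})

setMethod("show", "GroundTruth", function(object) {
  show(object@cell)
  cat(sprintf("GroundTruth: %d Bragg peaks, %s\n", nrow(object@peakTable),
              if (length(object@intensity))
                sprintf("calibrated (%.4g photons/frame, %.0f%% background)",
                        object@meanPhotons, 100 * object@backgroundFraction)
              else "uncalibrated"))
})

setMethod("show", "ProbabilityMatrix", function(object) {
  cat(sprintf("ProbabilityMatrix: %d rotations x %d frames%s\n",
              nrow(object@values), ncol(object@values),
              if (length(object@logLik)) sprintf(", logLik %.6g", object@logLik) else ""))
})

setMethod("show", "SliceSet", function(object) {
  cat(sprintf("SliceSet: %d pixels x %d rotations (%d undefined entries)\n",
              nrow(object@values), ncol(object@values), sum(is.na(object@values))))
})

setMethod("show", "PixelMap", function(object) {
  cat(sprintf("PixelMap: %d mapped pixels x %d rotations (%d out-of-range pixels dropped)\n",
              length(object@pixelIndex), length(object@rotations@angles),
              object@nDropped))
})

setMethod("show", "Segmentation", function(object) {
  cat(sprintf("Segmentation: n = %d window, gamma %s; %d signal voxels (%.2f%%)\n",
              object@window, paste(format(object@gammaSchedule), collapse = " -> "),
              sum(object@labels), 100 * mean(object@labels)))
})
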