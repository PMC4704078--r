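#' @include AllClasses.R emc.R
NULL

#' Assemble the reference intensity from known true orientations
#'
#' Deposits every frame's photons at the reciprocal positions given by its
#' recorded true angle, with trilinear weights and per-voxel normalization by
#' the accumulated weights.  Equivalent to one maximize-plus-compress pass
#' with a one-hot probability matrix at the true angles; used only for
#' validation.
#'
#' @param frames a \linkS4class{FrameSet} whose \code{trueAngles} are set.
#' @param geom the \linkS4class{DetectorGeometry}.
#' @param grid target \linkS4class{ReciprocalGrid}.
#' @param axis rotation-axis direction.
#' @return an \linkS4class{IntensityModel} in expected-photons-per-frame
#'   units.
#' @export
assembleReference <- function(frames, geom, grid, axis = c(0, 1, 0)) {
  if (nFrames(frames) > 0L && !length(frames@trueAngles)) {
    configError("frames carry no true angles; reference assembly impossible")
  }
  npx <- geom@nFast * geom@nSlow
  ext <- grid@extent
  num <- numeric(prod(ext))
  wt <- numeric(prod(ext))
  if (nFrames(frames) > 0L) {
    # single-rotation map just to get the retained pixel set and q vectors
    map <- buildPixelMap(geom, rotationSet(1, axis = axis), grid)
    K <- framesOnMap(frames, map@pixelIndex)
    ang <- wrapAngle(frames@trueAngles)
    groups <- split(seq_len(ncol(K)), ang)
    for (g in names(groups)) {
      idx <- groups[[g]]
      a <- as.numeric(g)
      coords <- gridCoords(grid, map@q0 %*% t(rotationMatrix(axis, -a)))
      meanCounts <- rowSums(K[, idx, drop = FALSE]) / length(idx)
      .cpp_trilinear_scatter(num, wt, ext, coords, meanCounts, numeric(0))
    }
  }
  vals <- ifelse(wt > 0, num / wt, 0)
  intensityModel(array(vals, dim = ext), grid,
                 observed = array(wt > 0, dim = ext))
}

#' Amplitude R factor between two reflection lists
#'
#' \deqn{R = \frac{\sum | |F_{ref}| - s |F_{rec}| |}{\sum |F_{ref}|}} over the
#' common, fully recorded (h, k, l) keys, with amplitudes
#' \eqn{|F| = \sqrt{\max(I, 0)}}.  The global scale s is fitted by least
#' absolute residuals (a weighted median), which makes the metric invariant
#' to an overall intensity scale; set \code{fitScale = FALSE} to fix s = 1
#' for photon-count-normalized inputs.  The denominator uses the reference,
#' so the metric is deliberately not symmetric.
#'
#' @param reference,reconstructed reflection data.frames from
#'   \code{\link{integrateReflections}} (or any frame with h, k, l, I).
#' @param fitScale fit the global scale (default) or fix s = 1.
#' @return the R factor as a fraction, with attributes \code{scale} and
#'   \code{nCommon}.
#' @export
rFactor <- function(reference, reconstructed, fitScale = TRUE) {
  ok <- function(df) !df$partial & is.finite(df$I)
  if (is.null(reference$partial)) reference$partial <- FALSE
  if (is.null(reconstructed$partial)) reconstructed$partial <- FALSE
  a <- reference[ok(reference), c("h", "k", "l", "I")]
  b <- reconstructed[ok(reconstructed), c("h", "k", "l", "I")]
  m <- merge(a, b, by = c("h", "k", "l"), suffixes = c(".ref", ".rec"))
  if (!nrow(m)) configError("no common fully recorded reflections")
  Fref <- sqrt(pmax(m$I.ref, 0))
  Frec <- sqrt(pmax(m$I.rec, 0))
  s <- 1
  if (fitScale) {
    use <- Frec > 0
    if (any(use)) s <- weightedMedian(Fref[use] / Frec[use], Frec[use])
  }
  R <- sum(abs(Fref - s * Frec)) / sum(Fref)
  attr(R, "scale") <- s
  attr(R, "nCommon") <- nrow(m)
  R
}

#' Orientation-assignment errors of the EMC probabilities
#'
#' Takes each frame's most probable rotation (ties break toward the lower
#' angle), then fits the single global angular offset -- and optionally a
#' sense flip -- that the reconstruction gauge leaves undetermined, by
#' maximizing the fraction of frames within the tolerance over all offsets on
#' the rotation grid.  Errors are wrapped to (-180, 180].  A frame counts as
#' correct within 1 degree when its wrapped error is at most
#' \code{max(1, spacing / 2)} degrees, so the metric stays meaningful on
#' rotation grids coarser than 1 degree (at 1/3 degree spacing the bound is
#' exactly 1 degree).
#'
#' @param P a \linkS4class{ProbabilityMatrix}.
#' @param trueAngles true frame angles in degrees (same frames as \code{P}).
#' @param threshold tolerance in degrees; default \code{max(1, spacing/2)}.
#' @param tryFlip also consider the reversed rotation sense.
#' @return list (class \code{"OrientationReport"}) with \code{perFrame}
#'   (assigned, true, error after gauge alignment), \code{offset} (degrees),
#'   \code{flipped}, \code{fractionWithin}, \code{threshold} and
#'   \code{histogram} (data.frame of binned wrapped errors).
#' @export
orientationErrors <- function(P, trueAngles, threshold = NULL,
                              tryFlip = FALSE) {
  angles <- P@rotations@angles
  if (ncol(P@values) != length(trueAngles)) {
    configError("probabilities cover %d frames but %d true angles were given",
                ncol(P@values), length(trueAngles))
  }
  spacing <- if (length(angles) > 1) diff(angles)[1] else 360
  if (is.null(threshold)) threshold <- max(1, spacing / 2)
  jhat <- apply(P@values, 2, which.max)   # first max = lower angle on ties
  assigned <- angles[jhat]
  evalSense <- function(sign) {
    err0 <- wrapAngle(sign * assigned - trueAngles, centered = TRUE)
    frac <- vapply(angles, function(off) {
      mean(abs(wrapAngle(err0 - off, centered = TRUE)) <= threshold + 1e-9)
    }, numeric(1))
    best <- which.max(frac)
    list(offset = angles[best], frac = frac[best],
         err = wrapAngle(err0 - angles[best], centered = TRUE))
  }
  res <- evalSense(1)
  flipped <- FALSE
  if (tryFlip) {
    resF <- evalSense(-1)
    if (resF$frac > res$frac) { res <- resF; flipped <- TRUE }
  }
  br <- seq(-180, 180, by = max(spacing, 1))
  hist <- data.frame(lower = head(br, -1), upper = br[-1],
                     count = as.integer(table(cut(res$err, br,
                                                  include.lowest = TRUE))))
  structure(list(
    perFrame = data.frame(assigned = assigned, true = trueAngles,
                          error = res$err),
    offset = res$offset, flipped = flipped, fractionWithin = res$frac,
    threshold = threshold, histogram = hist
  ), class = "OrientationReport")
}

#' Compact display of an orientation-error report
#' @param x an \code{OrientationReport} from \code{\link{orientationErrors}}.
#' @param ... unused.
#' @return \code{x}, invisibly.
#' @method print OrientationReport
#' @export
print.OrientationReport <- function(x, ...) {
  cat(sprintf("OrientationReport: %.2f%% of %d frames within %.3g deg (gauge offset %.3g deg%s)\n",
              100 * x$fractionWithin, nrow(x$perFrame), x$threshold, x$offset,
              if (x$flipped) ", sense flipped" else ""))
  invisible(x)
}

#' Check space-group reflection conditions
#'
#' For each axis-class rule, compares the mean integrated intensity of the
#' allowed and forbidden reflections of that class; absences recovered by the
#' reconstruction show a forbidden/allowed ratio near zero.  Negative
#' intensities are clipped at zero for the ratio.
#'
#' @param reflections a reflection data.frame (partials excluded
#'   automatically).
#' @param rules list of rules as in \code{\link{defaultReflectionRules}}.
#' @param ratioThreshold pass when forbidden mean < this fraction of allowed
#'   mean.
#' @return data.frame with per-rule class means, ratio, testable flag and
#'   pass flag (\code{NA} when a class is empty, i.e. not testable).
#' @export
checkReflectionConditions <- function(reflections,
                                      rules = defaultReflectionRules(),
                                      ratioThreshold = 0.05) {
  r <- reflections[!reflections$partial & is.finite(reflections$I), ]
  out <- lapply(rules, function(rule) {
    sel <- rule$select(r$h, r$k, r$l)
    allow <- rule$allowed(r$h, r$k, r$l)
    ia <- pmax(r$I[sel & allow], 0)
    if_ <- pmax(r$I[sel & !allow], 0)
    testable <- length(ia) > 0 && length(if_) > 0
    ratio <- if (testable && mean(ia) > 0) mean(if_) / mean(ia) else NA_real_
    data.frame(rule = rule$name, nAllowed = length(ia),
               nForbidden = length(if_),
               meanAllowed = if (length(ia)) mean(ia) else NA_real_,
               meanForbidden = if (length(if_)) mean(if_) else NA_real_,
               ratio = ratio, testable = testable,
               pass = if (testable) ratio < ratioThreshold else NA)
  })
  do.call(rbind, out)
}

#' Background-photon fraction of a reconstruction
#'
#' With the model rescaled so that its voxel sum equals the total recorded
#' photons, the share of counts attributed to diffuse background is the sum
#' of the model over background-labeled voxels divided by the total sum.
#'
#' @param model rescaled \linkS4class{IntensityModel} (sum within 1 percent
#'   of \code{totalPhotons}, else a consistency error).
#' @param segmentation a \linkS4class{Segmentation} of \code{model}.
#' @param totalPhotons total recorded photons (number or
#'   \linkS4class{FrameSet}).
#' @return fraction in [0, 1].
#' @export
backgroundFraction <- function(model, segmentation, totalPhotons) {
  if (is(totalPhotons, "FrameSet")) totalPhotons <- sum(totalPhotons@counts@x)
  s <- sum(model@values)
  if (abs(s - totalPhotons) > 0.01 * totalPhotons) {
    dataError("model sum %.6g differs from total photons %.6g by more than 1%%; rescale first",
              s, totalPhotons)
  }
  sum(model@values[!segmentation@labels]) / s
}

#' Integrate two maps with literally identical per-reflection ellipsoids
#'
#' Reference-vs-reconstruction comparisons must not let the per-peak window
#' choice differ between the two maps, or window truncation differences
#' masquerade as intensity differences.  Each map is first integrated with
#' its own adaptive window choice; every common reflection is then
#' re-integrated in both maps with the larger of the two chosen fractions,
#' raised one further schedule step (integration windows are deliberately
#' larger than the segmented cores, so that sub-voxel peak-shape differences
#' between the maps fall inside the window rather than across its boundary).
#'
#' @param modelA,modelB the two \linkS4class{IntensityModel}s (same grid).
#' @param cell refined \linkS4class{UnitCell}.
#' @param orientation crystal orientation matrix.
#' @param windowFractions candidate ellipsoid fractions.
#' @param segmentationA,segmentationB per-map segmentations.
#' @param ... further arguments passed to \code{\link{integrateReflections}}.
#' @return list with elements \code{a} and \code{b}, the two reflection
#'   data.frames on identical windows.
#' @export
integrateConsistently <- function(modelA, modelB, cell, orientation = diag(3),
                                  windowFractions = c(0.10, 0.25, 0.50),
                                  segmentationA = NULL, segmentationB = NULL,
                                  ...) {
  ra <- integrateReflections(modelA, cell, orientation, windowFractions,
                             segmentation = segmentationA, ...)
  rb <- integrateReflections(modelB, cell, orientation, windowFractions,
                             segmentation = segmentationB, ...)
  fr <- merge(ra[, c("h", "k", "l", "fraction")],
              rb[, c("h", "k", "l", "fraction")], by = c("h", "k", "l"))
  fr$fraction <- pmax(fr$fraction.x, fr$fraction.y)
  wf <- sort(windowFractions)
  bump <- function(f) wf[pmin(match(f, wf) + 1L, length(wf))]
  fr$fraction <- vapply(fr$fraction, bump, numeric(1))
  fr <- fr[, c("h", "k", "l", "fraction")]
  list(a = integrateReflections(modelA, cell, orientation, windowFractions,
                                segmentation = segmentationA, fractions = fr,
                                ...),
       b = integrateReflections(modelB, cell, orientation, windowFractions,
                                segmentation = segmentationB, fractions = fr,
                                ...))
}
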