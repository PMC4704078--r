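#' @include AllClasses.R
NULL

#' Map detector pixels to reciprocal space (Ewald construction)
#'
#' For a pixel at position r on the detector, with unit scattering direction
#' \eqn{\hat s = r / |r|} and beam direction \eqn{\hat z}, the scattering
#' vector is \eqn{q = (\hat s - \hat z) / \lambda}, so \eqn{|q| = 2
#' \sin\theta / \lambda} and every q lies on the Ewald sphere of radius
#' \eqn{1/\lambda} centered at \eqn{-\hat z / \lambda}.
#'
#' @param geom a \linkS4class{DetectorGeometry}.
#' @param pixel matrix (or length-2 vector) of (fast, slow) pixel indices,
#'   1-based, pixel centers at integer indices.
#' @return N x 3 matrix of q vectors in 1/Angstrom (lab frame: x = fast,
#'   y = slow = rotation axis, z = beam).
#' @examples
#' geom <- detectorGeometry(64, 64, 0.1, 33, 1.54, c(32.5, 32.5))
#' q <- pixelToQ(geom, c(50, 40))
#' 1 / sqrt(sum(q^2))      # resolution d = 1/|q| in Angstrom
#' @export
pixelToQ <- function(geom, pixel) {
  if (is.null(dim(pixel))) pixel <- matrix(pixel, ncol = 2)
  if (any(pixel[, 1] < 1 | pixel[, 1] > geom@nFast |
          pixel[, 2] < 1 | pixel[, 2] > geom@nSlow)) {
    dataError("pixel index outside the %d x %d detector", geom@nFast, geom@nSlow)
  }
  x <- (pixel[, 1] - geom@beamCenter[1]) * geom@pixelPitch
  y <- (pixel[, 2] - geom@beamCenter[2]) * geom@pixelPitch
  z <- geom@distance
  nrm <- sqrt(x^2 + y^2 + z^2)
  cbind(x / nrm, y / nrm, z / nrm - 1) / geom@wavelength
}

#' Rotate vectors about an axis
#'
#' Rodrigues rotation of one or more 3-vectors; preserves the norm and the
#' component along the axis.
#'
#' @param q 3-vector or N x 3 matrix.
#' @param axis rotation axis (normalized internally; zero axis is an error).
#' @param angle angle in degrees (right-hand rule).
#' @return rotated vector(s), same shape as \code{q}.
#' @export
rotateAboutAxis <- function(q, axis, angle) {
  R <- rotationMatrix(axis, angle)
  if (is.null(dim(q))) as.numeric(R %*% q) else q %*% t(R)
}

#' Precompute the pixel-to-grid mapping for all rotations
#'
#' Retains usable (unmasked) pixels whose scattering vectors stay strictly
#' inside both the resolution sphere and the grid interior for every rotation
#' (rotation about the axis preserves \code{|q|}, so the test is rotation
#' independent).  Dropped pixels are counted and reported in a message.
#'
#' @param geom a \linkS4class{DetectorGeometry}.
#' @param rotations a \linkS4class{RotationSet}.
#' @param grid a \linkS4class{ReciprocalGrid}.
#' @return a \linkS4class{PixelMap}.
#' @export
buildPixelMap <- function(geom, rotations, grid) {
  idx <- which(geom@mask)
  fast <- ((idx - 1L) %% geom@nFast) + 1L
  slow <- ((idx - 1L) %/% geom@nFast) + 1L
  q <- pixelToQ(geom, cbind(fast, slow))
  qn <- sqrt(rowSums(q^2))
  # interior margin of one voxel so that the full trilinear support exists
  qlim <- min(1 / grid@resolutionLimit,
              (min(grid@extent - 1) / 2 - 1) * grid@voxelSize)
  keep <- qn <= qlim
  nDropped <- sum(!keep)
  if (nDropped > 0) {
    message(sprintf("buildPixelMap: dropped %d of %d usable pixels beyond |q| = %.5g 1/A",
                    nDropped, length(idx), qlim))
  }
  new("PixelMap", pixelIndex = as.integer(idx[keep]),
      q0 = q[keep, , drop = FALSE], rotations = rotations, grid = grid,
      nDropped = as.integer(nDropped))
}

#' Fractional voxel coordinates of mapped pixels at one rotation
#'
#' A crystal rotated by angle \eqn{\alpha} about the axis presents, at lab
#' scattering vector q, the model value at \eqn{R(-\alpha) q}; the returned
#' coordinates are those rotated vectors in 1-based fractional voxel units.
#'
#' @param map a \linkS4class{PixelMap}.
#' @param angle rotation angle in degrees (any real; normalized mod 360).
#' @return N x 3 matrix of fractional voxel coordinates.
#' @export
mapCoords <- function(map, angle) {
  R <- rotationMatrix(map@rotations@axis, -angle)
  gridCoords(map@grid, map@q0 %*% t(R))
}
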