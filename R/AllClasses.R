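#' @include utils.R
NULL

#' DetectorGeometry: flat pixel detector in the rotation-method lab frame
#'
#' Coordinate convention (documented once, used everywhere): right-handed lab
#' frame with the beam along +z, the rotation axis along +y and the detector
#' plane normal to z at \code{distance} mm downstream of the sample.  Pixel
#' centers sit at integer (fast, slow) indices starting at 1; \code{beamCenter}
#' is expressed in the same pixel units and may lie outside the active area
#' (e.g. in one corner, as when chasing the highest corner resolution).
#'
#' @slot nFast,nSlow integer pixel counts along the fast (x) and slow (y) axes.
#' @slot pixelPitch pixel pitch in mm.
#' @slot distance sample-detector distance in mm.
#' @slot wavelength X-ray wavelength in Angstrom.
#' @slot beamCenter numeric length-2, (fast, slow) beam center in pixel units.
#' @slot mask logical \code{nFast x nSlow} matrix, \code{TRUE} = usable pixel
#'   (bad pixels, gaps and the beamstop shadow are \code{FALSE}).
#' @export
setClass("DetectorGeometry",
  representation(nFast = "integer", nSlow = "integer", pixelPitch = "numeric",
                 distance = "numeric", wavelength = "numeric",
                 beamCenter = "numeric", mask = "matrix"),
  validity = function(object) {
    msg <- character()
    if (object@nFast < 1L || object@nSlow < 1L) msg <- c(msg, "pixel counts must be >= 1")
    if (!(object@pixelPitch > 0)) msg <- c(msg, "pixelPitch must be > 0")
    if (!(object@distance > 0)) msg <- c(msg, "distance must be > 0")
    if (!(object@wavelength > 0)) msg <- c(msg, "wavelength must be > 0")
    if (length(object@beamCenter) != 2L) msg <- c(msg, "beamCenter must have length 2")
    if (!identical(dim(object@mask), c(as.integer(object@nFast), as.integer(object@nSlow))))
      msg <- c(msg, "mask must be an nFast x nSlow logical matrix")
    if (length(msg)) msg else TRUE
  })

#' Construct a DetectorGeometry
#'
#' @param nFast,nSlow pixel counts.
#' @param pixelPitch pixel pitch (mm).
#' @param distance sample-detector distance (mm).
#' @param wavelength wavelength (Angstrom).
#' @param beamCenter length-2 beam center in pixel units (may be fractional or
#'   outside the active area).
#' @param mask optional logical matrix (\code{TRUE} = usable); default all
#'   usable.
#' @param beamstopRadius optional radius in pixels: pixels within this radius
#'   of the beam center are masked out (a simple circular beamstop shadow).
#' @return a \linkS4class{DetectorGeometry}.
#' @examples
#' geom <- detectorGeometry(64, 64, pixelPitch = 0.1, distance = 33,
#'                          wavelength = 1.54, beamCenter = c(32.5, 32.5))
#' @export
detectorGeometry <- function(nFast, nSlow, pixelPitch, distance, wavelength,
                             beamCenter, mask = NULL, beamstopRadius = 0) {
  nFast <- as.integer(nFast); nSlow <- as.integer(nSlow)
  if (is.null(mask)) mask <- matrix(TRUE, nFast, nSlow)
  if (beamstopRadius > 0) {
    fx <- seq_len(nFast) - beamCenter[1]
    sy <- seq_len(nSlow) - beamCenter[2]
    r2 <- outer(fx^2, sy^2, "+")
    mask <- mask & (r2 > beamstopRadius^2)
  }
  new("DetectorGeometry", nFast = nFast, nSlow = nSlow,
      pixelPitch = as.numeric(pixelPitch), distance = as.numeric(distance),
      wavelength = as.numeric(wavelength), beamCenter = as.numeric(beamCenter),
      mask = mask)
}

#' RotationSet: uniformly spaced one-dimensional rotations about a fixed axis
#'
#' The sampled orientation group is the set of rotations about a single axis
#' perpendicular to the beam (the goniometer axis), uniformly spaced on
#' \code{[0, 360)} degrees.
#'
#' @slot axis unit 3-vector of the rotation axis (lab frame).
#' @slot angles strictly increasing, uniformly spaced angles in degrees.
#' @export
setClass("RotationSet",
  representation(axis = "numeric", angles = "numeric"),
  validity = function(object) {
    msg <- character()
    if (abs(sqrt(sum(object@axis^2)) - 1) > 1e-8) msg <- c(msg, "axis must be a unit vector")
    a <- object@angles
    if (length(a) < 1L) msg <- c(msg, "at least one angle required")
    if (length(a) > 1L) {
      d <- diff(a)
      if (any(d <= 0)) msg <- c(msg, "angles must be strictly increasing")
      if (max(d) - min(d) > 1e-8) msg <- c(msg, "angle spacing must be uniform")
    }
    if (any(a < 0 | a >= 360)) msg <- c(msg, "angles must lie in [0, 360)")
    if (length(msg)) msg else TRUE
  })

#' Construct a RotationSet
#'
#' @param count number of uniformly spaced rotations on \code{[0, 360)};
#'   ignored when \code{angles} is given.
#' @param axis rotation-axis direction (normalized internally); default +y.
#' @param angles explicit angles (degrees), must be uniformly spaced.
#' @param beam beam direction used for the perpendicularity check.
#' @param axisTolerance maximum allowed deviation (degrees) of the axis from
#'   perpendicular to the beam.
#' @return a \linkS4class{RotationSet}.
#' @examples
#' rot <- rotationSet(360)   # 1 degree spacing
#' @export
rotationSet <- function(count = NULL, axis = c(0, 1, 0), angles = NULL,
                        beam = c(0, 0, 1), axisTolerance = 1e-6) {
  axis <- axis / sqrt(sum(axis^2))
  ang <- 90 - acos(abs(sum(axis * beam) / sqrt(sum(beam^2)))) * 180 / pi
  if (abs(ang) > axisTolerance) {
    configError("rotation axis deviates from perpendicular to the beam by %.3g deg", ang)
  }
  if (is.null(angles)) {
    if (is.null(count) || count < 1) configError("rotation count must be >= 1")
    angles <- seq(0, 360, length.out = count + 1)[seq_len(count)]
  }
  new("RotationSet", axis = axis, angles = as.numeric(angles))
}

#' ReciprocalGrid: cubic voxel grid over reciprocal space, centered on q = 0
#'
#' Voxels are cubes of side \code{voxelSize} (inverse Angstrom); the extent is
#' odd along each axis so that the central voxel sits exactly at the origin.
#' Voxel \code{i} (1-based) maps to \eqn{q = (i - c) \cdot v} with
#' \code{c = (extent + 1) / 2}.
#'
#' @slot voxelSize voxel edge, 1/Angstrom.
#' @slot extent integer length-3 voxel counts (odd).
#' @slot resolutionLimit high-resolution cutoff d_min in Angstrom.
#' @export
setClass("ReciprocalGrid",
  representation(voxelSize = "numeric", extent = "integer",
                 resolutionLimit = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!(object@voxelSize > 0)) msg <- c(msg, "voxelSize must be > 0")
    if (length(object@extent) != 3L || any(object@extent %% 2L == 0L))
      msg <- c(msg, "extent must be three odd voxel counts")
    if (!(object@resolutionLimit > 0)) msg <- c(msg, "resolutionLimit must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a ReciprocalGrid
#'
#' The conventional voxel size is a stated fraction of the reciprocal cell
#' constant a* (e.g. a*/7 coarse, a*/9 fine); pass it directly via
#' \code{voxelSize} or as \code{aStar / divisor}.
#'
#' @param voxelSize voxel edge (1/Angstrom); if missing, computed as
#'   \code{aStar / divisor}.
#' @param resolutionLimit d_min in Angstrom.
#' @param extent odd voxel count (scalar or length 3); if \code{NULL}, the
#'   smallest odd extent whose interior ball reaches \code{1/resolutionLimit}.
#' @param aStar,divisor alternative voxel-size specification.
#' @return a \linkS4class{ReciprocalGrid}.
#' @examples
#' g <- reciprocalGrid(aStar = 1 / 77, divisor = 7, resolutionLimit = 11.5)
#' @export
reciprocalGrid <- function(voxelSize = NULL, resolutionLimit, extent = NULL,
                           aStar = NULL, divisor = NULL) {
  if (is.null(voxelSize)) {
    if (is.null(aStar) || is.null(divisor))
      configError("give either voxelSize or aStar and divisor")
    voxelSize <- aStar / divisor
  }
  if (is.null(extent)) {
    half <- ceiling(1 / resolutionLimit / voxelSize) + 1L
    extent <- 2L * as.integer(half) + 1L
  }
  extent <- as.integer(rep(extent, length.out = 3L))
  new("ReciprocalGrid", voxelSize = as.numeric(voxelSize), extent = extent,
      resolutionLimit = as.numeric(resolutionLimit))
}

# q vector (rows) -> fractional 1-based voxel coordinates, and back.
gridCoords <- function(grid, q) {
  ctr <- (grid@extent[1] + 1) / 2
  q / grid@voxelSize + ctr
}
gridQ <- function(grid, coords) {
  ctr <- (grid@extent[1] + 1) / 2
  (coords - ctr) * grid@voxelSize
}

#' IntensityModel: 3D voxel model of mean diffracted intensity W(q)
#'
#' Values are expected photon counts per frame-equivalent observation, on a
#' \linkS4class{ReciprocalGrid}.  The \code{observed} array flags voxels that
#' received at least some interpolation weight during compression (voxels
#' never crossed by the rotating Ewald sphere stay 0 and unobserved).
#'
#' @slot values nonnegative 3D array.
#' @slot grid the \linkS4class{ReciprocalGrid}.
#' @slot observed logical array of the same shape (all-\code{TRUE} when not
#'   tracked).
#' @export
setClass("IntensityModel",
  representation(values = "array", grid = "ReciprocalGrid", observed = "array"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@values), as.integer(object@grid@extent)))
      msg <- c(msg, "values must match grid extent")
    if (any(!is.finite(object@values))) msg <- c(msg, "values must be finite")
    if (any(object@values < 0)) msg <- c(msg, "values must be nonnegative")
    if (!identical(dim(object@observed), dim(object@values)))
      msg <- c(msg, "observed must match values shape")
    if (length(msg)) msg else TRUE
  })

#' Construct an IntensityModel
#'
#' @param values 3D array matching \code{grid@extent} (default all zero).
#' @param grid a \linkS4class{ReciprocalGrid}.
#' @param observed optional logical array (default all \code{TRUE}).
#' @return an \linkS4class{IntensityModel}.
#' @export
intensityModel <- function(values = NULL, grid, observed = NULL) {
  if (is.null(values)) values <- array(0, dim = grid@extent)
  if (is.null(observed)) observed <- array(TRUE, dim = dim(values))
  new("IntensityModel", values = values, grid = grid, observed = observed)
}

#' FrameSet: sparse photon counts for many frames
#'
#' Per-frame photon lists stored column-wise in a sparse matrix whose rows are
#' linear detector pixel indices (fast-major: \code{fast + (slow-1) * nFast})
#' and whose columns are frames.  Simulated sets carry the hidden true
#' rotation angle of every frame for validation; experimental sets would not.
#'
#' @slot counts \code{dgCMatrix}, (nFast*nSlow) x K, nonnegative integers.
#' @slot trueAngles numeric length K (degrees) or length 0 when unknown.
#' @slot geometry the \linkS4class{DetectorGeometry} the pixels refer to.
#' @export
setClass("FrameSet",
  representation(counts = "dgCMatrix", trueAngles = "numeric",
                 geometry = "DetectorGeometry"),
  validity = function(object) {
    msg <- character()
    npx <- object@geometry@nFast * object@geometry@nSlow
    if (nrow(object@counts) != npx)
      msg <- c(msg, "counts must have nFast*nSlow rows")
    if (length(object@trueAngles) &&
        length(object@trueAngles) != ncol(object@counts))
      msg <- c(msg, "trueAngles must be empty or one per frame")
    x <- object@counts@x
    if (length(x) && (any(x < 0) || any(x != round(x))))
      msg <- c(msg, "photon counts must be nonnegative integers")
    if (length(msg)) msg else TRUE
  })

#' UnitCell: tetragonal unit cell
#'
#' Tetragonal metric (a = b, 90 degree angles); reciprocal constants are
#' \code{aStar = 1/a}, \code{cStar = 1/c}.
#'
#' @slot a,c direct cell lengths in Angstrom.
#' @export
setClass("UnitCell",
  representation(a = "numeric", c = "numeric"),
  validity = function(object) {
    if (!(object@a > 0) || !(object@c > 0)) "cell lengths must be > 0" else TRUE
  })

#' Construct a tetragonal UnitCell
#' @param a,c cell edges in Angstrom (a = b).
#' @return a \linkS4class{UnitCell}.
#' @examples
#' cell <- unitCell(77, 36)
#' @export
unitCell <- function(a, c) new("UnitCell", a = as.numeric(a), c = as.numeric(c))

#' @describeIn unitCell reciprocal constant a* = 1/a (1/Angstrom).
#' @param cell a \linkS4class{UnitCell}.
#' @export
aStar <- function(cell) 1 / cell@a

#' @describeIn unitCell reciprocal constant c* = 1/c (1/Angstrom).
#' @export
cStar <- function(cell) 1 / cell@c

#' GroundTruth: simulator ground truth (known intensity, cell, orientation)
#'
#' Holds the Bragg-peak component and the smooth diffuse-background component
#' of the true intensity separately (unit scale), plus, after
#' \code{\link{calibrateGroundTruth}}, the combined intensity in
#' expected-photons-per-frame units and the realized photon budget.
#'
#' @slot cell true \linkS4class{UnitCell}.
#' @slot orientation 3x3 rotation matrix: crystal axes in the lab frame at
#'   rotation angle 0 (lattice axes are deliberately not aligned to the grid).
#' @slot peakTable data.frame with columns h, k, l, qx, qy, qz, intensity
#'   (unit scale), photons (per frame, after calibration) and sigma (voxels).
#' @slot peaks,background 3D arrays on \code{grid}: unit-scale components.
#' @slot grid the \linkS4class{ReciprocalGrid}.
#' @slot intensity calibrated combined array (length 0 until calibrated).
#' @slot meanPhotons,backgroundFraction calibration targets (length 0 until
#'   calibrated).
#' @slot peakScale,backgroundScale calibration factors applied to the unit
#'   components.
#' @export
setClass("GroundTruth",
  representation(cell = "UnitCell", orientation = "matrix",
                 peakTable = "data.frame", peaks = "array",
                 background = "array", grid = "ReciprocalGrid",
                 intensity = "array", meanPhotons = "numeric",
                 backgroundFraction = "numeric",
                 peakScale = "numeric", backgroundScale = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@peaks), as.integer(object@grid@extent)))
      msg <- c(msg, "peaks array must match grid extent")
    if (!identical(dim(object@background), dim(object@peaks)))
      msg <- c(msg, "background array must match peaks array")
    if (length(msg)) msg else TRUE
  })

#' SliceSet: expected photon counts per (pixel, rotation)
#'
#' The expansion of an \linkS4class{IntensityModel} onto the Ewald-sphere
#' pixel positions of every sampled rotation: \code{values[i, j]} is the mean
#' photon count at mapped pixel i when the crystal sits at rotation j.
#' Undefined entries (rotations with vanishing posterior mass in an M step)
#' are \code{NA}.
#'
#' @slot values numeric N x J matrix (N mapped pixels, J rotations).
#' @slot pixelIndex linear detector index of each row.
#' @slot rotations the \linkS4class{RotationSet}.
#' @slot grid the grid the slices were sampled from.
#' @export
setClass("SliceSet",
  representation(values = "matrix", pixelIndex = "integer",
                 rotations = "RotationSet", grid = "ReciprocalGrid"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@values) != length(object@pixelIndex))
      msg <- c(msg, "one pixelIndex per row required")
    if (ncol(object@values) != length(object@rotations@angles))
      msg <- c(msg, "one column per rotation required")
    if (any(object@values < 0, na.rm = TRUE)) msg <- c(msg, "values must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' ProbabilityMatrix: conditional orientation probabilities P[j, k]
#'
#' Column k holds the posterior probability, given the current intensity
#' model, that frame k was recorded at each sampled rotation j; every column
#' sums to 1.
#'
#' @slot values J x K matrix.
#' @slot rotations the \linkS4class{RotationSet} indexing the rows.
#' @slot logLik total data log-likelihood (up to the K!-type constant) of the
#'   model the probabilities were computed from.
#' @export
setClass("ProbabilityMatrix",
  representation(values = "matrix", rotations = "RotationSet",
                 logLik = "numeric"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@values) != length(object@rotations@angles))
      msg <- c(msg, "one row per rotation required")
    if (any(object@values < 0)) msg <- c(msg, "probabilities must be >= 0")
    cs <- colSums(object@values)
    if (length(cs) && max(abs(cs - 1)) > 1e-9)
      msg <- c(msg, "columns must sum to 1 (1e-9)")
    if (length(msg)) msg else TRUE
  })

#' PixelMap: precomputed pixel -> reciprocal-grid mapping
#'
#' For each usable, in-range detector pixel, the scattering vector at rotation
#' angle 0; per-rotation fractional voxel coordinates are generated on demand
#' by rotating these vectors (see \code{\link{mapCoords}}).  Pixels falling
#' outside the resolution limit or the grid interior are dropped (counted in
#' \code{nDropped}).
#'
#' @slot pixelIndex linear detector indices of retained pixels.
#' @slot q0 N x 3 matrix of scattering vectors at angle 0 (1/Angstrom).
#' @slot rotations,grid the rotation samples and target grid.
#' @slot nDropped number of usable pixels dropped as out of range.
#' @export
setClass("PixelMap",
  representation(pixelIndex = "integer", q0 = "matrix",
                 rotations = "RotationSet", grid = "ReciprocalGrid",
                 nDropped = "integer"))

#' Segmentation: signal/background voxel classification
#'
#' @slot labels logical array, \code{TRUE} = signal (Bragg) voxel.
#' @slot window odd cube edge n of the local-statistics window.
#' @slot gammaSchedule the non-decreasing z-score thresholds, one per pass.
#' @export
setClass("Segmentation",
  representation(labels = "array", window = "integer",
                 gammaSchedule = "numeric"),
  validity = function(object) {
    if (any(diff(object@gammaSchedule) < 0)) "gamma schedule must be non-decreasing" else TRUE
  })
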