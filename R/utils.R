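# Internal helpers: error conditions, angle arithmetic, rotation matrices.

semcError <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "semc_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

configError  <- function(msg, ...) semcError("semc_config_error", msg, ...)
dataError    <- function(msg, ...) semcError("semc_data_error", msg, ...)
numericError <- function(msg, ...) semcError("semc_numeric_error", msg, ...)

#' Wrap angles into a half-open interval
#'
#' @param x angles in degrees.
#' @param centered if \code{TRUE} wrap into \code{(-180, 180]}, otherwise into
#'   \code{[0, 360)}.
#' @return wrapped angles, degrees.
#' @keywords internal
wrapAngle <- function(x, centered = FALSE) {
  y <- x %% 360
  if (centered) {
    y[y > 180] <- y[y > 180] - 360
  }
  y
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues form; rotates vectors by \code{angle} degrees about \code{axis}
#' (right-hand rule).
#'
#' @param axis 3-vector, need not be normalized (zero axis is an error).
#' @param angle rotation angle in degrees.
#' @return 3x3 orthonormal rotation matrix.
#' @export
rotationMatrix <- function(axis, angle) {
  nrm <- sqrt(sum(axis^2))
  if (!is.numeric(axis) || length(axis) != 3L || nrm < 1e-12) {
    configError("rotation axis must be a nonzero 3-vector")
  }
  u <- axis / nrm
  th <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Uniform random rotation matrix (subgroup algorithm via quaternion).
randomRotationMatrix <- function() {
  u <- runif(3)
  q <- c(
    sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3])
  )
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

# Weighted median: minimizes sum(w * |x - m|).
weightedMedian <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

# Encode integer (h,k,l) triplets as a single integer key (|index| < 500).
hklKey <- function(h, k, l) {
  (h + 500) + 1001 * ((k + 500) + 1001 * (l + 500))
}

keyToHkl <- function(key) {
  h <- key %% 1001 - 500
  key <- key %/% 1001
  k <- key %% 1001 - 500
  l <- key %/% 1001 - 500
  cbind(h = h, k = k, l = l)
}
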