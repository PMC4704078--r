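#' @include AllClasses.R
NULL

FRAME_MAGIC <- "SEMCFRM"
FRAME_VERSION <- 1L

#' Write a FrameSet container
#'
#' One little-endian binary container per dataset (millions of tiny frames
#' make per-frame files infeasible).  Layout, all little-endian: 7-byte magic
#' \code{"SEMCFRM"}, int32 version, the geometry block (int32 nFast, nSlow;
#' float64 pixelPitch, distance, wavelength, beamCenter[2]), the mask as
#' int8, int32 K (frames), int32 hasAngles, float64 angles[K] (if present),
#' int32 nnz, then column pointers (int32, K+1), row indices (int32, 1-based
#' pixel ids) and counts (int32).  Writing the same set twice produces
#' identical bytes.
#'
#' @param frames a \linkS4class{FrameSet}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFrameSet <- function(frames, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  g <- frames@geometry
  writeChar(FRAME_MAGIC, con, nchars = 7, eos = NULL)
  writeBin(FRAME_VERSION, con, size = 4, endian = "little")
  writeBin(c(g@nFast, g@nSlow), con, size = 4, endian = "little")
  writeBin(c(g@pixelPitch, g@distance, g@wavelength, g@beamCenter), con,
           size = 8, endian = "little")
  writeBin(as.integer(g@mask), con, size = 1, endian = "little")
  K <- ncol(frames@counts)
  writeBin(as.integer(K), con, size = 4, endian = "little")
  hasAngles <- as.integer(length(frames@trueAngles) > 0)
  writeBin(hasAngles, con, size = 4, endian = "little")
  if (hasAngles) writeBin(frames@trueAngles, con, size = 8, endian = "little")
  m <- frames@counts
  writeBin(length(m@x), con, size = 4, endian = "little")
  writeBin(m@p, con, size = 4, endian = "little")
  writeBin(m@i + 1L, con, size = 4, endian = "little")
  writeBin(as.integer(m@x), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a FrameSet container
#' @param path file written by \code{\link{writeFrameSet}}.
#' @return a \linkS4class{FrameSet}.
#' @export
readFrameSet <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 7, useBytes = TRUE)
  if (!identical(magic, FRAME_MAGIC)) dataError("'%s' is not a frame container (bad magic)", path)
  ver <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(ver, FRAME_VERSION)) dataError("unsupported frame container version %d", ver)
  np <- readBin(con, "integer", 2, size = 4, endian = "little")
  gd <- readBin(con, "numeric", 5, size = 8, endian = "little")
  mask <- matrix(readBin(con, "integer", np[1] * np[2], size = 1,
                         endian = "little") > 0, np[1], np[2])
  geom <- detectorGeometry(np[1], np[2], gd[1], gd[2], gd[3], gd[4:5],
                           mask = mask)
  K <- readBin(con, "integer", 1, size = 4, endian = "little")
  hasAngles <- readBin(con, "integer", 1, size = 4, endian = "little")
  angles <- if (hasAngles) readBin(con, "numeric", K, size = 8,
                                   endian = "little") else numeric(0)
  nnz <- readBin(con, "integer", 1, size = 4, endian = "little")
  p <- readBin(con, "integer", K + 1L, size = 4, endian = "little")
  i <- readBin(con, "integer", nnz, size = 4, endian = "little")
  x <- readBin(con, "integer", nnz, size = 4, endian = "little")
  counts <- new("dgCMatrix", i = i - 1L, p = p, x = as.numeric(x),
                Dim = c(np[1] * np[2], K))
  new("FrameSet", counts = counts, trueAngles = angles, geometry = geom)
}

#' Write an intensity model as an MRC/CCP4 map
#'
#' Standard 1024-byte MRC header, mode 2 (float32), axis order X Y Z with the
#' voxel size recorded through the cell dimensions (extent times voxel size,
#' nominal Angstrom units) so external crystallographic viewers open it.  The
#' map origin is the grid center (q = 0); float32 storage is lossy relative
#' to the in-memory doubles.
#'
#' @param model an \linkS4class{IntensityModel}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeMRC <- function(model, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  ext <- model@grid@extent
  v <- model@grid@voxelSize
  wI <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wF <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wI(ext)                         # NX NY NZ
  wI(2L)                          # MODE 2 = float32
  wI(-(ext - 1L) / 2L)            # NXSTART.. : origin at grid center
  wI(ext)                         # MX MY MZ
  wF(ext * v)                     # CELLA
  wF(c(90, 90, 90))               # CELLB
  wI(1:3)                         # MAPC MAPR MAPS
  wF(c(min(model@values), max(model@values), mean(model@values)))
  wI(c(0L, 0L))                   # ISPG, NSYMBT
  wI(rep(0L, 25))                 # EXTRA
  wF(c(0, 0, 0))                  # ORIGIN
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)   # little-endian stamp
  wF(sd(as.vector(model@values)))
  wI(0L)                          # NLABL
  writeBin(raw(800), con)
  wF(as.vector(model@values))
  invisible(path)
}

#' Read an MRC/CCP4 map written by \code{\link{writeMRC}}
#'
#' @param path map file.
#' @return an \linkS4class{IntensityModel} (observed flags are not stored in
#'   MRC; all voxels are marked observed).
#' @export
readMRC <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ext <- readBin(con, "integer", 3, size = 4, endian = "little")
  mode <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (mode != 2L) dataError("only mode-2 (float32) MRC maps are supported, got %d", mode)
  invisible(readBin(con, "integer", 3, size = 4, endian = "little"))
  mx <- readBin(con, "integer", 3, size = 4, endian = "little")
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  seek(con, 1024)
  vals <- readBin(con, "numeric", prod(ext), size = 4, endian = "little")
  v <- cella[1] / mx[1]
  half <- (min(ext) - 1) / 2
  grid <- new("ReciprocalGrid", voxelSize = v, extent = as.integer(ext),
              resolutionLimit = 1 / ((half - 1) * v))
  vals[vals < 0] <- 0
  intensityModel(array(vals, dim = ext), grid)
}

#' Write reflections as SHELX-style hkl text
#'
#' Fixed-width \code{3I4, 2F8.2} rows (h, k, l, I, sigma(I)); partial
#' reflections are skipped.  Intensities are scaled into the field width if
#' necessary (scale recorded in the first comment-free convention is not part
#' of SHELX; the file carries raw values, so pre-scale if needed).
#'
#' @param reflections reflection data.frame.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeHKL <- function(reflections, path) {
  r <- reflections[!reflections$partial & is.finite(reflections$I), ]
  lines <- sprintf("%4d%4d%4d%8.2f%8.2f", r$h, r$k, r$l, r$I,
                   ifelse(is.finite(r$sigma), r$sigma, 0))
  writeLines(lines, path)
  invisible(path)
}

#' Read a SHELX-style hkl file
#' @param path file written by \code{\link{writeHKL}}.
#' @return data.frame with h, k, l, I, sigma, partial (all \code{FALSE}).
#' @export
readHKL <- function(path) {
  txt <- readLines(path)
  txt <- txt[nzchar(trimws(txt))]
  df <- data.frame(
    h = as.integer(substr(txt, 1, 4)),
    k = as.integer(substr(txt, 5, 8)),
    l = as.integer(substr(txt, 9, 12)),
    I = as.numeric(substr(txt, 13, 20)),
    sigma = as.numeric(substr(txt, 21, 28))
  )
  df$partial <- FALSE
  df
}

PROB_MAGIC <- "SEMCPRB"

#' Write a ProbabilityMatrix container
#'
#' Little-endian binary: magic \code{"SEMCPRB"}, int32 version, int32 J and
#' K, float64 axis[3], float64 angles[J], float64 values (column-major J x K).
#'
#' @param P a \linkS4class{ProbabilityMatrix}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeProbabilityMatrix <- function(P, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(PROB_MAGIC, con, nchars = 7, eos = NULL)
  writeBin(1L, con, size = 4, endian = "little")
  writeBin(c(nrow(P@values), ncol(P@values)), con, size = 4, endian = "little")
  writeBin(P@rotations@axis, con, size = 8, endian = "little")
  writeBin(P@rotations@angles, con, size = 8, endian = "little")
  writeBin(as.vector(P@values), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a ProbabilityMatrix container
#' @param path file written by \code{\link{writeProbabilityMatrix}}.
#' @return a \linkS4class{ProbabilityMatrix}.
#' @export
readProbabilityMatrix <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 7, useBytes = TRUE)
  if (!identical(magic, PROB_MAGIC)) dataError("'%s' is not a probability container", path)
  ver <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (ver != 1L) dataError("unsupported probability container version %d", ver)
  d <- readBin(con, "integer", 2, size = 4, endian = "little")
  axis <- readBin(con, "numeric", 3, size = 8, endian = "little")
  angles <- readBin(con, "numeric", d[1], size = 8, endian = "little")
  vals <- readBin(con, "numeric", d[1] * d[2], size = 8, endian = "little")
  new("ProbabilityMatrix", values = matrix(vals, d[1], d[2]),
      rotations = new("RotationSet", axis = axis, angles = angles),
      logLik = numeric(0))
}
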