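#' @include AllClasses.R
NULL

#' Default run configuration (toy preset)
#'
#' The full-experiment analogues of these parameters are 1080 rotations, 30
#' iterations, an a*/7 coarse and a*/9 fine grid and a 2.0 / 1.3 Angstrom
#' two-stage resolution schedule; the toy preset keeps the same photon
#' statistics (200 photons per frame, 80 percent diffuse background) at sizes
#' a laptop handles in minutes.
#'
#' @return nested named list of configuration values.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    detector = list(
      n_fast = 64L, n_slow = 64L, pixel_pitch_mm = 0.1, distance_mm = 33,
      wavelength_A = 1.54, beam_center_fast = 32.5, beam_center_slow = 32.5,
      beamstop_radius_px = 4
    ),
    cell = list(a_A = 77, c_A = 36),
    rotations = list(count = 180L, axis = c(0, 1, 0)),
    grid = list(divisor = 7, fine_divisor = 9, resolution_A = 11.5),
    emc = list(iterations = 20L, tolerance = 0, extend = FALSE,
               floor = 1e-10, beta_start = 0.1, beta_double = 3),
    segmentation = list(window = 15L, gamma = seq(1, 3, length.out = 4)),
    integration = list(window_fractions = c(0.10, 0.25, 0.50),
                       refine_width = 0.025, refine_steps = 21L,
                       refine_fraction = 0.02),
    simulate = list(n_frames = 2000L, mean_photons = 200,
                    background_fraction = 0.8, peak_sigma_vox = 0.8,
                    mode = "discrete")
  )
}

mergeValidate <- function(user, defaults, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    configError("unknown configuration key%s: %s",
                if (length(unknown) > 1) "s" else "",
                paste0(path, unknown, collapse = ", "))
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- mergeValidate(user[[nm]], defaults[[nm]],
                                      paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Read and validate a run configuration
#'
#' YAML file with the structure of \code{\link{defaultRunConfig}}; missing
#' fields take their defaults, unknown keys are rejected with a clear error,
#' and basic sanity constraints are enforced.
#'
#' @param path YAML file, or a named list to validate directly.
#' @return the effective configuration (defaults filled in).
#' @export
readRunConfig <- function(path) {
  user <- if (is.character(path)) {
    if (!file.exists(path)) configError("config file '%s' does not exist", path)
    yaml::read_yaml(path)
  } else if (is.list(path)) path else {
    configError("config must be a YAML path or a named list")
  }
  cfg <- mergeValidate(user, defaultRunConfig())
  with(cfg, {
    if (detector$pixel_pitch_mm <= 0 || detector$distance_mm <= 0 ||
        detector$wavelength_A <= 0) {
      configError("detector pitch, distance and wavelength must be positive")
    }
    if (cell$a_A <= 0 || cell$c_A <= 0) configError("cell constants must be positive")
    if (rotations$count < 1) configError("rotation count must be >= 1")
    if (emc$iterations < 0) configError("iteration count must be >= 0")
    if (simulate$background_fraction < 0 || simulate$background_fraction > 1) {
      configError("background_fraction must lie in [0, 1]")
    }
  })
  cfg
}

# Materialize the core objects described by a configuration.
configObjects <- function(cfg, fine = FALSE) {
  d <- cfg$detector
  geom <- detectorGeometry(d$n_fast, d$n_slow, d$pixel_pitch_mm,
                           d$distance_mm, d$wavelength_A,
                           c(d$beam_center_fast, d$beam_center_slow),
                           beamstopRadius = d$beamstop_radius_px)
  cell <- unitCell(cfg$cell$a_A, cfg$cell$c_A)
  rot <- rotationSet(cfg$rotations$count, axis = unlist(cfg$rotations$axis))
  div <- if (fine) cfg$grid$fine_divisor else cfg$grid$divisor
  grid <- reciprocalGrid(aStar = aStar(cell), divisor = div,
                         resolutionLimit = cfg$grid$resolution_A)
  list(geom = geom, cell = cell, rotations = rot, grid = grid)
}

#' Write the effective configuration and run metadata to a log file
#'
#' @param cfg effective configuration list.
#' @param path log file path.
#' @param extra named list of extra fields (photon statistics, seeds, ...).
#' @return \code{path}, invisibly.
#' @export
writeRunLog <- function(cfg, path, extra = list()) {
  hdr <- sprintf("# SparseEMC run log — %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  body <- yaml::as.yaml(c(list(config = cfg), extra))
  writeLines(c(hdr, body), path)
  invisible(path)
}
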