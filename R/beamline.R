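# Beam and detector geometry shared by the simulator, sizing and phasing.
#
# Conventions (fixed package-wide):
#  * q = (4*pi/lambda) * sin(theta/2), theta the full scattering angle.
#  * Pixel coordinates are 0-based (row, col) at pixel centers; the assembled
#    frame stacks the two pnCCD panels with the inter-panel gap inserted as
#    absent (NA) rows, never interpolated.
#  * hc = 1239.842 eV nm.

.hc_eV_nm <- 1239.842

#' Photon wavelength from energy
#'
#' @param photon_energy_eV photon energy in eV.
#' @return wavelength in nm.
#' @examples
#' wavelength_from_energy(800) # ~1.55 nm
#' @export
wavelength_from_energy <- function(photon_energy_eV) {
  if (any(!is.finite(photon_energy_eV)) || any(photon_energy_eV <= 0))
    stop("photon energy must be positive")
  .hc_eV_nm / photon_energy_eV
}

#' Effective pulse rate after dumped pulses
#'
#' Accelerators periodically dump pulses (e.g. to monitor dark background);
#' the effective rate delivered to the interaction region is
#' \code{rate * (1 - dumped_fraction)}.
#'
#' @param repetition_rate pulses per second.
#' @param dumped_fraction fraction of pulses dumped, in [0, 1).
#' @return effective pulses per second.
#' @export
effective_pulse_rate <- function(repetition_rate, dumped_fraction) {
  if (any(dumped_fraction < 0) || any(dumped_fraction >= 1))
    stop("dumped_fraction must lie in [0, 1)")
  repetition_rate * (1 - dumped_fraction)
}

#' Beam parameter set
#'
#' @param photon_energy_eV photon energy (eV).
#' @param peak_fluence_mJ_um2 peak fluence in the focus (mJ/um^2).
#' @param pulse_energy_mJ pulse energy (mJ).
#' @param pulse_duration_fs pulse duration (fs).
#' @param repetition_rate_hz machine repetition rate (pulses/s).
#' @param dumped_fraction fraction of dumped pulses, in [0, 1).
#' @return object of class \code{beam_parameters}; the wavelength (nm) is
#'   derived and stored.
#' @export
beam_parameters <- function(photon_energy_eV = 800,
                            peak_fluence_mJ_um2 = 0.02,
                            pulse_energy_mJ = 1.5,
                            pulse_duration_fs = 170,
                            repetition_rate_hz = 120,
                            dumped_fraction = 0.05) {
  if (photon_energy_eV <= 0) stop("photon energy must be positive")
  if (peak_fluence_mJ_um2 < 0) stop("peak fluence must be nonnegative")
  if (dumped_fraction < 0 || dumped_fraction >= 1)
    stop("dumped_fraction must lie in [0, 1)")
  structure(list(
    photon_energy_eV = photon_energy_eV,
    wavelength_nm = wavelength_from_energy(photon_energy_eV),
    peak_fluence_mJ_um2 = peak_fluence_mJ_um2,
    pulse_energy_mJ = pulse_energy_mJ,
    pulse_duration_fs = pulse_duration_fs,
    repetition_rate_hz = repetition_rate_hz,
    dumped_fraction = dumped_fraction
  ), class = "beam_parameters")
}

#' @export
print.beam_parameters <- function(x, ...) {
  cat(sprintf("X-ray beam: %g eV (lambda %.4f nm), peak fluence %g mJ/um^2\n",
              x$photon_energy_eV, x$wavelength_nm, x$peak_fluence_mJ_um2))
  cat(sprintf("  %g fs pulses at %g Hz (%.0f Hz effective after %g%% dumped)\n",
              x$pulse_duration_fs, x$repetition_rate_hz,
              effective_pulse_rate(x$repetition_rate_hz, x$dumped_fraction),
              100 * x$dumped_fraction))
  invisible(x)
}

#' Two-panel pnCCD detector geometry
#'
#' Describes a pair of pnCCD panels mounted above and below the beam axis.
#' Each panel has \code{panel_rows} x \code{panel_cols} pixels at pitch
#' \code{pixel_pitch_um}; the assembled frame stacks panel 1, a gap of absent
#' rows (width rounded to whole pixels), and panel 2. The beam passes through
#' the middle of the gap.
#'
#' @param detector_distance_mm sample-to-detector distance (mm).
#' @param gap_mm physical width of the inter-panel gap (mm).
#' @param panel_rows,panel_cols pixels per panel (defaults: 512 x 1024,
#'   i.e. a 38.4 mm x 76.8 mm sensitive area per panel at 75 um pitch).
#' @param pixel_pitch_um pixel pitch (um).
#' @param beam_center optional (row, col), 0-based pixel-center coordinates in
#'   the assembled frame; defaults to the frame center.
#' @return object of class \code{detector_geometry}.
#' @export
detector_geometry <- function(detector_distance_mm,
                              gap_mm,
                              panel_rows = 512,
                              panel_cols = 1024,
                              pixel_pitch_um = 75,
                              beam_center = NULL) {
  if (detector_distance_mm <= 0) stop("detector distance must be positive")
  if (gap_mm <= 0) stop("gap width must be positive")
  pitch_mm <- pixel_pitch_um / 1000
  gap_px <- max(1L, as.integer(round(gap_mm / pitch_mm)))
  n_rows <- 2L * panel_rows + gap_px
  n_cols <- as.integer(panel_cols)
  if (is.null(beam_center)) beam_center <- c((n_rows - 1) / 2, (n_cols - 1) / 2)
  if (beam_center[1] < 0 || beam_center[1] > n_rows - 1 ||
      beam_center[2] < 0 || beam_center[2] > n_cols - 1)
    warning("beam center lies outside the assembled frame extent")
  panel_rows_idx <- list(seq_len(panel_rows),
                         seq.int(panel_rows + gap_px + 1L, n_rows))
  gap_rows <- seq.int(panel_rows + 1L, panel_rows + gap_px)
  structure(list(
    detector_distance_mm = detector_distance_mm,
    gap_mm = gap_mm,
    gap_px = gap_px,
    panel_rows = as.integer(panel_rows),
    panel_cols = n_cols,
    pixel_pitch_um = pixel_pitch_um,
    pixel_pitch_mm = pitch_mm,
    n_rows = n_rows,
    n_cols = n_cols,
    beam_center = beam_center,
    panel_rows_idx = panel_rows_idx,
    gap_rows = gap_rows
  ), class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf(paste0("pnCCD geometry: 2 panels of %d x %d px (%g um pitch), ",
                     "gap %.1f mm (%d px), distance %.0f mm\n"),
              x$panel_rows, x$panel_cols, x$pixel_pitch_um,
              x$gap_mm, x$gap_px, x$detector_distance_mm))
  cat(sprintf("  assembled frame %d x %d, beam center (%.1f, %.1f)\n",
              x$n_rows, x$n_cols, x$beam_center[1], x$beam_center[2]))
  invisible(x)
}

#' Logical gap mask for the assembled frame (TRUE = absent pixel)
#' @param geometry a \code{detector_geometry}.
#' @return logical matrix of assembled-frame shape.
#' @export
gap_mask <- function(geometry) {
  m <- matrix(FALSE, geometry$n_rows, geometry$n_cols)
  m[geometry$gap_rows, ] <- TRUE
  m
}

#' Reciprocal-space map of the assembled frame
#'
#' Per-pixel scattering-vector magnitude q = (4 pi / lambda) sin(theta / 2)
#' (full scattering angle theta from the detector distance), solid angle, and
#' radial pixel distance from the beam center. Gap rows receive well-defined
#' geometric values but are flagged in \code{$gap}.
#'
#' @param geometry a \code{detector_geometry}.
#' @param beam a \code{beam_parameters}.
#' @return object of class \code{qmap}: matrices \code{q} (nm^-1),
#'   \code{solid_angle} (sr), \code{r_px} (pixels), logical \code{gap},
#'   and scalars \code{wavelength_nm}, \code{q_max}.
#' @export
build_qmap <- function(geometry, beam) {
  stopifnot(inherits(geometry, "detector_geometry"),
            inherits(beam, "beam_parameters"))
  pitch <- geometry$pixel_pitch_mm
  rows <- (seq_len(geometry$n_rows) - 1) - geometry$beam_center[1]
  cols <- (seq_len(geometry$n_cols) - 1) - geometry$beam_center[2]
  dy <- matrix(rows * pitch, geometry$n_rows, geometry$n_cols)
  dx <- matrix(cols * pitch, geometry$n_rows, geometry$n_cols, byrow = TRUE)
  radius_mm <- sqrt(dx^2 + dy^2)
  theta <- atan(radius_mm / geometry$detector_distance_mm)
  q <- (4 * pi / beam$wavelength_nm) * sin(theta / 2)
  sa <- (pitch / geometry$detector_distance_mm)^2 * cos(theta)^3
  gp <- gap_mask(geometry)
  structure(list(
    q = q,
    solid_angle = sa,
    r_px = radius_mm / pitch,
    gap = gp,
    wavelength_nm = beam$wavelength_nm,
    q_max = max(q[!gp]),
    geometry = geometry
  ), class = "qmap")
}

#' Bundled beamline presets
#'
#' Presets mirror the experiment configurations: carboxysome/sucrose runs at
#' 370 mm detector distance (5.5 mm gap), TBSV at 259 mm (3.3 mm gap; a
#' nominal 250 mm variant is also provided), Rubisco at 130 mm. Stored as a
#' YAML config under \code{inst/extdata}.
#'
#' @param name preset name: one of "carboxysome", "sucrose", "tbsv",
#'   "tbsv_nominal", "rubisco".
#' @param config_file optional path to an alternative preset YAML.
#' @return list with elements \code{beam} and \code{geometry}.
#' @export
beamline_preset <- function(name, config_file = NULL) {
  if (is.null(config_file))
    config_file <- system.file("extdata", "beamline_presets.yaml",
                               package = "espraydiff", mustWork = TRUE)
  cfg <- yaml::read_yaml(config_file)
  if (!name %in% names(cfg$presets))
    stop("unknown beamline preset: ", name,
         " (available: ", paste(names(cfg$presets), collapse = ", "), ")")
  p <- cfg$presets[[name]]
  beam <- do.call(beam_parameters, cfg$beam)
  geometry <- detector_geometry(detector_distance_mm = p$detector_distance_mm,
                                gap_mm = p$gap_mm)
  list(beam = beam, geometry = geometry, name = name)
}
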