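# Diffraction-geometry arithmetic for continuous-rotation electron
# diffraction: electron wavelength, resolution at a detector radius,
# spot-separation estimates, per-frame oscillation and exposure ledgers.

# CODATA 2018 constants (SI)
.PLANCK_H <- 6.62607015e-34
.ELECTRON_M0 <- 9.1093837015e-31
.ELEMENTARY_E <- 1.602176634e-19
.LIGHT_C <- 299792458

#' Acquisition geometry for a MicroED data set
#'
#' Bundles the camera and microscope parameters from which all diffraction
#' geometry derives: acceleration voltage, virtual sample-to-detector
#' distance (camera length), detector pixel size and binning, frame shape,
#' rotation speed, exposure time per frame and the incident exposure rate.
#'
#' @param voltage_kv Acceleration voltage in kilovolts (> 0).
#' @param distance_mm Virtual sample-to-detector distance in mm (> 0). The
#'   distance in an equivalent lensless system reproducing the observed
#'   diffraction magnification; it is a calibration input, not derived.
#' @param physical_pixel_um Physical detector pixel edge in micrometres.
#' @param binning Integer binning factor (>= 1); the effective pixel is
#'   `physical_pixel_um * binning`.
#' @param frame_shape Integer vector `c(rows, cols)` of the (binned) frame.
#' @param rotation_speed_deg_s Stage rotation speed in degrees per second
#'   (>= 0; 0 means stills).
#' @param exposure_time_s Exposure time per frame in seconds (> 0).
#' @param exposure_rate Incident exposure rate in e- / Angstrom^2 / s.
#' @return An object of class `acquisition_geometry`.
#' @examples
#' geom <- acquisition_geometry(voltage_kv = 200, distance_mm = 2380,
#'                              physical_pixel_um = 14, binning = 2,
#'                              frame_shape = c(2048, 2048),
#'                              rotation_speed_deg_s = 0.45,
#'                              exposure_time_s = 1, exposure_rate = 0.01)
#' edge_resolution(geom)
#' @export
acquisition_geometry <- function(voltage_kv, distance_mm = NA_real_,
                                 physical_pixel_um = 14, binning = 1L,
                                 frame_shape = c(2048L, 2048L),
                                 rotation_speed_deg_s = 0,
                                 exposure_time_s = 1,
                                 exposure_rate = 0.01) {
  stopifnot(is.numeric(voltage_kv), length(voltage_kv) == 1L)
  if (voltage_kv <= 0) stop("voltage_kv must be positive", call. = FALSE)
  if (!is.na(distance_mm) && distance_mm <= 0)
    stop("distance_mm must be positive", call. = FALSE)
  binning <- as.integer(binning)
  if (binning < 1L) stop("binning must be >= 1", call. = FALSE)
  if (exposure_time_s <= 0) stop("exposure_time_s must be positive", call. = FALSE)
  if (rotation_speed_deg_s < 0) stop("rotation_speed_deg_s must be >= 0", call. = FALSE)
  structure(list(
    voltage_kv = voltage_kv,
    distance_mm = distance_mm,
    physical_pixel_um = physical_pixel_um,
    binning = binning,
    frame_shape = as.integer(frame_shape),
    rotation_speed_deg_s = rotation_speed_deg_s,
    exposure_time_s = exposure_time_s,
    exposure_rate = exposure_rate
  ), class = "acquisition_geometry")
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat(sprintf(
    "Acquisition geometry: %g kV, D = %g mm, %g um px (bin %d), %dx%d frames\n",
    x$voltage_kv, x$distance_mm, x$physical_pixel_um, x$binning,
    x$frame_shape[1], x$frame_shape[2]))
  cat(sprintf("  rotation %g deg/s, t_exp %g s, exposure rate %g e-/A^2/s\n",
              x$rotation_speed_deg_s, x$exposure_time_s, x$exposure_rate))
  invisible(x)
}

#' Relativistic electron wavelength
#'
#' Computes the de Broglie wavelength of an electron accelerated through a
#' potential `V`, with the relativistic correction:
#' \deqn{\lambda = h / \sqrt{2 m_0 e V (1 + eV / (2 m_0 c^2))}}
#' At 200 kV this gives 0.025079 Angstrom.
#'
#' @param voltage_kv Acceleration voltage in kilovolts (> 0); vectorised.
#' @return Wavelength in Angstrom.
#' @export
electron_wavelength <- function(voltage_kv) {
  if (any(!is.finite(voltage_kv)) || any(voltage_kv <= 0))
    stop("voltage_kv must be positive and finite", call. = FALSE)
  v <- voltage_kv * 1e3
  lam <- .PLANCK_H / sqrt(2 * .ELECTRON_M0 * .ELEMENTARY_E * v *
                            (1 + .ELEMENTARY_E * v / (2 * .ELECTRON_M0 * .LIGHT_C^2)))
  lam * 1e10
}

#' Resolution at a detector radius
#'
#' Bragg d-spacing recorded at radius `r` from the beam centre, using the
#' exact relation `d = lambda / (2 sin(theta))` with `2 theta = atan(r / D)`.
#' No small-angle approximation is made.
#'
#' @param geom An [acquisition_geometry()].
#' @param radius_mm Radius on the detector in mm (> 0); vectorised.
#' @return d-spacing in Angstrom.
#' @export
resolution_at_radius <- function(geom, radius_mm) {
  stopifnot(inherits(geom, "acquisition_geometry"))
  if (any(radius_mm <= 0)) stop("radius_mm must be positive", call. = FALSE)
  if (is.na(geom$distance_mm))
    stop("distance_mm is not set; the virtual sample-to-detector distance must be supplied",
         call. = FALSE)
  lambda <- electron_wavelength(geom$voltage_kv)
  theta <- atan(radius_mm / geom$distance_mm) / 2
  lambda / (2 * sin(theta))
}

#' Resolution at the detector edge
#'
#' d-spacing at the half-width of the frame's shorter axis (edge, not corner):
#' radius = `min(frame_shape)/2 * physical_pixel_um * binning / 1000` mm.
#'
#' @inheritParams resolution_at_radius
#' @return d-spacing in Angstrom.
#' @export
edge_resolution <- function(geom) {
  stopifnot(inherits(geom, "acquisition_geometry"))
  radius <- (min(geom$frame_shape) / 2) * geom$physical_pixel_um *
    geom$binning / 1000
  resolution_at_radius(geom, radius)
}

#' Bragg-spot separation on the detector in pixels
#'
#' For a cell edge `a`, adjacent reflections along that axis are spaced
#' 1/a apart in reciprocal space. When the detector half-width corresponds
#' to 1/d_min, that spacing maps to
#' `half_width_px * d_min / cell_edge_a` pixels. Used to judge whether spots
#' overlap on small-chip detectors.
#'
#' @param cell_edge_a Unit-cell edge in Angstrom.
#' @param d_min Resolution at the detector half-width in Angstrom.
#' @param half_width_px Detector half-width in pixels.
#' @return Spot separation in pixels.
#' @export
spot_separation_px <- function(cell_edge_a, d_min, half_width_px) {
  if (any(c(cell_edge_a, d_min, half_width_px) <= 0))
    stop("all arguments must be positive", call. = FALSE)
  if (d_min >= cell_edge_a)
    stop("d_min must be smaller than the cell edge (no reflections in range)",
         call. = FALSE)
  half_width_px * d_min / cell_edge_a
}

#' Linear-range pixel threshold for frame-averaged readout
#'
#' Detectors that report the average of `n` subframes scale the per-frame
#' linear range down by `n`: a single-frame linear limit of 6000 ADU with
#' 40-frame averaging implies averaged pixel values below 150 ADU are linear.
#'
#' @param single_frame_limit Linear-range limit per single frame, ADU (> 0).
#' @param n_averaged Number of frames averaged into one stored value (> 0).
#' @return Threshold in ADU on the stored (averaged) scale.
#' @export
linear_adu_threshold <- function(single_frame_limit, n_averaged) {
  if (single_frame_limit <= 0) stop("single_frame_limit must be positive", call. = FALSE)
  if (n_averaged <= 0) stop("n_averaged must be positive", call. = FALSE)
  single_frame_limit / n_averaged
}

#' Oscillation per frame
#'
#' `delta_phi = rotation_speed * exposure_time`, degrees. Zero for stills.
#'
#' @inheritParams resolution_at_radius
#' @return Degrees of rotation covered by one frame.
#' @export
delta_phi_per_frame <- function(geom) {
  stopifnot(inherits(geom, "acquisition_geometry"))
  geom$rotation_speed_deg_s * geom$exposure_time_s
}

#' Cumulative exposure ledger
#'
#' Assigns frame `i` (1-based) the exposure accumulated by its end,
#' `i * exposure_rate * exposure_time_s`, so the last merged frame's entry
#' equals E_max, the maximum exposure of any frame in the merged set.
#'
#' @inheritParams resolution_at_radius
#' @param n_frames Number of frames (>= 1).
#' @return An `exposure_ledger` with `per_frame_exposure` (e-/A^2),
#'   `cumulative_exposure` (length `n_frames`, strictly increasing) and
#'   `E_max`.
#' @export
exposure_ledger <- function(geom, n_frames) {
  stopifnot(inherits(geom, "acquisition_geometry"))
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  per_frame <- geom$exposure_rate * geom$exposure_time_s
  cum <- seq_len(n_frames) * per_frame
  structure(list(per_frame_exposure = per_frame,
                 cumulative_exposure = cum,
                 E_max = cum[n_frames]),
            class = "exposure_ledger")
}

#' @export
print.exposure_ledger <- function(x, ...) {
  cat(sprintf("Exposure ledger: %d frames, %g e-/A^2 per frame, E_max %g e-/A^2\n",
              length(x$cumulative_exposure), x$per_frame_exposure, x$E_max))
  invisible(x)
}
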