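#' Specification of the CCD spectrograph model
#'
#' Describes the simulated imaging spectrograph: detector format, smile
#' aberration (a second-order polynomial column shift versus row),
#' pixel-to-wavelength dispersion, fixed-pattern gain, broadband spectral
#' response, dark level, additive read noise and cosmic-ray statistics.
#' The gain map and broadband response are generated deterministically
#' from `pattern_seed` so that a given spec always describes the same
#' instrument.
#'
#' @param n_cols,n_rows Detector format in pixels (default 1024 x 256).
#' @param smile_coeffs Coefficients `c(c0, c1, c2)` of the column shift
#'   `s(r) = c0 + c1 r + c2 r^2` (pixels) at 0-based row `r`.
#' @param wavelength_coeffs Coefficients of the true pixel-to-wavelength
#'   map `lambda(c) = w0 + w1 c + w2 c^2` (nm) at 0-based column `c`.
#' @param laser_wavelength_nm True excitation wavelength (default 830 nm).
#' @param gain_sd Lognormal sd of the per-pixel fixed-pattern gain
#'   (default 0.05); the map is normalized to unit mean.
#' @param dark_level Dark offset in counts (default 500).
#' @param noise_sigma SD of additive Gaussian read noise, counts per
#'   pixel per frame (default 0.4; see the package vignette for how this
#'   interacts with the cosmic-ray MAD floor).
#' @param cosmic_rate Expected number of cosmic-ray spikes per frame
#'   (default 5).
#' @param cosmic_amplitude Range (counts) of single-pixel spike
#'   amplitudes, drawn uniformly (default 200-2000).
#' @param crop_length Number of spectral pixels retained after
#'   rectification cropping (default 499).
#' @param pattern_seed Seed for the deterministic gain/response patterns.
#' @return An object of class `detector_spec` carrying, in addition to
#'   the arguments, the realized `gain_map` (rows x cols) and
#'   `broadband_response` (per column, unit mean).
#' @examples
#' det <- detector_spec()
#' dim(det$gain_map)
#' @export
detector_spec <- function(n_cols = 1024, n_rows = 256,
                          smile_coeffs = c(0, 0, 4e-5),
                          wavelength_coeffs = c(840, 0.18, 1e-6),
                          laser_wavelength_nm = 830,
                          gain_sd = 0.05,
                          dark_level = 500,
                          noise_sigma = 0.4,
                          cosmic_rate = 5,
                          cosmic_amplitude = c(200, 2000),
                          crop_length = 499,
                          pattern_seed = 7) {
  stopifnot(n_cols >= crop_length + 2, n_rows >= 1, noise_sigma >= 0, cosmic_rate >= 0)
  max_shift <- max(abs(polyval(smile_coeffs, c(0, n_rows - 1, n_rows / 2))))
  margin <- (n_cols - crop_length) / 2
  if (max_shift >= margin) {
    stop("smile shift (", round(max_shift, 1), " px) exceeds the crop margin (",
      margin, " px)",
      call. = FALSE
    )
  }
  gain_map <- with_seed(pattern_seed, {
    g <- matrix(exp(rnorm(n_rows * n_cols, 0, gain_sd)), n_rows, n_cols)
    g / mean(g)
  })
  xc <- (0:(n_cols - 1)) / (n_cols - 1)
  br <- 0.72 + 0.55 * exp(-((xc - 0.58) / 0.38)^2)
  br <- br / mean(br)
  structure(
    list(
      n_cols = n_cols, n_rows = n_rows, smile_coeffs = smile_coeffs,
      wavelength_coeffs = wavelength_coeffs,
      laser_wavelength_nm = laser_wavelength_nm,
      gain_sd = gain_sd, dark_level = dark_level,
      noise_sigma = noise_sigma, cosmic_rate = cosmic_rate,
      cosmic_amplitude = cosmic_amplitude, crop_length = crop_length,
      pattern_seed = pattern_seed,
      gain_map = gain_map, broadband_response = br
    ),
    class = "detector_spec"
  )
}

#' @export
print.detector_spec <- function(x, ...) {
  cat(sprintf(
    "CCD spectrograph model: %d x %d px, laser %.1f nm, smile c2=%.2g px/row^2\n",
    x$n_cols, x$n_rows, x$laser_wavelength_nm, x$smile_coeffs[3]
  ))
  invisible(x)
}

# Column shift (px) at 0-based row r.
smile_at <- function(det, row0) polyval(det$smile_coeffs, row0)

# True wavelength (nm) at (possibly fractional) 0-based column.
wavelength_at <- function(det, col0) polyval(det$wavelength_coeffs, col0)

# Default 1-based start column of the centered crop window.
default_crop_start <- function(det) {
  floor((det$n_cols - det$crop_length) / 2) + 1L
}

#' Fiber-bundle to detector-row mapping
#'
#' The three collection bundles (4, 12 and 26 fibers at 0, 3 and 6 mm
#' lateral offset) are imaged onto disjoint row blocks of the detector;
#' summing each block yields one spectrum per offset.
#'
#' @param rows Named list mapping offset (mm, as character) to the
#'   (1-based, contiguous) detector rows of that bundle.
#' @param fibers Named vector of fiber counts per bundle.
#' @return Object of class `bundle_layout`.
#' @export
bundle_layout <- function(rows = list("0" = 30:33, "3" = 110:121, "6" = 190:215),
                          fibers = c("0" = 4, "3" = 12, "6" = 26)) {
  offs <- names(rows)
  if (anyDuplicated(offs)) stop("offsets must be unique", call. = FALSE)
  all_rows <- unlist(rows)
  if (anyDuplicated(all_rows)) {
    stop("bundle row ranges must be disjoint", call. = FALSE)
  }
  structure(
    list(offsets = as.numeric(offs), rows = rows, fibers = fibers),
    class = "bundle_layout"
  )
}

#' True Raman-shift axis of the simulated instrument
#'
#' The ground-truth wavenumber axis over the cropped detector window,
#' computed from the detector's true dispersion and laser wavelength.
#' This is what [calibrate_axis()] must recover from the calibration
#' frames.
#'
#' @param det A [detector_spec()].
#' @param crop_start 1-based first column of the crop window (default:
#'   centered).
#' @return A `wavenumber_axis` object with `shift_cm` (strictly
#'   increasing), `wavelength_nm` and `lambda0_nm`.
#' @export
true_axis <- function(det, crop_start = default_crop_start(det)) {
  cols0 <- (crop_start - 1):(crop_start + det$crop_length - 2)
  lambda <- wavelength_at(det, cols0)
  new_wavenumber_axis(
    shift_cm = raman_shift_cm(lambda, det$laser_wavelength_nm),
    wavelength_nm = lambda,
    lambda0_nm = det$laser_wavelength_nm
  )
}

new_wavenumber_axis <- function(shift_cm, wavelength_nm, lambda0_nm,
                                wl_coefs = NULL, residual_cm = NA_real_) {
  if (any(diff(shift_cm) <= 0)) {
    stop("Raman-shift axis must be strictly increasing", call. = FALSE)
  }
  structure(
    list(
      shift_cm = shift_cm, wavelength_nm = wavelength_nm,
      lambda0_nm = lambda0_nm, wl_coefs = wl_coefs,
      residual_cm = residual_cm, n = length(shift_cm)
    ),
    class = "wavenumber_axis"
  )
}

#' @export
print.wavenumber_axis <- function(x, ...) {
  cat(sprintf(
    "Raman-shift axis: %d px, %.1f-%.1f cm^-1, lambda0 = %.3f nm\n",
    x$n, min(x$shift_cm), max(x$shift_cm), x$lambda0_nm
  ))
  invisible(x)
}

#' Neon emission lines used for pixel-wavelength calibration
#'
#' Fifteen near-infrared neon lamp lines (nm) spanning the simulated
#' detector range.
#'
#' @return Numeric vector of 15 wavelengths in nm.
#' @export
default_neon_lines <- function() {
  c(
    846.336, 849.536, 854.469, 859.126, 863.465, 868.192, 878.062,
    885.387, 891.950, 898.857, 914.867, 920.176, 927.552, 942.538,
    966.542
  )
}

#' Acetaminophen Raman shifts used for laser-wavelength calibration
#'
#' Thirteen acetaminophen (paracetamol) Raman shift standards (cm^-1)
#' used to solve for the effective laser wavelength.
#'
#' @return Numeric vector of 13 Raman shifts in cm^-1.
#' @export
default_acetaminophen_shifts <- function() {
  c(
    465.1, 651.6, 710.8, 797.2, 834.5, 857.9, 968.7, 1105.5, 1168.5,
    1236.8, 1323.9, 1561.5, 1648.4
  )
}
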