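#' Construct a CCD frame
#'
#' @param data Numeric matrix of counts (rows x columns).
#' @param role One of `dark`, `neon`, `acetaminophen`, `white`, `glass`,
#'   `sample`.
#' @param exposure_s Exposure time in seconds.
#' @param accumulation Accumulation index within a replicate series.
#' @return Object of class `ccd_frame`.
#' @export
ccd_frame <- function(data, role = c(
                        "sample", "dark", "neon", "acetaminophen",
                        "white", "glass"
                      ),
                      exposure_s = 60, accumulation = 1L) {
  role <- match.arg(role)
  data <- as.matrix(data)
  if (!is.numeric(data) || any(!is.finite(data))) {
    stop("frame data must be a finite numeric matrix", call. = FALSE)
  }
  structure(
    list(
      data = data, role = role, exposure_s = exposure_s,
      accumulation = as.integer(accumulation)
    ),
    class = "ccd_frame"
  )
}

#' @export
print.ccd_frame <- function(x, ...) {
  cat(sprintf(
    "CCD frame [%s]: %d x %d px, %gs exposure\n", x$role,
    nrow(x$data), ncol(x$data), x$exposure_s
  ))
  invisible(x)
}

new_bundle_spectrum <- function(shift_cm, intensity, offset_mm, meta = list()) {
  stopifnot(length(shift_cm) == length(intensity))
  structure(
    list(
      shift_cm = shift_cm, intensity = intensity,
      offset_mm = offset_mm, meta = meta
    ),
    class = "bundle_spectrum"
  )
}

#' @export
print.bundle_spectrum <- function(x, ...) {
  cat(sprintf(
    "Bundle spectrum: offset %g mm, %d px, max %.3g\n",
    x$offset_mm, length(x$intensity), max(x$intensity)
  ))
  invisible(x)
}

#' Render the noise-free spectrum of a specimen at a collection offset
#'
#' Evaluates the two-layer mixture model: the spectrum is the sum over
#' layers of `w_layer(offset)` times that layer's band amplitudes placed
#' as unit-height Gaussian profiles on the Raman-shift axis. The
#' subcortical weight increases with lateral offset (deeper photon paths
#' at larger offsets), the two weights sum to 1, and no baseline or noise
#' is added.
#'
#' @param specimen A `ground_truth_specimen` from [generate_cohort()].
#' @param offset_mm Collection offset; must be one of the names of
#'   `weights`.
#' @param axis A `wavenumber_axis` (e.g. [true_axis()]).
#' @param bands Band table giving centers and widths ([bone_bands()]).
#' @param weights Named vector of subcortical weights per offset, as in
#'   [cohort_spec()].
#' @return A `bundle_spectrum`.
#' @export
render_clean_spectrum <- function(specimen, offset_mm, axis,
                                  bands = bone_bands(),
                                  weights = c("0" = 0.2, "3" = 0.5, "6" = 0.6)) {
  key <- as.character(offset_mm)
  if (!key %in% names(weights)) {
    stop("unknown offset: ", offset_mm, " mm", call. = FALSE)
  }
  if (any(diff(axis$shift_cm) <= 0)) {
    stop("axis must be strictly increasing", call. = FALSE)
  }
  w_sub <- weights[[key]]
  amp <- specimen$layer_amplitudes
  blended <- (1 - w_sub) * amp[, "surface"] + w_sub * amp[, "subcortical"]
  centers <- bands$center + specimen$axis_jitter
  y <- rep(0, length(axis$shift_cm))
  for (b in seq_len(nrow(bands))) {
    y <- y + blended[[bands$band[b]]] *
      gaussian_peak(axis$shift_cm, centers[b], bands$fwhm[b])
  }
  new_bundle_spectrum(axis$shift_cm, y, offset_mm,
    meta = list(
      specimen_id = specimen$specimen_id, clean = TRUE,
      # continuous band model, so downstream rendering can evaluate the
      # scene at arbitrary wavenumbers instead of re-interpolating
      model = list(
        amplitude = unname(blended[bands$band]),
        center = centers, fwhm = bands$fwhm
      )
    )
  )
}

# Evaluate a bundle spectrum at arbitrary wavenumbers: analytically when
# the generative band model is attached, by linear interpolation otherwise.
eval_spectrum_at <- function(sp, nu) {
  m <- sp$meta$model
  if (!is.null(m)) {
    y <- rep(0, length(nu))
    for (b in seq_along(m$amplitude)) {
      y <- y + m$amplitude[b] * gaussian_peak(nu, m$center[b], m$fwhm[b])
    }
    y
  } else {
    approx(sp$shift_cm, sp$intensity, xout = nu, yleft = 0, yright = 0)$y
  }
}

# Per-specimen fluorescence background evaluated at Raman shifts nu,
# with the shape polynomial parameterized over nu_range scaled to [-1,1].
fluorescence_at <- function(specimen, nu, nu_range) {
  u <- unit_scale(nu, nu_range)
  pmax(polyval(specimen$fluorescence_coeffs, u), 0)
}

# Apply the instrument chain (gain, broadband response, dark, read noise)
# to a matrix of pre-instrument signal; noise drawn from the current RNG.
instrument_apply <- function(signal, det, noise = TRUE) {
  out <- signal * det$gain_map *
    matrix(det$broadband_response, det$n_rows, det$n_cols, byrow = TRUE)
  out <- out + det$dark_level
  if (noise && det$noise_sigma > 0) {
    out <- out + matrix(
      rnorm(length(out), 0, det$noise_sigma),
      nrow(out), ncol(out)
    )
  }
  out
}

# Add Poisson-count single-pixel cosmic-ray spikes; returns the frame and
# a record of spike positions for test oracles.
add_cosmic_rays <- function(data, det) {
  n_sp <- rpois(1, det$cosmic_rate)
  if (n_sp == 0) {
    return(list(data = data, spikes = data.frame(
      row = integer(), col = integer(), amplitude = numeric()
    )))
  }
  r <- sample.int(nrow(data), n_sp, replace = TRUE)
  cl <- sample.int(ncol(data), n_sp, replace = TRUE)
  a <- runif(n_sp, det$cosmic_amplitude[1], det$cosmic_amplitude[2])
  data[cbind(r, cl)] <- data[cbind(r, cl)] + a
  list(data = data, spikes = data.frame(row = r, col = cl, amplitude = a))
}

#' Render a stack of raw detector frames for one specimen
#'
#' Places the clean spectrum of each offset (plus the specimen's smooth
#' fluorescence background) into the corresponding bundle row block,
#' shifted per row by the smile polynomial, applies the fixed-pattern
#' gain and broadband response, adds the dark level, Gaussian read noise
#' and Poisson-count single-pixel cosmic-ray spikes. Each bundle row
#' carries `1/n_rows` of the bundle signal so that row summation
#' reconstructs the input spectrum.
#'
#' @param spectra A single `bundle_spectrum` or a list of them (one per
#'   offset), from [render_clean_spectrum()].
#' @param specimen The `ground_truth_specimen` the spectra belong to
#'   (supplies the fluorescence background).
#' @param det A [detector_spec()].
#' @param layout A [bundle_layout()].
#' @param n_frames Number of replicate accumulations (default 5).
#' @param seed Optional RNG seed for reproducible noise and spikes.
#' @param fluorescence Include the fluorescence background (default TRUE).
#' @return List of `ccd_frame` objects with attribute `spikes`, a data
#'   frame of seeded spike positions (`frame`, `row`, `col`,
#'   `amplitude`) for use as a test oracle.
#' @export
render_frame_stack <- function(spectra, specimen, det,
                               layout = bundle_layout(), n_frames = 5,
                               seed = NULL, fluorescence = TRUE) {
  stopifnot(n_frames >= 1)
  if (inherits(spectra, "bundle_spectrum")) spectra <- list(spectra)
  with_seed(seed, {
    # pre-instrument signal is identical across frames; build it once
    base <- matrix(0, det$n_rows, det$n_cols)
    cols0 <- 0:(det$n_cols - 1)
    for (sp in spectra) {
      key <- as.character(sp$offset_mm)
      rows <- layout$rows[[key]]
      if (is.null(rows)) {
        stop("no bundle rows defined for offset ", key, " mm", call. = FALSE)
      }
      nu_range <- range(sp$shift_cm)
      for (r in rows) {
        lam <- wavelength_at(det, cols0 + smile_at(det, r - 1))
        nu <- raman_shift_cm(lam, det$laser_wavelength_nm)
        sig <- eval_spectrum_at(sp, nu)
        if (fluorescence) {
          sig <- sig + fluorescence_at(specimen, nu, nu_range)
        }
        base[r, ] <- base[r, ] + sig / length(rows)
      }
    }
    spikes <- vector("list", n_frames)
    frames <- vector("list", n_frames)
    for (k in seq_len(n_frames)) {
      fr <- instrument_apply(base, det)
      cr <- add_cosmic_rays(fr, det)
      frames[[k]] <- ccd_frame(cr$data, "sample", accumulation = k)
      if (nrow(cr$spikes)) {
        spikes[[k]] <- cbind(frame = k, cr$spikes)
      }
    }
    spikes <- do.call(rbind, c(
      list(data.frame(
        frame = integer(), row = integer(),
        col = integer(), amplitude = numeric()
      )),
      spikes[!vapply(spikes, is.null, TRUE)]
    ))
    attr(frames, "spikes") <- spikes
    frames
  })
}

# Render one calibration frame whose pre-instrument signal is a function
# of wavelength evaluated through the smile model.
render_wavelength_frame <- function(det, f, role, noise = TRUE) {
  sig <- matrix(0, det$n_rows, det$n_cols)
  cols0 <- 0:(det$n_cols - 1)
  for (r in seq_len(det$n_rows)) {
    sig[r, ] <- f(wavelength_at(det, cols0 + smile_at(det, r - 1)))
  }
  ccd_frame(instrument_apply(sig, det, noise = noise), role)
}

# Sum of Gaussian lines in the wavelength domain.
line_profile <- function(centers_nm, heights, sigma_nm) {
  force(centers_nm)
  force(heights)
  force(sigma_nm)
  function(lam) {
    y <- rep(0, length(lam))
    for (k in seq_along(centers_nm)) {
      y <- y + heights[k] * exp(-(lam - centers_nm[k])^2 / (2 * sigma_nm^2))
    }
    y
  }
}

#' Generate the calibration frame set of the simulated instrument
#'
#' Renders dark, neon-lamp, acetaminophen, white-lamp and green-glass
#' fluorescence-standard frames through the same instrument model used
#' for sample frames, and returns them together with the certified glass
#' emission curve and the ground-truth line lists (both the full 15
#' neon / 13 acetaminophen lists and the sublists visible inside the
#' cropped spectral window, which are what [calibrate_axis()] needs).
#'
#' @param det A [detector_spec()].
#' @param seed Optional RNG seed for the frame noise.
#' @return Object of class `calibration_set`: frames `dark`, `neon`,
#'   `acetaminophen`, `white`, `glass`; `glass_certified` (data frame
#'   `wavelength_nm`, `intensity`); line lists and their `_visible`
#'   counterparts; the `detector`.
#' @export
generate_calibration_set <- function(det, seed = NULL) {
  with_seed(seed, {
    neon <- default_neon_lines()
    acet_shifts <- default_acetaminophen_shifts()
    acet_nm <- shift_to_wavelength(acet_shifts, det$laser_wavelength_nm)
    neon_h <- 700 + 400 * sin(1.7 * seq_along(neon))
    acet_h <- 650 + 350 * cos(1.3 * seq_along(acet_nm))

    dark <- ccd_frame(
      det$dark_level +
        matrix(
          rnorm(det$n_rows * det$n_cols, 0, det$noise_sigma),
          det$n_rows, det$n_cols
        ) * (det$noise_sigma > 0),
      "dark"
    )
    neon_fr <- render_wavelength_frame(
      det, line_profile(neon, neon_h, 0.40), "neon"
    )
    acet_fr <- render_wavelength_frame(
      det, line_profile(acet_nm, acet_h, 0.45), "acetaminophen"
    )
    white_fr <- render_wavelength_frame(
      det, function(l) 2000 * exp(-((l - 960) / 250)^2) + 200, "white"
    )
    glass_shape <- function(l) 0.15 + exp(-((l - 910) / 70)^2)
    glass_fr <- render_wavelength_frame(
      det, function(l) 1500 * glass_shape(l), "glass"
    )
    wl_grid <- seq(800, 1100, by = 0.5)
    certified <- data.frame(
      wavelength_nm = wl_grid,
      intensity = glass_shape(wl_grid) / max(glass_shape(wl_grid))
    )

    # lines visible inside the (default, centered) crop window, with a
    # 12-px margin so centroid windows stay clear of the edges
    cs <- default_crop_start(det)
    margin_px <- 12
    lam_lo <- wavelength_at(det, cs - 1 + margin_px)
    lam_hi <- wavelength_at(det, cs - 1 + det$crop_length - 1 - margin_px)
    structure(
      list(
        dark = dark, neon = neon_fr, acetaminophen = acet_fr,
        white = white_fr, glass = glass_fr,
        glass_certified = certified,
        neon_lines_nm = neon,
        acetaminophen_shifts_cm = acet_shifts,
        neon_lines_visible = neon[neon > lam_lo & neon < lam_hi],
        acetaminophen_shifts_visible =
          acet_shifts[acet_nm > lam_lo & acet_nm < lam_hi],
        detector = det
      ),
      class = "calibration_set"
    )
  })
}
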