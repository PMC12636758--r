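# Shared fixtures, all built in code.

# A noiseless instrument (smile, gain and response still active).
quiet_detector <- function(...) {
  detector_spec(noise_sigma = 0, cosmic_rate = 0, ...)
}

# Short detector + matching bundle layout for fast frame tests.
small_detector <- function(...) {
  detector_spec(n_rows = 64, noise_sigma = 0, cosmic_rate = 0, ...)
}

small_layout <- function() {
  bundle_layout(rows = list("0" = 8:11, "3" = 20:31, "6" = 36:61))
}

# Plain linear Raman-shift axis (no instrument) for cleanup/metric tests.
plain_axis <- function(n = 499, from = 800, to = 1820) {
  sorsbone:::new_wavenumber_axis(
    shift_cm = seq(from, to, length.out = n),
    wavelength_nm = sorsbone:::shift_to_wavelength(
      seq(from, to, length.out = n), 830
    ),
    lambda0_nm = 830
  )
}

make_spectrum <- function(shift, intensity, offset = 3, meta = list()) {
  sorsbone:::new_bundle_spectrum(shift, intensity, offset, meta)
}

# A specimen with fully controlled layer amplitudes (no randomness).
manual_specimen <- function(amp_surface, amp_subcortical,
                            bands = bone_bands(), tscore = 0,
                            fluor = c(3000, -1000, 300, 150),
                            jitter = 0) {
  amp <- cbind(surface = amp_surface, subcortical = amp_subcortical)
  rownames(amp) <- bands$band
  structure(
    list(
      specimen_id = "T01",
      who_class = as.character(classify_who(tscore)),
      tscore = tscore,
      layer_amplitudes = amp,
      fluorescence_coeffs = fluor,
      axis_jitter = jitter
    ),
    class = "ground_truth_specimen"
  )
}

# Literal per-pixel re-implementation of the cosmic-ray rule, used as a
# brute-force oracle against the vectorized path.
brute_force_cosmic <- function(X, k_mad = 10, n_lowest = 4, mad_floor = 1) {
  K <- nrow(X)
  mask <- matrix(FALSE, K, ncol(X))
  out <- X
  for (j in seq_len(ncol(X))) {
    v <- sort(X[, j])[seq_len(n_lowest)]
    mu <- mean(v)
    m <- median(abs(v - median(v)))
    thr <- mu + k_mad * max(m, mad_floor)
    hit <- X[, j] > thr
    mask[, j] <- hit
    out[hit, j] <- mu
  }
  list(intensity = out, mask = mask)
}
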