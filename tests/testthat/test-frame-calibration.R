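test_that("dark subtraction is elementwise and validates shapes", {
  dark <- ccd_frame(matrix(500, 8, 16), "dark")
  same <- ccd_frame(matrix(500, 8, 16), "sample")
  expect_true(all(dark_subtract(same, dark)$data == 0))
  plus <- ccd_frame(matrix(600, 8, 16), "sample")
  expect_true(all(dark_subtract(plus, dark)$data == 100))
  expect_equal(dark_subtract(plus, dark)$role, "sample")
  expect_error(
    dark_subtract(ccd_frame(matrix(1, 4, 16), "sample"), dark),
    "shapes differ"
  )
  expect_error(dark_subtract(plus, same), "role 'dark'")
})

test_that("rectification recovers the smile curvature and crops to 499", {
  det <- quiet_detector(smile_coeffs = c(0, 0, 4e-5))
  calib <- generate_calibration_set(det)
  map <- fit_rectification(calib)
  expect_equal(map$crop_length, 499)
  # fitted drift is the negative of the optical shift
  expect_lt(abs(map$shift_coef[2] + det$smile_coeffs[3]) /
    det$smile_coeffs[3], 0.01)

  # zero-smile, zero-fixed-pattern instrument: fitted polynomial vanishes
  det0 <- quiet_detector(smile_coeffs = c(0, 0, 0), gain_sd = 0)
  map0 <- fit_rectification(generate_calibration_set(det0))
  expect_lt(max(abs(map0$shift_coef)), 1e-6)
})

test_that("rectified peaks align across rows and intensity is conserved", {
  det <- quiet_detector(smile_coeffs = c(0, 0, 4e-5))
  calib <- generate_calibration_set(det)
  map <- fit_rectification(calib)
  neon <- apply_rectification(dark_subtract(calib$neon, calib$dark), map)
  prof <- colMeans(neon$data)
  pk <- which.max(prof)
  cents <- vapply(seq_len(nrow(neon$data)), function(r) {
    sorsbone:::centroid_in_window(neon$data[r, ], pk, 5)
  }, 0)
  expect_lt(max(cents) - min(cents), 0.2) # +/- 0.1 px about the mean

  # row-sum conservation for an interior peak
  raw <- dark_subtract(calib$neon, calib$dark)
  r_last <- det$n_rows
  win_raw <- (map$crop_start + pk - 21):(map$crop_start + pk + 19)
  before <- sum(raw$data[r_last, win_raw])
  after <- sum(neon$data[r_last, (pk - 20):(pk + 20)])
  expect_lt(abs(after - before) / before, 1e-3)

  # idempotence: re-fitting on rectified-equivalent geometry, the
  # zero-smile map leaves centroids unchanged to < 0.1 px
  det0 <- quiet_detector(smile_coeffs = c(0, 0, 0), gain_sd = 0)
  map0 <- fit_rectification(generate_calibration_set(det0))
  expect_lt(
    max(abs(sorsbone:::polyval(c(0, map0$shift_coef), c(0, det0$n_rows - 1)))),
    0.1
  )
})

test_that("axis calibration solves the laser wavelength and the shift law", {
  det <- quiet_detector()
  calib <- generate_calibration_set(det)
  map <- fit_rectification(calib)
  neon <- apply_rectification(dark_subtract(calib$neon, calib$dark), map)
  acet <- apply_rectification(dark_subtract(calib$acetaminophen, calib$dark), map)
  axis <- calibrate_axis(
    neon, calib$neon_lines_visible,
    acet, calib$acetaminophen_shifts_visible
  )
  expect_equal(axis$n, 499)
  expect_lt(abs(axis$lambda0_nm - det$laser_wavelength_nm), 0.01)
  # exact algebraic relation between the returned fields, every pixel
  expect_equal(
    axis$shift_cm,
    1e7 * (1 / axis$lambda0_nm - 1 / axis$wavelength_nm),
    tolerance = 1e-12
  )
  expect_true(all(diff(axis$shift_cm) > 0))
  # shift error at the acetaminophen lines below 2 cm^-1
  expect_lt(axis$residual_cm, 2)
  # and against the true instrument axis
  expect_lt(max(abs(axis$shift_cm - true_axis(det)$shift_cm)), 2)
  expect_error(calibrate_axis(neon, c(900, 910), acet,
    calib$acetaminophen_shifts_visible
  ), "at least 3 neon")
})

test_that("response correction is the identity for a flat instrument", {
  axis <- plain_axis(499)
  n_rows <- 16
  white <- ccd_frame(matrix(1000, n_rows, 499), "white")
  cert <- data.frame(
    wavelength_nm = seq(820, 1050, by = 0.5),
    intensity = 0.2 + exp(-((seq(820, 1050, by = 0.5) - 910) / 70)^2)
  )
  glass_sig <- approx(cert$wavelength_nm, cert$intensity,
    xout = axis$wavelength_nm
  )$y
  glass <- ccd_frame(
    matrix(800 * glass_sig, n_rows, 499, byrow = TRUE),
    "glass"
  )
  signal <- matrix(runif(n_rows * 499, 50, 150), n_rows, 499)
  out <- correct_response(
    ccd_frame(signal, "sample"), white, glass, cert, axis
  )
  expect_equal(out$data, signal, tolerance = 1e-6)
})

test_that("response correction removes a known gain and broadband response", {
  set.seed(4)
  n_rows <- 32
  axis <- plain_axis(499)
  gain <- matrix(exp(rnorm(n_rows * 499, 0, 0.05)), n_rows, 499)
  resp <- 0.7 + 0.6 * exp(-((seq_len(499) / 499 - 0.55) / 0.35)^2)
  cert <- data.frame(
    wavelength_nm = seq(820, 1050, by = 0.5),
    intensity = 0.2 + exp(-((seq(820, 1050, by = 0.5) - 910) / 70)^2)
  )
  glass_sig <- approx(cert$wavelength_nm, cert$intensity,
    xout = axis$wavelength_nm
  )$y
  mkframe <- function(spec_row, role) {
    ccd_frame(gain * matrix(spec_row * resp, n_rows, 499, byrow = TRUE), role)
  }
  white <- mkframe(rep(1200, 499), "white")
  glass <- mkframe(900 * glass_sig, "glass")
  truth <- 100 + 900 * exp(-(axis$shift_cm - 1200)^2 / (2 * 25^2))
  sample <- mkframe(truth, "sample")
  out <- correct_response(sample, white, glass, cert, axis)
  # bundle-level recovery: sum rows, compare shape to truth
  rec <- colSums(out$data)
  sc <- sum(rec * truth) / sum(rec^2)
  expect_lt(
    sqrt(mean((sc * rec - truth)^2)) / sqrt(mean(truth^2)), 0.01
  )
  # two frames differing only by the fixed pattern: after correction the
  # difference is exactly that pattern (the shared steps divide out)
  f1 <- ccd_frame(gain * 77, "sample")
  f2 <- ccd_frame(matrix(77, n_rows, 499), "sample")
  o1 <- correct_response(f1, white, glass, cert, axis)
  o2 <- correct_response(f2, white, glass, cert, axis)
  expect_equal(o1$data, o2$data * gain, tolerance = 1e-10)
  # and the patterned frame comes out flat where the estimate matches
  expect_lt(sd(o1$data / o2$data / gain), 1e-10)
})

test_that("bundle extraction sums disjoint row blocks", {
  axis <- plain_axis(499)
  layout <- small_layout()
  ones <- ccd_frame(matrix(1, 64, 499), "sample")
  out <- extract_bundle_spectra(ones, layout, axis)
  expect_named(out, c("0", "3", "6"))
  expect_true(all(out[["3"]]$intensity == 12))
  expect_true(all(out[["0"]]$intensity == 4))
  expect_true(all(out[["6"]]$intensity == 26))
  # additivity: the three spectra sum to the column sums over their rows
  m <- matrix(runif(64 * 499), 64, 499)
  fr <- ccd_frame(m, "sample")
  ex <- extract_bundle_spectra(fr, layout, axis)
  total <- ex[["0"]]$intensity + ex[["3"]]$intensity + ex[["6"]]$intensity
  expect_equal(total, colSums(m[unlist(layout$rows), ]), tolerance = 1e-12)
  # overlapping bundles rejected
  bad <- layout
  bad$rows[["0"]] <- 20:23
  expect_error(extract_bundle_spectra(fr, bad, axis), "overlap")
})

test_that("the calibration chain inverts the instrument on bundle spectra", {
  # compact end-to-end check on the short detector; the full-size
  # configuration is exercised in the acceptance suite
  det <- small_detector(smile_coeffs = c(0, 0, 6e-4))
  layout <- small_layout()
  calib <- generate_calibration_set(det)
  map <- fit_rectification(calib)
  rect <- lapply(
    calib[c("neon", "acetaminophen", "white", "glass")],
    function(fr) apply_rectification(dark_subtract(fr, calib$dark), map)
  )
  axis <- calibrate_axis(
    rect$neon, calib$neon_lines_visible,
    rect$acetaminophen, calib$acetaminophen_shifts_visible
  )
  sp <- manual_specimen(
    c(1000, 240, 160, 320, 280), c(1000, 300, 260, 420, 360)
  )
  clean <- render_clean_spectrum(sp, 3, true_axis(det))
  frames <- render_frame_stack(clean, sp, det, layout,
    n_frames = 1,
    fluorescence = FALSE
  )
  resp <- sorsbone:::response_model(
    rect$white, rect$glass, calib$glass_certified, axis
  )
  fr <- sorsbone:::apply_response(
    apply_rectification(dark_subtract(frames[[1]], calib$dark), map), resp
  )
  rec <- extract_bundle_spectra(fr, layout, axis)[["3"]]$intensity
  truth <- clean$intensity
  sc <- sum(rec * truth) / sum(rec^2)
  expect_lt(sqrt(mean((sc * rec - truth)^2)) / sqrt(mean(truth^2)), 0.02)
})
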