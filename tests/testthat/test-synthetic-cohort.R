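test_that("default cohort has the study composition and consistent labels", {
  cohort <- generate_cohort(cohort_spec(seed = 1))
  expect_length(cohort, 25)
  tab <- cohort_table(cohort)
  counts <- table(factor(tab$who_class, who_classes()))
  expect_equal(as.integer(counts[who_classes()]), c(8L, 6L, 11L))
  # every label agrees with the WHO classification of its own T-score
  expect_equal(as.character(classify_who(tab$tscore)), tab$who_class)
  # all band amplitudes strictly positive
  for (sp in cohort) expect_true(all(sp$layer_amplitudes > 0))
})

test_that("a fixed seed reproduces cohorts and frames bit for bit", {
  expect_identical(
    generate_cohort(cohort_spec(seed = 42)),
    generate_cohort(cohort_spec(seed = 42))
  )
  det <- detector_spec(n_rows = 64, noise_sigma = 2, cosmic_rate = 3)
  sp <- generate_cohort(cohort_spec(seed = 3))[[1]]
  s3 <- render_clean_spectrum(sp, 3, true_axis(det))
  f1 <- render_frame_stack(s3, sp, det, small_layout(), n_frames = 2, seed = 7)
  f2 <- render_frame_stack(s3, sp, det, small_layout(), n_frames = 2, seed = 7)
  expect_identical(f1, f2)
  expect_identical(attr(f1, "spikes"), attr(f2, "spikes"))
})

test_that("zero noise and zero link give identical amplitudes everywhere", {
  b0 <- bone_bands()
  b0$link_slope <- 0
  cohort <- generate_cohort(cohort_spec(
    bands = b0, residual_sd = 0, matrix_sd = 0, seed = 2
  ))
  amps <- lapply(cohort, `[[`, "layer_amplitudes")
  for (a in amps[-1]) expect_equal(a, amps[[1]])
  expect_equal(unname(amps[[1]][, "surface"]), b0$base_amplitude)
})

test_that("truncated T-score sampler matches the closed-form truncated mean", {
  n <- 1000
  cohort <- generate_cohort(cohort_spec(
    n_per_class = c(osteoporosis = n), seed = 11
  ))
  t <- cohort_table(cohort)$tscore
  expect_true(all(t <= -2.5))
  # E[X | X <= b] for X ~ N(mu, sd), b = -2.5 (one-sided truncation)
  mu <- -4.19
  s <- 0.90
  alpha <- (-2.5 - mu) / s
  m_trunc <- mu - s * stats::dnorm(alpha) / stats::pnorm(alpha)
  se <- sd(t) / sqrt(n)
  expect_lt(abs(mean(t) - m_trunc), 3 * se)
  # and the configured (untruncated) mean also lies within the band
  expect_lt(abs(mean(t) - mu), 3 * se + abs(m_trunc - mu))
})

test_that("layer mixing follows the stated blend and conserves weight", {
  axis <- plain_axis()
  bands <- bone_bands()
  sp <- manual_specimen(
    amp_surface = c(1000, 200, 100, 300, 250),
    amp_subcortical = c(1000, 400, 500, 600, 450)
  )
  w <- c("0" = 0.2, "3" = 0.5, "6" = 0.6)
  for (off in c(0, 3, 6)) {
    got <- render_clean_spectrum(sp, off, axis, bands, weights = w)
    blend <- (1 - w[[as.character(off)]]) * sp$layer_amplitudes[, "surface"] +
      w[[as.character(off)]] * sp$layer_amplitudes[, "subcortical"]
    expected <- rep(0, axis$n)
    for (b in seq_len(nrow(bands))) {
      expected <- expected + blend[b] *
        exp(-(axis$shift_cm - bands$center[b])^2 /
          (2 * (bands$fwhm[b] / (2 * sqrt(2 * log(2))))^2))
    }
    expect_equal(got$intensity, expected, tolerance = 1e-12)
  }
  # equal layers: spectrum independent of offset
  sp_eq <- manual_specimen(rep(500, 5), rep(500, 5))
  s0 <- render_clean_spectrum(sp_eq, 0, axis, bands, weights = w)
  s6 <- render_clean_spectrum(sp_eq, 6, axis, bands, weights = w)
  expect_equal(s0$intensity, s6$intensity, tolerance = 1e-12)
  # single unit band: maximum 1.0 at the band center (on-grid axis)
  axis_grid <- plain_axis(n = 511, from = 800, to = 1820) # 960 on the grid
  sp_one <- manual_specimen(c(1, 0, 0, 0, 0), c(1, 0, 0, 0, 0))
  s1 <- render_clean_spectrum(sp_one, 3, axis_grid, bands, weights = w)
  expect_equal(max(s1$intensity), 1, tolerance = 1e-12)
  expect_equal(axis_grid$shift_cm[which.max(s1$intensity)], 960)
  expect_error(render_clean_spectrum(sp, 2, axis, bands, weights = w),
    "unknown offset"
  )
})

test_that("mineral-to-matrix ratios fall monotonically with T-score", {
  # noise-free link: only the T-score drives amplitudes
  spec <- cohort_spec(residual_sd = 0, matrix_sd = 0, axis_jitter_sd = 0)
  axis <- plain_axis()
  tscores <- c(0.5, -1.5, -3, -4.5)
  ratios <- lapply(tscores, function(t) {
    amp <- sapply(c(spec$surface_link, 1), function(k) {
      spec$bands$base_amplitude * (1 + k * spec$bands$link_slope * (0 - t))
    })
    colnames(amp) <- c("surface", "subcortical")
    sp <- manual_specimen(amp[, 1], amp[, 2], tscore = t)
    compute_ratio_set(render_clean_spectrum(sp, 3, axis,
      weights = spec$subsurface_weights
    ))
  })
  for (col in c("PO4_CO3", "PO4_AmideIII", "PO4_CH2", "PO4_AmideI")) {
    v <- vapply(ratios, `[[`, 0, col)
    expect_true(all(diff(v) < 0)) # lower T => lower mineral-to-matrix
  }
})

test_that("rendered frames reproduce the smile shift law and the spectrum", {
  det <- small_detector(smile_coeffs = c(0, 0, 3e-4), gain_sd = 0, dark_level = 0)
  axis <- true_axis(det)
  sp <- manual_specimen(
    c(1000, 0, 0, 0, 0), c(1000, 0, 0, 0, 0),
    fluor = c(0, 0, 0, 0)
  )
  layout <- small_layout()
  s3 <- render_clean_spectrum(sp, 3, axis)
  frames <- render_frame_stack(s3, sp, det, layout,
    n_frames = 1,
    fluorescence = FALSE
  )
  d <- frames[[1]]$data
  rows <- layout$rows[["3"]]
  cent <- vapply(rows, function(r) {
    p <- which.max(d[r, ])
    sorsbone:::centroid_in_window(d[r, ], p, 5)
  }, 0)
  # peak drifts by -c2 r^2 columns relative to row 0 geometry
  drift_expected <- -det$smile_coeffs[3] * (rows - 1)^2
  drift_measured <- cent - (cent[1] - drift_expected[1])
  expect_lt(max(abs(drift_measured - drift_expected)), 0.1)

  # identity instrument: summed bundle rows reproduce the spectrum
  det_id <- small_detector(
    smile_coeffs = c(0, 0, 0), gain_sd = 0,
    dark_level = 0
  )
  det_id$broadband_response[] <- 1
  frames_id <- render_frame_stack(s3, sp, det_id, layout,
    n_frames = 1,
    fluorescence = FALSE
  )
  rec <- colSums(frames_id[[1]]$data[rows, ])
  keep <- sorsbone:::default_crop_start(det_id) + seq_len(det_id$crop_length) - 1
  expect_equal(rec[keep], s3$intensity, tolerance = 1e-10)
})

test_that("calibration set carries full ground truth and a recoverable gain", {
  det <- quiet_detector()
  calib <- generate_calibration_set(det)
  expect_length(calib$neon_lines_nm, 15)
  expect_length(calib$acetaminophen_shifts_cm, 13)
  expect_true(all(calib$neon_lines_visible %in% calib$neon_lines_nm))
  # white frame / its smooth component recovers the fixed-pattern gain
  white <- dark_subtract(calib$white, calib$dark)$data
  pat <- t(apply(white, 1, function(row) row / runmed(row, 31, endrule = "median")))
  err <- pat / det$gain_map - 1
  expect_lt(sqrt(mean(err^2)), 0.03)
  expect_gt(cor(as.vector(pat), as.vector(det$gain_map)), 0.9)
})
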