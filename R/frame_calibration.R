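#' Subtract a dark frame
#'
#' @param frame,dark `ccd_frame` objects of identical shape; `dark` must
#'   have role `dark`.
#' @return The dark-subtracted `ccd_frame` (role preserved). Values may
#'   be negative; clipping happens later in the pipeline.
#' @export
dark_subtract <- function(frame, dark) {
  if (!identical(dim(frame$data), dim(dark$data))) {
    stop("frame and dark shapes differ", call. = FALSE)
  }
  if (dark$role != "dark") {
    stop("`dark` must have role 'dark'", call. = FALSE)
  }
  frame$data <- frame$data - dark$data
  frame
}

# Local maxima of y above min_frac * max(y), greedily thinned to a
# minimum separation (px), returned in column order.
find_peaks <- function(y, min_frac = 0.05, min_sep = 8) {
  n <- length(y)
  thr <- min_frac * max(y)
  cand <- which(y > thr &
    y >= c(-Inf, y[-n]) &
    y >= c(y[-1], -Inf))
  if (!length(cand)) return(integer())
  cand <- cand[order(y[cand], decreasing = TRUE)]
  keep <- integer()
  for (p in cand) {
    if (!length(keep) || all(abs(keep - p) >= min_sep)) keep <- c(keep, p)
  }
  sort(keep)
}

# Intensity-weighted centroid (fractional column) in a window of
# half-width `half` around `center`, with the window minimum subtracted.
# The window is recentered on the running centroid (`iterate` passes) so
# that shifted peaks are not truncated asymmetrically.
centroid_in_window <- function(y, center, half = 5, iterate = 3) {
  est <- center
  for (k in seq_len(iterate)) {
    idx <- max(1, round(est) - half):min(length(y), round(est) + half)
    w <- y[idx] - min(y[idx])
    s <- sum(w)
    if (s <= 0) return(NA_real_)
    est <- sum(idx * w) / s
  }
  est
}

#' Fit the smile rectification map from calibration frames
#'
#' Computes per-row intensity-weighted centroids of every resolvable
#' neon and acetaminophen calibration peak and fits a single shared
#' second-order polynomial of column drift versus detector row (one
#' curvature for the whole detector, a free intercept per peak). The
#' crop window is chosen so that all shifted columns stay in range and
#' `crop_length` spectral pixels remain.
#'
#' @param calib A `calibration_set` (needs `dark`, `neon`,
#'   `acetaminophen` frames).
#' @param crop_start 1-based first column of the crop window (default:
#'   centered).
#' @param window Centroid window width in pixels (odd; default 11).
#' @param min_peak_frac Minimum peak height, as a fraction of the frame
#'   maximum, for a peak to be used.
#' @return Object of class `rectification_map`: `shift_coef`
#'   `c(b1, b2)` such that the drift at 0-based row `r` is
#'   `b1 r + b2 r^2` (pixels, relative to row 0), per-peak intercepts,
#'   centroid residual sd, crop window and detector shape.
#' @export
fit_rectification <- function(calib, crop_start = NULL, window = 11,
                              min_peak_frac = 0.05) {
  det <- calib$detector
  half <- (window - 1) %/% 2
  frames <- list(
    dark_subtract(calib$neon, calib$dark),
    dark_subtract(calib$acetaminophen, calib$dark)
  )
  obs <- list()
  peak_counter <- 0L
  for (fr in frames) {
    prof <- colMeans(fr$data)
    pks <- find_peaks(prof, min_frac = min_peak_frac)
    for (p in pks) {
      peak_counter <- peak_counter + 1L
      cent <- vapply(
        seq_len(nrow(fr$data)),
        function(r) centroid_in_window(fr$data[r, ], p, half),
        0
      )
      ok <- which(!is.na(cent))
      if (length(ok) < nrow(fr$data)) {
        warning("peak ", peak_counter, ": ", nrow(fr$data) - length(ok),
          " rows excluded (insufficient signal)",
          call. = FALSE
        )
      }
      obs[[peak_counter]] <- data.frame(
        peak = peak_counter, row0 = ok - 1, centroid = cent[ok]
      )
    }
  }
  if (peak_counter < 3) {
    stop("need at least 3 resolvable calibration peaks, found ",
      peak_counter,
      call. = FALSE
    )
  }
  d <- do.call(rbind, obs)
  d$peak <- factor(d$peak)
  fit <- lm(centroid ~ 0 + peak + row0 + I(row0^2), data = d)
  cf <- coef(fit)
  shift_coef <- unname(c(cf[["row0"]], cf[["I(row0^2)"]]))
  if (is.null(crop_start)) crop_start <- default_crop_start(det)
  crop_len <- det$crop_length
  max_drift <- max(abs(polyval(
    c(0, shift_coef),
    c(0, det$n_rows - 1, det$n_rows / 2)
  )))
  if (crop_start - 1 < max_drift ||
    det$n_cols - (crop_start + crop_len - 1) < max_drift) {
    stop("modeled drift exceeds the crop margin", call. = FALSE)
  }
  structure(
    list(
      shift_coef = shift_coef,
      peak_intercepts = unname(cf[grep("^peak", names(cf))]),
      residual_px = sd(stats::residuals(fit)),
      n_peaks = peak_counter,
      crop_start = crop_start, crop_length = crop_len,
      n_cols = det$n_cols, n_rows = det$n_rows,
      centroids = d
    ),
    class = "rectification_map"
  )
}

#' @export
print.rectification_map <- function(x, ...) {
  cat(sprintf(
    "Rectification map: %d peaks, drift = %.3g r + %.3g r^2 px, residual %.3g px, crop [%d, %d]\n",
    x$n_peaks, x$shift_coef[1], x$shift_coef[2], x$residual_px,
    x$crop_start, x$crop_start + x$crop_length - 1
  ))
  invisible(x)
}

#' Rectify and crop a CCD frame
#'
#' Resamples each row by its modeled column drift (linear interpolation)
#' so that spectral features align vertically, then crops to the map's
#' spectral window.
#'
#' @param frame A `ccd_frame` on the same detector geometry as the map.
#' @param map A `rectification_map` from [fit_rectification()].
#' @return The rectified, cropped `ccd_frame`.
#' @export
apply_rectification <- function(frame, map) {
  d <- frame$data
  if (ncol(d) != map$n_cols) {
    stop("frame width does not match the rectification map", call. = FALSE)
  }
  cols <- seq_len(ncol(d))
  keep <- map$crop_start:(map$crop_start + map$crop_length - 1)
  out <- matrix(0, nrow(d), map$crop_length)
  for (r in seq_len(nrow(d))) {
    drift <- polyval(c(0, map$shift_coef), r - 1)
    samp <- approx(cols, d[r, ], xout = cols + drift, rule = 2)$y
    out[r, ] <- samp[keep]
  }
  frame$data <- out
  frame
}

#' Calibrate the Raman-shift axis from neon and acetaminophen frames
#'
#' Fits a second-order pixel-to-wavelength polynomial to the neon line
#' centroids, then solves for the effective laser wavelength by least
#' squares so that the acetaminophen line positions best match their
#' known Raman shifts under `shift = 1e7 (1/lambda0 - 1/lambda)`.
#'
#' @param neon,acet Rectified, dark-subtracted `ccd_frame`s.
#' @param neon_lines_nm Known wavelengths (nm) of the neon lines visible
#'   inside the cropped window, in increasing order.
#' @param acet_shifts_cm Known Raman shifts (cm^-1) of the acetaminophen
#'   lines visible inside the cropped window, in increasing order.
#' @param window Centroid window width in pixels (default 11).
#' @return A `wavenumber_axis` over the cropped pixels, carrying the
#'   fitted wavelength polynomial, the solved `lambda0_nm` and the rms
#'   acetaminophen shift residual (`residual_cm`).
#' @export
calibrate_axis <- function(neon, neon_lines_nm, acet, acet_shifts_cm,
                           window = 11) {
  if (length(neon_lines_nm) < 3) {
    stop("need at least 3 neon lines", call. = FALSE)
  }
  if (length(acet_shifts_cm) < 2) {
    stop("need at least 2 acetaminophen lines", call. = FALSE)
  }
  half <- (window - 1) %/% 2
  # candidate peak centroids of a calibration frame, sorted, edges excluded
  candidates <- function(frame) {
    spec <- colMeans(frame$data)
    pks <- find_peaks(spec, min_frac = 0.02, min_sep = 6)
    pks <- pks[pks > half & pks <= length(spec) - half]
    sort(vapply(pks, function(p) centroid_in_window(spec, p, half), 0))
  }
  # pick the order-preserving subset of `cents` matching `values` that
  # minimizes the rms residual returned by fit_resid(subset)
  match_lines <- function(cents, values, fit_resid, what) {
    m <- length(cents)
    k <- length(values)
    if (m < k) {
      stop("found only ", m, " usable peaks for ", k, " known ", what,
        " lines",
        call. = FALSE
      )
    }
    if (m == k) return(cents)
    combs <- utils::combn(m, k)
    if (ncol(combs) > 20000) {
      stop("too many spurious peaks in the ", what, " frame", call. = FALSE)
    }
    resids <- apply(combs, 2, function(ix) fit_resid(cents[ix]))
    cents[combs[, which.min(resids)]]
  }
  n_px <- ncol(neon$data)
  z_of <- function(px) 2 * (px - 1) / (n_px - 1) - 1

  neon_lines_nm <- sort(neon_lines_nm)
  neon_resid <- function(px) {
    z <- z_of(px)
    sqrt(mean(stats::residuals(lm(neon_lines_nm ~ z + I(z^2)))^2))
  }
  neon_px <- match_lines(
    candidates(neon), neon_lines_nm, neon_resid, "neon"
  )
  zf <- z_of(neon_px)
  wfit <- lm(neon_lines_nm ~ zf + I(zf^2))
  wl_coefs <- unname(coef(wfit))

  z_all <- z_of(seq_len(n_px))
  lambda <- polyval(wl_coefs, z_all)
  if (any(diff(lambda) <= 0)) {
    stop("fitted pixel-wavelength map is not monotone", call. = FALSE)
  }

  shifts <- sort(acet_shifts_cm)
  # shift_k = 1e7/lambda0 - 1e7/lambda_k, linear in 1/lambda0
  solve_l0 <- function(lam) 1 / mean(shifts * 1e-7 + 1 / lam)
  acet_resid <- function(px) {
    lam <- polyval(wl_coefs, z_of(px))
    sqrt(mean((raman_shift_cm(lam, solve_l0(lam)) - shifts)^2))
  }
  acet_px <- match_lines(
    candidates(acet), shifts, acet_resid, "acetaminophen"
  )
  acet_lambda <- polyval(wl_coefs, z_of(acet_px))
  lambda0 <- solve_l0(acet_lambda)
  resid <- raman_shift_cm(acet_lambda, lambda0) - shifts

  new_wavenumber_axis(
    shift_cm = raman_shift_cm(lambda, lambda0),
    wavelength_nm = lambda,
    lambda0_nm = lambda0,
    wl_coefs = wl_coefs,
    residual_cm = sqrt(mean(resid^2))
  )
}

# Precompute the two response corrections: the high-frequency
# fixed-pattern from the white frame (per pixel) and the broadband
# spectral response from the glass standard (per column, unit mean).
response_model <- function(white, glass, glass_certified, axis,
                           pattern_width = 31) {
  pat <- t(apply(white$data, 1, function(row) {
    lp <- runmed(row, pattern_width, endrule = "median")
    p <- row / lp
    p[!is.finite(p) | lp <= .Machine$double.eps^0.5] <- 1
    p
  }))
  n_masked <- sum(pat == 1 & white$data <= 0)
  if (n_masked > 0) {
    warning(n_masked, " near-zero white-lamp pixels masked", call. = FALSE)
  }
  gspec <- colMeans(glass$data / pat)
  cert <- approx(glass_certified$wavelength_nm, glass_certified$intensity,
    xout = axis$wavelength_nm, rule = 2
  )$y
  resp <- runmed(gspec / cert, pattern_width, endrule = "median")
  resp <- pmax(resp, .Machine$double.eps)
  resp <- resp / mean(resp)
  list(pattern = pat, broadband = resp)
}

apply_response <- function(frame, model) {
  frame$data <- sweep(frame$data / model$pattern, 2, model$broadband, "/")
  frame
}

#' Correct detector response using white-lamp and glass standards
#'
#' Two-step normalization of detector quantum efficiency and fiber
#' throughput: (i) division by the high-frequency fixed pattern of the
#' broadband white-lamp frame (the frame divided by its moving-median
#' low-pass); (ii) division by the broadband spectral response, estimated
#' as the smoothed ratio of the measured glass-standard fluorescence to
#' its certified emission curve, normalized to unit mean.
#'
#' @param frame Frame to correct (dark-subtracted, rectified).
#' @param white,glass Dark-subtracted, rectified standard frames.
#' @param glass_certified Data frame `wavelength_nm`, `intensity`: the
#'   certified emission curve of the glass standard.
#' @param axis The `wavenumber_axis` of the rectified frames (supplies
#'   the wavelength of each column).
#' @param pattern_width Moving-median width (px) separating the fixed
#'   pattern from the smooth lamp shape (default 31).
#' @return The corrected `ccd_frame`.
#' @export
correct_response <- function(frame, white, glass, glass_certified, axis,
                             pattern_width = 31) {
  model <- response_model(white, glass, glass_certified, axis, pattern_width)
  apply_response(frame, model)
}

#' Sum bundle rows into per-offset spectra
#'
#' @param frame A rectified, response-corrected `ccd_frame`.
#' @param layout A [bundle_layout()]; row ranges must be disjoint.
#' @param axis The frame's `wavenumber_axis`.
#' @return Named list of `bundle_spectrum` objects, one per offset.
#' @export
extract_bundle_spectra <- function(frame, layout, axis) {
  if (ncol(frame$data) != axis$n) {
    stop("frame width does not match the axis", call. = FALSE)
  }
  if (anyDuplicated(unlist(layout$rows))) {
    stop("bundle row ranges overlap", call. = FALSE)
  }
  out <- lapply(names(layout$rows), function(key) {
    rows <- layout$rows[[key]]
    if (max(rows) > nrow(frame$data)) {
      stop("bundle rows exceed frame height", call. = FALSE)
    }
    new_bundle_spectrum(
      axis$shift_cm, colSums(frame$data[rows, , drop = FALSE]),
      as.numeric(key),
      meta = list(accumulation = frame$accumulation)
    )
  })
  names(out) <- names(layout$rows)
  out
}
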