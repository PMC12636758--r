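#' Construct a replicate frame stack
#'
#' Bundles K replicate spectra of one specimen/offset (already extracted
#' onto a shared axis) for cosmic-ray rejection and averaging.
#'
#' @param spectra List of `bundle_spectrum` objects of equal length and
#'   offset, or a K x n numeric matrix.
#' @param shift_cm Raman-shift axis (required when `spectra` is a
#'   matrix).
#' @param offset_mm Collection offset (required when `spectra` is a
#'   matrix).
#' @param meta Optional provenance list.
#' @return Object of class `frame_stack` with fields `intensity`
#'   (K x n), `shift_cm`, `offset_mm`, `mask` (NULL until
#'   [reject_cosmic_rays()] has run).
#' @export
frame_stack <- function(spectra, shift_cm = NULL, offset_mm = NULL,
                        meta = list()) {
  if (is.matrix(spectra)) {
    if (is.null(shift_cm) || is.null(offset_mm)) {
      stop("matrix input needs `shift_cm` and `offset_mm`", call. = FALSE)
    }
    intensity <- spectra
  } else {
    lens <- vapply(spectra, function(s) length(s$intensity), 0L)
    offs <- vapply(spectra, `[[`, 0, "offset_mm")
    if (length(unique(lens)) != 1 || length(unique(offs)) != 1) {
      stop("replicate spectra must share length and offset", call. = FALSE)
    }
    intensity <- do.call(rbind, lapply(spectra, `[[`, "intensity"))
    shift_cm <- spectra[[1]]$shift_cm
    offset_mm <- offs[1]
  }
  if (nrow(intensity) < 2) {
    stop("a frame stack needs at least 2 replicates", call. = FALSE)
  }
  structure(
    list(
      intensity = intensity, shift_cm = shift_cm,
      offset_mm = offset_mm, mask = NULL, meta = meta
    ),
    class = "frame_stack"
  )
}

#' Cosmic-ray rejection configuration
#'
#' @param k_mad Threshold multiplier (default 10).
#' @param n_lowest Size of the per-pixel reference subset: the lowest
#'   `n_lowest` of the K replicate values (default 4 of 5).
#' @param mad_floor Minimum MAD in counts, guarding against the
#'   zero-MAD degeneracy of a four-sample MAD (default 1 count). At the
#'   default read noise this floor sets a ~10-count detection limit.
#' @return Object of class `cosmic_ray_config`.
#' @export
cosmic_ray_config <- function(k_mad = 10, n_lowest = 4, mad_floor = 1) {
  stopifnot(k_mad > 0, n_lowest >= 2, mad_floor >= 0)
  structure(
    list(k_mad = k_mad, n_lowest = n_lowest, mad_floor = mad_floor),
    class = "cosmic_ray_config"
  )
}

# Row `k` of each column of X sorted within columns (radix order trick;
# no per-column apply).
col_sort <- function(X) {
  matrix(X[order(col(X), X)], nrow = nrow(X))
}

# Unscaled median absolute deviation (no 1.4826 consistency factor).
mad_unscaled <- function(x) median(abs(x - median(x)))

#' Reject cosmic-ray spikes across replicate frames
#'
#' Per pixel, the reference is the mean of the `n_lowest` lowest of the
#' K replicate values; a value is flagged as a cosmic ray if it exceeds
#' that reference by more than `k_mad` times the (unscaled) median
#' absolute deviation of the reference subset, floored at `mad_floor`
#' counts. Flagged values are replaced by the reference mean so that
#' subsequent frame averaging stays balanced.
#'
#' @param stack A [frame_stack()] with K > `n_lowest` replicates.
#' @param cfg A [cosmic_ray_config()].
#' @return The stack with flagged values replaced and `mask` set to the
#'   K x n logical flag matrix.
#' @examples
#' st <- frame_stack(rbind(100, 102, 98, 101, 500),
#'   shift_cm = 1, offset_mm = 3
#' )
#' reject_cosmic_rays(st)$intensity # 500 replaced by 100.25
#' @export
reject_cosmic_rays <- function(stack, cfg = cosmic_ray_config()) {
  X <- stack$intensity
  K <- nrow(X)
  nl <- cfg$n_lowest
  if (K <= nl) {
    stop("need more replicates (K = ", K, ") than `n_lowest` = ", nl,
      call. = FALSE
    )
  }
  Xs <- col_sort(X)
  ref <- Xs[seq_len(nl), , drop = FALSE]
  mu <- colMeans(ref)
  med <- if (nl %% 2) {
    ref[(nl + 1) / 2, ]
  } else {
    (ref[nl / 2, ] + ref[nl / 2 + 1, ]) / 2
  }
  dev <- col_sort(abs(sweep(ref, 2, med)))
  m <- if (nl %% 2) {
    dev[(nl + 1) / 2, ]
  } else {
    (dev[nl / 2, ] + dev[nl / 2 + 1, ]) / 2
  }
  thr <- mu + cfg$k_mad * pmax(m, cfg$mad_floor)
  mask <- sweep(X, 2, thr, ">")
  repl <- matrix(mu, K, ncol(X), byrow = TRUE)
  X[mask] <- repl[mask]
  stack$intensity <- X
  stack$mask <- mask
  stack
}

#' Average a cosmic-filtered frame stack
#'
#' Per-pixel arithmetic mean of the replicates. The stack must have been
#' through [reject_cosmic_rays()] first (the fixed pipeline order
#' reject -> average is enforced, since averaging before rejection would
#' smear spikes into the mean).
#'
#' @param stack A `frame_stack` with a non-NULL `mask`.
#' @return A `bundle_spectrum` of the per-pixel means.
#' @export
average_frames <- function(stack) {
  if (is.null(stack$mask)) {
    stop("run reject_cosmic_rays() before averaging", call. = FALSE)
  }
  new_bundle_spectrum(
    stack$shift_cm, colMeans(stack$intensity), stack$offset_mm,
    meta = c(stack$meta, list(n_frames = nrow(stack$intensity)))
  )
}

#' Fluorescence-removal configuration
#'
#' @param poly_order Polynomial order of the iterative baseline fit
#'   (default 7).
#' @param max_iter Maximum iterations (default 10).
#' @param tol Convergence tolerance: relative L2 change of successive
#'   fitted polynomials (default 5e-4, i.e. 0.05%).
#' @return Object of class `fluorescence_config`.
#' @export
fluorescence_config <- function(poly_order = 7, max_iter = 10, tol = 5e-4) {
  stopifnot(poly_order >= 0, max_iter >= 1, tol > 0)
  structure(
    list(poly_order = poly_order, max_iter = max_iter, tol = tol),
    class = "fluorescence_config"
  )
}

#' Remove fluorescence background by iterative modified polynomial fitting
#'
#' Classic modified-polyfit baseline removal: starting from the spectrum
#' itself, an order-`poly_order` polynomial is fitted (on the axis
#' rescaled to \[-1, 1\] for conditioning) and the working vector is
#' clipped to the pointwise minimum of itself and the fit; iteration
#' stops when the relative L2 change of the fitted polynomial drops
#' below `tol` or after `max_iter` iterations. The final polynomial is
#' subtracted from the input.
#'
#' @param spectrum A `bundle_spectrum`.
#' @param cfg A [fluorescence_config()].
#' @return A `clean_spectrum`: the baseline-subtracted intensity plus
#'   fields `baseline`, `n_iter`, `converged`.
#' @export
remove_fluorescence <- function(spectrum, cfg = fluorescence_config()) {
  y <- spectrum$intensity
  n <- length(y)
  if (n < cfg$poly_order + 1) {
    stop("spectrum shorter than poly_order + 1", call. = FALSE)
  }
  if (any(!is.finite(y))) stop("spectrum must be finite", call. = FALSE)
  u <- unit_scale(spectrum$shift_cm)
  D <- outer(u, 0:cfg$poly_order, "^")
  b <- y
  p_prev <- NULL
  rel_change <- numeric()
  converged <- FALSE
  it <- 0L
  while (it < cfg$max_iter) {
    it <- it + 1L
    p <- drop(D %*% .lm.fit(D, b)$coefficients)
    if (!is.null(p_prev)) {
      rel <- sqrt(sum((p - p_prev)^2)) / sqrt(sum(p_prev^2))
      rel_change <- c(rel_change, rel)
      if (rel < cfg$tol) {
        p_prev <- p
        converged <- TRUE
        break
      }
    }
    p_prev <- p
    b <- pmin(b, p)
  }
  out <- spectrum
  out$intensity <- y - p_prev
  out$baseline <- p_prev
  out$n_iter <- it
  out$rel_change <- rel_change
  out$converged <- converged
  class(out) <- c("clean_spectrum", "bundle_spectrum")
  out
}

#' Estimate the noise floor from a signal-free spectral window
#'
#' Standard deviation of the residual about a local linear trend inside
#' a window free of Raman bands (default 1750-1800 cm^-1).
#'
#' @param spectrum A `bundle_spectrum` or `clean_spectrum`.
#' @param window Shift range (cm^-1) of the signal-free window.
#' @return Estimated sigma_noise in counts.
#' @export
estimate_noise_sd <- function(spectrum, window = c(1750, 1800)) {
  idx <- which(spectrum$shift_cm >= window[1] & spectrum$shift_cm <= window[2])
  if (length(idx) < 5) {
    stop("noise window [", window[1], ", ", window[2],
      "] cm^-1 holds fewer than 5 pixels",
      call. = FALSE
    )
  }
  x <- spectrum$shift_cm[idx]
  y <- spectrum$intensity[idx]
  sd(stats::residuals(lm(y ~ x)))
}

#' Clip intensities below the noise floor
#'
#' Values below `-0.5 * sigma_noise` are saturated at that bound
#' (negative residuals within half a noise sd of zero are physical and
#' stay untouched).
#'
#' @param spectrum A `clean_spectrum` (or `bundle_spectrum`).
#' @param sigma_noise Noise sd in counts; if NULL it is estimated with
#'   [estimate_noise_sd()] over `window`.
#' @param window Signal-free window passed to the estimator.
#' @return The spectrum with clipped values, `sigma_noise`, and a
#'   logical `clip_mask`.
#' @export
clip_to_noise_floor <- function(spectrum, sigma_noise = NULL,
                                window = c(1750, 1800)) {
  if (is.null(sigma_noise)) {
    sigma_noise <- estimate_noise_sd(spectrum, window)
  }
  if (sigma_noise < 0) stop("`sigma_noise` must be >= 0", call. = FALSE)
  floor_val <- -0.5 * sigma_noise
  mask <- spectrum$intensity < floor_val
  spectrum$intensity[mask] <- floor_val
  spectrum$sigma_noise <- sigma_noise
  spectrum$clip_mask <- mask
  if (!inherits(spectrum, "clean_spectrum")) {
    class(spectrum) <- c("clean_spectrum", class(spectrum))
  }
  spectrum
}
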