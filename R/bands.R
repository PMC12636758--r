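#' Diagnostic Raman bands of bone
#'
#' The five bands used for mineral-to-matrix analysis: the phosphate
#' nu1 stretch at 960 cm^-1 (the normalization reference), carbonate
#' substitution at ~1070 cm^-1, and the collagen-associated Amide III,
#' CH2 wag and Amide I bands. Centers other than 960 cm^-1 are the
#' literature-standard positions for bone. The table also carries the
#' parameters the synthetic generator uses for each band: Gaussian full
#' width at half maximum, baseline amplitude at the reference T-score,
#' and the (unitless) slope linking subcortical band amplitude to
#' T-score.
#'
#' @param half_window Half width (cm^-1) of the quantification window
#'   around each band center.
#' @return A data frame with columns `band`, `center`, `fwhm`,
#'   `half_window`, `base_amplitude`, `link_slope`.
#' @examples
#' bone_bands()
#' @export
bone_bands <- function(half_window = 20) {
  data.frame(
    band = c("PO4", "CO3", "AmideIII", "CH2", "AmideI"),
    center = c(960, 1070, 1250, 1450, 1660),
    fwhm = c(12, 18, 22, 20, 25),
    half_window = half_window,
    base_amplitude = c(1000, 250, 180, 350, 300),
    link_slope = c(0, 0.06, 0.12, 0.10, 0.11),
    stringsAsFactors = FALSE
  )
}

# The five diagnostic ratios, as numerator/denominator band pairs.
ratio_definitions <- function() {
  data.frame(
    ratio = c("PO4/CO3", "PO4/AmideIII", "PO4/CH2", "PO4/AmideI", "CO3/AmideIII"),
    num = c("PO4", "PO4", "PO4", "PO4", "CO3"),
    den = c("CO3", "AmideIII", "CH2", "AmideI", "AmideIII"),
    stringsAsFactors = FALSE
  )
}
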